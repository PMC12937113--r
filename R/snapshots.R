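#' Snapshot pipeline: droplets, ensemble statistics, solvatochromic shifts
#'
#' Per-frame excitation energies from MD-style snapshot geometries are
#' assembled into ensemble statistics; droplets are solute-centered spheres
#' of whole solvent molecules cut from each frame.
#'
#' @name snapshot_pipeline
NULL

#' Construct a snapshot
#'
#' @param elements character vector of element labels.
#' @param positions_ang n x 3 coordinates in Angstrom.
#' @param solute_atom_indices indices of the solute atoms.
#' @param solvent_molecules list of integer vectors (disjoint solvent
#'   molecule atom groups).
#' @param frame_id identifier.
#' @return object of class `snapshot`.
#' @export
snapshot <- function(elements, positions_ang, solute_atom_indices,
                     solvent_molecules, frame_id = 1L) {
  if (length(solute_atom_indices) < 1L) stop("solute must be non-empty")
  all_solv <- unlist(solvent_molecules)
  if (anyDuplicated(c(solute_atom_indices, all_solv)))
    stop("solute and solvent groups must be disjoint")
  structure(list(frame_id = frame_id, elements = elements,
                 positions_ang = as.matrix(positions_ang),
                 solute_atom_indices = as.integer(solute_atom_indices),
                 solvent_molecules = lapply(solvent_molecules, as.integer)),
            class = "snapshot")
}

#' Extract a solute-centered droplet
#'
#' Retains the full solute and every solvent molecule with at least one atom
#' within `radius` (Angstrom) of the nearest solute atom; molecules are kept
#' whole, never fragmented. An alternative center-of-mass membership rule is
#' available via `rule = "com"` (distance of the molecule's unweighted
#' centroid to the nearest solute atom).
#'
#' @param snap a `snapshot`.
#' @param radius droplet radius in Angstrom.
#' @param rule "any_atom" (default) or "com".
#' @return a `snapshot` containing the retained atoms (indices remapped).
#' @export
extract_droplet <- function(snap, radius, rule = c("any_atom", "com")) {
  rule <- match.arg(rule)
  if (radius <= 0) stop("radius must be positive")
  pos <- snap$positions_ang
  solute_pos <- pos[snap$solute_atom_indices, , drop = FALSE]
  keep_mol <- vapply(snap$solvent_molecules, function(idx) {
    mp <- pos[idx, , drop = FALSE]
    if (rule == "com") mp <- matrix(colMeans(mp), 1L)
    dmin <- min(vapply(seq_len(nrow(mp)), function(i)
      min(sqrt(rowSums(sweep(solute_pos, 2L, mp[i, ])^2))), numeric(1)))
    dmin <= radius
  }, logical(1))
  if (!any(keep_mol))
    message("droplet contains no solvent molecules beyond the solute")
  kept <- snap$solvent_molecules[keep_mol]
  sel <- c(snap$solute_atom_indices, unlist(kept))
  new_index <- stats::setNames(seq_along(sel), sel)
  snapshot(snap$elements[sel], pos[sel, , drop = FALSE],
           solute_atom_indices = as.integer(new_index[as.character(snap$solute_atom_indices)]),
           solvent_molecules = lapply(kept, function(idx)
             as.integer(new_index[as.character(idx)])),
           frame_id = snap$frame_id)
}

#' Ensemble statistics of per-frame excitation energies
#'
#' @param energies numeric vector (eV), n >= 1.
#' @param bin_width histogram bin width for the mode estimate (eV).
#' @return object of class `ensemble_result` with `per_frame_energies`,
#'   `mean`, `median`, `mode`, `standard_error` (sample sd / sqrt(n)),
#'   `spread` (max - min) and `n`.
#' @export
ensemble_statistics <- function(energies, bin_width = 0.05) {
  if (length(energies) < 1L) stop("need at least one energy")
  if (any(!is.finite(energies))) stop("non-finite excitation energy")
  n <- length(energies)
  # histogram mode: center of the most populated bin, lowest bin on ties
  lo <- floor(min(energies) / bin_width) * bin_width
  bins <- pmin(floor((energies - lo) / bin_width),
               ceiling((max(energies) - lo) / bin_width))
  counts <- table(bins)
  top <- as.integer(names(counts)[which.max(counts)])
  mode_est <- lo + (top + 0.5) * bin_width
  se <- if (n > 1L) stats::sd(energies) / sqrt(n) else 0
  structure(list(per_frame_energies = energies, mean = mean(energies),
                 median = stats::median(energies), mode = mode_est,
                 standard_error = se,
                 spread = max(energies) - min(energies), n = n),
            class = "ensemble_result")
}

#' Running-mean convergence check over snapshot counts
#'
#' @param energies per-frame energies in acquisition order (eV).
#' @param checkpoints snapshot counts at which to report running means.
#' @param threshold convergence threshold on successive checkpoint means (eV).
#' @return list with `checkpoints`, `means`, `converged`.
#' @export
convergence_check <- function(energies, checkpoints = c(50, 100, 150, 200),
                              threshold = 0.02) {
  n <- length(energies)
  if (n < max(checkpoints)) {
    warning("fewer frames than the last checkpoint; truncating checkpoints")
    checkpoints <- unique(pmin(checkpoints, n))
  }
  means <- vapply(checkpoints, function(k) mean(energies[seq_len(k)]),
                  numeric(1))
  converged <- length(means) >= 2L &&
    all(abs(diff(means)) < threshold)
  list(checkpoints = checkpoints, means = means, converged = converged)
}

#' Solvatochromic shift
#'
#' shift = mean excitation energy in solution minus the gas-phase reference;
#' positive values are blue shifts (solution above gas phase).
#'
#' @param mean_solution solution-phase mean excitation energy (eV).
#' @param gas_reference gas-phase excitation energy (eV).
#' @return shift in eV.
#' @export
solvatochromic_shift <- function(mean_solution, gas_reference) {
  if (!is.finite(mean_solution) || !is.finite(gas_reference))
    stop("inputs must be finite")
  mean_solution - gas_reference
}

#' Read snapshots from a multi-frame XYZ file plus grouping sidecar
#'
#' The sidecar (YAML) declares `solute_atoms: [..]` (1-based indices) and
#' either `solvent_molecule_size: k` (fixed-size blocks over the remaining
#' atoms) or an explicit `solvent_molecules:` list.
#'
#' @param xyz_path multi-frame XYZ file.
#' @param grouping_path YAML sidecar.
#' @return list of `snapshot` objects.
#' @export
read_snapshots <- function(xyz_path, grouping_path) {
  frames <- read_xyz_frames(xyz_path)
  grp <- yaml::read_yaml(grouping_path)
  solute <- as.integer(grp$solute_atoms)
  lapply(seq_along(frames), function(i) {
    fr <- frames[[i]]
    n <- length(fr$elements)
    if (!is.null(grp$solvent_molecules)) {
      solvent <- lapply(grp$solvent_molecules, as.integer)
    } else {
      rest <- setdiff(seq_len(n), solute)
      k <- as.integer(grp$solvent_molecule_size)
      if (length(rest) %% k != 0L)
        stop("solvent atom count not divisible by solvent_molecule_size")
      solvent <- split(rest, ceiling(seq_along(rest) / k))
    }
    snapshot(fr$elements, fr$positions_ang, solute, solvent, frame_id = i)
  })
}

#' Per-frame excitation energies through the coupled solver
#'
#' Runs ground- and excited-state DMRG/FQ calculations on each snapshot's
#' droplet and returns the vertical gaps. Frames are independent jobs;
#' results do not depend on processing order.
#'
#' @param snaps list of `snapshot`s.
#' @param qm_elements,qm_basis QM-region element labels (the solute atoms of
#'   each frame must match) and basis name.
#' @param fq_params FQ parameter set ([read_fq_params()] shape).
#' @param config configuration from [dmrgfq_config()] (state field ignored).
#' @param radius droplet radius (Angstrom); NULL to use frames as-is.
#' @param solvent_molecule_size atoms per solvent molecule for FQ grouping.
#' @return data.frame with frame, gap_ev, e_gs, e_es.
#' @export
snapshot_excitations <- function(snaps, qm_elements, qm_basis = "sto3g.s",
                                 fq_params, config, radius = NULL,
                                 solvent_molecule_size = NULL) {
  rows <- lapply(snaps, function(snap) {
    if (!is.null(radius)) snap <- extract_droplet(snap, radius)
    sol_idx <- snap$solute_atom_indices
    qm <- list(elements = snap$elements[sol_idx],
               positions_ang = snap$positions_ang[sol_idx, , drop = FALSE],
               basis = qm_basis)
    fq <- NULL
    solv_idx <- unlist(snap$solvent_molecules)
    if (length(solv_idx) > 0L) {
      groups <- lapply(snap$solvent_molecules, function(idx)
        fq_group(match(idx, solv_idx), 0))
      fq <- fq_system(
        fq_atoms_from_params(snap$elements[solv_idx],
                             snap$positions_ang[solv_idx, , drop = FALSE],
                             fq_params), groups)
    }
    cfg_gs <- config; cfg_gs$state <- "gs"
    cfg_es <- config; cfg_es$state <- "es"
    gs <- run_dmrgscf_fq(qm, fq, cfg_gs)
    es <- run_dmrgscf_fq(qm, fq, cfg_es, orbitals = gs$orbitals)
    data.frame(frame = snap$frame_id,
               gap_ev = excitation_energy(gs, es),
               e_gs = gs$energy_total, e_es = es$energy_total)
  })
  do.call(rbind, rows)
}

fq_atoms_from_params <- function(elements, positions_ang, params) {
  tab <- params$parameters
  row <- match(elements, tab$element)
  if (any(is.na(row)))
    stop("missing FQ parameters for element(s): ",
         paste(unique(elements[is.na(row)]), collapse = ", "))
  fq_atoms(positions_ang * ANGSTROM_TO_BOHR, tab$chi[row], tab$eta[row],
           elements)
}
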