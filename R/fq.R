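#' Fluctuating-charge (FQ) force field
#'
#' The FQ model assigns each classical atom a charge that responds to its
#' surroundings. The energy is a second-order expansion in the charges,
#'
#'   E_FQ(q) = sum_i q_i chi_i + 1/2 q^T T q,
#'
#' where chi is the atomic electronegativity and T the charge-charge
#' interaction kernel whose diagonal is the chemical hardness eta. Charges are
#' obtained by electronegativity equalization: stationarity of the Lagrangian
#' with per-molecule total-charge constraints sum_{i in alpha} q_i = Q_alpha,
#' i.e. a bordered symmetric linear system. An external potential V (e.g. the
#' electrostatic potential of a QM region) enters as an additional linear
#' source term, polarizing the charges.
#'
#' @name fq_model
NULL

#' Construct an FQ atom set
#'
#' @param positions numeric matrix, n x 3, positions in Bohr.
#' @param chi numeric vector of electronegativities (Hartree / charge).
#' @param eta numeric vector of chemical hardnesses (Hartree / charge^2),
#'   all strictly positive.
#' @param elements character vector of element labels.
#' @return object of class `fq_atoms`.
#' @export
fq_atoms <- function(positions, chi, eta, elements = NULL) {
  positions <- as.matrix(positions)
  if (ncol(positions) != 3L) stop("positions must be an n x 3 matrix")
  n <- nrow(positions)
  if (n < 1L) stop("at least one atom required")
  if (length(chi) != n || length(eta) != n)
    stop("chi and eta must have one entry per atom")
  if (!all(is.finite(positions))) stop("non-finite atomic position")
  if (any(!is.finite(eta)) || any(eta <= 0))
    stop("chemical hardness eta must be positive and finite")
  if (is.null(elements)) elements <- rep("X", n)
  structure(list(positions = positions, chi = as.numeric(chi),
                 eta = as.numeric(eta), elements = as.character(elements)),
            class = "fq_atoms")
}

#' Build the Ohno interaction kernel
#'
#' Diagonal entries are the atomic hardnesses eta_i. Off-diagonal entries use
#' the Ohno form T_ij = eta_ij / sqrt(1 + eta_ij^2 r_ij^2) with
#' eta_ij = (eta_i + eta_j)/2 and r_ij in Bohr, which interpolates smoothly
#' between the hardness mean at r -> 0 and the bare Coulomb 1/r at large r,
#' avoiding the polarization catastrophe of an undamped 1/r at short range.
#' The Ohno form is applied to all pairs, intra- and inter-molecular alike.
#'
#' @param atoms an `fq_atoms` object.
#' @param groups optional list of `fq_group`s; used only to reject coincident
#'   atoms that belong to different molecules.
#' @return symmetric n x n matrix (Hartree / charge^2).
#' @export
build_ohno_kernel <- function(atoms, groups = NULL) {
  stopifnot(inherits(atoms, "fq_atoms"))
  n <- nrow(atoms$positions)
  eta <- atoms$eta
  d2 <- as.matrix(stats::dist(atoms$positions))^2
  if (n > 1L) {
    coincident <- which(d2 < 1e-20 & upper.tri(d2), arr.ind = TRUE)
    if (nrow(coincident) > 0L) {
      # coincident atoms make the bordered system singular
      same_group <- FALSE
      if (!is.null(groups)) {
        gid <- group_index_of(groups, n)
        same_group <- all(gid[coincident[, 1L]] == gid[coincident[, 2L]])
      }
      stop(sprintf("coincident FQ atoms (singular geometry): pairs %s",
                   paste(apply(coincident, 1L, paste, collapse = "/"),
                         collapse = ", ")))
    }
  }
  ebar <- outer(eta, eta, `+`) / 2
  kern <- ebar / sqrt(1 + ebar^2 * d2)
  diag(kern) <- eta
  dimnames(kern) <- NULL
  (kern + t(kern)) / 2
}

#' Define a molecule group with a total-charge constraint
#'
#' @param atom_indices integer indices of the member atoms.
#' @param total_charge constrained total charge Q (elementary charges).
#' @return object of class `fq_group`.
#' @export
fq_group <- function(atom_indices, total_charge = 0) {
  atom_indices <- as.integer(atom_indices)
  if (length(atom_indices) < 1L) stop("group must contain at least one atom")
  structure(list(atom_indices = atom_indices,
                 total_charge = as.numeric(total_charge)),
            class = "fq_group")
}

group_index_of <- function(groups, n_atoms) {
  gid <- rep(NA_integer_, n_atoms)
  for (g in seq_along(groups)) {
    idx <- groups[[g]]$atom_indices
    if (any(idx < 1L | idx > n_atoms)) stop("group atom index out of range")
    if (any(!is.na(gid[idx]))) stop("groups must be disjoint")
    gid[idx] <- g
  }
  if (any(is.na(gid))) stop("groups must cover every atom")
  gid
}

#' Assemble an FQ system
#'
#' @param atoms an `fq_atoms` object.
#' @param groups list of `fq_group`s, disjoint and covering all atoms.
#' @return object of class `fq_system` with the Ohno kernel built.
#' @export
fq_system <- function(atoms, groups) {
  stopifnot(inherits(atoms, "fq_atoms"))
  if (inherits(groups, "fq_group")) groups <- list(groups)
  n <- nrow(atoms$positions)
  gid <- group_index_of(groups, n)
  kernel <- build_ohno_kernel(atoms, groups)
  structure(list(atoms = atoms, groups = groups, group_index = gid,
                 kernel = kernel, charges = NULL, multipliers = NULL),
            class = "fq_system")
}

#' Solve the constrained electronegativity-equalization system
#'
#' Solves the bordered symmetric linear system
#'
#'   [ T  C ] [ q      ]   [ -chi - V ]
#'   [ C' 0 ] [ lambda ] = [  Q       ]
#'
#' where C is the group-membership indicator matrix. The solution is the
#' unique stationary point of E_FQ(q) + q.V under the group-charge
#' constraints. With a nonzero V the charges are polarized by the external
#' potential.
#'
#' @param system an `fq_system`.
#' @param external_potential per-atom potential vector (Hartree / charge), or
#'   NULL / 0 for the unpolarized solve.
#' @return the system with `charges` and `multipliers` filled in.
#' @export
solve_fq <- function(system, external_potential = NULL) {
  stopifnot(inherits(system, "fq_system"))
  n <- nrow(system$atoms$positions)
  ng <- length(system$groups)
  v <- external_potential
  if (is.null(v)) v <- numeric(n)
  if (length(v) == 1L) v <- rep(v, n)
  if (length(v) != n) stop("external potential length must equal atom count")
  C <- matrix(0, n, ng)
  for (g in seq_len(ng)) C[system$groups[[g]]$atom_indices, g] <- 1
  A <- rbind(cbind(system$kernel, C), cbind(t(C), matrix(0, ng, ng)))
  rhs <- c(-system$atoms$chi - v,
           vapply(system$groups, function(g) g$total_charge, numeric(1)))
  sol <- tryCatch(solve(A, rhs), error = function(e) {
    # identify near-dependent rows to make the failure actionable
    qrA <- qr(A)
    bad <- if (qrA$rank < nrow(A)) qrA$pivot[seq(qrA$rank + 1L, nrow(A))]
           else integer(0)
    stop(sprintf(
      "singular bordered FQ system (rank %d of %d); offending rows: %s",
      qrA$rank, nrow(A), paste(bad, collapse = ", ")), call. = FALSE)
  })
  q <- unname(sol[seq_len(n)])
  lambda <- unname(sol[n + seq_len(ng)])
  resid <- abs(as.numeric(t(C) %*% q) -
               vapply(system$groups, function(g) g$total_charge, numeric(1)))
  if (any(resid > 1e-10))
    stop("group-charge constraint violated after solve")
  system$charges <- q
  system$multipliers <- lambda
  system
}

#' FQ energy of a charge configuration
#'
#' Returns sum(q * chi) + 0.5 * q' T q; with `external_potential` given, the
#' interaction term sum(q * V) is added (the Lagrange term vanishes for any
#' feasible q).
#'
#' @param charges charge vector.
#' @param chi electronegativity vector.
#' @param kernel interaction kernel matrix.
#' @param external_potential optional per-atom potential.
#' @return energy in Hartree.
#' @export
fq_energy <- function(charges, chi, kernel, external_potential = NULL) {
  n <- length(charges)
  if (length(chi) != n || !all(dim(kernel) == c(n, n)))
    stop("dimension mismatch between charges, chi and kernel")
  e <- sum(charges * chi) + 0.5 * sum(charges * (kernel %*% charges))
  if (!is.null(external_potential)) {
    if (length(external_potential) != n) stop("dimension mismatch for potential")
    e <- e + sum(charges * external_potential)
  }
  e
}

#' Read an FQ parameter file
#'
#' YAML file mapping a parameterization name and element labels to
#' (chi, eta) in Hartree-based atomic units, e.g.
#' `name: fq_custom` / `parameters:` / `  O: {chi: 0.4, eta: 0.6}`.
#'
#' @param path file path.
#' @return list with `name` and a data.frame `parameters`
#'   (element, chi, eta).
#' @export
read_fq_params <- function(path) {
  doc <- yaml::read_yaml(path)
  if (is.null(doc$parameters)) stop("FQ parameter file lacks 'parameters'")
  pars <- doc$parameters
  df <- data.frame(element = names(pars),
                   chi = vapply(pars, function(p) as.numeric(p$chi), 1),
                   eta = vapply(pars, function(p) as.numeric(p$eta), 1),
                   stringsAsFactors = FALSE)
  if (any(df$eta <= 0)) stop("eta must be positive for every element")
  list(name = doc$name %||% "custom", parameters = df)
}

#' Build an FQ system from a geometry and a parameter set
#'
#' @param elements character vector of element labels.
#' @param positions_ang n x 3 matrix in Angstrom.
#' @param params parameter list from [read_fq_params()] (or same shape).
#' @param molecule_size atoms per molecule for fixed-size-block grouping
#'   (e.g. 3 for water), or NULL with `groups` given explicitly.
#' @param groups optional explicit list of `fq_group`s.
#' @param total_charges per-molecule total charges (recycled), default 0.
#' @return an `fq_system`.
#' @export
fq_system_from_geometry <- function(elements, positions_ang, params,
                                    molecule_size = NULL, groups = NULL,
                                    total_charges = 0) {
  n <- length(elements)
  tab <- params$parameters
  row <- match(elements, tab$element)
  if (any(is.na(row)))
    stop("missing FQ parameters for element(s): ",
         paste(unique(elements[is.na(row)]), collapse = ", "))
  atoms <- fq_atoms(positions_ang * ANGSTROM_TO_BOHR,
                    chi = tab$chi[row], eta = tab$eta[row],
                    elements = elements)
  if (is.null(groups)) {
    if (is.null(molecule_size)) stop("need molecule_size or explicit groups")
    if (n %% molecule_size != 0L)
      stop("atom count not divisible by molecule_size")
    nmol <- n %/% molecule_size
    qtot <- rep_len(total_charges, nmol)
    groups <- lapply(seq_len(nmol), function(m)
      fq_group((m - 1L) * molecule_size + seq_len(molecule_size), qtot[m]))
  }
  fq_system(atoms, groups)
}
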