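#' Synthetic fixture generator
#'
#' Deterministic (seeded) generators for the inputs the package consumes:
#' random small-L active-space Hamiltonians with full permutational symmetry,
#' an H2-like two-orbital Hamiltonian with a known singlet spectrum, toy
#' solute + solvent snapshot sets with seeded positional jitter, and
#' synthetic FQ parameter sets. Every fixture round-trips through its reader.
#'
#' @name fixtures
NULL

#' Random active-space integrals
#'
#' Symmetric h and 8-fold-symmetric g, scaled so correlation strength is
#' controlled by `strength` (ratio of two-electron to one-electron scales).
#' A diagonal-dominant h keeps spectra well separated.
#'
#' @param L active orbital count.
#' @param n_electrons electron count (default L, half filling).
#' @param strength two-electron scale.
#' @param ms2 spin projection.
#' @return an `active_space_integrals`.
#' @export
random_integrals <- function(L, n_electrons = L, strength = 0.4, ms2 = 0L) {
  h <- matrix(stats::rnorm(L * L, sd = 0.5), L, L)
  h <- (h + t(h)) / 2
  diag(h) <- -1 - stats::runif(L)
  g <- array(0, c(L, L, L, L))
  for (p in seq_len(L)) for (q in seq_len(p))
    for (r in seq_len(p)) for (s in seq_len(r)) {
      if ((r - 1L) * r / 2 + s > (p - 1L) * p / 2 + q) next
      v <- stats::rnorm(1, sd = strength)
      if (p == q && r == s && p == r) v <- abs(v) + 0.1  # (pp|pp) > 0
      for (ix in list(c(p,q,r,s), c(q,p,r,s), c(p,q,s,r), c(q,p,s,r),
                      c(r,s,p,q), c(s,r,p,q), c(r,s,q,p), c(s,r,q,p)))
        g[ix[1], ix[2], ix[3], ix[4]] <- v
    }
  active_space_integrals(h, g, core_energy = stats::rnorm(1, sd = 0.1),
                         n_electrons = n_electrons, ms2 = ms2)
}

#' H2-like two-orbital Hamiltonian
#'
#' Minimal-basis hydrogen-molecule-style CAS(2,2) integrals in the MO basis
#' (bonding/antibonding), with singlet ground and excited states split by
#' roughly twice the hopping gap.
#'
#' @param gap one-electron bonding/antibonding splitting.
#' @param u on-site repulsion scale.
#' @return an `active_space_integrals` with 2 electrons in 2 orbitals.
#' @export
h2like_integrals <- function(gap = 1.0, u = 0.6) {
  h <- diag(c(-gap / 2 - 1, gap / 2 - 1))
  g <- array(0, c(2, 2, 2, 2))
  g[1, 1, 1, 1] <- u
  g[2, 2, 2, 2] <- u
  g[1, 1, 2, 2] <- g[2, 2, 1, 1] <- 0.7 * u
  g[1, 2, 1, 2] <- g[2, 1, 1, 2] <- g[1, 2, 2, 1] <- g[2, 1, 2, 1] <- 0.15 * u
  active_space_integrals(h, g, core_energy = 0.7, n_electrons = 2L)
}

#' Generate fixture files
#'
#' @param kind one of "fcidump_random", "fcidump_h2like", "toy_snapshots",
#'   "fq_params".
#' @param seed integer seed; identical seeds give byte-identical files.
#' @param dir output directory.
#' @param params kind-specific parameters: `L`, `n_electrons`, `strength`
#'   (fcidump_random); `n_frames`, `n_solvent`, `jitter_ang`, `spacing_ang`
#'   (toy_snapshots); `elements`, `chi0`, `eta0` (fq_params).
#' @return character vector of written file paths.
#' @export
generate_fixtures <- function(kind, seed, dir = ".", params = list()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  switch(kind,
    fcidump_random = {
      L <- params$L %||% 4L
      ints <- random_integrals(L, params$n_electrons %||% L,
                               params$strength %||% 0.4)
      path <- file.path(dir, sprintf("random_L%d_seed%d.fcidump", L, seed))
      write_fcidump(ints, path)
      path
    },
    fcidump_h2like = {
      ints <- h2like_integrals(params$gap %||% 1.0, params$u %||% 0.6)
      path <- file.path(dir, sprintf("h2like_seed%d.fcidump", seed))
      write_fcidump(ints, path)
      path
    },
    toy_snapshots = {
      paths <- toy_snapshot_files(dir, seed,
                                  n_frames = params$n_frames %||% 3L,
                                  n_solvent = params$n_solvent %||% 3L,
                                  jitter = params$jitter_ang %||% 0.3,
                                  spacing = params$spacing_ang %||% 3,
                                  distances = params$distances_ang)
      paths
    },
    fq_params = {
      elements <- params$elements %||% c("H", "O")
      chi0 <- params$chi0 %||% 0.1
      eta0 <- params$eta0 %||% 0.5
      pars <- lapply(seq_along(elements), function(i)
        list(chi = round(chi0 * i + stats::runif(1, 0, 0.05), 6),
             eta = round(eta0 + 0.1 * i + stats::runif(1, 0, 0.05), 6)))
      names(pars) <- elements
      path <- file.path(dir, sprintf("fq_params_seed%d.yaml", seed))
      yaml::write_yaml(list(name = sprintf("synthetic_seed%d", seed),
                            parameters = pars), path)
      path
    },
    stop("unknown fixture kind: ", kind)
  )
}

# toy solute (H2) + diatomic solvent molecules at programmed or jittered
# distances along distinct directions; writes frames.xyz + grouping.yaml
toy_snapshot_files <- function(dir, seed, n_frames, n_solvent, jitter,
                               spacing, distances = NULL) {
  solute <- rbind(c(0, 0, 0), c(0.74, 0, 0))
  dirs <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1), c(-1, 0, 0),
                c(0, -1, 0), c(0, 0, -1),
                c(1, 1, 0) / sqrt(2), c(1, 0, 1) / sqrt(2))
  frames <- list()
  for (f in seq_len(n_frames)) {
    elements <- c("H", "H")
    pos <- solute
    for (m in seq_len(n_solvent)) {
      d0 <- if (!is.null(distances)) distances[m] else spacing * m
      base <- dirs[(m - 1L) %% nrow(dirs) + 1L, ] * d0
      jit <- if (is.null(distances)) stats::rnorm(3, sd = jitter) else c(0, 0, 0)
      a1 <- base + jit
      a2 <- a1 + c(0.74, 0, 0)
      pos <- rbind(pos, a1, a2)
      elements <- c(elements, "H", "H")
    }
    frames[[f]] <- list(elements = elements, positions_ang = pos,
                        comment = sprintf("toy frame %d seed %d", f, seed))
  }
  xyz_path <- file.path(dir, sprintf("toy_frames_seed%d.xyz", seed))
  write_xyz(frames, xyz_path)
  grouping_path <- file.path(dir, sprintf("toy_grouping_seed%d.yaml", seed))
  yaml::write_yaml(list(solute_atoms = c(1L, 2L),
                        solvent_molecule_size = 2L), grouping_path)
  c(xyz_path, grouping_path)
}

#' Synthetic FQ parameter table in memory
#' @param elements element labels.
#' @return parameter list in the [read_fq_params()] shape.
#' @export
synthetic_fq_params <- function(elements = c("H", "O")) {
  df <- data.frame(element = elements,
                   chi = 0.08 + 0.12 * seq_along(elements),
                   eta = 0.45 + 0.1 * seq_along(elements),
                   stringsAsFactors = FALSE)
  list(name = "synthetic", parameters = df)
}
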