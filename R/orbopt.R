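#' Orbital optimization under the extended Brillouin condition
#'
#' The orbital gradient g_rs = <Psi|[H, E_rs - E_sr]|Psi> over non-redundant
#' rotation pairs (inactive-active, inactive-virtual, active-virtual) is
#' evaluated through the generalized Fock matrix built from the full-space
#' one- and two-particle densities. Classical charges enter exactly through
#' the folded one-electron integrals, so the same expressions produce the
#' FQ-augmented gradient. Orbitals are updated as C exp(kappa) with kappa
#' antisymmetric over the non-redundant pairs and a trust cap on |kappa|;
#' active-active rotations are treated as redundant (standard CAS practice;
#' at truncated bond dimension this is an accepted approximation).
#'
#' @name orbital_optimizer
NULL

#' Non-redundant orbital-rotation pairs
#' @param partition list with `inactive`, `active`, `virtual` index vectors.
#' @return two-column matrix of (r, s) pairs with r > s ordering convention
#'   (row index = rotated-down orbital).
#' @export
nonredundant_pairs <- function(partition) {
  pairs <- rbind(
    as.matrix(expand.grid(r = partition$active, s = partition$inactive)),
    as.matrix(expand.grid(r = partition$virtual, s = partition$inactive)),
    as.matrix(expand.grid(r = partition$virtual, s = partition$active)))
  if (nrow(pairs) == 0L) return(matrix(integer(0), 0, 2))
  pairs
}

# full-space one- and two-particle densities from CAS densities + core
full_space_densities <- function(rdms, partition, n_mo) {
  inact <- partition$inactive; act <- partition$active
  D <- matrix(0, n_mo, n_mo)
  for (i in inact) D[i, i] <- 2
  D[act, act] <- rdms$one_particle
  G <- array(0, c(n_mo, n_mo, n_mo, n_mo))
  G[act, act, act, act] <- rdms$two_particle
  Da <- rdms$one_particle
  for (i in inact) {
    for (j in inact) {
      G[i, i, j, j] <- G[i, i, j, j] + 4
      G[i, j, j, i] <- G[i, j, j, i] - 2
    }
    G[i, i, act, act] <- G[i, i, act, act] + 2 * Da
    G[act, act, i, i] <- G[act, act, i, i] + 2 * Da
    G[act, i, i, act] <- G[act, i, i, act] - Da
    G[i, act, act, i] <- G[i, act, act, i] - t(Da)
  }
  list(D = D, G = G)
}

# total electronic + nuclear energy for given MO coefficients at fixed
# densities; h_ao may include folded classical charges
fixed_density_energy <- function(C, ao, dens, h_ao, e_const) {
  h_mo <- t(C) %*% h_ao %*% C
  g_mo <- transform_eri(ao$eri, C)
  e_const + sum(h_mo * dens$D) + 0.5 * sum(g_mo * dens$G)
}

# generalized Fock matrix F_mn = sum_q D_mq h_nq + sum_qrs G_mqrs g_nqrs
generalized_fock <- function(h_mo, g_mo, dens) {
  n <- nrow(h_mo)
  Fm <- dens$D %*% h_mo
  Gm <- matrix(aperm(dens$G, c(1, 2, 3, 4)), n, n^3)
  gm <- matrix(aperm(g_mo, c(1, 2, 3, 4)), n, n^3)
  Fm + Gm %*% t(gm)
}

#' Orbital gradient of the total energy
#'
#' Gradient of E(C exp(kappa)) at kappa = 0, at fixed CI (MPS) coefficients
#' and fixed charges, over the non-redundant pairs. Charges are folded into
#' the AO one-electron matrix before the transform, which reproduces the
#' FQ-augmented gradient.
#'
#' @param rdms active-space `density_matrices`.
#' @param ao AO integrals from [ao_integrals()].
#' @param orbitals an `orbital_set`.
#' @param charges optional FQ charge vector.
#' @param esp_ao optional list of AO ESP matrices (one per charge site).
#' @return list with `pairs`, `gradient` (per pair), `matrix` (full
#'   antisymmetric gradient) and `norm`.
#' @export
orbital_gradient <- function(rdms, ao, orbitals, charges = NULL,
                             esp_ao = NULL) {
  C <- orbitals$coefficients
  n <- ncol(C)
  h_ao <- fold_charges_ao(ao$hcore, charges, esp_ao)
  dens <- full_space_densities(rdms, orbitals$partition, n)
  h_mo <- t(C) %*% h_ao %*% C
  g_mo <- transform_eri(ao$eri, C)
  Fm <- generalized_fock(h_mo, g_mo, dens)
  # sign convention: rotation C exp(kappa) with kappa[r, s] = x on the
  # non-redundant pairs (r > s); dE/dx = 2 (F_sr - F_rs)
  gmat <- 2 * (t(Fm) - Fm)
  pairs <- nonredundant_pairs(orbitals$partition)
  gvec <- if (nrow(pairs) > 0L) gmat[pairs] else numeric(0)
  full <- matrix(0, n, n)
  if (nrow(pairs) > 0L) {
    full[pairs] <- gvec
    full <- full - t(full)
  }
  list(pairs = pairs, gradient = gvec, matrix = full,
       norm = sqrt(sum(gvec^2)))
}

fold_charges_ao <- function(hcore, charges, esp_ao) {
  if (is.null(charges) || length(charges) == 0L) return(hcore)
  if (is.null(esp_ao)) stop("charges given without ESP matrices")
  for (s in seq_along(charges)) hcore <- hcore - charges[s] * esp_ao[[s]]
  hcore
}

skew_from_pairs <- function(x, pairs, n) {
  A <- matrix(0, n, n)
  if (nrow(pairs) > 0L) A[pairs] <- x
  A - t(A)
}

matrix_exp <- function(A) as.matrix(Matrix::expm(Matrix::Matrix(A)))

# minimize the fixed-density energy over kappa (quasi-Newton), returning the
# rotated coefficients; step length capped by trust
rotate_orbitals <- function(C, ao, dens, h_ao, pairs, trust = 0.4,
                            e_const = 0) {
  n <- ncol(C)
  if (nrow(pairs) == 0L) return(C)
  fn <- function(x) {
    K <- skew_from_pairs(x, pairs, n)
    fixed_density_energy(C %*% matrix_exp(K), ao, dens, h_ao, e_const)
  }
  gr <- function(x) {
    K <- skew_from_pairs(x, pairs, n)
    Cx <- C %*% matrix_exp(K)
    h_mo <- t(Cx) %*% h_ao %*% Cx
    g_mo <- transform_eri(ao$eri, Cx)
    Fm <- generalized_fock(h_mo, g_mo, dens)
    (2 * (t(Fm) - Fm))[pairs]
  }
  opt <- stats::optim(rep(0, nrow(pairs)), fn, gr, method = "BFGS",
                      control = list(reltol = 1e-14, maxit = 200))
  x <- opt$par
  nx <- sqrt(sum(x^2))
  e0 <- fn(rep(0, nrow(pairs)))
  if (nx > trust) x <- x * trust / nx
  # backtrack so the fixed-density energy strictly decreases
  for (bt in 1:25) {
    if (fn(x) <= e0 + 1e-13) break
    x <- x / 2
  }
  K <- skew_from_pairs(x, pairs, n)
  C %*% matrix_exp(K)
}

# re-orthonormalize coefficients against the AO overlap (symmetric)
symmetric_reorthonormalize <- function(C, S) {
  M <- t(C) %*% S %*% C
  es <- eigen((M + t(M)) / 2, symmetric = TRUE)
  C %*% es$vectors %*% diag(1 / sqrt(es$values), ncol(C)) %*% t(es$vectors)
}

#' Solve for an electronic state of an active-space Hamiltonian
#'
#' Two-site DMRG for the lowest state, or the first excited state in the
#' same (N, 2Sz) sector via orthogonality projection against the freshly
#' converged ground state (root homing by projection).
#'
#' @param ints an `active_space_integrals`.
#' @param root 1 for the ground state, 2 for the first excited state.
#' @param max_bond bond dimension M.
#' @param n_sweeps sweep limit.
#' @param guess optional starting `mps`.
#' @param use_sector_penalty add a commuting (N, Sz) penalty to keep stray
#'   sectors out of the excited-state window.
#' @param penalty_weight penalty strength (Hartree).
#' @param singlet_penalty weight of an S^2 penalty for singlet targeting;
#'   defaults to 5 when ms2 = 0 (singlets unaffected, higher-spin states
#'   pushed up), 0 otherwise.
#' @return list with `energy`, `mps`, `sweep_energies`, `converged`, and for
#'   root 2 also `ground` (the root-1 result).
#' @export
solve_state <- function(ints, root = 1L, max_bond = 32L, n_sweeps = 24L,
                        guess = NULL, use_sector_penalty = TRUE,
                        penalty_weight = 10,
                        singlet_penalty = if (ints$ms2 == 0L) 5 else 0) {
  L <- ints$n_orbitals
  H <- build_mpo(ints)
  if (use_sector_penalty && L > 1L) {
    Hpen <- mpo_add(H, sector_penalty_mpo(
      L, ints$n_electrons, ints$ms2, weight = penalty_weight))
    if (singlet_penalty > 0)
      Hpen <- mpo_add(Hpen, spin_squared_mpo(L, weight = singlet_penalty))
    Hpen <- mpo_compress(Hpen)
  } else Hpen <- H
  if (is.null(guess))
    guess <- random_sector_mps(L, ints$n_electrons, ints$ms2,
                               max_bond = min(max_bond, 8L))
  gs <- optimize_mps(Hpen, guess, max_bond = max_bond, n_sweeps = n_sweeps)
  gs$energy_total <- gs$energy + ints$core_energy
  if (root == 1L) return(gs)
  es_guess <- perturb_guess(gs$mps, max_bond)
  es <- optimize_mps(Hpen, es_guess, max_bond = max_bond,
                     n_sweeps = n_sweeps, orthogonal_to = list(gs$mps))
  es$energy_total <- es$energy + ints$core_energy
  es$ground <- gs
  es
}

# deterministic perturbed copy of a converged state used to seed root 2
perturb_guess <- function(psi, max_bond) {
  q <- mps_quantum_numbers(psi)
  L <- psi$length
  occs <- sector_occupations(L, round(q$n), round(q$sz2))
  best <- NULL
  for (k in seq_len(nrow(occs))) {
    cand <- product_mps(occs[k, ])
    ov <- abs(mps_overlap(cand, psi))
    if (is.null(best) || ov < best$ov) best <- list(mps = cand, ov = ov)
  }
  mix <- mps_add(best$mps, {
    p <- psi; p$tensors[[p$gauge_center]] <- p$tensors[[p$gauge_center]] * 0.25; p
  })
  mps_normalize(mps_compress(mix, max_bond = max_bond))
}

#' Orbital-optimized DMRG (CASSCF-style macro-iterations)
#'
#' Alternates MPS re-optimization with orbital-rotation steps until the
#' extended-Brillouin gradient norm falls below `tol`. Classical charges, if
#' given, are held fixed and folded into the one-electron integrals
#' throughout (charge relaxation belongs to the outer DMRG/FQ loop).
#'
#' @param ao AO integrals.
#' @param orbitals starting `orbital_set`.
#' @param n_active_electrons,ms2 active-space electron count and 2Sz.
#' @param root 1 (ground) or 2 (first excited state).
#' @param max_bond bond dimension.
#' @param charges,esp_ao optional fixed charges and AO ESP matrices.
#' @param e_charge_nuc scalar charge-nuclear energy added to the core.
#' @param max_macro macro-iteration limit.
#' @param tol gradient-norm convergence threshold.
#' @param n_sweeps DMRG sweep limit per macro-iteration.
#' @param mps_guess optional starting MPS.
#' @return list with `energy`, `orbitals`, `mps`, `rdms`, `ints`,
#'   `gradient_norm`, `trace` (per-macro energies), `converged`, `solution`
#'   (full solve_state result).
#' @export
optimize_orbitals <- function(ao, orbitals, n_active_electrons, ms2 = 0L,
                              root = 1L, max_bond = 32L, charges = NULL,
                              esp_ao = NULL, e_charge_nuc = 0,
                              max_macro = 40L, tol = 1e-7, n_sweeps = 16L,
                              mps_guess = NULL) {
  h_ao <- fold_charges_ao(ao$hcore, charges, esp_ao)
  trace <- numeric(0)
  converged <- FALSE
  sol <- NULL; rdms <- NULL; ints <- NULL; gnorm <- NA_real_
  for (macro in seq_len(max_macro)) {
    ints <- transform_to_active(ao, orbitals, n_active_electrons, ms2,
                                h_extra_ao = h_ao - ao$hcore)
    ints$core_energy <- ints$core_energy + e_charge_nuc
    sol <- solve_state(ints, root = root, max_bond = max_bond,
                       n_sweeps = n_sweeps, guess = mps_guess)
    mps_guess <- NULL  # reuse only on the first macro-iteration
    rdms <- compute_rdms(sol$mps)
    trace <- c(trace, sol$energy_total)
    grad <- orbital_gradient(rdms, ao, orbitals, charges, esp_ao)
    gnorm <- grad$norm
    if (gnorm < tol) { converged <- TRUE; break }
    dens <- full_space_densities(rdms, orbitals$partition, ncol(orbitals$coefficients))
    Cnew <- rotate_orbitals(orbitals$coefficients, ao, dens, h_ao,
                            grad$pairs, e_const = ao$nuclear_repulsion)
    Cnew <- symmetric_reorthonormalize(Cnew, ao$S)
    orbitals <- orbital_set(Cnew, orbitals$partition, ao$S)
  }
  if (!converged)
    warning("orbital optimization hit max_macro; returning best iterate")
  list(energy = sol$energy_total, orbitals = orbitals, mps = sol$mps,
       rdms = rdms, ints = ints, gradient_norm = gnorm, trace = trace,
       converged = converged, solution = sol)
}
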