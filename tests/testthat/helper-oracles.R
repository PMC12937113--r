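# Independent oracles for module-level tests (kept free of the package's
# internal code paths wherever the quantity under test is concerned).

# Constrained quadratic minimizer via augmented Lagrangian with exact inner
# solves: minimizes chi.q + 1/2 q'Tq + q.V subject to C'q = Q.
fq_minimizer_oracle <- function(kernel, chi, groups, v = NULL,
                                tol = 1e-13, max_outer = 60L) {
  n <- nrow(kernel)
  if (is.null(v)) v <- numeric(n)
  ng <- length(groups)
  C <- matrix(0, n, ng)
  Q <- numeric(ng)
  for (g in seq_len(ng)) {
    C[groups[[g]]$atom_indices, g] <- 1
    Q[g] <- groups[[g]]$total_charge
  }
  lambda <- numeric(ng)
  rho <- 10
  q <- numeric(n)
  for (it in seq_len(max_outer)) {
    # inner minimization of the augmented Lagrangian is an exact linear solve
    A <- kernel + rho * C %*% t(C)
    b <- -chi - v - C %*% lambda + rho * C %*% Q
    q <- solve(A, b)
    resid <- as.numeric(t(C) %*% q - Q)
    if (max(abs(resid)) < tol) break
    lambda <- lambda + rho * resid
    rho <- min(rho * 4, 1e10)
  }
  list(charges = as.numeric(q), residual = max(abs(as.numeric(t(C) %*% q - Q))))
}

# lowest singlet eigenvalues in the (N, 2Sz = 0) sector, identified by S^2
# of the exact eigenvectors
oracle_fci_singlets <- function(ints, n_singlets = 2L, max_roots = 60L) {
  fci <- oracle_fci(ints, n_roots = min(max_roots, 4^ints$n_orbitals))
  L <- ints$n_orbitals
  ops <- oracle_ops(L)
  Sp <- Reduce(`+`, lapply(seq_len(L), function(p)
    ops$cu[[p]] %*% Matrix::t(ops$cd[[p]])))
  lab <- oracle_sector_labels(L)
  szv <- lab$sz2 / 2
  out <- numeric(0)
  for (j in seq_along(fci$values)) {
    v <- fci$vectors[, j]
    s2 <- sum(v * as.numeric(Matrix::t(Sp) %*% (Sp %*% v))) +
      sum(szv * (szv + 1) * v^2)
    if (s2 < 1e-8) out <- c(out, fci$values[j])
    if (length(out) >= n_singlets) break
  }
  out
}

# independent CASSCF oracle: exact-diagonalization CI energy minimized over
# orbital-rotation parameters with a generic quasi-Newton optimizer
casscf_oracle <- function(ao, C0, partition, n_act_el, root = 1L) {
  pairs <- nonredundant_pairs(partition)
  n <- ncol(C0)
  efci <- function(x) {
    K <- matrix(0, n, n); K[pairs] <- x; K <- K - t(K)
    Cx <- C0 %*% as.matrix(Matrix::expm(Matrix::Matrix(K)))
    o <- orbital_set(Cx, partition, ao$S)
    ints <- transform_to_active(ao, o, n_act_el)
    oracle_fci_singlets(ints, n_singlets = root)[root]
  }
  x <- rep(0, nrow(pairs))
  for (pass in 1:3)
    x <- stats::optim(x, efci, method = "BFGS",
                      control = list(reltol = 1e-15, maxit = 400))$par
  list(energy = efci(x), par = x)
}

# shared toy geometries -------------------------------------------------

toy_h2_qm <- function(r_ang = 0.74)
  list(elements = c("H", "H"),
       positions_ang = rbind(c(0, 0, 0), c(r_ang, 0, 0)))

toy_water_env <- function(origins = list(c(2.5, 0.5, 0), c(-1.5, 1.8, 0.5),
                                         c(0.3, -2.2, 1.0))) {
  mk <- function(o) rbind(o, o + c(0.96, 0, 0), o + c(-0.24, 0.93, 0))
  pos <- do.call(rbind, lapply(origins, mk))
  fq_system_from_geometry(rep(c("O", "H", "H"), length(origins)), pos,
                          synthetic_fq_params(c("O", "H")),
                          molecule_size = 3L)
}

toy_h4_context <- function() {
  nuc <- list(Z = rep(1, 4),
              positions = rbind(c(0, 0, 0), c(1.6, 0, 0),
                                c(3.2, 0, 0), c(4.8, 0, 0)))
  bas <- build_basis(rep("H", 4), nuc$positions)
  ao <- ao_integrals(bas, nuc)
  hf <- rhf(ao, 4L)
  list(nuclei = nuc, basis = bas, ao = ao, hf = hf)
}
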