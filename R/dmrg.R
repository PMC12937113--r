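#' Two-site DMRG engine
#'
#' Variational optimization of an MPS against an MPO Hamiltonian. Partial
#' contractions of <Psi|H|Psi> from the left and right (boundaries) reduce
#' each local problem to a standard eigenproblem for the two-site tensor,
#' solved by a Davidson iteration; the optimized pair tensor is split by SVD
#' with truncation to the maximum bond dimension M, and the process sweeps
#' back and forth until the energy is stationary. Excited states are targeted
#' by projecting the local problem orthogonal to previously converged states.
#'
#' @name dmrg_engine
NULL

# Left boundary update across one site.
# L[ab, ak, b] -> L'[ab', ak', b'] using bra tensor Mb, ket tensor Mk and
# MPO tensor W[b, s_out, s_in, b'].
contract_left <- function(Lenv, Mb, Mk, W) {
  db <- dim(Mb); dk <- dim(Mk); dw <- dim(W)
  # T[s, alpha_b, ak, b] = sum_ab Mb[ab, s, alpha_b] L[ab, ak, b]
  Tm <- crossprod(matrix(Mb, db[1], 4L * db[3]),
                  matrix(Lenv, db[1], dk[1] * dw[1]))
  Tm <- array(Tm, c(4L, db[3], dk[1], dw[1]))
  # U[alpha_b, ak, s', b'] = sum_{s, b} T[s, alpha_b, ak, b] W[b, s, s', b']
  Tp <- matrix(aperm(Tm, c(2, 3, 1, 4)), db[3] * dk[1], 4L * dw[1])
  Wp <- matrix(aperm(W, c(2, 1, 3, 4)), 4L * dw[1], 4L * dw[4])
  U <- array(Tp %*% Wp, c(db[3], dk[1], 4L, dw[4]))
  # L'[alpha_b, b', alpha_k] = sum_{ak, s'} U[alpha_b, ak, s', b'] Mk[ak, s', alpha_k]
  Up <- matrix(aperm(U, c(1, 4, 2, 3)), db[3] * dw[4], dk[1] * 4L)
  out <- Up %*% matrix(Mk, dk[1] * 4L, dk[3])
  aperm(array(out, c(db[3], dw[4], dk[3])), c(1, 3, 2))
}

# Right boundary update across one site.
# R[ab, ak, b] at cut l -> R'[ab', ak', b'] at cut l-1.
contract_right <- function(Renv, Mb, Mk, W) {
  db <- dim(Mb); dk <- dim(Mk); dw <- dim(W)
  # T[alpha_b, s, ak, b'] = sum_ab Mb[alpha_b, s, ab] R[ab, ak, b']
  Tm <- matrix(Mb, db[1] * 4L, db[3]) %*% matrix(Renv, db[3], dk[3] * dw[4])
  Tm <- array(Tm, c(db[1], 4L, dk[3], dw[4]))
  # U[alpha_b, ak, b, s'] = sum_{s, b'} T[alpha_b, s, ak, b'] W[b, s, s', b']
  Tp <- matrix(aperm(Tm, c(1, 3, 2, 4)), db[1] * dk[3], 4L * dw[4])
  Wp <- matrix(aperm(W, c(2, 4, 1, 3)), 4L * dw[4], dw[1] * 4L)
  U <- array(Tp %*% Wp, c(db[1], dk[3], dw[1], 4L))
  # R'[alpha_b, b, alpha_k] = sum_{ak, s'} U[alpha_b, ak, b, s'] Mk[alpha_k, s', ak]
  Up <- matrix(aperm(U, c(1, 3, 2, 4)), db[1] * dw[1], dk[3] * 4L)
  Mkp <- matrix(aperm(Mk, c(3, 2, 1)), dk[3] * 4L, dk[1])
  out <- Up %*% Mkp
  aperm(array(out, c(db[1], dw[1], dk[1])), c(1, 3, 2))
}

boundary_start <- function() array(1, c(1, 1, 1))

#' Expectation value <bra|O|ket> via boundary contraction
#'
#' @param mps ket MPS (and bra unless `bra` given).
#' @param mpo an `mpo`.
#' @param bra optional bra MPS.
#' @return scalar expectation value (not normalized).
#' @export
expectation <- function(mps, mpo, bra = NULL) {
  if (is.null(bra)) bra <- mps
  stopifnot(mps$length == mpo$length, bra$length == mpo$length)
  env <- boundary_start()
  for (l in seq_len(mps$length))
    env <- contract_left(env, bra$tensors[[l]], mps$tensors[[l]],
                         mpo$tensors[[l]])
  env[1, 1, 1]
}

#' Recompute all right boundaries of <bra|H|ket>
#' @keywords internal
right_boundaries <- function(mpo, ket, bra = NULL) {
  if (is.null(bra)) bra <- ket
  L <- ket$length
  renv <- vector("list", L + 1L)
  renv[[L + 1L]] <- boundary_start()
  for (l in L:1)
    renv[[l]] <- contract_right(renv[[l + 1L]], bra$tensors[[l]],
                                ket$tensors[[l]], mpo$tensors[[l]])
  renv
}

# overlap environments of a fixed state phi against the working state:
# lov[[l]] is the contraction of sites < l, rov[[l]] of sites > l,
# each a (bond_phi x bond_psi) matrix.
overlap_left_env <- function(env, Mphi, Mpsi) {
  dp <- dim(Mphi); dq <- dim(Mpsi)
  out <- matrix(0, dp[3], dq[3])
  for (s in seq_len(4L))
    out <- out + t(matrix(Mphi[, s, ], dp[1], dp[3])) %*% env %*%
      matrix(Mpsi[, s, ], dq[1], dq[3])
  out
}

overlap_right_env <- function(env, Mphi, Mpsi) {
  dp <- dim(Mphi); dq <- dim(Mpsi)
  out <- matrix(0, dp[1], dq[1])
  for (s in seq_len(4L))
    out <- out + matrix(Mphi[, s, ], dp[1], dp[3]) %*% env %*%
      t(matrix(Mpsi[, s, ], dq[1], dq[3]))
  out
}

# Effective two-site Hamiltonian matvec.
# theta: array (a_left, 4, 4, a_right) flattened; returns H_eff theta.
twosite_matvec <- function(theta_vec, Lenv, W1, W2, Renv, dims) {
  aL <- dims[1]; aR <- dims[4]
  d1 <- dim(W1); d2 <- dim(W2)
  theta <- array(theta_vec, dims)
  # A[ab, b0, s1k, s2k, bk] = sum_ak L[ab, ak, b0] theta[ak, s1k, s2k, bk]
  Lp <- matrix(aperm(Lenv, c(1, 3, 2)), dim(Lenv)[1] * d1[1], dims[1])
  A <- array(Lp %*% matrix(theta, dims[1], 16L * aR),
             c(dim(Lenv)[1], d1[1], 4L, 4L, aR))
  # B[ab, s2k, bk, s1b, b1] = sum_{b0, s1k} A[...] W1[b0, s1b, s1k, b1]
  Ap <- matrix(aperm(A, c(1, 4, 5, 2, 3)), dim(Lenv)[1] * 4L * aR, d1[1] * 4L)
  W1p <- matrix(aperm(W1, c(1, 3, 2, 4)), d1[1] * 4L, 4L * d1[4])
  B <- array(Ap %*% W1p, c(dim(Lenv)[1], 4L, aR, 4L, d1[4]))
  # C[ab, bk, s1b, s2b, b2] = sum_{b1, s2k} B[...] W2[b1, s2b, s2k, b2]
  Bp <- matrix(aperm(B, c(1, 3, 4, 5, 2)), dim(Lenv)[1] * aR * 4L, d2[1] * 4L)
  W2p <- matrix(aperm(W2, c(1, 3, 2, 4)), d2[1] * 4L, 4L * d2[4])
  Cc <- array(Bp %*% W2p, c(dim(Lenv)[1], aR, 4L, 4L, d2[4]))
  # phi[ab, s1b, s2b, bb] = sum_{bk, b2} C[...] R[bb, bk, b2]
  Cp <- matrix(aperm(Cc, c(1, 3, 4, 2, 5)), dim(Lenv)[1] * 16L, aR * d2[4])
  Rp <- matrix(aperm(Renv, c(2, 3, 1)), aR * d2[4], dim(Renv)[1])
  as.numeric(Cp %*% Rp)
}

#' Davidson iteration for the lowest eigenpair
#'
#' Deterministic Davidson with diagonal preconditioning and optional
#' projection orthogonal to fixed vectors (used for excited-state targeting).
#' Falls back to a dense solve for small problems.
#'
#' @param matvec function(v) returning A v.
#' @param n problem dimension.
#' @param v0 start vector.
#' @param diag_A diagonal of A for preconditioning (optional).
#' @param tol residual tolerance.
#' @param max_iter maximum subspace expansions.
#' @param project_out list of vectors to project out of the search space.
#' @return list(value, vector, converged, iterations).
#' @export
davidson <- function(matvec, n, v0 = NULL, diag_A = NULL, tol = 1e-10,
                     max_iter = 200L, project_out = list()) {
  P <- NULL
  if (length(project_out) > 0L) {
    P <- do.call(cbind, project_out)
    P <- qr.Q(qr(P))  # orthonormal basis of the excluded space
  }
  proj <- function(v) if (is.null(P)) v else v - P %*% crossprod(P, v)
  Amv <- function(v) proj(matvec(proj(v)))
  if (n <= 256L) {
    A <- vapply(seq_len(n), function(j) {
      e <- numeric(n); e[j] <- 1; Amv(e)
    }, numeric(n))
    A <- (A + t(A)) / 2
    # keep the spectrum of the excluded space out of the way
    if (!is.null(P)) A <- A + 1e6 * tcrossprod(P)
    es <- eigen(A, symmetric = TRUE)
    k <- which.min(es$values)
    return(list(value = es$values[k], vector = es$vectors[, k],
                converged = TRUE, iterations = 1L))
  }
  if (is.null(v0)) { v0 <- numeric(n); v0[1] <- 1 }
  v0 <- proj(v0)
  nv <- sqrt(sum(v0^2))
  if (nv < 1e-12) { v0 <- proj(stats::rnorm(n)); nv <- sqrt(sum(v0^2)) }
  V <- matrix(v0 / nv, n, 1L)
  AV <- matrix(Amv(V[, 1L]), n, 1L)
  if (is.null(diag_A)) diag_A <- rep(1, n)
  theta <- NA_real_; x <- V[, 1L]; converged <- FALSE; it <- 0L
  max_space <- 30L
  while (it < max_iter) {
    it <- it + 1L
    H <- crossprod(V, AV)
    H <- (H + t(H)) / 2
    es <- eigen(H, symmetric = TRUE)
    k <- which.min(es$values)
    theta <- es$values[k]
    y <- es$vectors[, k]
    x <- as.numeric(V %*% y)
    r <- as.numeric(AV %*% y) - theta * x
    if (sqrt(sum(r^2)) < tol) { converged <- TRUE; break }
    denom <- diag_A - theta
    denom[abs(denom) < 1e-8] <- sign(denom[abs(denom) < 1e-8] + 1e-30) * 1e-8
    t_new <- proj(r / denom)
    # orthogonalize against current space (twice for stability)
    for (rep in 1:2) t_new <- t_new - V %*% crossprod(V, t_new)
    tn <- sqrt(sum(t_new^2))
    if (tn < 1e-12) { converged <- TRUE; break }
    if (ncol(V) >= max_space) {  # restart with current best
      V <- matrix(x / sqrt(sum(x^2)), n, 1L)
      AV <- matrix(Amv(V[, 1L]), n, 1L)
      next
    }
    V <- cbind(V, t_new / tn)
    AV <- cbind(AV, Amv(V[, ncol(V)]))
  }
  list(value = theta, vector = x / sqrt(sum(x^2)), converged = converged,
       iterations = it)
}

# diagonal of the effective two-site Hamiltonian, for preconditioning
twosite_diag <- function(Lenv, W1, W2, Renv) {
  dl <- dim(Lenv); dr <- dim(Renv)
  d1 <- dim(W1); d2 <- dim(W2)
  Ld <- matrix(0, dl[1], dl[3])  # [a, b0] diagonal a_b = a_k
  for (b in seq_len(dl[3])) Ld[, b] <- diag(matrix(Lenv[, , b], dl[1], dl[2]))
  Rd <- matrix(0, dr[1], dr[3])
  for (b in seq_len(dr[3])) Rd[, b] <- diag(matrix(Renv[, , b], dr[1], dr[2]))
  W1d <- array(0, c(d1[1], 4L, d1[4]))
  for (s in 1:4) W1d[, s, ] <- W1[, s, s, ]
  W2d <- array(0, c(d2[1], 4L, d2[4]))
  for (s in 1:4) W2d[, s, ] <- W2[, s, s, ]
  out <- array(0, c(dl[1], 4L, 4L, dr[1]))
  for (s1 in 1:4) for (s2 in 1:4) {
    # sum_{b0,b1,b2} Ld[a,b0] W1d[b0,s1,b1] W2d[b1,s2,b2] Rd[ar,b2]
    m <- Ld %*% matrix(W1d[, s1, ], d1[1], d1[4])
    m <- m %*% matrix(W2d[, s2, ], d2[1], d2[4])
    out[, s1, s2, ] <- m %*% t(Rd)
  }
  as.numeric(out)
}

#' Optimize an MPS by two-site DMRG sweeps
#'
#' @param mpo Hamiltonian `mpo`.
#' @param initial normalized starting `mps`.
#' @param max_bond maximum bond dimension M.
#' @param n_sweeps maximum number of full sweeps.
#' @param tol energy-change convergence threshold per sweep (Hartree).
#' @param orthogonal_to list of `mps` objects the solution must stay
#'   orthogonal to (excited-state targeting).
#' @param cutoff SVD truncation cutoff (relative).
#' @return list with `energy`, `mps`, `sweep_energies`, `discarded_weights`,
#'   `converged`.
#' @export
optimize_mps <- function(mpo, initial, max_bond = 32L, n_sweeps = 20L,
                         tol = 1e-10, orthogonal_to = list(),
                         cutoff = 1e-14) {
  L <- initial$length
  if (L == 1L) return(optimize_single_site(mpo, initial, orthogonal_to))
  psi <- mps_compress(initial, max_bond = max_bond)
  psi <- mps_normalize(psi)  # gauge at site 1
  renv <- right_boundaries(mpo, psi)
  lenv <- vector("list", L + 1L)
  lenv[[1L]] <- boundary_start()
  n_orth <- length(orthogonal_to)
  lov <- rov <- list()
  if (n_orth > 0L) {
    lov <- lapply(orthogonal_to, function(phi) {
      e <- vector("list", L + 1L); e[[1L]] <- matrix(1, 1, 1); e
    })
    rov <- lapply(orthogonal_to, function(phi) {
      e <- vector("list", L + 1L); e[[L + 1L]] <- matrix(1, 1, 1)
      for (l in L:1)
        e[[l]] <- overlap_right_env(e[[l + 1L]], phi$tensors[[l]],
                                    psi$tensors[[l]])
      e
    })
  }
  sweep_energies <- numeric(0)
  discarded <- numeric(0)
  converged <- FALSE
  psi_prev <- psi
  # davidson tolerance tightens with sweep index
  dav_tols <- pmax(1e-10, 1e-6 * 10^(-(seq_len(n_sweeps) - 1L)))
  for (sweep in seq_len(n_sweeps)) {
    disc <- 0
    # left-to-right half sweep
    for (l in seq_len(L - 1L)) {
      upd <- local_update(mpo, psi, l, lenv, renv, max_bond, cutoff,
                          orthogonal_to, lov, rov, sweep_dir = "LR",
                          dav_tol = dav_tols[sweep])
      psi <- upd$psi; lenv <- upd$lenv; renv <- upd$renv
      lov <- upd$lov; rov <- upd$rov
      disc <- disc + upd$discarded
    }
    # right-to-left half sweep
    for (l in (L - 1L):1) {
      upd <- local_update(mpo, psi, l, lenv, renv, max_bond, cutoff,
                          orthogonal_to, lov, rov, sweep_dir = "RL",
                          dav_tol = dav_tols[sweep])
      psi <- upd$psi; lenv <- upd$lenv; renv <- upd$renv
      lov <- upd$lov; rov <- upd$rov
      disc <- disc + upd$discarded
    }
    # variational energy of the (truncated, normalized) state
    e_sweep <- expectation(psi, mpo)
    if (n_orth == 0L && sweep > 1L &&
        e_sweep > sweep_energies[length(sweep_energies)] + 1e-12) {
      # truncation-induced rise near the fixed point: keep the previous
      # sweep's state so the reported trace stays variationally monotone
      psi <- psi_prev
      converged <- TRUE
      break
    }
    sweep_energies <- c(sweep_energies, e_sweep)
    discarded <- c(discarded, disc)
    psi_prev <- psi
    if (sweep > 1L &&
        abs(sweep_energies[sweep] - sweep_energies[sweep - 1L]) < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged && n_sweeps > 1L)
    warning("DMRG not converged after ", n_sweeps, " sweeps; returning best")
  psi <- mps_normalize(psi)
  psi$max_bond <- max_bond
  energy <- sweep_energies[length(sweep_energies)]
  list(energy = energy, mps = psi, sweep_energies = sweep_energies,
       discarded_weights = discarded, converged = converged)
}

optimize_single_site <- function(mpo, initial, orthogonal_to = list()) {
  H <- mpo_to_matrix(mpo)
  pr <- lapply(orthogonal_to, mps_to_vector)
  res <- davidson(function(v) as.numeric(H %*% v), nrow(H),
                  v0 = mps_to_vector(initial), project_out = pr)
  psi <- new_mps(list(array(res$vector, c(1, 4, 1))), 1L)
  list(energy = res$value, mps = psi, sweep_energies = res$value,
       discarded_weights = 0, converged = TRUE)
}

# One two-site update at bond (l, l+1); assumes gauge center at l (LR) or
# l+1 (RL) and valid lenv[1..l], renv[l+2..L+1].
local_update <- function(mpo, psi, l, lenv, renv, max_bond, cutoff,
                         orthogonal_to, lov, rov, sweep_dir, dav_tol) {
  M1 <- psi$tensors[[l]]; M2 <- psi$tensors[[l + 1L]]
  d1 <- dim(M1); d2 <- dim(M2)
  dims <- c(d1[1], 4L, 4L, d2[3])
  theta0 <- array(0, dims)
  m <- matrix(M1, d1[1] * 4L, d1[3]) %*% matrix(M2, d2[1], 4L * d2[3])
  theta0 <- array(m, dims)
  Lenv <- lenv[[l]]; Renv <- renv[[l + 2L]]
  W1 <- mpo$tensors[[l]]; W2 <- mpo$tensors[[l + 1L]]
  project_out <- list()
  n_orth <- length(orthogonal_to)
  if (n_orth > 0L) {
    for (k in seq_len(n_orth)) {
      phi <- orthogonal_to[[k]]
      P1 <- phi$tensors[[l]]; P2 <- phi$tensors[[l + 1L]]
      e1 <- dim(P1); e2 <- dim(P2)
      thphi <- array(matrix(P1, e1[1] * 4L, e1[3]) %*%
                       matrix(P2, e2[1], 4L * e2[3]),
                     c(e1[1], 4L, 4L, e2[3]))
      # g[ak-, s1, s2, ak+] = sum lov[a_phi, a_psi] theta_phi R...
      lo <- lov[[k]][[l]]; ro <- rov[[k]][[l + 2L]]
      g <- array(0, dims)
      tmp <- crossprod(lo, matrix(thphi, e1[1], 16L * e2[3]))  # (a_psi, ...)
      tmp <- array(tmp, c(d1[1], 4L, 4L, e2[3]))
      g <- array(matrix(tmp, d1[1] * 16L, e2[3]) %*% ro, dims)
      nv <- sqrt(sum(g^2))
      if (nv > 1e-14)
        project_out[[length(project_out) + 1L]] <- as.numeric(g)
    }
  }
  dg <- twosite_diag(Lenv, W1, W2, Renv)
  res <- davidson(function(v) twosite_matvec(v, Lenv, W1, W2, Renv, dims),
                  prod(dims), v0 = as.numeric(theta0), diag_A = dg,
                  tol = dav_tol, project_out = project_out)
  theta <- array(res$vector, dims)
  sv <- svd(matrix(theta, dims[1] * 4L, 4L * dims[4]))
  keep <- svd_keep(sv$d, max_bond, cutoff)
  w_disc <- sum(sv$d^2) - sum(sv$d[seq_len(keep)]^2)
  U <- sv$u[, seq_len(keep), drop = FALSE]
  V <- sv$v[, seq_len(keep), drop = FALSE]
  S <- sv$d[seq_len(keep)] / sqrt(sum(sv$d[seq_len(keep)]^2))
  if (sweep_dir == "LR") {
    psi$tensors[[l]] <- array(U, c(dims[1], 4L, keep))
    psi$tensors[[l + 1L]] <- array(t(V * rep(S, each = nrow(V)))[, , drop = FALSE],
                                   c(keep, 4L, dims[4]))
    psi$gauge_center <- l + 1L
    lenv[[l + 1L]] <- contract_left(lenv[[l]], psi$tensors[[l]],
                                    psi$tensors[[l]], W1)
    if (n_orth > 0L) for (k in seq_len(n_orth))
      lov[[k]][[l + 1L]] <- overlap_left_env(lov[[k]][[l]],
                                             orthogonal_to[[k]]$tensors[[l]],
                                             psi$tensors[[l]])
    renv[[l + 1L]] <- contract_right(renv[[l + 2L]], psi$tensors[[l + 1L]],
                                     psi$tensors[[l + 1L]], W2)
    if (n_orth > 0L) for (k in seq_len(n_orth))
      rov[[k]][[l + 1L]] <- overlap_right_env(rov[[k]][[l + 2L]],
                                              orthogonal_to[[k]]$tensors[[l + 1L]],
                                              psi$tensors[[l + 1L]])
  } else {
    US <- U * rep(S, each = nrow(U))
    psi$tensors[[l]] <- array(US, c(dims[1], 4L, keep))
    psi$tensors[[l + 1L]] <- array(t(V), c(keep, 4L, dims[4]))
    psi$gauge_center <- l
    renv[[l + 1L]] <- contract_right(renv[[l + 2L]], psi$tensors[[l + 1L]],
                                     psi$tensors[[l + 1L]], W2)
    if (n_orth > 0L) for (k in seq_len(n_orth))
      rov[[k]][[l + 1L]] <- overlap_right_env(rov[[k]][[l + 2L]],
                                              orthogonal_to[[k]]$tensors[[l + 1L]],
                                              psi$tensors[[l + 1L]])
    lenv[[l + 1L]] <- contract_left(lenv[[l]], psi$tensors[[l]],
                                    psi$tensors[[l]], W1)
    if (n_orth > 0L) for (k in seq_len(n_orth))
      lov[[k]][[l + 1L]] <- overlap_left_env(lov[[k]][[l]],
                                             orthogonal_to[[k]]$tensors[[l]],
                                             psi$tensors[[l]])
  }
  list(psi = psi, lenv = lenv, renv = renv, lov = lov, rov = rov,
       energy = res$value, discarded = w_disc)
}
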