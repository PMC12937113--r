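#' Matrix product operators
#'
#' An MPO stores one 4-index tensor per site with index order
#' (left operator bond, physical out, physical in, right operator bond).
#' Hamiltonians are assembled symbolically: every second-quantized term is a
#' product of on-site 4x4 operators with Jordan-Wigner parity strings along
#' the orbital chain; terms are summed as rank-1 MPOs in batches and the
#' running sum is recompressed by SVD, yielding an operator bond dimension
#' polynomial in the orbital count.
#'
#' @name mpo
NULL

# on-site fermionic operators in the |0>, |up>, |dn>, |updn> basis,
# with |updn> = c_up^dag c_dn^dag |0>
local_ops <- local({
  cu_dag <- matrix(0, 4, 4); cu_dag[2, 1] <- 1; cu_dag[4, 3] <- 1
  cd_dag <- matrix(0, 4, 4); cd_dag[3, 1] <- 1; cd_dag[4, 2] <- -1
  list(cu_dag = cu_dag, cu = t(cu_dag), cd_dag = cd_dag, cd = t(cd_dag),
       parity = diag(c(1, -1, -1, 1)), id = diag(4),
       n_tot = diag(c(0, 1, 1, 2)), sz2 = diag(c(0, 1, -1, 0)))
})

new_mpo <- function(tensors) {
  structure(list(tensors = tensors, length = length(tensors)), class = "mpo")
}

mpo_bond_dims <- function(op)
  c(1L, vapply(op$tensors, function(tn) dim(tn)[4], integer(1)))

#' Identity MPO
#' @param L number of sites.
#' @return an `mpo`.
#' @export
mpo_identity <- function(L)
  new_mpo(lapply(seq_len(L), function(l) array(diag(4), c(1, 4, 4, 1))))

# A term is list(coeff, ops) where ops is an ordered list of
# list(site =, mat =, fermionic = TRUE/FALSE). Returns per-site 4x4 local
# matrices of the operator product including Jordan-Wigner parities.
term_local_matrices <- function(term, L) {
  locs <- lapply(seq_len(L), function(l) diag(4))
  for (op in term$ops) {
    s <- op$site
    if (isTRUE(op$fermionic) && s > 1L)
      for (j in seq_len(s - 1L))
        locs[[j]] <- locs[[j]] %*% local_ops$parity
    locs[[s]] <- locs[[s]] %*% op$mat
  }
  locs
}

# direct-sum MPO of a batch of terms (bond dimension = batch size)
terms_to_mpo <- function(terms, L) {
  K <- length(terms)
  locs <- lapply(terms, term_local_matrices, L = L)
  coefs <- vapply(terms, function(tm) tm$coeff, numeric(1))
  if (L == 1L) {
    W <- array(0, c(1, 4, 4, 1))
    for (k in seq_len(K)) W[1, , , 1] <- W[1, , , 1] + coefs[k] * locs[[k]][[1]]
    return(new_mpo(list(W)))
  }
  tensors <- vector("list", L)
  W1 <- array(0, c(1, 4, 4, K))
  for (k in seq_len(K)) W1[1, , , k] <- coefs[k] * locs[[k]][[1]]
  tensors[[1L]] <- W1
  if (L > 2L) for (l in 2:(L - 1L)) {
    W <- array(0, c(K, 4, 4, K))
    for (k in seq_len(K)) W[k, , , k] <- locs[[k]][[l]]
    tensors[[l]] <- W
  }
  WL <- array(0, c(K, 4, 4, 1))
  for (k in seq_len(K)) WL[k, , , 1] <- locs[[k]][[L]]
  tensors[[L]] <- WL
  new_mpo(tensors)
}

#' Add two MPOs (direct sum on operator bonds)
#' @param a,b `mpo` objects of equal length.
#' @return an `mpo` representing a + b.
#' @export
mpo_add <- function(a, b) {
  L <- a$length
  stopifnot(b$length == L)
  if (L == 1L)
    return(new_mpo(list(a$tensors[[1L]] + b$tensors[[1L]])))
  tensors <- vector("list", L)
  for (l in seq_len(L)) {
    ta <- a$tensors[[l]]; tb <- b$tensors[[l]]
    da <- dim(ta); db <- dim(tb)
    if (l == 1L) {
      tn <- array(0, c(1, 4, 4, da[4] + db[4]))
      tn[, , , seq_len(da[4])] <- ta
      tn[, , , da[4] + seq_len(db[4])] <- tb
    } else if (l == L) {
      tn <- array(0, c(da[1] + db[1], 4, 4, 1))
      tn[seq_len(da[1]), , , ] <- ta
      tn[da[1] + seq_len(db[1]), , , ] <- tb
    } else {
      tn <- array(0, c(da[1] + db[1], 4, 4, da[4] + db[4]))
      tn[seq_len(da[1]), , , seq_len(da[4])] <- ta
      tn[da[1] + seq_len(db[1]), , , da[4] + seq_len(db[4])] <- tb
    }
    tensors[[l]] <- tn
  }
  new_mpo(tensors)
}

#' Compress an MPO by sweeping SVDs
#'
#' Treats the MPO as a matrix product train with fused physical dimension 16
#' and removes numerically null operator-bond directions (relative singular
#' value cutoff).
#'
#' @param op an `mpo`.
#' @param cutoff relative singular-value cutoff.
#' @return compressed `mpo`.
#' @export
mpo_compress <- function(op, cutoff = 1e-14) {
  L <- op$length
  if (L == 1L) return(op)
  tens <- op$tensors
  # left-to-right QR sweep
  for (l in seq_len(L - 1L)) {
    tn <- tens[[l]]; d <- dim(tn)
    dec <- qr_thin(matrix(tn, d[1] * 16L, d[4]))
    r <- dec$rank
    Q <- dec$Q
    R <- dec$R
    tens[[l]] <- array(Q, c(d[1], 4, 4, r))
    nxt <- tens[[l + 1L]]; dn <- dim(nxt)
    tens[[l + 1L]] <- array(R %*% matrix(nxt, dn[1], 16L * dn[4]),
                            c(r, 4, 4, dn[4]))
  }
  # right-to-left SVD sweep with truncation
  for (l in L:2) {
    tn <- tens[[l]]; d <- dim(tn)
    sv <- svd(matrix(tn, d[1], 16L * d[4]))
    keep <- svd_keep(sv$d, NULL, cutoff)
    tens[[l]] <- array(t(sv$v[, seq_len(keep), drop = FALSE]),
                       c(keep, 4, 4, d[4]))
    US <- sv$u[, seq_len(keep), drop = FALSE] %*% diag(sv$d[seq_len(keep)], keep)
    prv <- tens[[l - 1L]]; dp <- dim(prv)
    tens[[l - 1L]] <- array(matrix(prv, dp[1] * 16L, dp[4]) %*% US,
                            c(dp[1], 4, 4, keep))
  }
  new_mpo(tens)
}

# spin-orbital creation/annihilation elementary ops at orbital site
sorb_op <- function(site, spin, dagger) {
  key <- paste0("c", if (spin == 1L) "u" else "d", if (dagger) "_dag" else "")
  list(site = site, mat = local_ops[[key]], fermionic = TRUE)
}

#' Hamiltonian term list from active-space integrals
#'
#' H = sum_pq h_pq E_pq + 1/2 sum_pqrs g_pqrs (E_pq E_rs - delta_rq E_ps)
#' expanded in spin orbitals: the two-electron part becomes
#' 1/2 sum (pq|rs) a+_ps a+_rt a_st a_qs over spin labels s,t.
#'
#' @keywords internal
hamiltonian_terms <- function(ints, tol = 1e-14) {
  L <- ints$n_orbitals
  h <- ints$h; g <- ints$g
  terms <- list()
  add <- function(coeff, ops)
    terms[[length(terms) + 1L]] <<- list(coeff = coeff, ops = ops)
  for (p in seq_len(L)) for (q in seq_len(L)) {
    if (abs(h[p, q]) <= tol) next
    for (sp in 1:2)
      add(h[p, q], list(sorb_op(p, sp, TRUE), sorb_op(q, sp, FALSE)))
  }
  for (p in seq_len(L)) for (q in seq_len(L))
    for (r in seq_len(L)) for (s in seq_len(L)) {
      v <- g[p, q, r, s]
      if (abs(v) <= tol) next
      for (sp in 1:2) for (tp in 1:2)
        add(0.5 * v, list(sorb_op(p, sp, TRUE), sorb_op(r, tp, TRUE),
                          sorb_op(s, tp, FALSE), sorb_op(q, sp, FALSE)))
    }
  terms
}

#' Build the Hamiltonian MPO from active-space integrals
#'
#' @param ints an `active_space_integrals`.
#' @param batch_size number of terms summed before each recompression.
#' @param cutoff relative singular-value cutoff for MPO compression.
#' @return an `mpo`.
#' @export
build_mpo <- function(ints, batch_size = 64L, cutoff = 1e-14) {
  if (max(abs(ints$h - t(ints$h))) > 1e-9)
    stop("non-symmetric one-electron matrix")
  terms <- hamiltonian_terms(ints)
  mpo_from_terms(terms, ints$n_orbitals, batch_size, cutoff)
}

#' Build an MPO from a list of operator-string terms
#' @keywords internal
mpo_from_terms <- function(terms, L, batch_size = 64L, cutoff = 1e-14) {
  if (length(terms) == 0L) {
    op <- mpo_identity(L)
    op$tensors[[1L]] <- op$tensors[[1L]] * 0
    return(op)
  }
  acc <- NULL
  idx <- split(seq_along(terms),
               ceiling(seq_along(terms) / batch_size))
  for (piece in idx) {
    batch <- terms_to_mpo(terms[piece], L)
    acc <- if (is.null(acc)) batch else mpo_add(acc, batch)
    acc <- mpo_compress(acc, cutoff)
  }
  acc
}

#' Sector-penalty MPO
#'
#' w [ (N_hat - N)^2 + (2Sz_hat - ms2)^2 / 4 ]. Both operators commute with
#' any particle- and spin-projection-conserving Hamiltonian, so eigenvalues
#' in the targeted (N, 2Sz) sector are unchanged while every other sector is
#' shifted up by at least w.
#'
#' @param L number of sites.
#' @param n_electrons target particle number.
#' @param ms2 target 2Sz.
#' @param weight penalty strength w (Hartree).
#' @return an `mpo`.
#' @export
sector_penalty_mpo <- function(L, n_electrons, ms2 = 0L, weight = 5) {
  terms <- list()
  add <- function(coeff, ops)
    terms[[length(terms) + 1L]] <<- list(coeff = coeff, ops = ops)
  nt <- local_ops$n_tot; sz <- local_ops$sz2
  for (i in seq_len(L)) for (j in seq_len(L)) {
    if (i == j) {
      add(weight, list(list(site = i, mat = nt %*% nt, fermionic = FALSE)))
      add(weight / 4, list(list(site = i, mat = sz %*% sz, fermionic = FALSE)))
    } else {
      add(weight, list(list(site = i, mat = nt, fermionic = FALSE),
                       list(site = j, mat = nt, fermionic = FALSE)))
      add(weight / 4, list(list(site = i, mat = sz, fermionic = FALSE),
                           list(site = j, mat = sz, fermionic = FALSE)))
    }
  }
  for (i in seq_len(L)) {
    add(-2 * weight * n_electrons,
        list(list(site = i, mat = nt, fermionic = FALSE)))
    add(-2 * weight * ms2 / 4,
        list(list(site = i, mat = sz, fermionic = FALSE)))
  }
  add(weight * (n_electrons^2 + ms2^2 / 4),
      list(list(site = 1L, mat = diag(4), fermionic = FALSE)))
  mpo_from_terms(terms, L)
}

#' Total-spin operator as an MPO
#'
#' S^2 = Sz^2 + Sz + S- S+ assembled from operator strings. Multiplied by a
#' positive weight it acts as a singlet-targeting penalty: singlets are
#' unaffected, every S > 0 state is shifted up by at least 2w.
#'
#' @param L number of sites.
#' @param weight scale factor w.
#' @return an `mpo`.
#' @export
spin_squared_mpo <- function(L, weight = 1) {
  sz <- local_ops$sz2 / 2
  terms <- list()
  add <- function(coeff, ops)
    terms[[length(terms) + 1L]] <<- list(coeff = coeff, ops = ops)
  for (p in seq_len(L)) for (q in seq_len(L)) {
    if (p == q)
      add(weight, list(list(site = p, mat = sz %*% sz, fermionic = FALSE)))
    else
      add(weight, list(list(site = p, mat = sz, fermionic = FALSE),
                       list(site = q, mat = sz, fermionic = FALSE)))
    add(weight, list(sorb_op(p, 2L, TRUE), sorb_op(p, 1L, FALSE),
                     sorb_op(q, 1L, TRUE), sorb_op(q, 2L, FALSE)))
  }
  for (p in seq_len(L))
    add(weight, list(list(site = p, mat = sz, fermionic = FALSE)))
  mpo_from_terms(terms, L)
}

#' Densify an MPO into a full Fock-space matrix
#'
#' Basis ordering matches [mps_to_vector()] (site 1 fastest). Intended for
#' small L only.
#'
#' @param op an `mpo`.
#' @return dense 4^L x 4^L matrix.
#' @export
mpo_to_matrix <- function(op) {
  L <- op$length
  # accumulate over bond: list over right-bond index of dense operators
  tn <- op$tensors[[1L]]
  d <- dim(tn)
  acc <- lapply(seq_len(d[4]), function(b) matrix(tn[1, , , b], 4, 4))
  if (L > 1L) for (l in 2:L) {
    tn <- op$tensors[[l]]
    d <- dim(tn)
    nxt <- vector("list", d[4])
    for (b2 in seq_len(d[4])) {
      m <- NULL
      for (b1 in seq_len(d[1])) {
        w <- matrix(tn[b1, , , b2], 4, 4)
        if (max(abs(w)) == 0) next
        term <- kronecker(w, acc[[b1]])  # site 1 fastest
        m <- if (is.null(m)) term else m + term
      }
      if (is.null(m)) m <- matrix(0, 4^l, 4^l)
      nxt[[b2]] <- m
    }
    acc <- nxt
  }
  acc[[1L]]
}
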