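# Independent dense Fock-space oracle.
# Builds second-quantized operators as explicit Kronecker products with
# Jordan-Wigner parity strings (basis |0>,|up>,|dn>,|updn> per site, site 1
# fastest), independently of the package's symbolic MPO machinery.

oracle_local <- local({
  au <- matrix(0, 4, 4); au[2, 1] <- 1; au[4, 3] <- 1   # a_up^dag
  ad <- matrix(0, 4, 4); ad[3, 1] <- 1; ad[4, 2] <- -1  # a_dn^dag
  list(au_dag = au, ad_dag = ad, par = diag(c(1, -1, -1, 1)))
})

# creation operator for spin-orbital (site, spin) on L sites
oracle_creator <- function(L, site, spin) {
  op <- if (spin == 1L) oracle_local$au_dag else oracle_local$ad_dag
  jw <- Matrix::Diagonal(1)
  if (site > 1L) for (k in seq_len(site - 1L))
    jw <- Matrix::kronecker(Matrix::Matrix(oracle_local$par, sparse = TRUE), jw)
  full <- Matrix::kronecker(Matrix::Matrix(op, sparse = TRUE), jw)
  post <- 4^(L - site)
  if (post > 1) full <- Matrix::kronecker(Matrix::Diagonal(post), full)
  full
}

oracle_ops <- function(L) {
  cu <- lapply(seq_len(L), oracle_creator, L = L, spin = 1L)
  cd <- lapply(seq_len(L), oracle_creator, L = L, spin = 2L)
  list(cu = cu, cd = cd)
}

# dense Fock-space Hamiltonian (without core energy) from integrals
oracle_hamiltonian <- function(ints, ops = NULL) {
  L <- ints$n_orbitals
  if (is.null(ops)) ops <- oracle_ops(L)
  dim_f <- 4^L
  H <- Matrix::Matrix(0, dim_f, dim_f, sparse = TRUE)
  E <- function(p, q) ops$cu[[p]] %*% Matrix::t(ops$cu[[q]]) +
    ops$cd[[p]] %*% Matrix::t(ops$cd[[q]])
  Ecache <- list()
  Eget <- function(p, q) {
    key <- paste(p, q)
    if (is.null(Ecache[[key]])) Ecache[[key]] <<- E(p, q)
    Ecache[[key]]
  }
  for (p in seq_len(L)) for (q in seq_len(L)) {
    if (abs(ints$h[p, q]) > 1e-15) H <- H + ints$h[p, q] * Eget(p, q)
  }
  for (p in seq_len(L)) for (q in seq_len(L))
    for (r in seq_len(L)) for (s in seq_len(L)) {
      v <- ints$g[p, q, r, s]
      if (abs(v) < 1e-15) next
      term <- Eget(p, q) %*% Eget(r, s)
      if (r == q) term <- term - Eget(p, s)
      H <- H + 0.5 * v * term
    }
  H
}

# particle number and 2Sz labels of the Fock basis (site 1 fastest)
oracle_sector_labels <- function(L) {
  nup_loc <- c(0L, 1L, 0L, 1L); ndn_loc <- c(0L, 0L, 1L, 1L)
  idx <- 0:(4^L - 1)
  nup <- integer(length(idx)); ndn <- integer(length(idx))
  rem <- idx
  for (l in seq_len(L)) {
    d <- rem %% 4L
    nup <- nup + nup_loc[d + 1L]
    ndn <- ndn + ndn_loc[d + 1L]
    rem <- rem %/% 4L
  }
  list(n = nup + ndn, sz2 = nup - ndn)
}

# exact eigenvalues (ascending) within an (N, 2Sz) sector, plus vectors
oracle_fci <- function(ints, n_roots = 2L) {
  H <- oracle_hamiltonian(ints)
  lab <- oracle_sector_labels(ints$n_orbitals)
  sel <- which(lab$n == ints$n_electrons & lab$sz2 == ints$ms2)
  Hs <- as.matrix(H[sel, sel, drop = FALSE])
  es <- eigen((Hs + t(Hs)) / 2, symmetric = TRUE)
  ord <- order(es$values)
  k <- min(n_roots, length(sel))
  vecs <- matrix(0, 4^ints$n_orbitals, k)
  for (j in seq_len(k)) vecs[sel, j] <- es$vectors[, ord[j]]
  list(values = es$values[ord[seq_len(k)]] + ints$core_energy,
       values_electronic = es$values[ord[seq_len(k)]],
       vectors = vecs, sector_dim = length(sel))
}
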