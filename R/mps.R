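#' Matrix product states
#'
#' An MPS stores one 3-index tensor per active orbital with index order
#' (left bond, physical, right bond); the physical dimension is 4 with local
#' occupation basis |0>, |up>, |dn>, |updn>. Boundary bonds have dimension 1.
#' The gauge center marks the site up to which tensors are left-orthogonal
#' (sites < center) and from which they are right-orthogonal (sites >
#' center).
#'
#' @name mps
NULL

PHYS_DIM <- 4L
# per-site occupation labels of the local basis: (n_up, n_dn)
LOCAL_NUP <- c(0L, 1L, 0L, 1L)
LOCAL_NDN <- c(0L, 0L, 1L, 1L)

new_mps <- function(tensors, gauge_center = 1L, max_bond = NULL) {
  structure(list(tensors = tensors, gauge_center = as.integer(gauge_center),
                 max_bond = max_bond, length = length(tensors)),
            class = "mps")
}

mps_bond_dims <- function(psi) {
  c(1L, vapply(psi$tensors, function(tn) dim(tn)[3], integer(1)))
}

#' Product-state MPS from per-site occupations
#'
#' @param occ integer vector in 1..4 per site indexing the local basis
#'   |0>, |up>, |dn>, |updn>.
#' @return an `mps` (normalized, bond dimension 1).
#' @export
product_mps <- function(occ) {
  tensors <- lapply(occ, function(s) {
    tn <- array(0, c(1L, PHYS_DIM, 1L)); tn[1L, s, 1L] <- 1; tn
  })
  new_mps(tensors, gauge_center = length(occ))
}

#' Random MPS in a fixed (N, 2Sz) sector
#'
#' Builds a seeded random linear combination of product states with the
#' requested particle number and spin projection, compressed to at most
#' `max_bond`. Deterministic given the RNG state.
#'
#' @param L number of sites.
#' @param n_electrons target particle number.
#' @param ms2 target 2Sz.
#' @param max_bond bond-dimension cap.
#' @param n_components number of random determinants to combine.
#' @return a normalized `mps`.
#' @export
random_sector_mps <- function(L, n_electrons, ms2 = 0L, max_bond = 16L,
                              n_components = 8L) {
  occs <- sector_occupations(L, n_electrons, ms2)
  if (nrow(occs) == 0L) stop("empty (N, 2Sz) sector")
  pick <- sample.int(nrow(occs), min(n_components, nrow(occs)))
  psi <- NULL
  for (k in pick) {
    contrib <- product_mps(occs[k, ])
    coef <- stats::rnorm(1)
    contrib$tensors[[1L]] <- contrib$tensors[[1L]] * coef
    psi <- if (is.null(psi)) contrib else mps_add(psi, contrib)
  }
  psi <- mps_compress(psi, max_bond = max_bond)
  mps_normalize(psi)
}

# enumerate local-basis index vectors of a sector (small L only)
sector_occupations <- function(L, n_electrons, ms2) {
  grid <- as.matrix(expand.grid(rep(list(1:4), L)))
  nup <- rowSums(matrix(LOCAL_NUP[grid], nrow(grid)))
  ndn <- rowSums(matrix(LOCAL_NDN[grid], nrow(grid)))
  grid[nup + ndn == n_electrons & nup - ndn == ms2, , drop = FALSE]
}

#' Add two MPSs (direct sum on bonds)
#' @param a,b `mps` objects of equal length.
#' @return unnormalized `mps` representing a + b.
#' @export
mps_add <- function(a, b) {
  L <- a$length
  stopifnot(b$length == L)
  if (L == 1L)
    return(new_mps(list(a$tensors[[1L]] + b$tensors[[1L]])))
  tensors <- vector("list", L)
  for (l in seq_len(L)) {
    ta <- a$tensors[[l]]; tb <- b$tensors[[l]]
    da <- dim(ta); db <- dim(tb)
    if (l == 1L) {
      tn <- array(0, c(1L, PHYS_DIM, da[3] + db[3]))
      tn[, , seq_len(da[3])] <- ta
      tn[, , da[3] + seq_len(db[3])] <- tb
    } else if (l == L) {
      tn <- array(0, c(da[1] + db[1], PHYS_DIM, 1L))
      tn[seq_len(da[1]), , ] <- ta
      tn[da[1] + seq_len(db[1]), , ] <- tb
    } else {
      tn <- array(0, c(da[1] + db[1], PHYS_DIM, da[3] + db[3]))
      tn[seq_len(da[1]), , seq_len(da[3])] <- ta
      tn[da[1] + seq_len(db[1]), , da[3] + seq_len(db[3])] <- tb
    }
    tensors[[l]] <- tn
  }
  new_mps(tensors, gauge_center = 1L)
}

# thin QR with column-pivot correction so that m == Q %*% R exactly;
# LAPACK householder QR, with an SVD fallback for pathological inputs
qr_thin <- function(m) {
  r <- min(dim(m))
  qrm <- tryCatch(qr(m, LAPACK = TRUE), error = function(e) NULL)
  if (!is.null(qrm)) {
    Q <- qr.Q(qrm)[, seq_len(r), drop = FALSE]
    R <- qr.R(qrm)[seq_len(r), , drop = FALSE]
    if (all(is.finite(Q)) && all(is.finite(R))) {
      R <- R[, order(qrm$pivot), drop = FALSE]
      return(list(Q = Q, R = R, rank = r))
    }
  }
  sv <- svd(m, nu = r, nv = r)
  list(Q = sv$u, R = sv$d[seq_len(r)] * t(sv$v), rank = r)
}

# left-orthogonalize site l, pushing the remainder right (QR)
push_right <- function(psi, l) {
  tn <- psi$tensors[[l]]
  d <- dim(tn)
  dec <- qr_thin(matrix(tn, d[1] * d[2], d[3]))
  r <- dec$rank
  Q <- dec$Q
  R <- dec$R
  psi$tensors[[l]] <- array(Q, c(d[1], d[2], r))
  nxt <- psi$tensors[[l + 1L]]
  dn <- dim(nxt)
  psi$tensors[[l + 1L]] <- array(R %*% matrix(nxt, dn[1], dn[2] * dn[3]),
                                 c(r, dn[2], dn[3]))
  psi
}

# right-orthogonalize site l, pushing the remainder left (LQ via QR)
push_left <- function(psi, l) {
  tn <- psi$tensors[[l]]
  d <- dim(tn)
  m <- matrix(tn, d[1], d[2] * d[3])
  dec <- qr_thin(t(m))
  r <- dec$rank
  Q <- dec$Q
  R <- dec$R
  psi$tensors[[l]] <- array(t(Q), c(r, d[2], d[3]))
  prv <- psi$tensors[[l - 1L]]
  dp <- dim(prv)
  psi$tensors[[l - 1L]] <- array(matrix(prv, dp[1] * dp[2], dp[3]) %*% t(R),
                                 c(dp[1], dp[2], r))
  psi
}

#' Move the gauge center of an MPS
#' @param psi an `mps`.
#' @param center target site.
#' @return `mps` in mixed-canonical form about `center`.
#' @export
mps_gauge <- function(psi, center) {
  center <- as.integer(center)
  while (psi$gauge_center < center) {
    psi <- push_right(psi, psi$gauge_center)
    psi$gauge_center <- psi$gauge_center + 1L
  }
  while (psi$gauge_center > center) {
    psi <- push_left(psi, psi$gauge_center)
    psi$gauge_center <- psi$gauge_center - 1L
  }
  psi
}

#' Canonicalize and truncate an MPS by successive SVDs
#'
#' @param psi an `mps`.
#' @param max_bond bond-dimension cap M (NULL for no cap).
#' @param cutoff relative singular-value cutoff.
#' @return truncated `mps` with gauge at site 1.
#' @export
mps_compress <- function(psi, max_bond = NULL, cutoff = 1e-14) {
  L <- psi$length
  psi <- mps_gauge(psi, L)
  if (L == 1L) return(psi)
  for (l in L:2) {
    tn <- psi$tensors[[l]]
    d <- dim(tn)
    sv <- svd(matrix(tn, d[1], d[2] * d[3]))
    keep <- svd_keep(sv$d, max_bond, cutoff)
    psi$tensors[[l]] <- array(t(sv$v[, seq_len(keep), drop = FALSE]),
                              c(keep, d[2], d[3]))
    US <- sv$u[, seq_len(keep), drop = FALSE] %*%
      diag(sv$d[seq_len(keep)], keep)
    prv <- psi$tensors[[l - 1L]]
    dp <- dim(prv)
    psi$tensors[[l - 1L]] <- array(matrix(prv, dp[1] * dp[2], dp[3]) %*% US,
                                   c(dp[1], dp[2], keep))
  }
  psi$gauge_center <- 1L
  psi
}

# deterministic truncation rank: singular values above cutoff, capped at M
svd_keep <- function(s, max_bond, cutoff = 1e-14) {
  smax <- if (length(s) > 0L) s[1] else 0
  keep <- sum(s > smax * cutoff)
  keep <- max(keep, 1L)
  if (!is.null(max_bond)) keep <- min(keep, max_bond)
  keep
}

#' Norm of an MPS
#' @param psi an `mps`.
#' @return sqrt(<psi|psi>).
#' @export
mps_norm <- function(psi) sqrt(abs(mps_overlap(psi, psi)))

#' Normalize an MPS
#' @param psi an `mps`.
#' @return normalized `mps` (scaling absorbed at the gauge center).
#' @export
mps_normalize <- function(psi) {
  nrm <- mps_norm(psi)
  if (nrm < 1e-300) stop("cannot normalize a zero MPS")
  psi$tensors[[psi$gauge_center]] <- psi$tensors[[psi$gauge_center]] / nrm
  psi
}

#' Overlap of two MPSs
#' @param a,b `mps` objects of equal length.
#' @return <a|b>.
#' @export
mps_overlap <- function(a, b) {
  L <- a$length
  stopifnot(b$length == L)
  E <- matrix(1, 1, 1)
  for (l in seq_len(L)) {
    ta <- a$tensors[[l]]; tb <- b$tensors[[l]]
    da <- dim(ta); db <- dim(tb)
    Enew <- matrix(0, da[3], db[3])
    for (s in seq_len(PHYS_DIM)) {
      As <- matrix(ta[, s, ], da[1], da[3])
      Bs <- matrix(tb[, s, ], db[1], db[3])
      Enew <- Enew + t(As) %*% E %*% Bs
    }
    E <- Enew
  }
  E[1, 1]
}

#' Densify an MPS into a full state vector
#'
#' Index convention: the coefficient of |s1 ... sL> sits at position
#' 1 + sum_l (s_l - 1) 4^(l-1) (site 1 fastest). Intended for small L.
#'
#' @param psi an `mps`.
#' @return numeric vector of length 4^L.
#' @export
mps_to_vector <- function(psi) {
  L <- psi$length
  acc <- matrix(1, 1, 1)  # (config, bond)
  for (l in seq_len(L)) {
    tn <- psi$tensors[[l]]
    d <- dim(tn)
    # acc: (n_conf, d1) ; tensor: (d1, phys*right)
    nxt <- acc %*% matrix(tn, d[1], d[2] * d[3])
    # nxt: (n_conf, phys, right) -> (n_conf*phys, right)
    acc <- matrix(nxt, nrow(acc) * d[2], d[3])
  }
  as.numeric(acc)
}

#' Check the canonical-form invariants of an MPS
#'
#' @param psi an `mps`.
#' @return max deviation from orthogonality identities over all sites.
#' @export
mps_gauge_error <- function(psi) {
  err <- 0
  for (l in seq_len(psi$length)) {
    tn <- psi$tensors[[l]]
    d <- dim(tn)
    if (l < psi$gauge_center) {
      m <- matrix(tn, d[1] * d[2], d[3])
      err <- max(err, max(abs(crossprod(m) - diag(d[3]))))
    } else if (l > psi$gauge_center) {
      m <- matrix(tn, d[1], d[2] * d[3])
      err <- max(err, max(abs(tcrossprod(m) - diag(d[1]))))
    }
  }
  err
}

#' Per-site particle-number and spin-projection expectations
#' @param psi a normalized `mps`.
#' @return list with totals `n` and `sz2` (2Sz).
#' @keywords internal
mps_quantum_numbers <- function(psi) {
  nop <- diag(LOCAL_NUP + LOCAL_NDN)
  szop <- diag(LOCAL_NUP - LOCAL_NDN)
  n <- 0; sz2 <- 0
  for (l in seq_len(psi$length)) {
    n <- n + mps_local_expectation(psi, l, nop)
    sz2 <- sz2 + mps_local_expectation(psi, l, szop)
  }
  list(n = n, sz2 = sz2)
}

mps_local_expectation <- function(psi, site, op) {
  psi <- mps_gauge(psi, site)
  tn <- psi$tensors[[site]]
  d <- dim(tn)
  val <- 0
  for (s in seq_len(PHYS_DIM)) for (sp in seq_len(PHYS_DIM)) {
    if (op[s, sp] == 0) next
    val <- val + op[s, sp] *
      sum(matrix(tn[, s, ], d[1], d[3]) * matrix(tn[, sp, ], d[1], d[3]))
  }
  val
}

#' Save an MPS checkpoint
#'
#' Stores site tensors, gauge data and metadata (orbital order, seed) in an
#' RDS container.
#'
#' @param psi an `mps`.
#' @param path output path.
#' @param metadata optional list stored alongside the tensors.
#' @export
save_mps <- function(psi, path, metadata = list()) {
  saveRDS(list(tensors = psi$tensors, gauge_center = psi$gauge_center,
               max_bond = psi$max_bond, metadata = metadata), path)
  invisible(path)
}

#' Load an MPS checkpoint
#' @param path checkpoint path.
#' @return list with `mps` and `metadata`.
#' @export
load_mps <- function(path) {
  obj <- readRDS(path)
  list(mps = new_mps(obj$tensors, obj$gauge_center, obj$max_bond),
       metadata = obj$metadata)
}
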