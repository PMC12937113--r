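#' Reduced density matrices from an MPS
#'
#' The one-particle density D_pq = <E_pq> and the two-particle density
#' P_pqrs = <E_pq E_rs - delta_rq E_ps> (spin-summed, chemist index order,
#' matching the Hamiltonian h.D + 1/2 g.P + core energy reconstruction) are
#' evaluated as expectations of Jordan-Wigner operator strings over the MPS.
#' The state is brought to left-canonical form once, so each string costs a
#' single transfer-matrix pass over its support.
#'
#' @name rdm
NULL

# right identity environments rho[[l]] (a_l x a_l) for a left-canonical MPS:
# contraction of sites l+1..L of <psi|psi>
right_identity_envs <- function(psi) {
  L <- psi$length
  rho <- vector("list", L + 1L)
  rho[[L + 1L]] <- matrix(1, 1, 1)
  for (l in L:1) {
    tn <- psi$tensors[[l]]
    d <- dim(tn)
    acc <- matrix(0, d[1], d[1])
    for (s in 1:4) {
      Ms <- matrix(tn[, s, ], d[1], d[3])
      acc <- acc + Ms %*% rho[[l + 1L]] %*% t(Ms)
    }
    rho[[l]] <- acc
  }
  rho
}

# expectation of a product of local operators (term format of mpo.R) over a
# left-canonical MPS with precomputed right identity environments
string_expectation <- function(psi, rho, term) {
  L <- psi$length
  sites <- vapply(term$ops, function(o) o$site, integer(1))
  s1 <- min(sites); s2 <- max(sites)
  locs <- term_local_matrices(term, L)
  E <- diag(dim(psi$tensors[[s1]])[1])  # left-canonical: identity env at cut
  for (l in s1:s2) {
    tn <- psi$tensors[[l]]
    d <- dim(tn)
    O <- locs[[l]]
    Enew <- matrix(0, d[3], d[3])
    for (sb in 1:4) {
      Mb <- matrix(tn[, sb, ], d[1], d[3])
      for (sk in 1:4) {
        if (O[sb, sk] == 0) next
        Mk <- matrix(tn[, sk, ], d[1], d[3])
        Enew <- Enew + O[sb, sk] * (t(Mb) %*% E %*% Mk)
      }
    }
    E <- Enew
  }
  term$coeff * sum(E * rho[[s2 + 1L]])
}

#' One- and two-particle reduced density matrices
#'
#' @param psi a normalized `mps`.
#' @return list of class `density_matrices` with `one_particle` (D),
#'   `two_particle` (P) and `n_electrons` = trace(D).
#' @export
compute_rdms <- function(psi) {
  L <- psi$length
  psi <- mps_gauge(psi, L)
  psi <- mps_normalize(psi)
  rho <- right_identity_envs(psi)
  Dm <- matrix(0, L, L)
  for (p in seq_len(L)) for (q in seq_len(p)) {
    val <- 0
    for (sp in 1:2)
      val <- val + string_expectation(psi, rho, list(coeff = 1, ops = list(
        sorb_op(p, sp, TRUE), sorb_op(q, sp, FALSE))))
    Dm[p, q] <- val; Dm[q, p] <- val
  }
  E2 <- array(NA_real_, c(L, L, L, L))
  lin <- function(p, q, r, s) ((p - 1L) * L + q - 1L) * L * L + (r - 1L) * L + s
  for (p in seq_len(L)) for (q in seq_len(L))
    for (r in seq_len(L)) for (s in seq_len(L)) {
      if (!is.na(E2[p, q, r, s])) next
      val <- 0
      for (sp in 1:2) for (tp in 1:2)
        val <- val + string_expectation(psi, rho, list(coeff = 1, ops = list(
          sorb_op(p, sp, TRUE), sorb_op(q, sp, FALSE),
          sorb_op(r, tp, TRUE), sorb_op(s, tp, FALSE))))
      E2[p, q, r, s] <- val
      # real wave function: <(E_pq E_rs)^dag> = <E_sr E_qp>
      if (is.na(E2[s, r, q, p])) E2[s, r, q, p] <- val
    }
  P <- E2
  for (q in seq_len(L))
    P[, q, q, ] <- P[, q, q, ] - Dm
  structure(list(one_particle = Dm, two_particle = P,
                 n_electrons = sum(diag(Dm))),
            class = "density_matrices")
}

#' Energy from density matrices and integrals
#'
#' E = sum h.D + 1/2 sum g.P + core_energy; equals the MPO expectation for
#' the state the densities came from.
#'
#' @param rdms a `density_matrices`.
#' @param ints an `active_space_integrals`.
#' @return energy in Hartree.
#' @export
rdm_energy <- function(rdms, ints) {
  sum(ints$h * rdms$one_particle) +
    0.5 * sum(ints$g * rdms$two_particle) + ints$core_energy
}

#' Total-spin expectation <S^2> of an MPS
#'
#' <S^2> = Sz(Sz + 1) + <S- S+> with S+ = sum_p a+_p,up a_p,dn evaluated as
#' operator strings.
#'
#' @param psi a normalized `mps`.
#' @return scalar <S^2>.
#' @export
spin_squared <- function(psi) {
  L <- psi$length
  psi <- mps_gauge(psi, L)
  psi <- mps_normalize(psi)
  rho <- right_identity_envs(psi)
  sz <- 0
  for (p in seq_len(L))
    sz <- sz + string_expectation(psi, rho, list(coeff = 0.5, ops = list(
      list(site = p, mat = local_ops$sz2, fermionic = FALSE))))
  smsp <- 0
  for (p in seq_len(L)) for (q in seq_len(L))
    smsp <- smsp + string_expectation(psi, rho, list(coeff = 1, ops = list(
      sorb_op(p, 2L, TRUE), sorb_op(p, 1L, FALSE),
      sorb_op(q, 1L, TRUE), sorb_op(q, 2L, FALSE))))
  sz * (sz + 1) + smsp
}

#' Fiedler ordering of active orbitals
#'
#' Builds the exchange-coupling graph with weights w_pq = |K_pq| = |(pq|qp)|,
#' forms its Laplacian and sorts orbitals by the Fiedler vector (eigenvector
#' of the second-smallest Laplacian eigenvalue). Disconnected components are
#' ordered independently (warning emitted) and concatenated by their smallest
#' original index. Ties broken by ascending orbital index; overall direction
#' fixed so the first orbital index precedes the last.
#'
#' @param ints an `active_space_integrals`.
#' @return integer permutation of 1..L.
#' @export
fiedler_order <- function(ints) {
  L <- ints$n_orbitals
  if (L < 2L) return(seq_len(L))
  w <- abs(sapply(seq_len(L), function(q)
    sapply(seq_len(L), function(p) ints$g[p, q, q, p])))
  diag(w) <- 0
  comps <- graph_components(w > 1e-12)
  if (length(comps) > 1L)
    warning("disconnected orbital coupling graph; ordering components independently")
  out <- integer(0)
  for (comp in comps[order(vapply(comps, min, integer(1)))]) {
    if (length(comp) == 1L) { out <- c(out, comp); next }
    wsub <- w[comp, comp, drop = FALSE]
    lap <- diag(rowSums(wsub)) - wsub
    es <- eigen((lap + t(lap)) / 2, symmetric = TRUE)
    fv <- es$vectors[, length(comp) - 1L]
    ord <- order(fv, seq_along(comp))
    perm <- comp[ord]
    if (perm[1L] > perm[length(perm)]) perm <- rev(perm)
    out <- c(out, perm)
  }
  out
}

graph_components <- function(adj) {
  n <- nrow(adj)
  seen <- rep(FALSE, n)
  comps <- list()
  for (v in seq_len(n)) {
    if (seen[v]) next
    queue <- v; seen[v] <- TRUE; comp <- integer(0)
    while (length(queue) > 0L) {
      u <- queue[1L]; queue <- queue[-1L]
      comp <- c(comp, u)
      nb <- which(adj[u, ] & !seen)
      seen[nb] <- TRUE
      queue <- c(queue, nb)
    }
    comps[[length(comps) + 1L]] <- sort(comp)
  }
  comps
}

#' Permute the orbitals of an integral set
#'
#' @param ints an `active_space_integrals`.
#' @param perm permutation of 1..L.
#' @return permuted `active_space_integrals`.
#' @export
permute_integrals <- function(ints, perm) {
  active_space_integrals(ints$h[perm, perm],
                         ints$g[perm, perm, perm, perm],
                         ints$core_energy, ints$n_electrons, ints$ms2)
}
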