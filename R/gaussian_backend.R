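#' Minimal s-type Gaussian integral backend
#'
#' Analytic one- and two-electron integrals over contracted s-type Gaussian
#' shells: overlap, kinetic energy, nuclear attraction, point-charge
#' electrostatic-potential matrices and electron-repulsion integrals. All
#' closed forms reduce to the zeroth-order Boys function
#' F0(t) = 0.5 sqrt(pi/t) erf(sqrt(t)). Intended for compact model systems;
#' the basis sets shipped with the package are synthetic minimal sets.
#'
#' A "backend" in this package is anything producing AO overlap, core
#' Hamiltonian, ERI and 1/|r-c| matrices for a molecule and basis; FCIDUMP
#' import bypasses the backend entirely.
#'
#' @name gaussian_backend
NULL

boys_f0 <- function(t) {
  out <- numeric(length(t))
  small <- t < 1e-10
  out[small] <- 1 - t[small] / 3
  tb <- t[!small]
  # erf via pnorm to stay in base R
  out[!small] <- 0.5 * sqrt(pi / tb) * (2 * stats::pnorm(sqrt(2 * tb)) - 1)
  out
}

#' Define a basis of contracted s shells
#'
#' @param shells list of shells; each shell is a list with `center`
#'   (3-vector, Bohr), `exponents`, `coefficients` (contraction, applied to
#'   normalized primitives).
#' @return object of class `s_basis`.
#' @export
s_basis <- function(shells) {
  for (sh in shells) {
    if (length(sh$exponents) != length(sh$coefficients))
      stop("exponents/coefficients length mismatch in shell")
    if (any(sh$exponents <= 0)) stop("Gaussian exponents must be positive")
  }
  structure(list(shells = shells), class = "s_basis")
}

#' Built-in synthetic minimal s-only basis sets
#'
#' `"sto3g.s"`: STO-3G-style 3-primitive contractions for H and He;
#' heavier elements get a single 1s-like contraction plus a diffuse s
#' function (synthetic, for model studies only). `"minimal.s"`: one
#' contracted shell per atom.
#'
#' @param elements element labels.
#' @param positions n x 3 positions in Bohr.
#' @param name basis name.
#' @return an `s_basis`.
#' @export
build_basis <- function(elements, positions, name = "sto3g.s") {
  positions <- as.matrix(positions)
  h_exp <- c(3.42525091, 0.62391373, 0.16885540)
  h_coef <- c(0.15432897, 0.53532814, 0.44463454)
  he_exp <- c(6.36242139, 1.15892300, 0.31364979)
  shells <- list()
  add <- function(center, ex, co)
    shells[[length(shells) + 1L]] <<- list(center = center, exponents = ex,
                                           coefficients = co)
  for (i in seq_along(elements)) {
    el <- elements[i]; c0 <- positions[i, ]
    if (name == "minimal.s") {
      z <- element_charge(el)
      add(c0, h_exp * z^2 / 1.24^2, h_coef)
    } else if (name == "sto3g.s") {
      if (el == "H") add(c0, h_exp, h_coef)
      else if (el == "He") add(c0, he_exp, h_coef)
      else {
        z <- element_charge(el)
        add(c0, h_exp * z^2 / 1.24^2, h_coef)  # core-like s
        add(c0, h_exp * (z / 4 + 0.5)^2 / 1.24^2, h_coef)  # valence-like s
      }
    } else stop("unknown basis name: ", name)
  }
  s_basis(shells)
}

element_charge <- function(el) {
  z <- match(el, c("H", "He", "Li", "Be", "B", "C", "N", "O", "F", "Ne"))
  if (is.na(z)) stop("unknown element label: ", el)
  z
}

prim_norm <- function(a) (2 * a / pi)^0.75

# pairwise primitive tables for two shells
shell_pair <- function(sa, sb) {
  ga <- sa$exponents; gb <- sb$exponents
  ca <- sa$coefficients * prim_norm(ga)
  cb <- sb$coefficients * prim_norm(gb)
  p <- outer(ga, gb, `+`)
  mu <- outer(ga, gb) / p
  r2 <- sum((sa$center - sb$center)^2)
  K <- exp(-mu * r2)
  # Gaussian product centers, one (i,j, xyz) at a time
  list(ga = ga, gb = gb, ca = ca, cb = cb, p = p, mu = mu, r2 = r2, K = K,
       A = sa$center, B = sb$center)
}

pair_centers <- function(sp) {
  # array npa x npb x 3 of product centers
  npa <- length(sp$ga); npb <- length(sp$gb)
  P <- array(0, c(npa, npb, 3L))
  for (k in 1:3)
    P[, , k] <- (outer(sp$ga, rep(1, npb)) * sp$A[k] +
                 outer(rep(1, npa), sp$gb) * sp$B[k]) / sp$p
  P
}

#' AO integrals for an s-only basis
#'
#' @param basis an `s_basis`.
#' @param nuclei list with `Z` (charges) and `positions` (n x 3, Bohr).
#' @return list with `S`, `T`, `Vne`, `hcore` = T + Vne, `eri`
#'   (4-index array, chemist convention (pq|rs)), `n_ao`,
#'   `nuclear_repulsion`.
#' @export
ao_integrals <- function(basis, nuclei) {
  sh <- basis$shells
  n <- length(sh)
  S <- matrix(0, n, n); Tm <- matrix(0, n, n); V <- matrix(0, n, n)
  pairs <- vector("list", n * n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    sp <- shell_pair(sh[[i]], sh[[j]])
    pairs[[(i - 1L) * n + j]] <- sp
    w <- outer(sp$ca, sp$cb) * sp$K
    s_ij <- (pi / sp$p)^1.5
    S[i, j] <- sum(w * s_ij)
    Tm[i, j] <- sum(w * s_ij * sp$mu * (3 - 2 * sp$mu * sp$r2))
    P <- pair_centers(sp)
    vsum <- 0
    for (k in seq_along(nuclei$Z)) {
      rpc2 <- (P[, , 1] - nuclei$positions[k, 1])^2 +
              (P[, , 2] - nuclei$positions[k, 2])^2 +
              (P[, , 3] - nuclei$positions[k, 3])^2
      vsum <- vsum - nuclei$Z[k] *
        sum(w * (2 * pi / sp$p) * boys_f0(sp$p * rpc2))
    }
    V[i, j] <- vsum
  }
  eri <- array(0, c(n, n, n, n))
  for (i in seq_len(n)) for (j in seq_len(i)) {
    spij <- pairs[[(i - 1L) * n + j]]
    Pij <- pair_centers(spij)
    wij <- outer(spij$ca, spij$cb) * spij$K
    for (k in seq_len(n)) for (l in seq_len(k)) {
      if ((k - 1L) * k / 2 + l > (i - 1L) * i / 2 + j) next
      spkl <- pairs[[(k - 1L) * n + l]]
      Pkl <- pair_centers(spkl)
      wkl <- outer(spkl$ca, spkl$cb) * spkl$K
      val <- 0
      for (a in seq_along(spij$ga)) for (b in seq_along(spij$gb)) {
        p <- spij$p[a, b]
        for (c0 in seq_along(spkl$ga)) for (d in seq_along(spkl$gb)) {
          q <- spkl$p[c0, d]
          rpq2 <- sum((Pij[a, b, ] - Pkl[c0, d, ])^2)
          val <- val + wij[a, b] * wkl[c0, d] *
            2 * pi^2.5 / (p * q * sqrt(p + q)) *
            boys_f0(p * q / (p + q) * rpq2)
        }
      }
      for (idx in unique(list(c(i, j, k, l), c(j, i, k, l), c(i, j, l, k),
                              c(j, i, l, k), c(k, l, i, j), c(l, k, i, j),
                              c(k, l, j, i), c(l, k, j, i))))
        eri[idx[1], idx[2], idx[3], idx[4]] <- val
    }
  }
  enuc <- 0
  nz <- length(nuclei$Z)
  if (nz > 1L) for (a in 1:(nz - 1L)) for (b in (a + 1L):nz)
    enuc <- enuc + nuclei$Z[a] * nuclei$Z[b] /
      sqrt(sum((nuclei$positions[a, ] - nuclei$positions[b, ])^2))
  list(S = S, T = Tm, Vne = V, hcore = Tm + V, eri = eri, n_ao = n,
       nuclear_repulsion = enuc)
}

#' Point-charge potential matrices over an s-only basis
#'
#' Computes the positive-definite matrices <phi_p | 1/|r - c| | phi_q> for
#' each site c. The sign convention of the total potential (nuclear minus
#' electronic) is applied at assembly points, not here.
#'
#' @param basis an `s_basis`.
#' @param sites m x 3 matrix of site positions (Bohr).
#' @return list of m symmetric n_ao x n_ao matrices.
#' @export
ao_esp_matrices <- function(basis, sites) {
  sites <- matrix(sites, ncol = 3L)
  sh <- basis$shells
  n <- length(sh)
  out <- vector("list", nrow(sites))
  for (m in seq_len(nrow(sites))) out[[m]] <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(i)) {
    sp <- shell_pair(sh[[i]], sh[[j]])
    w <- outer(sp$ca, sp$cb) * sp$K
    P <- pair_centers(sp)
    for (m in seq_len(nrow(sites))) {
      rpc2 <- (P[, , 1] - sites[m, 1])^2 + (P[, , 2] - sites[m, 2])^2 +
              (P[, , 3] - sites[m, 3])^2
      v <- sum(w * (2 * pi / sp$p) * boys_f0(sp$p * rpc2))
      out[[m]][i, j] <- v
      out[[m]][j, i] <- v
    }
  }
  out
}

#' Nuclear electrostatic potential at sites
#'
#' value_i = sum_N Z_N / |r_i - R_N|.
#'
#' @param nuclei list with `Z` and `positions` (Bohr).
#' @param sites m x 3 matrix of site positions (Bohr).
#' @return numeric vector of per-site potentials (Hartree / charge).
#' @export
nuclear_potential_at_sites <- function(nuclei, sites) {
  sites <- matrix(sites, ncol = 3L)
  vapply(seq_len(nrow(sites)), function(i) {
    d <- sqrt(rowSums(sweep(nuclei$positions, 2L, sites[i, ])^2))
    if (any(d < 1e-6))
      stop("FQ site within 1e-6 Bohr of a nucleus; potential singular")
    sum(nuclei$Z / d)
  }, numeric(1))
}

#' Restricted Hartree-Fock in an s-only basis
#'
#' Plain closed-shell SCF with symmetric orthogonalization, used to produce
#' starting orbitals. Point charges may be folded into the core Hamiltonian.
#'
#' @param ao output of [ao_integrals()].
#' @param n_electrons even electron count.
#' @param h_extra optional additional one-electron AO matrix (e.g. folded
#'   FQ charges).
#' @param max_iter,tol SCF controls.
#' @return list with `coefficients`, `energy_electronic`, `energy`
#'   (electronic + nuclear repulsion), `orbital_energies`, `converged`.
#' @export
rhf <- function(ao, n_electrons, h_extra = NULL, max_iter = 200, tol = 1e-10) {
  if (n_electrons %% 2 != 0) stop("rhf requires an even electron count")
  nocc <- n_electrons / 2L
  h <- ao$hcore + if (is.null(h_extra)) 0 else h_extra
  es <- eigen(ao$S, symmetric = TRUE)
  X <- es$vectors %*% diag(1 / sqrt(es$values), ao$n_ao) %*% t(es$vectors)
  n <- ao$n_ao
  eri <- ao$eri
  Fm <- h
  e_old <- Inf; Cocc <- NULL; converged <- FALSE; Cfull <- NULL; eps <- NULL
  for (it in seq_len(max_iter)) {
    Fp <- X %*% Fm %*% X
    ef <- eigen((Fp + t(Fp)) / 2, symmetric = TRUE)
    ord <- order(ef$values)
    Cfull <- X %*% ef$vectors[, ord, drop = FALSE]
    eps <- ef$values[ord]
    Cocc <- Cfull[, seq_len(nocc), drop = FALSE]
    D <- 2 * Cocc %*% t(Cocc)
    J <- apply(eri, c(1, 2), function(g) sum(g * D))
    K <- apply(aperm(eri, c(1, 3, 2, 4)), c(1, 2), function(g) sum(g * D))
    Fm <- h + J - 0.5 * K
    e_el <- 0.5 * sum(D * (h + Fm))
    if (abs(e_el - e_old) < tol) { converged <- TRUE; break }
    e_old <- e_el
  }
  list(coefficients = Cfull, energy_electronic = e_el,
       energy = e_el + ao$nuclear_repulsion,
       orbital_energies = eps, converged = converged)
}
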