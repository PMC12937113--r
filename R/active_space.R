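#' Active-space Hamiltonian container
#'
#' Holds the one-electron matrix h_pq, the two-electron tensor g_pqrs in
#' chemist notation (pq|rs), a scalar core energy (nuclear repulsion plus
#' inactive-orbital contributions, plus any classical-charge terms), the
#' active electron count and the spin projection 2Sz.
#'
#' @param h symmetric L x L matrix (Hartree).
#' @param g L^4 array with 8-fold permutational symmetry (Hartree).
#' @param core_energy scalar (Hartree).
#' @param n_electrons active electron count.
#' @param ms2 spin projection 2Sz.
#' @return object of class `active_space_integrals`.
#' @export
active_space_integrals <- function(h, g, core_energy = 0, n_electrons,
                                   ms2 = 0L) {
  h <- as.matrix(h)
  L <- nrow(h)
  if (L < 1L) stop("need at least one active orbital")
  scale_h <- max(1, max(abs(h)))
  if (max(abs(h - t(h))) > 1e-9 * scale_h)
    stop("one-electron matrix h must be symmetric")
  if (!all(dim(g) == L)) stop("g must be L^4")
  scale_g <- max(1, max(abs(g)))
  if (max(abs(g - aperm(g, c(2, 1, 3, 4)))) > 1e-9 * scale_g ||
      max(abs(g - aperm(g, c(3, 4, 1, 2)))) > 1e-9 * scale_g ||
      max(abs(g - aperm(g, c(1, 2, 4, 3)))) > 1e-9 * scale_g)
    stop("g must have 8-fold permutational symmetry")
  if (n_electrons < 0 || n_electrons > 2 * L)
    stop("electron count outside [0, 2L]")
  structure(list(h = (h + t(h)) / 2, g = g, core_energy = core_energy,
                 n_electrons = as.integer(n_electrons), ms2 = as.integer(ms2),
                 n_orbitals = L),
            class = "active_space_integrals")
}

#' Read an FCIDUMP file
#'
#' Standard Molpro FCIDUMP: namelist header with NORB, NELEC, MS2, ORBSYM,
#' then `value i j k l` records; (ij|kl) in chemist notation, core energy on
#' the all-zero index record. All 8 index permutations are filled in.
#'
#' @param path file path.
#' @return an `active_space_integrals`.
#' @export
read_fcidump <- function(path) {
  lines <- readLines(path)
  hdr_end <- grep("^\\s*(&END|/)\\s*$", toupper(lines))[1]
  if (is.na(hdr_end)) stop("FCIDUMP header terminator not found")
  hdr <- paste(lines[seq_len(hdr_end)], collapse = " ")
  getn <- function(key) {
    m <- regmatches(hdr, regexpr(paste0(key, "\\s*=\\s*-?[0-9]+"), hdr,
                                 ignore.case = TRUE))
    if (length(m) == 0L) return(NA_integer_)
    as.integer(sub(".*=\\s*", "", m))
  }
  L <- getn("NORB"); nel <- getn("NELEC"); ms2 <- getn("MS2")
  if (is.na(L) || is.na(nel)) stop("FCIDUMP header lacks NORB/NELEC")
  if (is.na(ms2)) ms2 <- 0L
  h <- matrix(0, L, L)
  g <- array(0, c(L, L, L, L))
  core <- 0
  for (ln in lines[-seq_len(hdr_end)]) {
    if (!nzchar(trimws(ln))) next
    tk <- strsplit(trimws(ln), "\\s+")[[1]]
    v <- as.numeric(tk[1]); ii <- as.integer(tk[2:5])
    i <- ii[1]; j <- ii[2]; k <- ii[3]; l <- ii[4]
    if (i == 0L) core <- v
    else if (k == 0L) { h[i, j] <- v; h[j, i] <- v }
    else {
      for (p in list(c(i,j,k,l), c(j,i,k,l), c(i,j,l,k), c(j,i,l,k),
                     c(k,l,i,j), c(l,k,i,j), c(k,l,j,i), c(l,k,j,i)))
        g[p[1], p[2], p[3], p[4]] <- v
    }
  }
  active_space_integrals(h, g, core, nel, ms2)
}

#' Write an FCIDUMP file
#'
#' @param ints an `active_space_integrals`.
#' @param path output path.
#' @param orbsym orbital symmetry labels (default all 1).
#' @export
write_fcidump <- function(ints, path, orbsym = NULL) {
  L <- ints$n_orbitals
  if (is.null(orbsym)) orbsym <- rep(1L, L)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("&FCI NORB=%d,NELEC=%d,MS2=%d,", L, ints$n_electrons,
                     ints$ms2), con)
  writeLines(sprintf(" ORBSYM=%s", paste0(orbsym, collapse = ",")), con)
  writeLines(" ISYM=1,", con)
  writeLines("&END", con)
  fmt <- function(v, i, j, k, l) sprintf("%23.16E %3d %3d %3d %3d", v, i, j, k, l)
  for (i in seq_len(L)) for (j in seq_len(i))
    for (k in seq_len(i)) for (l in seq_len(k)) {
      if ((k - 1L) * k / 2 + l > (i - 1L) * i / 2 + j) next
      v <- ints$g[i, j, k, l]
      if (abs(v) > 1e-14) writeLines(fmt(v, i, j, k, l), con)
    }
  for (i in seq_len(L)) for (j in seq_len(i))
    if (abs(ints$h[i, j]) > 1e-14)
      writeLines(fmt(ints$h[i, j], i, j, 0L, 0L), con)
  writeLines(fmt(ints$core_energy, 0L, 0L, 0L, 0L), con)
  invisible(path)
}

#' Orbital set over an AO basis
#'
#' @param coefficients AO x MO coefficient matrix T with T' S T = I.
#' @param partition list with integer vectors `inactive`, `active`,
#'   `virtual` (disjoint, covering all MOs).
#' @param overlap AO overlap matrix S.
#' @return object of class `orbital_set`.
#' @export
orbital_set <- function(coefficients, partition, overlap) {
  Tm <- as.matrix(coefficients)
  idx <- c(partition$inactive, partition$active, partition$virtual)
  if (anyDuplicated(idx) || length(idx) != ncol(Tm))
    stop("partition must be disjoint and cover all orbitals")
  ortho <- t(Tm) %*% overlap %*% Tm
  if (max(abs(ortho - diag(ncol(Tm)))) > 1e-8)
    stop("orbital coefficients not orthonormal under the AO overlap")
  structure(list(coefficients = Tm, partition = partition, overlap = overlap),
            class = "orbital_set")
}

# 4-index transform of an AO ERI array to the MO basis (small systems).
# Each pass transforms the leading index and rotates it to the back, so four
# passes restore the original index order with all indices transformed.
transform_eri <- function(eri, C) {
  n <- dim(eri)[1]; m <- ncol(C)
  g <- eri
  for (pass in 1:4) {
    d <- dim(g)
    g <- array(crossprod(C, matrix(g, n, prod(d[-1]))), c(m, d[-1]))
    g <- aperm(g, c(2, 3, 4, 1))
  }
  g
}

#' Transform AO integrals to an active-space Hamiltonian
#'
#' Folds the inactive (doubly occupied) orbitals into a core Fock
#' contribution to the active one-electron matrix and into the core energy
#' (nuclear repulsion plus 2 sum_i h_ii + sum_ij 2(ii|jj) - (ij|ji)). When FQ
#' charges and ESP matrices are supplied, their interaction with the core
#' density and the nuclei is folded into the core energy and the active block
#' into h (see [fold_fq_into_oei()]).
#'
#' @param ao output of [ao_integrals()].
#' @param orbitals an `orbital_set`.
#' @param n_active_electrons electron count in the active space.
#' @param ms2 spin projection 2Sz.
#' @param h_extra_ao optional extra AO one-electron matrix folded into h
#'   before the transform (e.g. -sum_s q_s V_s for fixed charges); any
#'   associated scalar must be added to the returned core energy by the
#'   caller.
#' @return an `active_space_integrals`.
#' @export
transform_to_active <- function(ao, orbitals, n_active_electrons, ms2 = 0L,
                                h_extra_ao = NULL) {
  C <- orbitals$coefficients
  inact <- orbitals$partition$inactive
  act <- orbitals$partition$active
  h_ao <- ao$hcore + if (is.null(h_extra_ao)) 0 else h_extra_ao
  h_mo <- t(C) %*% h_ao %*% C
  g_mo <- transform_eri(ao$eri, C)
  core_e <- ao$nuclear_repulsion
  if (length(inact) > 0L) {
    hi <- h_mo[inact, inact, drop = FALSE]
    core_e <- core_e + 2 * sum(diag(hi))
    for (i in inact) for (j in inact)
      core_e <- core_e + 2 * g_mo[i, i, j, j] - g_mo[i, j, j, i]
    # core Fock contribution to the active one-electron matrix
    h_act <- h_mo[act, act, drop = FALSE]
    for (i in inact)
      h_act <- h_act + 2 * g_mo[act, act, i, i] - g_mo[act, i, i, act]
  } else {
    h_act <- h_mo[act, act, drop = FALSE]
  }
  g_act <- g_mo[act, act, act, act, drop = FALSE]
  active_space_integrals(h_act, g_act, core_e, n_active_electrons, ms2)
}

#' Electrostatic-potential operator at classical sites
#'
#' For each site, the nuclear potential sum_N Z_N/|r - R_N| and the
#' electronic-potential matrix <phi_p|1/|r - r_site||phi_q>, expressed over
#' the molecular orbitals of `orbitals` and split into the active block plus
#' a scalar core (inactive doubly-occupied) contribution. The total
#' potential at a site is V(D) = nuclear - Tr(D_total V); the minus sign on
#' the electronic part is applied only at assembly points
#' ([fold_fq_into_oei()], [interaction_energy()]).
#'
#' @param basis an `s_basis` for the QM region.
#' @param nuclei list with `Z` and `positions` (Bohr).
#' @param orbitals an `orbital_set`.
#' @param sites m x 3 matrix of site positions (Bohr).
#' @return object of class `esp_operator` with fields `site_positions`,
#'   `nuclear_potential` (length m), `v_active` (list of L x L matrices) and
#'   `v_core` (length m, = 2 sum_i V_ii over inactive MOs).
#' @export
electronic_esp_matrices <- function(basis, nuclei, orbitals, sites) {
  sites <- matrix(sites, ncol = 3L)
  vao <- ao_esp_matrices(basis, sites)
  C <- orbitals$coefficients
  act <- orbitals$partition$active
  inact <- orbitals$partition$inactive
  v_active <- vector("list", nrow(sites))
  v_core <- numeric(nrow(sites))
  for (m in seq_len(nrow(sites))) {
    vmo <- t(C) %*% vao[[m]] %*% C
    vmo <- (vmo + t(vmo)) / 2
    v_active[[m]] <- vmo[act, act, drop = FALSE]
    v_core[m] <- if (length(inact) > 0L) 2 * sum(diag(vmo)[inact]) else 0
  }
  structure(list(site_positions = sites,
                 nuclear_potential = nuclear_potential_at_sites(nuclei, sites),
                 v_active = v_active, v_core = v_core,
                 v_ao = vao),
            class = "esp_operator")
}

#' Fold classical charges into the one-electron integrals
#'
#' Builds the effective Hamiltonian integrals: h_eff = h - sum_s q_s V_s
#' (active block) and core_energy += sum_s q_s (V_nuc,s - V_core,s), so that
#' <Psi|H_eff|Psi> + core_eff - <Psi|H|Psi> - core equals the electrostatic
#' interaction energy sum_s q_s V_s(D) with the total (core + active)
#' density. Linear in q.
#'
#' @param ints an `active_space_integrals` (unpolarized).
#' @param charges charge vector, one per ESP site.
#' @param esp an `esp_operator` over the same orbital set as `ints`.
#' @return an `active_space_integrals` with folded charges.
#' @export
fold_fq_into_oei <- function(ints, charges, esp) {
  m <- length(esp$nuclear_potential)
  if (length(charges) != m)
    stop("charge vector length must equal the number of ESP sites")
  h <- ints$h
  for (s in seq_len(m)) h <- h - charges[s] * esp$v_active[[s]]
  core <- ints$core_energy +
    sum(charges * (esp$nuclear_potential - esp$v_core))
  active_space_integrals(h, ints$g, core, ints$n_electrons, ints$ms2)
}

#' Electrostatic interaction energy of charges with a QM density
#'
#' E_int = sum_s q_s V_s(D) with V_s(D) = nuclear_s - Tr(D_total V_s), where
#' D_total combines the doubly occupied core and the active one-particle
#' density.
#'
#' @param charges charge vector.
#' @param esp an `esp_operator`.
#' @param d_active active-space one-particle density matrix.
#' @return energy in Hartree.
#' @export
interaction_energy <- function(charges, esp, d_active) {
  v_of_d <- esp_potential_of_density(esp, d_active)
  sum(charges * v_of_d)
}

#' Total electrostatic potential of the QM system at the ESP sites
#'
#' V_s(D) = nuclear_s - (core_s + Tr(D_active V_active,s)).
#'
#' @param esp an `esp_operator`.
#' @param d_active active one-particle density matrix.
#' @return per-site potential vector.
#' @export
esp_potential_of_density <- function(esp, d_active) {
  m <- length(esp$nuclear_potential)
  vapply(seq_len(m), function(s)
    esp$nuclear_potential[s] - esp$v_core[s] -
      sum(d_active * esp$v_active[[s]]), numeric(1))
}
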