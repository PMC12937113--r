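test_that("nuclear potential at sites is the bare Coulomb sum", {
  nuc1 <- list(Z = 1, positions = rbind(c(0, 0, 0)))
  expect_equal(nuclear_potential_at_sites(nuc1, rbind(c(2, 0, 0))), 0.5)
  nuc8 <- list(Z = 8, positions = rbind(c(0, 0, 0)))
  expect_equal(nuclear_potential_at_sites(nuc8, rbind(c(4, 0, 0))), 2.0)
  # water-like 3-nucleus toy vs direct hand sum
  nuc <- list(Z = c(8, 1, 1),
              positions = rbind(c(0, 0, 0), c(1.8, 0, 0), c(-0.45, 1.75, 0)))
  site <- c(3, 2, 1)
  expected <- sum(nuc$Z / sqrt(rowSums(sweep(nuc$positions, 2, site)^2)))
  expect_equal(as.numeric(nuclear_potential_at_sites(nuc, rbind(site))),
               expected)
  expect_error(nuclear_potential_at_sites(nuc1, rbind(c(0, 0, 1e-8))),
               "singular")
})

test_that("s-Gaussian backend reproduces H2 reference energies", {
  # literature STO-3G values at R = 1.4 Bohr: RHF -1.1167, FCI -1.1373
  nuc <- list(Z = c(1, 1), positions = rbind(c(0, 0, 0), c(1.4, 0, 0)))
  bas <- build_basis(c("H", "H"), nuc$positions, "sto3g.s")
  ao <- ao_integrals(bas, nuc)
  expect_equal(ao$S[1, 1], 1, tolerance = 1e-8)   # normalized contractions
  hf <- rhf(ao, 2L)
  expect_true(hf$converged)
  expect_equal(hf$energy, -1.11671, tolerance = 1e-4)
  orbs <- orbital_set(hf$coefficients,
                      list(inactive = integer(0), active = 1:2,
                           virtual = integer(0)), ao$S)
  ints <- transform_to_active(ao, orbs, 2L)
  expect_equal(oracle_fci(ints, 1L)$values[1], -1.13727, tolerance = 1e-4)
})

test_that("ESP matrices are symmetric and have the right far field", {
  nuc <- list(Z = c(1, 1), positions = rbind(c(0, 0, 0), c(1.4, 0, 0)))
  bas <- build_basis(c("H", "H"), nuc$positions)
  ao <- ao_integrals(bas, nuc)
  hf <- rhf(ao, 2L)
  orbs <- orbital_set(hf$coefficients,
                      list(inactive = integer(0), active = 1:2,
                           virtual = integer(0)), ao$S)
  # single normalized s orbital, far site: V_11 -> 1/r (monopole limit)
  nuc1 <- list(Z = 1, positions = rbind(c(0, 0, 0)))
  bas1 <- build_basis("H", nuc1$positions)
  v1 <- ao_esp_matrices(bas1, rbind(c(50, 0, 0)))[[1]][1, 1]
  expect_lt(abs(v1 - 1 / 50) * 50, 1e-3)
  esp <- electronic_esp_matrices(bas, nuc, orbs, rbind(c(50, 0, 0)))
  expect_equal(esp$v_active[[1]], t(esp$v_active[[1]]))
  # neutral system: total potential screens to zero far away
  rd <- compute_rdms(solve_state(transform_to_active(ao, orbs, 2L),
                                 max_bond = 4L)$mps)
  esp100 <- electronic_esp_matrices(bas, nuc, orbs, rbind(c(100, 2, -3)))
  vtot <- esp_potential_of_density(esp100, rd$one_particle)
  expect_lt(abs(vtot), 1e-5)
  # random-geometry symmetry check
  set.seed(2)
  esp_r <- electronic_esp_matrices(bas, nuc, orbs, matrix(rnorm(9, sd = 5), 3))
  for (m in 1:3)
    expect_equal(esp_r$v_active[[m]], t(esp_r$v_active[[m]]))
})

test_that("active-space folding matches restricted exact diagonalization", {
  ctx <- toy_h4_context()
  part <- list(inactive = 1L, active = 2:4, virtual = integer(0))
  orbs <- orbital_set(ctx$hf$coefficients, part, ctx$ao$S)
  ints <- transform_to_active(ctx$ao, orbs, 2L)
  # oracle: full-space FCI restricted to determinants with orbital 1 doubly
  # occupied (site 1 local state |updn>)
  full_orbs <- orbital_set(ctx$hf$coefficients,
                           list(inactive = integer(0), active = 1:4,
                                virtual = integer(0)), ctx$ao$S)
  fints <- transform_to_active(ctx$ao, full_orbs, 4L)
  H <- oracle_hamiltonian(fints)
  lab <- oracle_sector_labels(4L)
  idx <- 0:(4^4 - 1)
  sel <- which(lab$n == 4 & lab$sz2 == 0 & idx %% 4 == 3)
  Hs <- as.matrix(H[sel, sel])
  e_restricted <- min(eigen((Hs + t(Hs)) / 2, symmetric = TRUE,
                            only.values = TRUE)$values) + fints$core_energy
  e_cas <- oracle_fci(ints, 1L)$values[1]
  expect_equal(e_cas, e_restricted, tolerance = 1e-10)
})

test_that("folding is invariant under rotations within the inactive block", {
  # two inactive orbitals: mix them by a random rotation; the active
  # Hamiltonian and core energy must not change
  nuc <- list(Z = rep(1, 4),
              positions = rbind(c(0, 0, 0), c(1.5, 0, 0), c(3.1, 0, 0),
                                c(4.5, 0, 0)))
  bas <- build_basis(rep("H", 4), nuc$positions)
  ao <- ao_integrals(bas, nuc)
  hf <- rhf(ao, 4L)
  part <- list(inactive = 1:2, active = 3:4, virtual = integer(0))
  orbs <- orbital_set(hf$coefficients, part, ao$S)
  ints <- transform_to_active(ao, orbs, 0L)
  set.seed(8)
  th <- runif(1, 0, pi)
  R <- diag(4)
  R[1:2, 1:2] <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  orbs_rot <- orbital_set(hf$coefficients %*% R, part, ao$S)
  ints_rot <- transform_to_active(ao, orbs_rot, 0L)
  expect_equal(ints_rot$core_energy, ints$core_energy, tolerance = 1e-10)
  expect_equal(ints_rot$h, ints$h, tolerance = 1e-10)
  expect_equal(ints_rot$g, ints$g, tolerance = 1e-10)
})

test_that("charge folding is linear and energetically consistent", {
  nuc <- list(Z = c(1, 1), positions = rbind(c(0, 0, 0), c(1.4, 0, 0)))
  bas <- build_basis(c("H", "H"), nuc$positions)
  ao <- ao_integrals(bas, nuc)
  hf <- rhf(ao, 2L)
  orbs <- orbital_set(hf$coefficients,
                      list(inactive = integer(0), active = 1:2,
                           virtual = integer(0)), ao$S)
  ints <- transform_to_active(ao, orbs, 2L)
  sites <- rbind(c(4, 1, 0), c(-3, -2, 1))
  esp <- electronic_esp_matrices(bas, nuc, orbs, sites)

  # q = 0 leaves the integrals unchanged
  f0 <- fold_fq_into_oei(ints, c(0, 0), esp)
  expect_equal(f0$h, ints$h)
  expect_equal(f0$core_energy, ints$core_energy)

  # linearity in q
  q1 <- c(0.3, -0.1); q2 <- c(-0.2, 0.5)
  f1 <- fold_fq_into_oei(ints, q1, esp)
  f2 <- fold_fq_into_oei(ints, q2, esp)
  f12 <- fold_fq_into_oei(ints, q1 + q2, esp)
  expect_equal(f1$h + f2$h - 2 * f0$h, f12$h - f0$h, tolerance = 1e-12)
  expect_equal(f1$core_energy + f2$core_energy - 2 * f0$core_energy,
               f12$core_energy - f0$core_energy, tolerance = 1e-12)

  # interaction-energy consistency: <H_eff> + core_eff - <H> - core equals
  # sum_s q_s V_s(D) for an arbitrary normalized state
  set.seed(3)
  psi <- random_sector_mps(2L, 2L, 0L, max_bond = 4L)
  rd <- compute_rdms(psi)
  e_eff <- expectation(psi, build_mpo(f1)) + f1$core_energy
  e_bare <- expectation(psi, build_mpo(ints)) + ints$core_energy
  expect_equal(e_eff - e_bare, interaction_energy(q1, esp, rd$one_particle),
               tolerance = 1e-10)

  # finite-difference consistency of dE/dq at q = 0 with the unperturbed
  # density: dE/dq_s = V_s(D)
  d <- 1e-4
  gs0 <- solve_state(ints, max_bond = 4L)
  rd0 <- compute_rdms(gs0$mps)
  v0 <- esp_potential_of_density(esp, rd0$one_particle)
  for (s in 1:2) {
    qp <- c(0, 0); qp[s] <- d
    qm <- c(0, 0); qm[s] <- -d
    ep <- solve_state(fold_fq_into_oei(ints, qp, esp), max_bond = 4L)$energy_total
    em <- solve_state(fold_fq_into_oei(ints, qm, esp), max_bond = 4L)$energy_total
    expect_equal((ep - em) / (2 * d), v0[s], tolerance = 1e-4)
  }

  # sign check: a positive charge near the cloud attracts electrons
  # (electronic term lowers h) and repels against the nuclei (core rises)
  fpos <- fold_fq_into_oei(ints, c(1, 0), esp)
  expect_lt(fpos$h[1, 1], ints$h[1, 1])
  expect_gt(fpos$core_energy, ints$core_energy)

  expect_error(fold_fq_into_oei(ints, c(1, 2, 3), esp), "length")
})

test_that("FCIDUMP files round-trip bit-consistently", {
  dir <- withr::local_tempdir()
  set.seed(21)
  ints <- random_integrals(4L, 4L)
  path <- file.path(dir, "t.fcidump")
  write_fcidump(ints, path)
  back <- read_fcidump(path)
  expect_equal(back$h, ints$h, tolerance = 1e-14)
  expect_equal(back$g, ints$g, tolerance = 1e-14)
  expect_equal(back$core_energy, ints$core_energy, tolerance = 1e-14)
  expect_identical(back$n_electrons, ints$n_electrons)
  expect_identical(back$ms2, ints$ms2)
  # a second write of the re-read integrals is byte-identical
  path2 <- file.path(dir, "t2.fcidump")
  write_fcidump(back, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("XYZ frames round-trip through write and read", {
  dir <- withr::local_tempdir()
  frames <- list(
    list(elements = c("O", "H"), positions_ang = rbind(c(0, 0, 0), c(1, 0, 0)),
         comment = "frame a"),
    list(elements = c("H", "H"), positions_ang = rbind(c(0, 0, 0), c(0, .7, 0)),
         comment = "frame b"))
  path <- file.path(dir, "frames.xyz")
  write_xyz(frames, path)
  back <- read_xyz_frames(path)
  expect_length(back, 2L)
  expect_equal(back[[1]]$elements, frames[[1]]$elements)
  expect_equal(back[[2]]$positions_ang, frames[[2]]$positions_ang,
               tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(back[[1]]$positions,
               frames[[1]]$positions_ang * ANGSTROM_TO_BOHR,
               tolerance = 1e-9, ignore_attr = TRUE)
})
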