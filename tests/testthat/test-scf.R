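test_that("gas-phase run equals the independent CASSCF oracle", {
  qm <- toy_h2_qm()
  cfg <- dmrgfq_config(2L, 2L, state = "gs", max_bond = 16L,
                       embedding = "none")
  gs <- run_dmrgscf_fq(qm, NULL, cfg)
  expect_true(gs$converged)
  ctx <- gs$context
  part <- list(inactive = integer(0), active = 1:2, virtual = integer(0))
  hf <- rhf(ctx$ao, 2L)
  orbs <- orbital_set(hf$coefficients, part, ctx$ao$S)
  e_oracle <- oracle_fci_singlets(transform_to_active(ctx$ao, orbs, 2L), 1L)
  expect_equal(gs$energy_total, e_oracle[1], tolerance = 1e-8)
  expect_identical(gs$energy_fq, 0)
  expect_identical(gs$energy_interaction, 0)
})

test_that("FCIDUMP input runs gas-phase and rejects embedding", {
  dir <- withr::local_tempdir()
  path <- generate_fixtures("fcidump_h2like", seed = 1, dir = dir)
  cfg <- dmrgfq_config(2L, 2L, state = "gs", max_bond = 8L)
  gs <- run_dmrgscf_fq(list(fcidump = path), NULL, cfg)
  expect_equal(gs$energy_total,
               oracle_fci_singlets(h2like_integrals(), 1L)[1],
               tolerance = 1e-9)
  fq <- toy_water_env()
  expect_error(run_dmrgscf_fq(list(fcidump = path), fq, cfg), "gas-phase")
})

test_that("coupled run converges with consistent energy decomposition", {
  qm <- toy_h2_qm()
  fq <- toy_water_env()
  cfg <- dmrgfq_config(2L, 2L, state = "gs", max_bond = 16L)
  gs <- run_dmrgscf_fq(qm, fq, cfg)
  expect_true(gs$converged)
  # E_total = E_DMRG + E_FQ + E_int (Hartree, to 1e-10)
  expect_equal(gs$energy_dmrg + gs$energy_fq + gs$energy_interaction,
               gs$energy_total, tolerance = 1e-10)
  # group-charge conservation
  for (g in seq_along(fq$groups))
    expect_equal(sum(gs$charges[fq$groups[[g]]$atom_indices]),
                 fq$groups[[g]]$total_charge, tolerance = 1e-10)
  # energy trace monotone non-increasing after the first macro-iteration
  tr <- gs$convergence_trace
  if (length(tr) > 1L) expect_true(all(diff(tr) <= 1e-9))
  # stationarity: single-charge perturbations of the assembled functional
  # change the energy only at second order
  d <- 1e-4
  for (i in seq_along(gs$charges)) {
    qp <- gs$charges; qp[i] <- qp[i] + d
    qm_ <- gs$charges; qm_[i] <- qm_[i] - d
    first_order <- (assemble_energy(gs, qp) - assemble_energy(gs, qm_)) / (2 * d)
    expect_lt(abs(first_order), 1e-7)
  }
})

test_that("frozen-charge mode equals a single statically folded run", {
  qm <- toy_h2_qm()
  fq <- toy_water_env()
  q0 <- solve_fq(fq)$charges
  cfg <- dmrgfq_config(2L, 2L, state = "gs", max_bond = 16L,
                       embedding = "frozen")
  frozen <- run_dmrgscf_fq(qm, fq, cfg, frozen_charges = q0)
  expect_true(frozen$converged)
  expect_equal(frozen$charges, q0)
  # polarizable relaxation from the same start can only lower the energy
  cfg_pol <- dmrgfq_config(2L, 2L, state = "gs", max_bond = 16L)
  pol <- run_dmrgscf_fq(qm, fq, cfg_pol)
  expect_lte(pol$energy_total, frozen$energy_total + 1e-10)
})

test_that("far-field environment reproduces the gas phase and isolated FQ", {
  qm <- toy_h2_qm()
  cfg <- dmrgfq_config(2L, 2L, state = "gs", max_bond = 16L)
  gas <- run_dmrgscf_fq(qm, NULL,
                        dmrgfq_config(2L, 2L, state = "gs", max_bond = 16L,
                                      embedding = "none"))
  shift_b <- 1e4 / ANGSTROM_TO_BOHR
  fq_far <- toy_water_env(list(c(2.5, 0.5, 0) + shift_b,
                               c(-1.5, 1.8, 0.5) + shift_b,
                               c(0.3, -2.2, 1.0) + shift_b))
  far <- run_dmrgscf_fq(qm, fq_far, cfg)
  expect_equal(far$energy_dmrg + far$energy_interaction, gas$energy_total,
               tolerance = 1e-8)
  iso <- solve_fq(fq_far)
  expect_equal(far$charges, iso$charges, tolerance = 1e-8)
})

test_that("rigid translation of QM and FQ geometry leaves the energy fixed", {
  qm <- toy_h2_qm()
  fq <- toy_water_env()
  cfg <- dmrgfq_config(2L, 2L, state = "gs", max_bond = 16L)
  gs <- run_dmrgscf_fq(qm, fq, cfg)
  shift <- c(3.1, -2.4, 5.0)
  qm2 <- list(elements = qm$elements,
              positions_ang = sweep(qm$positions_ang, 2L, -shift))
  fq2 <- toy_water_env(list(c(2.5, 0.5, 0) + shift, c(-1.5, 1.8, 0.5) + shift,
                            c(0.3, -2.2, 1.0) + shift))
  gs2 <- run_dmrgscf_fq(qm2, fq2, cfg)
  expect_equal(gs2$energy_total, gs$energy_total, tolerance = 1e-9)
})

test_that("state-specific GS and ES carry distinct optimal charge vectors", {
  qm <- toy_h2_qm()
  fq <- toy_water_env(list(c(1.8, 0.4, 0), c(-1.2, 1.4, 0.4),
                           c(0.3, -1.8, 0.8)))
  cfg_gs <- dmrgfq_config(2L, 2L, state = "gs", max_bond = 16L)
  cfg_es <- dmrgfq_config(2L, 2L, state = "es", max_bond = 16L)
  gs <- run_dmrgscf_fq(qm, fq, cfg_gs)
  es <- run_dmrgscf_fq(qm, fq, cfg_es, orbitals = gs$orbitals)
  expect_true(gs$converged && es$converged)
  expect_gt(max(abs(gs$charges - es$charges)), 1e-8)
  # swapping the charge vectors never lowers either state's functional
  expect_gte(assemble_energy(gs, es$charges), gs$energy_total - 1e-10)
  expect_gte(assemble_energy(es, gs$charges), es$energy_total - 1e-10)
})

test_that("excitation energies are gaps in eV with root-flip detection", {
  dir <- withr::local_tempdir()
  path <- generate_fixtures("fcidump_h2like", seed = 2, dir = dir)
  cfg_gs <- dmrgfq_config(2L, 2L, state = "gs", max_bond = 8L)
  cfg_es <- dmrgfq_config(2L, 2L, state = "es", max_bond = 8L)
  gs <- run_dmrgscf_fq(list(fcidump = path), NULL, cfg_gs)
  es <- run_dmrgscf_fq(list(fcidump = path), NULL, cfg_es)
  singlets <- oracle_fci_singlets(h2like_integrals(), 2L)
  expect_equal(excitation_energy(gs, es),
               (singlets[2] - singlets[1]) * HARTREE_TO_EV,
               tolerance = 1e-7)
  # es = gs gives exactly zero
  expect_identical(excitation_energy(gs, gs), 0)
  # swapped arguments flag a root flip rather than silently returning
  expect_warning(gap <- excitation_energy(es, gs), "root flip")
  expect_lt(gap, 0)
  # a uniform diagonal shift of h moves both states equally: gap unchanged
  ints <- h2like_integrals()
  ints_shift <- active_space_integrals(ints$h + diag(2) * 0.37, ints$g,
                                       ints$core_energy, ints$n_electrons)
  s1 <- oracle_fci_singlets(ints_shift, 2L)
  expect_equal(s1[2] - s1[1], singlets[2] - singlets[1], tolerance = 1e-10)
  # unconverged inputs are rejected
  gs_bad <- gs; gs_bad$converged <- FALSE
  expect_error(excitation_energy(gs_bad, es), "converged")
})

test_that("configs round-trip through YAML", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "run.yaml")
  yaml::write_yaml(list(n_active_electrons = 2L, n_active_orbitals = 2L,
                        state = "es", max_bond = 12L, embedding = "frozen",
                        tol_e = 1e-9), path)
  cfg <- read_config(path)
  expect_identical(cfg$state, "es")
  expect_identical(cfg$max_bond, 12L)
  expect_identical(cfg$embedding, "frozen")
  expect_equal(cfg$tol_e, 1e-9)
  expect_equal(cfg$tol_q, 1e-6)  # default filled in
})
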