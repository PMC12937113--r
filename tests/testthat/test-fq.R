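test_that("Ohno kernel has hardness diagonal and the stated limits", {
  # single atom: kernel is the hardness
  a1 <- fq_atoms(rbind(c(0, 0, 0)), chi = 0, eta = 0.5)
  expect_equal(build_ohno_kernel(a1), matrix(0.5), ignore_attr = TRUE)

  # short-range limit -> mean hardness (no polarization catastrophe)
  a2 <- fq_atoms(rbind(c(0, 0, 0), c(1e-7, 0, 0)), chi = c(0, 0),
                 eta = c(1, 1))
  K <- build_ohno_kernel(a2)
  expect_equal(K[1, 2], 1.0, tolerance = 1e-10)

  # finite-distance value equals the analytic Ohno form, approaching 1/r
  a3 <- fq_atoms(rbind(c(0, 0, 0), c(10, 0, 0)), chi = c(0, 0),
                 eta = c(0.6, 0.6))
  K3 <- build_ohno_kernel(a3)
  expect_equal(K3[1, 2], 0.6 / sqrt(1 + 0.36 * 100), tolerance = 1e-14)
  expect_lt(abs(K3[1, 2] - 0.1) / 0.1, 0.015)

  # long-range Coulomb limit: <1% relative deviation once eta*r > 10
  a4 <- fq_atoms(rbind(c(0, 0, 0), c(25, 0, 0)), chi = c(0, 0),
                 eta = c(0.6, 0.6))
  K4 <- build_ohno_kernel(a4)
  expect_lt(abs(K4[1, 2] - 1 / 25) * 25, 0.01)

  # off-diagonal strictly below mean hardness for r > 0
  set.seed(4)
  a5 <- fq_atoms(matrix(rnorm(15), 5, 3), chi = rnorm(5),
                 eta = runif(5, 0.3, 1))
  K5 <- build_ohno_kernel(a5)
  ebar <- outer(a5$eta, a5$eta, `+`) / 2
  off <- upper.tri(K5)
  expect_true(all(K5[off] < ebar[off]))
  expect_equal(K5, t(K5))
  expect_equal(diag(K5), a5$eta)
})

test_that("degenerate FQ inputs are rejected", {
  expect_error(fq_atoms(rbind(c(0, 0, 0)), chi = 0, eta = 0),
               "positive")
  a <- fq_atoms(rbind(c(0, 0, 0), c(0, 0, 0)), chi = c(0, 0),
                eta = c(0.5, 0.5))
  expect_error(build_ohno_kernel(a), "coincident")
})

test_that("symmetric diatomic solve gives zero charges and lambda = -chi", {
  a <- fq_atoms(rbind(c(0, 0, 0), c(2, 0, 0)), chi = c(0.1, 0.1),
                eta = c(0.5, 0.5))
  sys <- solve_fq(fq_system(a, list(fq_group(1:2, 0))))
  expect_equal(sys$charges, c(0, 0), tolerance = 1e-14)
  expect_equal(sys$multipliers, -0.1, tolerance = 1e-14)
})

test_that("polarized diatomic matches the closed-form bordered solution", {
  eta <- 0.5; v <- 0.03
  a <- fq_atoms(rbind(c(0, 0, 0), c(2, 0, 0)), chi = c(0.1, 0.1),
                eta = c(eta, eta))
  sys <- fq_system(a, list(fq_group(1:2, 0)))
  t_off <- sys$kernel[1, 2]
  sys <- solve_fq(sys, c(v, -v))
  expect_equal(sys$charges[1], -v / (eta - t_off), tolerance = 1e-12)
  expect_equal(sys$charges[2], +v / (eta - t_off), tolerance = 1e-12)
})

test_that("bordered solve matches the augmented-Lagrangian minimizer", {
  set.seed(42)
  for (case in 1:6) {
    n <- sample(4:9, 1)
    sizes <- diff(sort(unique(c(0, sample(seq_len(n - 1), 1), n))))
    idx <- split(seq_len(n), rep(seq_along(sizes), sizes))
    groups <- lapply(seq_along(idx), function(g)
      fq_group(idx[[g]], sample(c(-1, 0, 0, 1), 1)))
    a <- fq_atoms(matrix(rnorm(3 * n, sd = 3), n, 3), chi = rnorm(n, sd = 0.2),
                  eta = runif(n, 0.3, 1.2))
    sys <- fq_system(a, groups)
    v <- if (case %% 2 == 0) rnorm(n, sd = 0.05) else NULL
    sys <- solve_fq(sys, v)
    oracle <- fq_minimizer_oracle(sys$kernel, a$chi, groups, v)
    expect_lt(max(abs(sys$charges - oracle$charges)), 1e-10)
    for (g in seq_along(groups))
      expect_equal(sum(sys$charges[groups[[g]]$atom_indices]),
                   groups[[g]]$total_charge, tolerance = 1e-10)
  }
})

test_that("solved charges minimize the energy over the constraint manifold", {
  set.seed(11)
  a <- fq_atoms(matrix(rnorm(18, sd = 3), 6, 3), chi = rnorm(6, sd = 0.2),
                eta = runif(6, 0.4, 1))
  groups <- list(fq_group(1:3, 0), fq_group(4:6, 1))
  sys <- solve_fq(fq_system(a, groups))
  e0 <- fq_energy(sys$charges, a$chi, sys$kernel)
  for (k in 1:100) {
    dq <- rnorm(6, sd = 0.05)
    # project onto the feasible subspace (zero group sums)
    dq[1:3] <- dq[1:3] - mean(dq[1:3])
    dq[4:6] <- dq[4:6] - mean(dq[4:6])
    expect_gte(fq_energy(sys$charges + dq, a$chi, sys$kernel), e0 - 1e-12)
  }
})

test_that("electronegativity is equalized within each group at the solution", {
  set.seed(12)
  a <- fq_atoms(matrix(rnorm(24, sd = 3), 8, 3), chi = rnorm(8, sd = 0.3),
                eta = runif(8, 0.4, 1.2))
  groups <- list(fq_group(1:4, 0), fq_group(5:8, -1))
  v <- rnorm(8, sd = 0.02)
  sys <- solve_fq(fq_system(a, groups), v)
  eff <- a$chi + as.numeric(sys$kernel %*% sys$charges) + v
  for (g in groups)
    expect_lt(diff(range(eff[g$atom_indices])), 1e-9)
})

test_that("polarization by an external potential lowers the energy", {
  set.seed(13)
  a <- fq_atoms(matrix(rnorm(18, sd = 4), 6, 3), chi = rnorm(6, sd = 0.2),
                eta = runif(6, 0.4, 1))
  groups <- list(fq_group(1:3, 0), fq_group(4:6, 0))
  sys0 <- solve_fq(fq_system(a, groups))
  v <- rnorm(6, sd = 0.05)
  sysv <- solve_fq(fq_system(a, groups), v)
  e_pol <- fq_energy(sysv$charges, a$chi, sysv$kernel, v)
  e_unpol <- fq_energy(sys0$charges, a$chi, sys0$kernel, v)
  expect_lte(e_pol, e_unpol + 1e-14)
  # constant potential within every group: no polarization change
  vc <- rep(c(0.3, -0.1), each = 3)
  sysc <- solve_fq(fq_system(a, groups), vc)
  expect_equal(sysc$charges, sys0$charges, tolerance = 1e-11)
})

test_that("fq_energy evaluates the quadratic form", {
  expect_identical(fq_energy(c(0, 0), c(1, 2), diag(2)), 0)
  expect_equal(fq_energy(c(1, -1), c(0, 0),
                         matrix(c(1, 0.5, 0.5, 1), 2, 2)), 0.5)
  expect_error(fq_energy(c(1, 2, 3), c(0, 0), diag(2)), "mismatch")
})

test_that("FQ parameter files round-trip and drive geometry assembly", {
  dir <- withr::local_tempdir()
  path <- generate_fixtures("fq_params", seed = 9, dir = dir,
                            params = list(elements = c("O", "H")))
  pars <- read_fq_params(path)
  expect_setequal(pars$parameters$element, c("O", "H"))
  expect_true(all(pars$parameters$eta > 0))
  pos <- rbind(c(0, 0, 0), c(0.96, 0, 0), c(-0.24, 0.93, 0))
  sys <- fq_system_from_geometry(c("O", "H", "H"), pos, pars,
                                 molecule_size = 3L)
  expect_equal(nrow(sys$kernel), 3L)
  sys <- solve_fq(sys)
  expect_equal(sum(sys$charges), 0, tolerance = 1e-12)
})
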