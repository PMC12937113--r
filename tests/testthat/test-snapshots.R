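make_toy_frame <- function(distances_ang) {
  # solute: H2 at the origin; diatomic solvent molecules along +x at the
  # programmed minimum distances from the nearest solute atom
  solute <- rbind(c(0, 0, 0), c(0.74, 0, 0))
  pos <- solute
  groups <- list()
  for (m in seq_along(distances_ang)) {
    a1 <- c(0.74 + distances_ang[m], 0.9 * m, 0)
    # rotate per molecule so distances stay as programmed from atom 2
    d <- sqrt(sum((a1 - solute[2, ])^2))
    a1 <- solute[2, ] + (a1 - solute[2, ]) * distances_ang[m] / d
    a2 <- a1 + c(0.74, 0, 0)
    pos <- rbind(pos, a1, a2)
    groups[[m]] <- 2L + (m - 1L) * 2L + 1:2
  }
  snapshot(rep("H", nrow(pos)), pos, 1:2, groups)
}

test_that("droplet extraction keeps whole molecules by nearest-atom distance", {
  snap <- make_toy_frame(c(5, 14, 16))
  # radius 15: molecules at 5 and 14 kept, 16 dropped
  drop <- extract_droplet(snap, 15)
  expect_length(drop$solvent_molecules, 2L)
  expect_length(drop$elements, 6L)
  # huge radius keeps everything
  all_in <- extract_droplet(snap, 1e6)
  expect_length(all_in$solvent_molecules, 3L)
  # straddling molecule: first atom inside, partner outside -> fully kept
  straddle <- snapshot(rep("H", 4),
                       rbind(c(0, 0, 0), c(0.74, 0, 0),
                             c(0.74 + 9.9, 0, 0), c(0.74 + 9.9 + 5, 0, 0)),
                       1:2, list(3:4))
  kept <- extract_droplet(straddle, 10)
  expect_length(kept$solvent_molecules, 1L)
  expect_length(kept$solvent_molecules[[1L]], 2L)
  # idempotence: extracting again with the same radius is a no-op
  again <- extract_droplet(drop, 15)
  expect_equal(again$positions_ang, drop$positions_ang)
  expect_equal(again$solvent_molecules, drop$solvent_molecules)
  expect_error(extract_droplet(snap, 0), "positive")
})

test_that("ensemble statistics cover mean, median, mode, spread and SE", {
  one <- ensemble_statistics(2.0)
  expect_equal(one$mean, 2.0)
  expect_equal(one$spread, 0)
  expect_equal(one$standard_error, 0)
  tri <- ensemble_statistics(c(1, 2, 3))
  expect_equal(tri$mean, 2)
  expect_equal(tri$median, 2)
  expect_equal(tri$spread, 2)
  expect_equal(tri$standard_error, sd(c(1, 2, 3)) / sqrt(3))
  # seeded normal sample: SE close to sigma / sqrt(n)
  set.seed(71)
  x <- rnorm(200, mean = 4.5, sd = 0.2)
  st <- ensemble_statistics(x)
  expect_lt(abs(st$standard_error - 0.2 / sqrt(200)) / (0.2 / sqrt(200)), 0.2)
  expect_lt(abs(st$mode - 4.5), 0.2)
  # permutation invariance
  st2 <- ensemble_statistics(rev(x))
  expect_equal(st2$mean, st$mean)
  expect_equal(st2$mode, st$mode)
  expect_equal(st2$spread, st$spread)
  expect_error(ensemble_statistics(numeric(0)), "at least one")
})

test_that("running means converge as prescribed", {
  const <- convergence_check(rep(3.3, 200))
  expect_true(const$converged)
  expect_true(all(const$means == 3.3))
  alt <- convergence_check(rep(c(1, -1), 100))
  expect_equal(alt$means, rep(0, 4))
  set.seed(72)
  x <- rnorm(200)
  cc <- convergence_check(x)
  expect_equal(cc$means,
               vapply(c(50, 100, 150, 200),
                      function(k) mean(x[seq_len(k)]), numeric(1)))
  expect_warning(convergence_check(rnorm(80)), "truncating")
})

test_that("solvatochromic shift is solution minus gas (positive = blue)", {
  expect_equal(solvatochromic_shift(3.32, 3.73), -0.41)
  expect_equal(solvatochromic_shift(4.0, 4.0), 0)
  expect_equal(solvatochromic_shift(5.0, 4.8), 0.2)
  expect_error(solvatochromic_shift(NaN, 1), "finite")
})

test_that("fixture generators are seed-deterministic and round-trip", {
  dir <- withr::local_tempdir()
  p1 <- generate_fixtures("toy_snapshots", seed = 31, dir = file.path(dir, "a"),
                          params = list(n_frames = 2L, n_solvent = 3L))
  p2 <- generate_fixtures("toy_snapshots", seed = 31, dir = file.path(dir, "b"),
                          params = list(n_frames = 2L, n_solvent = 3L))
  expect_identical(readLines(p1[1]), readLines(p2[1]))
  expect_identical(readLines(p1[2]), readLines(p2[2]))
  snaps <- read_snapshots(p1[1], p1[2])
  expect_length(snaps, 2L)
  expect_identical(snaps[[1]]$solute_atom_indices, 1:2)
  expect_length(snaps[[1]]$solvent_molecules, 3L)

  # random FCIDUMP respects the 8-fold symmetry (asserted on permutations)
  fp <- generate_fixtures("fcidump_random", seed = 32, dir = dir,
                          params = list(L = 4L))
  ints <- read_fcidump(fp)
  g <- ints$g
  expect_equal(g, aperm(g, c(2, 1, 3, 4)), tolerance = 1e-14)
  expect_equal(g, aperm(g, c(1, 2, 4, 3)), tolerance = 1e-14)
  expect_equal(g, aperm(g, c(3, 4, 1, 2)), tolerance = 1e-14)
  expect_equal(g, aperm(g, c(4, 3, 2, 1)), tolerance = 1e-14)

  # programmed distances reproduce the droplet example
  pd <- generate_fixtures("toy_snapshots", seed = 33, dir = dir,
                          params = list(n_frames = 1L, n_solvent = 3L,
                                        distances_ang = c(5, 14, 16)))
  snap <- read_snapshots(pd[1], pd[2])[[1]]
  drop <- extract_droplet(snap, 15)
  expect_length(drop$solvent_molecules, 2L)
})

test_that("a 5-frame toy ensemble runs end to end with finite gaps", {
  dir <- withr::local_tempdir()
  paths <- generate_fixtures("toy_snapshots", seed = 34, dir = dir,
                             params = list(n_frames = 5L, n_solvent = 3L))
  snaps <- read_snapshots(paths[1], paths[2])
  cfg <- dmrgfq_config(2L, 2L, max_bond = 16L)
  t0 <- Sys.time()
  df <- snapshot_excitations(snaps, c("H", "H"),
                             fq_params = synthetic_fq_params("H"),
                             config = cfg, radius = 15)
  elapsed <- as.numeric(Sys.time() - t0, units = "mins")
  expect_identical(nrow(df), 5L)
  expect_true(all(is.finite(df$gap_ev)))
  expect_true(all(df$gap_ev > 0))
  expect_lt(elapsed, 5)
  st <- ensemble_statistics(df$gap_ev)
  expect_gte(st$spread, 0)
  expect_equal(st$standard_error, sd(df$gap_ev) / sqrt(5))
  # frames are independent jobs: a permuted frame order gives identical
  # per-frame energies
  df2 <- snapshot_excitations(snaps[c(3, 1, 5, 2, 4)], c("H", "H"),
                              fq_params = synthetic_fq_params("H"),
                              config = cfg, radius = 15)
  expect_equal(df2$gap_ev[order(df2$frame)], df$gap_ev, tolerance = 1e-9)
})
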