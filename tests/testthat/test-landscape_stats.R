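test_that("landscape TSV round trip and validation work", {
  L <- make_landscape(replicas = 3, jitter = 0.5, seed = 4)
  f <- tempfile(fileext = ".tsv")
  write_landscape(L, f)
  L2 <- read_landscape(f)
  expect_equal(as.data.frame(L2), as.data.frame(L), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(length(unique(L2$k)), 3L)

  one <- energy_landscape(k = 1, z = 0, phi = 0, dG = -30)
  expect_equal(nrow(one), 1L)

  expect_error(energy_landscape(k = c(1, 1), z = c(0, 0), phi = c(0, 0),
                                dG = c(-1, -2)), "duplicate")
  bad <- tempfile(fileext = ".tsv")
  writeLines("k\tz\tphi\n1\t0\t0", bad)
  expect_error(read_landscape(bad), "missing: dG")
})

test_that("mode membership uses strict half-circle boundaries", {
  expect_true(in_mode(0, "I"))
  expect_true(in_mode(173, "II"))
  expect_false(in_mode(90, "I"))
  expect_false(in_mode(90, "II"))
  expect_false(in_mode(-90, "I"))
  expect_false(in_mode(-90, "II"))
  expect_false(in_mode(270, "I"))  # wraps to the -90 boundary
  expect_true(in_mode(200, "II"))  # wraps to -160
  # the two modes partition everything off the boundaries
  phis <- seq(-179, 179, by = 1)
  expect_true(all(xor(in_mode(phis, "I"), in_mode(phis, "II")) |
                    phis %in% c(-90, 90)))
})

test_that("mode free energy matches analytic single- and two-state values", {
  # single state: F equals its dG
  L1 <- energy_landscape(1, 0, 0, -30)
  expect_equal(mode_free_energy(L1, "I", E_c = -25, T = 298), -30)

  # two equal states: F = dG - kT ln 2
  L2 <- energy_landscape(c(1, 1), c(0, 1), c(0, 0), c(-30, -30))
  expect_equal(mode_free_energy(L2, "I", T = 298),
               -30 - kB_kcal * 298 * log(2), tolerance = 1e-12)

  # cutoff excludes states at or above E_c
  L3 <- energy_landscape(c(1, 1), c(0, 1), c(0, 0), c(-30, -20))
  expect_equal(mode_free_energy(L3, "I", E_c = -25, T = 298), -30)
  expect_error(mode_free_energy(L3, "I", E_c = -35, T = 298), "no allowed")
  expect_error(mode_free_energy(L1, "II", T = 298), "no allowed")
})

test_that("aggregation equals a brute-force Boltzmann sum to 1e-9", {
  L <- make_landscape(replicas = 4, jitter = 1, seed = 11)
  for (mode in c("I", "II")) {
    for (Ec in c(-25, -15, Inf)) {
      expect_equal(mode_free_energy(L, mode, Ec, T = 298),
                   bf_mode_free_energy(L, mode, Ec, 298),
                   tolerance = 1e-9)
    }
  }
  # no overflow at dG/kT ~ -65: dG = -38.5 at 298 K
  deep <- energy_landscape(1, 0, 0, -38.5)
  expect_equal(mode_free_energy(deep, "I", T = 298), -38.5,
               tolerance = 1e-12)
})

test_that("free energy respects Boltzmann-sum bounds and k-permutation", {
  L <- make_landscape(replicas = 3, jitter = 1, seed = 21)
  sub <- L[L$allowed & in_mode(L$phi, "I"), ]
  Fv <- mode_free_energy(L, "I", T = 298)
  kT <- kB_kcal * 298
  expect_lte(Fv, min(sub$dG))
  expect_gte(Fv, min(sub$dG) - kT * log(nrow(sub)))

  # permuting the replica index leaves the aggregate unchanged
  Lp <- L
  Lp$k <- c(3, 1, 2)[Lp$k]
  expect_equal(mode_free_energy(Lp, "I", T = 298), Fv, tolerance = 1e-12)
})

test_that("F is non-increasing in E_c and the plateau is localized", {
  L <- make_landscape(replicas = 2, jitter = 1, seed = 5)
  scan <- saturation_scan(L, "I", seq(-45, -5, by = 0.5), T = 298)
  Fs <- scan$curve$F[!is.na(scan$curve$F)]
  expect_true(all(diff(Fs) <= 1e-12))

  # all states below -40: constant for E_c > -40
  Lc <- energy_landscape(1, c(0, 1, 2), c(0, 0, 0), c(-42, -41, -40.5))
  sc <- saturation_scan(Lc, "I", seq(-40, -10, by = 1), T = 298)
  expect_equal(diff(range(sc$curve$F)), 0, tolerance = 1e-12)
})

test_that("plateau detection on two-level systems", {
  # states 1 kcal/mol apart: F keeps moving until the second state is
  # admitted, so the plateau starts just above the upper level
  L2 <- energy_landscape(1, c(0, 1), c(0, 0), c(-38, -37))
  sc2 <- saturation_scan(L2, "I", seq(-40, -10, by = 0.5), T = 298)
  expect_gt(sc2$plateau_onset, -37)
  expect_lte(sc2$plateau_onset, -36.5)
  expect_equal(sc2$saturation, bf_mode_free_energy(L2, "I", Inf, 298),
               tolerance = 1e-9)

  # a state 14 kcal/mol up carries Boltzmann weight e^-23.6 at 298 K:
  # F is already saturated just above the lower level
  L3 <- energy_landscape(1, c(0, 1), c(0, 0), c(-38, -24))
  sc3 <- saturation_scan(L3, "I", seq(-40, -10, by = 0.5), T = 298)
  expect_lte(sc3$plateau_onset, -37)
  expect_equal(sc3$saturation, -38, tolerance = 1e-9)
})

test_that("mode probabilities follow the Boltzmann ratio", {
  eq <- probability_ratio(-30, -30, T = 298)
  expect_equal(eq$ratio, 1)
  expect_equal(eq$p_I, 0.5)

  # reciprocal ratios multiply to one
  a <- probability_ratio(-38.5, -35.3, T = 298)
  b <- probability_ratio(-35.3, -38.5, T = 298)
  expect_equal(a$ratio * b$ratio, 1, tolerance = 1e-12)
  expect_equal(a$p_I + a$p_II, 1, tolerance = 1e-12)

  # ratio tends to 1 as T grows, monotonically for fixed dF
  rs <- vapply(c(298, 308, 1000, 1e5, 1e8),
               function(Tk) probability_ratio(-38.5, -35.3, Tk)$ratio,
               numeric(1))
  expect_true(all(diff(rs) < 0))
  expect_equal(rs[5], 1, tolerance = 1e-3)
  # 298 -> 308 K is a small, continuous change
  expect_lt(abs(rs[2] - rs[1]) / rs[1], 0.2)
})

test_that("minimum report finds per-mode minima and their locations", {
  L <- make_landscape(seed = 1)  # clean two-basin default, no jitter
  mI <- minimum_report(L, "I")
  mII <- minimum_report(L, "II")
  # basins at (0, 3) and (0, 173); grid nodes at phi = 2 or 4
  expect_equal(mI$overall$z, 0)
  expect_lte(abs(mI$overall$phi - 3), 1)
  expect_lte(abs(mII$overall$phi - 173), 1)
  expect_lte(mI$overall$dG_min, min(-38, mI$per_k$dG_min))
  expect_error(minimum_report(energy_landscape(1, 0, 0, -5), "II"),
               "no allowed")

  # constant landscape: first cell in scan order
  Lc <- energy_landscape(1, c(0, 0, 1), c(0, 4, 0), c(-7, -7, -7))
  expect_equal(minimum_report(Lc, "I")$overall$z, 0)
})
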