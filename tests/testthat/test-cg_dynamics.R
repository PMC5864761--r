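test_that("identical seeds give bit-identical trajectories", {
  topo <- build_topology(make_hairpin())
  a <- integrate_langevin(topo, T = 0.3, steps = 2000, stride = 200,
                          seed = 99)
  b <- integrate_langevin(topo, T = 0.3, steps = 2000, stride = 200,
                          seed = 99)
  expect_identical(a$frames, b$frames)
  c <- integrate_langevin(topo, T = 0.3, steps = 2000, stride = 200,
                          seed = 100)
  expect_false(identical(c$frames, b$frames))
})

test_that("undamped zero-temperature dynamics conserves energy", {
  topo <- build_topology(make_helix(10))
  set.seed(3)
  start <- topo$coords + matrix(rnorm(length(topo$coords), sd = 0.05),
                                ncol = 3)
  tr <- integrate_langevin(topo, T = 0, gamma = 0, steps = 10000,
                           stride = 100, start = start, seed = 1)
  expect_lt(max(tr$total_energy) - min(tr$total_energy), 1e-4)
})

test_that("a tethered bead satisfies positional and kinetic equipartition", {
  # single bead in a harmonic well of stiffness k: var(x) = kB T / k
  topo <- single_bead_topology()
  k <- 0.5; Temp <- 0.4
  tether <- list(bead = 1L, anchor = matrix(0, 1, 3), k = k)
  tr <- integrate_langevin(topo, T = Temp, steps = 4e5, stride = 40,
                           seed = 7, tethers = tether)
  burn <- -(1:1000)
  xs <- tr$frames[burn, 1]
  v <- stats::var(xs)
  se <- sqrt(2 / length(xs)) * Temp / k  # crude SE of the variance
  expect_lt(abs(v - Temp / k), 3 * max(se, 0.02 * Temp / k) + 0.01)

  # kinetic energy per degree of freedom on a 20-bead fixture
  topo20 <- build_topology(make_helix(20))
  st <- native_state_stats(topo20, T_values = 0.3, n_traj = 3,
                           steps = 20000, equil_steps = 2000, seed = 5)
  expect_equal(st$mean_ke_per_dof, 0.15, tolerance = 0.05)
})

test_that("P0 and Q bracket the folded-unfolded transition", {
  topo <- build_topology(make_hairpin())
  st <- native_state_stats(topo, T_values = c(0.05, 0.5, 2.2), n_traj = 5,
                           steps = 10000, equil_steps = 2000, seed = 2)
  expect_true(all(st$P0 <= st$Q + 1e-12))
  expect_equal(st$P0[1], 1)
  expect_equal(st$Q[1], 1, tolerance = 0.01)
  expect_lt(st$P0[3], 0.05)
  # both non-increasing in T on this fixture
  expect_true(all(diff(st$P0) <= 0.02))
  expect_true(all(diff(st$Q) <= 0.02))
})

test_that("unfolding times define a finite, T-decreasing median", {
  topo <- build_topology(make_hairpin())
  # no nonlocal contacts: vacuous unfolding at t = 0
  h <- build_topology(make_helix(8))
  expect_warning(u0 <- unfolding_times(h, 1.0, n_traj = 2, max_time = 10),
                 "no nonlocal")
  expect_equal(u0$t_u, 0)

  ut <- unfolding_times(topo, c(1.2, 1.8), n_traj = 50, max_time = 400,
                        seed = 3)
  expect_gt(ut$unfolded_fraction[2], 0.5)
  expect_lt(ut$t_u[ut$T == 1.8], ut$t_u[ut$T == 1.2])
  times <- attr(ut, "times")[[2]]
  expect_true(all(times[is.finite(times)] <= 400))
})

test_that("censoring makes the median infinite when unfolding is rare", {
  topo <- build_topology(make_hairpin())
  ut <- unfolding_times(topo, 0.1, n_traj = 5, max_time = 5, seed = 4)
  expect_equal(ut$unfolded_fraction, 0)
  expect_equal(ut$t_u, Inf)
})

test_that("pulling a single free bead settles to the viscous drag force", {
  topo <- single_bead_topology()
  v_p <- 0.01
  cv <- pull(topo, pulled_bead = 1, fixed_bead = NA, v_p = v_p, T = 0,
             max_d = 30, seed = 1)
  tail_F <- cv$F[cv$d > 15]
  # overdamped steady state: F = gamma * m * v_p
  expect_equal(mean(tail_F), topo$params$gamma * v_p, tolerance = 0.1)
  expect_lt(stats::sd(tail_F), 1e-3)
})

test_that("quasi-static rupture force approaches the bond's force maximum", {
  topo <- two_bead_topology(r0 = 3.8)
  sigma <- topo$contact_sigma
  # strongest restoring force of the 12-6 well along the pull axis
  rr <- seq(2^(1/6) * sigma, 3 * sigma, by = 1e-4)
  f_star <- max(abs(native_lj_energy(rr, sigma)$force))
  fast <- pull(topo, pulled_bead = 2, fixed_bead = 1, v_p = 5e-3, T = 0,
               max_d = 25, seed = 1)
  slow <- pull(topo, pulled_bead = 2, fixed_bead = 1, v_p = 5e-4, T = 0,
               max_d = 25, seed = 1)
  expect_lt(abs(slow$F_max - f_star) / f_star, 0.2)
  # single force peak
  pk <- which(diff(sign(diff(slow$F))) == -2)
  expect_lte(length(pk[slow$F[pk + 1] > 0.2 * slow$F_max]), 1L)
  # slip-bond regime: F_max non-decreasing over a decade of speed
  expect_gte(fast$F_max, slow$F_max - 1e-6)
})

test_that("interface break log precedes dissociation on the toy complex", {
  topo <- build_topology(make_two_body_complex())
  cv <- pull(topo, v_p = 5e-3, max_d = 60, seed = 11)
  expect_false(is.na(cv$dissociation_d))
  iface <- cv$last_break[cv$last_break$class == "interface", ]
  expect_true(all(is.finite(iface$d)))
  expect_true(all(iface$d <= cv$dissociation_d + 1 + 1e-9))
  expect_true(all(diff(cv$d) > 0))
  expect_equal(cv$F_max, max(cv$F))
})

test_that("re-formed contacts record their last break, not their first", {
  # moderate temperature makes breakage flicker before final rupture
  topo <- two_bead_topology(r0 = 3.8)
  seen_reform <- FALSE
  for (seed in 1:8) {
    cv <- pull(topo, pulled_bead = 2, fixed_bead = 1, v_p = 2e-3, T = 0.25,
               max_d = 20, seed = seed)
    lb <- cv$last_break
    if (any(lb$n_breaks > 1, na.rm = TRUE)) {
      seen_reform <- TRUE
      i <- which(lb$n_breaks > 1)[1]
      expect_gt(lb$d[i], lb$first_d[i])
    }
  }
  expect_true(seen_reform)
})

test_that("trajectory classification splits ensembles at the threshold", {
  expect_equal(classify_trajectory(10, threshold_d = 100), "short")
  expect_equal(classify_trajectory(150, threshold_d = 100), "long")

  # synthetic bimodal ensemble with known mixing weights
  set.seed(13)
  n <- 300
  w <- 0.66
  long <- stats::rbinom(n, 1, w) == 1
  dd <- ifelse(long, rnorm(n, 200, 12), rnorm(n, 80, 10))
  curves <- lapply(dd, function(d) {
    structure(list(d = c(1, d), F = c(0.1, 0.1), F_max = 0.1,
                   last_break = data.frame(contact = integer(0),
                                           class = character(0),
                                           d = numeric(0)),
                   dissociation_d = d, final_d = d),
              class = "dualbind_force_extension")
  })
  rep140 <- scenario_report(curves, threshold_d = 140)
  phat <- rep140$fraction_long
  expect_lt(abs(phat - w), 3 * sqrt(w * (1 - w) / n))
  expect_true(rep140$ci_long[1] < w && w < rep140$ci_long[2])

  # derived threshold lands between the modes
  repauto <- scenario_report(curves)
  expect_gt(repauto$threshold_d, 110)
  expect_lt(repauto$threshold_d, 170)
  expect_equal(repauto$labels, rep140$labels)

  # degenerate cases
  all_long <- scenario_report(curves, threshold_d = 0)
  expect_equal(all_long$fraction_long, 1)
  one <- scenario_report(curves[1], threshold_d = 140)
  expect_equal(one$n, 1L)
})
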