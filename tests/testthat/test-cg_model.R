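test_that("topology counts bonds, contacts and chirality terms", {
  h4 <- make_helix(4)
  t4 <- build_topology(h4)
  expect_equal(length(t4$bond_i), 3L)
  expect_equal(length(t4$chir_q0), 1L)

  hp <- make_hairpin()
  thp <- build_topology(hp)
  m <- native_contacts(hp)
  expect_equal(length(thp$contact_i), nrow(m))

  # native configuration: bond and chirality zero, native = -eps per contact
  e <- total_energy(thp)
  expect_equal(e$bond, 0, tolerance = 1e-9)
  expect_equal(e$chirality, 0, tolerance = 1e-9)
  expect_equal(e$native, -length(thp$contact_i), tolerance = 1e-9)
  expect_equal(e$total, e$bond + e$native + e$repulsive + e$chirality,
               tolerance = 1e-10)

  # a chain break is rejected unless explicitly allowed
  broken <- hp[!(hp$resno %in% 11:12), ]
  broken <- dualbind:::new_structure(broken)
  expect_error(build_topology(broken), "chain break")
  expect_s3_class(build_topology(broken, allow_breaks = TRUE),
                  "dualbind_topology")
})

test_that("pair potentials match their closed forms", {
  expect_equal(native_lj_energy(1, 1)$energy, 0, tolerance = 1e-12)
  mn <- native_lj_energy(2^(1/6), 1)
  expect_equal(mn$energy, -1, tolerance = 1e-12)
  expect_equal(mn$force, 0, tolerance = 1e-12)
  # generic point against direct evaluation at extended precision
  r <- 1.5 * 2^(1/6) * 3.3
  s6 <- (3.3 / r)^6
  expect_equal(native_lj_energy(r, 3.3)$energy, 4 * (s6^2 - s6),
               tolerance = 1e-14)

  expect_equal(repulsive_energy(4), 0, tolerance = 1e-12)
  expect_equal(repulsive_energy(10), 0)
  s6r <- ((4 / 2^(1/6)) / 3)^6
  expect_equal(repulsive_energy(3), 4 * (s6r^2 - s6r) + 1,
               tolerance = 1e-12)
  expect_gt(repulsive_energy(3), 0)
  # continuity at the cutoff
  expect_lt(abs(repulsive_energy(4 - 1e-9)), 1e-7)
})

test_that("chirality energy is zero at native, positive for the mirror", {
  h <- make_helix(8)
  ca <- as.matrix(calpha_coords(h)[, c("x", "y", "z")])
  expect_equal(chirality_energy(ca, native = ca), 0, tolerance = 1e-12)

  mirror <- ca %*% diag(c(1, 1, -1))
  refs <- dualbind:::chain_chirality(
    ca, mean(sqrt(rowSums(diff(ca)^2))))
  want <- 2 * 1 * sum(refs^2)  # (kappa/2)(C - (-C))^2 summed
  expect_equal(chirality_energy(mirror, native = ca), want,
               tolerance = 1e-9)

  # random perturbation agrees with the direct formula
  set.seed(31)
  pert <- ca + matrix(rnorm(length(ca), sd = 0.3), ncol = 3)
  d0 <- mean(sqrt(rowSums(diff(ca)^2)))
  C <- dualbind:::chain_chirality(pert, d0)
  expect_equal(chirality_energy(pert, native = ca),
               sum(0.5 * (C - refs)^2), tolerance = 1e-12)
})

test_that("analytic forces agree with central finite differences", {
  hp <- make_hairpin()
  topo <- build_topology(hp)
  set.seed(41)
  x <- topo$coords + matrix(rnorm(length(topo$coords), sd = 0.15), ncol = 3)
  f <- total_force(topo, x)
  h <- 1e-6
  for (i in sample(nrow(x), 6)) {
    for (d in 1:3) {
      xp <- x; xp[i, d] <- xp[i, d] + h
      xm <- x; xm[i, d] <- xm[i, d] - h
      num <- -(total_energy(topo, xp)$total -
                 total_energy(topo, xm)$total) / (2 * h)
      expect_equal(f[i, d], num, tolerance = 1e-4,
                   info = sprintf("bead %d axis %d", i, d))
    }
  }
})

test_that("internal forces conserve momentum and torque", {
  topo <- build_topology(make_two_body_complex())
  set.seed(43)
  for (rep in 1:3) {
    x <- topo$coords + matrix(rnorm(length(topo$coords), sd = 0.2), ncol = 3)
    f <- total_force(topo, x)
    expect_lt(max(abs(colSums(f))), 1e-9)
    tq <- colSums(cbind(x[, 2] * f[, 3] - x[, 3] * f[, 2],
                        x[, 3] * f[, 1] - x[, 1] * f[, 3],
                        x[, 1] * f[, 2] - x[, 2] * f[, 1]))
    expect_lt(max(abs(tq)), 1e-8)
  }
})

test_that("energy is rigid-invariant and forces rotate covariantly", {
  topo <- build_topology(make_hairpin())
  set.seed(47)
  x <- topo$coords + matrix(rnorm(length(topo$coords), sd = 0.2), ncol = 3)
  e0 <- total_energy(topo, x)$total
  f0 <- total_force(topo, x)
  tr <- random_rigid_transform(49)
  x2 <- sweep(x %*% t(tr$R), 2, -tr$t)
  expect_equal(total_energy(topo, x2)$total, e0, tolerance = 1e-9)
  expect_equal(total_force(topo, x2), f0 %*% t(tr$R), tolerance = 1e-7)
})

test_that("native state is a stationary point of the full Hamiltonian", {
  for (s in list(make_helix(10), make_hairpin(), make_two_body_complex())) {
    topo <- build_topology(s)
    expect_lt(max(abs(total_force(topo))), 1e-8)
  }
})

test_that("overlapping beads are rejected and topology serializes", {
  topo <- build_topology(make_helix(6))
  x <- topo$coords
  x[4, ] <- x[1, ]
  expect_error(total_energy(topo, x), "overlapping")

  f <- tempfile(fileext = ".tsv")
  write_topology(topo, f)
  txt <- readLines(f)
  expect_true(any(grepl("^# beads", txt)))
  expect_true(any(grepl("^# contacts", txt)))
})
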