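test_that("difference vectors pair equivalent helix residues", {
  doc <- make_helix(60)
  v0 <- difference_vectors(doc, doc)
  # 13 + 12 residues in the two binding helices; identical docs give zeros
  expect_equal(dim(v0), c(25L, 3L))
  expect_lt(max(abs(v0)), 1e-12)

  # rotation by 180 degrees about an axis through the centroid gives
  # vectors perpendicular to that axis
  pr <- make_rotated_pair(doc, axis = c(1, 1, 0), angle = 180, seed = 2)
  v <- difference_vectors(pr$a, pr$b)
  proj <- v %*% pr$ground_truth$axis
  expect_lt(max(abs(proj)), 1e-8)

  expect_error(difference_vectors(make_helix(8), make_helix(8),
                                  helices = list(h = 100:110)),
               "missing")
})

test_that("symmetry axis is the plane normal for planar vectors", {
  set.seed(9)
  # vectors spanning a random plane with normal nvec
  nvec <- c(2, -1, 2) / 3
  b1 <- c(1, 2, 0); b1 <- b1 - sum(b1 * nvec) * nvec
  b2 <- c(0, -1, 3); b2 <- b2 - sum(b2 * nvec) * nvec
  V <- t(sapply(1:8, function(i) runif(1, -2, 2) * b1 + runif(1, -2, 2) * b2))
  fr <- find_symmetry_axis(V)
  expect_lt(attr(fr, "rms_z"), 1e-6)
  expect_equal(abs(sum(fr$axes[3, ] * nvec)), 1, tolerance = 1e-6)
  # residuals non-increasing
  expect_true(all(diff(attr(fr, "residuals")) <= 1e-12))
})

test_that("axis and mode angle recover the generator ground truth", {
  base <- make_helix(60)
  for (seed in 1:4) {
    set.seed(seed)
    ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
    pr <- make_rotated_pair(base, axis = ax, angle = 160, seed = seed)
    v <- difference_vectors(pr$a, pr$b)
    fr <- find_symmetry_axis(v)
    got <- fr$axes[3, ]
    ang_axis <- acos(min(1, abs(sum(got * ax)))) * 180 / pi
    expect_lt(ang_axis, 1)
    ang <- mode_rotation_angle(pr$a, pr$b, fr)
    # sign of the derived axis is arbitrary: 160 or 200 degrees
    expect_true(min(abs(ang - 160), abs(ang - 200)) < 0.5)
  }
  # with coordinate noise the angle is still recovered within 2 degrees
  # (axis transverse to the helix, so the lever arms are long)
  errs <- vapply(1:10, function(seed) {
    pr <- make_rotated_pair(base, axis = c(1, 0, 0), angle = 160,
                            noise = 0.3, seed = seed)
    fr <- find_symmetry_axis(difference_vectors(pr$a, pr$b))
    ang <- mode_rotation_angle(pr$a, pr$b, fr)
    min(abs(ang - 160), abs(ang - 200))
  }, numeric(1))
  expect_lt(max(errs), 2)
})

test_that("axis recovery is invariant under a common rigid transform", {
  base <- make_helix(60)
  pr <- make_rotated_pair(base, axis = c(0.2, 0.3, 0.93), angle = 174,
                          seed = 3)
  fr0 <- find_symmetry_axis(difference_vectors(pr$a, pr$b))
  ang0 <- mode_rotation_angle(pr$a, pr$b, fr0)
  tr <- random_rigid_transform(17)
  a2 <- transform_structure(pr$a, tr$R, tr$t)
  b2 <- transform_structure(pr$b, tr$R, tr$t)
  fr2 <- find_symmetry_axis(difference_vectors(a2, b2))
  ang2 <- mode_rotation_angle(a2, b2, fr2)
  expect_equal(min(abs(ang2 - ang0), abs(ang2 + ang0 - 360)), 0,
               tolerance = 0.1)
  # transformed axis equals the rotation of the original axis
  want <- as.numeric(tr$R %*% fr0$axes[3, ])
  expect_equal(abs(sum(fr2$axes[3, ] * want)), 1, tolerance = 1e-4)
})

test_that("mode angles of the two directions sum to a full turn", {
  base <- make_helix(60)
  pr <- make_rotated_pair(base, axis = c(0, 0, 1), angle = 130, noise = 0.2,
                          seed = 8)
  fr <- find_symmetry_axis(difference_vectors(pr$a, pr$b))
  ab <- mode_rotation_angle(pr$a, pr$b, fr)
  ba <- mode_rotation_angle(pr$b, pr$a, fr)
  expect_equal((ab + ba) %% 360, 0, tolerance = 0.5)
})

test_that("rigid poses compose, wrap and invert as rotations should", {
  doc <- make_helix(12)
  fr <- dualbind:::new_symmetry_frame(c(1, 2, 3), diag(3))

  same <- apply_pose(doc, fr, rigid_pose(0, 0))
  expect_equal(as.matrix(same[, c("x", "y", "z")]),
               as.matrix(doc[, c("x", "y", "z")]), tolerance = 1e-12)

  full <- apply_pose(doc, fr, rigid_pose(0, 360))
  expect_lt(max(abs(as.matrix(full[, c("x", "y", "z")]) -
                      as.matrix(doc[, c("x", "y", "z")]))), 1e-6)

  # composition of pure rotations
  p1 <- apply_pose(apply_pose(doc, fr, rigid_pose(0, 40)), fr,
                   rigid_pose(0, 35))
  p2 <- apply_pose(doc, fr, rigid_pose(0, 75))
  expect_equal(as.matrix(p1[, c("x", "y", "z")]),
               as.matrix(p2[, c("x", "y", "z")]), tolerance = 1e-9)

  # z shift moves along +Z only
  sh <- apply_pose(doc, fr, rigid_pose(2.5, 0))
  expect_equal(sh$z - doc$z, rep(2.5, nrow(doc)), tolerance = 1e-12)

  # phi wraps into [-180, 180)
  expect_equal(rigid_pose(0, 270)$phi, -90)
})

test_that("posing a mode pair by its recovered angle superposes the modes", {
  base <- make_helix(60)
  pr <- make_rotated_pair(base, axis = c(0, 0, 1), angle = 174, seed = 1)
  fr <- find_symmetry_axis(difference_vectors(pr$a, pr$b))
  ang <- mode_rotation_angle(pr$a, pr$b, fr)
  posed <- apply_pose(pr$a, fr, rigid_pose(0, ang))
  # direct (unsuperposed) coordinate RMSD: the pose must land on mode II
  raw_rmsd <- function(s1, s2) {
    a <- as.matrix(calpha_coords(s1)[, c("x", "y", "z")])
    b <- as.matrix(calpha_coords(s2)[, c("x", "y", "z")])
    sqrt(mean(rowSums((a - b)^2)))
  }
  rms0 <- raw_rmsd(pr$a, pr$b)
  rms1 <- raw_rmsd(posed, pr$b)
  expect_lt(rms1, rms0)
  # small residual remains because the frame origin (mode midpoint) need
  # not lie exactly on the generator's axis for angles other than 180
  expect_lt(rms1, 0.1)
})

test_that("steric mask rejects clashes and is monotone on approach", {
  a <- make_helix(10)
  b_far <- transform_structure(a, diag(3), c(100, 0, 0))
  expect_true(steric_allowed(a, b_far))
  expect_false(steric_allowed(a, a))  # on top of itself

  # head-on approach along +z: once forbidden, stays forbidden
  coh <- transform_structure(make_helix(10), diag(3), c(0, 0, 20))
  fr <- dualbind:::new_symmetry_frame(c(0, 0, 0), diag(3))
  allowed <- vapply(seq(0, 16, by = 1), function(zs) {
    steric_allowed(coh, apply_pose(a, fr, rigid_pose(zs, 0)))
  }, logical(1))
  first_forbidden <- which(!allowed)[1]
  expect_false(is.na(first_forbidden))
  expect_true(all(!allowed[first_forbidden:length(allowed)]))
})

test_that("pose grids carry a filled steric mask and a manifest", {
  tb <- make_two_body_complex()
  coh <- dualbind:::subset_chain(tb, "A")
  doc <- dualbind:::subset_chain(tb, "B")
  fr <- dualbind:::new_symmetry_frame(c(0, 0, 0), diag(3))

  single <- generate_pose_grid(coh, doc, fr, z_values = 0, phi_values = 0)
  expect_true(single$allowed[1, 1])

  grid <- generate_pose_grid(coh, doc, fr, z_values = seq(-4, 6, 2),
                             phi_values = seq(-180, 120, 60))
  frac <- mean(grid$allowed)
  expect_gt(frac, 0)
  expect_lt(frac, 1)

  # export + re-read: manifest matches and poses round-trip
  dir <- tempfile("poses")
  grid2 <- generate_pose_grid(coh, doc, fr, z_values = c(0, 2),
                              phi_values = c(0, 90), out_dir = dir)
  man <- read.table(file.path(dir, "manifest.tsv"), header = TRUE, sep = "\t")
  expect_equal(nrow(man), 4L)
  expect_equal(man$allowed, as.vector(grid2$allowed))
  one <- man[man$allowed, ][1, ]
  reposed <- read_pdb(file.path(dir, one$filename))
  direct <- apply_pose(doc, fr, rigid_pose(one$z, one$phi))
  expect_lt(max(abs(as.matrix(reposed[, c("x", "y", "z")]) -
                      as.matrix(direct[, c("x", "y", "z")]))), 1e-3)

  expect_error(generate_pose_grid(coh, doc, fr, z_values = numeric(0),
                                  phi_values = 0), "empty")
})
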