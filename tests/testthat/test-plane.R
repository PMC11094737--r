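# Quartet-plane fitting, planarity, tilt, rise, axis and twist.

test_that("planarity of constructed clouds matches closed-form values", {
  # coplanar points: zero planarity, normal along z
  set.seed(11)
  flat <- cbind(matrix(runif(32, -5, 5), 16, 2), 0)
  p <- fit_quartet_plane(flat)
  expect_lt(p$planarity, 1e-9)
  expect_equal(abs(p$normal[3]), 1, tolerance = 1e-9)

  # points alternating z = +0.5 / -0.5: RMSD of equal |z| is 0.5
  alt <- cbind(cos(seq(0, 2 * pi, length.out = 13)[-13]),
               sin(seq(0, 2 * pi, length.out = 13)[-13]),
               rep(c(0.5, -0.5), 6))
  expect_equal(fit_quartet_plane(alt)$planarity, 0.5, tolerance = 1e-9)
})

test_that("SVD planarity equals the brute-force plane-search RMSD", {
  set.seed(42)
  for (i in 1:8) {
    cloud <- matrix(rnorm(60, sd = 3), 20, 3)
    cloud[, 3] <- cloud[, 3] * 0.1          # roughly planar
    p <- fit_quartet_plane(cloud)
    expect_equal(p$planarity, bruteforce_planarity(cloud), tolerance = 1e-6)
  }
})

test_that("planarity equals the explicit residual RMSD about the fitted plane", {
  set.seed(7)
  for (i in 1:10) {
    cloud <- matrix(rnorm(45), 15, 3)
    p <- fit_quartet_plane(cloud)
    res <- sweep(cloud, 2, p$centroid) %*% p$normal
    expect_equal(p$planarity, sqrt(mean(res^2)), tolerance = 1e-9)
  }
})

test_that("planarity, tilt, rise and |twist| are rigid-motion invariant", {
  set.seed(13)
  stem <- ideal_stem(4)
  g0 <- stem_geometry(stem$traj, stem$topology)
  cloud <- matrix(rnorm(60, sd = 2), 20, 3)
  p0 <- fit_quartet_plane(cloud)
  for (i in 1:5) {
    rg <- random_rigid()
    expect_equal(fit_quartet_plane(apply_rigid(cloud, rg))$planarity,
                 p0$planarity, tolerance = 1e-8)
    xyz <- apply_rigid(frame_coords(stem$traj, 1), rg)
    traj <- gq_trajectory(stem$traj$atoms, xyz)
    g <- stem_geometry(traj, stem$topology)
    expect_equal(g$steps$tilt, g0$steps$tilt, tolerance = 1e-8)
    expect_equal(g$steps$rise, g0$steps$rise, tolerance = 1e-8)
    expect_equal(abs(g$steps$twist), abs(g0$steps$twist), tolerance = 1e-8)
  }
})

test_that("buckling one base strictly increases planarity", {
  d0 <- make_deformation_traj(stem_blueprint(3), n_frames = 1)
  d1 <- make_deformation_traj(stem_blueprint(3), n_frames = 1,
                              buckle = list(strand = 1, quartet = 3, angle = 25))
  g0 <- stem_geometry(d0$traj, d0$topology)
  g1 <- stem_geometry(d1$traj, d1$topology)
  expect_gt(g1$quartets$planarity[3], g0$quartets$planarity[3] + 0.05)
  expect_equal(g1$quartets$planarity[1:2], g0$quartets$planarity[1:2],
               tolerance = 1e-9)
})

test_that("tilt reproduces constructed rotations and is symmetric", {
  sq <- cbind(c(1, -1, -1, 1, 2, -2), c(1, 1, -1, -1, 0, 0), 0)
  pa <- fit_quartet_plane(sq)
  expect_equal(tilt(pa, pa), 0, tolerance = 1e-12)
  for (ang in c(5, 15, 60)) {
    R <- gqmech:::rotation_matrix(c(1, 0, 0), ang)
    pb <- fit_quartet_plane(sq %*% t(R))
    expect_equal(tilt(pa, pb), ang, tolerance = 1e-6)
    expect_equal(tilt(pb, pa), tilt(pa, pb), tolerance = 1e-12)
  }
  # random pair agrees with the direct arccos oracle on co-oriented normals
  set.seed(3)
  for (i in 1:5) {
    ca <- matrix(rnorm(30), 10, 3); cb <- matrix(rnorm(30), 10, 3)
    pa <- fit_quartet_plane(ca); pb <- fit_quartet_plane(cb)
    na <- pa$normal; nb <- pb$normal
    if (sum(na * nb) < 0) nb <- -nb
    expect_equal(tilt(pa, pb), acos(min(1, sum(na * nb))) * 180 / pi,
                 tolerance = 1e-9)
  }
})

test_that("rise reproduces symmetric displacements and generator truth", {
  sq <- 5 * cbind(c(1, -1, -1, 1, 0.5, -0.5), c(1, 1, -1, -1, 0.2, -0.2), 0)
  up <- sweep(sq, 2, c(0, 0, 3.3), "+")
  expect_equal(rise(sq, up), 3.3, tolerance = 1e-6)
  expect_equal(rise(sq, sq), 0, tolerance = 1e-9)
  stem <- build_ideal_stem(stem_blueprint(4, rise_per_step = 3.4))
  g <- stem_geometry(stem$traj, stem$topology)
  expect_equal(g$steps$rise, rep(3.4, 3), tolerance = 0.01)
})

test_that("stem axis is the centroid principal direction, oriented 5'->3'", {
  stem <- ideal_stem(4)
  xyz <- frame_coords(stem$traj, 1)
  g <- stem_geometry(stem$traj, stem$topology)
  expect_equal(abs(sum(g$axes[1, ] * c(0, 0, 1))), 1, tolerance = 1e-6)
  # two-quartet stem: forced to the normalized centroid difference
  c2 <- rbind(c(0, 0, 0), c(1, 2, 2))
  expect_equal(stem_axis(c2), c(1, 2, 2) / 3, tolerance = 1e-12)
  # equivariance under rotation
  set.seed(5)
  cents <- cbind(rnorm(4, sd = 0.1), rnorm(4, sd = 0.1), c(0, 3.3, 6.8, 10))
  rg <- random_rigid()
  expect_equal(stem_axis(apply_rigid(cents, rg)),
               as.vector(rg$R %*% stem_axis(cents)), tolerance = 1e-9)
})

test_that("step and total twist match construction, with mirror parity", {
  per_step <- c(25, 30, 35)
  d <- make_deformation_traj(stem_blueprint(4), n_frames = 1,
                             twist = matrix(per_step, 1, 3))
  g <- stem_geometry(d$traj, d$topology)
  expect_equal(g$steps$twist, per_step, tolerance = 1e-6)
  expect_equal(g$frames$total_twist, sum(per_step), tolerance = 1e-6)

  stem_l <- build_ideal_stem(stem_blueprint(3, twist_per_step = -30))
  gl <- stem_geometry(stem_l$traj, stem_l$topology)
  expect_equal(gl$steps$twist, c(-30, -30), tolerance = 1e-6)
  expect_equal(gl$frames$total_twist, -60, tolerance = 1e-6)
  expect_equal(gl$frames$handedness, -1)

  # mirror image of a right-handed stem: twist flips sign exactly
  stem_r <- ideal_stem(3)
  xyz <- frame_coords(stem_r$traj, 1)
  xyz[, 1] <- -xyz[, 1]
  gm <- stem_geometry(gq_trajectory(stem_r$traj$atoms, xyz), stem_r$topology)
  gr <- stem_geometry(stem_r$traj, stem_r$topology)
  expect_equal(gm$steps$twist, -gr$steps$twist, tolerance = 1e-8)
})

test_that("degenerate inputs raise informative geometry errors", {
  expect_error(fit_quartet_plane(rbind(c(0, 0, 0), c(1, 1, 1))), "3 points")
  line <- cbind(1:10, 2 * (1:10), -1 * (1:10))
  expect_error(fit_quartet_plane(line), "collinear")
  expect_error(fit_quartet_plane(rbind(c(0, 0, NA), c(1, 0, 0), c(0, 1, 0))),
               "finite")
  expect_error(stem_axis(matrix(1, 3, 3)), "coincident")
  expect_error(stem_axis(matrix(c(0, 0, 0), 1, 3)), "at least 2")
  # reference vector parallel to the axis
  expect_error(step_twist(c(0, 0, 1), c(1, 0, 0), c(0, 0, 1)), "parallel")
})
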