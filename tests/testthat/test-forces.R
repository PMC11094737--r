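# Spring-force reconstruction, decomposition, edge overlap, rupture forces.

test_that("spring force converts harmonic extension to pN via Avogadro", {
  s <- pulling_schedule(force_constant = 180)
  expect_equal(spring_force(0, 1, s, center = 1)$force_pN, 0)
  # dimensional-analysis oracle: kJ/mol/nm -> pN through N_A
  pn_per_kjmolnm <- 1e3 / 6.02214076e23 / 1e-9 * 1e12
  expect_equal(spring_force(0, 1, s, center = 2)$force_pN,
               180 * pn_per_kjmolnm, tolerance = 1e-6)
  expect_equal(round(spring_force(0, 1, s, center = 2)$force_pN, 1), 298.9)
  expect_equal(round(spring_force(0, 1, s, center = 1.5)$force_pN, 1), 149.4)
  # compression is negative
  expect_lt(spring_force(0, 2, s, center = 1)$force_pN, 0)
  expect_error(spring_force(c(0, 1, 1), c(1, 1, 1), s), "increasing")
})

test_that("restraint center moves at the scheduled speed", {
  s <- pulling_schedule(pull_speed = 5.4, d0 = 1)
  sf <- spring_force(c(0, 1000), c(1, 1), s)   # 1 us apart
  expect_equal(sf$center, c(1, 6.4), tolerance = 1e-12)
})

test_that("out-of-plane angle is signed and handles degenerate force", {
  n <- c(0, 0, 1)
  expect_equal(out_of_plane_angle(c(5, 0, 0), n), 0)
  expect_equal(out_of_plane_angle(c(0, 0, 7), n), 90)
  expect_equal(out_of_plane_angle(c(0, 0, -7), n), -90)
  f30 <- c(cos(30 * pi / 180), 0, sin(30 * pi / 180))
  expect_equal(out_of_plane_angle(f30, n), 30, tolerance = 1e-6)
  expect_true(is.na(out_of_plane_angle(c(0, 0, 0), n)))
  # average over co-oriented normals
  ns <- rbind(c(0, 0, 1), c(0.05, 0, sqrt(1 - 0.05^2)))
  expect_gt(out_of_plane_angle(c(0, 0, 1), ns), 85)
})

test_that("force decomposition is an exact trigonometric identity", {
  expect_equal(decompose_force(5, 90)$F_horizontal, 0, tolerance = 1e-12)
  expect_equal(decompose_force(5, 90)$F_vertical, 5)
  expect_equal(decompose_force(5, 0)$F_horizontal, 5)
  expect_equal(decompose_force(5, 0)$F_vertical, 0)
  expect_equal(decompose_force(123, 45)$vh_ratio, 1, tolerance = 1e-12)
  expect_true(is.na(decompose_force(5, 90)$vh_ratio))
  set.seed(99)
  Fm <- runif(10000, 0, 500)
  beta <- runif(10000, -90, 90)
  d <- decompose_force(Fm, beta)
  expect_equal(d$F_horizontal^2 + d$F_vertical^2, Fm^2, tolerance = 1e-8)
  expect_equal(d$vh_ratio, d$F_vertical / d$F_horizontal, tolerance = 1e-8)
})

test_that("edge unit vectors lie in the quartet plane and co-rotate", {
  stem <- ideal_stem(4)
  xyz <- frame_coords(stem$traj, 1)
  atoms <- stem$traj$atoms
  eu <- edge_unit_vectors(xyz, atoms, stem$topology, s = 1, k = 2)
  expect_equal(gqmech:::vnorm(eu$u_wc), 1, tolerance = 1e-9)
  expect_equal(gqmech:::vnorm(eu$u_h), 1, tolerance = 1e-9)
  # in-plane: negligible component along the stem normal (z)
  expect_lt(abs(eu$u_wc[3]), 0.05)
  expect_lt(abs(eu$u_h[3]), 0.05)

  # direct bisector oracle from the constructed H-bond vectors
  get <- function(s, k, nm) {
    st <- stem$topology$strands[[s]]
    xyz[gqmech:::atom_index(atoms, st$chain, st$g_resno[k], nm), ]
  }
  v1 <- (get(2, 2, "O6") - get(1, 2, "N1"))
  v2 <- (get(2, 2, "N7") - get(1, 2, "N2"))
  bis <- v1 / gqmech:::vnorm(v1) + v2 / gqmech:::vnorm(v2)
  expect_equal(eu$u_wc, bis / gqmech:::vnorm(bis), tolerance = 1e-9)

  # equivariance under a rigid rotation
  set.seed(21)
  rg <- random_rigid()
  xyz2 <- apply_rigid(xyz, rg)
  eu2 <- edge_unit_vectors(xyz2, atoms, stem$topology, s = 1, k = 2)
  expect_equal(eu2$u_wc, as.vector(rg$R %*% eu$u_wc), tolerance = 1e-9)
  expect_equal(eu2$u_h, as.vector(rg$R %*% eu$u_h), tolerance = 1e-9)
})

test_that("force-edge overlap matches hand examples and stays bounded", {
  e <- list(u_wc = c(1, 0, 0), u_h = c(0, 1, 0))
  expect_equal(force_edge_overlap(c(2, 0, 0), e), 1)
  expect_equal(force_edge_overlap(c(0, -3, 0), e), -1)
  expect_equal(force_edge_overlap(c(3, 4, 0), e), -0.2)
  expect_true(is.na(force_edge_overlap(c(0, 0, 0), e)))
  set.seed(31)
  for (i in 1:200) {
    ew <- rnorm(3); eh <- rnorm(3)
    e <- list(u_wc = ew / gqmech:::vnorm(ew), u_h = eh / gqmech:::vnorm(eh))
    feo <- force_edge_overlap(rnorm(3, sd = 10), e)
    expect_true(feo >= -1 && feo <= 1)
  }
})

test_that("beta and feo are invariant under joint rigid rotation", {
  stem <- ideal_stem(3)
  xyz <- frame_coords(stem$traj, 1)
  atoms <- stem$traj$atoms
  g <- stem_geometry(stem$traj, stem$topology)
  f <- c(120, -40, 260)
  eu <- edge_unit_vectors(xyz, atoms, stem$topology, 2, 3)
  b0 <- out_of_plane_angle(f, c(0, 0, 1))
  feo0 <- force_edge_overlap(f, eu)
  set.seed(8)
  for (i in 1:3) {
    rg <- random_rigid()
    xyz2 <- apply_rigid(xyz, rg)
    traj2 <- gq_trajectory(atoms, xyz2)
    g2 <- stem_geometry(traj2, stem$topology)
    f2 <- as.vector(rg$R %*% f)
    eu2 <- edge_unit_vectors(xyz2, atoms, stem$topology, 2, 3)
    n2 <- as.vector(rg$R %*% c(0, 0, 1))
    expect_equal(out_of_plane_angle(f2, n2), b0, tolerance = 1e-8)
    expect_equal(force_edge_overlap(f2, eu2), feo0, tolerance = 1e-8)
  }
})

test_that("rupture force recovers plateaus, ramps and noisy plateaus", {
  # constant 350 pN for 10 ns
  s <- structure(data.frame(time = seq(0, 10, 0.1), distance = 1, center = 1,
                            force_pN = 350),
                 class = c("force_series", "data.frame"))
  expect_equal(rupture_force(s, 10), 350)

  # linear ramp 0 -> 400 over 100 ns: discretized windowed-mean oracle
  tt <- seq(0, 100, 0.1)
  ramp <- structure(data.frame(time = tt, distance = 1, center = 1,
                               force_pN = 4 * tt),
                    class = c("force_series", "data.frame"))
  nwin <- 21
  oracle <- max(stats::filter(4 * tt, rep(1 / nwin, nwin), sides = 2),
                na.rm = TRUE)
  expect_equal(rupture_force(ramp, 100), oracle, tolerance = 1e-9)
  expect_equal(rupture_force(ramp, 100), 396, tolerance = 1)

  # noisy plateau: within 3 sigma / sqrt(n_window) of the plateau mean
  set.seed(17)
  noisy <- structure(data.frame(time = tt, distance = 1, center = 1,
                                force_pN = 350 + rnorm(length(tt), 0, 10)),
                     class = c("force_series", "data.frame"))
  rf <- rupture_force(noisy, 100)
  expect_lt(abs(rf - 350), 350 * 0.02 + 3 * 10 / sqrt(nwin))

  # maximality: result >= every windowed mean before the event
  rm_all <- stats::filter(abs(noisy$force_pN), rep(1 / nwin, nwin), sides = 2)
  expect_gte(rupture_force(noisy, 50) + 1e-9,
             max(rm_all[11:floor(50 / 0.1 - 10)], na.rm = TRUE))

  expect_error(rupture_force(s, -5), "precedes")
  expect_error(rupture_force(s, 0.5), "exceeds")
})

test_that("transition forces average trailing windows per event", {
  tt <- seq(0, 30, 0.1)
  f <- ifelse(tt < 15, 200, 320)
  ser <- structure(data.frame(time = tt, distance = 1, center = 1,
                              force_pN = f),
                   class = c("force_series", "data.frame"))
  tf <- transition_forces(ser, c(10, 25))
  expect_equal(tf$transition_force_pN, c(200, 320))
  # single event on a constant trace
  expect_equal(transition_forces(ser, 10)$transition_force_pN, 200)
  # windowed-mean oracle on a scripted sawtooth
  tr <- make_force_trace(pulling_schedule(d0 = 1),
                         ruptures = data.frame(time = c(40, 80),
                                               plateau = c(300, 380)),
                         t_total = 100, dt = 0.1, seed = 5, noise_sd = 4)
  for (te in c(40, 80)) {
    sel <- tr$series$time >= te - 2 & tr$series$time <= te
    expect_equal(transition_forces(tr$series, te)$transition_force_pN,
                 mean(abs(tr$series$force_pN[sel])), tolerance = 1e-9)
  }
  expect_warning(transition_forces(ser, 1), "truncated")
  expect_error(transition_forces(ser, c(25, 10)), "ordered")
})
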