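# The synthetic generator: blueprint invariants, determinism, validation.

test_that("built stems satisfy the blueprint contracts for 3-5 quartets", {
  for (nq in 3:5) {
    stem <- ideal_stem(nq)
    g <- stem_geometry(stem$traj, stem$topology)
    expect_equal(g$steps$twist, rep(30, nq - 1), tolerance = 1e-6)
    expect_equal(g$steps$rise, rep(3.4, nq - 1), tolerance = 1e-6)
    expect_equal(g$frames$total_twist, 30 * (nq - 1), tolerance = 1e-6)
    expect_true(all(g$quartets$planarity < 0.1))
    st <- hbond_state(frame_coords(stem$traj, 1), stem$traj$atoms,
                      stem$topology)
    for (k in seq_len(nq))
      expect_equal(gqmech:::quartet_row_bonds(st, k), 8)
    # n_quartets - 1 channel ions
    expect_equal(sum(stem$traj$atoms$elety == "K"), nq - 1)
  }
})

test_that("impossible blueprints are rejected", {
  expect_error(stem_blueprint(rise_per_step = -1), "positive")
  expect_error(stem_blueprint(n_quartets = 1), ">= 2")
  expect_error(stem_blueprint(radius = 2), "too small")
  # a radius far off the exact-H-bond family implies unphysical bonds
  expect_error(build_ideal_stem(stem_blueprint(radius = 12)), "radius")
})

test_that("deformation trajectories realize their schedules exactly", {
  tw <- seq(30, 20, length.out = 20)
  d <- make_deformation_traj(stem_blueprint(4), n_frames = 20, twist = tw,
                             seed = 2)
  g <- stem_geometry(d$traj, d$topology)
  rec <- tapply(g$steps$twist, g$steps$frame, mean)
  expect_equal(as.numeric(rec), tw, tolerance = 1e-6)
  expect_equal(d$truth$step_twist[, 1], tw)

  # zero-amplitude schedule: all descriptors constant
  d0 <- make_deformation_traj(stem_blueprint(3), n_frames = 5, seed = 3)
  g0 <- stem_geometry(d0$traj, d0$topology)
  expect_equal(diff(range(g0$frames$total_twist)), 0, tolerance = 1e-9)
  expect_equal(diff(range(g0$steps$rise)), 0, tolerance = 1e-9)
})

test_that("generators are bit-deterministic under a fixed seed", {
  a <- make_deformation_traj(stem_blueprint(3), n_frames = 6, noise_sd = 0.2,
                             seed = 42)
  b <- make_deformation_traj(stem_blueprint(3), n_frames = 6, noise_sd = 0.2,
                             seed = 42)
  expect_identical(a$traj$xyz, b$traj$xyz)

  s <- list(list(type = "unzip", frame = 20, strand = 1, level = 3,
                 edge = "wc"))
  u1 <- make_unfolding_traj(stem_blueprint(3), s, n_frames = 40,
                            noise_sd = 0.1, seed = 7)
  u2 <- make_unfolding_traj(stem_blueprint(3), s, n_frames = 40,
                            noise_sd = 0.1, seed = 7)
  expect_identical(u1$traj$xyz, u2$traj$xyz)

  t1 <- make_force_trace(pulling_schedule(d0 = 1),
                         ruptures = data.frame(time = 30, plateau = 300),
                         t_total = 50, noise_sd = 5, seed = 12)
  t2 <- make_force_trace(pulling_schedule(d0 = 1),
                         ruptures = data.frame(time = 30, plateau = 300),
                         t_total = 50, noise_sd = 5, seed = 12)
  expect_identical(t1$colvar, t2$colvar)
})

test_that("scripts violating detachment composability are rejected", {
  bad <- list(list(type = "detachment", frame = 50, strand = 2),
              list(type = "unzip", frame = 100, strand = 2, level = 1))
  expect_error(make_unfolding_traj(stem_blueprint(3), bad), "after its detachment")
  unordered <- list(list(type = "unzip", frame = 100, strand = 1, level = 1),
                    list(type = "detachment", frame = 50, strand = 2))
  expect_error(make_unfolding_traj(stem_blueprint(3), unordered), "increasing")
  expect_error(make_unfolding_traj(stem_blueprint(3),
                                   list(list(type = "warp", frame = 10))),
               "unknown")
  # empty script: a native trajectory
  u <- make_unfolding_traj(stem_blueprint(3), list(), n_frames = 5, seed = 1)
  expect_equal(u$traj$xyz[, , 1], u$traj$xyz[, , 5])
  expect_equal(nrow(detect_events(u$traj, u$topology)$events), 0)
})

test_that("force traces reconstruct exactly and encode scripted ruptures", {
  sch <- pulling_schedule(d0 = 1)
  tr <- make_force_trace(sch, ruptures = data.frame(time = 50, plateau = 350),
                         t_total = 70, dt = 0.05, seed = 4)
  rec <- spring_force(tr$colvar$time, tr$colvar$distance, sch,
                      center = tr$colvar$center)
  expect_lt(max(abs(rec$force_pN - tr$series$force_pN)), 1e-6)
  expect_equal(rupture_force(tr$series, 50), 350, tolerance = 1e-9)

  # zero noise, zero ruptures: a linear ramp
  tr0 <- make_force_trace(sch, t_total = 10, dt = 0.1, seed = 1)
  expect_equal(diff(tr0$series$force_pN),
               rep(diff(tr0$series$force_pN)[1], length(tr0$series$time) - 1),
               tolerance = 1e-9)
  rec0 <- spring_force(tr0$colvar$time, tr0$colvar$distance, sch,
                       center = tr0$colvar$center)
  expect_lt(max(abs(rec0$force_pN - tr0$series$force_pN)), 1e-6)
})
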