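# Unfolding-event classification: scripted-pathway recovery, persistence,
# permanence, edge ordering, statistics.

expect_timeline_matches <- function(timeline, truth, tol_frames = 10) {
  ev <- timeline$events
  expect_equal(nrow(ev), nrow(truth))
  expect_equal(ev$type, truth$type)
  for (i in seq_len(nrow(truth))) {
    expect_lte(abs(ev$frame[i] - truth$frame[i]), tol_frames)
    if (!is.na(truth$strand[i])) expect_equal(ev$strand[i], truth$strand[i])
    if (!is.na(truth$level[i])) expect_equal(ev$level[i], truth$level[i])
  }
}

test_that("a native-only trajectory yields an empty timeline", {
  d <- make_deformation_traj(stem_blueprint(3), n_frames = 30, noise_sd = 0.05,
                             seed = 9)
  tl <- detect_events(d$traj, d$topology)
  expect_equal(nrow(tl$events), 0)
})

test_that("a scripted multi-event pathway is recovered in type, order and frame", {
  script <- list(
    list(type = "anchorT_unstack", frame = 30, terminus = 8),
    list(type = "unzip", frame = 100, strand = 4, level = 4, edge = "wc"),
    list(type = "strand_slippage", frame = 200, strand = 2),
    list(type = "detachment", frame = 300, strand = 4)
  )
  u <- make_unfolding_traj(stem_blueprint(4), script, n_frames = 350, seed = 3)
  tl <- detect_events(u$traj, u$topology)
  expect_timeline_matches(tl, u$truth)
  # exact frames in the noise-free case
  expect_equal(tl$events$frame, u$truth$frame)
  # unzip annotations: 3' terminus of strand 4 is label 8; WC edge first
  unz <- tl$events[tl$events$type == "unzip", ]
  expect_equal(unz$terminus, 8L)
  expect_equal(unz$edge, "wc")
  expect_equal(unz$quartets_remaining_before, 4L)
})

test_that("single-frame H-bond flicker below persistence is suppressed", {
  stem <- ideal_stem(3)
  atoms <- stem$traj$atoms
  xyz0 <- frame_coords(stem$traj, 1)
  nfr <- 60
  arr <- array(rep(xyz0, nfr), c(nrow(atoms), 3, nfr))
  # eject one G for 3 frames only (shorter than the persistence window)
  tp <- stem$topology$strands[[1]]
  idx <- gqmech:::atom_index(atoms, tp$chain, tp$g_resno[3])
  for (f in 30:32) arr[idx, 1, f] <- arr[idx, 1, f] + 15
  tl <- detect_events(gq_trajectory(atoms, arr), stem$topology)
  expect_equal(nrow(tl$events), 0)
})

test_that("spirals are classified with their scripted handedness at both ends", {
  for (cfg in list(list(hand = "left", end = "3'", strand = 3),
                   list(hand = "right", end = "3'", strand = 1),
                   list(hand = "left", end = "5'", strand = 2),
                   list(hand = "right", end = "5'", strand = 4))) {
    script <- list(list(type = "spiral_form", frame = 40, strand = cfg$strand,
                        handedness = cfg$hand, end = cfg$end),
                   list(type = "spiral_resolve", frame = 120,
                        strand = cfg$strand))
    u <- make_unfolding_traj(stem_blueprint(4), script, n_frames = 170,
                             seed = 11)
    tl <- detect_events(u$traj, u$topology)
    expect_equal(tl$events$type, c("spiral_form", "spiral_resolve"))
    expect_equal(tl$events$frame, c(40, 120))
    expect_equal(tl$events$handedness[1], cfg$hand)
  }
})

test_that("opening, refold and cross-like rotation are recovered", {
  script <- list(list(type = "opening", frame = 50, strand = 1),
                 list(type = "refold", frame = 150),
                 list(type = "rotation_crosslike", frame = 250, strand = 2))
  u <- make_unfolding_traj(stem_blueprint(4), script, n_frames = 300, seed = 5)
  tl <- detect_events(u$traj, u$topology)
  expect_equal(tl$events$type, c("opening", "refold", "rotation_crosslike"))
  expect_equal(tl$events$frame, c(50, 150, 250))
  expect_equal(tl$events$strand[c(1, 3)], c(1L, 2L))
})

test_that("detachment is permanent: no later events involve the strand", {
  # choreograph post-detachment motion of the detached strand and check
  # the classifier stays silent about it
  script <- list(list(type = "unzip", frame = 60, strand = 1, level = 1,
                      edge = "hoogsteen"),
                 list(type = "detachment", frame = 150, strand = 1),
                 list(type = "strand_slippage", frame = 250, strand = 3))
  u <- make_unfolding_traj(stem_blueprint(4), script, n_frames = 320, seed = 6)
  tl <- detect_events(u$traj, u$topology)
  expect_equal(tl$events$type, c("unzip", "detachment", "strand_slippage"))
  det_i <- which(tl$events$type == "detachment")
  later <- tl$events[seq_len(nrow(tl$events)) > det_i, ]
  expect_false(any(later$strand == tl$events$strand[det_i], na.rm = TRUE))
  # 5' unzip annotations: terminus label = strand index, Hoogsteen first
  expect_equal(tl$events$terminus[1], 1L)
  expect_equal(tl$events$edge[1], "hoogsteen")
})

test_that("classification is robust to coordinate noise", {
  script <- list(list(type = "unzip", frame = 80, strand = 2, level = 4,
                      edge = "wc"),
                 list(type = "detachment", frame = 200, strand = 2))
  u <- make_unfolding_traj(stem_blueprint(4), script, n_frames = 260,
                           noise_sd = 0.1, seed = 7)
  tl <- detect_events(u$traj, u$topology)
  expect_timeline_matches(tl, u$truth, tol_frames = 10)
})

test_that("first_unzip_edge reports terminus, edge and contemporaneous feo", {
  script <- list(list(type = "unzip", frame = 60, strand = 3, level = 4,
                      edge = "wc"))
  u <- make_unfolding_traj(stem_blueprint(4), script, n_frames = 110, seed = 8)
  tl <- detect_events(u$traj, u$topology)
  feo <- data.frame(time = u$traj$time, feo = 0.35)
  fu <- first_unzip_edge(tl, feo)
  expect_true(fu$is_unzip)
  expect_equal(fu$edge, "wc")
  expect_equal(fu$terminus, 7L)          # 3' end of strand 3
  expect_equal(fu$feo_at_event, 0.35)
  # non-unzip first event gives an n/a record
  script2 <- list(list(type = "strand_slippage", frame = 50, strand = 2))
  u2 <- make_unfolding_traj(stem_blueprint(4), script2, n_frames = 100,
                            seed = 9)
  fu2 <- first_unzip_edge(detect_events(u2$traj, u2$topology))
  expect_false(fu2$is_unzip)
  expect_true(is.na(fu2$edge))
})

test_that("simultaneous loss of both edges is tie-broken as 'both'", {
  # unzip without a scripted edge: one-step ejection loses both edges in
  # the same frame
  script <- list(list(type = "unzip", frame = 50, strand = 1, level = 4))
  u <- make_unfolding_traj(stem_blueprint(4), script, n_frames = 100,
                           seed = 10)
  tl <- detect_events(u$traj, u$topology)
  expect_equal(tl$events$edge[tl$events$type == "unzip"], "both")
})

test_that("event statistics aggregate counts, termini and handedness", {
  # 45 runs, 36 of which start with a 3'-terminal unzip
  tls <- c(replicate(36, fake_timeline("unzip", terminus = 8), simplify = FALSE),
           replicate(9, fake_timeline("unzip", terminus = 1), simplify = FALSE))
  st <- event_stats(tls)
  expect_equal(st$first_3prime$count, 36)
  expect_equal(st$first_3prime$total, 45)
  expect_equal(st$first_3prime$fraction, 0.8)

  # spiral handedness 4 left / 6 right
  tls2 <- c(replicate(4, fake_timeline("spiral_form", handedness = "left"),
                      simplify = FALSE),
            replicate(6, fake_timeline("spiral_form", handedness = "right"),
                      simplify = FALSE))
  st2 <- event_stats(tls2)
  expect_equal(st2$spiral_handedness$left, 4)
  expect_equal(st2$spiral_handedness$fraction_left, 0.4)

  # single empty timeline: all-zero table
  st3 <- event_stats(list(fake_timeline(character(0))))
  expect_true(all(st3$counts == 0))
  expect_equal(st3$n_runs, 1)
})
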