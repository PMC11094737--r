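# Synthetic trajectories with ground truth: scheduled elastic deformations
# (twist/rise ramps, quartet buckling) and scripted unfolding pathways.
# No physics is claimed: the only contract is label fidelity — every frame
# realizes its scheduled parameters, every scripted event happens at its
# scripted frame.

#' Synthetic elastic-deformation trajectory
#'
#' Generates frames of an ideal stem whose per-step twist and rise follow
#' per-frame schedules, optionally with one or more guanines buckled out of
#' their quartet plane and seeded Gaussian coordinate noise. The returned
#' truth records the scheduled values per frame for parameter-recovery
#' tests.
#'
#' @param blueprint a [stem_blueprint()].
#' @param n_frames number of frames.
#' @param twist per-step twist schedule (degrees): `NULL` (constant at the
#'   blueprint value), a vector of length `n_frames` (same value for every
#'   step), or an `n_frames x (n_quartets - 1)` matrix.
#' @param rise per-step rise schedule (Angstrom), same shapes as `twist`.
#' @param buckle optional list(s) `list(strand =, quartet =, angle =)`
#'   where `angle` is a scalar or length-`n_frames` vector of degrees: the
#'   G base is rotated by that angle about the in-plane tangential axis
#'   through its base centroid.
#' @param noise_sd Gaussian coordinate noise SD in Angstrom (default 0).
#' @param dt frame spacing in ns (default 0.1).
#' @param seed integer RNG seed.
#' @return list of class `"synthetic_deformation"`: `traj`, `topology`,
#'   `truth` (list with `step_twist`, `step_rise` matrices
#'   `n_frames x (n_quartets-1)`, `buckle`, `noise_sd`, `seed`).
#' @export
make_deformation_traj <- function(blueprint = stem_blueprint(), n_frames = 50,
                                  twist = NULL, rise = NULL, buckle = NULL,
                                  noise_sd = 0, dt = 0.1, seed = 1) {
  nq <- blueprint$n_quartets
  nstep <- nq - 1
  expand <- function(x, default) {
    if (is.null(x)) return(matrix(default, n_frames, nstep))
    if (is.matrix(x)) {
      stopifnot(nrow(x) == n_frames, ncol(x) == nstep)
      return(x)
    }
    stopifnot(length(x) %in% c(1, n_frames))
    matrix(rep(x, length.out = n_frames), n_frames, nstep)
  }
  tw <- expand(twist, blueprint$twist_per_step)
  ri <- expand(rise, blueprint$rise_per_step)
  if (!is.null(buckle) && !is.null(buckle$strand)) buckle <- list(buckle)

  placement <- solve_quartet_placement(blueprint$radius, blueprint$hbond_length)
  built0 <- build_stem_coords(blueprint, placement = placement)
  atoms <- built0$atoms
  topology <- built0$topology

  set.seed(seed)
  xyz <- array(NA_real_, c(nrow(atoms), 3, n_frames))
  for (f in seq_len(n_frames)) {
    b <- build_stem_coords(blueprint, step_twists = tw[f, ],
                           step_rises = ri[f, ], placement = placement)
    co <- b$xyz
    for (bk in buckle) {
      ang <- if (length(bk$angle) == 1) bk$angle else bk$angle[f]
      co <- buckle_g(co, atoms, topology, bk$strand, bk$quartet, ang)
    }
    if (noise_sd > 0)
      co <- co + matrix(stats::rnorm(length(co), 0, noise_sd), nrow(co), 3)
    xyz[, , f] <- co
  }
  traj <- gq_trajectory(atoms, xyz, time = (seq_len(n_frames) - 1) * dt)
  structure(list(traj = traj, topology = topology,
                 truth = list(step_twist = tw, step_rise = ri,
                              buckle = buckle, noise_sd = noise_sd,
                              seed = seed, dt = dt)),
            class = "synthetic_deformation")
}

# Rotate the base (+C1') of the G at (strand, quartet) about the in-plane
# axis tangential to the helix through the base centroid.
buckle_g <- function(coords, atoms, topology, strand, quartet, angle) {
  if (abs(angle) < 1e-12) return(coords)
  st <- topology$strands[[strand]]
  idx <- atom_index(atoms, st$chain, st$g_resno[quartet])
  ctr <- colMeans(coords[idx, , drop = FALSE])
  radial <- c(ctr[1], ctr[2], 0)
  axis <- vcross(c(0, 0, 1), radial)          # tangential, in-plane
  R <- rotation_matrix(axis, angle)
  coords[idx, ] <- sweep(sweep(coords[idx, , drop = FALSE], 2, ctr) %*% t(R),
                         2, ctr, "+")
  coords
}

#' Scripted unfolding trajectory
#'
#' Generates a trajectory of an ideal stem realizing an ordered script of
#' unfolding events as step transitions at the scripted frames (a scripted
#' unzip with a declared first-breaking edge is realized in two stages: an
#' edge-selective displacement a few frames ahead, then full ejection at
#' the scripted frame). The returned truth timeline is the script itself.
#'
#' Supported event types and their script fields:
#' \describe{
#'   \item{unzip}{`strand`, `level`, optional `edge` ("wc"/"hoogsteen")}
#'   \item{strand_slippage}{`strand`, optional `offset` (default +1)}
#'   \item{opening}{`strand` (the donor strand of the pair interface that
#'     opens)}
#'   \item{detachment}{`strand`}
#'   \item{spiral_form}{`strand`, `handedness` ("left"/"right"), optional
#'     `end` ("5'" or "3'", default "3'")}
#'   \item{spiral_resolve}{`strand` (reverts that strand's spiral)}
#'   \item{rotation_crosslike}{`strand`}
#'   \item{refold}{no fields (restores the native stem)}
#'   \item{anchorT_unstack}{`terminus` (label 1-8)}
#' }
#'
#' @param blueprint a [stem_blueprint()].
#' @param script list of event lists, each with `type`, `frame` and the
#'   fields above. Frames must be increasing and well separated (>= the
#'   classifier persistence window apart to be recoverable).
#' @param n_frames trajectory length in frames.
#' @param noise_sd Gaussian coordinate noise SD in Angstrom (default 0).
#' @param dt frame spacing in ns (default 0.1).
#' @param seed integer RNG seed.
#' @param edge_lag frames between the edge-selective stage and full
#'   ejection of a scripted unzip (default 5).
#' @return list of class `"synthetic_unfolding"`: `traj`, `topology`,
#'   `truth` (data.frame: type, frame, time, strand, level, edge,
#'   handedness, terminus), `blueprint`.
#' @export
make_unfolding_traj <- function(blueprint = stem_blueprint(), script,
                                n_frames = NULL, noise_sd = 0, dt = 0.1,
                                seed = 1, edge_lag = 5) {
  validate_script(script, blueprint)
  if (is.null(n_frames))
    n_frames <- max(vapply(script, `[[`, numeric(1), "frame"), 0) + 50
  placement <- solve_quartet_placement(blueprint$radius, blueprint$hbond_length)
  built <- build_stem_coords(blueprint, placement = placement)
  atoms <- built$atoms
  topology <- built$topology
  native <- built$xyz

  # expand script into timed coordinate patches
  stages <- list()
  for (ev in script) {
    if (identical(ev$type, "unzip") && !is.null(ev$edge)) {
      stages[[length(stages) + 1]] <- list(frame = ev$frame - edge_lag,
                                           ev = ev, stage = "edge")
      stages[[length(stages) + 1]] <- list(frame = ev$frame, ev = ev,
                                           stage = "eject")
    } else {
      stages[[length(stages) + 1]] <- list(frame = ev$frame, ev = ev,
                                           stage = "full")
    }
  }
  stages <- stages[order(vapply(stages, `[[`, numeric(1), "frame"))]

  set.seed(seed)
  xyz <- array(NA_real_, c(nrow(atoms), 3, n_frames))
  cur <- native
  spiral_saved <- list()
  si <- 1
  for (f in seq_len(n_frames)) {
    while (si <= length(stages) && stages[[si]]$frame <= f) {
      st <- stages[[si]]
      cur <- apply_event_stage(cur, native, atoms, topology, blueprint,
                               st$ev, st$stage, spiral_saved)
      if (identical(st$ev$type, "spiral_form"))
        spiral_saved[[as.character(st$ev$strand)]] <- attr(cur, "saved")
      attr(cur, "saved") <- NULL
      si <- si + 1
    }
    fr <- cur
    if (noise_sd > 0)
      fr <- fr + matrix(stats::rnorm(length(fr), 0, noise_sd), nrow(fr), 3)
    xyz[, , f] <- fr
  }
  truth <- do.call(rbind, lapply(script, function(ev) data.frame(
    type = ev$type, frame = ev$frame, time = (ev$frame - 1) * dt,
    strand = if (is.null(ev$strand)) NA_integer_ else ev$strand,
    level = if (is.null(ev$level)) NA_integer_ else ev$level,
    edge = if (is.null(ev$edge)) NA_character_ else ev$edge,
    handedness = if (is.null(ev$handedness)) NA_character_ else ev$handedness,
    terminus = if (is.null(ev$terminus)) NA_integer_ else ev$terminus,
    stringsAsFactors = FALSE)))
  traj <- gq_trajectory(atoms, xyz, time = (seq_len(n_frames) - 1) * dt)
  structure(list(traj = traj, topology = topology, truth = truth,
                 blueprint = blueprint,
                 params = list(noise_sd = noise_sd, seed = seed, dt = dt,
                               edge_lag = edge_lag)),
            class = "synthetic_unfolding")
}

validate_script <- function(script, blueprint) {
  if (!length(script)) return(invisible(TRUE))
  frames <- vapply(script, `[[`, numeric(1), "frame")
  if (is.unsorted(frames, strictly = TRUE))
    stop("script event frames must be strictly increasing", call. = FALSE)
  detached <- integer(0)
  for (ev in script) {
    s <- ev$strand
    if (!is.null(s) && s %in% detached)
      stop(sprintf("script event '%s' at frame %d involves strand %d after its detachment",
                   ev$type, ev$frame, s), call. = FALSE)
    if (identical(ev$type, "detachment")) detached <- c(detached, ev$strand)
    if (identical(ev$type, "unzip") &&
        (ev$level < 1 || ev$level > blueprint$n_quartets))
      stop("unzip level outside the stem", call. = FALSE)
    if (identical(ev$type, "refold")) detached <- integer(0)
  }
  invisible(TRUE)
}

# indices of every atom of a strand (Gs and flanking Ts)
strand_atoms <- function(atoms, topology, s) {
  st <- topology$strands[[s]]
  which(atoms$chain == st$chain)
}

# helical transform of the blueprint: rotate about z by `levels` steps of
# twist and translate by `levels` steps of rise
helix_transform <- function(coords, blueprint, levels) {
  R <- rotation_matrix(c(0, 0, 1), levels * blueprint$twist_per_step)
  sweep(coords %*% t(R), 2, c(0, 0, levels * blueprint$rise_per_step), "+")
}

apply_event_stage <- function(cur, native, atoms, topology, blueprint, ev,
                              stage, spiral_saved) {
  type <- ev$type
  nq <- topology$n_quartets
  if (type == "unzip") {
    s <- ev$strand; k <- ev$level
    st <- topology$strands[[s]]
    gidx <- atom_index(atoms, st$chain, st$g_resno[k])
    if (stage == "edge") {
      cur[gidx, ] <- sweep(cur[gidx, , drop = FALSE], 2,
                           edge_break_shift(cur, atoms, topology, s, k, ev$edge),
                           "+")
    } else {
      ctr <- colMeans(cur[gidx, , drop = FALSE])
      radial <- unit(c(ctr[1], ctr[2], 0))
      cur[gidx, ] <- sweep(cur[gidx, , drop = FALSE], 2, 8 * radial, "+")
    }
  } else if (type == "strand_slippage") {
    off <- if (is.null(ev$offset)) 1 else ev$offset
    idx <- strand_atoms(atoms, topology, ev$strand)
    cur[idx, ] <- helix_transform(cur[idx, , drop = FALSE], blueprint, off)
  } else if (type == "opening") {
    cur <- open_interface(cur, atoms, topology, ev$strand)
  } else if (type == "detachment") {
    idx <- strand_atoms(atoms, topology, ev$strand)
    ctr <- colMeans(cur[idx, , drop = FALSE])
    radial <- unit(c(ctr[1], ctr[2], 0))
    cur[idx, ] <- sweep(cur[idx, , drop = FALSE], 2, 20 * radial, "+")
  } else if (type == "spiral_form") {
    s <- ev$strand
    st <- topology$strands[[s]]
    hand <- if (identical(ev$handedness, "left")) -1 else 1
    at5 <- identical(ev$end, "5'")
    # slip the terminal G (and its flanking T) one level beyond the stem
    # with an extra azimuthal wind; the winding measured 5'->3' carries the
    # handedness sign, so the 5'-side extra rotation is inverted
    move <- if (at5) {
      c(atom_index(atoms, st$chain, st$g_resno[1]),
        if (!is.na(st$t5_resno)) atom_index(atoms, st$chain, st$t5_resno))
    } else {
      c(atom_index(atoms, st$chain, st$g_resno[nq]),
        if (!is.na(st$t3_resno)) atom_index(atoms, st$chain, st$t3_resno))
    }
    saved <- cur[move, , drop = FALSE]
    shifted <- helix_transform(cur[move, , drop = FALSE], blueprint,
                               if (at5) -1 else 1)
    R <- rotation_matrix(c(0, 0, 1), if (at5) -hand * 90 else hand * 90)
    cur[move, ] <- shifted %*% t(R)
    attr(cur, "saved") <- list(idx = move, coords = saved)
  } else if (type == "spiral_resolve") {
    sv <- spiral_saved[[as.character(ev$strand)]]
    if (is.null(sv))
      stop("spiral_resolve without a prior spiral_form for that strand",
           call. = FALSE)
    cur[sv$idx, ] <- sv$coords
  } else if (type == "rotation_crosslike") {
    # flip the strand end-over-end about the tangential axis through its
    # centroid, nudged outward so its quartet H-bonds are gone while
    # heavy-atom contacts with the stem persist
    idx <- strand_atoms(atoms, topology, ev$strand)
    ctr <- colMeans(cur[idx, , drop = FALSE])
    radial <- unit(c(ctr[1], ctr[2], 0) + c(1e-6, 0, 0))
    axis <- vcross(c(0, 0, 1), radial)
    R <- rotation_matrix(axis, 150)
    cur[idx, ] <- sweep(sweep(cur[idx, , drop = FALSE], 2, ctr) %*% t(R),
                        2, ctr + 3 * radial, "+")
  } else if (type == "refold") {
    cur <- native
  } else if (type == "anchorT_unstack") {
    lab <- ev$terminus
    t <- topology$terminus_labels
    row <- t[t$label == lab, ]
    st <- topology$strands[[row$strand]]
    tres <- if (row$end == "5'") st$t5_resno else st$t3_resno
    if (is.na(tres)) stop("terminus has no flanking T", call. = FALSE)
    idx <- atom_index(atoms, row$chain, tres)
    dir <- if (row$end == "5'") c(0, 0, -5) else c(0, 0, 5)
    cur[idx, ] <- sweep(cur[idx, , drop = FALSE], 2, dir, "+")
  } else {
    stop("unknown script event type: ", type, call. = FALSE)
  }
  cur
}

# Displacement that breaks one H-bond edge of the G at (s, k) while keeping
# the other edge bonded; searched over magnitudes along the edge direction
# orthogonalized against the other edge.
edge_break_shift <- function(coords, atoms, topology, s, k, edge,
                             d_cut = 3.4) {
  eu <- edge_unit_vectors(coords, atoms, topology, s, k)
  if (identical(edge, "wc")) {
    u_break <- eu$u_wc; u_keep <- eu$u_h
  } else {
    u_break <- eu$u_h; u_keep <- eu$u_wc
  }
  d0 <- u_break - sum(u_break * u_keep) * u_keep
  d0 <- -unit(d0)
  get <- function(strand, name) {
    st <- topology$strands[[strand]]
    coords[atom_index(atoms, st$chain, st$g_resno[k], name), ]
  }
  s_next <- s %% 4 + 1
  s_prev <- (s + 2) %% 4 + 1
  wc_pairs <- list(list(get(s, "N1"), get(s_next, "O6")),
                   list(get(s, "N2"), get(s_next, "N7")))
  h_pairs  <- list(list(get(s, "O6"), get(s_prev, "N1")),
                   list(get(s, "N7"), get(s_prev, "N2")))
  brk <- if (identical(edge, "wc")) wc_pairs else h_pairs
  keep <- if (identical(edge, "wc")) h_pairs else wc_pairs
  for (m in seq(0.8, 3.5, by = 0.1)) {
    shift <- m * d0
    d_brk <- vapply(brk, function(p) vnorm(p[[2]] - (p[[1]] + shift)), numeric(1))
    d_keep <- vapply(keep, function(p) vnorm(p[[2]] - (p[[1]] + shift)), numeric(1))
    if (all(d_brk > d_cut + 0.5) && all(d_keep < d_cut - 0.2))
      return(shift)
  }
  # fall back to the widest separation achievable when the strict margins
  # are geometrically unreachable
  for (m in seq(0.8, 3.5, by = 0.1)) {
    shift <- m * d0
    d_brk <- vapply(brk, function(p) vnorm(p[[2]] - (p[[1]] + shift)), numeric(1))
    d_keep <- vapply(keep, function(p) vnorm(p[[2]] - (p[[1]] + shift)), numeric(1))
    if (all(d_brk > d_cut + 0.25) && all(d_keep < d_cut - 0.15))
      return(shift)
  }
  stop(sprintf("no edge-selective displacement found for strand %d level %d (%s edge)",
               s, k, edge), call. = FALSE)
}

# Book-opening of the interface between strand s (donor) and strand s+1:
# the block {s+1, s+2} swings about a vertical hinge near the far interface
# (between s+2 and s+3), breaking pair s -> s+1 while every other pair
# stays bonded.
open_interface <- function(coords, atoms, topology, s, d_cut = 3.4) {
  nq <- topology$n_quartets
  s1 <- s %% 4 + 1          # acceptor neighbor: interface s -> s1 opens
  s2 <- s1 %% 4 + 1
  s3 <- s2 %% 4 + 1
  block <- c(strand_atoms(atoms, topology, s1), strand_atoms(atoms, topology, s2))
  # hinge: vertical line through the midpoint of the still-bonded part of
  # the s2 -> s3 interface
  idx <- hb_indices(atoms, topology)
  hinge_rows <- integer(0)
  for (k in 1:nq) for (b in 1:2) {
    dn <- idx$don[s2, k, b]; ac <- idx$acc[s3, k, b]
    if (vnorm(coords[ac, ] - coords[dn, ]) <= d_cut)
      hinge_rows <- c(hinge_rows, dn, ac)
  }
  if (!length(hinge_rows))
    stop(sprintf("interface %d-%d has no bonds left to hinge on", s2, s3),
         call. = FALSE)
  hinge <- colMeans(coords[hinge_rows, , drop = FALSE])
  pair_dists <- function(co, p) {
    sa <- p %% 4 + 1
    c(vapply(1:nq, function(k) vnorm(co[idx$acc[sa, k, 1], ] - co[idx$don[p, k, 1], ]),
             numeric(1)),
      vapply(1:nq, function(k) vnorm(co[idx$acc[sa, k, 2], ] - co[idx$don[p, k, 2], ]),
             numeric(1)))
  }
  # constrain only bonds that exist before the opening (earlier events may
  # already have broken some)
  pre_open <- pair_dists(coords, s) <= d_cut
  pre_k1 <- pair_dists(coords, s1) <= d_cut
  pre_k2 <- pair_dists(coords, s2) <= d_cut
  for (ang in seq(20, 80, by = 5)) for (sgn in c(1, -1)) {
    R <- rotation_matrix(c(0, 0, 1), sgn * ang)
    co <- coords
    co[block, ] <- sweep(sweep(co[block, , drop = FALSE], 2, hinge) %*% t(R),
                         2, hinge, "+")
    # the opened interface must lose every pre-existing bond; the kept
    # interfaces must retain a solid majority of theirs (a single stretched
    # bond near the hinge is tolerable - the classifier only requires the
    # kept interfaces to stay bonded)
    ok_open <- all(pair_dists(co, s)[pre_open] > d_cut + 0.3)
    solid1 <- sum(pair_dists(co, s1)[pre_k1] < d_cut - 0.25)
    solid2 <- sum(pair_dists(co, s2)[pre_k2] < d_cut - 0.25)
    ok_keep <- solid1 >= min(4, sum(pre_k1)) && solid2 >= min(4, sum(pre_k2))
    # the fourth interface (s3 -> s) is untouched by construction
    if (ok_open && ok_keep) return(co)
  }
  stop(sprintf("no opening hinge found for interface %d-%d", s, s1),
       call. = FALSE)
}
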