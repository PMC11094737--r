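# Rule-based classification of unfolding transitions from per-frame H-bond
# and geometry descriptors. All thresholds are explicit parameters; a
# candidate state change must persist for `persistence` consecutive frames
# to commit as an event, and the event is stamped at the onset frame.

EVENT_TYPES <- c("unzip", "strand_slippage", "opening", "detachment",
                 "spiral_form", "spiral_resolve", "rotation_crosslike",
                 "refold", "anchorT_unstack")

#' Detect and classify unfolding events
#'
#' Scans a trajectory for the unfolding-transition taxonomy of parallel
#' G-stems. Operational rules (per frame, committed after `persistence`
#' consecutive frames, stamped at onset):
#' \describe{
#'   \item{unzip}{one G holds zero quartet H-bonds while at least two bonds
#'     among the remaining Gs of its quartet persist and its strand is
#'     still bonded elsewhere.}
#'   \item{strand_slippage}{the strand register (modal H-bond level shift,
#'     anchored at strand 1) changes by +-1 with bonds re-formed at the new
#'     level.}
#'   \item{opening}{one strand-strand interface retains zero H-bonds while
#'     both of its strands stay bonded to their other neighbor.}
#'   \item{detachment}{a strand has zero inter-strand H-bonds and no heavy
#'     atom within `contact_cut` of another strand; terminal for that
#'     strand.}
#'   \item{spiral_form / spiral_resolve}{monotone non-decreasing per-residue
#'     geometric level offsets along a strand (at least one G displaced a
#'     full level) plus cumulative backbone winding about the stem axis
#'     exceeding `winding_threshold` degrees per slipped level beyond the
#'     native value; the winding sign gives the handedness. The spiral
#'     resolves when the condition ends.}
#'   \item{rotation_crosslike}{a strand's 5'-3' end-to-end vector makes more
#'     than `rotation_angle` degrees with the stem axis while some
#'     inter-strand contact persists.}
#'   \item{refold}{the complete native H-bond set returns after at least
#'     one prior stem event.}
#'   \item{anchorT_unstack}{a flanking anchor thymine's base centroid moves
#'     beyond `unstack_cut` from the terminal quartet plane. Not a stem
#'     event (it alters no stem H-bond).}
#' }
#' At coincident onsets (within one persistence window) strand-level events
#' suppress per-G unzips of the same strand, and nothing involving a strand
#' is reported after its detachment.
#'
#' @param traj a [gq_trajectory()].
#' @param topology a `"stem_topology"`.
#' @param persistence frames a condition must hold to commit (default 10).
#' @param d_cut H-bond distance cutoff in A (default 3.4, distance-only).
#' @param contact_cut inter-strand heavy-atom contact distance in A
#'   (default 6).
#' @param unstack_cut anchor-T unstacking distance in A (default 5.5).
#' @param winding_threshold spiral winding threshold in degrees per slipped
#'   level (default 45).
#' @param rotation_angle end-to-end flip threshold in degrees (default 120).
#' @return object of class `"event_timeline"`: `events` data.frame (type,
#'   frame, time, strand, level, edge, handedness, terminus, residues,
#'   quartets_remaining_before), plus the parameters used.
#' @export
detect_events <- function(traj, topology, persistence = 10, d_cut = 3.4,
                          contact_cut = 6, unstack_cut = 5.5,
                          winding_threshold = 45, rotation_angle = 120) {
  atoms <- traj$atoms
  nq <- topology$n_quartets
  nf <- n_frames(traj)
  if (nf >= 2) {
    dts <- diff(traj$time)
    if (max(dts) - min(dts) > 1e-6 * max(abs(dts)))
      stop("non-uniform frame spacing; resample the trajectory first",
           call. = FALSE)
  }
  idx <- hb_indices(atoms, topology)
  gctr_idx <- lapply(1:4, function(s) lapply(1:nq, function(k)
    g_base_index(atoms, topology, s, k)))
  strand_idx <- lapply(1:4, function(s) strand_atoms(atoms, topology, s))
  tinfo <- topology$terminus_labels
  tinfo <- tinfo[!is.na(vapply(seq_len(nrow(tinfo)), function(i) {
    st <- topology$strands[[tinfo$strand[i]]]
    if (tinfo$end[i] == "5'") st$t5_resno else st$t3_resno
  }, numeric(1))), ]
  t_idx <- lapply(seq_len(nrow(tinfo)), function(i) {
    st <- topology$strands[[tinfo$strand[i]]]
    tres <- if (tinfo$end[i] == "5'") st$t5_resno else st$t3_resno
    atom_index(atoms, st$chain, tres,
               intersect(T_BASE_ATOMS, atoms$elety[atoms$chain == st$chain &
                                                   atoms$resno == tres]))
  })

  # ---- per-frame descriptors -------------------------------------------
  desc <- vector("list", nf)
  native_wind <- NULL
  native_zlev <- NULL
  lad_off <- rep(0, 4)   # ladder register, kept continuous across frames
  for (f in seq_len(nf)) {
    xyz <- frame_coords(traj, f)
    hb <- hbond_state(xyz, atoms, topology, d_cut = d_cut, idx = idx)
    gb <- matrix(0L, 4, nq)
    for (s in 1:4) for (k in 1:nq) gb[s, k] <- g_bond_count(hb, s, k)
    iface <- vapply(1:4, function(p) sum(hb[p, , , ]), numeric(1))
    sbonds <- vapply(1:4, function(s) sum(strand_pair_bonds(hb, s)), numeric(1))

    gctr <- array(NA_real_, c(4, nq, 3))
    for (s in 1:4) for (k in 1:nq)
      gctr[s, k, ] <- colMeans(xyz[gctr_idx[[s]][[k]], , drop = FALSE])
    # register-aware level ladder: each bonded G is assigned to the
    # physical level where it currently bonds. A partner's physical level
    # is its native index plus its strand's register offset (from the raw
    # H-bond state), so rows stay correct when a neighbor strand has
    # slipped; incidental off-register contacts are outvoted by the modal
    # rule.
    reg_raw <- register_matrix(hb)$offsets
    # the raw offsets are anchored arbitrarily; realign them to the
    # previous frame's ladder register so the ladder does not jump a level
    # when the best-bonded (anchor) strand changes
    both <- which(!is.na(reg_raw) & !is.na(lad_off))
    if (length(both)) {
      tb <- table(lad_off[both] - reg_raw[both])
      g <- as.numeric(names(tb)[which.max(tb)])
      reg_raw <- reg_raw + g
    }
    lad_off[!is.na(reg_raw)] <- reg_raw[!is.na(reg_raw)]
    assign_lev <- matrix(NA_integer_, 4, nq)
    for (s in 1:4) for (k in 1:nq) {
      s_next <- s %% 4 + 1            # acceptor of this strand's WC bonds
      p_acc <- (s + 2) %% 4 + 1       # pair whose acceptor strand is s
      votes <- numeric(0)
      if (!is.na(reg_raw[s_next]))
        votes <- c(votes, rep(1:nq + reg_raw[s_next],
                              rowSums(matrix(hb[s, k, , ], nq, 2))))
      if (!is.na(reg_raw[p_acc]))
        votes <- c(votes, rep(1:nq + reg_raw[p_acc],
                              rowSums(matrix(hb[p_acc, , k, ], nq, 2))))
      votes <- votes[votes >= 1 & votes <= nq]
      if (length(votes)) {
        tb <- table(votes)
        assign_lev[s, k] <- as.integer(names(tb)[which.max(tb)])
      }
    }
    qctr <- matrix(NA_real_, nq, 3)
    row_n <- integer(nq)
    row_pts <- vector("list", nq)
    for (lev in 1:nq) {
      members <- which(assign_lev == lev, arr.ind = TRUE)
      row_n[lev] <- nrow(members)
      if (row_n[lev] > 0) {
        pts <- t(vapply(seq_len(nrow(members)), function(i)
          gctr[members[i, 1], members[i, 2], ], numeric(3)))
        row_pts[[lev]] <- pts
        qctr[lev, ] <- colMeans(pts)
      }
    }
    have <- which(!is.na(qctr[, 1]))
    if (length(have) < 2) {   # no usable ladder: fall back to raw rows
      qctr <- t(vapply(1:nq, function(k) colMeans(gctr[, k, ]), numeric(3)))
      have <- 1:nq
      row_n <- rep(4L, nq)
      row_pts <- lapply(1:nq, function(k) t(vapply(1:4, function(s)
        gctr[s, k, ], numeric(3))))
    }
    # axis: mean of co-oriented level-plane normals (insensitive to a
    # missing strand, which would pull a centroid-line fit sideways)
    span <- qctr[max(have), ] - qctr[min(have), ]
    plane_rows <- which(row_n >= 3)
    axis <- NULL
    if (length(plane_rows) && vnorm(span) > 1e-6) {
      nsum <- c(0, 0, 0)
      for (lev in plane_rows) {
        pl <- tryCatch(fit_quartet_plane(row_pts[[lev]]),
                       error = function(e) NULL)
        if (is.null(pl)) next
        n <- if (sum(pl$normal * span) < 0) -pl$normal else pl$normal
        nsum <- nsum + n
      }
      if (vnorm(nsum) > 1e-6) axis <- unit(nsum)
    }
    if (is.null(axis))
      axis <- tryCatch(stem_axis(qctr[have, , drop = FALSE]),
                       error = function(e) c(0, 0, 1))
    full_rows <- which(row_n == 4)
    origin_rows <- if (length(full_rows) >= 2) full_rows else have
    origin <- colMeans(qctr[origin_rows, , drop = FALSE])

    zlev <- rep(NA_real_, nq)
    zlev[have] <- as.vector((qctr[have, , drop = FALSE] -
                               matrix(origin, length(have), 3, byrow = TRUE)) %*% axis)
    # fill missing levels from the linear ladder fit z ~ level
    if (anyNA(zlev)) {
      co <- stats::lm.fit(cbind(1, have), zlev[have])$coefficients
      miss <- which(is.na(zlev))
      zlev[miss] <- co[1] + co[2] * miss
    }
    if (f == 1) native_zlev <- zlev
    # geometric level of each G: nearest level on the (extrapolated) native
    # ladder of this frame's quartet centroids
    rise_f <- mean(diff(zlev))
    grid <- c(zlev[1] - rise_f, zlev, zlev[nq] + rise_f, zlev[nq] + 2 * rise_f)
    grid_lab <- c(0, 1:nq, nq + 1, nq + 2)
    zg <- matrix(NA_real_, 4, nq)
    geo_lev <- matrix(NA_integer_, 4, nq)
    for (s in 1:4) for (k in 1:nq) {
      zg[s, k] <- sum((gctr[s, k, ] - origin) * axis)
      geo_lev[s, k] <- grid_lab[which.min(abs(grid - zg[s, k]))]
    }

    # cumulative backbone winding per strand (sum of signed azimuth
    # increments of consecutive G centroids about the axis)
    wind <- numeric(4)
    for (s in 1:4) {
      rad <- lapply(1:nq, function(k) {
        v <- gctr[s, k, ] - origin
        v - sum(v * axis) * axis
      })
      wind[s] <- sum(vapply(seq_len(nq - 1), function(k)
        signed_angle_about(rad[[k]], rad[[k + 1]], axis), numeric(1)))
    }
    if (f == 1) native_wind <- wind

    # end-to-end orientation vs axis
    ete <- vapply(1:4, function(s)
      angle_between(gctr[s, nq, ] - gctr[s, 1, ], axis), numeric(1))

    # register offsets, masking strands in a flipped (cross-like)
    # orientation: their incidental contacts carry no register information
    reg_hb <- hb
    for (s in which(ete > rotation_angle)) {
      p_acc <- (s + 2) %% 4 + 1
      reg_hb[s, , , ] <- FALSE
      reg_hb[p_acc, , , ] <- FALSE
    }
    reg <- register_matrix(reg_hb)
    # align to the continuous ladder register: the anchor strand chosen
    # inside register_matrix may flip between frames under noise
    both <- which(!is.na(reg$offsets) & !is.na(lad_off))
    if (length(both)) {
      tb <- table(lad_off[both] - reg$offsets[both])
      reg$offsets <- reg$offsets +
        as.numeric(names(tb)[which.max(tb)])
    }

    # min heavy-atom distance from each strand to any other strand
    mind <- rep(Inf, 4)
    for (s in 1:4) {
      A <- xyz[strand_idx[[s]], , drop = FALSE]
      B <- xyz[unlist(strand_idx[-s]), , drop = FALSE]
      d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
      mind[s] <- sqrt(max(0, min(d2)))
    }

    # anchor-T unstacking: axis-projected separation between the T base
    # centroid and the terminal quartet level of the bonded ladder (native
    # value ~ the rise)
    tdist <- rep(NA_real_, nrow(tinfo))
    for (i in seq_len(nrow(tinfo))) {
      k_term <- if (tinfo$end[i] == "5'") 1 else nq
      tct <- colMeans(xyz[t_idx[[i]], , drop = FALSE])
      tdist[i] <- abs(sum((tct - origin) * axis) - zlev[k_term])
    }

    qrow <- vapply(1:nq, function(k) quartet_row_bonds(hb, k), numeric(1))
    desc[[f]] <- list(hb = hb, gb = gb, iface = iface, sbonds = sbonds,
                      axis = axis, origin = origin, zlev = zlev,
                      row_n = row_n, assign_lev = assign_lev,
                      offsets = reg$offsets, geo_lev = geo_lev,
                      wind = wind, ete = ete, mind = mind, tdist = tdist,
                      qrow = qrow,
                      native_complete = sum(vapply(1:nq, function(k)
                        sum(hb[, k, k, ]), numeric(1))) == 8 * nq)
  }

  # ---- candidate conditions per frame ----------------------------------
  committed_offs <- rep(0, 4)
  runs <- new.env(parent = emptyenv())      # key -> list(start, len, meta)
  events <- list()
  spiral_active <- rep(FALSE, 4)
  spiral_off <- rep(0L, 4)   # frames since spiral condition went false
  detached <- rep(FALSE, 4)
  # refold is armed by any committed H-bond-altering stem event and
  # disarmed once a refold commits, so bond flicker around an already
  # refolded state cannot re-fire it
  refold_armed <- FALSE

  commit <- function(type, frame, strand = NA, level = NA, meta = list()) {
    events[[length(events) + 1]] <<- c(list(type = type, frame = frame,
                                            strand = strand, level = level),
                                       meta)
    if (!type %in% c("anchorT_unstack", "refold")) refold_armed <<- TRUE
  }

  step_key <- function(key, cond, f, meta = NULL) {
    r <- runs[[key]]
    if (cond) {
      if (is.null(r)) {
        runs[[key]] <- list(start = f, len = 1L, done = FALSE, meta = meta)
      } else {
        r$len <- r$len + 1L
        runs[[key]] <- r
      }
      r <- runs[[key]]
      if (!r$done && r$len >= persistence) {
        r$done <- TRUE
        runs[[key]] <- r
        return(r)      # signal commitment; meta captured at run start
      }
    } else if (!is.null(r)) {
      rm(list = key, envir = runs)
    }
    NULL
  }

  for (f in seq_len(nf)) {
    d <- desc[[f]]
    offs <- d$offsets

    for (s in 1:4) {
      if (detached[s]) next
      # detachment
      r <- step_key(paste0("detach_", s),
                    d$sbonds[s] == 0 && d$mind[s] > contact_cut, f)
      if (!is.null(r)) {
        commit("detachment", r$start, strand = s)
        detached[s] <- TRUE
        next
      }
      # rotation (cross-like)
      r <- step_key(paste0("rot_", s),
                    d$ete[s] > rotation_angle && d$mind[s] <= contact_cut, f)
      if (!is.null(r)) commit("rotation_crosslike", r$start, strand = s)

      # spiral
      og <- d$geo_lev[s, ] - seq_len(nq)
      sp_cond <- !is.unsorted(og) && max(abs(og)) >= 1 &&
        length(unique(og)) >= 2 &&
        abs(d$wind[s] - native_wind[s]) > winding_threshold * max(abs(og))
      r <- step_key(paste0("spiral_", s), sp_cond, f,
                    meta = list(hand = if (d$wind[s] - native_wind[s] > 0)
                      "right" else "left"))
      if (!is.null(r) && !spiral_active[s]) {
        commit("spiral_form", r$start, strand = s,
               meta = list(handedness = r$meta$hand))
        spiral_active[s] <- TRUE
        spiral_off[s] <- 0L
      }
      if (spiral_active[s]) {
        if (!sp_cond) {
          spiral_off[s] <- spiral_off[s] + 1L
          if (spiral_off[s] >= persistence) {
            commit("spiral_resolve", f - persistence + 1L, strand = s)
            spiral_active[s] <- FALSE
          }
        } else spiral_off[s] <- 0L
      }

      # unzip candidates; a G whose strand register carries it beyond the
      # stem (slipped top/bottom G) is out of register, not unzipped
      r_s <- if (is.na(offs[s])) 0 else offs[s]
      for (k in 1:nq) {
        u_cond <- (k + r_s) >= 1 && (k + r_s) <= nq &&
          d$gb[s, k] == 0 && d$sbonds[s] > 0 &&
          (d$qrow[k] - 0) >= 2   # bonds among the rest of the quartet
        # exclude bonds involving strand s from the quartet-row count
        if (u_cond) {
          hb <- d$hb
          rest <- 0
          for (p in 1:4) {
            sa <- p %% 4 + 1
            if (p == s || sa == s) next
            rest <- rest + sum(hb[p, k, k, ])
          }
          u_cond <- rest >= 2
        }
        r <- step_key(paste0("unzip_", s, "_", k), u_cond, f)
        if (!is.null(r)) commit("unzip", r$start, strand = s, level = k)
      }
    }

    # slippage: compare offsets (register changes) against the committed
    # baseline over strands where both are defined; a uniform shift is a
    # re-anchoring artifact, the strand deviating from the mode slipped
    dev <- offs - committed_offs
    def <- which(!is.na(dev))
    if (length(def) >= 2 && any(dev[def] != 0)) {
      tb <- table(dev[def])
      mode_dev <- as.numeric(names(tb)[which.max(tb)])
      changed <- def[dev[def] != mode_dev]
      if (length(changed) == 1 && !detached[changed]) {
        slip <- dev[changed] - mode_dev
        # a genuinely slipped strand re-forms bonds on both interfaces;
        # incidental contacts of a displaced strand do not
        spb <- strand_pair_bonds(d$hb, changed)
        r <- step_key(paste0("slip_", changed),
                      abs(slip) >= 1 && all(spb >= 2), f,
                      meta = list(slip = slip, new_offs = offs))
        if (!is.null(r)) {
          commit("strand_slippage", r$start, strand = changed,
                 meta = list(slip = r$meta$slip))
          committed_offs <- r$meta$new_offs
        }
      }
    } else if (length(def) >= 2) {
      stale <- grep("^slip_", ls(runs), value = TRUE)
      if (length(stale)) rm(list = stale, envir = runs)
    }

    # opening per interface
    for (p in 1:4) {
      sa <- p %% 4 + 1
      o_cond <- d$iface[p] == 0 && d$sbonds[p] > 0 && d$sbonds[sa] > 0 &&
        !detached[p] && !detached[sa]
      r <- step_key(paste0("open_", p), o_cond, f)
      if (!is.null(r)) commit("opening", r$start, strand = p,
                              meta = list(pair = c(p, sa)))
    }

    # refold
    r <- step_key("refold", d$native_complete && refold_armed, f)
    if (!is.null(r)) {
      commit("refold", r$start)
      refold_armed <- FALSE
      committed_offs <- desc[[r$start]]$offsets
      detached <- rep(FALSE, 4)
    }

    # anchor-T unstacking
    for (i in seq_len(nrow(tinfo))) {
      r <- step_key(paste0("unstack_", tinfo$label[i]),
                    !is.na(d$tdist[i]) && d$tdist[i] > unstack_cut, f)
      if (!is.null(r)) commit("anchorT_unstack", r$start,
                              strand = tinfo$strand[i],
                              meta = list(terminus = tinfo$label[i]))
    }
  }

  tl <- finalize_timeline(events, desc, traj, topology, persistence, d_cut)
  if (isTRUE(getOption("gqmech.events.debug"))) attr(tl, "desc") <- desc
  tl
}

# assemble, order, apply precedence suppression and permanence, annotate
finalize_timeline <- function(events, desc, traj, topology, persistence,
                              d_cut) {
  nq <- topology$n_quartets
  if (!length(events)) {
    ev <- data.frame(type = character(), frame = integer(), time = numeric(),
                     strand = integer(), level = integer(),
                     edge = character(), handedness = character(),
                     terminus = integer(), residues = character(),
                     quartets_remaining_before = integer(),
                     stringsAsFactors = FALSE)
    return(structure(list(events = ev, persistence = persistence),
                     class = "event_timeline"))
  }
  df <- do.call(rbind, lapply(events, function(e) data.frame(
    type = e$type, frame = e$frame,
    strand = if (is.null(e$strand) || is.na(e$strand)) NA_integer_ else e$strand,
    level = if (is.null(e$level) || is.na(e$level)) NA_integer_ else e$level,
    handedness = if (is.null(e$handedness)) NA_character_ else e$handedness,
    terminus = if (is.null(e$terminus)) NA_integer_ else e$terminus,
    slip = if (is.null(e$slip)) NA_real_ else e$slip,
    stringsAsFactors = FALSE)))
  df <- df[order(df$frame), , drop = FALSE]

  # a spiral resolving back to the native state is one event, not a
  # spiral_resolve plus a refold: drop a refold whose latest preceding
  # stem event is that spiral_resolve
  keep <- rep(TRUE, nrow(df))
  for (i in which(df$type == "refold")) {
    prev <- which(df$frame <= df$frame[i] & df$type != "anchorT_unstack" &
                    df$type != "refold")
    if (length(prev) && df$type[max(prev)] == "spiral_resolve")
      keep[i] <- FALSE
  }
  df <- df[keep, , drop = FALSE]

  # during an active spiral the wound G holds no bonds and carries its
  # flanking T with it; neither is a separate unzip or T-unstacking event
  keep <- rep(TRUE, nrow(df))
  for (i in which(df$type == "spiral_form")) {
    s <- df$strand[i]
    res <- which(df$type == "spiral_resolve" & df$strand == s &
                   df$frame >= df$frame[i])
    hi <- if (length(res)) df$frame[min(res)] + persistence else Inf
    drop <- df$type %in% c("unzip", "anchorT_unstack") &
      !is.na(df$strand) & df$strand == s &
      df$frame >= df$frame[i] - persistence & df$frame <= hi
    keep[drop] <- FALSE
  }
  df <- df[keep, , drop = FALSE]

  strand_level_types <- c("detachment", "strand_slippage", "spiral_form",
                          "opening", "rotation_crosslike", "refold")
  same_strand_clash <- function(i, types) {
    s <- df$strand[i]
    clash <- df$type %in% types &
      (is.na(df$strand) | df$strand == s |
         (df$type == "opening" & (df$strand == s | df$strand %% 4 + 1 == s))) &
      abs(df$frame - df$frame[i]) <= persistence
    clash[is.na(clash)] <- FALSE
    any(clash & seq_len(nrow(df)) != i)
  }
  keep <- rep(TRUE, nrow(df))
  for (i in seq_len(nrow(df))) {
    # a strand-level motion explains the per-G bond losses: no extra unzips
    if (df$type[i] == "unzip" && same_strand_clash(i, strand_level_types))
      keep[i] <- FALSE
    # a moving strand carries its anchor T along: not an unstacking event
    if (df$type[i] == "anchorT_unstack" &&
        same_strand_clash(i, strand_level_types))
      keep[i] <- FALSE
    # incidental off-register bonds of a flipped/detaching strand fake a
    # register shift
    if (df$type[i] %in% c("strand_slippage", "spiral_form") &&
        same_strand_clash(i, c("rotation_crosslike", "detachment")))
      keep[i] <- FALSE
  }
  df <- df[keep, , drop = FALSE]

  # detachment permanence
  keep <- rep(TRUE, nrow(df))
  for (i in which(df$type == "detachment")) {
    s <- df$strand[i]
    later <- seq_len(nrow(df)) > i & !is.na(df$strand) &
      (df$strand == s | (df$type == "opening" & df$strand %% 4 + 1 == s))
    refold_after <- which(df$type == "refold" & seq_len(nrow(df)) > i)
    if (length(refold_after)) later <- later & seq_len(nrow(df)) < min(refold_after)
    keep[later] <- FALSE
  }
  df <- df[keep, , drop = FALSE]
  rownames(df) <- NULL

  # annotations
  df$time <- traj$time[df$frame]
  df$edge <- NA_character_
  df$quartets_remaining_before <- NA_integer_
  df$residues <- NA_character_
  for (i in seq_len(nrow(df))) {
    f <- df$frame[i]
    if (f > 1)
      df$quartets_remaining_before[i] <-
        sum(desc[[f - 1]]$qrow >= 6)
    else df$quartets_remaining_before[i] <- nq
    s <- df$strand[i]
    if (df$type[i] == "unzip") {
      k <- df$level[i]
      df$terminus[i] <- if (k == 1) s else if (k == nq) s + 4L else NA_integer_
      df$edge[i] <- first_broken_edge_of(desc, f, s, k)
      st <- topology$strands[[s]]
      df$residues[i] <- paste0(st$chain, ":", st$g_resno[k])
    } else if (!is.na(s)) {
      st <- topology$strands[[s]]
      df$residues[i] <- paste0(st$chain, ":", paste(st$g_resno, collapse = ","))
    }
  }
  df <- df[, c("type", "frame", "time", "strand", "level", "edge",
               "handedness", "terminus", "slip", "residues",
               "quartets_remaining_before")]
  structure(list(events = df, persistence = persistence, d_cut = d_cut),
            class = "event_timeline")
}

# which edge of the unzipped G lost its native-register bonds first,
# looking back from the commit onset: "wc" (donor side), "hoogsteen"
# (acceptor side) or "both"
first_broken_edge_of <- function(desc, onset, s, k) {
  p_acc <- (s + 2) %% 4 + 1
  last_wc <- NA_integer_; last_h <- NA_integer_
  # debounced presence: an edge counts as present at f only if it is also
  # present at f-1, so single-frame noise flickers do not reset the order
  present <- function(f, donor_side) {
    hb <- desc[[f]]$hb
    now <- if (donor_side) any(hb[s, k, k, ]) else any(hb[p_acc, k, k, ])
    if (!now || f == 1) return(now)
    hb0 <- desc[[f - 1]]$hb
    if (donor_side) any(hb0[s, k, k, ]) else any(hb0[p_acc, k, k, ])
  }
  for (f in seq(onset - 1, max(1, onset - 60))) {
    if (is.na(last_wc) && present(f, TRUE)) last_wc <- f
    if (is.na(last_h) && present(f, FALSE)) last_h <- f
    if (!is.na(last_wc) && !is.na(last_h)) break
  }
  if (is.na(last_wc) && is.na(last_h)) return(NA_character_)
  if (is.na(last_wc)) return("wc")
  if (is.na(last_h)) return("hoogsteen")
  if (last_wc < last_h) "wc" else if (last_h < last_wc) "hoogsteen" else "both"
}

#' @export
print.event_timeline <- function(x, ...) {
  ev <- x$events
  cat(sprintf("event_timeline: %d event(s)\n", nrow(ev)))
  if (nrow(ev)) {
    for (i in seq_len(nrow(ev)))
      cat(sprintf("  %-18s frame %5d (t=%.2f ns)%s%s%s\n",
                  ev$type[i], ev$frame[i], ev$time[i],
                  if (!is.na(ev$strand[i])) sprintf(" strand %d", ev$strand[i]) else "",
                  if (!is.na(ev$level[i])) sprintf(" level %d", ev$level[i]) else "",
                  if (!is.na(ev$handedness[i])) paste0(" ", ev$handedness[i]) else ""))
  }
  invisible(x)
}

#' First unzip: terminus, broken edge and contemporaneous force-edge overlap
#'
#' For the first H-bond-altering stem event of a timeline (anchor-T
#' unstacking excluded): if it is an unzip, reports the terminus, which
#' edge's H-bonds broke first from the perspective of the pulled-out G, and
#' the force-edge overlap at the event time when an feo series is supplied.
#' If the first stem event is not an unzip an `n/a` record is returned.
#'
#' @param timeline an `"event_timeline"`.
#' @param feo optional data.frame with columns `time` and `feo`; the value
#'   nearest the event time is reported.
#' @return list: `is_unzip`, `type`, `time`, `terminus`, `edge`,
#'   `feo_at_event`.
#' @export
first_unzip_edge <- function(timeline, feo = NULL) {
  ev <- timeline$events
  stem <- ev[ev$type != "anchorT_unstack", , drop = FALSE]
  if (!nrow(stem))
    return(list(is_unzip = FALSE, type = NA_character_, time = NA_real_,
                terminus = NA_integer_, edge = NA_character_,
                feo_at_event = NA_real_))
  first <- stem[1, ]
  out <- list(is_unzip = identical(first$type, "unzip"), type = first$type,
              time = first$time, terminus = first$terminus,
              edge = if (identical(first$type, "unzip")) first$edge
                     else NA_character_,
              feo_at_event = NA_real_)
  if (!is.null(feo) && nrow(feo))
    out$feo_at_event <- feo$feo[which.min(abs(feo$time - first$time))]
  out
}

#' Aggregate event statistics across runs
#'
#' Summarizes a collection of timelines: counts by event type (optionally
#' crossed with run labels such as anchor pair or water model), the
#' fraction of runs whose first stem event starts at a 3' terminus, and the
#' spiral handedness split.
#'
#' @param timelines list of `"event_timeline"` objects.
#' @param labels optional data.frame of per-run metadata (one row per
#'   timeline), e.g. columns `anchors`, `n_quartets`, `water`.
#' @return list of class `"event_stats"`: `counts` (type x label table),
#'   `n_runs`, `first_3prime` (count, fraction over runs with a terminus-
#'   resolved first stem event), `spiral_handedness` (left/right counts and
#'   fractions), `events` (all events with run ids).
#' @export
event_stats <- function(timelines, labels = NULL) {
  stopifnot(length(timelines) >= 1)
  all_ev <- do.call(rbind, lapply(seq_along(timelines), function(i) {
    ev <- timelines[[i]]$events
    if (!nrow(ev)) return(NULL)
    ev$run <- i
    ev
  }))
  if (is.null(all_ev))
    all_ev <- data.frame(type = character(), run = integer(),
                         handedness = character(), terminus = integer())
  counts <- table(factor(all_ev$type, levels = EVENT_TYPES))
  if (!is.null(labels) && nrow(all_ev)) {
    lab <- labels[all_ev$run, , drop = FALSE]
    counts_by <- table(factor(all_ev$type, levels = EVENT_TYPES),
                       apply(lab, 1, paste, collapse = "/"))
  } else counts_by <- NULL

  firsts <- lapply(timelines, function(tl) {
    st <- tl$events[tl$events$type != "anchorT_unstack", , drop = FALSE]
    if (nrow(st)) st[1, ] else NULL
  })
  term <- vapply(firsts, function(x)
    if (is.null(x)) NA_integer_ else x$terminus, integer(1))
  resolved <- !is.na(term)
  n3 <- sum(term[resolved] >= 5)
  sp <- all_ev$handedness[all_ev$type == "spiral_form"]
  sp <- sp[!is.na(sp)]
  structure(list(
    counts = counts, counts_by_label = counts_by,
    n_runs = length(timelines),
    first_3prime = list(count = n3, total = sum(resolved),
                        fraction = if (sum(resolved)) n3 / sum(resolved)
                                   else NA_real_),
    spiral_handedness = list(left = sum(sp == "left"),
                             right = sum(sp == "right"),
                             fraction_left = if (length(sp))
                               mean(sp == "left") else NA_real_),
    events = all_ev), class = "event_stats")
}

#' @export
print.event_stats <- function(x, ...) {
  cat(sprintf("event_stats over %d run(s)\n", x$n_runs))
  print(x$counts)
  f3 <- x$first_3prime
  if (f3$total)
    cat(sprintf("first stem event at 3' terminus: %d/%d (%.0f%%)\n",
                f3$count, f3$total, 100 * f3$fraction))
  sh <- x$spiral_handedness
  if (sh$left + sh$right)
    cat(sprintf("spirals: %d left / %d right (%.0f%% left)\n",
                sh$left, sh$right, 100 * sh$fraction_left))
  invisible(x)
}
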