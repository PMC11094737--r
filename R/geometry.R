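#' Per-frame quartet-plane geometry of a G-stem
#'
#' For every frame: fits a best-fit plane to the heavy base atoms of each
#' quartet, co-orients the normals along the 5' to 3' stem axis, and derives
#' the elastic-deformation descriptors — per-quartet planarity, and per
#' quartet-quartet step the tilt (angle between neighboring co-oriented
#' normals), rise (sum of the two centroid distances from the pooled
#' best-fit plane) and signed helical twist (rotation of the in-plane
#' centroid-to-N9 reference vector of the same strand about the axis,
#' positive = right-handed advancing 5' to 3'). The total twist is the sum
#' of step twists; its sign is the handedness.
#'
#' @param traj a [gq_trajectory()].
#' @param topology a `"stem_topology"`.
#' @param frames integer vector of frame indices (default all).
#' @param ref_strand strand (1-4) whose G supplies the twist reference
#'   vector in every quartet.
#' @param rise_method `"pooled"` (default) or `"bisector"`, see [rise()].
#' @return object of class `"gq_geometry"`: list of data.frames `quartets`
#'   (frame, time, quartet, planarity), `steps` (frame, time, step, tilt,
#'   rise, twist) and `frames` (frame, time, total_twist, handedness), plus
#'   `axes` (frames x 3 matrix of stem-axis unit vectors).
#' @examples
#' stem <- build_ideal_stem(stem_blueprint(n_quartets = 3))
#' g <- stem_geometry(stem$traj, stem$topology)
#' g$steps$twist    # +30, +30
#' @export
stem_geometry <- function(traj, topology, frames = seq_len(n_frames(traj)),
                          ref_strand = 1, rise_method = "pooled") {
  nq <- topology$n_quartets
  atoms <- traj$atoms
  gidx <- lapply(1:nq, function(k)
    lapply(1:4, function(s) g_base_index(atoms, topology, s, k)))
  n9idx <- vapply(1:nq, function(k) {
    st <- topology$strands[[ref_strand]]
    atom_index(atoms, st$chain, st$g_resno[k], "N9")
  }, integer(1))

  q_rows <- list(); s_rows <- list(); f_rows <- list()
  axes <- matrix(NA_real_, length(frames), 3)
  for (fi in seq_along(frames)) {
    f <- frames[fi]
    xyz <- frame_coords(traj, f)
    planes <- lapply(1:nq, function(k)
      fit_quartet_plane(xyz[unlist(gidx[[k]]), ]))
    centroids <- t(vapply(planes, `[[`, numeric(3), "centroid"))
    axis <- stem_axis(centroids)
    axes[fi, ] <- axis
    # co-orient normals 5'->3'
    for (k in 1:nq)
      if (sum(planes[[k]]$normal * axis) < 0)
        planes[[k]]$normal <- -planes[[k]]$normal

    refs <- lapply(1:nq, function(k)
      xyz[n9idx[k], ] - planes[[k]]$centroid)
    tw <- ti <- ri <- numeric(nq - 1)
    for (k in seq_len(nq - 1)) {
      tw[k] <- step_twist(refs[[k]], refs[[k + 1]], axis)
      ti[k] <- tilt(planes[[k]], planes[[k + 1]], axis)
      ri[k] <- rise(xyz[unlist(gidx[[k]]), ], xyz[unlist(gidx[[k + 1]]), ],
                    method = rise_method)
    }
    tt <- sum(tw)
    q_rows[[fi]] <- data.frame(frame = f, time = traj$time[f], quartet = 1:nq,
                               planarity = vapply(planes, `[[`, numeric(1),
                                                  "planarity"))
    s_rows[[fi]] <- data.frame(frame = f, time = traj$time[f],
                               step = seq_len(nq - 1),
                               tilt = ti, rise = ri, twist = tw)
    f_rows[[fi]] <- data.frame(frame = f, time = traj$time[f],
                               total_twist = tt, handedness = sign(tt))
  }
  structure(list(quartets = do.call(rbind, q_rows),
                 steps = do.call(rbind, s_rows),
                 frames = do.call(rbind, f_rows),
                 axes = axes, n_quartets = nq),
            class = "gq_geometry")
}

#' Total helical twist of a stem geometry
#'
#' Sum of the signed step twists (3'-quartet rotation relative to the
#' 5'-quartet about the stem axis); the sign reflects the handedness of the
#' helix (positive = right-handed).
#'
#' @param geometry a `"gq_geometry"` from [stem_geometry()].
#' @return numeric vector, total twist in degrees per analyzed frame.
#' @export
total_twist <- function(geometry) {
  stopifnot(inherits(geometry, "gq_geometry"))
  geometry$frames$total_twist
}

#' @export
print.gq_geometry <- function(x, ...) {
  nf <- nrow(x$frames)
  cat(sprintf("gq_geometry: %d quartets, %d frame(s)\n", x$n_quartets, nf))
  cat(sprintf("  total twist  %7.2f deg (mean), handedness %+d\n",
              mean(x$frames$total_twist), as.integer(sign(mean(x$frames$total_twist)))))
  cat(sprintf("  step twist   %7.2f deg (mean)\n", mean(x$steps$twist)))
  cat(sprintf("  rise         %7.3f A   (mean)\n", mean(x$steps$rise)))
  cat(sprintf("  tilt         %7.3f deg (mean)\n", mean(x$steps$tilt)))
  cat(sprintf("  planarity    %7.4f A   (mean)\n", mean(x$quartets$planarity)))
  invisible(x)
}

#' @export
summary.gq_geometry <- function(object, ...) {
  agg <- function(df, col) c(mean = mean(df[[col]]), sd = stats::sd(df[[col]]),
                             min = min(df[[col]]), max = max(df[[col]]))
  out <- rbind(planarity_A = agg(object$quartets, "planarity"),
               tilt_deg = agg(object$steps, "tilt"),
               rise_A = agg(object$steps, "rise"),
               step_twist_deg = agg(object$steps, "twist"),
               total_twist_deg = agg(object$frames, "total_twist"))
  class(out) <- c("summary.gq_geometry", class(out))
  out
}

#' Flatten a stem geometry to one long table
#'
#' One row per frame x (quartet or step) with the descriptor columns used by
#' the TSV writer: frame, time, quartet/step index, planarity, tilt, rise,
#' step twist, total twist, handedness.
#'
#' @param x a `"gq_geometry"`.
#' @param ... unused.
#' @return data.frame.
#' @export
as.data.frame.gq_geometry <- function(x, ...) {
  q <- x$quartets
  s <- x$steps
  s$planarity <- NA_real_
  q$tilt <- q$rise <- q$twist <- NA_real_
  q$index <- q$quartet; q$kind <- "quartet"
  s$index <- s$step; s$kind <- "step"
  cols <- c("frame", "time", "kind", "index", "planarity", "tilt", "rise", "twist")
  out <- rbind(q[, cols], s[, cols])
  out <- merge(out, x$frames[, c("frame", "total_twist", "handedness")],
               by = "frame", sort = FALSE)
  out[order(out$frame, out$kind, out$index), ]
}
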