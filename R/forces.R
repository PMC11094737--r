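# Spring-force reconstruction and decomposition for constant-velocity
# pulling with a moving harmonic distance restraint.

#' Unit conversion: spring force to piconewton
#'
#' 1 kJ mol^-1 nm^-1 = 1.660539 pN (via the Avogadro constant); fixed here
#' so force outputs are bit-reproducible.
#' @export
KJMOL_NM_TO_PN <- 1.660539

#' Pulling schedule of a moving harmonic restraint
#'
#' The restraint center moves at constant velocity, c(t) = d0 + v t, and the
#' spring force magnitude is k (c(t) - d) where d is the instantaneous
#' anchor-anchor distance. Anchors are the geometric centers of the C2, C4
#' and C6 atoms of the two terminal thymines named by their terminus labels.
#'
#' @param force_constant spring constant k in kJ mol^-1 nm^-2 (default 180).
#' @param pull_speed restraint-center velocity in nm per microsecond
#'   (default 5.4).
#' @param d0 initial restraint center in nm.
#' @param anchors integer length-2 vector of terminus labels (1-8), e.g.
#'   `c(1, 8)` for 1-8 pulling; optional (only needed for vector forces).
#' @return object of class `"pulling_schedule"`.
#' @export
pulling_schedule <- function(force_constant = 180, pull_speed = 5.4,
                             d0 = 0, anchors = NULL) {
  if (force_constant <= 0) stop("force_constant must be positive", call. = FALSE)
  if (pull_speed < 0) stop("pull_speed must be >= 0", call. = FALSE)
  structure(list(force_constant = force_constant, pull_speed = pull_speed,
                 d0 = d0, anchors = anchors),
            class = "pulling_schedule")
}

# restraint center (nm) at time t (ns); pull_speed is nm/us = 1e-3 nm/ns
restraint_center <- function(schedule, time_ns) {
  schedule$d0 + schedule$pull_speed * 1e-3 * time_ns
}

#' Reconstruct the spring force from a pulling record
#'
#' Computes the harmonic restraint force k (c(t) - d) for each record and
#' converts it to pN. The sign convention: positive when the restraint
#' center exceeds the anchor distance (the spring pulls the anchors apart);
#' compressive episodes are negative. Use `abs()` for magnitude averages.
#'
#' @param time time stamps in ns (strictly increasing).
#' @param distance anchor-anchor distance d in nm.
#' @param schedule a [pulling_schedule()].
#' @param center optional restraint-center values c(t) in nm; computed from
#'   the schedule when omitted.
#' @return data.frame of class `"force_series"` with columns `time` (ns),
#'   `distance` (nm), `center` (nm) and `force_pN` (signed).
#' @examples
#' s <- pulling_schedule(force_constant = 180)
#' spring_force(0, 1, s, center = 2)$force_pN  # 180 * 1 * 1.660539 = 298.9
#' @export
spring_force <- function(time, distance, schedule, center = NULL) {
  stopifnot(inherits(schedule, "pulling_schedule"))
  if (length(time) > 1 && any(diff(time) <= 0))
    stop("time stamps must be strictly increasing", call. = FALSE)
  if (is.null(center)) center <- restraint_center(schedule, time)
  force <- schedule$force_constant * (center - distance) * KJMOL_NM_TO_PN
  structure(data.frame(time = time, distance = distance, center = center,
                       force_pN = force),
            class = c("force_series", "data.frame"))
}

#' Force vector between the two pulling anchors
#'
#' Signed spring-force 3-vector along the anchor-1 to anchor-2 line for one
#' frame, from the anchor coordinates and the scalar spring force.
#'
#' @param coords `n_atoms x 3` frame coordinates (Angstrom).
#' @param atoms atom table.
#' @param topology a `"stem_topology"`.
#' @param schedule a [pulling_schedule()] with `anchors` set.
#' @param time_ns frame time (ns) used for the restraint center.
#' @return list with `F` (pN 3-vector, directed from anchor 1 toward anchor
#'   2 for extension), `magnitude` (signed pN) and `distance_nm`.
#' @export
anchor_force_vector <- function(coords, atoms, topology, schedule, time_ns) {
  if (is.null(schedule$anchors) || length(schedule$anchors) != 2)
    stop("schedule must name two anchor termini (labels 1-8)", call. = FALSE)
  a1 <- colMeans(coords[anchor_atoms(topology, schedule$anchors[1], atoms), ])
  a2 <- colMeans(coords[anchor_atoms(topology, schedule$anchors[2], atoms), ])
  d_nm <- vnorm(a2 - a1) / 10
  mag <- schedule$force_constant *
    (restraint_center(schedule, time_ns) - d_nm) * KJMOL_NM_TO_PN
  list(F = mag * unit(a2 - a1), magnitude = mag, distance_nm = d_nm)
}

#' Force out-of-plane angle
#'
#' Angle beta between the pulling force and the average quartet plane:
#' beta = 90 deg minus the angle between the force and the mean of the
#' co-oriented quartet normals. Signed by the 5' to 3' normal orientation
#' (positive when the force points toward the 3' side), in [-90, 90];
#' 0 for an in-plane force. A zero force returns `NA` (undefined), not an
#' error: the spring force can vanish mid-trajectory.
#'
#' @param force pN 3-vector.
#' @param normals matrix (quartets x 3) of quartet-plane unit normals
#'   co-oriented 5' to 3' (a single normal vector is accepted).
#' @return beta in degrees, or `NA` for a zero force.
#' @export
out_of_plane_angle <- function(force, normals) {
  if (vnorm(force) < 1e-12) return(NA_real_)
  normals <- matrix(normals, ncol = 3)
  n <- unit(colMeans(normals))
  asin(clamp1(sum(unit(force) * n))) * DEG
}

#' Decompose a force into horizontal and vertical components
#'
#' Trigonometric split relative to the average quartet plane:
#' F_horizontal = F cos(beta) (in-plane), F_vertical = F sin(beta)
#' (along the normal), and their ratio F_v / F_h = tan(beta), which keeps
#' the sign of beta. At |beta| = 90 deg the ratio is undefined (`NA`).
#'
#' @param force_magnitude |F| in pN (>= 0).
#' @param beta out-of-plane angle in degrees (vectorized).
#' @return data.frame with `beta`, `F_horizontal`, `F_vertical`, `vh_ratio`.
#' @export
decompose_force <- function(force_magnitude, beta) {
  stopifnot(all(force_magnitude >= 0 | is.na(force_magnitude)))
  b <- beta / DEG
  data.frame(beta = beta,
             F_horizontal = force_magnitude * cos(b),
             F_vertical = force_magnitude * sin(b),
             vh_ratio = ifelse(abs(abs(beta) - 90) < 1e-9, NA_real_, tan(b)))
}

#' Watson-Crick and Hoogsteen edge unit vectors of a quartet guanine
#'
#' For the designated G (strand `s`, level `k`): `u_wc` is the normalized
#' mean of its two donated H-bond directions (N1 to O6 and N2 to N7 of the
#' next strand's G), `u_h` the normalized mean of its two accepted H-bond
#' directions (O6 to N1 and N7 to N2 of the previous strand's G). Both lie
#' in the quartet plane for an ideal quartet; downstream use takes absolute
#' dot products, so the orientation sign is immaterial.
#'
#' @param coords frame coordinates (`n_atoms x 3`).
#' @param atoms atom table.
#' @param topology a `"stem_topology"`.
#' @param s strand index of the G (1-4).
#' @param k quartet level of the G.
#' @return list with unit 3-vectors `u_wc` and `u_h`.
#' @export
edge_unit_vectors <- function(coords, atoms, topology, s, k) {
  get <- function(strand, name) {
    st <- topology$strands[[strand]]
    coords[atom_index(atoms, st$chain, st$g_resno[k], name), ]
  }
  s_next <- s %% 4 + 1
  s_prev <- (s + 2) %% 4 + 1
  u_wc <- unit(unit(get(s_next, "O6") - get(s, "N1")) +
               unit(get(s_next, "N7") - get(s, "N2")))
  u_h  <- unit(unit(get(s_prev, "N1") - get(s, "O6")) +
               unit(get(s_prev, "N2") - get(s, "N7")))
  list(u_wc = u_wc, u_h = u_h)
}

#' Force-edge overlap
#'
#' Alignment of the pulling force with one H-bond edge over the other:
#' feo = (|F . u_wc| - |F . u_h|) / |F|, in [-1, 1]. Positive means the
#' force is aligned more with the Watson-Crick edge of the designated G,
#' negative more with its Hoogsteen edge. A zero force returns `NA`.
#'
#' @param force pN 3-vector.
#' @param edges list with unit vectors `u_wc`, `u_h`
#'   (see [edge_unit_vectors()]).
#' @return feo, dimensionless in [-1, 1], or `NA` for zero force.
#' @examples
#' force_edge_overlap(c(3, 4, 0),
#'                    list(u_wc = c(1, 0, 0), u_h = c(0, 1, 0)))  # -0.2
#' @export
force_edge_overlap <- function(force, edges) {
  fm <- vnorm(force)
  if (fm < 1e-12) return(NA_real_)
  (abs(sum(force * edges$u_wc)) - abs(sum(force * edges$u_h))) / fm
}

# centered or trailing running mean of x with an integer window (odd for
# centered); positions without a full window are NA.
running_mean <- function(x, n, align = c("centered", "trailing")) {
  align <- match.arg(align)
  if (n < 1) stop("window must span at least one sample", call. = FALSE)
  sides <- if (align == "centered") 2 else 1
  as.numeric(stats::filter(x, rep(1 / n, n), sides = sides))
}

#' Rupture force of the stem
#'
#' Maximum running-average force magnitude ahead of the first unfolding
#' event: |F| is averaged in a `window` ns running window (centered by
#' default) and the maximum is taken over window positions lying entirely
#' inside [0, `first_event_time`].
#'
#' @param series a `"force_series"` (see [spring_force()] /
#'   [read_pull_series()]); samples must be uniformly spaced in time.
#' @param first_event_time time of the first H-bond-altering stem event, ns.
#' @param window averaging window in ns (default 2).
#' @param align `"centered"` (default) or `"trailing"` window alignment.
#' @return rupture force in pN.
#' @export
rupture_force <- function(series, first_event_time, window = 2,
                          align = c("centered", "trailing")) {
  align <- match.arg(align)
  t <- series$time
  if (first_event_time < t[1])
    stop("first_event_time precedes the force series", call. = FALSE)
  dt <- diff(t)
  if (max(dt) - min(dt) > 1e-6 * stats::median(dt))
    stop("force series must be uniformly sampled", call. = FALSE)
  dt <- stats::median(dt)
  nwin <- max(1L, round(window / dt)) + 1L
  if (align == "centered" && nwin %% 2 == 0) nwin <- nwin + 1L
  pre <- which(t <= first_event_time)
  if (length(pre) < nwin)
    stop(sprintf("window (%g ns) exceeds the pre-event span (%g ns)",
                 window, t[length(pre)] - t[1]), call. = FALSE)
  rm_all <- running_mean(abs(series$force_pN), nwin, align)
  valid <- if (align == "centered") {
    half <- (nwin - 1L) / 2L
    idx <- seq_along(t)
    idx[idx - half >= 1 & idx + half <= length(pre)]
  } else {
    which(!is.na(rm_all) & seq_along(t) <= length(pre))
  }
  max(rm_all[valid], na.rm = TRUE)
}

#' Transition-inducing force of each unfolding event
#'
#' Average force magnitude over a trailing `window` ns window ending at each
#' event time (the force that induced the transition). Windows overlapping
#' the start of the series are truncated with a warning. Each event is
#' annotated with the number of quartets remaining before it when the
#' timeline provides it.
#'
#' @param series a `"force_series"`, uniformly sampled.
#' @param event_times numeric vector of event times (ns), ordered, or an
#'   `"event_timeline"` object.
#' @param window trailing window in ns (default 2).
#' @return data.frame: `time`, `transition_force_pN`, and
#'   `quartets_remaining_before` when available.
#' @export
transition_forces <- function(series, event_times, window = 2) {
  qrb <- NULL
  if (inherits(event_times, "event_timeline")) {
    qrb <- event_times$events$quartets_remaining_before
    event_times <- event_times$events$time
  }
  if (is.unsorted(event_times))
    stop("events must be time-ordered", call. = FALSE)
  t <- series$time
  f <- abs(series$force_pN)
  out <- vapply(event_times, function(te) {
    sel <- which(t >= te - window & t <= te)
    if (!length(sel)) return(NA_real_)
    if (te - window < t[1] - 1e-9)
      warning(sprintf("window truncated at trajectory start for event at %g ns", te),
              call. = FALSE)
    mean(f[sel])
  }, numeric(1))
  res <- data.frame(time = event_times, transition_force_pN = out)
  if (!is.null(qrb)) res$quartets_remaining_before <- qrb
  res
}
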