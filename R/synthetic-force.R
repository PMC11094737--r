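#' Synthetic constant-velocity pulling force trace
#'
#' Generates a COLVAR-style sawtooth force trace for a moving harmonic
#' restraint: between ruptures the force rises linearly toward the scripted
#' plateau, holds flat at the plateau for `plateau_hold` ns, and at the
#' rupture time the anchor distance jumps so the spring force drops to a
#' fraction of the plateau. Gaussian noise (in pN) is added
#' to the force profile, the anchor distance is derived from it, and the
#' bias column is written consistently, so [spring_force()] reconstruction
#' matches the stored bias exactly. Identical inputs and seed give
#' bit-identical traces.
#'
#' @param schedule a [pulling_schedule()].
#' @param ruptures data.frame with columns `time` (ns, increasing) and
#'   `plateau` (pN): force reached just before each rupture. May be empty.
#' @param t_total total trace length in ns.
#' @param dt sampling interval in ns (default 0.1).
#' @param noise_sd Gaussian force noise SD in pN (default 0).
#' @param plateau_hold ns the force stays flat at the plateau before each
#'   rupture (default 5).
#' @param drop_fraction force retained right after a rupture, as a fraction
#'   of the plateau (default 0.2).
#' @param seed integer RNG seed.
#' @return list of class `"synthetic_force_trace"`: `colvar` (data.frame
#'   time/distance/center/bias), `series` (the corresponding
#'   `"force_series"` in pN) and `truth` (list: ruptures, noise_sd, seed,
#'   dt, schedule).
#' @export
make_force_trace <- function(schedule, ruptures = data.frame(time = numeric(),
                                                             plateau = numeric()),
                             t_total = 100, dt = 0.1, noise_sd = 0,
                             plateau_hold = 5, drop_fraction = 0.2, seed = 1) {
  stopifnot(inherits(schedule, "pulling_schedule"))
  if (nrow(ruptures) && is.unsorted(ruptures$time, strictly = TRUE))
    stop("rupture times must be strictly increasing", call. = FALSE)
  if (nrow(ruptures) && any(ruptures$time >= t_total))
    stop("rupture times must lie inside the trace", call. = FALSE)
  time <- seq(0, t_total, by = dt)

  # piecewise-linear noise-free force profile (pN)
  force0 <- numeric(length(time))
  seg_start_t <- 0
  seg_start_f <- 0
  if (nrow(ruptures)) {
    for (i in seq_len(nrow(ruptures))) {
      t_rup <- ruptures$time[i]
      t_plat <- max(seg_start_t, t_rup - plateau_hold)  # plateau onset
      ramp <- time >= seg_start_t & time < t_plat
      force0[ramp] <- seg_start_f + (ruptures$plateau[i] - seg_start_f) *
        (time[ramp] - seg_start_t) / (t_plat - seg_start_t)
      hold <- time >= t_plat & time <= t_rup
      force0[hold] <- ruptures$plateau[i]
      seg_start_t <- t_rup
      seg_start_f <- drop_fraction * ruptures$plateau[i]
    }
    sel <- time > seg_start_t
    # post-rupture reload at the mean pre-rupture slope
    slope <- ruptures$plateau[1] / ruptures$time[1]
    force0[sel] <- seg_start_f + slope * (time[sel] - seg_start_t)
  } else {
    # pure elastic loading of a stiff anchor pair: force tracks the center
    slope <- schedule$force_constant * schedule$pull_speed * 1e-3 * KJMOL_NM_TO_PN
    force0 <- slope * time
  }

  set.seed(seed)
  force <- force0 + if (noise_sd > 0) stats::rnorm(length(time), 0, noise_sd) else 0

  center <- restraint_center(schedule, time)
  bias_kj <- force / KJMOL_NM_TO_PN                  # kJ mol^-1 nm^-1
  distance <- center - bias_kj / schedule$force_constant
  colvar <- data.frame(time = time, distance = distance, center = center,
                       bias = bias_kj)
  series <- structure(data.frame(time = time, distance = distance,
                                 center = center, force_pN = force),
                      class = c("force_series", "data.frame"))
  structure(list(colvar = colvar, series = series,
                 truth = list(ruptures = ruptures, noise_sd = noise_sd,
                              seed = seed, dt = dt,
                              plateau_hold = plateau_hold,
                              drop_fraction = drop_fraction,
                              schedule = schedule)),
            class = "synthetic_force_trace")
}
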