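# Ideal tetrameric parallel all-anti G-stem generator.
#
# Bases are represented by their heavy atoms plus C1' (a minimal backbone
# proxy): that is every atom the analyses need (base planes, glycosidic N9
# reference, Hoogsteen/Watson-Crick edge atoms, anchor-T C2/C4/C6). Base
# internal geometry uses the standard nucleic-acid base reference-frame
# coordinates; the in-plane placement of the guanine within its quartet is
# solved numerically so that the cyclic N1(H)...O6 / N2(H)...N7 hydrogen
# bonds reach a target donor-acceptor distance at the requested C1' radius.

# Planar heavy-atom templates (x, y in A; base plane z = 0). C1' included.
.G_TEMPLATE <- local({
  m <- rbind(
    "C1'" = c(-2.477, 5.399),
    N9    = c(-1.289, 4.551),
    C8    = c( 0.023, 4.962),
    N7    = c( 0.870, 3.969),
    C5    = c( 0.071, 2.833),
    C6    = c( 0.424, 1.460),
    O6    = c( 1.554, 0.955),
    N1    = c(-0.700, 0.641),
    C2    = c(-1.999, 1.087),
    N2    = c(-2.949, 0.139),
    N3    = c(-2.342, 2.364),
    C4    = c(-1.265, 3.177))
  colnames(m) <- c("x", "y"); m
})

.T_TEMPLATE <- local({
  m <- rbind(
    "C1'" = c(-2.481, 5.354),
    N1    = c(-1.284, 4.500),
    C2    = c(-1.462, 3.135),
    O2    = c(-2.562, 2.608),
    N3    = c(-0.298, 2.407),
    C4    = c( 0.994, 2.897),
    O4    = c( 1.944, 2.119),
    C5    = c( 1.106, 4.338),
    C7    = c( 2.466, 4.961),
    C6    = c(-0.024, 5.057))
  colnames(m) <- c("x", "y"); m
})

rot2 <- function(theta_deg) {
  th <- theta_deg / DEG
  matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
}

# Solve the in-plane placement (rotation theta, translation tx/ty) of the
# guanine template such that, with the four quartet guanines related by
# successive +90 deg rotations about the origin, the Watson-Crick edge of
# each G (donor N1, N2) meets the Hoogsteen edge of the next G (acceptor
# O6, N7).
#
# Modulo the global-rotation gauge the exact-register placement is rigid:
# requiring d(N1-O6) = d(N2-N7) = hbond leaves two discrete geometries
# (an inward- and an outward-facing arrangement), so the C1' radius is a
# consequence of the bond length, not a free parameter. With radius = NULL
# the outward (larger-radius, sterically sensible) branch is returned. When
# a radius is requested, the two bond distances are kept equal, the common
# bond length floats, and the placement matching that radius is returned
# (with an error if the implied bond length is unphysical).
.placement_cache <- new.env(parent = emptyenv())

solve_quartet_placement <- function(radius = NULL, hbond = 2.9) {
  key <- paste0("r", if (is.null(radius)) "auto" else format(radius),
                "_h", format(hbond))
  if (!is.null(.placement_cache[[key]])) return(.placement_cache[[key]])
  tmpl <- .G_TEMPLATE
  R90 <- rot2(90)
  dists <- function(par) {
    M <- rot2(par[1]); tt <- par[2:3]
    place <- function(a) as.vector(M %*% tmpl[a, ]) + tt
    c(vnorm(R90 %*% place("O6") - place("N1")),
      vnorm(R90 %*% place("N7") - place("N2")),
      vnorm(place("C1'")))
  }
  objective <- function(par) {
    d <- dists(par)
    if (is.null(radius))
      (d[1] - hbond)^2 + (d[2] - hbond)^2
    else
      (d[1] - d[2])^2 + (d[3] - radius)^2
  }
  sols <- list()
  for (th0 in seq(0, 330, by = 30)) {
    for (t0 in list(c(6, 0), c(0, 6), c(-6, 0), c(0, -6), c(3, 3), c(-3, -3))) {
      fit <- stats::optim(c(th0, t0), objective,
                          control = list(maxit = 5000, reltol = 1e-16))
      fit <- stats::optim(fit$par, objective,
                          control = list(maxit = 5000, reltol = 1e-16))
      if (fit$value < 1e-10) sols[[length(sols) + 1]] <- fit$par
    }
  }
  if (!length(sols))
    stop(sprintf("no quartet placement found (radius %s, H-bond %.2f A)",
                 if (is.null(radius)) "auto" else format(radius), hbond),
         call. = FALSE)
  dmat <- t(vapply(sols, dists, numeric(3)))
  pick <- if (is.null(radius)) {
    which.max(dmat[, 3])                       # outward branch
  } else {
    cand <- which(abs(dmat[, 3] - radius) < 0.05)
    if (!length(cand))
      stop(sprintf("no quartet placement reaches C1' radius %.2f A", radius),
           call. = FALSE)
    cand[which.min(abs(dmat[cand, 1] - hbond))] # bond length nearest target
  }
  d <- dmat[pick, ]
  if (d[1] < 2.5 || d[1] > 3.35)
    stop(sprintf(paste0("C1' radius %.2f A implies a quartet H-bond length of ",
                        "%.2f A, outside the physical range [2.5, 3.35]"),
                 d[3], d[1]), call. = FALSE)
  par <- sols[[pick]]
  placed <- t(rot2(par[1]) %*% t(tmpl)) +
    matrix(par[2:3], nrow(tmpl), 2, byrow = TRUE)
  rownames(placed) <- rownames(tmpl)
  attr(placed, "achieved") <- c(hbond_1 = d[1], hbond_2 = d[2], radius = d[3])
  .placement_cache[[key]] <- placed
  placed
}

# Place the thymine template so that its glycosidic C1'/N1 roughly overlays
# the guanine C1'/N9 of the slot it stacks into; good enough for anchor
# geometry and stacking detection (no H-bond role).
place_thymine <- function(g_placed) {
  t_tmpl <- .T_TEMPLATE
  # rigid 2D fit of T (C1', N1) onto G (C1', N9)
  src <- t_tmpl[c("C1'", "N1"), ]
  dst <- g_placed[c("C1'", "N9"), ]
  sc <- colMeans(src); dc <- colMeans(dst)
  v1 <- src[2, ] - src[1, ]; v2 <- dst[2, ] - dst[1, ]
  ang <- (atan2(v2[2], v2[1]) - atan2(v1[2], v1[1])) * DEG
  placed <- t(rot2(ang) %*% t(sweep(t_tmpl, 2, sc))) +
    matrix(dc, nrow(t_tmpl), 2, byrow = TRUE)
  rownames(placed) <- rownames(t_tmpl)
  placed
}

#' Blueprint of an ideal parallel G-stem
#'
#' Parameters of the synthetic tetramolecular parallel all-anti G-quadruplex:
#' number of stacked quartets, helical rise and twist per quartet step, the
#' C1' radius of the quartet, and whether each strand carries flanking
#' thymines (the pulling anchors).
#'
#' @param n_quartets number of G-quartets (3-5 typical; >= 2 accepted).
#' @param rise_per_step rise per quartet step in Angstrom (default 3.4).
#' @param twist_per_step signed helical twist per step in degrees; positive
#'   is right-handed (default +30).
#' @param radius C1' distance from the channel axis in Angstrom, or `NULL`
#'   (default) to derive it from the H-bond length: the exact cyclic H-bond
#'   register fixes the quartet geometry up to rotation, giving ~8.2 A for
#'   2.9 A bonds. An explicit radius keeps the two bond distances equal and
#'   lets the common bond length float (error outside 2.5-3.35 A).
#' @param flanking_t logical, add a thymine at both ends of every strand.
#' @param hbond_length target donor-acceptor distance of the quartet
#'   H-bonds in Angstrom (default 2.9).
#' @return object of class `"stem_blueprint"`.
#' @export
stem_blueprint <- function(n_quartets = 4, rise_per_step = 3.4,
                           twist_per_step = 30, radius = NULL,
                           flanking_t = TRUE, hbond_length = 2.9) {
  if (n_quartets < 2) stop("n_quartets must be >= 2", call. = FALSE)
  if (rise_per_step <= 0) stop("rise_per_step must be positive", call. = FALSE)
  if (!is.null(radius) && radius <= 4) stop("radius too small for a G-quartet", call. = FALSE)
  structure(list(n_quartets = as.integer(n_quartets),
                 rise_per_step = rise_per_step,
                 twist_per_step = twist_per_step,
                 radius = radius, flanking_t = isTRUE(flanking_t),
                 hbond_length = hbond_length),
            class = "stem_blueprint")
}

# Build the coordinates of the stem for arbitrary per-step twist/rise
# vectors (length n_quartets - 1; flanking T levels extrapolate the first /
# last step). Returns list(atoms, xyz, topology).
build_stem_coords <- function(blueprint,
                              step_twists = NULL, step_rises = NULL,
                              placement = NULL) {
  nq <- blueprint$n_quartets
  if (is.null(step_twists)) step_twists <- rep(blueprint$twist_per_step, nq - 1)
  if (is.null(step_rises))  step_rises  <- rep(blueprint$rise_per_step, nq - 1)
  stopifnot(length(step_twists) == nq - 1, length(step_rises) == nq - 1)
  if (is.null(placement))
    placement <- solve_quartet_placement(blueprint$radius, blueprint$hbond_length)
  t_placed <- place_thymine(placement)

  # cumulative azimuth/height per level; level 0 = 5' T, level nq+1 = 3' T
  ang_g <- c(0, cumsum(step_twists))   # quartet levels 1..nq
  z_g   <- c(0, cumsum(step_rises))
  ang <- c(-step_twists[1], ang_g, ang_g[nq] + step_twists[nq - 1])
  z   <- c(-step_rises[1],  z_g,   z_g[nq]   + step_rises[nq - 1])
  names(ang) <- names(z) <- as.character(0:(nq + 1))

  chains <- c("A", "B", "C", "D")
  rows <- list(); coords <- list()
  for (s in 1:4) {
    resno <- 0L
    levels <- if (blueprint$flanking_t) 0:(nq + 1) else 1:nq
    for (lev in levels) {
      resno <- resno + 1L
      is_t <- lev == 0 || lev == nq + 1
      tmpl2 <- if (is_t) t_placed else placement
      az <- (s - 1) * 90 + ang[as.character(lev)]
      xy <- t(rot2(az) %*% t(tmpl2))
      xyz <- cbind(xy, z[as.character(lev)])
      rows[[length(rows) + 1]] <- data.frame(
        elety = rownames(tmpl2),
        resid = if (is_t) "DT" else "DG",
        resno = resno, chain = chains[s], stringsAsFactors = FALSE)
      coords[[length(coords) + 1]] <- xyz
    }
  }
  atoms <- do.call(rbind, rows)
  xyz <- do.call(rbind, coords)

  # channel K+ between adjacent quartets (nq - 1 ions, on axis)
  zq <- z[as.character(1:nq)]
  for (k in seq_len(nq - 1)) {
    atoms <- rbind(atoms, data.frame(elety = "K", resid = "K",
                                     resno = k, chain = "I",
                                     stringsAsFactors = FALSE))
    xyz <- rbind(xyz, c(0, 0, (zq[k] + zq[k + 1]) / 2))
  }
  rownames(atoms) <- NULL
  dimnames(xyz) <- NULL

  off <- if (blueprint$flanking_t) 1L else 0L
  strands <- lapply(chains, function(ch)
    list(chain = ch, g_resno = (1:nq) + off,
         t5_resno = if (blueprint$flanking_t) 1L else NA,
         t3_resno = if (blueprint$flanking_t) nq + 2L else NA))
  list(atoms = atoms, xyz = xyz, topology = stem_topology(strands))
}

#' Build an ideal parallel G-stem
#'
#' Constructs an idealized tetramolecular parallel all-anti G-quadruplex:
#' four symmetric strands related by 90 degree rotations about the channel
#' axis, quartet k rotated by k times the step twist and raised by k times
#' the step rise, flanking thymines at both ends of each strand (the pulling
#' anchors), and channel potassium ions midway between adjacent quartets.
#' The generated structure satisfies the full cyclic quartet H-bond register
#' (8 bonds per quartet under the default distance criterion).
#'
#' @param blueprint a [stem_blueprint()].
#' @return list with `traj` (a single-frame [gq_trajectory()]) and
#'   `topology` (a `"stem_topology"`).
#' @examples
#' stem <- build_ideal_stem(stem_blueprint(n_quartets = 4))
#' geom <- stem_geometry(stem$traj, stem$topology)
#' geom$frames$total_twist   # +90 for 3 steps of +30 deg
#' @export
build_ideal_stem <- function(blueprint = stem_blueprint()) {
  built <- build_stem_coords(blueprint)
  traj <- gq_trajectory(built$atoms, built$xyz, time = 0)
  list(traj = traj, topology = built$topology, blueprint = blueprint)
}
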