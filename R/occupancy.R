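#' Channel cation occupancy between adjacent quartets
#'
#' For every channel site (the region between two adjacent quartets) and
#' every frame, a site counts as occupied when at least one selected ion
#' has its projection on the stem axis strictly between the projections of
#' the two adjacent quartet centroids and lies within `radial_cut` of the
#' axis. Reported as the percentage of frames occupied, per site.
#'
#' @param traj a [gq_trajectory()].
#' @param topology a `"stem_topology"`.
#' @param ion_elety atom names treated as channel ions (default K+ naming
#'   variants).
#' @param radial_cut maximal ion distance from the stem axis in A
#'   (default 2.5).
#' @return object of class `"occupancy_series"`: `percent` (length
#'   `n_quartets - 1`), `per_frame` (sites x frames logical matrix),
#'   `n_frames`.
#' @examples
#' stem <- build_ideal_stem(stem_blueprint(n_quartets = 3))
#' channel_occupancy(stem$traj, stem$topology)$percent  # 100 100
#' @export
channel_occupancy <- function(traj, topology, ion_elety = ION_NAMES,
                              radial_cut = 2.5) {
  atoms <- traj$atoms
  nq <- topology$n_quartets
  ion_idx <- which(atoms$elety %in% ion_elety | atoms$resid %in% ion_elety)
  if (!length(ion_idx))
    stop("no channel ions selected (looked for atom/residue names: ",
         paste(ion_elety, collapse = ", "), ")", call. = FALSE)
  gctr_idx <- lapply(1:nq, function(k)
    unlist(lapply(1:4, function(s) g_base_index(atoms, topology, s, k))))

  nf <- n_frames(traj)
  occ <- matrix(FALSE, nq - 1, nf)
  for (f in seq_len(nf)) {
    xyz <- frame_coords(traj, f)
    qctr <- t(vapply(gctr_idx, function(ii)
      colMeans(xyz[ii, , drop = FALSE]), numeric(3)))
    axis <- stem_axis(qctr)
    origin <- colMeans(qctr)
    zq <- as.vector((qctr - matrix(origin, nq, 3, byrow = TRUE)) %*% axis)
    ions <- xyz[ion_idx, , drop = FALSE]
    rel <- sweep(ions, 2, origin)
    zi <- as.vector(rel %*% axis)
    radial <- sqrt(pmax(0, rowSums(rel^2) - zi^2))
    for (site in seq_len(nq - 1)) {
      lo <- min(zq[site], zq[site + 1]); hi <- max(zq[site], zq[site + 1])
      occ[site, f] <- any(zi > lo & zi < hi & radial <= radial_cut)
    }
  }
  structure(list(percent = 100 * rowMeans(occ), per_frame = occ,
                 n_frames = nf, radial_cut = radial_cut),
            class = "occupancy_series")
}

#' @export
print.occupancy_series <- function(x, ...) {
  cat(sprintf("channel K+ occupancy over %d frame(s):\n", x$n_frames))
  for (i in seq_along(x$percent))
    cat(sprintf("  site %d (quartets %d-%d): %.1f%%\n", i, i, i + 1,
                x$percent[i]))
  invisible(x)
}
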