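# Structure / trajectory reading and writing. Standard formats go through
# bio3d: PDB topology, multi-model PDB frames, DCD trajectories.

#' Read a structure and trajectory
#'
#' Reads a PDB topology and optional trajectory frames into a
#' [gq_trajectory()]. A multi-model PDB supplies both at once; a DCD file
#' supplies frames for the PDB topology. Residue numbering and chain
#' identifiers are preserved verbatim from the input.
#'
#' @param pdb path to a PDB file (single- or multi-model).
#' @param traj optional path to a DCD trajectory with frames for `pdb`.
#' @param dt frame spacing in ns; required when the trajectory carries no
#'   time metadata (multi-model PDB, DCD) and more than one frame is read.
#' @return a `"gq_trajectory"`.
#' @export
read_trajectory <- function(pdb, traj = NULL, dt = NULL) {
  if (!file.exists(pdb)) stop("cannot read PDB file: ", pdb, call. = FALSE)
  p <- bio3d::read.pdb(pdb, multi = TRUE, verbose = FALSE)
  atoms <- data.frame(elety = p$atom$elety, resid = p$atom$resid,
                      resno = p$atom$resno,
                      chain = ifelse(is.na(p$atom$chain), "", p$atom$chain),
                      stringsAsFactors = FALSE)
  xyz <- p$xyz
  if (!is.null(traj)) {
    if (!file.exists(traj)) stop("cannot read trajectory: ", traj, call. = FALSE)
    xyz <- bio3d::read.dcd(traj, verbose = FALSE)
    if (ncol(xyz) != 3 * nrow(atoms))
      stop(sprintf("atom-count mismatch: topology has %d atoms, trajectory %d",
                   nrow(atoms), ncol(xyz) / 3), call. = FALSE)
  }
  xyz <- if (is.matrix(xyz)) xyz else matrix(xyz, nrow = 1)
  nf <- nrow(xyz)
  arr <- array(NA_real_, c(nrow(atoms), 3, nf))
  for (f in seq_len(nf))
    arr[, , f] <- matrix(xyz[f, ], ncol = 3, byrow = TRUE)
  if (nf > 1 && is.null(dt))
    stop("multi-frame input without time metadata: supply dt (ns)",
         call. = FALSE)
  time <- (seq_len(nf) - 1) * if (is.null(dt)) 1 else dt
  gq_trajectory(atoms, arr, time = time)
}

#' Write a trajectory as a (multi-model) PDB
#'
#' @param traj a `"gq_trajectory"`.
#' @param path output PDB path.
#' @return `path`, invisibly.
#' @export
write_trajectory_pdb <- function(traj, path) {
  nf <- n_frames(traj)
  xyz <- t(vapply(seq_len(nf), function(f) as.vector(t(frame_coords(traj, f))),
                  numeric(3 * nrow(traj$atoms))))
  if (nf == 1) xyz <- matrix(xyz, nrow = 1)
  bio3d::write.pdb(file = path, xyz = xyz,
                   type = rep("ATOM", nrow(traj$atoms)),
                   resno = traj$atoms$resno, resid = traj$atoms$resid,
                   elety = traj$atoms$elety, chain = traj$atoms$chain)
  invisible(path)
}

#' Write a stem geometry as TSV
#'
#' Long-format table (one row per frame x quartet or step) with units in
#' the header comment: planarity in Angstrom, tilt and twist in degrees,
#' rise in Angstrom.
#'
#' @param geometry a `"gq_geometry"`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_geometry_tsv <- function(geometry, path) {
  df <- as.data.frame(geometry)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste("# units: planarity/rise A; tilt/twist/total_twist deg;",
                   "time ns"), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write an event timeline as TSV or JSON
#'
#' @param timeline an `"event_timeline"`.
#' @param path output path; format chosen by extension (`.json` or TSV
#'   otherwise).
#' @return `path`, invisibly.
#' @export
write_timeline <- function(timeline, path) {
  ev <- timeline$events
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(ev, path, auto_unbox = TRUE, digits = NA,
                         na = "null", pretty = TRUE)
  } else {
    utils::write.table(ev, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
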