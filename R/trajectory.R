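#' Trajectory container
#'
#' Lightweight container for a molecular trajectory: an atom table plus a
#' coordinate array. Coordinates are stored in Angstrom; times in ns.
#'
#' @param atoms data.frame with columns `elety` (atom name), `resid`
#'   (residue name), `resno` (residue number, as in the input file) and
#'   `chain` (chain/segment identifier).
#' @param xyz numeric array `n_atoms x 3 x n_frames` (a single `n_atoms x 3`
#'   matrix is accepted for one frame).
#' @param time numeric vector of frame times in ns (length `n_frames`).
#' @return object of class `"gq_trajectory"`.
#' @export
gq_trajectory <- function(atoms, xyz, time = NULL) {
  stopifnot(is.data.frame(atoms),
            all(c("elety", "resid", "resno", "chain") %in% names(atoms)))
  if (length(dim(xyz)) == 2) xyz <- array(xyz, dim = c(dim(xyz), 1))
  stopifnot(length(dim(xyz)) == 3, dim(xyz)[2] == 3)
  if (dim(xyz)[1] != nrow(atoms))
    stop(sprintf("atom-count mismatch: %d atoms in table, %d in coordinates",
                 nrow(atoms), dim(xyz)[1]), call. = FALSE)
  nf <- dim(xyz)[3]
  if (is.null(time)) time <- seq_len(nf) - 1
  if (length(time) != nf)
    stop("time vector length must equal the number of frames", call. = FALSE)
  structure(list(atoms = atoms, xyz = xyz, time = as.numeric(time)),
            class = "gq_trajectory")
}

#' Number of frames in a trajectory
#' @param traj a `"gq_trajectory"`.
#' @return integer frame count.
#' @export
n_frames <- function(traj) dim(traj$xyz)[3]

#' Coordinates of one frame
#' @param traj a `"gq_trajectory"`.
#' @param frame frame index (1-based).
#' @return `n_atoms x 3` numeric matrix (Angstrom).
#' @export
frame_coords <- function(traj, frame) {
  stopifnot(frame >= 1, frame <= n_frames(traj))
  traj$xyz[, , frame, drop = TRUE]
}

# Row indices of atoms matching chain/resno (and optionally atom names).
atom_index <- function(atoms, chain, resno, elety = NULL) {
  idx <- which(atoms$chain == chain & atoms$resno == resno)
  if (!is.null(elety)) {
    m <- match(elety, atoms$elety[idx])
    if (anyNA(m))
      stop(sprintf("missing atom(s) %s in residue %s/%s",
                   paste(elety[is.na(m)], collapse = ","), chain, resno),
           call. = FALSE)
    idx <- idx[m]
  }
  idx
}

#' @export
print.gq_trajectory <- function(x, ...) {
  cat(sprintf("gq_trajectory: %d atoms, %d frame(s), t = %.3f..%.3f ns\n",
              nrow(x$atoms), n_frames(x), min(x$time), max(x$time)))
  cat(sprintf("  residues: %s\n",
              paste(utils::head(unique(x$atoms$resid), 6), collapse = " ")))
  invisible(x)
}
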