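#' Best-fit plane of a G-quartet by singular value decomposition
#'
#' Fits a plane to a set of atomic coordinates (typically the heavy base atoms
#' of the four guanines of one quartet). The plane passes through the centroid;
#' its normal is the singular direction of smallest variance. The planarity is
#' the root-mean-square deviation of the points from the plane, which equals
#' sigma3 / sqrt(N) where sigma3 is the third (smallest) singular value of the
#' centered coordinate matrix.
#'
#' @param coords numeric matrix, N x 3 (Angstrom), N >= 3.
#' @return An object of class `"quartet_plane"`: a list with `centroid`
#'   (3-vector, A), `normal` (unit 3-vector), `singular_values` (sigma1 >=
#'   sigma2 >= sigma3, A), `planarity` (A) and `n_atoms`.
#' @examples
#' sq <- cbind(c(1, -1, -1, 1), c(1, 1, -1, -1), 0)
#' p <- fit_quartet_plane(sq)
#' p$planarity            # 0: points are coplanar
#' abs(p$normal[3])       # 1: plane is z = 0
#' @export
fit_quartet_plane <- function(coords) {
  coords <- as.matrix(coords)
  if (!is.numeric(coords) || ncol(coords) != 3)
    stop("coords must be an N x 3 numeric matrix", call. = FALSE)
  if (nrow(coords) < 3)
    stop("degenerate geometry: plane fit needs at least 3 points", call. = FALSE)
  if (!all(is.finite(coords)))
    stop("coords contain non-finite values", call. = FALSE)

  centroid <- colMeans(coords)
  centered <- sweep(coords, 2, centroid)
  sv <- svd(centered, nu = 0)
  # sigma2 ~ 0 means the points are (nearly) collinear: no unique plane.
  if (sv$d[2] < 1e-6 * max(sv$d[1], 1e-6))
    stop("degenerate geometry: points are (nearly) collinear", call. = FALSE)

  structure(list(
    centroid        = centroid,
    normal          = sv$v[, 3] / vnorm(sv$v[, 3]),
    singular_values = sv$d,
    planarity       = sv$d[3] / sqrt(nrow(coords)),
    n_atoms         = nrow(coords)
  ), class = "quartet_plane")
}

#' Quartet planarity
#'
#' RMSD of the fitted atoms from their best-fit plane, sigma3/sqrt(N).
#' Invariant under rigid rotation and translation of the coordinates.
#'
#' @param plane a `"quartet_plane"` from [fit_quartet_plane()].
#' @return planarity in Angstrom (non-negative scalar).
#' @export
planarity <- function(plane) {
  stopifnot(inherits(plane, "quartet_plane"))
  plane$planarity
}

# Signed distance of point(s) from a plane (positive along the normal).
plane_distance <- function(plane, points) {
  points <- matrix(points, ncol = 3)
  as.vector(sweep(points, 2, plane$centroid) %*% plane$normal)
}

#' Tilt angle between two quartet planes
#'
#' Angle between the normals of two neighboring quartet planes, in degrees.
#' The normals are co-oriented before comparison when a stem `axis` is given
#' (both flipped, if needed, to a positive dot product with the axis), so the
#' result measures buckling/tilting rather than an arbitrary SVD sign flip.
#'
#' @param plane_a,plane_b `"quartet_plane"` objects.
#' @param axis optional 3-vector used to co-orient the two normals
#'   (5' to 3' stem axis). If `NULL`, the second normal is co-oriented with
#'   the first.
#' @return tilt angle in degrees, in [0, 180] (in [0, 90] once co-oriented).
#' @export
tilt <- function(plane_a, plane_b, axis = NULL) {
  stopifnot(inherits(plane_a, "quartet_plane"), inherits(plane_b, "quartet_plane"))
  na <- plane_a$normal
  nb <- plane_b$normal
  if (is.null(axis)) {
    if (sum(na * nb) < 0) nb <- -nb
  } else {
    if (sum(na * axis) < 0) na <- -na
    if (sum(nb * axis) < 0) nb <- -nb
  }
  acos(clamp1(sum(na * nb))) * DEG
}

#' Rise distance between two stacked quartets
#'
#' Vertical separation of two adjacent quartets, computed as the sum of the
#' distances of the two quartets' geometric centers from the quartets' average
#' best-fit plane. By default the average plane is the single plane fitted to
#' the pooled heavy base atoms of both quartets, which is well defined even
#' when the quartets are mutually tilted; `method = "bisector"` instead uses
#' the plane through the mid-centroid whose normal bisects the two individual
#' co-oriented normals.
#'
#' @param coords_a,coords_b N x 3 coordinate matrices (heavy base atoms) of
#'   the two quartets, same frame.
#' @param method `"pooled"` (default) or `"bisector"`.
#' @return rise in Angstrom (unsigned).
#' @export
rise <- function(coords_a, coords_b, method = c("pooled", "bisector")) {
  method <- match.arg(method)
  coords_a <- as.matrix(coords_a)
  coords_b <- as.matrix(coords_b)
  ca <- colMeans(coords_a)
  cb <- colMeans(coords_b)
  if (method == "pooled") {
    mid <- fit_quartet_plane(rbind(coords_a, coords_b))
  } else {
    pa <- fit_quartet_plane(coords_a)
    pb <- fit_quartet_plane(coords_b)
    nb <- if (sum(pa$normal * pb$normal) < 0) -pb$normal else pb$normal
    mid <- list(centroid = (ca + cb) / 2, normal = unit(pa$normal + nb))
  }
  abs(sum((ca - mid$centroid) * mid$normal)) +
    abs(sum((cb - mid$centroid) * mid$normal))
}

#' Stem axis from quartet centroids
#'
#' Best-fit line direction through the quartet centroids (principal direction
#' of the centered centroid matrix), oriented 5' to 3' (positive dot product
#' with the vector from the first to the last centroid). With two quartets
#' this reduces to the normalized centroid difference.
#'
#' @param centroids K x 3 matrix of quartet centroids, ordered 5' to 3'.
#' @return unit 3-vector.
#' @export
stem_axis <- function(centroids) {
  centroids <- as.matrix(centroids)
  if (nrow(centroids) < 2)
    stop("stem axis needs at least 2 quartet centroids", call. = FALSE)
  span <- centroids[nrow(centroids), ] - centroids[1, ]
  if (vnorm(span) < 1e-6)
    stop("degenerate geometry: quartet centroids (nearly) coincident", call. = FALSE)
  if (nrow(centroids) == 2) return(unit(span))
  centered <- sweep(centroids, 2, colMeans(centroids))
  v <- svd(centered, nu = 0)$v[, 1]
  if (sum(v * span) < 0) v <- -v
  unit(v)
}

#' Helical twist of one quartet-quartet step
#'
#' Signed rotation angle between the in-plane reference vectors of two
#' adjacent quartets about the stem axis. Reference vectors are projected
#' onto the plane orthogonal to the axis; the sign is positive for a
#' right-handed rotation advancing 5' to 3' along the axis. Range
#' (-180, 180].
#'
#' @param ref_a,ref_b in-plane reference 3-vectors of the 5'- and 3'-side
#'   quartet of the step (e.g. centroid to glycosidic N9 of the same strand's
#'   G in each quartet).
#' @param axis stem axis oriented 5' to 3' (see [stem_axis()]).
#' @return signed step twist in degrees.
#' @export
step_twist <- function(ref_a, ref_b, axis) {
  signed_angle_about(ref_a, ref_b, axis)
}

#' @export
print.quartet_plane <- function(x, ...) {
  cat(sprintf("G-quartet best-fit plane: %d atoms, planarity %.4f A\n",
              x$n_atoms, x$planarity))
  cat(sprintf("  centroid  [%7.3f %7.3f %7.3f] A\n",
              x$centroid[1], x$centroid[2], x$centroid[3]))
  cat(sprintf("  normal    [%7.4f %7.4f %7.4f]\n",
              x$normal[1], x$normal[2], x$normal[3]))
  invisible(x)
}
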