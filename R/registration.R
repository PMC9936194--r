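# Point-cloud registration: origin reset at the right ankle, PCA-derived
# realignment of the global frame to progression / mediolateral /
# vertical axes, and cropping to a fixed travel distance.
#
# Wearable (IMU-derived) point clouds drift and their calibration frame
# need not align with the direction of sprinting. Treating every
# marker-frame 3D point as an observation, the leading component of
# positional variation is the axis of progression, the second is
# mediolateral and the third vertical; rotating onto these axes registers
# all trials to a common frame and absorbs the bulk of slow drift into
# the progression axis.

#' Reset the trial origin to the right ankle's starting position
#'
#' Translates all markers by a common constant so the right ankle sits at
#' (0, 0, 0) in the first frame. Idempotent; preserves all inter-marker
#' distances.
#'
#' @param trial a \linkS4class{MarkerTrial}.
#' @return the translated trial.
#' @export
resetOrigin <- function(trial) {
  stopifnot(is(trial, "MarkerTrial"))
  origin <- trial@positions[1L, .markerIndex(trial, "RightAnkle"), ]
  pos <- sweep(trial@positions, 3L, origin, "-")
  methods::initialize(trial, positions = pos)
}

.checkRotation <- function(R, tol = 1e-9) {
  if (!is.matrix(R) || !all(dim(R) == c(3L, 3L)))
    stop("rotation must be a 3 x 3 matrix")
  if (max(abs(crossprod(R) - diag(3))) > tol)
    stop("rotation matrix is not orthonormal")
  if (abs(det(R) - 1) > tol)
    stop("rotation matrix must have determinant +1")
  invisible(R)
}

#' Derive the frame-alignment rotation from a trial's point cloud
#'
#' PCA of the centered frames-by-markers 3D point cloud (every
#' marker-frame position is one observation) yields the three dominant
#' spatial axes. The returned rotation maps the original coordinates
#' onto them: new x = progression, new y = mediolateral, new z =
#' vertical. The leading loading is always the progression axis; of the
#' remaining two, the one better aligned with the original vertical
#' becomes z and the other y (for standing-height point clouds the
#' vertical spread can rival the mediolateral spread, so anchoring z by
#' alignment rather than by variance rank keeps the assignment stable).
#' Signs are fixed deterministically: x points along the net T8
#' displacement, z has positive dot product with the original vertical,
#' and y is negated if needed to keep the frame right-handed
#' (determinant +1).
#'
#' @param trial a \linkS4class{MarkerTrial} with at least 3 frames and
#'   nondegenerate motion.
#' @return 3 x 3 rotation matrix \code{R}; registered coordinates are
#'   \code{p_new = R \%*\% p_old}.
#' @export
deriveAlignmentRotation <- function(trial) {
  stopifnot(is(trial, "MarkerTrial"))
  d <- dim(trial@positions)
  if (d[1] < 3L) stop("at least 3 frames are required")
  pts <- matrix(trial@positions, ncol = 3L)  # (frames*markers) x 3
  pts <- sweep(pts, 2L, colMeans(pts), "-")
  sv <- svd(pts, nu = 0)
  if (!(sv$d[3] > 1e-12 * max(sv$d[1], 1e-12)))
    stop("degenerate point cloud: motion is collinear or static")
  V <- sv$v  # columns are PC axes in original coordinates

  # z = whichever of the two minor loadings aligns best with the
  # original vertical; y = the other
  if (abs(V[3, 2]) > abs(V[3, 3])) V <- V[, c(1, 3, 2)]
  t8 <- .markerXYZ(trial, "T8")
  disp <- t8[nrow(t8), ] - t8[1L, ]
  if (sum(V[, 1] * disp) < 0) V[, 1] <- -V[, 1]
  if (V[3, 3] < 0) V[, 3] <- -V[, 3]
  if (det(V) < 0) V[, 2] <- -V[, 2]
  R <- t(V)
  .checkRotation(R)
  R
}

#' Rotate a trial into the aligned frame and crop to a travel distance
#'
#' Applies \code{R} about the (already reset) origin and truncates the
#' trial at the first frame where the T8 marker's x-position has
#' advanced \code{cropDistance} meters from its starting x.
#'
#' @param trial a \linkS4class{MarkerTrial}, typically after
#'   \code{\link{resetOrigin}}.
#' @param R 3 x 3 rotation from \code{\link{deriveAlignmentRotation}}.
#' @param cropDistance travel distance in meters (default 60); use
#'   \code{NULL} to skip cropping.
#' @return the registered (rotated, cropped) trial.
#' @export
registerTrial <- function(trial, R, cropDistance = 60) {
  stopifnot(is(trial, "MarkerTrial"))
  .checkRotation(R)
  d <- dim(trial@positions)
  pts <- matrix(trial@positions, ncol = 3L)
  pts <- pts %*% t(R)
  pos <- array(pts, dim = d)
  out <- markerTrial(pos, trial@labels, trial@rate, trial@subject)
  if (!is.null(cropDistance)) {
    t8x <- .markerXYZ(out, "T8")[, 1]
    travel <- t8x - t8x[1L]
    hit <- which(travel >= cropDistance)
    if (!length(hit))
      stop("trial travels only ", sprintf("%.1f", max(travel)),
           " m; cannot crop to ", cropDistance, " m")
    out <- methods::initialize(out,
      positions = out@positions[seq_len(hit[1L]), , , drop = FALSE])
  }
  out
}

#' Register a raw trial end to end
#'
#' Convenience wrapper: \code{\link{resetOrigin}}, then
#' \code{\link{deriveAlignmentRotation}}, then
#' \code{\link{registerTrial}}.
#'
#' @inheritParams registerTrial
#' @return list with \code{trial} (registered) and \code{rotation}.
#' @export
registerSprint <- function(trial, cropDistance = 60) {
  trial <- resetOrigin(trial)
  R <- deriveAlignmentRotation(trial)
  list(trial = registerTrial(trial, R, cropDistance), rotation = R)
}
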