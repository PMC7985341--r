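# Distortion physics: field offset <-> voxel shift conversion and the 1-D
# forward/inverse warps along the phase-encoding axis.

#' Convert a phase-rate map to a field-offset map
#'
#' Field maps estimated from phase differences come out in radian/s; dividing
#' by \eqn{2\pi} yields the per-voxel static-field deviation \eqn{\Delta B_0}
#' in Hz.
#'
#' @param field numeric array of phase rates (rad/s), or a
#'   \linkS4class{FieldOffsetMap}-shaped array plus \code{mask}.
#' @param mask optional logical mask of valid voxels.
#' @return A \linkS4class{FieldOffsetMap} in Hz.
#' @examples
#' radpsToHz(array(2 * pi, c(2, 2, 2)))   # 1 Hz everywhere
#' @export
radpsToHz <- function(field, mask = NULL) {
  if (is.null(mask)) mask <- array(TRUE, dim(field))
  if (any(!is.finite(field[mask])))
    stop("non-finite phase-rate values inside the mask")
  FieldOffsetMap(field / (2 * pi), mask)
}

#' Convert a field-offset map to a voxel-shift map
#'
#' The displacement (mm) of each voxel along the phase-encoding direction is
#' \deqn{VSM = s_y \, \Delta B_0 / (BW_{PE} \times R)}
#' with \eqn{BW_{PE} = 1/(\mathrm{echospacing} \times n_y)} the PE bandwidth
#' and \eqn{R} the in-plane acceleration factor. The map is linear in
#' \eqn{\Delta B_0}; using the nominal echo spacing with \eqn{R = 2} is
#' identical to using the effective (halved) spacing with \eqn{R = 1}.
#'
#' @param field a \linkS4class{FieldOffsetMap} (Hz).
#' @param geom an \linkS4class{EPIGeometry}.
#' @return A \linkS4class{VoxelShiftMap} (mm).
#' @examples
#' f <- FieldOffsetMap(array(-76, c(1, 1, 1)))
#' mapValues(db0ToVsm(f, EPIGeometry()))   # about -4.2 mm
#' @export
db0ToVsm <- function(field, geom = EPIGeometry()) {
  stopifnot(is(field, "FieldOffsetMap"), is(geom, "EPIGeometry"))
  if (geom@accel < 1L || geom@echoSpacing <= 0)
    stop("invalid geometry: accel and echoSpacing must be positive")
  scale <- geom@voxelSizePE / (peBandwidth(geom) * geom@accel)
  VoxelShiftMap(field@values * scale, field@mask)
}

# Shift map in voxel units along the PE axis, as (n_pe x n_lines) matrix,
# with the restore closure. Positive = shift toward larger PE index.
.peShiftVox <- function(vsm, geom) {
  d <- .alongAxis(mapValues(vsm) * (geom@pePolarity / geom@voxelSizePE),
                  geom@peAxis)
  d
}

.checkInvertible <- function(dmat, what = "warp") {
  slopes <- diff(dmat)
  bad <- abs(slopes) >= 1
  if (any(bad)) {
    stop(sprintf(
      "%s not invertible: |d(shift)/dy| >= 1 voxel/voxel at %d of %d locations (max %.3f)",
      what, sum(bad), length(bad), max(abs(slopes))))
  }
  invisible(TRUE)
}

# Shift values at cell edges k +/- 1/2 by linear interpolation with constant
# end extension; input (n x m), output (n+1 x m).
.edgeShifts <- function(dmat) {
  n <- nrow(dmat)
  rbind(dmat[1, , drop = FALSE],
        (dmat[-n, , drop = FALSE] + dmat[-1, , drop = FALSE]) / 2,
        dmat[n, , drop = FALSE])
}

#' Apply the susceptibility distortion forward model
#'
#' Warps a volume along the phase-encoding axis: signal at true position
#' \eqn{y} appears at \eqn{y + p \cdot VSM(y)/s_y} (voxel units), where
#' \eqn{p} is the PE polarity. With \code{conserveMass = TRUE} the signal is
#' redistributed conservatively (each voxel cell's mass is spread over its
#' mapped interval), so compressed regions brighten, stretched regions dim,
#' and every PE line's total signal is preserved to machine precision while
#' mass stays inside the grid. With \code{conserveMass = FALSE} intensities
#' are resampled through the inverse map without Jacobian modulation.
#' Out-of-grid signal reads as zero background.
#'
#' @param volume 3-D intensity array.
#' @param vsm a \linkS4class{VoxelShiftMap} (mm).
#' @param geom an \linkS4class{EPIGeometry} (supplies PE axis, polarity and
#'   voxel size).
#' @param conserveMass logical; apply Jacobian intensity modulation.
#' @return Distorted array of the same shape.
#' @seealso [unwarpVolume()] for the inverse operation.
#' @export
applyDistortion <- function(volume, vsm, geom = EPIGeometry(),
                            conserveMass = TRUE) {
  stopifnot(identical(dim(volume), dim(mapValues(vsm))))
  d <- .peShiftVox(vsm, geom)
  .checkInvertible(d$mat, "forward distortion")
  v <- .alongAxis(volume, geom@peAxis)
  n <- nrow(v$mat)
  if (conserveMass) {
    edges <- seq_len(n + 1) - 0.5
    mapped <- edges + .edgeShifts(d$mat)          # (n+1 x m), strictly increasing
    M <- apply(v$mat, 2, function(col) c(0, cumsum(col)))
    L <- .colInterpNonuniform(mapped, M, matrix(edges, n + 1, ncol(v$mat)),
                              rule = 2)
    out <- L[-1, , drop = FALSE] - L[-(n + 1), , drop = FALSE]
  } else {
    grid <- seq_len(n)
    fwd <- grid + d$mat                            # m(y) at cell centres
    inv <- .colInterpNonuniform(fwd, matrix(grid, n, ncol(v$mat)),
                                matrix(grid, n, ncol(v$mat)), rule = 1)
    inv[is.na(inv)] <- -1                          # outside -> background
    out <- .colInterp(v$mat, inv, fill = 0)
  }
  v$restore(out)
}

#' Undo a susceptibility distortion
#'
#' Pull-back inverse of [applyDistortion()]: the corrected value at true
#' position \eqn{y} is read from the distorted volume at
#' \eqn{y + p \cdot VSM(y)/s_y} by linear interpolation along PE, multiplied
#' (when \code{conserveMass = TRUE}) by the local Jacobian
#' \eqn{1 + \partial d/\partial y} (central differences, floored at 0.05) to
#' restore intensities that the mass-conserving forward model rescaled.
#'
#' @inheritParams applyDistortion
#' @return Corrected array of the same shape.
#' @export
unwarpVolume <- function(volume, vsm, geom = EPIGeometry(),
                         conserveMass = TRUE) {
  stopifnot(identical(dim(volume), dim(mapValues(vsm))))
  d <- .peShiftVox(vsm, geom)
  .checkInvertible(d$mat, "unwarp")
  plan <- .unwarpPlan(d$mat, conserveMass)
  v <- .alongAxis(volume, geom@peAxis)
  v$restore(.applyUnwarpPlan(plan, v$mat))
}

# Precompute the pull sampling positions and Jacobian for one shift field so
# that a whole 4-D series can be unwarped without re-deriving them.
.unwarpPlan <- function(dmat, conserveMass) {
  n <- nrow(dmat)
  pos <- seq_len(n) + dmat
  jac <- NULL
  if (conserveMass) {
    fwd <- dmat[c(2:n, n), , drop = FALSE]
    bwd <- dmat[c(1, 1:(n - 1)), , drop = FALSE]
    denom <- c(1, rep(2, n - 2), 1)
    grad <- (fwd - bwd) / denom
    jac <- pmax(1 + grad, 0.05)
  }
  list(pos = pos, jac = jac)
}

.applyUnwarpPlan <- function(plan, vmat) {
  out <- .colInterp(vmat, plan$pos, fill = 0)
  if (!is.null(plan$jac)) out <- out * plan$jac
  out
}

#' Unwarp every volume of a 4-D series with one shift field
#'
#' A single estimated displacement field is taken as valid for all volumes of
#' a motion-corrected run, so the same 1-D correction is applied volume-wise.
#'
#' @param series 4-D array (x, y, z, time).
#' @inheritParams applyDistortion
#' @return Corrected 4-D array.
#' @export
correctSeries <- function(series, vsm, geom = EPIGeometry(),
                          conserveMass = TRUE) {
  stopifnot(length(dim(series)) == 4L,
            identical(dim(series)[1:3], dim(mapValues(vsm))))
  d <- .peShiftVox(vsm, geom)
  .checkInvertible(d$mat, "unwarp")
  plan <- .unwarpPlan(d$mat, conserveMass)
  out <- series
  for (t in seq_len(dim(series)[4])) {
    v <- .alongAxis(series[, , , t], geom@peAxis)
    out[, , , t] <- v$restore(.applyUnwarpPlan(plan, v$mat))
  }
  out
}
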