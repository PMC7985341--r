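# GRE field-mapping correction chain:
# rescale -> unwrap -> /dTE -> /2pi -> smooth -> VSM -> unwarp.

#' Rescale an integer-exported phase image to wrapped radians
#'
#' Scanner exports often store the phase difference on an arbitrary integer
#' scale. The affine map \eqn{(x - \mathrm{mid}) \cdot 2\pi/\mathrm{span}}
#' sends the centre of \code{inputRange} to 0 and its ends to \eqn{\mp\pi};
#' values landing exactly on \eqn{-\pi} are folded to \eqn{+\pi} so the
#' result lies in \eqn{(-\pi, \pi]}.
#'
#' @param raw numeric array on the export scale.
#' @param inputRange length-2 numeric, the stored range (e.g. \code{c(0, 4094)}).
#'   \code{NULL} means the input is already in radians and is returned after
#'   range validation.
#' @return Array of wrapped radians in \eqn{(-\pi, \pi]}.
#' @export
rescalePhase <- function(raw, inputRange = c(0, 4094)) {
  if (is.null(inputRange)) {
    if (any(raw <= -pi - 1e-12 | raw > pi + 1e-12, na.rm = TRUE))
      stop("phase not in (-pi, pi]; provide inputRange to rescale")
    return(raw)
  }
  span <- diff(inputRange)
  if (span == 0) stop("zero-width input range")
  out <- (raw - mean(inputRange)) * (2 * pi / span)
  out[out == -pi] <- pi
  out
}

#' Unwrap a wrapped phase image
#'
#' Quality-guided region growing: voxels are integrated in decreasing quality
#' order starting at the highest-quality voxel of the mask, adding at each
#' step the wrapped difference of raw phases. The output is congruent with
#' the input modulo \eqn{2\pi} at every voxel and the seed voxel is left
#' unchanged, so the result is anchored to the seed region. Disconnected mask
#' components are unwrapped independently with a warning (their relative
#' \eqn{2\pi} offsets are indeterminate).
#'
#' @param wrapped array of wrapped radians.
#' @param mask logical array of voxels to unwrap.
#' @param quality optional per-voxel quality (e.g. a magnitude image; higher
#'   is better). By default the inverse local variance of the wrapped phase
#'   gradient is used.
#' @return Array of unwrapped radians (unchanged outside the mask).
#' @export
unwrapPhase <- function(wrapped, mask = NULL, quality = NULL) {
  if (is.null(mask)) mask <- array(TRUE, dim(wrapped))
  if (!any(mask)) stop("mask is empty")
  if (is.null(quality)) quality <- .phaseQuality(wrapped)
  res <- .unwrapCpp(as.numeric(wrapped), as.logical(mask),
                    as.numeric(quality), as.integer(dim(wrapped)))
  if (res$ncomponents > 1L)
    warning(sprintf("mask has %d disconnected components; 2*pi offsets between them are indeterminate",
                    res$ncomponents))
  array(res$unwrapped, dim(wrapped))
}

# Quality = negative local variance of wrapped phase gradients over the six
# face neighbours (standard phase-derivative-variance criterion).
.phaseQuality <- function(wrapped) {
  d <- dim(wrapped)
  grads <- vector("list", 6)
  i <- 1
  for (ax in 1:3) {
    a <- .alongAxis(wrapped, ax)
    if (nrow(a$mat) < 2) {            # singleton axis: no gradient
      zero <- array(0, d)
      grads[[i]] <- zero; grads[[i + 1]] <- zero
      i <- i + 2
      next
    }
    g <- .wrapToPi(diff(a$mat))
    if (is.null(dim(g))) g <- matrix(g, nrow = 1)
    gf <- rbind(g, g[nrow(g), , drop = FALSE])
    gb <- rbind(g[1, , drop = FALSE], g)
    grads[[i]] <- a$restore(gf); grads[[i + 1]] <- a$restore(gb)
    i <- i + 2
  }
  mu <- Reduce(`+`, grads) / 6
  v <- Reduce(`+`, lapply(grads, function(g) (g - mu)^2)) / 6
  -v
}

#' Convert unwrapped phase to a phase-rate map
#'
#' Element-wise division of the unwrapped phase difference by the echo-time
#' difference yields radian/s; pass the result to [radpsToHz()] for Hz.
#'
#' @param unwrapped array of unwrapped radians.
#' @param dTE echo-time difference in seconds (> 0).
#' @return Array in radian/s.
#' @export
phaseToField <- function(unwrapped, dTE) {
  if (dTE <= 0) stop("dTE must be > 0")
  unwrapped / dTE
}

#' Smooth a field map within its brain mask
#'
#' Gaussian smoothing with mask-renormalized weights, so values near the mask
#' edge are not diluted by the zero background; \code{fwhm = 0} is the
#' identity.
#'
#' @param field a \linkS4class{FieldOffsetMap} or \linkS4class{VoxelShiftMap}.
#' @param fwhm full width at half maximum of the kernel, mm.
#' @param voxelSize mm per voxel along each axis (length 1 or 3).
#' @return The smoothed map, same class.
#' @export
smoothField <- function(field, fwhm = 4, voxelSize = 2.5) {
  stopifnot(fwhm >= 0)
  if (fwhm == 0) return(field)
  voxelSize <- rep(voxelSize, length.out = 3)
  sm <- .gaussSmoothMasked(mapValues(field), brainMask(field), fwhm, voxelSize)
  initialize(field, values = sm)
}

#' Correct EPI data with a dual-echo GRE field map
#'
#' Runs the full field-mapping chain: the wrapped phase difference is
#' unwrapped (quality-guided, seeded by the first-echo magnitude), divided by
#' \eqn{\Delta TE} to radian/s and by \eqn{2\pi} to Hz, smoothed within a
#' magnitude-derived brain mask, converted to a voxel-shift map through the
#' acquisition geometry, and used to unwarp the EPI input.
#'
#' @param epi a 3-D volume or 4-D series to correct.
#' @param dualEcho a \linkS4class{DualEchoGRE} (grids aligned with the EPI).
#' @param geom an \linkS4class{EPIGeometry} describing the EPI acquisition.
#' @param fwhm smoothing kernel FWHM in mm (0 = no smoothing).
#' @param mask optional logical brain mask; by default the first-echo
#'   magnitude thresholded at \code{maskQuantile} times its Otsu threshold.
#' @param maskQuantile fraction of the Otsu threshold used for masking.
#' @param conserveMass passed to [unwarpVolume()].
#' @return A list with \code{corrected} (same shape as \code{epi}),
#'   \code{field} (\linkS4class{FieldOffsetMap}, Hz) and \code{vsm}
#'   (\linkS4class{VoxelShiftMap}, mm).
#' @export
correctGRE <- function(epi, dualEcho, geom = EPIGeometry(), fwhm = 4,
                       mask = NULL, maskQuantile = 0.75, conserveMass = TRUE) {
  stopifnot(is(dualEcho, "DualEchoGRE"))
  mag <- dualEcho@magnitude1
  if (is.null(mask))   # threshold, then drop noise speckles off the head
    mask <- .largestComponent(mag > maskQuantile * .otsu(mag))
  unwrapped <- unwrapPhase(dualEcho@phaseDiff, mask, quality = mag)
  field <- radpsToHz(phaseToField(unwrapped, deltaTE(dualEcho)), mask)
  # isolated 2*pi unwrap failures at low-SNR voxels read as half-cycle field
  # jumps (1/(2 dTE) Hz); replace them with the local median before smoothing
  field@values <- .despikeField(field@values, mask, 0.5 / (2 * deltaTE(dualEcho)))
  field <- smoothField(field, fwhm, geom@voxelSizePE)
  # extrapolate beyond the mask, then slope-limit the extrapolated region so
  # the warp stays invertible at the brain edge (in-mask values untouched)
  ext <- .extendOutsideMask(field@values, mask)
  voxPerHz <- 1 / (peBandwidth(geom) * geom@accel)
  field@values <- .limitSlopeOutsideMask(ext, mask, geom@peAxis, voxPerHz)
  vsm <- db0ToVsm(field, geom)
  corrected <- if (length(dim(epi)) == 4L) {
    correctSeries(epi, vsm, geom, conserveMass)
  } else {
    unwarpVolume(epi, vsm, geom, conserveMass)
  }
  list(corrected = corrected, field = field, vsm = vsm)
}
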