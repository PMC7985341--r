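#' @import methods
#' @importFrom stats approx convolve qnorm pt rnorm runif sd var quantile fft mvfft
#' @importFrom utils head read.csv write.csv
#' @useDynLib epiwarp, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' EPI acquisition geometry
#'
#' Acquisition constants that turn a static-field offset (Hz) into a spatial
#' shift along the phase-encoding (PE) axis: the PE voxel size \eqn{s_y}, the
#' number of echoes per excitation \eqn{n_y}, the nominal echo spacing, the
#' in-plane acceleration factor \eqn{R}, plus the index and polarity of the PE
#' axis in the voxel grid. The PE bandwidth is
#' \eqn{BW_{PE} = 1/(\mathrm{echospacing} \times n_y)} Hz per pixel.
#'
#' @slot voxelSizePE mm per voxel along the PE axis.
#' @slot nPE echoes per excitation along PE (acquisition matrix size).
#' @slot echoSpacing nominal echo spacing in seconds.
#' @slot accel in-plane (GRAPPA) acceleration factor, integer \eqn{\ge} 1.
#' @slot peAxis index (1-based) of the PE axis in the voxel grid.
#' @slot pePolarity +1 for an AP acquisition, -1 for PA.
#' @name EPIGeometry-class
#' @aliases EPIGeometry-class
#' @exportClass EPIGeometry
setClass("EPIGeometry",
  representation(voxelSizePE = "numeric", nPE = "integer",
                 echoSpacing = "numeric", accel = "integer",
                 peAxis = "integer", pePolarity = "integer"),
  prototype(voxelSizePE = 2.5, nPE = 78L, echoSpacing = 0.57e-3,
            accel = 2L, peAxis = 2L, pePolarity = 1L))

setValidity("EPIGeometry", function(object) {
  msg <- character()
  if (object@voxelSizePE <= 0) msg <- c(msg, "voxelSizePE must be > 0")
  if (object@nPE < 2L) msg <- c(msg, "nPE must be >= 2")
  if (object@echoSpacing <= 0) msg <- c(msg, "echoSpacing must be > 0")
  if (object@accel < 1L) msg <- c(msg, "accel must be >= 1")
  if (!object@pePolarity %in% c(1L, -1L)) msg <- c(msg, "pePolarity must be +1 or -1")
  if (length(msg)) msg else TRUE
})

#' Construct an EPIGeometry
#'
#' Defaults mirror a typical accelerated 3T GE-EPI protocol: 2.5 mm voxels,
#' 78 echoes per excitation, 0.57 ms nominal echo spacing, 2x in-plane
#' acceleration, PE along the second grid axis with AP (+1) polarity.
#'
#' @param voxelSizePE mm per voxel along PE.
#' @param nPE echoes per excitation.
#' @param echoSpacing nominal echo spacing (s).
#' @param accel in-plane acceleration factor.
#' @param peAxis PE axis index in the voxel grid.
#' @param pePolarity +1 (AP) or -1 (PA).
#' @return An \linkS4class{EPIGeometry}.
#' @examples
#' g <- EPIGeometry()
#' peBandwidth(g)   # Hz per pixel
#' @export
EPIGeometry <- function(voxelSizePE = 2.5, nPE = 78L, echoSpacing = 0.57e-3,
                        accel = 2L, peAxis = 2L, pePolarity = 1L) {
  new("EPIGeometry", voxelSizePE = voxelSizePE, nPE = as.integer(nPE),
      echoSpacing = echoSpacing, accel = as.integer(accel),
      peAxis = as.integer(peAxis), pePolarity = as.integer(pePolarity))
}

#' PE-direction bandwidth of an acquisition
#'
#' \eqn{BW_{PE} = 1/(\mathrm{echospacing} \times n_y)} in Hz per pixel.
#' @param geom An \linkS4class{EPIGeometry}.
#' @return Bandwidth in Hz/pixel.
#' @export
peBandwidth <- function(geom) 1 / (geom@echoSpacing * geom@nPE)

setMethod("show", "EPIGeometry", function(object) {
  cat("EPIGeometry: s_y =", object@voxelSizePE, "mm, n_y =", object@nPE,
      ", echo spacing =", object@echoSpacing * 1e3, "ms, R =", object@accel,
      "\n  PE axis", object@peAxis, "polarity", object@pePolarity,
      "| BW_PE =", round(peBandwidth(object), 3), "Hz/px\n")
})

# ---- voxel maps -------------------------------------------------------------

#' Per-voxel brain maps
#'
#' \code{BrainMap} is the virtual parent of \linkS4class{FieldOffsetMap}
#' (static-field offset, Hz) and \linkS4class{VoxelShiftMap} (PE-direction
#' displacement, mm). Both hold a 3-D numeric grid plus a logical brain mask
#' of the same shape; values must be finite inside the mask. For shift maps,
#' negative values are shifts in the anterior-to-posterior direction.
#'
#' @slot values numeric 3-D array.
#' @slot mask logical 3-D array, same shape.
#' @name BrainMap-class
#' @aliases BrainMap-class FieldOffsetMap-class VoxelShiftMap-class
#' @exportClass BrainMap
#' @exportClass FieldOffsetMap
#' @exportClass VoxelShiftMap
setClass("BrainMap", representation("VIRTUAL", values = "array", mask = "array"))

setValidity("BrainMap", function(object) {
  msg <- character()
  if (!identical(dim(object@values), dim(object@mask)))
    msg <- c(msg, "values and mask must share one grid")
  if (!is.logical(object@mask)) msg <- c(msg, "mask must be logical")
  if (any(object@mask) && !all(is.finite(object@values[object@mask])))
    msg <- c(msg, "values must be finite inside the mask")
  if (length(msg)) msg else TRUE
})

setClass("FieldOffsetMap", contains = "BrainMap")
setClass("VoxelShiftMap", contains = "BrainMap")

#' @param values numeric 3-D array (Hz for field maps, mm for shift maps).
#' @param mask logical 3-D array; defaults to everywhere-TRUE.
#' @return A \linkS4class{FieldOffsetMap} / \linkS4class{VoxelShiftMap}.
#' @rdname BrainMap-class
#' @export
FieldOffsetMap <- function(values, mask = NULL) {
  if (is.null(mask)) mask <- array(TRUE, dim(values))
  new("FieldOffsetMap", values = values, mask = mask)
}

#' @rdname BrainMap-class
#' @export
VoxelShiftMap <- function(values, mask = NULL) {
  if (is.null(mask)) mask <- array(TRUE, dim(values))
  new("VoxelShiftMap", values = values, mask = mask)
}

#' Accessors for BrainMap objects
#' @param x a \linkS4class{BrainMap}.
#' @return \code{mapValues}: the value array; \code{brainMask}: the mask.
#' @export
mapValues <- function(x) x@values

#' @rdname mapValues
#' @export
brainMask <- function(x) x@mask

setMethod("show", "BrainMap", function(object) {
  unit <- if (is(object, "FieldOffsetMap")) "Hz" else "mm"
  v <- object@values[object@mask]
  cat(class(object), paste(dim(object@values), collapse = " x "),
      sprintf("| in-mask range [%.2f, %.2f] %s (%d voxels)\n",
              if (length(v)) min(v) else NA, if (length(v)) max(v) else NA,
              unit, sum(object@mask)))
})

# ---- acquisition bundles ----------------------------------------------------

#' Dual-echo gradient-echo field-map acquisition
#'
#' Two magnitude images (one per echo time) and one wrapped phase-difference
#' image, as exported by a double-echo spoiled GRE field-mapping sequence.
#' The phase difference lives in \eqn{(-\pi, \pi]} and encodes
#' \eqn{2\pi \Delta B_0 \Delta TE} modulo \eqn{2\pi}.
#'
#' @slot magnitude1,magnitude2 intensity grids at TE1 and TE2.
#' @slot phaseDiff wrapped phase difference, radians in \eqn{(-\pi, \pi]}.
#' @slot TE1,TE2 echo times in seconds (TE2 > TE1).
#' @name DualEchoGRE-class
#' @exportClass DualEchoGRE
setClass("DualEchoGRE",
  representation(magnitude1 = "array", magnitude2 = "array",
                 phaseDiff = "array", TE1 = "numeric", TE2 = "numeric"))

setValidity("DualEchoGRE", function(object) {
  msg <- character()
  if (object@TE2 <= object@TE1) msg <- c(msg, "TE2 must exceed TE1 (dTE > 0)")
  if (!identical(dim(object@magnitude1), dim(object@phaseDiff)) ||
      !identical(dim(object@magnitude2), dim(object@phaseDiff)))
    msg <- c(msg, "magnitudes and phase must share one grid")
  p <- object@phaseDiff
  if (any(p <= -pi - 1e-12 | p > pi + 1e-12))
    msg <- c(msg, "phaseDiff must lie in (-pi, pi]")
  if (length(msg)) msg else TRUE
})

#' @param magnitude1,magnitude2 magnitude grids.
#' @param phaseDiff wrapped phase-difference grid (radians).
#' @param TE1,TE2 echo times (s).
#' @return A \linkS4class{DualEchoGRE}.
#' @rdname DualEchoGRE-class
#' @export
DualEchoGRE <- function(magnitude1, magnitude2, phaseDiff,
                        TE1 = 4.92e-3, TE2 = 7.38e-3) {
  new("DualEchoGRE", magnitude1 = magnitude1, magnitude2 = magnitude2,
      phaseDiff = phaseDiff, TE1 = TE1, TE2 = TE2)
}

#' Echo-time difference of a dual-echo acquisition
#' @param x a \linkS4class{DualEchoGRE}.
#' @return \eqn{\Delta TE} in seconds.
#' @export
deltaTE <- function(x) x@TE2 - x@TE1

setMethod("show", "DualEchoGRE", function(object) {
  cat("DualEchoGRE", paste(dim(object@phaseDiff), collapse = " x "),
      sprintf("| TE1/TE2 = %.2f/%.2f ms (dTE %.2f ms)\n",
              object@TE1 * 1e3, object@TE2 * 1e3, deltaTE(object) * 1e3))
})

#' Reversed phase-encoding image pair
#'
#' One AP-encoded and one PA-encoded EPI volume on the same grid, the input
#' to blip-up/blip-down (TOPUP-style) displacement estimation. The two images
#' carry distortions of opposite sign; the undistorted image is assumed to
#' lie midway between them.
#'
#' @slot apVolume,paVolume intensity grids.
#' @slot geom the shared \linkS4class{EPIGeometry} (its polarity refers to
#'   the AP member; the PA member is the sign-flipped acquisition).
#' @name ReversedPair-class
#' @exportClass ReversedPair
setClass("ReversedPair",
  representation(apVolume = "array", paVolume = "array", geom = "EPIGeometry"))

setValidity("ReversedPair", function(object) {
  if (!identical(dim(object@apVolume), dim(object@paVolume)))
    "AP and PA volumes must share one grid" else TRUE
})

#' @param apVolume,paVolume AP- and PA-encoded volumes.
#' @param geom shared acquisition geometry.
#' @return A \linkS4class{ReversedPair}.
#' @rdname ReversedPair-class
#' @export
ReversedPair <- function(apVolume, paVolume, geom = EPIGeometry()) {
  new("ReversedPair", apVolume = apVolume, paVolume = paVolume, geom = geom)
}

setMethod("show", "ReversedPair", function(object) {
  cat("ReversedPair", paste(dim(object@apVolume), collapse = " x "),
      "| AP/PA EPI volumes\n")
})

# ---- statistics -------------------------------------------------------------

#' Voxel-wise Z-statistic map
#'
#' @slot zValues per-voxel Z grid.
#' @slot df effective degrees of freedom of the underlying t statistic.
#' @slot mask logical analysis mask.
#' @name StatMap-class
#' @exportClass StatMap
setClass("StatMap",
  representation(zValues = "array", df = "numeric", mask = "array"))

setValidity("StatMap", function(object) {
  msg <- character()
  if (!identical(dim(object@zValues), dim(object@mask)))
    msg <- c(msg, "zValues and mask must share one grid")
  if (any(object@mask) && !all(is.finite(object@zValues[object@mask])))
    msg <- c(msg, "zValues must be finite inside the mask")
  if (length(msg)) msg else TRUE
})

#' @param zValues Z grid.
#' @param df degrees of freedom.
#' @param mask logical mask (defaults to everywhere-TRUE).
#' @return A \linkS4class{StatMap}.
#' @rdname StatMap-class
#' @export
StatMap <- function(zValues, df = Inf, mask = NULL) {
  if (is.null(mask)) mask <- array(TRUE, dim(zValues))
  new("StatMap", zValues = zValues, df = df, mask = mask)
}

#' @rdname mapValues
#' @export
zValues <- function(x) x@zValues

setMethod("show", "StatMap", function(object) {
  z <- object@zValues[object@mask]
  cat("StatMap", paste(dim(object@zValues), collapse = " x "),
      sprintf("| df = %.1f, Z in [%.2f, %.2f]\n", object@df,
              if (length(z)) min(z) else NA, if (length(z)) max(z) else NA))
})

#' Mutually exclusive template-to-component assignment
#'
#' Result of the randomized greedy Dice assignment of spatial-ICA components
#' to network templates: an injective template-to-component mapping, the mean
#' Dice over templates, and the template order that won.
#'
#' @slot mapping integer vector, \code{mapping[t]} = component index for
#'   template t (named by template).
#' @slot meanDice mean Dice coefficient over the mapped pairs.
#' @slot orderUsed the winning template permutation.
#' @name RSNAssignment-class
#' @exportClass RSNAssignment
setClass("RSNAssignment",
  representation(mapping = "integer", meanDice = "numeric", orderUsed = "integer"))

setValidity("RSNAssignment", function(object) {
  if (anyDuplicated(object@mapping))
    "mapping must be injective (mutually exclusive)" else TRUE
})

setMethod("show", "RSNAssignment", function(object) {
  cat("RSNAssignment:", length(object@mapping), "templates, mean Dice =",
      round(object@meanDice, 4), "\n  mapping:",
      paste(names(object@mapping), "->", object@mapping, collapse = ", "), "\n")
})
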