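# Synthetic-data generator: multi-tissue head phantom, smooth dB0 field with
# focal sinus offsets, dual-echo GRE images, and distorted AP/PA EPI runs
# with task and network structure.

#' Phantom specification
#'
#' Describes the synthetic head: grid, voxel size, tissue intensities,
#' ventricle geometry, the focal field blobs near air-filled sinuses
#' (amplitudes in Hz, Table-1 scale: roughly -170 to +280 Hz), and a
#' low-order polynomial background field. Blob amplitudes and widths default
#' to values whose implied voxel shifts keep the forward warp invertible
#' (max |d(shift)/dy| about 0.7 voxel/voxel).
#'
#' @slot gridShape integer(3), voxels per axis (x = LR, y = AP/PE, z = IS).
#' @slot voxelSize numeric(3), mm per voxel.
#' @slot tissueParams data.frame with columns \code{class}, \code{mean},
#'   \code{sd} for gm/wm/csf/bg intensities.
#' @slot ventricles matrix with columns cx, cy, cz (mm, grid-centred) and r (mm).
#' @slot sinusBlobs data.frame with columns cx, cy, cz (mm), sigma (mm),
#'   amplitude (Hz).
#' @slot backgroundField numeric(4): constant and x/y/z linear terms (Hz) in
#'   coordinates normalized to [-1, 1].
#' @slot seed RNG seed for all generators that consume the spec.
#' @name PhantomSpec-class
#' @exportClass PhantomSpec
setClass("PhantomSpec",
  representation(gridShape = "integer", voxelSize = "numeric",
                 tissueParams = "data.frame", ventricles = "matrix",
                 sinusBlobs = "data.frame", backgroundField = "numeric",
                 seed = "integer"))

setValidity("PhantomSpec", function(object) {
  msg <- character()
  if (length(object@gridShape) != 3L || any(object@gridShape < 8L))
    msg <- c(msg, "gridShape must be 3 positive extents")
  if (any(object@voxelSize <= 0)) msg <- c(msg, "voxelSize must be > 0")
  if (!all(c("class", "mean", "sd") %in% names(object@tissueParams)))
    msg <- c(msg, "tissueParams needs class/mean/sd columns")
  if (length(msg)) msg else TRUE
})

#' Construct a PhantomSpec
#'
#' The default grid is 48 x 64 x 32 at 2.5 mm isotropic (PE along y), small
#' enough for second-scale runtimes while matching a typical fMRI voxel size.
#' Default blobs place a +280 Hz offset in the inferior frontal region and a
#' -170 Hz offset near the temporal lobe, emulating the compression seen near
#' air-filled sinuses.
#'
#' @param gridShape,voxelSize grid extents and voxel size (mm).
#' @param tissueParams tissue intensity table (see class docs).
#' @param ventricles ventricle centres/radii (mm, grid-centred).
#' @param sinusBlobs focal field offsets (mm centres, mm widths, Hz amplitudes).
#' @param backgroundField polynomial background field coefficients (Hz).
#' @param seed RNG seed.
#' @return A \linkS4class{PhantomSpec}.
#' @export
PhantomSpec <- function(gridShape = c(48L, 64L, 32L),
                        voxelSize = c(2.5, 2.5, 2.5),
                        tissueParams = data.frame(
                          class = c("gm", "wm", "csf", "bg"),
                          mean = c(1000, 700, 1300, 0),
                          sd = c(20, 15, 25, 5)),
                        ventricles = cbind(cx = c(-8, 8), cy = c(5, 5),
                                           cz = c(2, 2), r = c(8, 8)),
                        sinusBlobs = data.frame(
                          cx = c(0, 20), cy = c(40, 10), cz = c(-20, -22),
                          sigma = c(14, 12), amplitude = c(280, -170)),
                        backgroundField = c(5, 0, 10, -8),
                        seed = 1L) {
  new("PhantomSpec", gridShape = as.integer(gridShape),
      voxelSize = rep(as.numeric(voxelSize), length.out = 3),
      tissueParams = tissueParams, ventricles = ventricles,
      sinusBlobs = sinusBlobs, backgroundField = backgroundField,
      seed = as.integer(seed))
}

setMethod("show", "PhantomSpec", function(object) {
  cat("PhantomSpec", paste(object@gridShape, collapse = " x "), "at",
      paste(object@voxelSize, collapse = "/"), "mm;",
      nrow(object@sinusBlobs), "field blobs, amplitudes",
      paste(object@sinusBlobs$amplitude, collapse = "/"), "Hz\n")
})

#' Block task design
#'
#' Timing of a block stimulation paradigm: onsets and durations in seconds,
#' repetition time, run length in volumes, and the BOLD amplitude as a
#' fractional signal change. The default emulates a motion-localizer
#' structure (28 s cycles: 18 s stimulation + 10 s rest) at 2% signal change,
#' scaled to 6 blocks for desk-scale runtimes.
#'
#' @slot TR repetition time, seconds.
#' @slot nVolumes number of volumes in the run.
#' @slot blocks two-column matrix (onset_s, duration_s).
#' @slot amplitude fractional signal change (>= 0).
#' @slot activeMask optional logical grid of truly active voxels (NULL =
#'   let the generator place one in the high-|dB0| region).
#' @name TaskDesign-class
#' @exportClass TaskDesign
setClass("TaskDesign",
  representation(TR = "numeric", nVolumes = "integer", blocks = "matrix",
                 amplitude = "numeric", activeMask = "ANY"))

setValidity("TaskDesign", function(object) {
  msg <- character()
  if (object@TR <= 0) msg <- c(msg, "TR must be > 0")
  if (object@amplitude < 0) msg <- c(msg, "amplitude must be >= 0")
  run_s <- object@nVolumes * object@TR
  if (nrow(object@blocks) &&
      any(object@blocks[, 1] + object@blocks[, 2] > run_s + 1e-9))
    msg <- c(msg, "blocks must end within the run")
  if (length(msg)) msg else TRUE
})

#' @param TR repetition time (s).
#' @param nVolumes run length in volumes.
#' @param blocks matrix of (onset_s, duration_s) rows.
#' @param amplitude fractional BOLD signal change.
#' @param activeMask optional logical grid.
#' @return A \linkS4class{TaskDesign}.
#' @rdname TaskDesign-class
#' @export
TaskDesign <- function(TR = 1, nVolumes = 168L,
                       blocks = cbind(onset = seq(0, 140, by = 28),
                                      duration = 18),
                       amplitude = 0.02, activeMask = NULL) {
  new("TaskDesign", TR = TR, nVolumes = as.integer(nVolumes),
      blocks = blocks, amplitude = amplitude, activeMask = activeMask)
}

setMethod("show", "TaskDesign", function(object) {
  cat("TaskDesign:", object@nVolumes, "volumes at TR", object@TR, "s,",
      nrow(object@blocks), "blocks, amplitude",
      object@amplitude * 100, "%\n")
})

#' Ground truth of a simulated run
#'
#' Everything the assessment stage may compare against: the structural
#' volume, tissue labels (0 bg, 1 GM, 2 WM, 3 CSF), brain mask, WM boundary
#' points with outward unit normals, the true field and voxel-shift maps,
#' the active mask and the network masks — all on one grid.
#'
#' @slot structural noise-free intensity volume.
#' @slot tissueLabels integer label grid.
#' @slot brainMask logical grid.
#' @slot boundaryPoints n x 3 matrix of WM-surface voxel coordinates.
#' @slot boundaryNormals n x 3 matrix of outward unit normals (mm space).
#' @slot trueField \linkS4class{FieldOffsetMap} (Hz).
#' @slot trueVsm \linkS4class{VoxelShiftMap} (mm).
#' @slot activeMask logical grid of task-active voxels.
#' @slot networkMasks named list of logical grids.
#' @name GroundTruth-class
#' @exportClass GroundTruth
setClass("GroundTruth",
  representation(structural = "array", tissueLabels = "array",
                 brainMask = "array", boundaryPoints = "matrix",
                 boundaryNormals = "matrix", trueField = "ANY",
                 trueVsm = "ANY", activeMask = "array",
                 networkMasks = "list"))

setMethod("show", "GroundTruth", function(object) {
  cat("GroundTruth", paste(dim(object@structural), collapse = " x "), "|",
      sum(object@brainMask), "brain voxels,",
      nrow(object@boundaryPoints), "WM boundary points,",
      length(object@networkMasks), "networks\n")
})

# mm coordinates of voxel centres, grid-centred, as three arrays.
.gridCoords <- function(shape, voxelSize) {
  ax <- lapply(1:3, function(a)
    (seq_len(shape[a]) - (shape[a] + 1) / 2) * voxelSize[a])
  list(x = array(rep(ax[[1]], times = shape[2] * shape[3]), shape),
       y = array(rep(rep(ax[[2]], each = shape[1]), times = shape[3]), shape),
       z = array(rep(ax[[3]], each = shape[1] * shape[2]), shape))
}

.insideEllipsoid <- function(co, centre, semi) {
  ((co$x - centre[1]) / semi[1])^2 + ((co$y - centre[2]) / semi[2])^2 +
    ((co$z - centre[3]) / semi[3])^2 <= 1
}

#' Build the multi-tissue head phantom
#'
#' Deterministic given the spec: nested ellipsoids define brain (GM), WM and
#' CSF-filled ventricles; the structural volume holds the per-class mean
#' intensities. WM boundary points are the WM voxels with a non-WM face
#' neighbour; outward unit normals come from the gradient of a smoothed WM
#' indicator.
#'
#' @param spec a \linkS4class{PhantomSpec}.
#' @return A \linkS4class{GroundTruth} (field/VSM slots filled by
#'   [makeField()] / [makePhantomRun()]).
#' @export
makePhantom <- function(spec = PhantomSpec()) {
  stopifnot(is(spec, "PhantomSpec"))
  shape <- spec@gridShape
  vs <- spec@voxelSize
  co <- .gridCoords(shape, vs)
  extent <- shape * vs / 2
  brain <- .insideEllipsoid(co, c(0, 0, 0), extent * c(0.92, 0.88, 0.90))
  wm <- .insideEllipsoid(co, c(0, 0, 2), extent * c(0.64, 0.60, 0.62))
  vent <- array(FALSE, shape)
  if (nrow(spec@ventricles)) {
    for (i in seq_len(nrow(spec@ventricles))) {
      v <- spec@ventricles[i, ]
      vent <- vent | .insideEllipsoid(co, v[1:3], rep(v[4], 3))
    }
    vent <- vent & wm
  }
  labels <- array(0L, shape)
  labels[brain] <- 1L                       # GM
  labels[wm] <- 2L
  labels[vent] <- 3L                        # CSF
  if (!any(labels == 1L) || !any(labels == 2L))
    stop("degenerate phantom geometry: empty tissue class")
  tp <- spec@tissueParams
  means <- stats::setNames(tp$mean, tp$class)
  structural <- array(means["bg"], shape)
  structural[labels == 1L] <- means["gm"]
  structural[labels == 2L] <- means["wm"]
  structural[labels == 3L] <- means["csf"]

  # WM boundary points: WM voxels with a non-WM face neighbour.
  wmMask <- labels == 2L
  shifted <- function(m, ax, by) {
    a <- .alongAxis(m, ax)
    n <- nrow(a$mat)
    idx <- pmin(pmax(seq_len(n) + by, 1L), n)
    a$restore(a$mat[idx, , drop = FALSE])
  }
  nbAllWM <- shifted(wmMask, 1, 1) & shifted(wmMask, 1, -1) &
             shifted(wmMask, 2, 1) & shifted(wmMask, 2, -1) &
             shifted(wmMask, 3, 1) & shifted(wmMask, 3, -1)
  boundary <- wmMask & !nbAllWM
  pts <- which(boundary, arr.ind = TRUE)
  storage.mode(pts) <- "double"

  smooth <- .gaussSmooth3d(wmMask * 1, fwhm_mm = 6, voxel_mm = vs)
  grad <- vapply(1:3, function(ax) {
    a <- .alongAxis(smooth, ax)
    n <- nrow(a$mat)
    g <- (a$mat[pmin(seq_len(n) + 1L, n), , drop = FALSE] -
          a$mat[pmax(seq_len(n) - 1L, 1L), , drop = FALSE]) / (2 * vs[ax])
    a$restore(g)[cbind(pts[, 1], pts[, 2], pts[, 3])]
  }, numeric(nrow(pts)))
  nrm <- -grad                               # outward = down the WM indicator
  len <- sqrt(rowSums(nrm^2))
  keep <- len > 1e-9
  pts <- pts[keep, , drop = FALSE]
  nrm <- nrm[keep, , drop = FALSE] / len[keep]

  new("GroundTruth", structural = structural, tissueLabels = labels,
      brainMask = brain, boundaryPoints = pts, boundaryNormals = nrm,
      trueField = NULL, trueVsm = NULL,
      activeMask = array(FALSE, shape), networkMasks = list())
}

#' Generate the ground-truth field-offset map
#'
#' Smooth low-order polynomial background plus Gaussian blobs at the
#' configured sinus locations; values in Hz on the phantom grid with the
#' brain ellipsoid as mask.
#'
#' @param spec a \linkS4class{PhantomSpec}.
#' @param mask optional logical mask (defaults to the phantom's brain mask).
#' @return A \linkS4class{FieldOffsetMap}.
#' @export
makeField <- function(spec = PhantomSpec(), mask = NULL) {
  stopifnot(is(spec, "PhantomSpec"))
  shape <- spec@gridShape
  co <- .gridCoords(shape, spec@voxelSize)
  extent <- shape * spec@voxelSize / 2
  bf <- spec@backgroundField
  field <- bf[1] + bf[2] * co$x / extent[1] + bf[3] * co$y / extent[2] +
           bf[4] * co$z / extent[3]
  if (nrow(spec@sinusBlobs)) {
    for (i in seq_len(nrow(spec@sinusBlobs))) {
      b <- spec@sinusBlobs[i, ]
      r2 <- (co$x - b$cx)^2 + (co$y - b$cy)^2 + (co$z - b$cz)^2
      field <- field + b$amplitude * exp(-r2 / (2 * b$sigma^2))
    }
  }
  if (is.null(mask)) {
    mask <- .insideEllipsoid(co, c(0, 0, 0), extent * c(0.92, 0.88, 0.90))
  }
  FieldOffsetMap(field, mask)
}

# Default smooth network masks: blob pairs thresholded at half maximum.
# Centres are fractions of the half-extent so smaller test grids still get
# in-brain networks.
.defaultNetworks <- function(spec, brain) {
  co <- .gridCoords(spec@gridShape, spec@voxelSize)
  e <- spec@gridShape * spec@voxelSize / 2
  blobPair <- function(c1, c2, sigma = 10) {
    g <- exp(-((co$x - c1[1])^2 + (co$y - c1[2])^2 + (co$z - c1[3])^2) /
             (2 * sigma^2)) +
         exp(-((co$x - c2[1])^2 + (co$y - c2[2])^2 + (co$z - c2[3])^2) /
             (2 * sigma^2))
    (g > 0.5) & brain
  }
  list(dmn = blobPair(c(0, 0.56 * e[2], 0.2 * e[3]),
                      c(0, -0.56 * e[2], 0.2 * e[3])),
       motor = blobPair(c(-0.42 * e[1], -0.06 * e[2], 0.3 * e[3]),
                        c(0.42 * e[1], -0.06 * e[2], 0.3 * e[3])),
       visual = blobPair(c(-0.2 * e[1], -0.65 * e[2], -0.05 * e[3]),
                         c(0.2 * e[1], -0.65 * e[2], -0.05 * e[3])))
}

# Default task-active region: a sphere in the high-|dB0| inferior frontal
# area, restricted to brain tissue.
.defaultActiveMask <- function(spec, brain) {
  co <- .gridCoords(spec@gridShape, spec@voxelSize)
  e <- spec@gridShape * spec@voxelSize / 2
  r2 <- (co$x - 0)^2 + (co$y - 0.475 * e[2])^2 + (co$z + 0.4 * e[3])^2
  (r2 <= 9^2) & brain
}

# Low-frequency (< cutoff Hz) unit-variance time course.
.lowFreqTimecourse <- function(n, TR, cutoff = 0.1) {
  x <- stats::rnorm(n)
  X <- stats::fft(x)
  freq <- (seq_len(n) - 1) / (n * TR)
  freq <- pmin(freq, 1 / TR - freq)
  X[freq >= cutoff] <- 0
  y <- Re(stats::fft(X, inverse = TRUE)) / n
  if (stats::sd(y) < 1e-12) return(rep(0, n))
  (y - mean(y)) / stats::sd(y)
}

#' Simulate a dual-echo GRE acquisition
#'
#' Complex-signal model: each echo is \eqn{S e^{i 2\pi \Delta B_0 TE_e}} plus
#' complex Gaussian noise, so magnitudes are Rician and the wrapped phase
#' difference equals \eqn{2\pi \Delta B_0 \Delta TE} modulo \eqn{2\pi}
#' (noise-free). The GRE images are geometrically undistorted (standard GE
#' readout).
#'
#' @param structural noise-free intensity volume.
#' @param field \linkS4class{FieldOffsetMap} (Hz).
#' @param TE1,TE2 echo times (s), TE2 > TE1.
#' @param noiseSd complex-noise sd as a fraction of the mean brain intensity
#'   (1/SNR); 0 for noise-free.
#' @param seed RNG seed.
#' @return A \linkS4class{DualEchoGRE}.
#' @export
synthDualEcho <- function(structural, field, TE1 = 4.92e-3, TE2 = 7.38e-3,
                          noiseSd = 0, seed = 1L) {
  if (TE2 - TE1 <= 0) stop("dTE must be > 0")
  stopifnot(identical(dim(structural), dim(mapValues(field))))
  set.seed(seed)
  f <- mapValues(field)
  sig <- noiseSd * mean(structural[structural > 0])
  echo <- function(TE) {
    ph <- 2 * pi * f * TE
    z <- structural * exp(1i * ph)
    if (sig > 0)
      z <- z + complex(real = stats::rnorm(length(z), 0, sig),
                       imaginary = stats::rnorm(length(z), 0, sig))
    array(z, dim(structural))
  }
  z1 <- echo(TE1)
  z2 <- echo(TE2)
  DualEchoGRE(magnitude1 = abs(z1), magnitude2 = abs(z2),
              phaseDiff = .wrapToPi(Arg(z2 * Conj(z1))), TE1 = TE1, TE2 = TE2)
}

#' Simulate a distorted AP EPI run plus PA calibration volumes
#'
#' The BOLD series is baseline x (1 + task regressor + network fluctuations),
#' each volume is then pushed through the mass-conserving forward distortion
#' with AP polarity; \code{nPA} calibration volumes of the resting baseline
#' are distorted with the opposite (PA) polarity. Gaussian noise (sd =
#' \code{noiseSd} x mean brain intensity) is added after distortion,
#' emulating acquisition noise.
#'
#' @param truth a \linkS4class{GroundTruth} with structural and masks.
#' @param field \linkS4class{FieldOffsetMap} (Hz) used for the distortion.
#' @param geom \linkS4class{EPIGeometry} (AP polarity assumed +1).
#' @param design a \linkS4class{TaskDesign}.
#' @param networkAmp sd of each network's fractional fluctuation.
#' @param noiseSd acquisition noise as a fraction of mean brain intensity.
#' @param seed RNG seed.
#' @param nPA number of PA calibration volumes (the pipeline uses the last).
#' @return List with \code{ap} (4-D series), \code{pa} (4-D calibration
#'   volumes), \code{regressor} (HRF-convolved boxcar), \code{networkTs}
#'   (matrix of network time courses), and \code{vsm} (the true
#'   \linkS4class{VoxelShiftMap} used).
#' @export
synthEpiRun <- function(truth, field, geom = EPIGeometry(),
                        design = TaskDesign(), networkAmp = 0.01,
                        noiseSd = 0.02, seed = 1L, nPA = 10L) {
  stopifnot(is(truth, "GroundTruth"), is(field, "FieldOffsetMap"))
  set.seed(seed)
  shape <- dim(truth@structural)
  n <- design@nVolumes
  vsm <- db0ToVsm(field, geom)
  active <- if (!is.null(design@activeMask)) design@activeMask else
    truth@activeMask
  x <- taskRegressor(design)
  nets <- truth@networkMasks
  netTs <- if (length(nets))
    vapply(seq_along(nets), function(k) .lowFreqTimecourse(n, design@TR),
           numeric(n)) else matrix(0, n, 0)
  base <- truth@structural
  sig <- noiseSd * mean(base[truth@brainMask])
  geomPA <- initialize(geom, pePolarity = -geom@pePolarity)

  ap <- array(0, c(shape, n))
  for (t in seq_len(n)) {
    mod <- array(1, shape)
    if (design@amplitude > 0) mod <- mod + design@amplitude * x[t] * active
    for (k in seq_along(nets))
      mod <- mod + networkAmp * netTs[t, k] * nets[[k]]
    vol <- applyDistortion(base * mod, vsm, geom, conserveMass = TRUE)
    if (sig > 0) vol <- vol + array(stats::rnorm(length(vol), 0, sig), shape)
    ap[, , , t] <- vol
  }
  pa <- array(0, c(shape, nPA))
  paBase <- applyDistortion(base, vsm, geomPA, conserveMass = TRUE)
  for (t in seq_len(nPA)) {
    vol <- paBase
    if (sig > 0) vol <- vol + array(stats::rnorm(length(vol), 0, sig), shape)
    pa[, , , t] <- vol
  }
  list(ap = ap, pa = pa, regressor = x, networkTs = netTs, vsm = vsm)
}

#' HRF-convolved block regressor for a task design
#'
#' Unit boxcar (1 during stimulation blocks, 0 at baseline) sampled at the
#' TR and convolved with the canonical double-gamma HRF (unit peak).
#'
#' @param design a \linkS4class{TaskDesign}.
#' @return Numeric vector of length \code{nVolumes}.
#' @export
taskRegressor <- function(design) {
  n <- design@nVolumes
  t_s <- (seq_len(n) - 1) * design@TR
  box <- rep(0, n)
  for (i in seq_len(nrow(design@blocks))) {
    on <- design@blocks[i, 1]
    off <- on + design@blocks[i, 2]
    box[t_s >= on & t_s < off] <- 1
  }
  h <- doubleGammaHrf(design@TR)
  full <- stats::convolve(box, rev(h), type = "open")
  full[seq_len(n)]
}

#' Assemble a complete simulated study
#'
#' Phantom + field + dual-echo GRE + distorted AP/PA EPI run, bundled with
#' the ground truth. Fully deterministic under the spec's seed.
#'
#' @param spec a \linkS4class{PhantomSpec}.
#' @param geom an \linkS4class{EPIGeometry}.
#' @param design a \linkS4class{TaskDesign}.
#' @param networkAmp,noiseSd,nPA passed to [synthEpiRun()] (the same
#'   \code{noiseSd} is used for the dual-echo images).
#' @return A list with \code{truth} (\linkS4class{GroundTruth}, field and VSM
#'   slots filled), \code{dualEcho}, \code{ap}, \code{pa}, \code{regressor},
#'   \code{geom}, \code{design}, \code{spec}.
#' @export
makePhantomRun <- function(spec = PhantomSpec(), geom = EPIGeometry(),
                           design = TaskDesign(), networkAmp = 0.01,
                           noiseSd = 0.02, nPA = 10L) {
  truth <- makePhantom(spec)
  field <- makeField(spec, truth@brainMask)
  truth@trueField <- field
  truth@trueVsm <- db0ToVsm(field, geom)
  truth@activeMask <- .defaultActiveMask(spec, truth@brainMask)
  truth@networkMasks <- .defaultNetworks(spec, truth@brainMask)
  dualEcho <- synthDualEcho(truth@structural, field, noiseSd = noiseSd,
                            seed = spec@seed)
  run <- synthEpiRun(truth, field, geom, design, networkAmp = networkAmp,
                     noiseSd = noiseSd, seed = spec@seed + 1L, nPA = nPA)
  list(truth = truth, dualEcho = dualEcho, ap = run$ap, pa = run$pa,
       regressor = run$regressor, geom = geom, design = design, spec = spec)
}
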