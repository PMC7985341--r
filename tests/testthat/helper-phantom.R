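# Shared fixtures, built once per test run. The default phantom matches the
# package defaults (48 x 64 x 32 at 2.5 mm); the small spec keeps runner and
# estimator tests fast while preserving warp invertibility.

tpGeom <- EPIGeometry()
tpGeomPA <- EPIGeometry(pePolarity = -1L)

tpSpec <- PhantomSpec()
tpTruth <- makePhantom(tpSpec)
tpField <- makeField(tpSpec, tpTruth@brainMask)
tpVsm <- db0ToVsm(tpField, tpGeom)
tpBrain <- tpTruth@brainMask

smallSpec <- function(seed = 1L) {
  PhantomSpec(
    gridShape = c(32L, 32L, 16L),
    ventricles = cbind(cx = c(-5, 5), cy = c(3, 3), cz = c(1, 1), r = c(5, 5)),
    sinusBlobs = data.frame(cx = c(0, 8), cy = c(18, -10), cz = c(-8, -8),
                            sigma = c(10, 10), amplitude = c(120, -80)),
    backgroundField = c(2, 0, 5, -3),
    seed = seed)
}

smallDesign <- function(n = 40L) {
  TaskDesign(TR = 1, nVolumes = n, blocks = cbind(onset = 2, duration = 18),
             amplitude = 0.02)
}

# A smooth band-limited test volume (sum of low-frequency cosines) on the
# default grid, for round-trip accuracy checks. A smooth taper along the PE
# axis keeps the object inside the field of view (zero background at the
# grid edges, like any head phantom), so no signal is pushed off the grid.
bandLimitedVolume <- function(shape = c(48L, 64L, 32L)) {
  co <- lapply(seq_along(shape), function(a) seq_len(shape[a]) / shape[a])
  x <- array(rep(co[[1]], times = shape[2] * shape[3]), shape)
  y <- array(rep(rep(co[[2]], each = shape[1]), times = shape[3]), shape)
  z <- array(rep(co[[3]], each = shape[1] * shape[2]), shape)
  v <- 100 + 40 * cos(2 * pi * x) * sin(2 * pi * y) +
    25 * cos(2 * pi * (y + z)) + 15 * sin(4 * pi * y)
  v * sin(pi * (y - 0.5 / shape[2]))^2
}
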