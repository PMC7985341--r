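# Distortion physics: field/shift conversion, forward model, unwarping.

test_that("radpsToHz divides by 2*pi and rejects non-finite input", {
  x <- array(c(2 * pi, 0, pi, -4 * pi), c(4, 1, 1))
  out <- radpsToHz(x)
  expect_equal(as.numeric(mapValues(out)), c(1, 0, 0.5, -2))
  bad <- array(c(1, NA), c(2, 1, 1))
  expect_error(radpsToHz(bad), "non-finite")
  # NA outside the mask is tolerated
  m <- array(c(TRUE, FALSE), c(2, 1, 1))
  expect_silent(radpsToHz(bad, m))
})

test_that("db0ToVsm reproduces the printed shift extrema at 1 decimal", {
  # acquisition: s_y = 2.5 mm, nominal echo spacing 0.57 ms, n_y = 78, R = 2
  db0 <- c(-76, 61, -168, 282, -77, 280)
  printed <- c(-4.2, 3.4, -9.3, 15.7, -4.3, 15.6)
  f <- FieldOffsetMap(array(db0, c(6, 1, 1)))
  vsm <- db0ToVsm(f, tpGeom)
  expect_equal(round(as.numeric(mapValues(vsm)), 1), printed)
  expect_equal(as.numeric(mapValues(db0ToVsm(FieldOffsetMap(array(0, c(1, 1, 1))), tpGeom))), 0)
})

test_that("db0ToVsm is linear and nominal-vs-effective spacing agree", {
  f <- FieldOffsetMap(array(runif(24, -200, 300), c(4, 3, 2)))
  a <- 3.7
  v1 <- mapValues(db0ToVsm(FieldOffsetMap(a * mapValues(f)), tpGeom))
  v2 <- a * mapValues(db0ToVsm(f, tpGeom))
  expect_equal(v1, v2)
  gEff <- EPIGeometry(echoSpacing = 0.285e-3, accel = 1L)
  expect_equal(mapValues(db0ToVsm(f, tpGeom)), mapValues(db0ToVsm(f, gEff)))
})

test_that("applyDistortion: zero shift is identity, constant shift translates", {
  v <- bandLimitedVolume()
  zero <- VoxelShiftMap(array(0, dim(v)))
  expect_equal(applyDistortion(v, zero, tpGeom), v)
  expect_equal(applyDistortion(v, zero, tpGeom, conserveMass = FALSE), v)
  # +2.5 mm at s_y = 2.5 and polarity +1 -> exactly one voxel along PE
  one <- VoxelShiftMap(array(2.5, dim(v)))
  shifted <- applyDistortion(v, one, tpGeom, conserveMass = FALSE)
  expect_equal(shifted[, 2:64, ], v[, 1:63, ], tolerance = 1e-12)
})

test_that("mass-conserving warp matches a dense 1-D integration oracle", {
  # linear-ramp shift over a boxcar profile: the output cell masses must
  # equal the integral of the pushed piecewise-constant density
  n <- 64L
  prof <- rep(0, n); prof[20:36] <- 1                      # boxcar
  ramp_mm <- seq(-4, 4, length.out = n)                    # linear VSM ramp
  vol <- array(rep(prof, each = 4), c(4L, n, 2L))
  vsm <- VoxelShiftMap(array(rep(ramp_mm, each = 4), c(4L, n, 2L)))
  out <- applyDistortion(vol, vsm, tpGeom, conserveMass = TRUE)

  # oracle: dense numerical integration of the mapped density on one line
  d_vox <- ramp_mm / 2.5
  edges <- seq(0.5, n + 0.5)
  dEdge <- approx(seq_len(n), d_vox, xout = edges, rule = 2)$y
  mapped <- edges + dEdge
  fine <- seq(0.5, n + 0.5, by = 1e-3)
  dens <- numeric(length(fine))
  for (k in seq_len(n)) {
    if (prof[k] == 0) next
    lo <- mapped[k]; hi <- mapped[k + 1]
    inside <- fine >= lo & fine < hi
    dens[inside] <- dens[inside] + prof[k] / (hi - lo)
  }
  oracle <- vapply(seq_len(n), function(j)
    sum(dens[fine >= j - 0.5 & fine < j + 0.5]) * 1e-3, numeric(1))
  expect_equal(out[1, , 1], oracle, tolerance = 1e-3)
  # and per-line mass is conserved to 1e-6 relative
  expect_equal(sum(out[1, , 1]), sum(prof), tolerance = 1e-6)
  expect_equal(apply(out, c(1, 3), sum),
               apply(vol, c(1, 3), sum), tolerance = 1e-6)
})

test_that("mass conservation holds for the default phantom field", {
  dist <- applyDistortion(tpTruth@structural, tpVsm, tpGeom, conserveMass = TRUE)
  lines0 <- apply(tpTruth@structural, c(1, 3), sum)
  lines1 <- apply(dist, c(1, 3), sum)
  nz <- lines0 > 0
  expect_lt(max(abs(lines1[nz] - lines0[nz]) / lines0[nz]), 1e-6)
})

test_that("non-invertible warps are rejected with a diagnostic", {
  v <- bandLimitedVolume()
  n <- dim(v)[2]
  steep <- VoxelShiftMap(array(rep(seq(0, 3 * n, length.out = n), each = 48),
                               dim(v)))
  expect_error(applyDistortion(v, steep, tpGeom), "not invertible")
  expect_error(unwarpVolume(v, steep, tpGeom), "not invertible")
})

test_that("apply -> unwarp round trip is accurate on band-limited input", {
  v <- bandLimitedVolume()
  # |VSM|/s_y <= 0.8: smooth shift field capped at 2 mm (0.8 voxel)
  co <- seq_len(64) / 64
  shift <- array(rep(2 * sin(2 * pi * co), each = 48), dim(v))
  vsm <- VoxelShiftMap(shift)
  for (cm in c(TRUE, FALSE)) {
    dist <- applyDistortion(v, vsm, tpGeom, conserveMass = cm)
    back <- unwarpVolume(dist, vsm, tpGeom, conserveMass = cm)
    rmse <- sqrt(mean((back - v)^2))
    expect_lt(rmse / diff(range(v)), 0.01)
  }
})

test_that("zero-shift unwarp is identity; correctSeries matches unwarpVolume", {
  v <- bandLimitedVolume()
  zero <- VoxelShiftMap(array(0, dim(v)))
  expect_equal(unwarpVolume(v, zero, tpGeom), v)
  ser <- array(0, c(dim(v), 2L)); ser[, , , 1] <- v; ser[, , , 2] <- 2 * v
  out <- correctSeries(ser, tpVsm, tpGeom)
  expect_equal(out[, , , 1], unwarpVolume(v, tpVsm, tpGeom))
  expect_equal(out[, , , 2], unwarpVolume(2 * v, tpVsm, tpGeom))
})

test_that("AP and PA distortions unwarp to the same truth", {
  v <- tpTruth@structural
  ap <- applyDistortion(v, tpVsm, tpGeom)
  pa <- applyDistortion(v, tpVsm, tpGeomPA)
  uA <- unwarpVolume(ap, tpVsm, tpGeom)
  uP <- unwarpVolume(pa, tpVsm, tpGeomPA)
  # interiors agree within interpolation tolerance (edges are resampled)
  m <- tpBrain
  expect_lt(sqrt(mean((uA - uP)[m]^2)) / diff(range(v)), 0.02)
})
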