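# Synthetic-data generator: phantom, field, dual-echo GRE, EPI runs.

test_that("makePhantom is deterministic and geometrically sane", {
  p1 <- makePhantom(tpSpec)
  p2 <- makePhantom(tpSpec)
  expect_identical(p1@structural, p2@structural)
  expect_identical(p1@tissueLabels, p2@tissueLabels)
  expect_identical(p1@boundaryPoints, p2@boundaryPoints)
  # tissue classes are disjoint by construction of the label map
  expect_true(all(p1@tissueLabels %in% 0:3))
  expect_gt(sum(p1@tissueLabels == 2L), 0)  # WM present
  expect_gt(sum(p1@tissueLabels == 3L), 0)  # ventricles present
})

test_that("no-ventricle spec gives empty CSF and disjoint WM/CSF", {
  sp <- PhantomSpec(ventricles = cbind(cx = numeric(0), cy = numeric(0),
                                       cz = numeric(0), r = numeric(0)))
  p <- makePhantom(sp)
  expect_equal(sum(p@tissueLabels == 3L), 0)
  expect_equal(sum(p@tissueLabels == 2L & p@tissueLabels == 3L), 0)
})

test_that("boundary normals are unit length and outward", {
  p <- tpTruth
  len <- sqrt(rowSums(p@boundaryNormals^2))
  expect_lt(mean(abs(len - 1)), 1e-6)
  # outward: stepping 2 voxels along the normal must leave WM more often
  # than staying in it
  step <- p@boundaryPoints + 2 * p@boundaryNormals
  step <- round(step)
  d <- dim(p@tissueLabels)
  ok <- step[, 1] >= 1 & step[, 1] <= d[1] & step[, 2] >= 1 &
        step[, 2] <= d[2] & step[, 3] >= 1 & step[, 3] <= d[3]
  outsideWM <- p@tissueLabels[step[ok, , drop = FALSE]] != 2L
  expect_gt(mean(outsideWM), 0.9)
})

test_that("makeField honours amplitudes and the configured range", {
  # all amplitudes zero (and zero background) -> zero field
  sp0 <- PhantomSpec(sinusBlobs = data.frame(cx = 0, cy = 40, cz = -20,
                                             sigma = 14, amplitude = 0),
                     backgroundField = c(0, 0, 0, 0))
  expect_equal(max(abs(mapValues(makeField(sp0)))), 0)
  # single blob centred on a voxel peaks at its amplitude (the grid centre
  # itself falls between voxels on even-sized grids)
  sp1 <- PhantomSpec(sinusBlobs = data.frame(cx = 1.25, cy = 1.25, cz = 1.25,
                                             sigma = 12, amplitude = 150),
                     backgroundField = c(0, 0, 0, 0))
  f1 <- makeField(sp1)
  expect_lt(abs(max(mapValues(f1)) - 150) / 150, 0.01)
  # default spec covers the configured range inside the mask
  v <- mapValues(tpField)[brainMask(tpField)]
  expect_lte(min(v), -100)
  expect_gte(max(v), 200)
})

test_that("default field keeps the forward warp invertible", {
  d <- epiwarp:::.peShiftVox(tpVsm, tpGeom)
  expect_lt(max(abs(diff(d$mat))), 1)
})

test_that("synthDualEcho phase follows the closed-form wrap", {
  sp <- tpSpec
  # dB0 = 0 -> zero phase, noise-free
  de0 <- synthDualEcho(tpTruth@structural,
                       FieldOffsetMap(array(0, dim(tpTruth@structural))),
                       noiseSd = 0)
  expect_equal(max(abs(de0@phaseDiff)), 0)
  # dB0 = 101.63 Hz at dTE = 2.46 ms -> pi/2 rad, unwrapped
  f1 <- FieldOffsetMap(array(101.63, c(2, 2, 2)))
  de1 <- synthDualEcho(array(100, c(2, 2, 2)), f1, noiseSd = 0)
  expect_equal(de1@phaseDiff[1], 2 * pi * 101.63 * 2.46e-3, tolerance = 1e-9)
  expect_equal(de1@phaseDiff[1], pi / 2, tolerance = 1e-4)
  # dB0 = 250 Hz -> 3.864 rad wraps to -2.419 rad
  f2 <- FieldOffsetMap(array(250, c(2, 2, 2)))
  de2 <- synthDualEcho(array(100, c(2, 2, 2)), f2, noiseSd = 0)
  expect_equal(de2@phaseDiff[1], 2 * pi * 250 * 2.46e-3 - 2 * pi,
               tolerance = 1e-9)
  expect_lt(abs(de2@phaseDiff[1] - (-2.419)), 1e-3)
  # wrapped phase always in (-pi, pi], also with noise
  deN <- synthDualEcho(tpTruth@structural, tpField, noiseSd = 0.1, seed = 9)
  expect_true(all(deN@phaseDiff > -pi & deN@phaseDiff <= pi))
  expect_error(synthDualEcho(tpTruth@structural, tpField, TE1 = 5e-3,
                             TE2 = 5e-3), "dTE")
})

test_that("synthEpiRun injects the designed signal exactly", {
  sp <- smallSpec()
  truth <- makePhantom(sp)
  truth@activeMask <- epiwarp:::.defaultActiveMask(sp, truth@brainMask)
  zeroField <- FieldOffsetMap(array(0, sp@gridShape))
  des <- smallDesign(60L)

  # amplitude 0, noise 0 -> constant series at baseline
  des0 <- TaskDesign(TR = 1, nVolumes = 60L, blocks = des@blocks, amplitude = 0)
  r0 <- synthEpiRun(truth, zeroField, tpGeom, des0, networkAmp = 0, noiseSd = 0)
  expect_equal(max(abs(sweep(r0$ap, 1:3, r0$ap[, , , 1]))), 0)

  # injected 2% amplitude, noise 0: peak relative change = 2% x max regressor
  r1 <- synthEpiRun(truth, zeroField, tpGeom, des, networkAmp = 0, noiseSd = 0)
  act <- which(truth@activeMask & truth@structural > 0)[1]
  pos <- arrayInd(act, sp@gridShape)
  ts <- r1$ap[pos[1], pos[2], pos[3], ]
  base <- truth@structural[act]
  expect_equal(max(ts / base - 1), 0.02 * max(r1$regressor), tolerance = 1e-6)

  # zero field: AP and PA volumes identical up to independent noise draws
  r2 <- synthEpiRun(truth, zeroField, tpGeom, des0, networkAmp = 0,
                    noiseSd = 0.02, seed = 5)
  dif <- r2$ap[, , , 1] - r2$pa[, , , 1]
  sig <- 0.02 * mean(truth@structural[truth@brainMask])
  expect_lt(abs(sd(dif) - sqrt(2) * sig) / (sqrt(2) * sig), 0.05)

  # determinism under fixed seed
  r3 <- synthEpiRun(truth, zeroField, tpGeom, des0, networkAmp = 0,
                    noiseSd = 0.02, seed = 5)
  expect_identical(r2$ap, r3$ap)
  expect_identical(r2$pa, r3$pa)
})

test_that("makePhantomRun bundles aligned ground truth", {
  run <- makePhantomRun(smallSpec(), tpGeom, smallDesign(30L), noiseSd = 0)
  expect_s4_class(run$truth, "GroundTruth")
  expect_s4_class(run$dualEcho, "DualEchoGRE")
  expect_equal(dim(run$ap)[4], 30L)
  expect_equal(dim(run$pa)[4], 10L)
  expect_equal(dim(run$ap)[1:3], dim(mapValues(run$truth@trueVsm)))
  expect_length(run$truth@networkMasks, 3)
  expect_gt(sum(run$truth@activeMask), 0)
})
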