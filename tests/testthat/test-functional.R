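# GLM activation mapping, preprocessing, group statistics, spatial ICA.

test_that("double-gamma HRF has the canonical shape", {
  h <- doubleGammaHrf(0.5)
  t <- (seq_along(h) - 1) * 0.5
  peak <- t[which.max(h)]
  expect_gte(peak, 4); expect_lte(peak, 7)
  expect_equal(h[1], 0)
  expect_equal(max(h), 1)
  expect_lt(abs(h[t == 30]), 0.05)
  expect_lt(min(h), 0)                      # undershoot present
})

test_that("preprocessSeries removes drifts and keeps task frequencies", {
  nn <- 168L
  cc <- preprocessSeries(array(5, c(2, 2, 2, nn)), TR = 1, fwhm = 0)
  expect_lt(max(abs(cc)), 1e-10)
  # 0.05 Hz (20 s period) passes the 100 s high-pass nearly untouched
  s <- sin(2 * pi * 0.05 * (0:(nn - 1)))
  ser <- array(rep(s, each = 8), c(2, 2, 2, nn))
  pp <- preprocessSeries(ser, TR = 1, fwhm = 0)
  expect_gt(sd(pp[1, 1, 1, ]) / sd(s), 0.95)
  # a 200 s period drift is strongly attenuated
  dr <- sin(2 * pi * (0:(nn - 1)) / 200)
  ppd <- preprocessSeries(array(rep(dr, each = 8), c(2, 2, 2, nn)),
                          TR = 1, fwhm = 0)
  expect_lt(sd(ppd[1, 1, 1, ]) / sd(dr), 0.35)
  # spatial smoothing of an impulse gives the requested width
  nn2 <- 1L
  imp <- array(0, c(41, 41, 21, nn2)); imp[21, 21, 11, 1] <- 1
  sm <- preprocessSeries(imp, TR = 1, highpassCutoff = 0, fwhm = 10,
                         voxelSize = 2.5)
  prof <- sm[, 21, 11, 1]
  half <- max(prof) / 2
  above <- which(prof >= half)
  lo <- min(above); hi <- max(above)
  xl <- lo - 1 + (half - prof[lo - 1]) / (prof[lo] - prof[lo - 1])
  xr <- hi + (prof[hi] - half) / (prof[hi] - prof[hi + 1])
  expect_lt(abs((xr - xl) * 2.5 - 10) / 10, 0.05)
})

test_that("fitGlm is calibrated under the null and exact without noise", {
  set.seed(2)
  d <- TaskDesign()
  x <- taskRegressor(d)
  n <- d@nVolumes
  # null calibration (quick version; the full 1e5-draw check is in the
  # acceptance suite)
  Y <- matrix(rnorm(n * 20000), n, 20000)
  fit <- fitGlm(Y, GLMDesign(x))
  expect_equal(mean(abs(fit$z) > 1.96), 0.05, tolerance = 0.2)
  # noise-free effect: beta recovered exactly, Z capped
  ser <- array(100, c(6, 2, 1, n))
  act <- array(c(TRUE, FALSE), c(6, 2, 1))
  for (t in seq_len(n))
    ser[, , , t] <- 100 * (1 + 0.02 * x[t] * act)
  f2 <- fitGlm(ser, GLMDesign(x))
  expect_equal(max(abs(f2$beta[act] - 2)), 0, tolerance = 1e-6)
  expect_equal(max(zValues(f2$z)), 40)
  # confound-only signal leaves the task beta at zero
  conf <- sin(seq_len(n) / 5)
  serC <- array(rep(conf, each = 4), c(2, 2, 1, n))
  fC <- fitGlm(serC, GLMDesign(x, confounds = cbind(conf)))
  expect_lt(max(abs(fC$beta)), 1e-8)
  # rank-deficient design rejected
  expect_error(GLMDesign(x, confounds = cbind(x)), "rank deficient")
})

test_that("clusterThreshold keeps only large 26-connected components", {
  z <- array(0, c(12, 12, 12))
  expect_equal(sum(clusterThreshold(StatMap(z), 2.5, 10)), 0)
  z[2:5, 2:5, 2:4] <- 4                    # 48-voxel blob
  z[9:10, 9:10, 9] <- 4                    # 4-voxel blob
  keep <- clusterThreshold(StatMap(z), 2.5, 10)
  expect_equal(sum(keep), 48)
  expect_true(all(keep[2:5, 2:5, 2:4]))
  expect_false(any(keep[9:10, 9:10, 9]))
  # diagonal contact counts as connected (26-connectivity)
  z2 <- array(0, c(6, 6, 6))
  z2[1:2, 1:2, 1:2] <- 4
  z2[3, 3, 3] <- 4
  expect_equal(sum(clusterThreshold(StatMap(z2), 2.5, 9)), 9)
})

test_that("groupMap flags degenerate input and scales with sqrt(n)", {
  m <- array(1, c(4, 4, 2))
  expect_warning(g0 <- groupMap(list(m, m, m)), "zero between-subject")
  expect_equal(sum(g0@mask), 0)
  expect_error(groupMap(list(m)), "at least 2")
  # null calibration
  set.seed(8)
  null <- replicate(20, array(rnorm(4000), c(20, 20, 10)), simplify = FALSE)
  gn <- groupMap(null)
  expect_equal(mean(abs(zValues(gn)[gn@mask]) > 1.96), 0.05, tolerance = 0.3)
  # mean Z grows roughly as sqrt(n_subjects) for a fixed effect size
  mk <- function(n) {
    set.seed(100)
    replicate(n, array(rnorm(4000, mean = 0.5), c(20, 20, 10)),
              simplify = FALSE)
  }
  z8 <- mean(zValues(groupMap(mk(8)))[array(TRUE, c(20, 20, 10))])
  z32 <- mean(zValues(groupMap(mk(32)))[array(TRUE, c(20, 20, 10))])
  expect_equal(z32 / z8, 2, tolerance = 0.25)
})

test_that("extractComponents recovers planted networks and is seeded", {
  # networks must be small relative to the brain for a recovered indicator
  # source to clear the z = 3 threshold, so use the default-size phantom
  set.seed(31)
  nets <- epiwarp:::.defaultNetworks(tpSpec, tpBrain)
  expect_gt(sum(nets[[1]]), 0); expect_gt(sum(nets[[2]]), 0)
  n <- 80L
  shape <- tpSpec@gridShape
  ts1 <- epiwarp:::.lowFreqTimecourse(n, 1)
  ts2 <- epiwarp:::.lowFreqTimecourse(n, 1)
  ser <- array(rnorm(prod(shape) * n), c(shape, n))
  for (t in seq_len(n))
    ser[, , , t] <- ser[, , , t] + 5 * ts1[t] * nets[[1]] +
      5 * ts2[t] * nets[[2]]
  comps <- extractComponents(ser, K = 2, mask = tpBrain, seed = 1)
  D <- vapply(comps, function(cm)
    c(diceCoef(thresholdComponent(cm, 3), nets[[1]]),
      diceCoef(thresholdComponent(cm, 3), nets[[2]])), numeric(2))
  expect_gt(max(D[1, ]), 0.8)
  expect_gt(max(D[2, ]), 0.8)
  # determinism
  comps2 <- extractComponents(ser, K = 2, mask = tpBrain, seed = 1)
  expect_equal(comps, comps2)
  # absent network: no component resembles an unrelated mask
  null <- array(rnorm(prod(shape) * n), c(shape, n))
  compsN <- extractComponents(null, K = 2, mask = tpBrain, seed = 1)
  DN <- vapply(compsN, function(cm)
    diceCoef(thresholdComponent(cm, 3), nets[[1]]), numeric(1))
  expect_lt(max(DN), 0.3)
  expect_error(extractComponents(ser, K = 200L, mask = tpBrain),
               "smaller than the number of time points")
})
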