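# Assessment metrics.

test_that("nmse matches hand arithmetic and its invariants", {
  expect_equal(nmse(c(1, 2), c(2, 4)), 0.4)
  expect_equal(nmse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(nmse(c(1, 2), c(0, 0)), 2)
  A <- rnorm(100); B <- rnorm(100)
  expect_equal(nmse(A, B), nmse(B, A))
  expect_error(nmse(c(0, 0), c(0, 0)), "both images are zero")
  expect_error(nmse(A, B, rep(FALSE, 100)), "empty")
})

test_that("crossCorrelation is Pearson over the mask", {
  expect_equal(crossCorrelation(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(crossCorrelation(c(1, 2, 3), c(-1, -2, -3) + 10), -1)
  expect_equal(round(crossCorrelation(c(1, 2, 3), c(1, 2, 4)), 4), 0.982)
  # invariance to affine rescaling of either image
  A <- rnorm(200); B <- rnorm(200)
  expect_equal(crossCorrelation(3 * A - 7, B), crossCorrelation(A, B))
  expect_error(crossCorrelation(rep(1, 5), rnorm(5)), "zero variance")
})

test_that("diceCoef matches the formula and its symmetries", {
  a <- c(rep(TRUE, 3), rep(FALSE, 5))
  b <- c(TRUE, TRUE, FALSE, TRUE, TRUE, TRUE, FALSE, FALSE)
  expect_equal(diceCoef(a, b), 2 * 2 / (3 + 5))
  expect_equal(diceCoef(a, a), 1)
  expect_equal(diceCoef(a, !a), 0)
  expect_equal(diceCoef(a, b), diceCoef(b, a))
  expect_warning(d0 <- diceCoef(logical(4), logical(4)), "empty")
  expect_equal(d0, 0)
})

test_that("thresholdComponent is a one-sided positive threshold", {
  z <- array(0, c(4, 4, 4))
  expect_equal(sum(thresholdComponent(z)), 0)
  expect_equal(sum(thresholdComponent(z, -Inf)), 64)
  z[c(1, 5, 9, 13, 17, 21, 25)] <- 3.5
  expect_equal(sum(thresholdComponent(z, 3.0)), 7)
  z[2] <- NA
  expect_error(thresholdComponent(z))
})

test_that("assignRSNs: worked example, dominance, edge cases", {
  D <- rbind(c(0.8, 0.7, 0), c(0.1, 0.6, 0), c(0, 0, 0.5))
  asg <- assignRSNs(D)
  expect_equal(as.integer(asg@mapping), c(1L, 2L, 3L))
  expect_equal(asg@meanDice, mean(c(0.8, 0.6, 0.5)), tolerance = 1e-12)
  # diagonal-dominant matrix -> identity mapping
  set.seed(4)
  Dd <- matrix(runif(25, 0, 0.3), 5, 5); diag(Dd) <- runif(5, 0.7, 1)
  expect_equal(as.integer(assignRSNs(Dd)@mapping), 1:5)
  # one template -> argmax of its row
  D1 <- matrix(c(0.2, 0.9, 0.4), 1, 3)
  expect_equal(as.integer(assignRSNs(D1)@mapping), 2L)
  expect_error(assignRSNs(matrix(0.5, 3, 2)), "at least as many components")
})

test_that("assignRSNs enumeration equals brute force; sampling is seeded", {
  set.seed(7)
  for (trial in 1:25) {
    nT <- sample(2:5, 1); nC <- nT + sample(0:3, 1)
    D <- matrix(runif(nT * nC), nT, nC)
    asg <- assignRSNs(D)
    # independent oracle: greedy assignment over every permutation
    best <- -Inf
    perms <- function(v) if (length(v) <= 1) list(v) else
      do.call(c, lapply(seq_along(v), function(i)
        lapply(perms(v[-i]), function(p) c(v[i], p))))
    for (ord in perms(seq_len(nT))) {
      taken <- logical(nC); map <- integer(nT)
      for (t in ord) {
        row <- D[t, ]; row[taken] <- -Inf
        map[t] <- which.max(row); taken[map[t]] <- TRUE
      }
      best <- max(best, mean(D[cbind(seq_len(nT), map)]))
    }
    expect_equal(asg@meanDice, best, tolerance = 1e-12)
  }
  # sampled regime (T! > maxOrders) is deterministic under a fixed seed
  D8 <- matrix(runif(8 * 9), 8, 9)
  a1 <- assignRSNs(D8, maxOrders = 200L, seed = 42L)
  a2 <- assignRSNs(D8, maxOrders = 200L, seed = 42L)
  expect_identical(a1@mapping, a2@mapping)
  expect_identical(a1@meanDice, a2@meanDice)
})

test_that("bbrCost reflects boundary contrast and alignment", {
  p <- tpTruth
  vs <- tpSpec@voxelSize
  # uniform image -> cost exactly 0.5
  unif <- array(5, dim(p@structural))
  expect_equal(bbrCost(unif, p@boundaryPoints, p@boundaryNormals,
                       voxelSize = vs), 0.5)
  # phantom has bright GM outside dark WM: good contrast -> cost < 0.5,
  # approaching 0 at large slope; inverted contrast -> cost > 0.5 -> near 1
  cGood <- bbrCost(p@structural, p@boundaryPoints, p@boundaryNormals,
                   voxelSize = vs)
  expect_lt(cGood, 0.5)
  cSteep <- bbrCost(p@structural, p@boundaryPoints, p@boundaryNormals,
                    slope = 50, voxelSize = vs)
  expect_lt(cSteep, 0.05)
  inv <- max(p@structural) - p@structural
  cInv <- bbrCost(inv, p@boundaryPoints, p@boundaryNormals, slope = 50,
                  voxelSize = vs)
  expect_gt(cInv, 0.95)
  # cost decreases monotonically as misalignment shrinks
  shifts <- c(7.5, 5, 2.5, 0)
  costs <- vapply(shifts, function(s) {
    vol <- applyDistortion(p@structural,
                           VoxelShiftMap(array(s, dim(p@structural))), tpGeom,
                           conserveMass = FALSE)
    bbrCost(vol, p@boundaryPoints, p@boundaryNormals, voxelSize = vs)
  }, numeric(1))
  expect_true(all(diff(costs) < 0))
  # points off the grid are excluded; mostly-outside point sets are rejected
  far <- matrix(1000, 4, 3)
  expect_error(bbrCost(p@structural, far, matrix(1 / sqrt(3), 4, 3),
                       voxelSize = vs), "outside the grid")
})

test_that("vsmRoiRange extracts extrema over the ROI", {
  cst <- VoxelShiftMap(array(3.2, c(4, 4, 4)))
  roi <- array(FALSE, c(4, 4, 4)); roi[2:3, 2:3, 2:3] <- TRUE
  expect_equal(vsmRoiRange(cst, roi), c(min = 3.2, max = 3.2))
  one <- array(FALSE, c(4, 4, 4)); one[2, 2, 2] <- TRUE
  ramp <- VoxelShiftMap(array(seq(0, 10, length.out = 64), c(4, 4, 4)))
  expect_equal(unname(vsmRoiRange(ramp, one)[1]),
               unname(vsmRoiRange(ramp, one)[2]))
  full <- array(TRUE, c(4, 4, 4))
  expect_equal(unname(vsmRoiRange(ramp, full)), c(0, 10))
  expect_error(vsmRoiRange(ramp, array(FALSE, c(4, 4, 4))), "empty")
})
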