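# Assessment metrics: nMSE, cross-correlation, Dice, randomized mutually
# exclusive template assignment, boundary-based-registration cost, and
# per-ROI shift ranges.

#' Normalized mean squared error between two images
#'
#' Symmetric normalization:
#' \deqn{nMSE = 2 \sum_M (A-B)^2 / \sum_M (A^2 + B^2).}
#' Zero iff the images agree on the mask; equals 2 when one image is zero.
#' The absolute scale of reported values depends on this normalization
#' choice, which is recorded here because the literature uses several.
#'
#' @param A,B numeric arrays of one shape.
#' @param mask logical array; defaults to all voxels.
#' @return Non-negative scalar.
#' @examples
#' nmse(c(1, 2), c(2, 4))   # 0.4
#' @export
nmse <- function(A, B, mask = NULL) {
  stopifnot(identical(dim(A), dim(B)) || length(A) == length(B))
  if (is.null(mask)) mask <- rep(TRUE, length(A))
  if (!any(mask)) stop("mask is empty")
  a <- A[mask]; b <- B[mask]
  den <- sum(a^2 + b^2)
  if (den == 0) stop("nMSE undefined: both images are zero on the mask")
  2 * sum((a - b)^2) / den
}

#' Voxel-wise cross-correlation of two images
#'
#' Pearson correlation over the masked voxels.
#'
#' @inheritParams nmse
#' @return Scalar in [-1, 1].
#' @export
crossCorrelation <- function(A, B, mask = NULL) {
  if (is.null(mask)) mask <- rep(TRUE, length(A))
  a <- A[mask]; b <- B[mask]
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("cross-correlation undefined: zero variance on the mask")
  stats::cor(a, b)
}

#' Dice overlap coefficient of two binary masks
#'
#' \eqn{2|A \cap B| / (|A| + |B|)}; two empty masks give 0 by convention,
#' with a warning.
#'
#' @param maskA,maskB logical arrays of one shape.
#' @return Scalar in [0, 1].
#' @export
diceCoef <- function(maskA, maskB) {
  stopifnot(identical(dim(maskA), dim(maskB)) || length(maskA) == length(maskB))
  sA <- sum(maskA); sB <- sum(maskB)
  if (sA + sB == 0) {
    warning("both masks empty; Dice defined as 0")
    return(0)
  }
  2 * sum(maskA & maskB) / (sA + sB)
}

#' Threshold a component z map
#'
#' One-sided threshold on positive loadings: \code{z > zThresh}.
#'
#' @param zMap numeric array (or \linkS4class{StatMap}).
#' @param zThresh threshold (default 3.0, the usual IC-map threshold).
#' @return Logical mask.
#' @export
thresholdComponent <- function(zMap, zThresh = 3.0) {
  z <- if (is(zMap, "StatMap")) zValues(zMap) else zMap
  stopifnot(all(is.finite(z)))
  z > zThresh
}

#' Mutually exclusive assignment of components to network templates
#'
#' For a templates x components Dice matrix, templates are assigned greedily
#' in a given order, each taking the unassigned component with the highest
#' Dice (ties broken toward the lowest component index). The template order
#' is randomized: when \eqn{T! \le maxOrders} all permutations are
#' enumerated (deterministic); otherwise \code{maxOrders} random
#' permutations are sampled under the seed. The order with the highest mean
#' Dice across templates wins.
#'
#' @param D numeric matrix, rows = templates, columns = components, entries
#'   in [0, 1]. Row/column names are carried into the result.
#' @param maxOrders maximum number of template orders considered.
#' @param seed RNG seed for the sampled regime.
#' @return An \linkS4class{RSNAssignment}.
#' @examples
#' D <- rbind(c(0.8, 0.7, 0), c(0.1, 0.6, 0), c(0, 0, 0.5))
#' assignRSNs(D)   # T1->C1, T2->C2, T3->C3, mean 0.6333
#' @export
assignRSNs <- function(D, maxOrders = 10000L, seed = 1L) {
  D <- as.matrix(D)
  nT <- nrow(D); nC <- ncol(D)
  if (nC < nT) stop("need at least as many components as templates")
  stopifnot(all(D >= 0 & D <= 1))
  greedy <- function(ord) {
    taken <- logical(nC)
    map <- integer(nT)
    for (t in ord) {
      row <- D[t, ]
      row[taken] <- -Inf
      pick <- which.max(row)               # lowest index on ties
      map[t] <- pick
      taken[pick] <- TRUE
    }
    map
  }
  orders <- if (factorial(nT) <= maxOrders) {
    .permutations(nT)
  } else {
    set.seed(seed)
    unique(t(vapply(seq_len(maxOrders), function(i) sample.int(nT),
                    integer(nT))))
  }
  best <- NULL; bestDice <- -Inf; bestOrd <- NULL
  for (i in seq_len(nrow(orders))) {
    map <- greedy(orders[i, ])
    md <- mean(D[cbind(seq_len(nT), map)])
    if (md > bestDice + 1e-12) {
      bestDice <- md; best <- map; bestOrd <- orders[i, ]
    }
  }
  names(best) <- rownames(D)
  new("RSNAssignment", mapping = as.integer(best), meanDice = bestDice,
      orderUsed = as.integer(bestOrd))
}

# All permutations of 1..n as rows (n small).
.permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- .permutations(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  r <- 1L
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    for (j in seq_len(nrow(sub))) {
      out[r, ] <- c(k, rest[sub[j, ]])
      r <- r + 1L
    }
  }
  out
}

#' Boundary-based registration cost of a volume
#'
#' For each white-matter boundary point, intensities are sampled (trilinear)
#' at \code{offset} mm inside and outside the surface along its unit normal;
#' the percent contrast \eqn{Q = 100 (I_{out} - I_{in}) /
#' (0.5(|I_{out}| + |I_{in}|) + \epsilon)} is soft-clipped to a cost in
#' [0, 1] via \eqn{(1 + \tanh(-s Q / 100)) / 2} and averaged. Lower cost
#' means better WM-inside / GM-outside contrast, i.e. better alignment.
#' Points whose samples fall outside the grid are excluded; if more than
#' half are lost, the call errors.
#'
#' @param volume 3-D intensity array.
#' @param boundaryPoints n x 3 voxel coordinates of WM surface points.
#' @param normals n x 3 outward unit normals (mm space).
#' @param offset sampling offset in mm on each side of the boundary.
#' @param slope soft-clipping slope of the tanh.
#' @param voxelSize mm per voxel (length 1 or 3).
#' @return Scalar cost in [0, 1]; 0.5 for a contrast-free image.
#' @export
bbrCost <- function(volume, boundaryPoints, normals, offset = 2, slope = 0.5,
                    voxelSize = 2.5) {
  stopifnot(nrow(boundaryPoints) == nrow(normals))
  voxelSize <- rep(voxelSize, length.out = 3)
  stepVox <- sweep(normals * offset, 2, voxelSize, "/")
  pIn <- boundaryPoints - stepVox
  pOut <- boundaryPoints + stepVox
  iIn <- .trilinear(volume, pIn)
  iOut <- .trilinear(volume, pOut)
  ok <- is.finite(iIn) & is.finite(iOut)
  if (sum(ok) < nrow(boundaryPoints) / 2)
    stop(sprintf("more than half of the boundary samples (%d of %d) fall outside the grid",
                 sum(!ok), nrow(boundaryPoints)))
  eps <- 1e-6
  Q <- 100 * (iOut[ok] - iIn[ok]) / (0.5 * (abs(iOut[ok]) + abs(iIn[ok])) + eps)
  mean((1 + tanh(-slope * Q / 100)) / 2)
}

#' Shift range within a region of interest
#'
#' Minimum and maximum voxel shift (mm) of a \linkS4class{VoxelShiftMap}
#' over a region, as used to report how strongly each network or activation
#' map is affected by distortions.
#'
#' @param vsm a \linkS4class{VoxelShiftMap}.
#' @param roi logical array, nonempty.
#' @return Named numeric: \code{min}, \code{max} (mm).
#' @export
vsmRoiRange <- function(vsm, roi) {
  stopifnot(is(vsm, "VoxelShiftMap"))
  if (!any(roi)) stop("roi is empty")
  v <- mapValues(vsm)[roi]
  c(min = min(v), max = max(v))
}
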