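# Desk-scale fMRI analyses: high-pass + smoothing preprocessing, block-design
# GLM with the canonical double-gamma HRF, cluster thresholding, and a
# one-sample group statistic.

#' Canonical double-gamma hemodynamic response function
#'
#' Difference of two gamma densities with the canonical parameters (response
#' peak at ~5-6 s, undershoot at ~15-16 s, undershoot ratio 1:6), sampled at
#' the TR over \code{duration} seconds and normalized to unit peak.
#'
#' @param TR sampling interval (s).
#' @param duration kernel length (s).
#' @return Numeric kernel sampled at \code{seq(0, duration, by = TR)}.
#' @examples
#' h <- doubleGammaHrf(0.5)
#' (which.max(h) - 1) * 0.5   # peak time, ~5 s
#' @export
doubleGammaHrf <- function(TR, duration = 32) {
  stopifnot(TR > 0)
  t <- seq(0, duration, by = TR)
  a1 <- 6; b1 <- 1; a2 <- 16; b2 <- 1; ratio <- 1 / 6
  h <- stats::dgamma(t, shape = a1, rate = b1) -
       ratio * stats::dgamma(t, shape = a2, rate = b2)
  h / max(h)
}

#' Preprocess a 4-D BOLD series
#'
#' Discrete-cosine high-pass temporal filtering (the mean and all DCT basis
#' functions with period longer than \code{highpassCutoff} are regressed out)
#' followed by Gaussian spatial smoothing of each volume.
#'
#' @param series 4-D array (x, y, z, time).
#' @param TR repetition time (s).
#' @param highpassCutoff cut-off period (s); drifts slower than this are
#'   removed. 0 disables temporal filtering.
#' @param fwhm spatial smoothing kernel FWHM (mm); 0 disables smoothing.
#' @param voxelSize mm per voxel (length 1 or 3).
#' @return Filtered 4-D array.
#' @export
preprocessSeries <- function(series, TR = 1, highpassCutoff = 100, fwhm = 4,
                             voxelSize = 2.5) {
  stopifnot(length(dim(series)) == 4L)
  d <- dim(series)
  n <- d[4]
  voxelSize <- rep(voxelSize, length.out = 3)
  Y <- t(matrix(series, ncol = n))           # time x voxels
  if (highpassCutoff > 0) {
    K <- floor(2 * n * TR / highpassCutoff)
    t_i <- seq_len(n) - 0.5
    X <- cbind(rep(1, n), if (K >= 1)
      vapply(seq_len(K), function(k) cos(pi * k * t_i / n), numeric(n)))
    Y <- Y - X %*% qr.coef(qr(X), Y)
  }
  out <- array(Y, c(n, d[1:3]))
  out <- aperm(out, c(2, 3, 4, 1))
  if (fwhm > 0) {
    for (t in seq_len(n))
      out[, , , t] <- .gaussSmooth3d(out[, , , t], fwhm, voxelSize)
  }
  out
}

#' GLM design for a block run
#'
#' One HRF-convolved task regressor plus optional confound columns; an
#' intercept is always added at fit time.
#'
#' @slot regressor numeric vector, one value per time point.
#' @slot confounds numeric matrix (possibly 0 columns), same number of rows.
#' @slot TR repetition time (s).
#' @name GLMDesign-class
#' @exportClass GLMDesign
setClass("GLMDesign",
  representation(regressor = "numeric", confounds = "matrix", TR = "numeric"))

setValidity("GLMDesign", function(object) {
  msg <- character()
  if (ncol(object@confounds) && nrow(object@confounds) != length(object@regressor))
    msg <- c(msg, "confounds must have one row per time point")
  X <- cbind(1, object@regressor, object@confounds)
  if (qr(X)$rank < ncol(X)) msg <- c(msg, "design matrix is rank deficient")
  if (length(msg)) msg else TRUE
})

#' @param regressor HRF-convolved task regressor.
#' @param confounds optional confound matrix.
#' @param TR repetition time (s).
#' @return A \linkS4class{GLMDesign}.
#' @rdname GLMDesign-class
#' @export
GLMDesign <- function(regressor, confounds = NULL, TR = 1) {
  if (is.null(confounds))
    confounds <- matrix(numeric(0), nrow = length(regressor), ncol = 0)
  new("GLMDesign", regressor = regressor, confounds = confounds, TR = TR)
}

# t -> Z through tail log-probabilities (stable far into the tails).
.tToZ <- function(t, df, cap = 40) {
  z <- suppressWarnings(ifelse(t >= 0,
    stats::qnorm(stats::pt(t, df, lower.tail = FALSE, log.p = TRUE),
                 lower.tail = FALSE, log.p = TRUE),
    -stats::qnorm(stats::pt(-t, df, lower.tail = FALSE, log.p = TRUE),
                  lower.tail = FALSE, log.p = TRUE)))
  pmin(pmax(z, -cap), cap)
}

#' Fit a voxel-wise GLM
#'
#' Ordinary least squares of each voxel's time series on
#' \code{[1, regressor, confounds]}; the task effect is reported as
#' \eqn{t = \beta / SE(\beta)} converted to a Z score through the exact
#' normal-quantile transform of the t CDF (capped at |Z| = 40).
#'
#' @param series 4-D array or a time x voxels matrix.
#' @param design a \linkS4class{GLMDesign}.
#' @param mask optional logical grid restricting the fit.
#' @return A list with \code{z} (\linkS4class{StatMap}), \code{beta} (effect
#'   array, same grid) and \code{df}.
#' @export
fitGlm <- function(series, design, mask = NULL) {
  stopifnot(is(design, "GLMDesign"))
  isArr <- length(dim(series)) == 4L
  if (isArr) {
    d3 <- dim(series)[1:3]
    n <- dim(series)[4]
    if (is.null(mask)) mask <- array(TRUE, d3)
    Y <- t(matrix(series, ncol = n))[, as.vector(mask), drop = FALSE]
  } else {
    n <- nrow(series)
    Y <- series
  }
  if (n != length(design@regressor)) stop("series/design length mismatch")
  X <- cbind(1, design@regressor, design@confounds)
  p <- ncol(X)
  df <- n - p
  qrX <- qr(X)
  if (qrX$rank < p) stop("design matrix is rank deficient")
  coef <- qr.coef(qrX, Y)
  res <- Y - X %*% coef
  sigma2 <- colSums(res^2) / df
  XtXinv <- chol2inv(qr.R(qrX))
  se <- sqrt(pmax(sigma2 * XtXinv[2, 2], .Machine$double.xmin))
  tstat <- coef[2, ] / se
  z <- .tToZ(tstat, df)
  if (isArr) {
    zArr <- array(0, d3); zArr[mask] <- z
    bArr <- array(0, d3); bArr[mask] <- coef[2, ]
    list(z = StatMap(zArr, df = df, mask = mask), beta = bArr, df = df)
  } else {
    list(z = z, beta = coef[2, ], df = df)
  }
}

#' Cluster-extent thresholding of a Z map
#'
#' Retains 26-connected components of the suprathreshold set
#' \eqn{\{Z > z_{thresh}\}} (one-sided, positive loadings) with at least
#' \code{minExtent} voxels. A fixed extent threshold stands in for
#' random-field cluster p-values.
#'
#' @param zmap a \linkS4class{StatMap} or numeric 3-D array.
#' @param zThresh voxel-level threshold.
#' @param minExtent minimum cluster size in voxels.
#' @return Logical activation mask.
#' @export
clusterThreshold <- function(zmap, zThresh = 2.5, minExtent = 10) {
  z <- if (is(zmap, "StatMap")) zValues(zmap) else zmap
  supra <- z > zThresh
  if (!any(supra)) return(array(FALSE, dim(z)))
  lab <- .connComp26(supra)
  sizes <- tabulate(lab[supra])
  keep <- which(sizes >= minExtent)
  array(lab %in% keep & supra, dim(z))
}

# 26-connected component labelling by vectorized max-label propagation:
# every suprathreshold voxel starts with a unique label and repeatedly takes
# the maximum label over its in-mask 26-neighbourhood until a fixpoint.
# Labels are then renumbered consecutively.
.connComp26 <- function(mask) {
  d <- dim(mask)
  lab <- array(0, d)
  if (!any(mask)) return(lab)
  lab[mask] <- seq_len(sum(mask))
  shift3 <- function(a, off) {
    for (ax in 1:3) {
      if (off[ax] == 0) next
      al <- .alongAxis(a, ax)
      n <- nrow(al$mat)
      idx <- seq_len(n) + off[ax]
      pad <- matrix(0, sum(idx < 1 | idx > n), ncol(al$mat))
      core <- al$mat[idx[idx >= 1 & idx <= n], , drop = FALSE]
      a <- al$restore(if (off[ax] > 0) rbind(core, pad) else rbind(pad, core))
    }
    a
  }
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(offs != 0) > 0, , drop = FALSE]
  repeat {
    new <- lab
    for (k in seq_len(nrow(offs))) new <- pmax(new, shift3(lab, offs[k, ]))
    new[!mask] <- 0
    if (identical(new, lab)) break
    lab <- new
  }
  out <- array(0L, d)
  out[mask] <- as.integer(match(lab[mask], sort(unique(lab[mask]))))
  out
}

#' Group activation map from subject effect maps
#'
#' Fixed-effects within-subject averaging is assumed done upstream; across
#' subjects a one-sample t statistic of the effect maps is computed per voxel
#' and converted to Z (a stand-in for a mixed-effects group stage). Voxels
#' with zero between-subject variance are flagged NA with a warning.
#'
#' @param effectMaps list of per-subject effect arrays (same grid).
#' @param mask optional logical analysis mask.
#' @return A \linkS4class{StatMap} with \code{df = n_subjects - 1}.
#' @export
groupMap <- function(effectMaps, mask = NULL) {
  n <- length(effectMaps)
  if (n < 2L) stop("need at least 2 subjects")
  d <- dim(effectMaps[[1]])
  if (is.null(mask)) mask <- array(TRUE, d)
  M <- vapply(effectMaps, function(m) m[mask], numeric(sum(mask)))
  mu <- rowMeans(M)
  s <- apply(M, 1, stats::sd)
  degenerate <- s < .Machine$double.eps^0.5
  if (any(degenerate))
    warning(sprintf("%d voxels have zero between-subject variance; Z set to NA",
                    sum(degenerate)))
  tstat <- mu / (s / sqrt(n))
  z <- .tToZ(tstat, n - 1)
  z[degenerate] <- NA_real_
  zArr <- array(NA_real_, d)
  zArr[mask] <- z
  okMask <- mask & is.finite(zArr)
  zArr[!okMask] <- 0
  StatMap(zArr, df = n - 1, mask = okMask)
}
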