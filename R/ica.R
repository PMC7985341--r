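# Group spatial ICA: temporal concatenation, variance normalization, PCA
# whitening, FastICA (tanh contrast, symmetric decorrelation), z-scored
# spatial maps with skewness-fixed sign.

#' Extract spatial independent components from one or more runs
#'
#' Runs are converted to time x voxel matrices within the mask, each voxel's
#' time series is demeaned and variance-normalized, and all runs are
#' temporally concatenated. The concatenated data are whitened to \code{K}
#' principal components and rotated by FastICA with the tanh contrast and
#' symmetric decorrelation. Each spatial source is z-scored and its sign
#' fixed so that its skewness is non-negative (activations load positively).
#'
#' @param runs a 4-D array or a list of 4-D arrays (same grid).
#' @param K number of components; must be smaller than the total number of
#'   time points.
#' @param mask logical analysis grid; default: voxels with nonzero variance.
#' @param seed RNG seed for the FastICA initialization (deterministic result
#'   under a fixed seed).
#' @param maxIter,tol FastICA iteration controls.
#' @return List of \code{K} z-scored component maps (3-D arrays, zero outside
#'   the mask), ordered by explained variance of the whitening stage.
#' @export
extractComponents <- function(runs, K, mask = NULL, seed = 1L,
                              maxIter = 200L, tol = 1e-6) {
  if (!is.list(runs)) runs <- list(runs)
  d3 <- dim(runs[[1]])[1:3]
  mats <- lapply(runs, function(r) {
    stopifnot(identical(dim(r)[1:3], d3))
    t(matrix(r, ncol = dim(r)[4]))
  })
  X <- do.call(rbind, mats)                    # total time x all voxels
  if (is.null(mask)) {
    v <- apply(X, 2, stats::var)
    mask <- array(v > .Machine$double.eps, d3)
  }
  X <- X[, as.vector(mask), drop = FALSE]
  nT <- nrow(X)
  if (K >= nT) stop("K must be smaller than the number of time points")
  X <- sweep(X, 2, colMeans(X))
  sds <- sqrt(colSums(X^2) / (nT - 1))
  sds[sds < .Machine$double.eps] <- 1
  X <- sweep(X, 2, sds, "/")

  sv <- svd(X, nu = K, nv = 0)                 # X = U D V'
  # whitened spatial sources: rows of Z are uncorrelated, unit variance
  Z <- crossprod(sv$u, X) / sv$d[seq_len(K)] * sqrt(ncol(X))

  set.seed(seed)
  W <- matrix(stats::rnorm(K * K), K, K)
  sym <- function(W) {
    e <- eigen(W %*% t(W), symmetric = TRUE)
    e$vectors %*% diag(1 / sqrt(pmax(e$values, 1e-12)), K) %*%
      t(e$vectors) %*% W
  }
  W <- sym(W)
  nV <- ncol(Z)
  for (it in seq_len(maxIter)) {
    WX <- W %*% Z
    G <- tanh(WX)
    Gp <- rowMeans(1 - G^2)
    Wnew <- sym(G %*% t(Z) / nV - diag(Gp, K) %*% W)
    delta <- max(abs(1 - abs(rowSums(Wnew * W))))
    W <- Wnew
    if (delta < tol) break
  }
  S <- W %*% Z
  lapply(seq_len(K), function(k) {
    s <- S[k, ]
    s <- (s - mean(s)) / stats::sd(s)
    if (mean(s^3) < 0) s <- -s
    out <- array(0, d3)
    out[mask] <- s
    out
  })
}
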