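# Internal numerical helpers shared across modules.

# Permute an array so that axis `axis` comes first and flatten the rest,
# returning the matrix plus a closure that restores the original layout.
.alongAxis <- function(arr, axis) {
  d <- dim(arr)
  if (is.null(d)) d <- length(arr)
  nd <- length(d)
  stopifnot(axis >= 1L, axis <= nd)
  perm <- c(axis, setdiff(seq_len(nd), axis))
  m <- matrix(aperm(arr, perm), nrow = d[axis])
  restore <- function(mat) {
    a <- array(mat, dim = d[perm])
    aperm(a, order(perm))
  }
  list(mat = m, restore = restore)
}

# Columnwise linear interpolation: values V (n x m) on grid 1..n, sampled at
# positions P (k x m); out-of-range samples read as `fill` (zero background).
.colInterp <- function(V, P, fill = 0) {
  n <- nrow(V)
  m <- ncol(V)
  lo <- floor(P)
  w <- P - lo
  inside <- lo >= 1 & lo <= n - 1
  atEnd <- P == n            # exact upper end is valid
  lo[!inside] <- 1L
  colOff <- matrix(rep((seq_len(m) - 1L) * n, each = nrow(P)), nrow = nrow(P))
  idx <- lo + colOff
  out <- (1 - w) * V[idx] + w * V[pmin(idx + 1L, n * m)]
  out[!inside] <- fill
  out[atEnd] <- V[matrix(n + colOff, nrow = nrow(P))[atEnd]]
  out
}

# Columnwise linear interpolation with per-column non-uniform, strictly
# increasing abscissae X (n x m); queried at positions Q (k x m).
# rule = 1 -> NA outside, rule = 2 -> clamp to end values.
.colInterpNonuniform <- function(X, Y, Q, rule = 1) {
  k <- nrow(Q)
  m <- ncol(Q)
  out <- matrix(NA_real_, k, m)
  for (j in seq_len(m)) {
    out[, j] <- stats::approx(X[, j], Y[, j], xout = Q[, j],
                              rule = rule, ties = "ordered")$y
  }
  out
}

# 1-D Gaussian kernel matrix (n x n) for smoothing along one axis.
.gaussKernelMat <- function(n, fwhm_mm, voxel_mm) {
  if (fwhm_mm <= 0) return(diag(n))
  sigma <- fwhm_mm / (2 * sqrt(2 * log(2))) / voxel_mm   # in voxels
  d <- abs(outer(seq_len(n), seq_len(n), "-"))
  K <- exp(-0.5 * (d / sigma)^2)
  K[d > ceiling(6 * sigma)] <- 0
  K / rowSums(K)            # renormalized at edges
}

# Separable Gaussian smoothing of a 3-D array; voxel_mm is length-3.
.gaussSmooth3d <- function(arr, fwhm_mm, voxel_mm) {
  if (fwhm_mm <= 0) return(arr)
  for (ax in 1:3) {
    K <- .gaussKernelMat(dim(arr)[ax], fwhm_mm, voxel_mm[ax])
    a <- .alongAxis(arr, ax)
    arr <- a$restore(K %*% a$mat)
  }
  arr
}

# Mask-renormalized smoothing: smooth(x*m)/smooth(m) inside the mask.
.gaussSmoothMasked <- function(arr, mask, fwhm_mm, voxel_mm) {
  if (fwhm_mm <= 0) return(arr)
  num <- .gaussSmooth3d(arr * mask, fwhm_mm, voxel_mm)
  den <- .gaussSmooth3d(mask * 1, fwhm_mm, voxel_mm)
  out <- arr
  inside <- mask & den > .Machine$double.eps
  out[inside] <- num[inside] / den[inside]
  out
}

# Extend masked values outward by repeated nearest-neighbour averaging so a
# field estimated inside the brain decays smoothly instead of cliff-dropping
# to zero at the mask edge (which would make the warp non-invertible there).
.extendOutsideMask <- function(vals, mask) {
  out <- vals
  out[!mask] <- 0
  known <- mask
  d <- dim(vals)
  shift1 <- function(a, ax, by) {
    al <- .alongAxis(a, ax)
    n <- nrow(al$mat)
    idx <- seq_len(n) + by
    pad <- matrix(0, sum(idx < 1 | idx > n), ncol(al$mat))
    core <- al$mat[idx[idx >= 1 & idx <= n], , drop = FALSE]
    al$restore(if (by > 0) rbind(core, pad) else rbind(pad, core))
  }
  repeat {
    s <- array(0, d); cnt <- array(0, d)
    for (ax in 1:3) for (by in c(-1L, 1L)) {
      s <- s + shift1(out * known, ax, by)
      cnt <- cnt + shift1(known * 1, ax, by)
    }
    newly <- !known & cnt > 0
    if (!any(newly)) break
    out[newly] <- s[newly] / cnt[newly]
    known <- known | newly
  }
  out
}

# Largest 6-connected component of a logical mask, found by vectorized label
# propagation (each voxel takes the max label among itself and its in-mask
# neighbours until convergence).
.largestComponent <- function(mask) {
  d <- dim(mask)
  lab <- array(0, d)
  lab[mask] <- seq_len(sum(mask))
  shiftp <- function(a, ax, by) {
    al <- .alongAxis(a, ax)
    n <- nrow(al$mat)
    idx <- seq_len(n) + by
    pad <- matrix(0, sum(idx < 1 | idx > n), ncol(al$mat))
    core <- al$mat[idx[idx >= 1 & idx <= n], , drop = FALSE]
    al$restore(if (by > 0) rbind(core, pad) else rbind(pad, core))
  }
  repeat {
    new <- lab
    for (ax in 1:3) for (by in c(-1L, 1L)) new <- pmax(new, shiftp(lab, ax, by))
    new[!mask] <- 0
    if (identical(new, lab)) break
    lab <- new
  }
  ids <- lab[mask]
  winner <- as.numeric(names(which.max(table(ids))))
  mask & lab == winner
}

# Limit the along-PE slope of out-of-mask values to +/- maxSlope (voxel
# units) while leaving in-mask values untouched: each line's outside voxels
# are clamped into the Lipschitz envelope of the in-mask anchors. Keeps the
# warp invertible outside the brain without touching the estimate inside.
.limitSlopeOutsideMask <- function(vals, mask, peAxis, voxPerUnit, maxSlope = 0.8) {
  a <- .alongAxis(vals * voxPerUnit, peAxis)
  m <- .alongAxis(mask, peAxis)
  v <- a$mat
  anchor <- m$mat > 0
  n <- nrow(v)
  lo <- ifelse(anchor, v, -Inf)
  up <- ifelse(anchor, v, Inf)
  for (i in 2:n) {
    lo[i, ] <- pmax(lo[i, ], lo[i - 1, ] - maxSlope)
    up[i, ] <- pmin(up[i, ], up[i - 1, ] + maxSlope)
  }
  for (i in (n - 1):1) {
    lo[i, ] <- pmax(lo[i, ], lo[i + 1, ] - maxSlope)
    up[i, ] <- pmin(up[i, ], up[i + 1, ] + maxSlope)
  }
  conflict <- lo > up            # cannot happen if the in-mask field is smooth
  mid <- (lo[conflict] + up[conflict]) / 2
  lo[conflict] <- mid
  up[conflict] <- mid
  out <- pmin(pmax(v, lo), up)
  out[anchor] <- v[anchor]
  # anchor-free stretches (e.g. lines missing the head) still need the
  # Lipschitz property: alternate forward/backward clamp passes to a fixpoint
  for (pass in 1:100) {
    prev <- out
    for (i in 2:n) {
      free <- !anchor[i, ]
      out[i, free] <- pmin(pmax(out[i, free], out[i - 1, free] - maxSlope),
                           out[i - 1, free] + maxSlope)
    }
    for (i in (n - 1):1) {
      free <- !anchor[i, ]
      out[i, free] <- pmin(pmax(out[i, free], out[i + 1, free] - maxSlope),
                           out[i + 1, free] + maxSlope)
    }
    if (max(abs(out - prev)) < 1e-12) break
  }
  a$restore(out) / voxPerUnit
}

# Replace in-mask voxels that deviate from their local (3x3x3, in-mask)
# median by more than `thresh` with that median. Catches isolated 2*pi
# unwrap failures at low-SNR voxels before the field is smoothed.
.despikeField <- function(vals, mask, thresh) {
  d <- dim(vals)
  idx <- which(mask)
  co <- which(mask, arr.ind = TRUE)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  nb <- matrix(NA_real_, length(idx), nrow(offs))
  for (k in seq_len(nrow(offs))) {
    p <- sweep(co, 2, offs[k, ], "+")
    ok <- p[, 1] >= 1 & p[, 1] <= d[1] & p[, 2] >= 1 & p[, 2] <= d[2] &
          p[, 3] >= 1 & p[, 3] <= d[3]
    pi_ <- p[ok, , drop = FALSE]
    v <- rep(NA_real_, length(idx))
    inm <- mask[pi_]
    vv <- vals[pi_]
    vv[!inm] <- NA_real_
    v[ok] <- vv
    nb[, k] <- v
  }
  med <- apply(nb, 1, stats::median, na.rm = TRUE)
  out <- vals
  spike <- abs(vals[idx] - med) > thresh
  out[idx[spike]] <- med[spike]
  out
}

# Wrap phase into (-pi, pi].
.wrapToPi <- function(x) {
  w <- ((x + pi) %% (2 * pi)) - pi
  w[w == -pi] <- pi
  w
}

# Otsu threshold on a numeric vector (used for magnitude-based brain masks).
.otsu <- function(x, nbins = 256) {
  x <- x[is.finite(x)]
  h <- hist(x, breaks = seq(min(x), max(x), length.out = nbins + 1), plot = FALSE)
  p <- h$counts / sum(h$counts)
  mids <- h$mids
  omega <- cumsum(p)
  mu <- cumsum(p * mids)
  muT <- mu[length(mu)]
  sigmaB <- (muT * omega - mu)^2 / (omega * (1 - omega))
  sigmaB[!is.finite(sigmaB)] <- 0
  mids[which.max(sigmaB)]
}

# Trilinear sampling of a 3-D array at fractional voxel coordinates
# (rows of `pts`, 1-based). Out-of-grid points return NA.
.trilinear <- function(arr, pts) {
  d <- dim(arr)
  p0 <- floor(pts)
  f <- pts - p0
  ok <- p0[, 1] >= 1 & p0[, 1] <= d[1] - 1 &
        p0[, 2] >= 1 & p0[, 2] <= d[2] - 1 &
        p0[, 3] >= 1 & p0[, 3] <= d[3] - 1
  out <- rep(NA_real_, nrow(pts))
  if (!any(ok)) return(out)
  p0 <- p0[ok, , drop = FALSE]
  f <- f[ok, , drop = FALSE]
  acc <- 0
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    w <- (ifelse(dx == 1, f[, 1], 1 - f[, 1]) *
          ifelse(dy == 1, f[, 2], 1 - f[, 2]) *
          ifelse(dz == 1, f[, 3], 1 - f[, 3]))
    acc <- acc + w * arr[cbind(p0[, 1] + dx, p0[, 2] + dy, p0[, 3] + dz)]
  }
  out[ok] <- acc
  out
}
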