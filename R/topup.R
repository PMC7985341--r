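# Reversed phase-encoding (blip-up/blip-down) displacement estimation:
# a regularized Gauss-Newton fit of a coarse spline field, restricted to the
# PE direction, under the midway assumption.

#' Parameters of the reversed-PE field estimator
#'
#' @slot pyramidFwhm Gaussian pre-smoothing FWHM (mm) per pyramid level,
#'   coarse to fine.
#' @slot lambda bending-energy regularization weight; \code{NA} selects
#'   \code{0.1 * dataterm(0) / sum(diag(L))} automatically (L the bending
#'   penalty matrix).
#' @slot maxIter Gauss-Newton iterations per level.
#' @slot tol relative objective decrease below which a level stops.
#' @slot knotSpacing knot spacing of the displacement field, mm; either one
#'   value or one per pyramid level (coarse to fine), in which case the field
#'   is prolongated onto the finer knot grid between levels.
#' @name TopupParams-class
#' @exportClass TopupParams
setClass("TopupParams",
  representation(pyramidFwhm = "numeric", lambda = "numeric",
                 maxIter = "integer", tol = "numeric", knotSpacing = "numeric"))

setValidity("TopupParams", function(object) {
  msg <- character()
  if (any(object@pyramidFwhm < 0)) msg <- c(msg, "pyramidFwhm must be >= 0")
  if (is.unsorted(rev(object@pyramidFwhm)))
    msg <- c(msg, "pyramid levels must go coarse to fine")
  if (object@maxIter < 1L) msg <- c(msg, "maxIter must be >= 1")
  if (object@tol <= 0) msg <- c(msg, "tol must be > 0")
  if (any(object@knotSpacing <= 0)) msg <- c(msg, "knotSpacing must be > 0")
  if (length(object@knotSpacing) > 1 && is.unsorted(rev(object@knotSpacing)))
    msg <- c(msg, "knotSpacing levels must go coarse to fine")
  if (length(msg)) msg else TRUE
})

#' @param pyramidFwhm smoothing per level (mm), coarse to fine.
#' @param lambda regularization weight (NA = automatic).
#' @param maxIter iterations per level.
#' @param tol relative objective tolerance.
#' @param knotSpacing field knot spacing (mm).
#' @return A \linkS4class{TopupParams}.
#' @rdname TopupParams-class
#' @export
TopupParams <- function(pyramidFwhm = c(8, 4, 2), lambda = NA_real_,
                        maxIter = 10L, tol = 1e-4, knotSpacing = 15) {
  new("TopupParams", pyramidFwhm = pyramidFwhm, lambda = lambda,
      maxIter = as.integer(maxIter), tol = tol, knotSpacing = knotSpacing)
}

setMethod("show", "TopupParams", function(object) {
  cat("TopupParams: pyramid", paste(object@pyramidFwhm, collapse = "/"),
      "mm,", object@maxIter, "iter/level, knots every",
      paste(object@knotSpacing, collapse = "/"),
      "mm, lambda",
      if (is.na(object@lambda)) "auto" else object@lambda, "\n")
})

# Trilinear interpolation matrix from a coarse knot grid to the full grid,
# plus its spatial derivative along the PE axis (per voxel), needed for the
# Jacobian term of the data-term gradient.
.knotBasis <- function(shape, voxelSize, spacing_mm, peAxis = 2L) {
  sp <- pmax(1, round(spacing_mm / voxelSize))
  knots <- lapply(1:3, function(a) {
    k <- unique(c(seq(1, shape[a], by = sp[a]), shape[a]))
    if (length(k) < 2) k <- c(1, shape[a])
    k
  })
  nk <- vapply(knots, length, integer(1))
  # per-axis hat weights of each voxel onto its two bracketing knots,
  # and their derivative with respect to voxel position
  axw <- lapply(1:3, function(a) {
    pos <- seq_len(shape[a])
    i <- findInterval(pos, knots[[a]], rightmost.closed = TRUE)
    i <- pmin(i, nk[a] - 1L)
    gap <- knots[[a]][i + 1L] - knots[[a]][i]
    w <- (pos - knots[[a]][i]) / gap
    cbind(i0 = i, w = w, dw = 1 / gap)
  })
  nvox <- prod(shape)
  vox <- arrayInd(seq_len(nvox), shape)
  ii <- rep(seq_len(nvox), times = 8)
  jj <- integer(nvox * 8)
  xx <- numeric(nvox * 8)
  dd <- numeric(nvox * 8)
  slot <- 1L
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    up <- c(dx, dy, dz)
    kidx <- lapply(1:3, function(a) axw[[a]][vox[, a], "i0"] + up[a])
    wts <- lapply(1:3, function(a) {
      w <- axw[[a]][vox[, a], "w"]
      if (up[a] == 1) w else 1 - w
    })
    dwts <- lapply(1:3, function(a) {
      if (a != peAxis) return(wts[[a]])
      s <- axw[[a]][vox[, a], "dw"]
      if (up[a] == 1) s else -s
    })
    rng <- ((slot - 1L) * nvox + 1L):(slot * nvox)
    jj[rng] <- kidx[[1]] + nk[1] * (kidx[[2]] - 1L + nk[2] * (kidx[[3]] - 1L))
    xx[rng] <- wts[[1]] * wts[[2]] * wts[[3]]
    dd[rng] <- dwts[[1]] * dwts[[2]] * dwts[[3]]
    slot <- slot + 1L
  }
  B <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(nvox, prod(nk)))
  Bp <- Matrix::sparseMatrix(i = ii, j = jj, x = dd, dims = c(nvox, prod(nk)))
  list(B = B, Bp = Bp, nk = nk, knots = knots)
}

# Bending-energy penalty: squared second differences of the knot coefficients
# along each knot-grid axis.
.bendingPenalty <- function(nk) {
  n <- prod(nk)
  idx <- array(seq_len(n), nk)
  mats <- list()
  for (a in 1:3) {
    if (nk[a] < 3) next
    perm <- c(a, setdiff(1:3, a))
    id <- matrix(aperm(idx, perm), nrow = nk[a])
    m <- nk[a]
    rows <- integer(0); cols <- integer(0); vals <- numeric(0)
    for (j in seq_len(ncol(id))) {
      r <- seq_len(m - 2) + (j - 1) * (m - 2)
      rows <- c(rows, r, r, r)
      cols <- c(cols, id[1:(m - 2), j], id[2:(m - 1), j], id[3:m, j])
      vals <- c(vals, rep(1, m - 2), rep(-2, m - 2), rep(1, m - 2))
    }
    D <- Matrix::sparseMatrix(i = rows, j = cols, x = vals,
                              dims = c((m - 2) * ncol(id), n))
    mats[[length(mats) + 1]] <- Matrix::crossprod(D)
  }
  Reduce(`+`, mats)
}

# PE-axis central-difference gradient of a volume (voxel units).
.peGradient <- function(vol, peAxis) {
  a <- .alongAxis(vol, peAxis)
  n <- nrow(a$mat)
  g <- (a$mat[c(2:n, n), , drop = FALSE] - a$mat[c(1, 1:(n - 1)), , drop = FALSE]) /
       c(1, rep(2, n - 2), 1)
  a$restore(g)
}

#' Estimate the PE displacement field from a reversed-PE pair
#'
#' Finds the voxel-shift field \eqn{\hat v} (mm, along PE only) minimizing
#' \deqn{\sum_x [U(AP, +\hat v) - U(PA, -\hat v)]^2(x) +
#'   \lambda \, \mathrm{bending}(\hat v),}
#' where \eqn{U} is the Jacobian-modulated unwarp — the midway assumption
#' that the true image lies between the two oppositely distorted ones. The
#' field is parameterized by coefficients on a coarse knot grid
#' (trilinear basis, default 15 mm spacing) and optimized by Gauss-Newton
#' with backtracking line search over a coarse-to-fine smoothing pyramid.
#' The objective is non-increasing over accepted iterations.
#'
#' @param pair a \linkS4class{ReversedPair}.
#' @param params a \linkS4class{TopupParams}.
#' @return A list with \code{vsm} (the estimated
#'   \linkS4class{VoxelShiftMap}, mm), \code{trace} (data.frame of level,
#'   iteration, objective), and \code{converged} (logical; FALSE triggers a
#'   warning and returns the best iterate).
#' @export
estimateFieldTopup <- function(pair, params = TopupParams()) {
  stopifnot(is(pair, "ReversedPair"))
  geom <- pair@geom
  shape <- dim(pair@apVolume)
  vs <- rep(geom@voxelSizePE, 3)    # phantom grids are isotropic at s_y
  nLev <- length(params@pyramidFwhm)
  knotsPerLevel <- rep(params@knotSpacing, length.out = nLev)
  geomPA <- initialize(geom, pePolarity = -geom@pePolarity)
  ps <- geom@pePolarity / geom@voxelSizePE   # mm -> voxel shift, AP sign
  basis <- NULL
  coef <- NULL
  trace <- list()
  lambda <- params@lambda
  converged <- TRUE

  objective <- function(coef, ap, pa) {
    v <- VoxelShiftMap(array(as.numeric(B %*% coef), shape))
    ua <- unwarpVolume(ap, v, geom, conserveMass = TRUE)
    up <- unwarpVolume(pa, v, geomPA, conserveMass = TRUE)
    r <- ua - up
    list(data = sum(r^2), r = r, v = v)
  }

  for (lev in seq_along(params@pyramidFwhm)) {
    fw <- params@pyramidFwhm[lev]
    newBasis <- .knotBasis(shape, vs, knotsPerLevel[lev], geom@peAxis)
    if (is.null(basis)) {
      coef <- numeric(ncol(newBasis$B))
    } else if (!identical(newBasis$nk, basis$nk)) {
      # trilinear basis is interpolating: finer-level coefficients are the
      # current field sampled at the finer knot positions
      vField <- array(as.numeric(basis$B %*% coef), shape)
      kg <- as.matrix(expand.grid(newBasis$knots[[1]], newBasis$knots[[2]],
                                  newBasis$knots[[3]]))
      coef <- vField[kg]
    }
    basis <- newBasis
    B <- basis$B
    Bp <- basis$Bp
    L <- .bendingPenalty(basis$nk)
    if (!is.na(params@lambda)) lambda <- params@lambda else lambda <- NA
    ap <- if (fw > 0) .gaussSmooth3d(pair@apVolume, fw, vs) else pair@apVolume
    pa <- if (fw > 0) .gaussSmooth3d(pair@paVolume, fw, vs) else pair@paVolume
    apGrad <- .peGradient(ap, geom@peAxis)
    paGrad <- .peGradient(pa, geom@peAxis)
    st <- objective(coef, ap, pa)
    if (is.na(lambda))
      lambda <- 0.1 * st$data / sum(Matrix::diag(L))
    f <- st$data + lambda * as.numeric(Matrix::crossprod(coef, L %*% coef))
    trace[[length(trace) + 1]] <- data.frame(level = lev, iter = 0L,
                                             objective = f)
    for (it in seq_len(params@maxIter)) {
      # exact data-term Jacobian: U_A(y) = A(y + d) J_A with d = ps * B c and
      # J_A = 1 + ps * Bp c, so dU_A/dc = ps (A'(y+d) J_A B + A(y+d) Bp), and
      # the PA branch mirrors with -ps. Warped samples come from the
      # non-modulated pull interpolation of the images and their gradients.
      dpe <- array(as.numeric(Bp %*% coef), shape) * ps
      jA <- pmax(1 + dpe, 0.05)
      jP <- pmax(1 - dpe, 0.05)
      aAt <- unwarpVolume(ap, st$v, geom, conserveMass = FALSE)
      pAt <- unwarpVolume(pa, st$v, geomPA, conserveMass = FALSE)
      gaAt <- unwarpVolume(apGrad, st$v, geom, conserveMass = FALSE)
      gpAt <- unwarpVolume(paGrad, st$v, geomPA, conserveMass = FALSE)
      w1 <- ps * (gaAt * jA + gpAt * jP)
      w2 <- ps * (aAt + pAt)
      J <- B * as.numeric(w1) + Bp * as.numeric(w2)
      g <- as.numeric(Matrix::crossprod(J, as.numeric(st$r))) +
           lambda * as.numeric(L %*% coef)
      H <- Matrix::crossprod(J) + lambda * L +
           Matrix::Diagonal(ncol(B), 1e-8 * max(1, sum(w1^2) / ncol(B)))
      step <- as.numeric(Matrix::solve(H, g))
      accepted <- FALSE
      alpha <- 1
      for (ls in 1:12) {
        cand <- coef - alpha * step
        # reject steps that break warp invertibility outright
        vtry <- array(as.numeric(B %*% cand), shape) / geom@voxelSizePE
        a <- .alongAxis(vtry, geom@peAxis)
        if (max(abs(diff(a$mat))) < 0.99) {
          stTry <- objective(cand, ap, pa)
          fTry <- stTry$data +
            lambda * as.numeric(Matrix::crossprod(cand, L %*% cand))
          if (fTry < f) {
            coef <- cand; st <- stTry
            fPrev <- f; f <- fTry
            accepted <- TRUE
            break
          }
        }
        alpha <- alpha / 2
      }
      trace[[length(trace) + 1]] <- data.frame(level = lev, iter = it,
                                               objective = f)
      if (!accepted) break
      if ((fPrev - f) / max(fPrev, .Machine$double.eps) < params@tol) break
    }
    if (it == params@maxIter && accepted &&
        (fPrev - f) / max(fPrev, .Machine$double.eps) >= params@tol &&
        lev == length(params@pyramidFwhm)) {
      warning("reversed-PE estimation hit maxIter before convergence; returning best iterate")
      converged <- FALSE
    }
  }
  vsm <- VoxelShiftMap(array(as.numeric(B %*% coef), shape))
  list(vsm = vsm, trace = do.call(rbind, trace), converged = converged)
}

#' Correct a reversed-PE pair with an estimated shift field
#'
#' The AP member is unwarped with \eqn{+v}, the PA member with \eqn{-v}
#' (handled through the recorded polarities), and the midway image is their
#' mean — the estimate of the undistorted volume.
#'
#' @param pair a \linkS4class{ReversedPair}.
#' @param vsm a \linkS4class{VoxelShiftMap} on the same grid.
#' @param conserveMass passed to [unwarpVolume()].
#' @return List with \code{ap}, \code{pa} (corrected volumes) and
#'   \code{midway}.
#' @export
correctPair <- function(pair, vsm, conserveMass = TRUE) {
  stopifnot(identical(dim(pair@apVolume), dim(mapValues(vsm))))
  geom <- pair@geom
  geomPA <- initialize(geom, pePolarity = -geom@pePolarity)
  ap <- unwarpVolume(pair@apVolume, vsm, geom, conserveMass)
  pa <- unwarpVolume(pair@paVolume, vsm, geomPA, conserveMass)
  list(ap = ap, pa = pa, midway = (ap + pa) / 2)
}
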