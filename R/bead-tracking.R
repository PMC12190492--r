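#' @include AllClasses.R
NULL

# Clamped bilinear interpolation of a matrix image at continuous
# coordinates (x = column, y = row, 1-based). Vectorized over x, y.
.bilinear <- function(img, x, y) {
  nr <- nrow(img); nc <- ncol(img)
  x <- pmin(pmax(as.numeric(x), 1), nc)
  y <- pmin(pmax(as.numeric(y), 1), nr)
  x0 <- pmin(floor(x), nc - 1L); y0 <- pmin(floor(y), nr - 1L)
  fx <- x - x0; fy <- y - y0
  i00 <- img[cbind(y0, x0)];     i01 <- img[cbind(y0, x0 + 1)]
  i10 <- img[cbind(y0 + 1, x0)]; i11 <- img[cbind(y0 + 1, x0 + 1)]
  (1 - fy) * ((1 - fx) * i00 + fx * i01) + fy * ((1 - fx) * i10 + fx * i11)
}

#' Difference-of-Gaussian band-pass filter
#'
#' Subtracts a wide Gaussian blur from a narrow one,
#' `G(sigmaSmall) * I - G(sigmaLarge) * I`, suppressing both pixel noise
#' and slowly varying background so that spot-like features (fluorescent
#' beads) stand out. The output is approximately zero-mean on constant
#' backgrounds.
#'
#' @param image Numeric matrix (grayscale image, rows = y).
#' @param sigmaSmall,sigmaLarge Gaussian standard deviations in pixels,
#'   `0 < sigmaSmall < sigmaLarge`. Defaults 1.5 and 2.0 px, matched to
#'   diffraction-limited 100 nm beads.
#' @return Numeric matrix of the same shape.
#' @export
dogFilter <- function(image, sigmaSmall = 1.5, sigmaLarge = 2.0) {
  image <- as.matrix(image)
  if (!is.numeric(image) || length(dim(image)) != 2L)
    stop("'image' must be a 2D numeric matrix")
  if (!is.finite(sigmaSmall) || !is.finite(sigmaLarge) ||
      sigmaSmall <= 0 || sigmaLarge <= 0)
    stop("sigmas must be positive")
  if (sigmaSmall >= sigmaLarge)
    stop("'sigmaSmall' must be smaller than 'sigmaLarge'")
  EBImage::gblur(image, sigma = sigmaSmall) -
    EBImage::gblur(image, sigma = sigmaLarge)
}

# Quadratic 1D subpixel offset of a peak from its two neighbours;
# clamped to [-0.5, 0.5].
.quadOffset <- function(fm, f0, fp) {
  den <- fm - 2 * f0 + fp
  off <- ifelse(abs(den) > .Machine$double.eps, 0.5 * (fm - fp) / den, 0)
  pmin(pmax(off, -0.5), 0.5)
}

#' Detect fluorescent beads by the minimum-eigenvalue corner response
#'
#' Shi-Tomasi style point detection: the image is band-passed with
#' [dogFilter()], the local structure tensor (Gaussian-windowed outer
#' product of intensity gradients) is computed per pixel, and its smaller
#' eigenvalue forms the detection response. Pixels above
#' `qualityLevel * max(response)` that are strict 3x3 local maxima are
#' kept, non-maximum suppression enforces a minimum spacing, and each
#' surviving peak is refined to subpixel precision by separable quadratic
#' interpolation of the response.
#'
#' @param image Numeric matrix (grayscale, rows = y).
#' @param sigmaSmall,sigmaLarge DoG sigmas, see [dogFilter()].
#' @param qualityLevel Response threshold as a fraction of the global
#'   maximum response, in (0, 1). Default 0.05.
#' @param minDistance Minimum spacing between detections, px. Default 5.
#' @param border Margin (px) inside the image border excluded from
#'   detection. Default 5.
#' @return A `data.frame` with columns `x`, `y` (subpixel positions) and
#'   `response`, ordered by decreasing response. Zero rows for blank
#'   images.
#' @export
detectBeads <- function(image, sigmaSmall = 1.5, sigmaLarge = 2.0,
                        qualityLevel = 0.05, minDistance = 5, border = 5) {
  image <- as.matrix(image)
  if (length(image) == 0L) stop("'image' must be non-empty")
  if (qualityLevel <= 0 || qualityLevel >= 1)
    stop("'qualityLevel' must be in (0, 1)")
  if (minDistance < 1) stop("'minDistance' must be >= 1")
  dog <- dogFilter(image, sigmaSmall, sigmaLarge)
  nr <- nrow(dog); nc <- ncol(dog)
  # image gradients (central differences)
  gx <- matrix(0, nr, nc); gy <- matrix(0, nr, nc)
  gx[, 2:(nc - 1)] <- (dog[, 3:nc] - dog[, 1:(nc - 2)]) / 2
  gy[2:(nr - 1), ] <- (dog[3:nr, ] - dog[1:(nr - 2), ]) / 2
  # Gaussian-windowed structure tensor
  jxx <- EBImage::gblur(gx * gx, sigma = sigmaSmall)
  jyy <- EBImage::gblur(gy * gy, sigma = sigmaSmall)
  jxy <- EBImage::gblur(gx * gy, sigma = sigmaSmall)
  tr2 <- (jxx + jyy) / 2
  resp <- tr2 - sqrt(pmax((jxx - jyy)^2 / 4 + jxy^2, 0))
  peak <- max(resp)
  empty <- data.frame(x = numeric(0), y = numeric(0), response = numeric(0))
  if (peak <= 0) return(empty)
  thr <- qualityLevel * peak
  b <- max(2L, as.integer(border))
  cand <- which(resp >= thr, arr.ind = TRUE)
  cand <- cand[cand[, 1] > b & cand[, 1] <= nr - b &
               cand[, 2] > b & cand[, 2] <= nc - b, , drop = FALSE]
  if (nrow(cand) == 0L) return(empty)
  # strict 3x3 local maxima
  isMax <- vapply(seq_len(nrow(cand)), function(k) {
    i <- cand[k, 1]; j <- cand[k, 2]
    nb <- resp[(i - 1):(i + 1), (j - 1):(j + 1)]
    resp[i, j] >= max(nb) && sum(nb == resp[i, j]) == 1L
  }, logical(1))
  cand <- cand[isMax, , drop = FALSE]
  if (nrow(cand) == 0L) return(empty)
  r <- resp[cand]
  ord <- order(-r, cand[, 1], cand[, 2])
  cand <- cand[ord, , drop = FALSE]
  r <- r[ord]
  # greedy non-maximum suppression, strongest first
  keep <- logical(nrow(cand))
  ax <- numeric(0); ay <- numeric(0)
  md2 <- minDistance^2
  for (k in seq_len(nrow(cand))) {
    x <- cand[k, 2]; y <- cand[k, 1]
    if (!length(ax) || all((ax - x)^2 + (ay - y)^2 >= md2)) {
      keep[k] <- TRUE
      ax <- c(ax, x); ay <- c(ay, y)
    }
  }
  cand <- cand[keep, , drop = FALSE]
  r <- r[keep]
  i <- cand[, 1]; j <- cand[, 2]
  sx <- .quadOffset(resp[cbind(i, j - 1)], resp[cbind(i, j)],
                    resp[cbind(i, j + 1)])
  sy <- .quadOffset(resp[cbind(i - 1, j)], resp[cbind(i, j)],
                    resp[cbind(i + 1, j)])
  data.frame(x = j + sx, y = i + sy, response = r)
}

# Block-mean 2x downsampling (dims cropped to even).
.downsample2 <- function(img) {
  nr <- 2L * (nrow(img) %/% 2L); nc <- 2L * (ncol(img) %/% 2L)
  img <- img[seq_len(nr), seq_len(nc)]
  (img[seq(1, nr, 2), seq(1, nc, 2)] + img[seq(2, nr, 2), seq(1, nc, 2)] +
   img[seq(1, nr, 2), seq(2, nc, 2)] + img[seq(2, nr, 2), seq(2, nc, 2)]) / 4
}

# One-level iterative Lucas-Kanade refinement of displacement v for a
# single anchor. `wgt` is a spatial weighting of the window (centre
# emphasized), which reduces the bias a wide window incurs on spatially
# varying displacement fields. Returns list(v, residual, converged).
.lkRefine <- function(template, gxw, gyw, loaded, px, py, v, wgt,
                      maxIter = 25, tol = 0.005) {
  G <- matrix(c(sum(wgt * gxw * gxw), sum(wgt * gxw * gyw),
                sum(wgt * gxw * gyw), sum(wgt * gyw * gyw)), 2, 2)
  detG <- G[1, 1] * G[2, 2] - G[1, 2]^2
  if (!is.finite(detG) || detG <= .Machine$double.eps * (G[1, 1] + G[2, 2])^2)
    return(list(v = v, residual = Inf, converged = FALSE))
  Ginv <- matrix(c(G[2, 2], -G[1, 2], -G[1, 2], G[1, 1]), 2, 2) / detG
  half <- (nrow(template) - 1) / 2
  off <- seq(-half, half)
  xs <- matrix(px + rep(off, each = length(off)), length(off))
  ys <- matrix(py + rep(off, times = length(off)), length(off))
  conv <- FALSE
  warped <- template
  for (it in seq_len(maxIter)) {
    warped <- matrix(.bilinear(loaded, xs + v[1], ys + v[2]), nrow(template))
    err <- template - warped
    b <- c(sum(wgt * gxw * err), sum(wgt * gyw * err))
    delta <- as.numeric(Ginv %*% b)
    # template - warped decreases when moving v against delta sign:
    # I(x+v) ~ I(x) + g.v  =>  v_new = v + G^-1 b with b = sum g*(T - I(v))
    v <- v + delta
    if (sqrt(sum(delta^2)) < tol) { conv <- TRUE; break }
  }
  list(v = v, residual = mean(abs(template - warped)), converged = conv)
}

# One-level LK solve at a given window size; template and gradients are
# sampled around (px, py) in `img`, matching against `dst`.
.lkLevel <- function(img, dst, px, py, w, v) {
  half <- (w - 1) / 2
  off <- seq(-half, half)
  xs <- matrix(px + rep(off, each = w), w)
  ys <- matrix(py + rep(off, times = w), w)
  template <- matrix(.bilinear(img, xs, ys), w)
  gxw <- matrix((.bilinear(img, xs + 1, ys) -
                 .bilinear(img, xs - 1, ys)) / 2, w)
  gyw <- matrix((.bilinear(img, xs, ys + 1) -
                 .bilinear(img, xs, ys - 1)) / 2, w)
  wg <- exp(-(off^2) / (2 * (w / 4)^2))
  .lkRefine(template, gxw, gyw, dst, px, py, v, outer(wg, wg))
}

# Pyramidal LK track of one anchor from image pyramid `pyrA` (template
# source) to `pyrB`. The wide window gives a robust, smooth estimate;
# the optional final pass with a small window centred on the bead
# removes the spatial-averaging bias of the wide window. Positions are
# 1-based pixel coordinates on level 1.
.lkTrack <- function(pyrA, pyrB, x, y, window, refineWindow = 0) {
  L <- length(pyrA)
  v <- c(0, 0)
  res <- Inf
  for (lev in seq(L, 1)) {
    s <- 2^(lev - 1)
    px <- (x - 1) / s + 1; py <- (y - 1) / s + 1
    img <- pyrA[[lev]]
    w <- min(window, 2 * floor((min(dim(img)) - 3) / 2) + 1)
    if (w < 3) { v <- v * 2; next }
    fit <- .lkLevel(img, pyrB[[lev]], px, py, w, v)
    v <- fit$v
    res <- fit$residual
    if (lev > 1) v <- v * 2
  }
  if (refineWindow >= 3 && refineWindow < window) {
    fit <- .lkLevel(pyrA[[1]], pyrB[[1]], x, y, refineWindow, v)
    # keep the refined vector only if the local solve stayed close to
    # the wide-window estimate (guards against locking onto a neighbour)
    if (is.finite(fit$residual) && sqrt(sum((fit$v - v)^2)) <= 2) {
      v <- fit$v
      res <- fit$residual
    }
  }
  c(v, res)
}

.buildPyramid <- function(img, levels) {
  pyr <- vector("list", levels)
  pyr[[1]] <- img
  for (l in seq_len(levels - 1))
    pyr[[l + 1]] <- .downsample2(EBImage::gblur(pyr[[l]], sigma = 1))
  pyr
}

#' Track bead displacements by pyramidal optical flow
#'
#' Kanade-Lucas-Tomasi tracking of bead anchors from the relaxed
#' (traction-free) image into the loaded image: for each anchor a fixed
#' intensity window in the relaxed image is matched against the loaded
#' image by iterative gradient descent on a Gaussian image pyramid. The
#' displacement convention is loaded position minus relaxed position, i.e.
#' the gel deformation under load at material points of the relaxed
#' state. Tracks are discarded (flagged lost) when the final matching
#' residual exceeds `maxResidual`, the displacement magnitude exceeds
#' `maxDisplacement`, or the forward-backward consistency check fails
#' (tracking the end point back must land within `fbTol` of the anchor).
#'
#' @param relaxed,loaded Numeric matrices, same shape; the traction-free
#'   and traction-loaded bead images. Intensities are normalized
#'   internally.
#' @param anchors Two-column matrix or data.frame of anchor positions
#'   (`x`, `y`) detected in the relaxed image, e.g. from [detectBeads()].
#' @param window Side of the square tracking window, odd, px. Default 61.
#' @param pyramidLevels Number of pyramid levels (>= 1); automatically
#'   reduced for small images. Default 3.
#' @param maxResidual Maximum mean absolute intensity residual (on the
#'   normalized 0-1 scale) for a track to be kept. Default 0.1.
#' @param maxDisplacement Maximum plausible displacement magnitude, px.
#'   Default `window / 2`.
#' @param fbTol Forward-backward consistency tolerance, px. Default 1.
#' @param refineWindow Side of a small window for a final per-bead
#'   refinement pass after the wide-window solve has converged; removes
#'   the spatial-averaging bias of the wide window on non-uniform
#'   displacement fields. 0 disables. Default 15.
#' @return A [BeadDisplacements-class].
#' @export
trackDisplacements <- function(relaxed, loaded, anchors, window = 61,
                               pyramidLevels = 3, maxResidual = 0.1,
                               maxDisplacement = window / 2, fbTol = 1,
                               refineWindow = 15) {
  relaxed <- as.matrix(relaxed); loaded <- as.matrix(loaded)
  if (!identical(dim(relaxed), dim(loaded)))
    stop("'relaxed' and 'loaded' must have the same shape")
  if (is.data.frame(anchors)) anchors <- cbind(anchors$x, anchors$y)
  anchors <- as.matrix(anchors)
  if (nrow(anchors) == 0L) stop("no anchors to track")
  if (window < 3 || window %% 2 == 0) stop("'window' must be odd and >= 3")
  if (pyramidLevels < 1) stop("'pyramidLevels' must be >= 1")
  # normalize jointly so residuals are comparable across bit depths
  hi <- max(relaxed, loaded, 1e-12)
  relaxed <- relaxed / hi; loaded <- loaded / hi
  # keep pyramid levels on which the window still fits
  levels <- 1L
  while (levels < pyramidLevels &&
         min(dim(relaxed)) / 2^levels >= max(window, 16)) levels <- levels + 1L
  pyrA <- .buildPyramid(relaxed, levels)
  pyrB <- .buildPyramid(loaded, levels)
  n <- nrow(anchors)
  dx <- dy <- rep(NA_real_, n)
  tracked <- logical(n)
  for (k in seq_len(n)) {
    fw <- .lkTrack(pyrA, pyrB, anchors[k, 1], anchors[k, 2], window,
                   refineWindow)
    v <- fw[1:2]; res <- fw[3]
    ok <- is.finite(res) && res <= maxResidual &&
      sqrt(sum(v^2)) <= maxDisplacement
    if (ok && is.finite(fbTol)) {
      bw <- .lkTrack(pyrB, pyrA, anchors[k, 1] + v[1], anchors[k, 2] + v[2],
                     window, refineWindow)
      ok <- sqrt(sum((v + bw[1:2])^2)) <= fbTol
    }
    if (ok) {
      dx[k] <- v[1]; dy[k] <- v[2]; tracked[k] <- TRUE
    }
  }
  BeadDisplacements(anchors[, 1], anchors[, 2], dx, dy, tracked)
}

#' Remove rigid stage drift from a scattered displacement field
#'
#' Subtracts the component-wise median displacement of reference beads —
#' beads outside the cell mask when one is given, otherwise all tracked
#' beads — from every vector. Rigid drift between the two acquisitions
#' otherwise masquerades as a uniform traction signal.
#'
#' @param field A [BeadDisplacements-class].
#' @param mask Optional logical matrix (`TRUE` inside the cell); beads
#'   inside are excluded from the drift estimate.
#' @param minReference Minimum number of reference beads required;
#'   with fewer, a warning is issued and the field is returned unchanged.
#'   Default 5.
#' @return A drift-corrected [BeadDisplacements-class].
#' @export
driftCorrect <- function(field, mask = NULL, minReference = 5) {
  stopifnot(is(field, "BeadDisplacements"))
  ref <- field@tracked
  if (!is.null(mask)) {
    mask <- as.matrix(mask)
    ix <- pmin(pmax(round(field@x), 1), ncol(mask))
    iy <- pmin(pmax(round(field@y), 1), nrow(mask))
    ref <- ref & !(mask[cbind(iy, ix)] > 0)
  }
  if (sum(ref) < minReference) {
    warning("fewer than ", minReference,
            " reference beads; no drift correction applied")
    return(field)
  }
  mx <- stats::median(field@dx[ref])
  my <- stats::median(field@dy[ref])
  BeadDisplacements(field@x, field@y,
                    field@dx - mx, field@dy - my, field@tracked)
}

#' Interpolate scattered bead displacements onto a regular grid
#'
#' Moving-least-squares interpolation: at every grid node a local
#' polynomial (quadratic where enough neighbours are available, plane
#' otherwise) is fitted by weighted least squares (Gaussian weights)
#' through the `k` nearest tracked beads and evaluated at the node.
#' Affine displacement fields are reproduced exactly; the quadratic term
#' preserves the curvature of smooth fields near traction hotspots.
#' Outside the bead convex hull the local fit extrapolates smoothly.
#'
#' @param field A [BeadDisplacements-class] with >= 4 tracked,
#'   non-collinear beads.
#' @param spacing Grid spacing in pixels. Default 8.
#' @param imageDim Optional `c(nrow, ncol)` of the source image; the grid
#'   then spans the full image. Defaults to the bead bounding box.
#' @param k Number of nearest beads per node. Default 16.
#' @return A [DisplacementGrid-class] with unit `"px"`.
#' @export
gridDisplacements <- function(field, spacing = 8, imageDim = NULL, k = 16) {
  stopifnot(is(field, "BeadDisplacements"))
  sel <- field@tracked
  if (sum(sel) < 4) stop("need at least 4 tracked beads")
  bx <- field@x[sel]; by <- field@y[sel]
  vdx <- field@dx[sel]; vdy <- field@dy[sel]
  # collinearity guard: rank of centred positions
  P <- cbind(bx - mean(bx), by - mean(by))
  if (svd(P, nu = 0, nv = 0)$d[2] < 1e-8 * max(svd(P, nu = 0, nv = 0)$d[1], 1))
    stop("bead positions are collinear; cannot interpolate a 2D field")
  if (is.null(imageDim)) {
    xr <- range(bx); yr <- range(by)
  } else {
    xr <- c(1, imageDim[2]); yr <- c(1, imageDim[1])
  }
  xs <- seq(xr[1], xr[2], by = spacing)
  ys <- seq(yr[1], yr[2], by = spacing)
  k <- min(k, length(bx))
  ux <- matrix(0, length(ys), length(xs))
  uy <- matrix(0, length(ys), length(xs))
  for (j in seq_along(xs)) {
    d2x <- (bx - xs[j])^2
    for (i in seq_along(ys)) {
      d2 <- d2x + (by - ys[i])^2
      nb <- order(d2)[seq_len(k)]
      scale2 <- max(d2[nb][k], 1e-9)
      w <- exp(-d2[nb] / scale2)
      dxn <- bx[nb] - xs[j]; dyn <- by[nb] - ys[i]
      # quadratic MLS basis; drop to a plane, then to a weighted mean,
      # when the neighbourhood is rank-deficient
      A <- cbind(1, dxn, dyn, dxn^2, dxn * dyn, dyn^2) * sqrt(w)
      qrA <- qr(A)
      if (qrA$rank < 6) {
        A <- cbind(1, dxn, dyn) * sqrt(w)
        qrA <- qr(A)
      }
      if (qrA$rank < 3) {
        ux[i, j] <- sum(w * vdx[nb]) / sum(w)
        uy[i, j] <- sum(w * vdy[nb]) / sum(w)
      } else {
        # range limiter: the local polynomial must not overshoot the
        # values it was fitted to (suppresses edge ringing and spikes)
        ux[i, j] <- min(max(qr.coef(qrA, vdx[nb] * sqrt(w))[1],
                            min(vdx[nb])), max(vdx[nb]))
        uy[i, j] <- min(max(qr.coef(qrA, vdy[nb] * sqrt(w))[1],
                            min(vdy[nb])), max(vdy[nb]))
      }
    }
  }
  DisplacementGrid(ux, uy, origin = c(xs[1], ys[1]), spacing = spacing,
                   unit = "px")
}
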