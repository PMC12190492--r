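#' @include AllClasses.R
NULL

# Angular spatial frequencies (rad per length unit of `spacing`) for an
# n-point DFT with node spacing `spacing`.
.fftFreq <- function(n, spacing = 1) {
  m <- seq_len(n) - 1L
  m[m > n / 2] <- m[m > n / 2] - n
  2 * pi * m / (n * spacing)
}

# Boussinesq surface Green's tensor in Fourier space, E = 1, vectorized
# over wavevector arrays. With k in rad/px the product g %*% (T/E) gives
# displacement in px. Returns list(g11, g12, g22); entries at k = 0 are 0
# (the zero mode is handled by the callers).
.greensComponents <- function(kx, ky, nu) {
  k2 <- kx^2 + ky^2
  k <- sqrt(k2)
  pre <- ifelse(k > 0, 2 * (1 + nu) / k^3, 0)
  list(
    g11 = pre * ((1 - nu) * k2 + nu * ky^2),
    g12 = pre * (-nu * kx * ky),
    g22 = pre * ((1 - nu) * k2 + nu * kx^2)
  )
}

#' Boussinesq Green's tensor at one wavevector
#'
#' Fourier-space displacement response of a semi-infinite, homogeneous,
#' isotropic linear-elastic substrate to in-plane surface traction:
#' \deqn{\tilde G(k) = \frac{2(1+\nu)}{E |k|^3}
#'   \begin{pmatrix} (1-\nu)|k|^2 + \nu k_y^2 & -\nu k_x k_y \\
#'                   -\nu k_x k_y & (1-\nu)|k|^2 + \nu k_x^2 \end{pmatrix}}
#' The tensor is symmetric positive-definite for any wavevector and any
#' admissible Poisson ratio, including the incompressible limit
#' \eqn{\nu = 0.5}; it diverges as \eqn{|k| \to 0}, so the zero mode must
#' be treated separately by callers (see [reconstructTraction()]).
#'
#' @param kx,ky Angular spatial frequency components (rad per length);
#'   units of 1/length must match the desired displacement-per-traction
#'   units.
#' @param substrate A [SubstrateModel-class].
#' @return A symmetric 2x2 numeric matrix, displacement per unit traction.
#' @examples
#' s <- SubstrateModel(youngModulus = 1, poissonRatio = 0.5)
#' greensTensorFourier(1, 0, s)  # diag(1.5, 3)
#' @export
greensTensorFourier <- function(kx, ky, substrate) {
  stopifnot(is(substrate, "SubstrateModel"))
  if (length(kx) != 1L || length(ky) != 1L || !is.finite(kx) || !is.finite(ky))
    stop("'kx' and 'ky' must be finite scalars")
  if (kx == 0 && ky == 0)
    stop("Green's tensor is undefined at the zero wavevector")
  g <- .greensComponents(kx, ky, substrate@poissonRatio)
  matrix(c(g$g11, g$g12, g$g12, g$g22), 2, 2) / substrate@youngModulus
}

# Green's components on a full DFT frequency grid. The off-diagonal term
# is odd in kx and ky, which is sign-ambiguous at the Nyquist frequency
# of an even-length grid (+pi and -pi share one index); it is set to 0
# there so the multiplier respects the Hermitian symmetry of real fields.
.greensGrid <- function(dims, spacing, nu) {
  kx <- matrix(.fftFreq(dims[2], spacing), dims[1], dims[2], byrow = TRUE)
  ky <- matrix(.fftFreq(dims[1], spacing), dims[1], dims[2])
  g <- .greensComponents(kx, ky, nu)
  if (dims[2] %% 2 == 0) g$g12[, dims[2] / 2 + 1] <- 0
  if (dims[1] %% 2 == 0) g$g12[dims[1] / 2 + 1, ] <- 0
  g
}

# Embed a matrix in the top-left corner of a zeros matrix of size n2 x n2.
.zeroPad <- function(m, n2r, n2c) {
  out <- matrix(0, n2r, n2c)
  out[seq_len(nrow(m)), seq_len(ncol(m))] <- m
  out
}

# Separable 2D Tukey (cosine-taper) window: 1 in the interior, cosine
# ramp to 0 over `margin` nodes at each border.
.taperWindow <- function(nr, nc, margin) {
  ramp1 <- function(n) {
    w <- rep(1, n)
    if (margin > 0) {
      i <- seq_len(margin)
      edge <- 0.5 * (1 - cos(pi * (i - 1) / margin))
      w[i] <- edge
      w[n + 1 - i] <- edge
    }
    w
  }
  outer(ramp1(nr), ramp1(nc))
}

#' Forward elastic model: tractions to surface displacements
#'
#' Computes the substrate surface displacement produced by a gridded
#' traction field via per-wavevector multiplication with the Boussinesq
#' half-space Green's tensor, \eqn{\tilde u(k) = \tilde G(k) \tilde T(k)},
#' with the zero mode set to 0 (displacements are defined up to a rigid
#' offset). The transform treats the grid as periodic; set `pad = TRUE`
#' to zero-pad compactly supported tractions to twice the linear size,
#' which approximates the free-space solution.
#'
#' @param traction A [TractionGrid-class] (Pa).
#' @param substrate A [SubstrateModel-class].
#' @param pad Zero-pad to 2x linear size before transforming. Default
#'   `FALSE` (exact periodic operator, the inverse of
#'   [reconstructTraction()] at `lambda = 0` and `pad = FALSE`).
#' @return A [DisplacementGrid-class] on the same grid, unit micrometres.
#' @seealso [forwardDisplacementDirect()] for the direct-space reference
#'   solver, [reconstructTraction()] for the inverse.
#' @export
forwardDisplacement <- function(traction, substrate, pad = FALSE) {
  stopifnot(is(traction, "TractionGrid"), is(substrate, "SubstrateModel"))
  tx <- traction@vx / substrate@youngModulus
  ty <- traction@vy / substrate@youngModulus
  if (!all(is.finite(tx)) || !all(is.finite(ty)))
    stop("traction field contains non-finite values")
  d <- dim(tx)
  if (pad) {
    tx <- .zeroPad(tx, 2 * d[1], 2 * d[2])
    ty <- .zeroPad(ty, 2 * d[1], 2 * d[2])
  }
  dp <- dim(tx)
  g <- .greensGrid(dp, traction@spacing, substrate@poissonRatio)
  Tx <- stats::fft(tx); Ty <- stats::fft(ty)
  Ux <- g$g11 * Tx + g$g12 * Ty
  Uy <- g$g12 * Tx + g$g22 * Ty
  Ux[1, 1] <- 0; Uy[1, 1] <- 0
  ux <- Re(stats::fft(Ux, inverse = TRUE)) / prod(dp)
  uy <- Re(stats::fft(Uy, inverse = TRUE)) / prod(dp)
  if (pad) {
    ux <- ux[seq_len(d[1]), seq_len(d[2])]
    uy <- uy[seq_len(d[1]), seq_len(d[2])]
  }
  DisplacementGrid(ux * substrate@pixelSize, uy * substrate@pixelSize,
                   origin = traction@origin, spacing = traction@spacing,
                   unit = "um")
}

#' Direct-space Boussinesq convolution (reference solver)
#'
#' Brute-force free-space evaluation of the forward model: the real-space
#' Boussinesq surface kernel
#' \deqn{G(r) = \frac{1+\nu}{\pi E r^3}
#'   \begin{pmatrix} (1-\nu)r^2 + \nu x^2 & \nu x y \\
#'                   \nu x y & (1-\nu)r^2 + \nu y^2 \end{pmatrix}}
#' is summed over all traction-carrying nodes, with the singular
#' self-term integrated analytically over an equal-area disc. This is an
#' O(nodes x sources) computation kept as an independent reference for
#' validating the Fourier solver; use [forwardDisplacement()] for
#' analysis.
#'
#' @inheritParams forwardDisplacement
#' @return A [DisplacementGrid-class], unit micrometres, with the
#'   grid-mean displacement subtracted (matching the Fourier solver's
#'   zero-mode convention).
#' @export
forwardDisplacementDirect <- function(traction, substrate) {
  stopifnot(is(traction, "TractionGrid"), is(substrate, "SubstrateModel"))
  E <- substrate@youngModulus
  nu <- substrate@poissonRatio
  h <- traction@spacing * substrate@pixelSize   # node spacing, um
  dA <- h^2
  d <- dim(traction@vx)
  xs <- (seq_len(d[2]) - 1) * h
  ys <- (seq_len(d[1]) - 1) * h
  X <- matrix(xs, d[1], d[2], byrow = TRUE)
  Y <- matrix(ys, d[1], d[2])
  ux <- matrix(0, d[1], d[2]); uy <- matrix(0, d[1], d[2])
  src <- which(traction@vx != 0 | traction@vy != 0, arr.ind = TRUE)
  selfInt <- (1 + nu) * (2 - nu) * (h / sqrt(pi)) / E  # equal-area disc
  for (s in seq_len(nrow(src))) {
    i <- src[s, 1]; j <- src[s, 2]
    txs <- traction@vx[i, j]; tys <- traction@vy[i, j]
    dx <- X - xs[j]; dy <- Y - ys[i]
    r2 <- dx^2 + dy^2
    r3 <- r2^1.5
    pre <- ifelse(r2 > 0, (1 + nu) / (pi * E * r3), 0)
    gxx <- pre * ((1 - nu) * r2 + nu * dx^2)
    gyy <- pre * ((1 - nu) * r2 + nu * dy^2)
    gxy <- pre * nu * dx * dy
    ux <- ux + (gxx * txs + gxy * tys) * dA
    uy <- uy + (gxy * txs + gyy * tys) * dA
    ux[i, j] <- ux[i, j] + selfInt * txs
    uy[i, j] <- uy[i, j] + selfInt * tys
  }
  DisplacementGrid(ux - mean(ux), uy - mean(uy),
                   origin = traction@origin, spacing = traction@spacing,
                   unit = "um")
}

#' Regularized Fourier transform traction cytometry (FTTC)
#'
#' Recovers the traction field from a gridded displacement field by
#' per-wavevector Tikhonov (ridge) inversion of the Boussinesq operator:
#' \deqn{\tilde T(k) = (\tilde G^\top \tilde G + \lambda I)^{-1}
#'   \tilde G^\top \tilde u(k), \qquad \tilde T(0) = 0.}
#' Internally displacements are expressed in pixels and the Green's
#' tensor is nondimensionalized by the Young's modulus, so `lambda` acts
#' in pixel-normalized units (matching regularization constants quoted
#' "per pixel squared"); tractions are converted to Pa on output. The
#' grid mean of the displacement is subtracted before inversion and the
#' zero mode of the traction is set to zero, which enforces global force
#' balance. By default the field is tapered with a cosine border and
#' zero-padded to twice the linear size to suppress periodic wrap-around,
#' then cropped back; disable with `pad = FALSE` to obtain the exact
#' algebraic inverse of [forwardDisplacement()] at `lambda = 0`.
#'
#' @param disp A [DisplacementGrid-class], unit `"um"` or `"px"`.
#' @param substrate A [SubstrateModel-class].
#' @param lambda Regularization strength (pixel-normalized units),
#'   `>= 0`. Default `2.47e-5`.
#' @param pad Taper and zero-pad to 2x linear size. Default `TRUE`.
#' @param taperFraction Width of the cosine taper at each border as a
#'   fraction of the grid size (only when `pad = TRUE`). Default `1/8`.
#' @return A [TractionGrid-class] in Pa on the input grid.
#' @export
reconstructTraction <- function(disp, substrate, lambda = 2.47e-5,
                                pad = TRUE, taperFraction = 1 / 8) {
  stopifnot(is(disp, "DisplacementGrid"), is(substrate, "SubstrateModel"))
  if (length(lambda) != 1L || !is.finite(lambda) || lambda < 0)
    stop("'lambda' must be a single number >= 0")
  d <- dim(disp@vx)
  if (any(d < 4))
    stop("displacement grid must be at least 4 x 4")
  ux <- disp@vx; uy <- disp@vy
  if (!all(is.finite(ux)) || !all(is.finite(uy)))
    stop("displacement field contains non-finite values")
  if (disp@unit == "um") {
    ux <- ux / substrate@pixelSize
    uy <- uy / substrate@pixelSize
  }
  # zero mode / rigid offset removed before inversion (force balance)
  ux <- ux - mean(ux)
  uy <- uy - mean(uy)
  if (pad) {
    w <- .taperWindow(d[1], d[2], max(1L, round(min(d) * taperFraction)))
    ux <- .zeroPad(ux * w, 2 * d[1], 2 * d[2])
    uy <- .zeroPad(uy * w, 2 * d[1], 2 * d[2])
  }
  dp <- dim(ux)
  g <- .greensGrid(dp, disp@spacing, substrate@poissonRatio)
  Ux <- stats::fft(ux); Uy <- stats::fft(uy)
  # normal equations of the symmetric 2x2 tensor, solved in closed form
  A <- g$g11^2 + g$g12^2 + lambda
  B <- g$g12 * (g$g11 + g$g22)
  C <- g$g22^2 + g$g12^2 + lambda
  det <- A * C - B^2
  det[1, 1] <- 1  # zero mode overwritten below
  bx <- g$g11 * Ux + g$g12 * Uy
  by <- g$g12 * Ux + g$g22 * Uy
  Tx <- (C * bx - B * by) / det
  Ty <- (A * by - B * bx) / det
  Tx[1, 1] <- 0; Ty[1, 1] <- 0
  tx <- Re(stats::fft(Tx, inverse = TRUE)) / prod(dp)
  ty <- Re(stats::fft(Ty, inverse = TRUE)) / prod(dp)
  if (pad) {
    tx <- tx[seq_len(d[1]), seq_len(d[2])]
    ty <- ty[seq_len(d[1]), seq_len(d[2])]
  }
  TractionGrid(tx * substrate@youngModulus, ty * substrate@youngModulus,
               origin = disp@origin, spacing = disp@spacing)
}
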