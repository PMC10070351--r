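# Spectral building blocks.
#
# Convention: angular spatial frequencies kx = 2*pi*(cycles per um) computed
# from the pixel size; forward transform analyses with exp(-i k.r), so the
# derivative theorem reads F(dg/dx) = i*kx*G and the gradient-integration
# denominator is (i*kx - ky) exactly. x runs along matrix rows, y along
# columns.

#' @noRd
fft2 <- function(m) stats::fft(m)

#' @noRd
ifft2 <- function(m) stats::fft(m, inverse = TRUE) / length(m)

#' @noRd
fftfreq <- function(n) {
  # cycles per sample: 0, 1/n, ..., with the negative half after; for even n
  # the Nyquist bin -1/2 appears once.
  half <- floor(n / 2)
  c(0:(n - half - 1), -(half:1)) / n
}

#' Angular frequency grid for a 2D image
#'
#' Builds the `kx`, `ky` maps (1/um) matching an image shape under the
#' package's transform convention. The DC bin sits at index (1, 1) and is the
#' only zero of each map; for even dimensions `max(abs(kx)) = pi/pixel_size`.
#'
#' @param shape Either an integer vector `c(nrow, ncol)`, a matrix, or an
#'   [image_field()].
#' @param pixel_size Pixel size in um (taken from the field if given one).
#' @return An object of class `frequency_grid`: list with `kx`, `ky`, `k2`
#'   (\eqn{k_x^2+k_y^2}) matrices and `pixel_size`.
#' @export
frequency_grid <- function(shape, pixel_size = NULL) {
  if (inherits(shape, "image_field")) {
    pixel_size <- shape$pixel_size
    shape <- dim(shape$values)
  } else if (is.matrix(shape)) {
    shape <- dim(shape)
  }
  if (is.null(pixel_size) || pixel_size <= 0)
    stop("pixel_size must be a positive number (um)", call. = FALSE)
  n1 <- as.integer(shape[1]); n2 <- as.integer(shape[2])
  fx <- 2 * pi * fftfreq(n1) / pixel_size
  fy <- 2 * pi * fftfreq(n2) / pixel_size
  kx <- matrix(fx, n1, n2)
  ky <- matrix(fy, n1, n2, byrow = TRUE)
  structure(list(kx = kx, ky = ky, k2 = kx^2 + ky^2,
                 pixel_size = as.numeric(pixel_size)),
            class = "frequency_grid")
}

#' Tikhonov-regularised quotient
#'
#' Replaces the division `a / b` by `a * b / (b^2 + alpha)`, the standard
#' stabilisation of an ill-posed pointwise quotient. With `alpha = 0` it is
#' the exact quotient; a `b` of zero maps to zero for any `alpha > 0`.
#'
#' @param a,b Numeric arrays or scalars (recycled elementwise).
#' @param alpha Regularisation parameter, `>= 0`.
#' @return Elementwise `a*b/(b^2 + alpha)`.
#' @examples
#' tikhonov_quotient(6, 2, 1)  # 12/5
#' @export
tikhonov_quotient <- function(a, b, alpha) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha < 0)
    stop("invalid regulariser: alpha must be >= 0", call. = FALSE)
  a * b / (b^2 + alpha)
}

#' Transverse gradient of an image
#'
#' @param f Matrix or [image_field()].
#' @param pixel_size Pixel size in um (needed for a bare matrix).
#' @param method `"central"`: 2-pixel centred differences with reflective
#'   (mirror) edge handling, exact for linear ramps in the interior.
#'   `"spectral"`: Fourier derivative theorem (periodic).
#' @return List with matrices `x`, `y`: \eqn{\partial f/\partial x},
#'   \eqn{\partial f/\partial y} in units of f per um.
#' @export
gradient2d <- function(f, pixel_size = NULL, method = c("central", "spectral")) {
  method <- match.arg(method)
  ps <- field_pixel_size(f, pixel_size)
  v <- as_matrix_values(f)
  n1 <- nrow(v); n2 <- ncol(v)
  if (method == "central") {
    gx <- (v[reflect_up(n1), ] - v[reflect_down(n1), ]) / (2 * ps)
    gy <- (v[, reflect_up(n2)] - v[, reflect_down(n2)]) / (2 * ps)
  } else {
    g <- frequency_grid(dim(v), ps)
    Fv <- fft2(v)
    gx <- Re(ifft2(1i * g$kx * Fv))
    gy <- Re(ifft2(1i * g$ky * Fv))
  }
  list(x = gx, y = gy)
}

#' Transverse Laplacian of an image
#'
#' @inheritParams gradient2d
#' @param method `"central"`: 5-point stencil with reflective edges (exact for
#'   quadratics in the interior); `"spectral"`: multiplication by
#'   \eqn{-(k_x^2+k_y^2)}.
#' @return Matrix of \eqn{\nabla_\perp^2 f} in units of f per um^2.
#' @export
laplacian2d <- function(f, pixel_size = NULL, method = c("central", "spectral")) {
  method <- match.arg(method)
  ps <- field_pixel_size(f, pixel_size)
  v <- as_matrix_values(f)
  n1 <- nrow(v); n2 <- ncol(v)
  if (method == "central") {
    (v[reflect_up(n1), ] + v[reflect_down(n1), ] +
       v[, reflect_up(n2)] + v[, reflect_down(n2)] - 4 * v) / ps^2
  } else {
    g <- frequency_grid(dim(v), ps)
    Re(ifft2(-g$k2 * fft2(v)))
  }
}

#' Integrate a 2D gradient field in Fourier space
#'
#' Recovers `g` from its two spatial derivatives via
#' \deqn{g = F^{-1}[ F(g^x + i g^y) / (i k_x - k_y) ],}
#' the standard gradient-integration identity of differential phase imaging.
#' Only the DC bin is singular; it is replaced by `dc_value` (default 0, i.e.
#' a mean-free reconstruction - the global offset is unrecoverable from
#' derivatives alone).
#'
#' @param gx,gy Matrices of the x- and y-derivatives (same shape).
#' @param grid A [frequency_grid()] matching the shape.
#' @param dc_value Mean value assigned to the output.
#' @return Matrix of the integrated field.
#' @export
fourier_integrate_gradients <- function(gx, gy, grid, dc_value = 0) {
  gx <- as_matrix_values(gx); gy <- as_matrix_values(gy)
  if (!identical(dim(gx), dim(gy))) stop("gx and gy shapes differ", call. = FALSE)
  den <- 1i * grid$kx - grid$ky
  den[1, 1] <- 1  # singular DC bin, overwritten below
  G <- fft2(gx + 1i * gy) / den
  G[1, 1] <- dc_value * length(gx)
  Re(ifft2(G))
}

#' Fuse a dark-field map with its gradient-integrated counterpart
#'
#' The directly-solved effective diffusion coefficient `d` is reliable at low
#' spatial frequencies while the solution integrated from its derivatives
#' `(dx, dy)` is reliable at high frequencies. A Gaussian Fourier weight
#' \eqn{e^{-\rho(k_x^2+k_y^2)}} blends the two:
#' \deqn{D^{True} = F^{-1}[ e^{-\rho k^2} F(d)
#'   + (1 - e^{-\rho k^2}) F(d^x + i d^y) / (i k_x - k_y) ].}
#' The second term's weight vanishes at DC (removable singularity, set to 0
#' exactly); near-DC bins use the regularised division
#' \eqn{\overline{(i k_x - k_y)} / (k^2 + \epsilon)} with
#' \eqn{\epsilon = 10^{-12} \max(k^2)}. The output mean always equals
#' `mean(d)`.
#'
#' @param d Directly-solved map.
#' @param dx,dy Its two spatial-derivative maps.
#' @param rho Cut-off parameter in um^2 (`>= 0`); `rho = 0` returns `d`
#'   unchanged, `rho -> Inf` tends to the pure gradient-integrated solution
#'   off DC.
#' @param grid A [frequency_grid()].
#' @return Matrix of the fused map.
#' @export
combine_darkfield <- function(d, dx, dy, rho, grid) {
  if (!is.numeric(rho) || length(rho) != 1L || rho < 0)
    stop("invalid cut-off: rho must be >= 0", call. = FALSE)
  d <- as_matrix_values(d); dx <- as_matrix_values(dx); dy <- as_matrix_values(dy)
  w <- exp(-rho * grid$k2)
  eps <- 1e-12 * max(grid$k2)
  invden <- Conj(1i * grid$kx - grid$ky) / (grid$k2 + eps)  # 0 exactly at DC
  spec <- w * fft2(d) + (1 - w) * invden * fft2(dx + 1i * dy)
  Re(ifft2(spec))
}

#' Regularised inverse Laplacian
#'
#' Applies \eqn{\nabla_\perp^{-2} = -F^{-1} (k_x^2+k_y^2)^{-1} F} in its
#' Tikhonov-stabilised form
#' \eqn{-F^{-1}[ k^2/((k^2)^2 + \alpha) F ]}; with `alpha = 0` this is the
#' plain reciprocal off DC. The DC bin is set to 0, so the result is
#' mean-free.
#'
#' @param f Matrix to invert.
#' @param grid A [frequency_grid()].
#' @param alpha Regularisation parameter, `>= 0`.
#' @return Matrix with \eqn{\nabla_\perp^2} approximately inverted.
#' @export
inverse_laplacian <- function(f, grid, alpha = 0) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha < 0)
    stop("invalid regulariser: alpha must be >= 0", call. = FALSE)
  f <- as_matrix_values(f)
  filt <- grid$k2 / (grid$k2^2 + alpha)
  filt[1, 1] <- 0
  Re(ifft2(-filt * fft2(f)))
}
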