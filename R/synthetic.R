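# Synthetic speckle fields, ground-truth phantoms, and the Fokker-Planck
# forward model. These make the whole inversion testable without beamline
# data: the generator emulates a sandpaper-type mask (positive random field
# with controllable correlation length and visibility), and phantoms combine
# smooth refractive structure with piecewise-constant dark-field plateaus
# whose step edges are the regime the rapidly-varying inversion targets.

# Empirical autocorrelation-FWHM per unit Gaussian sigma of the soft-
# thresholded field at the default sharpness (tanh(g/(0.7 sd))); between the
# Gaussian-field value 4*sqrt(ln 2) ~ 3.33 and the hard-threshold value
# ~ 2.35.
.FWHM_PER_SIGMA <- 3.17

#' Generate a reference-speckle field
#'
#' Soft-thresholded Gaussian-correlated noise: white noise is smoothed to the
#' requested correlation length, passed through a tanh nonlinearity so that
#' the field has sharp, grain-like speckle structure (as a physical sandpaper
#' mask does), and affinely mapped to the requested mean intensity and
#' visibility. The field is strictly positive and periodic by construction.
#'
#' @param shape Integer vector `c(nrow, ncol)`.
#' @param correlation_length Target speckle size in um, measured as the
#'   full-width at half-maximum of the field's autocorrelation (averaged over
#'   the horizontal and vertical directions); must be at least
#'   `2 * pixel_size` so the speckle is well resolved.
#' @param pixel_size Pixel size in um.
#' @param visibility Requested `(max - min)/(max + min)` in (0, 1).
#' @param mean_intensity Mean of the returned field (> 0).
#' @param seed Optional integer; fixing it makes the field reproducible.
#' @param sharpness Width of the tanh soft threshold in units of the smoothed
#'   field's standard deviation; smaller values give harder, more binary
#'   grains.
#' @return An [image_field()] (dimensionless intensity).
#' @export
generate_speckle <- function(shape, correlation_length, pixel_size,
                             visibility = 0.4, mean_intensity = 1,
                             seed = NULL, sharpness = 0.7) {
  if (correlation_length < 2 * pixel_size)
    stop("unresolved speckle: correlation_length must be >= 2 * pixel_size",
         call. = FALSE)
  if (visibility <= 0 || visibility >= 1)
    stop("visibility must be in (0, 1)", call. = FALSE)
  if (mean_intensity <= 0) stop("mean_intensity must be > 0", call. = FALSE)
  n1 <- as.integer(shape[1]); n2 <- as.integer(shape[2])
  sigma_px <- correlation_length / pixel_size / .FWHM_PER_SIGMA
  g <- with_seed(seed, {
    w <- matrix(stats::rnorm(n1 * n2), n1, n2)
    grd <- frequency_grid(c(n1, n2), 1)  # frequencies in 1/pixel
    Re(ifft2(fft2(w) * exp(-0.5 * sigma_px^2 * grd$k2)))
  })
  s <- tanh((g - mean(g)) / (sharpness * stats::sd(g)))
  a <- (max(s) + min(s)) / 2
  b <- (max(s) - min(s)) / 2
  v <- mean_intensity * (1 + visibility * (s - a) / b)
  image_field(v, pixel_size, units = "dimensionless")
}

#' Measure the autocorrelation FWHM of a field
#'
#' Computes the (circular) autocorrelation via the Wiener-Khinchin theorem,
#' takes the lag profiles through the peak along the two axes, and returns
#' the full-width at half-maximum in um, averaged over the horizontal and
#' vertical directions, with linear interpolation at the half-maximum
#' crossing. This is how a speckle "size" is quoted for SB-PCXI masks.
#'
#' @param field An [image_field()] or matrix.
#' @param pixel_size Needed for a bare matrix.
#' @return FWHM in um.
#' @export
autocorrelation_fwhm <- function(field, pixel_size = NULL) {
  ps <- field_pixel_size(field, pixel_size)
  v <- as_matrix_values(field)
  v <- v - mean(v)
  ac <- Re(ifft2(Mod(fft2(v))^2))
  ac <- ac / ac[1, 1]
  half_width <- function(p) {
    # p[1] = 1 at lag 0; first crossing below 1/2
    i <- which(p < 0.5)[1]
    if (is.na(i)) return(NA_real_)
    lo <- p[i - 1]; hi <- p[i]
    (i - 2) + (lo - 0.5) / (lo - hi)
  }
  hx <- half_width(ac[seq_len(floor(nrow(ac) / 2)), 1])
  hy <- half_width(ac[1, seq_len(floor(ncol(ac) / 2))])
  2 * mean(c(hx, hy)) * ps
}

# C-infinity bump with exact compact support: 1 at the centre, 0 outside
# radius R.
#' @noRd
mollifier <- function(n1, n2, cx, cy, radius) {
  x <- matrix(seq_len(n1), n1, n2)
  y <- matrix(seq_len(n2), n1, n2, byrow = TRUE)
  r2 <- ((x - cx)^2 + (y - cy)^2) / radius^2
  out <- matrix(0, n1, n2)
  inside <- r2 < 1
  out[inside] <- exp(1 - 1 / (1 - r2[inside]))
  out
}

#' Generate a ground-truth phantom
#'
#' Builds matched ground-truth maps for the forward model and the recovery
#' tests: a smooth non-positive phase-shift `phi` (superposition of wide
#' compact bumps, support interior to the frame), an effective diffusion
#' coefficient `d_eff` that is smooth, sharp-edged (piecewise-constant discs,
#' a rectangle, and a 3-pixel-wide ridge), or both, and the single-material
#' attenuation term `i_ob = exp(2 phi / gamma)`. A binary interior mask at
#' Chebyshev distance > 3 px from every `d_eff` step edge is included for
#' edge-aware scoring.
#'
#' @param shape Integer vector `c(nrow, ncol)`, at least 64 x 64.
#' @param pixel_size Pixel size in um.
#' @param kind `"smooth"`, `"sharp"`, or `"mixed"` dark-field structure.
#' @param gamma Single-material ratio `delta/beta` (> 0).
#' @param phi_depth Peak magnitude of the (non-positive) phase-shift, rad.
#' @param d_level Plateau level of the dark-field, um. The default pairs with
#'   typical SB-PCXI geometry (metre-scale propagation, 10 um pixels) so the
#'   forward model stays within its validity range.
#' @return An object of class `phantom`: list with matrices `phi`, `d_eff`,
#'   `i_ob`, logical `interior_mask` and `edge_mask`, `gamma`, `pixel_size`,
#'   `kind`, and a `features` list describing the sharp primitives (used by
#'   profile-based tests).
#' @export
generate_phantom <- function(shape, pixel_size, kind = c("mixed", "smooth", "sharp"),
                             gamma = 1403, phi_depth = 3, d_level = 1e-5) {
  kind <- match.arg(kind)
  if (gamma <= 0) stop("invalid material ratio: gamma must be > 0", call. = FALSE)
  n1 <- as.integer(shape[1]); n2 <- as.integer(shape[2])
  if (n1 < 64L || n2 < 64L) stop("phantom grid must be at least 64x64", call. = FALSE)

  phi <- -phi_depth * mollifier(n1, n2, 0.40 * n1, 0.38 * n2, 0.30 * min(n1, n2)) -
    0.6 * phi_depth * mollifier(n1, n2, 0.64 * n1, 0.68 * n2, 0.22 * min(n1, n2))

  d_smooth <- 0.8 * d_level * mollifier(n1, n2, 0.28 * n1, 0.30 * n2, 0.20 * min(n1, n2)) +
    0.5 * d_level * mollifier(n1, n2, 0.70 * n1, 0.72 * n2, 0.16 * min(n1, n2))

  x <- matrix(seq_len(n1), n1, n2)
  y <- matrix(seq_len(n2), n1, n2, byrow = TRUE)
  d_sharp <- matrix(0, n1, n2)
  disc <- (x - 0.34 * n1)^2 + (y - 0.62 * n2)^2 < (0.12 * min(n1, n2))^2
  rect <- x >= round(0.56 * n1) & x <= round(0.74 * n1) &
    y >= round(0.18 * n2) & y <= round(0.36 * n2)
  ridge_col <- round(0.60 * n2)
  ridge <- x >= round(0.52 * n1) & x <= round(0.86 * n1) &
    y >= ridge_col - 1L & y <= ridge_col + 1L  # exactly 3 px wide
  d_sharp[disc] <- d_level
  d_sharp[rect] <- 0.7 * d_level
  d_sharp[ridge] <- d_level

  d_eff <- switch(kind,
                  smooth = d_smooth,
                  sharp = d_sharp,
                  mixed = d_smooth + d_sharp)

  # step-edge set of the piecewise-constant component (4-neighbour value jumps)
  edge <- matrix(FALSE, n1, n2)
  if (kind != "smooth") {
    jump <- 1e-9 * d_level
    edge[-n1, ] <- edge[-n1, ] | abs(d_sharp[-n1, ] - d_sharp[-1, ]) > jump
    edge[-1, ] <- edge[-1, ] | abs(d_sharp[-1, ] - d_sharp[-n1, ]) > jump
    edge[, -n2] <- edge[, -n2] | abs(d_sharp[, -n2] - d_sharp[, -1]) > jump
    edge[, -1] <- edge[, -1] | abs(d_sharp[, -1] - d_sharp[, -n2]) > jump
  }
  interior <- !dilate_mask(edge, 3L)

  structure(list(phi = phi, d_eff = d_eff,
                 i_ob = exp(2 * phi / gamma),
                 interior_mask = interior, edge_mask = edge,
                 gamma = gamma, pixel_size = as.numeric(pixel_size), kind = kind,
                 features = list(
                   ridge = list(rows = c(round(0.52 * n1), round(0.86 * n1)),
                                col = ridge_col, value = d_level),
                   disc_value = d_level, rect_value = 0.7 * d_level)),
            class = "phantom")
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf("<phantom '%s' %d x %d: phi in [%.3g, %.3g] rad, d_eff in [0, %.3g] um, gamma %g>\n",
              x$kind, nrow(x$phi), ncol(x$phi), min(x$phi), max(x$phi),
              max(x$d_eff), x$gamma))
  invisible(x)
}

#' Fokker-Planck forward model for one speckle set
#'
#' Propagates a reference-speckle field through the phantom:
#' \deqn{I_S = I_R - \frac{\Delta}{k} \nabla_\perp\cdot[I_R \nabla_\perp \phi]
#'   + \Delta \nabla_\perp^2 [D\, I_R]}
#' (`mode = "full"`), or with the coherent-flow term approximated by
#' \eqn{(\Delta/k) I_R \nabla_\perp^2 \phi} (`mode = "simplified"`). In
#' simplified mode the right-hand side is evaluated in its expanded
#' four-unknown form using exactly the same discrete derivative scheme as the
#' inversion's system assembly, so that forward + inversion are consistent up
#' to the linear solve. With `attenuate = TRUE` the result is multiplied
#' pixel-wise by the phantom's `i_ob` (projection approximation at the exit
#' surface), and the matching ground-truth dark-field for recovery tests
#' becomes `d_eff / i_ob`.
#'
#' @param i_r Reference-speckle [image_field()] (or matrix).
#' @param phantom A [generate_phantom()] object of matching shape.
#' @param geometry A [geometry()] object.
#' @param mode `"simplified"` or `"full"` coherent-flow treatment.
#' @param attenuate Multiply by the attenuation term?
#' @param method Discrete derivative scheme, `"central"` or `"spectral"`.
#' @return The sample-reference-speckle [image_field()] \eqn{I_S}.
#' @export
forward_fokker_planck <- function(i_r, phantom, geometry,
                                  mode = c("simplified", "full"),
                                  attenuate = FALSE,
                                  method = c("central", "spectral")) {
  mode <- match.arg(mode); method <- match.arg(method)
  ir <- as_matrix_values(i_r)
  if (!identical(dim(ir), dim(phantom$phi)))
    stop("inconsistent stack: speckle and phantom shapes differ", call. = FALSE)
  ps <- geometry$pixel_size
  delta <- geometry$delta; k <- geometry$wavenumber_k
  d <- phantom$d_eff; phi <- phantom$phi

  # The dark-field term is evaluated in its expanded form with the same
  # discrete operators in both modes (the two modes differ only in the
  # coherent-flow term), so that simplified-mode data are exactly consistent
  # with the inversion's system assembly.
  gd <- gradient2d(d, ps, method)
  gir <- gradient2d(ir, ps, method)
  df_term <- d * laplacian2d(ir, ps, method) + ir * laplacian2d(d, ps, method) +
    2 * gd$x * gir$x + 2 * gd$y * gir$y
  if (mode == "simplified") {
    i_s <- ir - (delta / k) * ir * laplacian2d(phi, ps, method) + delta * df_term
  } else {
    gphi <- gradient2d(phi, ps, method)
    flow <- gradient2d(ir * gphi$x, ps, method)$x +
      gradient2d(ir * gphi$y, ps, method)$y
    i_s <- ir - (delta / k) * flow + delta * df_term
  }
  if (attenuate) i_s <- i_s * phantom$i_ob
  if (min(i_s) < 0)
    stop("forward model out of validity range: negative intensity produced",
         call. = FALSE)
  image_field(i_s, ps, units = "dimensionless")
}

#' Add detector-like Gaussian noise to an intensity field
#'
#' @param field An [image_field()] or matrix.
#' @param sd_fraction Noise standard deviation as a fraction of the field's
#'   mean intensity.
#' @param seed Optional integer seed.
#' @return Same type as the input, clipped below at 0.
#' @export
add_gaussian_noise <- function(field, sd_fraction, seed = NULL) {
  v <- as_matrix_values(field)
  noise <- with_seed(seed, matrix(stats::rnorm(length(v)), nrow(v), ncol(v)))
  out <- pmax(v + sd_fraction * mean(v) * noise, 0)
  if (inherits(field, "image_field"))
    image_field(out, field$pixel_size, units = field$units)
  else out
}

#' Simulate a full speckle data set for a phantom
#'
#' Convenience wrapper generating `n_sets` independent reference-speckle
#' fields (independent seeds emulate independent mask positions) and the
#' matching forward-modelled sample images.
#'
#' @param phantom A [generate_phantom()] object.
#' @param geometry A [geometry()] object.
#' @param n_sets Number of mask positions.
#' @param correlation_length,visibility,mean_intensity Speckle parameters
#'   passed to [generate_speckle()].
#' @param mode,attenuate,method Passed to [forward_fokker_planck()].
#' @param noise_sd Gaussian noise fraction added to the sample images
#'   (0 = noiseless).
#' @param seed Base seed; set `n` uses `seed + n`.
#' @return A [speckle_set()].
#' @export
simulate_speckle_set <- function(phantom, geometry, n_sets = 4L,
                                 correlation_length = 130, visibility = 0.4,
                                 mean_intensity = 1,
                                 mode = "simplified", attenuate = FALSE,
                                 method = "central", noise_sd = 0, seed = 1L) {
  shp <- dim(phantom$phi)
  i_r <- vector("list", n_sets); i_s <- vector("list", n_sets)
  for (n in seq_len(n_sets)) {
    ir <- generate_speckle(shp, correlation_length, geometry$pixel_size,
                           visibility = visibility,
                           mean_intensity = mean_intensity, seed = seed + n)
    is_ <- forward_fokker_planck(ir, phantom, geometry, mode = mode,
                                 attenuate = attenuate, method = method)
    if (noise_sd > 0)
      is_ <- add_gaussian_noise(is_, noise_sd, seed = seed + 10000L + n)
    i_r[[n]] <- ir; i_s[[n]] <- is_
  }
  speckle_set(i_r, i_s, geometry, min_sets = min(n_sets, 4L))
}
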