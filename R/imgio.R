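# Image containers and TIFF/YAML I/O.
#
# All arithmetic is done in double precision; files are written as 32-bit
# TIFF with an affine offset/scale recorded in a YAML sidecar so that
# arbitrary-valued signal maps (phase in radians, diffusion in um) survive a
# round trip to better than single precision.

#' Create an image field
#'
#' A 2D intensity or signal map together with its physical pixel size. This is
#' the container passed through the whole pipeline; every spectral operator is
#' unit-bearing (frequencies in 1/um), so the pixel size travels with the
#' values and is checked for consistency wherever two fields meet.
#'
#' @param values Numeric matrix, at least 16 x 16, all values finite.
#' @param pixel_size Physical side length of one pixel in micrometres (> 0).
#' @param units Free-text unit label (e.g. `"dimensionless"`, `"um"`, `"rad"`).
#' @return An object of class `image_field`: a list with elements `values`,
#'   `pixel_size`, `units`.
#' @examples
#' f <- image_field(matrix(1, 32, 32), pixel_size = 10)
#' dim(f$values)
#' @export
image_field <- function(values, pixel_size, units = "dimensionless") {
  if (!is.matrix(values) || !is.numeric(values))
    stop("values must be a numeric matrix", call. = FALSE)
  if (nrow(values) < 16L || ncol(values) < 16L)
    stop("image grid must be at least 16x16", call. = FALSE)
  if (!all(is.finite(values)))
    stop("image values must all be finite", call. = FALSE)
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L || pixel_size <= 0)
    stop("pixel_size must be a single positive number (um)", call. = FALSE)
  structure(list(values = values + 0.0, pixel_size = as.numeric(pixel_size),
                 units = as.character(units)),
            class = "image_field")
}

#' @export
print.image_field <- function(x, ...) {
  cat(sprintf("<image_field %d x %d, pixel %g um, units '%s', range [%g, %g]>\n",
              nrow(x$values), ncol(x$values), x$pixel_size, x$units,
              min(x$values), max(x$values)))
  invisible(x)
}

# hc in keV.um: lambda[um] = 1.23984e-3 / E[keV].
HC_KEV_UM <- 1.23984e-3

#' Imaging geometry
#'
#' Sample-to-detector distance, X-ray wavenumber and detector pixel size. The
#' wavenumber may be given directly or derived from the photon energy via
#' \eqn{\lambda[\mu m] = 1.23984 \times 10^{-3} / E[keV]}, \eqn{k = 2\pi/\lambda};
#' if both are given they must agree to 1e-6 relative.
#'
#' @param delta Sample-to-detector (propagation) distance in micrometres.
#' @param pixel_size Detector pixel size in micrometres.
#' @param wavenumber_k X-ray wavenumber \eqn{2\pi/\lambda} in 1/um (optional if
#'   `energy_keV` given).
#' @param energy_keV Photon energy in keV (optional if `wavenumber_k` given).
#' @return An object of class `geometry`.
#' @examples
#' g <- geometry(delta = 2e6, pixel_size = 10, energy_keV = 25)
#' g$wavenumber_k
#' @export
geometry <- function(delta, pixel_size, wavenumber_k = NULL, energy_keV = NULL) {
  if (delta <= 0) stop("delta must be > 0", call. = FALSE)
  if (pixel_size <= 0) stop("pixel_size must be > 0", call. = FALSE)
  k_from_e <- if (!is.null(energy_keV)) 2 * pi * energy_keV / HC_KEV_UM else NULL
  if (is.null(wavenumber_k)) {
    if (is.null(k_from_e))
      stop("one of wavenumber_k or energy_keV is required", call. = FALSE)
    wavenumber_k <- k_from_e
  } else if (!is.null(k_from_e)) {
    if (abs(wavenumber_k - k_from_e) > 1e-6 * k_from_e)
      stop("wavenumber_k inconsistent with energy_keV", call. = FALSE)
  }
  if (wavenumber_k <= 0) stop("wavenumber_k must be > 0", call. = FALSE)
  structure(list(delta = as.numeric(delta),
                 wavenumber_k = as.numeric(wavenumber_k),
                 energy_keV = if (is.null(energy_keV)) NA_real_ else as.numeric(energy_keV),
                 pixel_size = as.numeric(pixel_size)),
            class = "geometry")
}

#' Bundle matched reference / sample-reference speckle pairs
#'
#' One SB-PCXI "set" is a reference-speckle image \eqn{I_{R,n}} (mask in,
#' sample out) and the matched sample-reference-speckle image \eqn{I_{S,n}}
#' (mask and sample in). The rapidly-varying inversion solves four unknowns
#' per pixel and therefore needs at least four sets; the slowly-varying
#' baseline needs two.
#'
#' @param i_r,i_s Lists of `image_field`s (or plain matrices) of equal length
#'   and identical shape; intensities must be non-negative.
#' @param geometry A [geometry()] object; its pixel size must match the images.
#' @param min_sets Minimum number of sets accepted (4 for the full solve; pass
#'   2 only for the slowly-varying baseline).
#' @return An object of class `speckle_set` with elements `i_r`, `i_s` (lists
#'   of matrices), `geometry`, `n_sets`.
#' @export
speckle_set <- function(i_r, i_s, geometry, min_sets = 4L) {
  if (!inherits(geometry, "geometry")) stop("geometry must be a geometry object", call. = FALSE)
  if (length(i_r) != length(i_s))
    stop("i_r and i_s must have the same number of frames", call. = FALSE)
  n <- length(i_r)
  if (n < min_sets)
    stop(if (min_sets >= 4L) "underdetermined for RV-MIST: need at least 4 speckle sets"
         else "underdetermined baseline: need at least 2 speckle sets", call. = FALSE)
  ir <- lapply(i_r, as_matrix_values)
  is_ <- lapply(i_s, as_matrix_values)
  shp <- dim(ir[[1]])
  for (m in c(ir, is_)) {
    if (!identical(dim(m), shp)) stop("inconsistent stack: image shapes differ", call. = FALSE)
    if (min(m) < 0) stop("intensities must be >= 0 after correction", call. = FALSE)
  }
  for (f in c(i_r, i_s)) {
    if (inherits(f, "image_field") &&
        !isTRUE(all.equal(f$pixel_size, geometry$pixel_size)))
      stop("pixel_size disagrees between images and geometry", call. = FALSE)
  }
  structure(list(i_r = ir, i_s = is_, geometry = geometry, n_sets = n),
            class = "speckle_set")
}

#' @export
print.speckle_set <- function(x, ...) {
  cat(sprintf("<speckle_set: %d sets of %d x %d, Delta %g um, k %g /um, pixel %g um>\n",
              x$n_sets, nrow(x$i_r[[1]]), ncol(x$i_r[[1]]),
              x$geometry$delta, x$geometry$wavenumber_k, x$geometry$pixel_size))
  invisible(x)
}

#' Load a stack of greyscale TIFF frames
#'
#' Reads each file as a 2D greyscale array, preserving integer sample values
#' exactly as doubles (16-bit counts are not rescaled). All frames must share
#' one shape.
#'
#' @param paths Character vector of TIFF file paths, in stack order.
#' @param pixel_size Pixel size in micrometres, attached to every frame.
#' @param units Unit label attached to every frame.
#' @return A list of [image_field()]s in path order.
#' @export
load_stack <- function(paths, pixel_size, units = "counts") {
  if (length(paths) < 1L) stop("no paths given", call. = FALSE)
  frames <- lapply(paths, function(p) {
    if (!file.exists(p)) stop(sprintf("file not found: %s", p), call. = FALSE)
    v <- tiff::readTIFF(p, as.is = TRUE)
    if (!is.matrix(v))
      stop("not greyscale: frame is not a single-channel 2D image", call. = FALSE)
    v + 0.0
  })
  shp <- dim(frames[[1]])
  for (v in frames) if (!identical(dim(v), shp))
    stop("inconsistent stack: frame shapes differ", call. = FALSE)
  lapply(frames, image_field, pixel_size = pixel_size, units = units)
}

#' Dark-current and flat-field correction
#'
#' Standard detector correction: `(raw - dark) / max(flat - dark, floor)`,
#' clipped below at zero. The result is a dimensionless transmission-like
#' intensity. If several dark or flat frames are supplied they are averaged
#' (mean) first.
#'
#' @param raw An [image_field()] (or matrix) of raw counts.
#' @param dark,flat Single frames or lists of frames (averaged).
#' @param floor Small positive value clamping the flat-dark denominator.
#' @return An `image_field` with units `"dimensionless"`.
#' @export
correct_flat_dark <- function(raw, dark, flat, floor = 1e-6) {
  if (floor <= 0) stop("floor must be > 0", call. = FALSE)
  avg <- function(x) {
    if (is.list(x) && !inherits(x, "image_field"))
      Reduce(`+`, lapply(x, as_matrix_values)) / length(x)
    else as_matrix_values(x)
  }
  rawv <- as_matrix_values(raw)
  darkv <- avg(dark); flatv <- avg(flat)
  if (!identical(dim(rawv), dim(darkv)) || !identical(dim(rawv), dim(flatv)))
    stop("inconsistent stack: raw/dark/flat shapes differ", call. = FALSE)
  den <- flatv - darkv
  if (mean(den <= 0) > 0.5)
    stop("invalid flat-field: flat <= dark over more than half the frame", call. = FALSE)
  out <- pmax((rawv - darkv) / pmax(den, floor), 0)
  ps <- if (inherits(raw, "image_field")) raw$pixel_size else NULL
  if (is.null(ps)) out else image_field(out, ps, units = "dimensionless")
}

#' Write a signal map to 32-bit TIFF with a YAML sidecar
#'
#' The map is stored as a normalised 32-bit TIFF; the affine offset/scale,
#' pixel size and unit label go into `<path>.yaml`. [load_signal_map()]
#' inverts the transform, reproducing the values to better than single
#' precision.
#'
#' @param field An [image_field()] (or matrix with `pixel_size` given).
#' @param path Output TIFF path.
#' @param units Unit label recorded in the sidecar (defaults to the field's).
#' @param pixel_size Required if `field` is a bare matrix.
#' @return Invisibly, the path.
#' @export
save_signal_map <- function(field, path, units = NULL, pixel_size = NULL) {
  v <- as_matrix_values(field)
  if (!all(is.finite(v))) stop("non-finite output", call. = FALSE)
  ps <- field_pixel_size(field, pixel_size)
  if (is.null(units))
    units <- if (inherits(field, "image_field")) field$units else "dimensionless"
  offset <- min(v)
  scale <- max(v) - offset
  if (scale == 0) scale <- 1.0
  tiff::writeTIFF((v - offset) / scale, path, bits.per.sample = 32L,
                  compression = "none", reduce = FALSE)
  yaml::write_yaml(list(units = units, pixel_size = ps,
                        offset = offset, scale = scale,
                        shape = dim(v)),
                   paste0(path, ".yaml"), precision = 17L)
  invisible(path)
}

#' Read a signal map written by [save_signal_map()]
#'
#' @param path TIFF path; `<path>.yaml` must exist alongside.
#' @return An [image_field()].
#' @export
load_signal_map <- function(path) {
  side <- paste0(path, ".yaml")
  if (!file.exists(side)) stop(sprintf("missing sidecar: %s", side), call. = FALSE)
  meta <- yaml::read_yaml(side)
  v <- tiff::readTIFF(path)  # normalised [0,1]
  if (!is.matrix(v)) stop("not greyscale: stored map is not 2D", call. = FALSE)
  image_field(v * meta$scale + meta$offset, meta$pixel_size, units = meta$units)
}
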