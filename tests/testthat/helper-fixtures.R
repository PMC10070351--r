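# Shared fixtures: canonical imaging geometry, band-limited periodic test
# fields, and interior-masked scoring helpers. Everything is generated in
# code under fixed seeds.

imbl_geometry <- function(pixel_size = 10) {
  geometry(delta = 2e6, pixel_size = pixel_size, energy_keV = 25)
}

# Mean-free band-limited periodic field: random spectrum truncated at a
# fraction of Nyquist, so spectral derivatives and inversions are exact.
band_limited_field <- function(n, pixel_size = 10, kmax_frac = 0.25, seed = 42) {
  set.seed(seed)
  g <- frequency_grid(c(n, n), pixel_size)
  spec <- matrix(complex(real = stats::rnorm(n * n),
                         imaginary = stats::rnorm(n * n)), n, n)
  spec[sqrt(g$k2) > kmax_frac * pi / pixel_size] <- 0
  v <- Re(stats::fft(spec, inverse = TRUE)) / n^2
  v - mean(v)
}

interior_rmse_frac <- function(recovered, truth, mask) {
  sqrt(mean((as_mat(recovered) - truth)[mask]^2)) / diff(range(truth))
}

masked_rmse_local <- function(a, b, mask) {
  sqrt(mean((as_mat(a) - as_mat(b))[mask]^2))
}

as_mat <- function(x) if (inherits(x, "image_field")) x$values else x

# Random per-pixel linear systems held as maps, for solver oracle tests.
random_system <- function(n1, n2, n_sets, m = 4L, seed = 3, consistent = FALSE) {
  set.seed(seed)
  A <- array(stats::rnorm(n1 * n2 * n_sets * m), c(n1, n2, n_sets, m))
  x_true <- array(stats::rnorm(n1 * n2 * m), c(n1, n2, m))
  b <- array(stats::rnorm(n1 * n2 * n_sets), c(n1, n2, n_sets))
  if (consistent) {
    b[] <- 0
    for (i in seq_len(n_sets)) for (j in seq_len(m))
      b[, , i] <- b[, , i] + A[, , i, j] * x_true[, , j]
  }
  list(A = A, b = b, x_true = x_true,
       derivative_method = "central", pixel_size = 1)
}

solution_fields <- function(sol) {
  if (!is.null(sol$combo)) list(sol$combo, sol$d_eff, sol$d_x, sol$d_y)
  else list(sol$d_eff)
}
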