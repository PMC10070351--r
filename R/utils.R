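# Internal helpers shared across modules.

#' @noRd
as_matrix_values <- function(x) {
  if (inherits(x, "image_field")) return(x$values)
  if (is.matrix(x)) return(x)
  stop("expected an image_field or a numeric matrix", call. = FALSE)
}

#' @noRd
field_pixel_size <- function(x, pixel_size = NULL) {
  if (inherits(x, "image_field")) {
    if (!is.null(pixel_size) && !isTRUE(all.equal(pixel_size, x$pixel_size)))
      stop("pixel_size disagrees with the image_field's pixel size", call. = FALSE)
    return(x$pixel_size)
  }
  if (is.null(pixel_size))
    stop("pixel_size must be supplied for a bare matrix", call. = FALSE)
  pixel_size
}

# Mirror (reflective, no edge duplication) index vectors for a dimension of
# length n: position 0 maps to 2, position n+1 maps to n-1.
#' @noRd
reflect_up <- function(n) c(2:n, n - 1L)

#' @noRd
reflect_down <- function(n) c(2L, 1:(n - 1L))

# Symmetric (mirror) padding by `pad` pixels on each side of each dimension.
# Requires pad <= n - 1 in each dimension.
#' @noRd
mirror_pad <- function(m, pad) {
  if (pad <= 0) return(m)
  n1 <- nrow(m); n2 <- ncol(m)
  pad1 <- min(pad, n1 - 1L); pad2 <- min(pad, n2 - 1L)
  i <- c((pad1 + 1L):2L, 1:n1, (n1 - 1L):(n1 - pad1))
  j <- c((pad2 + 1L):2L, 1:n2, (n2 - 1L):(n2 - pad2))
  m[i, j, drop = FALSE]
}

#' @noRd
crop_pad <- function(m, pad, n1, n2) {
  if (pad <= 0) return(m)
  pad1 <- min(pad, n1 - 1L); pad2 <- min(pad, n2 - 1L)
  m[(pad1 + 1L):(pad1 + n1), (pad2 + 1L):(pad2 + n2), drop = FALSE]
}

# Chebyshev dilation of a logical mask by `by` pixels (8-neighbourhood,
# iterated). Used to carve the interior mask away from dark-field step edges.
#' @noRd
dilate_mask <- function(mask, by = 1L) {
  m <- mask
  n1 <- nrow(m); n2 <- ncol(m)
  up <- c(1L, 1:(n1 - 1L)); dn <- c(2:n1, n1)
  lf <- c(1L, 1:(n2 - 1L)); rt <- c(2:n2, n2)
  for (k in seq_len(by)) {
    m <- m | m[up, ] | m[dn, ] | m[, lf] | m[, rt] |
      m[up, lf] | m[up, rt] | m[dn, lf] | m[dn, rt]
  }
  m
}

# Root-mean-square error over an optional logical mask.
#' @noRd
masked_rmse <- function(a, b, mask = NULL) {
  d <- a - b
  if (!is.null(mask)) d <- d[mask]
  sqrt(mean(d^2))
}

#' @noRd
dynamic_range <- function(x) diff(range(x))

# Seeded evaluation that restores the caller's RNG state.
#' @noRd
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' @noRd
log_msg <- function(level, ...) {
  message(sprintf("[%s] %s", level, paste0(...)))
}
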