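# The inversion core: per-pixel four-unknown linear system over N mask
# positions, Tikhonov-regularised pixel-wise least squares, Fourier fusion of
# the dark-field, phase retrieval through the inverse Laplacian, and the
# single-material attenuation closure. The slowly-varying two-unknown
# baseline (prior art) is kept alongside for comparison experiments.

#' Assemble the per-pixel linear system
#'
#' For each mask position n the speckle Fokker-Planck equation (simplified
#' coherent flow, dark-field derivatives retained) reads, per pixel,
#' \deqn{\frac{I_{R_n}-I_{S_n}}{\Delta} = I_{R_n}\,c - D\,\nabla^2 I_{R_n}
#'   - 2 D^x I_{R_n}^x - 2 D^y I_{R_n}^y,}
#' a linear equation in the four unknowns
#' `x = [c, d_eff, d_x, d_y]` where `c` is the combined Laplacian term
#' \eqn{\nabla^2(\phi/k - D)}. This builds the N x 4 coefficient rows and the
#' right-hand sides for every pixel.
#'
#' @param speckle A [speckle_set()] with at least 4 sets.
#' @param derivative_method `"central"` (default, for measured data) or
#'   `"spectral"` (periodic; used in self-consistency tests).
#' @return An object of class `mist_system`: list with `A` (array
#'   `nrow x ncol x N x 4`), `b` (array `nrow x ncol x N`), `n_sets`,
#'   `derivative_method`, `pixel_size`, `geometry`.
#' @export
assemble_system <- function(speckle, derivative_method = c("central", "spectral")) {
  derivative_method <- match.arg(derivative_method)
  if (!inherits(speckle, "speckle_set")) stop("expected a speckle_set", call. = FALSE)
  n <- speckle$n_sets
  if (n < 4L) stop("underdetermined for RV-MIST: need at least 4 speckle sets", call. = FALSE)
  ps <- speckle$geometry$pixel_size
  delta <- speckle$geometry$delta
  shp <- dim(speckle$i_r[[1]])
  A <- array(0, c(shp[1], shp[2], n, 4L))
  b <- array(0, c(shp[1], shp[2], n))
  for (i in seq_len(n)) {
    ir <- speckle$i_r[[i]]
    g <- gradient2d(ir, ps, derivative_method)
    A[, , i, 1] <- ir
    A[, , i, 2] <- -laplacian2d(ir, ps, derivative_method)
    A[, , i, 3] <- -2 * g$x
    A[, , i, 4] <- -2 * g$y
    b[, , i] <- (ir - speckle$i_s[[i]]) / delta
  }
  structure(list(A = A, b = b, n_sets = n,
                 derivative_method = derivative_method,
                 pixel_size = ps, geometry = speckle$geometry),
            class = "mist_system")
}

# Vectorised per-pixel Cholesky solve of (A'A + alpha^2 I) x = A'b for an
# m-unknown system held as maps. Returns list(x = list of m maps,
# flagged = logical map of pixels whose unregularised pivots collapsed).
#' @noRd
solve_normal_maps <- function(A, b, alpha) {
  dm <- dim(A)
  n <- dm[3]; m <- dm[4]
  M <- vector("list", m * m); dim(M) <- c(m, m)
  v <- vector("list", m)
  for (j in seq_len(m)) {
    vj <- 0
    for (i in seq_len(n)) vj <- vj + A[, , i, j] * b[, , i]
    v[[j]] <- vj
    for (k in j:m) {
      s <- 0
      for (i in seq_len(n)) s <- s + A[, , i, j] * A[, , i, k]
      M[[j, k]] <- s
    }
  }
  scale <- 0
  for (j in seq_len(m)) scale <- scale + M[[j, j]]
  tol <- 1e-13 * (scale / m + alpha^2)
  flagged <- scale <= 0  # all-zero coefficient rows
  chol_solve <- function(a2) {
    L <- vector("list", m * m); dim(L) <- c(m, m)
    for (j in seq_len(m)) {
      pivot <- M[[j, j]] + a2
      if (j > 1) for (p in seq_len(j - 1)) pivot <- pivot - L[[j, p]]^2
      bad <- pivot <= tol
      flagged <<- flagged | bad
      L[[j, j]] <- sqrt(pmax(pivot, tol, .Machine$double.xmin))
      if (j < m) for (k in (j + 1):m) {
        s <- M[[j, k]] + if (j == k) a2 else 0
        if (j > 1) for (p in seq_len(j - 1)) s <- s - L[[j, p]] * L[[k, p]]
        L[[k, j]] <- s / L[[j, j]]
      }
    }
    y <- vector("list", m)
    for (j in seq_len(m)) {
      s <- v[[j]]
      if (j > 1) for (p in seq_len(j - 1)) s <- s - L[[j, p]] * y[[p]]
      y[[j]] <- s / L[[j, j]]
    }
    x <- vector("list", m)
    for (j in rev(seq_len(m))) {
      s <- y[[j]]
      if (j < m) for (p in (j + 1):m) s <- s - L[[p, j]] * x[[p]]
      x[[j]] <- s / L[[j, j]]
    }
    x
  }
  x <- chol_solve(alpha^2)
  if (any(flagged) && alpha == 0) {
    # rank-deficient at alpha = 0: fill those pixels from a weakly
    # regularised solve so they stay finite, and keep them flagged
    a_fb <- sqrt(tol)
    x_fb <- chol_solve(a_fb^2)
    for (j in seq_len(m)) x[[j]][flagged] <- x_fb[[j]][flagged]
  }
  list(x = x, flagged = flagged)
}

#' @noRd
resolve_alpha <- function(alpha, A) {
  if (identical(alpha, "auto")) stats::sd(A) / 1e4 else {
    if (!is.numeric(alpha) || alpha < 0)
      stop("invalid regulariser: alpha must be >= 0 or \"auto\"", call. = FALSE)
    as.numeric(alpha)
  }
}

#' Solve the four-unknown system pixel-wise
#'
#' Least-squares solution of the Tikhonov-augmented system
#' `(A; alpha I) x = (b; 0)` at every pixel, equivalent to
#' `(A'A + alpha^2 I) x = A'b`. The default regularisation parameter follows
#' the rule: standard deviation of the full coefficient matrix divided by
#' 1e4. Pixels whose unregularised system is rank-deficient are flagged and
#' filled with a weakly regularised solution.
#'
#' @param system A [assemble_system()] result (or any list with `A`, `b`).
#' @param alpha `"auto"` (sd(A)/1e4) or a numeric `>= 0`.
#' @param method `"chol"`: vectorised normal-equations Cholesky (default);
#'   `"qr"`: literal per-pixel QR on the augmented system (slow reference
#'   path, identical results to rounding).
#' @return An object of class `linear_solution`: matrices `combo` (1/um),
#'   `d_eff` (um), `d_x`, `d_y` (dimensionless), logical `flagged`, the
#'   `alpha` used, and bookkeeping fields.
#' @export
solve_pixelwise <- function(system, alpha = "auto", method = c("chol", "qr")) {
  method <- match.arg(method)
  A <- system$A; b <- system$b
  if (dim(A)[3] < 4L)
    stop("underdetermined for RV-MIST: need at least 4 speckle sets", call. = FALSE)
  alpha <- resolve_alpha(alpha, A)
  sol <- if (method == "chol") solve_normal_maps(A, b, alpha)
         else solve_qr_maps(A, b, alpha)
  structure(list(combo = sol$x[[1]], d_eff = sol$x[[2]],
                 d_x = sol$x[[3]], d_y = sol$x[[4]],
                 flagged = sol$flagged, alpha = alpha, method = method,
                 derivative_method = system$derivative_method,
                 pixel_size = system$pixel_size),
            class = "linear_solution")
}

# Reference path: per-pixel QR decomposition of the augmented system
# (A; alpha I), as used on the beamline data. O(npix) lm-size solves; meant
# for modest image sizes and cross-checking the vectorised path.
#' @noRd
solve_qr_maps <- function(A, b, alpha) {
  dm <- dim(A); n <- dm[3]; m <- dm[4]
  x <- lapply(seq_len(m), function(j) matrix(0, dm[1], dm[2]))
  flagged <- matrix(FALSE, dm[1], dm[2])
  aug <- diag(alpha, m)
  zed <- rep(0, m)
  for (i in seq_len(dm[1])) for (j in seq_len(dm[2])) {
    Ap <- matrix(A[i, j, , ], n, m)
    qrA <- qr(rbind(Ap, aug))
    if (qr(Ap)$rank < m) flagged[i, j] <- TRUE
    if (qrA$rank < m) { next }  # all-zero system: leave solution 0, flagged
    xi <- qr.coef(qrA, c(b[i, j, ], zed))
    for (p in seq_len(m)) x[[p]][i, j] <- xi[p]
  }
  list(x = x, flagged = flagged)
}

#' Fuse the solved dark-field with its gradient-integrated counterpart
#'
#' Thin wrapper applying [combine_darkfield()] to a [solve_pixelwise()]
#' solution, giving the true phase-object effective diffusion coefficient
#' \eqn{D^{True}_{eff,Phase}}.
#'
#' @param sol A `linear_solution`.
#' @param rho Cut-off parameter (um^2, `>= 0`).
#' @param grid Optional [frequency_grid()]; built from the solution if NULL.
#' @param pad Mirror-padding width in pixels applied before the spectral
#'   blend (0 = none; the maps are periodic-consistent in synthetic tests,
#'   while measured data benefit from padding).
#' @return Matrix of the fused dark-field (um).
#' @export
recover_true_darkfield <- function(sol, rho, grid = NULL, pad = 0L) {
  d <- sol$d_eff; dx <- sol$d_x; dy <- sol$d_y
  n1 <- nrow(d); n2 <- ncol(d)
  if (pad > 0) {
    d <- mirror_pad(d, pad); dx <- mirror_pad(dx, pad); dy <- mirror_pad(dy, pad)
    grid <- frequency_grid(dim(d), sol$pixel_size)
  } else if (is.null(grid)) {
    grid <- frequency_grid(dim(d), sol$pixel_size)
  }
  out <- combine_darkfield(d, dx, dy, rho, grid)
  crop_pad(out, pad, n1, n2)
}

#' Reconstruct the phase-shift map
#'
#' Inverts the simplified Fokker-Planck relation for the phase once the true
#' dark-field is known: per set n,
#' \deqn{q_n = \frac{k}{\Delta I_{R_n}}\left(I_{R_n}-I_{S_n}
#'   + \Delta \nabla^2[D^{True} I_{R_n}]\right) \approx \nabla^2\phi,}
#' with the division by \eqn{I_{R_n}} Tikhonov-regularised relative to
#' `mean(I_R^2)`. The per-set estimates are combined (`"average"`: mean over
#' n; `"per-set-lsq"`: pixel-wise least squares of the stacked equations for
#' \eqn{\nabla^2\phi}) and the inverse Laplacian applied. The result is
#' mean-free: the global phase offset is unrecoverable, so comparisons must
#' be mean-adjusted.
#'
#' @param speckle A [speckle_set()].
#' @param d_true_phase Fused dark-field map from [recover_true_darkfield()].
#' @param alpha_phase Tikhonov parameter of the inverse Laplacian (the
#'   printed operating value 1e-4 suits noisy measured data; use 0 for
#'   noiseless synthetic recovery).
#' @param grid Optional [frequency_grid()].
#' @param mode `"average"` or `"per-set-lsq"` combination over sets.
#' @param derivative_method Scheme for the Laplacian of `D I_R`.
#' @param alpha_div_rel Regularisation of the division by `I_R`, relative to
#'   `mean(I_R^2)`.
#' @param pad Mirror-padding width (pixels) around the inverse Laplacian.
#' @return Matrix of the mean-free phase-shift (rad).
#' @export
reconstruct_phase <- function(speckle, d_true_phase, alpha_phase = 1e-4,
                              grid = NULL, mode = c("average", "per-set-lsq"),
                              derivative_method = c("central", "spectral"),
                              alpha_div_rel = 1e-6, pad = 0L) {
  mode <- match.arg(mode); derivative_method <- match.arg(derivative_method)
  ps <- speckle$geometry$pixel_size
  delta <- speckle$geometry$delta; k <- speckle$geometry$wavenumber_k
  d <- as_matrix_values(d_true_phase)
  if (!all(is.finite(d))) stop("d_true_phase must be finite", call. = FALSE)
  num_acc <- 0; den_acc <- 0; q_acc <- 0
  for (i in seq_len(speckle$n_sets)) {
    ir <- speckle$i_r[[i]]
    if (mean(ir <= 0) > 0.01)
      stop("invalid reference intensity: I_R <= 0 over more than 1% of pixels",
           call. = FALSE)
    r <- ir - speckle$i_s[[i]] +
      delta * laplacian2d(d * ir, ps, derivative_method)
    if (mode == "average") {
      a_div <- alpha_div_rel * mean(ir^2)
      q_acc <- q_acc + tikhonov_quotient((k / delta) * r, ir, a_div)
    } else {
      num_acc <- num_acc + ir * (k / delta) * r
      den_acc <- den_acc + ir^2
    }
  }
  lap_phi <- if (mode == "average") q_acc / speckle$n_sets
             else num_acc / (den_acc + alpha_div_rel * mean(den_acc))
  n1 <- nrow(lap_phi); n2 <- ncol(lap_phi)
  if (pad > 0) {
    lap_phi <- mirror_pad(lap_phi, pad)
    grid <- frequency_grid(dim(lap_phi), ps)
  } else if (is.null(grid)) {
    grid <- frequency_grid(dim(lap_phi), ps)
  }
  out <- crop_pad(inverse_laplacian(lap_phi, grid, alpha_phase), pad, n1, n2)
  out - mean(out)
}

#' Single-material attenuation term
#'
#' Projection approximation for a single-material object:
#' \eqn{I_{ob} = \exp(2\phi/\gamma)} with \eqn{\gamma = \delta/\beta}. A
#' non-positive phase gives \eqn{I_{ob} \in (0, 1]}.
#'
#' @param phi Phase-shift map (rad).
#' @param gamma Material ratio `delta/beta` (> 0).
#' @return Matrix of the attenuation term.
#' @export
attenuation_term <- function(phi, gamma) {
  if (!is.numeric(gamma) || length(gamma) != 1L || gamma <= 0)
    stop("invalid material ratio: gamma must be > 0", call. = FALSE)
  exp(2 * as_matrix_values(phi) / gamma)
}

#' Attenuating-object dark-field
#'
#' Converts the phase-object dark-field into the attenuating-object form by
#' dividing out the attenuation term, with Tikhonov stabilisation:
#' \eqn{D^{True}_{eff,Atten} = D^{True}_{eff,Phase} / I_{ob}}.
#'
#' @param d_true_phase Phase-object fused dark-field (um).
#' @param i_ob Attenuation term.
#' @param alpha Tikhonov parameter of the quotient (0 = exact division).
#' @return Matrix (um).
#' @export
attenuating_darkfield <- function(d_true_phase, i_ob, alpha = 0) {
  d <- as_matrix_values(d_true_phase); io <- as_matrix_values(i_ob)
  if (!identical(dim(d), dim(io))) stop("shapes differ", call. = FALSE)
  tikhonov_quotient(d, io, alpha)
}

#' Slowly-varying two-unknown baseline
#'
#' The prior-art inversion that assumes the dark-field to be spatially slowly
#' varying: the derivative terms are dropped, leaving two unknowns
#' `[combo, d_eff]` per pixel with rows `[I_Rn, -lap(I_Rn)]`, solved by the
#' same Tikhonov-regularised least squares. Needs only two sets. Kept as the
#' comparison baseline for edge-resolution experiments.
#'
#' @inheritParams assemble_system
#' @param alpha `"auto"` or numeric `>= 0`.
#' @return List with matrices `d_eff`, `combo`, logical `flagged`, `alpha`.
#' @export
solve_slowly_varying_baseline <- function(speckle, alpha = "auto",
                                          derivative_method = c("central", "spectral")) {
  derivative_method <- match.arg(derivative_method)
  n <- speckle$n_sets
  if (n < 2L) stop("underdetermined baseline: need at least 2 speckle sets", call. = FALSE)
  ps <- speckle$geometry$pixel_size
  delta <- speckle$geometry$delta
  shp <- dim(speckle$i_r[[1]])
  A <- array(0, c(shp[1], shp[2], n, 2L))
  b <- array(0, c(shp[1], shp[2], n))
  for (i in seq_len(n)) {
    ir <- speckle$i_r[[i]]
    A[, , i, 1] <- ir
    A[, , i, 2] <- -laplacian2d(ir, ps, derivative_method)
    b[, , i] <- (ir - speckle$i_s[[i]]) / delta
  }
  alpha <- resolve_alpha(alpha, A)
  sol <- solve_normal_maps(A, b, alpha)
  list(d_eff = sol$x[[2]], combo = sol$x[[1]], flagged = sol$flagged,
       alpha = alpha)
}

#' Full multimodal reconstruction
#'
#' Orchestrates the whole inversion: assemble the per-pixel system, solve it,
#' fuse the dark-field, retrieve the phase, close with the single-material
#' attenuation term and the attenuating-object dark-field.
#'
#' @param speckle A [speckle_set()] with at least 4 sets.
#' @param rho Fourier cut-off parameter (um^2).
#' @param gamma Single-material ratio `delta/beta`.
#' @param alpha Solver regularisation (`"auto"` = sd of the coefficient
#'   matrix / 1e4).
#' @param alpha_phase Inverse-Laplacian regularisation for the phase.
#' @param derivative_method `"central"` or `"spectral"`.
#' @param phase_mode `"average"` or `"per-set-lsq"`.
#' @param pad Mirror-padding width (pixels) for the spectral stages.
#' @return An object of class `multimodal_result`: matrices `d_true_phase`
#'   (um), `phi` (rad, mean-free), `i_ob`, `d_true_atten` (um), the
#'   intermediate `solution`, and `params`.
#' @export
mist_reconstruct <- function(speckle, rho, gamma, alpha = "auto",
                             alpha_phase = 1e-4,
                             derivative_method = c("central", "spectral"),
                             phase_mode = c("average", "per-set-lsq"),
                             pad = 0L) {
  derivative_method <- match.arg(derivative_method)
  phase_mode <- match.arg(phase_mode)
  sys <- assemble_system(speckle, derivative_method)
  sol <- solve_pixelwise(sys, alpha = alpha)
  grid <- frequency_grid(dim(sol$d_eff), speckle$geometry$pixel_size)
  d_true <- recover_true_darkfield(sol, rho, grid, pad = pad)
  phi <- reconstruct_phase(speckle, d_true, alpha_phase = alpha_phase,
                           grid = grid, mode = phase_mode,
                           derivative_method = derivative_method, pad = pad)
  i_ob <- attenuation_term(phi, gamma)
  d_atten <- attenuating_darkfield(d_true, i_ob, alpha = 0)
  structure(list(d_true_phase = d_true, phi = phi, i_ob = i_ob,
                 d_true_atten = d_atten, solution = sol,
                 params = list(rho = rho, gamma = gamma,
                               alpha_solve = sol$alpha,
                               alpha_phase = alpha_phase,
                               derivative_method = derivative_method,
                               phase_mode = phase_mode, pad = pad,
                               n_sets = speckle$n_sets)),
            class = "multimodal_result")
}

#' @export
print.multimodal_result <- function(x, ...) {
  cat(sprintf(paste0("<multimodal_result %d x %d from %d sets: ",
                     "d_true in [%.3g, %.3g] um, phi in [%.3g, %.3g] rad, ",
                     "i_ob in [%.4g, %.4g], rho %g um^2>\n"),
              nrow(x$d_true_phase), ncol(x$d_true_phase), x$params$n_sets,
              min(x$d_true_phase), max(x$d_true_phase),
              min(x$phi), max(x$phi), min(x$i_ob), max(x$i_ob),
              x$params$rho))
  invisible(x)
}
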