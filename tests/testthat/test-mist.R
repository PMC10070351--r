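test_that("assembled system is exactly consistent with the forward model", {
  geom <- imbl_geometry()
  ph <- generate_phantom(c(96, 96), 10, kind = "mixed")
  for (scheme in c("central", "spectral")) {
    ss <- simulate_speckle_set(ph, geom, n_sets = 4, method = scheme, seed = 2)
    sys <- assemble_system(ss, scheme)
    # construction oracle: A . x_true = b with the matching derivative scheme
    k <- geom$wavenumber_k
    x_true <- list(laplacian2d(ph$phi, 10, scheme) / k - laplacian2d(ph$d_eff, 10, scheme),
                   ph$d_eff,
                   gradient2d(ph$d_eff, 10, scheme)$x,
                   gradient2d(ph$d_eff, 10, scheme)$y)
    resid <- 0
    for (i in 1:4) {
      r <- sys$b[, , i]
      for (j in 1:4) r <- r - sys$A[, , i, j] * x_true[[j]]
      resid <- max(resid, max(abs(r)))
    }
    expect_lt(resid, 1e-8 * max(abs(sys$b)))
  }
  # null sample: b = 0 at every pixel
  ssn <- speckle_set(ss <- lapply(1:4, function(i)
    generate_speckle(c(64, 64), 80, 10, seed = i)$values), ss, geom)
  sysn <- assemble_system(ssn)
  expect_equal(max(abs(sysn$b)), 0)
  # a flat reference field contributes only through the intensity column
  flat <- lapply(1:4, function(i) matrix(1.0, 64, 64))
  sysf <- assemble_system(speckle_set(flat, flat, geom))
  expect_equal(max(abs(sysf$A[, , , 2:4])), 0)
  expect_equal(sysf$A[, , 2, 1], matrix(1, 64, 64))
})

test_that("pixel-wise solver matches direct and normal-equation oracles", {
  # exactly-determined noiseless N = 4: equals base-R Gaussian elimination
  sys <- random_system(12, 12, 4, consistent = TRUE)
  sol <- solve_pixelwise(sys, alpha = 0)
  xs <- solution_fields(sol)
  for (px in list(c(3, 4), c(7, 11), c(12, 1))) {
    Ap <- matrix(sys$A[px[1], px[2], , ], 4, 4)
    xd <- solve(Ap, sys$b[px[1], px[2], ])
    xg <- vapply(xs, function(m) m[px[1], px[2]], 0.0)
    expect_lt(max(abs(xg - xd)) / max(abs(xd)), 1e-8)
  }
  # b = 0 gives the zero solution for any alpha
  sys0 <- sys; sys0$b[] <- 0
  for (al in c(0, 0.5)) {
    s0 <- solve_pixelwise(sys0, alpha = al)
    expect_equal(max(abs(s0$d_eff)), 0)
    expect_equal(max(abs(s0$combo)), 0)
  }
  # overdetermined consistent N = 8: residual vanishes at alpha = 0
  sys8 <- random_system(10, 10, 8, seed = 5, consistent = TRUE)
  s8 <- solve_pixelwise(sys8, alpha = 0)
  x8 <- solution_fields(s8)
  res <- 0
  for (i in 1:8) {
    r <- sys8$b[, , i]
    for (j in 1:4) r <- r - sys8$A[, , i, j] * x8[[j]]
    res <- res + r^2
  }
  expect_lt(sqrt(max(res)), 1e-8 * sqrt(mean(sys8$b^2)))
  # regularised solve equals (A'A + a^2 I) x = A'b, and the augmented-QR
  # reference path agrees with the vectorised route
  sysr <- random_system(8, 8, 6, seed = 6)
  al <- 0.37
  sc <- solve_pixelwise(sysr, alpha = al, method = "chol")
  sq <- solve_pixelwise(sysr, alpha = al, method = "qr")
  expect_equal(sc$d_eff, sq$d_eff, tolerance = 1e-10)
  expect_equal(sc$combo, sq$combo, tolerance = 1e-10)
  Ap <- matrix(sysr$A[2, 5, , ], 6, 4)
  xo <- solve(crossprod(Ap) + al^2 * diag(4), crossprod(Ap, sysr$b[2, 5, ]))
  expect_lt(max(abs(c(xo) - vapply(solution_fields(sc),
                                   function(m) m[2, 5], 0.0))), 1e-10)
  # all-zero coefficients: flagged, solution zero
  sysz <- sysr; sysz$A[4, 4, , ] <- 0; sysz$b[4, 4, ] <- 0
  sz <- solve_pixelwise(sysz, alpha = 0.1)
  expect_true(sz$flagged[4, 4])
  expect_equal(sz$d_eff[4, 4], 0)
  # auto alpha follows the sd(A)/1e4 rule
  sa <- solve_pixelwise(sysr, alpha = "auto")
  expect_equal(sa$alpha, stats::sd(sysr$A) / 1e4)
})

test_that("true dark-field recovery delegates to the spectral fusion", {
  n <- 96; ps <- 10
  grd <- frequency_grid(c(n, n), ps)
  d <- band_limited_field(n, ps, seed = 12) + 0.3
  gr <- gradient2d(d, ps, "spectral")
  sol <- structure(list(combo = d * 0, d_eff = d, d_x = gr$x, d_y = gr$y,
                        flagged = matrix(FALSE, n, n), pixel_size = ps),
                   class = "linear_solution")
  for (rho in c(0, 40)) {
    expect_equal(recover_true_darkfield(sol, rho, grd),
                 combine_darkfield(d, gr$x, gr$y, rho, grd))
  }
  # inherited oracles through the wrapper: identity at rho = 0 and
  # consistency of the blend with the source field
  expect_lt(max(abs(recover_true_darkfield(sol, 0, grd) - d)), 1e-12)
  expect_lt(sqrt(mean((recover_true_darkfield(sol, 1e3 * ps^2, grd) - d)^2)),
            1e-6 * diff(range(d)))
})

test_that("phase retrieval inverts the simplified model", {
  geom <- imbl_geometry()
  # null data with zero dark-field: phi identically zero
  flat <- lapply(1:4, function(i) generate_speckle(c(96, 96), 80, 10, seed = i)$values)
  ssn <- speckle_set(flat, flat, geom)
  phi0 <- reconstruct_phase(ssn, matrix(0, 96, 96), alpha_phase = 0)
  expect_lt(max(abs(phi0)), 1e-12)
  # pure phase object: recovered phi matches the phantom up to its mean
  ph <- generate_phantom(c(128, 128), 10, kind = "smooth")
  ph$d_eff[] <- 0
  ss <- simulate_speckle_set(ph, geom, n_sets = 4, method = "central", seed = 3)
  for (mode in c("average", "per-set-lsq")) {
    phi <- reconstruct_phase(ss, matrix(0, 128, 128), alpha_phase = 0, mode = mode)
    expect_equal(mean(phi), 0, tolerance = 1e-10)  # gauge: mean-free
    expect_lt(sqrt(mean((phi - (ph$phi - mean(ph$phi)))^2)),
              0.02 * diff(range(ph$phi)))
  }
  # doubling Delta in forward and inverse leaves phi unchanged
  geom2 <- geometry(delta = 4e6, pixel_size = 10, energy_keV = 25)
  ss2 <- simulate_speckle_set(ph, geom2, n_sets = 4, method = "central", seed = 3)
  phi1 <- reconstruct_phase(ss, matrix(0, 128, 128), alpha_phase = 0)
  phi2 <- reconstruct_phase(ss2, matrix(0, 128, 128), alpha_phase = 0)
  expect_equal(phi1, phi2, tolerance = 1e-8)
  # reference intensity must be positive
  bad <- lapply(flat, function(m) { m[, 1:40] <- 0; m })
  ssb <- speckle_set(bad, bad, geom)
  expect_error(reconstruct_phase(ssb, matrix(0, 96, 96)),
               "invalid reference intensity")
})

test_that("attenuation closure follows the single-material projection", {
  expect_equal(attenuation_term(matrix(0, 16, 16), 1403), matrix(1, 16, 16))
  expect_equal(attenuation_term(matrix(-701.5, 16, 16), 1403)[1, 1], exp(-1))
  expect_error(attenuation_term(matrix(0, 16, 16), -2), "invalid material ratio")
  # attenuating dark-field: exact quotient in the alpha = 0 limit
  d <- matrix(4e-5, 16, 16)
  expect_equal(attenuating_darkfield(d, matrix(1, 16, 16), 0), d)
  expect_equal(attenuating_darkfield(d, matrix(0.5, 16, 16), 0)[1, 1], 8e-5)
})

test_that("slowly-varying baseline agrees off edges and fails on them", {
  geom <- imbl_geometry()
  # b = 0: both unknowns zero
  flat <- lapply(1:2, function(i) generate_speckle(c(64, 64), 80, 10, seed = i)$values)
  sv0 <- solve_slowly_varying_baseline(speckle_set(flat, flat, geom, min_sets = 2L),
                                       alpha = 0)
  expect_equal(max(abs(sv0$d_eff)), 0)
  expect_equal(max(abs(sv0$combo)), 0)
  expect_error(solve_slowly_varying_baseline(
    speckle_set(flat[1], flat[1], geom, min_sets = 1L)), "underdetermined baseline")
  # spatially constant dark-field: the dropped derivative terms truly vanish,
  # so baseline and RV solutions coincide
  ph <- generate_phantom(c(128, 128), 10, kind = "smooth")
  ph$d_eff[] <- 5e-6
  ss <- simulate_speckle_set(ph, geom, n_sets = 4, method = "central", seed = 4)
  rv <- solve_pixelwise(assemble_system(ss, "central"), alpha = 0)
  sv <- solve_slowly_varying_baseline(ss, alpha = 0)
  expect_lt(sqrt(mean((rv$d_eff - sv$d_eff)^2)) / 5e-6, 0.01)
  # sharp-edged dark-field: baseline error at edges strictly exceeds RV error
  phs <- generate_phantom(c(128, 128), 10, kind = "sharp")
  sss <- simulate_speckle_set(phs, geom, n_sets = 6, method = "central", seed = 5)
  rvs <- solve_pixelwise(assemble_system(sss, "central"), alpha = 0)
  svs <- solve_slowly_varying_baseline(sss, alpha = 0)
  grd <- frequency_grid(c(128, 128), 10)
  d_rv <- recover_true_darkfield(rvs, 27, grd)
  band <- !phs$interior_mask
  expect_gt(masked_rmse_local(svs$d_eff, phs$d_eff, band),
            masked_rmse_local(d_rv, phs$d_eff, band))
})

test_that("full pipeline recovers all three signals and derivative consistency", {
  geom <- imbl_geometry()
  # null sample in, null signals out
  flat <- lapply(1:4, function(i) generate_speckle(c(96, 96), 80, 10, seed = i)$values)
  ssn <- speckle_set(flat, flat, geom)
  resn <- mist_reconstruct(ssn, rho = 27, gamma = 1403, alpha = 0, alpha_phase = 0)
  expect_lt(max(abs(resn$d_true_phase)), 1e-12)
  expect_lt(max(abs(resn$phi)), 1e-12)
  expect_equal(resn$i_ob, matrix(1, 96, 96), tolerance = 1e-12)
  # smooth phantom round trip at modest size
  ph <- generate_phantom(c(128, 128), 10, kind = "smooth")
  ss <- simulate_speckle_set(ph, geom, n_sets = 4, method = "central", seed = 6)
  res <- mist_reconstruct(ss, rho = 27, gamma = ph$gamma, alpha = 0, alpha_phase = 0)
  expect_lt(masked_rmse_local(res$d_true_phase, ph$d_eff, ph$interior_mask) /
              diff(range(ph$d_eff)), 0.02)
  expect_lt(sqrt(mean((res$phi - (ph$phi - mean(ph$phi)))^2)) /
              diff(range(ph$phi)), 0.02)
  # result invariant: d_true_atten is the Tikhonov quotient of the two maps
  expect_equal(res$d_true_atten,
               tikhonov_quotient(res$d_true_phase, res$i_ob, 0),
               tolerance = 1e-12)
  expect_true(all(res$i_ob[res$phi <= 0] <= 1 + 1e-6))
  # derivative self-consistency of the solved maps on a smooth phantom
  ss8 <- simulate_speckle_set(ph, geom, n_sets = 8, method = "central", seed = 6)
  sol <- solve_pixelwise(assemble_system(ss8, "central"), alpha = 0)
  g <- gradient2d(sol$d_eff, 10, "central")
  num <- sqrt(mean((g$x - sol$d_x)[ph$interior_mask]^2 +
                     (g$y - sol$d_y)[ph$interior_mask]^2))
  den <- sqrt(mean(sol$d_x[ph$interior_mask]^2 + sol$d_y[ph$interior_mask]^2))
  expect_lt(num / den, 0.05)
})

test_that("reconstruction quality degrades smoothly, never abruptly, with noise", {
  geom <- imbl_geometry()
  ph <- generate_phantom(c(128, 128), 10, kind = "mixed")
  rng <- diff(range(ph$d_eff))
  err <- vapply(c(0, 0.005, 0.01), function(ns) {
    ss <- simulate_speckle_set(ph, geom, n_sets = 8, method = "central",
                               noise_sd = ns, seed = 11)
    r <- mist_reconstruct(ss, rho = 27, gamma = ph$gamma, alpha = "auto",
                          alpha_phase = 1e-4)
    masked_rmse_local(r$d_true_phase, ph$d_eff, ph$interior_mask) / rng
  }, 0.0)
  expect_true(all(diff(err) > 0))          # more noise, more error
  expect_lt(err[3], 2.5 * err[2] + 1e-12)  # and no cliff between noise levels
  expect_true(all(is.finite(err)))
})
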