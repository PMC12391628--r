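test_that("reference extraction averages labeled voxels then normalizes", {
  rs <- tiny_refset()
  set.seed(21)
  grid <- c(3, 4, 4)
  vol <- pa_volume(array(runif(6 * prod(grid)), dim = c(6, grid)),
                   wavelengths_in_vivo())
  # single-voxel ROI: that voxel's spectrum over its maximum
  roi1 <- array(0L, dim = grid); roi1[2, 3, 1] <- 1L
  sp <- extract_reference_spectrum(vol, roi1, 1)
  v <- vol$data[, 2, 3, 1]
  expect_equal(sp$values, v / max(v))

  # homogeneous ROI in spectrum s -> s / max(s)
  s <- c(1, 3, 2, 5, 4, 2)
  vol2 <- pa_volume(array(rep(s, prod(grid)), dim = c(6, grid)),
                    wavelengths_in_vivo())
  roi2 <- array(0L, dim = grid); roi2[1:2, , ] <- 2L
  expect_equal(extract_reference_spectrum(vol2, roi2, 2)$values, s / 5)

  # random 10-voxel ROI vs brute-force loop-over-voxels oracle
  roi3 <- array(0L, dim = grid)
  pick <- sample(prod(grid), 10)
  roi3[pick] <- 3L
  got <- extract_reference_spectrum(vol, roi3, 3)$values
  acc <- numeric(6)
  for (s_ in 1:grid[1]) for (r_ in 1:grid[2]) for (c_ in 1:grid[3])
    if (roi3[s_, r_, c_] == 3L) acc <- acc + vol$data[, s_, r_, c_]
  oracle <- (acc / 10) / max(acc / 10)
  expect_equal(got, oracle)

  expect_error(extract_reference_spectrum(vol, roi1, 9), "absent")
  volz <- pa_volume(array(0, dim = c(6, grid)), wavelengths_in_vivo())
  expect_error(extract_reference_spectrum(volz, roi1, 1), "all zero")
})

test_that("NNLS recovers dictionary atoms and noiseless mixtures", {
  rs <- tiny_refset()
  wl <- wavelengths_in_vivo()
  # exact dictionary atom
  atom <- pa_spectrum(wl, rs$spectra[, "hbo2"])
  r <- unmix_voxel(atom, rs)
  expect_equal(unname(r$abundances),
               c(0, 1), tolerance = 1e-8)
  expect_lt(r$residual, 1e-8)
  # noiseless 0.3 / 0.7 mixture
  mix <- pa_spectrum(wl, 0.3 * rs$spectra[, "aunr_cell"] +
                       0.7 * rs$spectra[, "hbo2"])
  r2 <- unmix_voxel(mix, rs)
  expect_equal(unname(r2$abundances), c(0.3, 0.7), tolerance = 1e-6)
  # and against the exhaustive grid-search oracle
  oracle <- oracle_grid_nnls2(rs$spectra, mix$values)
  expect_equal(unname(r2$abundances), oracle, tolerance = 2e-3)
  # all-zero spectrum
  r3 <- unmix_voxel(pa_spectrum(wl, rep(0, 6)), rs)
  expect_equal(unname(r3$abundances), c(0, 0))
  expect_equal(r3$residual, 0)
  expect_error(unmix_voxel(pa_spectrum(c(680, 730), c(1, 1)), rs),
               "mismatch")
})

test_that("NNLS equals unconstrained least squares when that is feasible", {
  set.seed(4)
  for (i in 1:20) {
    C <- matrix(runif(6 * 3, 0.1, 1), 6, 3)
    a_true <- runif(3, 0.2, 1)
    d <- as.numeric(C %*% a_true) + rnorm(6, sd = 0.01)
    ls <- qr.solve(C, d)
    if (all(ls >= 0)) {
      got <- unmix_voxel(pa_spectrum(wavelengths_in_vivo(), pmax(d, 0)),
                         new_refset3(C))
      expect_equal(unname(got$abundances),
                   unname(qr.solve(sweep(C, 2, apply(C, 2, max), "/"),
                                   pmax(d, 0))),
                   tolerance = 1e-6)
    }
  }
})

test_that("NNLS matches the grid-search oracle on random 2-component problems", {
  set.seed(99)
  for (i in 1:20) {
    p <- random_unmix_problem()
    expect_lt(max(abs(nnls_abundances(p$C, p$d) -
                        oracle_grid_nnls2(p$C, p$d))), 2e-3)
  }
})

test_that("unmixing is scale-equivariant and permutation-covariant", {
  rs <- tiny_refset()
  wl <- wavelengths_in_vivo()
  set.seed(12)
  for (i in 1:10) {
    v <- runif(6)
    base <- unmix_voxel(pa_spectrum(wl, v), rs)
    # residual never exceeds the input norm (abundance 0 is feasible)
    expect_lte(base$residual, sqrt(sum(v^2)) + 1e-12)
    # scaling by c > 0 scales abundances and residual by c
    c_ <- runif(1, 0.5, 3)
    sc <- unmix_voxel(pa_spectrum(wl, c_ * v), rs)
    expect_equal(sc$abundances, c_ * base$abundances, tolerance = 1e-8)
    expect_equal(sc$residual, c_ * base$residual, tolerance = 1e-8)
    # permuting dictionary columns permutes abundances identically
    perm <- new_ref_spectra_public(rs$wavelengths,
                                   rev(rs$components),
                                   rs$spectra[, rev(rs$components)])
    pr <- unmix_voxel(pa_spectrum(wl, v), perm)
    expect_equal(pr$abundances[names(base$abundances)],
                 base$abundances, tolerance = 1e-10)
  }
})

test_that("volume unmixing reduces to per-voxel unmixing and recovers truth", {
  rs <- make_reference_spectra(wavelengths_in_vivo(),
                               default_spectrum_configs())
  # single voxel volume == unmix_voxel
  v <- c(0.4, 0.5, 0.6, 1.0, 0.9, 0.5)
  vol1 <- pa_volume(array(v, dim = c(6, 1, 1, 1)), wavelengths_in_vivo())
  cm <- unmix_volume(vol1, rs)
  uv <- unmix_voxel(pa_spectrum(wavelengths_in_vivo(), v), rs)
  expect_equal(as.numeric(cm$abundance), unname(uv$abundances))
  expect_equal(as.numeric(cm$residual), uv$residual)

  # noiseless phantom round trip: mean absolute error < 1e-6
  cfg <- phantom_config(grid = c(4, 8, 8),
                        geometry = list(
                          list(component = "aunr_cell",
                               region = region_sphere(c(2, 4, 4), 2),
                               level = 0.8),
                          list(component = "hbo2",
                               region = region_box(c(1, 4), c(1, 8),
                                                   c(1, 4)), level = 0.5),
                          list(component = "melanin",
                               region = region_box(c(1, 1), c(1, 8),
                                                   c(1, 8)), level = 0.2)),
                        noise_sd = 0, seed = 2)
  sim <- simulate_phantom_volume(rs, cfg)
  est <- unmix_volume(sim$volume, rs)
  expect_lt(mean(abs(est$abundance - sim$truth$abundance)), 1e-6)
})

test_that("unmixing a noisy phantom still localizes the nanorod signal", {
  rs <- make_reference_spectra(wavelengths_in_vivo(),
                               default_spectrum_configs())
  cfg <- phantom_config(grid = c(4, 8, 8),
                        geometry = list(
                          list(component = "aunr_cell",
                               region = region_sphere(c(2, 4, 4), 2),
                               level = 1),
                          list(component = "hbo2",
                               region = region_box(c(1, 4), c(1, 8),
                                                   c(1, 8)), level = 0.4)),
                        noise_sd = 0.05, seed = 7)  # 5% of peak signal
  sim <- simulate_phantom_volume(rs, cfg)
  est <- unmix_volume(sim$volume, rs)
  k <- match("aunr_cell", rs$components)
  expect_gt(cor(as.numeric(est$abundance[k, , , ]),
                as.numeric(sim$truth$abundance[k, , , ])), 0.9)
})

test_that("relative spectral difference follows the normalize-then-divide rule", {
  wl <- c(700, 800)
  a <- pa_spectrum(wl, c(2, 1))
  b <- pa_spectrum(wl, c(1, 2))
  # a_norm = (1, 0.5), b_norm = (0.5, 1) -> (1.0, -0.5)
  expect_equal(relative_spectral_difference(a, b), c(1, -0.5))
  expect_equal(relative_spectral_difference(a, a), c(0, 0))
  # global scale invariance
  a2 <- pa_spectrum(wl, 2 * a$values)
  expect_equal(relative_spectral_difference(a2, a), c(0, 0))
  expect_error(relative_spectral_difference(a, pa_spectrum(wl, c(0, 1))),
               "zero")
  expect_error(
    relative_spectral_difference(a, pa_spectrum(c(700, 900), c(1, 1))),
    "mismatch")
})
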