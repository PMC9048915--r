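test_that("flat responses with flat calibration give flat unit sensitivity", {
  grid <- default_grid()
  p <- default_nr_params()
  flashes <- spectral_flash_series(grid, rep(30, length(grid)))
  sens <- derive_sensitivity(flashes, p, flat_calibration(grid))
  expect_equal(sens$sensitivity, rep(1, length(grid)))
})

test_that("the derive step inverts the generator exactly without noise", {
  grid <- default_grid()
  p <- default_nr_params()
  calib <- xenon_calibration(grid)
  s_true <- evaluate_template(pigment_template(470), grid)
  flashes <- spectral_flash_series(
    grid, nr_response(calib$relative_flux * s_true, p))
  sens <- derive_sensitivity(flashes, p, calib)
  # the only discrepancy is the max-renormalization on the 10 nm grid
  expect_lt(max(abs(sens$sensitivity - s_true)), 1e-5)
})

test_that("doubling calibration flux at one wavelength halves sensitivity there", {
  grid <- default_grid()
  p <- naka_rushton_params(60, 1 / 9, 1)     # n = 1
  s_true <- evaluate_template(pigment_template(470), grid)
  flashes <- spectral_flash_series(grid, nr_response(s_true, p))
  i <- which(grid == 400)
  flux <- rep(1, length(grid)); flux[i] <- 2
  sens1 <- derive_sensitivity(flashes, p, flat_calibration(grid))
  sens2 <- derive_sensitivity(flashes, p, flux_calibration(grid, flux))
  # flux_calibration max-normalizes, so compare ratios relative to a
  # wavelength whose flux did not change
  j <- which(grid == 470)
  expect_equal(sens2$sensitivity[i] / sens2$sensitivity[j],
               0.5 * sens1$sensitivity[i] / sens1$sensitivity[j],
               tolerance = 1e-9)
})

test_that("a flat calibration is a no-op regardless of its absolute level", {
  grid <- default_grid()
  p <- default_nr_params()
  s_true <- evaluate_template(pigment_template(555), grid)
  flashes <- spectral_flash_series(grid, nr_response(0.8 * s_true, p))
  a <- derive_sensitivity(flashes, p, flat_calibration(grid))
  b <- derive_sensitivity(flashes, p,
                          flux_calibration(grid, rep(0.37, length(grid))))
  expect_equal(a$sensitivity, b$sensitivity)
})

test_that("saturated and impossible responses are handled explicitly", {
  grid <- default_grid()
  p <- default_nr_params()
  v <- nr_response(evaluate_template(pigment_template(470), grid), p)
  v[grid == 470] <- 0.97 * p$v_max
  sens <- derive_sensitivity(spectral_flash_series(grid, v), p,
                             flat_calibration(grid))
  expect_true(is.na(sens$sensitivity[grid == 470]))
  v[grid == 470] <- p$v_max + 1
  # with exclusion active, an impossible response is excluded like any
  # other saturated one; with exclusion off it is a hard error
  sens2 <- derive_sensitivity(spectral_flash_series(grid, v), p,
                              flat_calibration(grid))
  expect_true(is.na(sens2$sensitivity[grid == 470]))
  expect_error(derive_sensitivity(spectral_flash_series(grid, v), p,
                                  flat_calibration(grid),
                                  saturation_frac = 1), "470")
  calib_short <- flat_calibration(seq(300, 690, 10))
  expect_error(derive_sensitivity(spectral_flash_series(grid, pmin(v, 50)),
                                  p, calib_short), "grid")
})

test_that("averaging one cell is the identity with zero SE", {
  sens <- template_sens(470)
  avg <- average_cells(list(sens))
  expect_equal(avg$sensitivity, sens$sensitivity)
  expect_equal(avg$se, rep(0, length(sens$wavelengths)))
  expect_equal(avg$n_cells, 1L)
})

test_that("mirror-noise replicates average back to the template", {
  grid <- default_grid()
  base <- evaluate_template(pigment_template(445), grid)
  set.seed(61)
  eps <- rnorm(length(grid), 0, 0.02)
  up <- pmin(pmax(base + eps, 0), 1)
  noise_applied <- up - base                   # clipping may trim eps
  dn <- pmax(base - noise_applied, 0)
  avg <- average_cells(list(spectral_sensitivity(grid, up),
                            spectral_sensitivity(grid, dn)))
  # inputs are renormalized individually, so allow a small tolerance
  expect_equal(avg$sensitivity, base / max(base), tolerance = 0.02)
})

test_that("replicate averaging yields positive SE off peak", {
  set.seed(71)
  cells <- lapply(1:7, function(i) {
    rec <- generate_recording(
      photoreceptor_model(c("470" = 1), label = "blue"),
      noise = noise_model(1))
    analyze_recording(rec)$sensitivity
  })
  avg <- average_cells(cells)
  expect_equal(avg$n_cells, 7L)
  off_peak <- avg$wavelengths %in% c(350, 400, 550)
  expect_true(all(avg$se[off_peak] > 0))
  expect_equal(max(avg$sensitivity, na.rm = TRUE), 1)
})

test_that("cells on mixed grids cannot be averaged", {
  expect_error(average_cells(list(template_sens(470),
                                  template_sens(470, seq(310, 700, 10)))),
               "different spectral grids")
})

test_that("a noiseless template self-fit recovers lambda_max to 0.1 nm", {
  fit <- fit_lambda_max(template_sens(445))
  expect_equal(fit$lambda_max_hat, 445, tolerance = 0.11)
  # residual comes only from max-renormalization on the coarse grid
  expect_lt(fit$rss, 1e-3)
})

test_that("the optimizer matches a 0.1 nm dense-grid oracle", {
  set.seed(81)
  grid <- default_grid()
  for (rep in 1:20) {
    lmax <- runif(1, 350, 600)
    base <- evaluate_template(pigment_template(lmax), grid)
    y <- pmax(base + rnorm(length(grid), 0, 0.02), 0)
    sens <- spectral_sensitivity(grid, y)
    fit <- suppressWarnings(fit_lambda_max(sens))
    dense <- seq(300, 700, by = 0.1)
    rss <- vapply(dense, function(l) {
      tpl <- pigment_template(l)
      sum((sens$sensitivity - evaluate_template(tpl, grid))^2)
    }, numeric(1))
    oracle <- dense[which.min(rss)]
    expect_lt(abs(fit$lambda_max_hat - oracle), 0.2)
  }
})

test_that("a fit at the search boundary warns", {
  sens <- template_sens(350)
  expect_warning(fit_lambda_max(sens, search_bounds = c(360, 700)),
                 "boundary")
})

test_that("end-to-end recovery holds for every reported pigment peak", {
  # direct-sensitivity noise (relative units), 50 replicates per peak
  grid <- default_grid()
  set.seed(91)
  for (lmax in c(355, 365, 390, 445, 470, 555, 570)) {
    base <- evaluate_template(pigment_template(lmax), grid)
    hats <- replicate(50, {
      y <- pmax(base + rnorm(length(grid), 0, 0.05), 0)
      suppressWarnings(
        fit_lambda_max(spectral_sensitivity(grid, y)))$lambda_max_hat
    })
    expect_lt(abs(mean(hats) - lmax), 3)
  }
})

test_that("normalization is conserved at every stage", {
  set.seed(101)
  rec <- generate_recording(photoreceptor_model(c("470" = 1)),
                            noise = noise_model(1))
  ana <- analyze_recording(rec)
  expect_equal(max(ana$sensitivity$sensitivity, na.rm = TRUE), 1)
  avg <- average_cells(list(ana$sensitivity, ana$sensitivity))
  expect_equal(max(avg$sensitivity, na.rm = TRUE), 1)
})
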