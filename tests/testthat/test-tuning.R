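test_that("zero filter density is the identity", {
  tpl <- pigment_template(570)
  f <- filter_spec(560, density = 0)
  s <- filtered_sensitivity(tpl, f, fine_grid())
  expect_equal(s$sensitivity, evaluate_template(tpl, fine_grid()))
})

test_that("increasing pigment density red-shifts and narrows the curve", {
  tpl <- pigment_template(570)
  lam <- fine_grid()
  fw0 <- half_width(tpl)
  peak0 <- template_peak(tpl)
  peaks <- c(); fws <- c()
  for (d in c(0.5, 1, 2, 4)) {
    s <- filtered_sensitivity(tpl, filter_spec(560, density = d), lam)
    peaks <- c(peaks, peak_wavelength(s))
    fws <- c(fws, half_width(s))
  }
  expect_true(all(diff(peaks) >= 0))
  expect_true(all(diff(fws) <= 0))
  expect_true(all(peaks >= peak0))
  expect_true(all(fws <= fw0))
})

test_that("filtering narrows for any positive density", {
  tpl <- pigment_template(570)
  fw0 <- half_width(tpl)
  for (d in c(0.1, 0.7, 3))
    expect_lt(half_width(filtered_sensitivity(
      tpl, filter_spec(560, density = d), fine_grid())), fw0)
})

test_that("calibrating to the unfiltered peak returns zero density", {
  cal <- calibrate_filter(pigment_template(570), 570)
  expect_equal(cal$density, 0)
})

test_that("bisection agrees with a brute-force density sweep", {
  tpl <- pigment_template(570)
  f <- filter_spec(560)
  cal <- calibrate_filter(tpl, 590, f)
  expect_gt(cal$density, 0)
  lam <- fine_grid()
  base <- evaluate_template(tpl, lam)
  absorb <- pigment_absorbance(f, lam)
  sweep <- seq(0, 10, by = 0.01)
  peaks <- vapply(sweep, function(d) lam[which.max(base * 10^(-d * absorb))],
                  numeric(1))
  d_sweep <- sweep[min(which(peaks >= 590))]
  expect_lt(abs(cal$density - d_sweep), 0.011)
})

test_that("the calibrated red filter reproduces the yellow-orange cell", {
  tpl <- pigment_template(570)
  cal <- calibrate_filter(tpl, 590)
  s <- filtered_sensitivity(tpl, cal, fine_grid())
  expect_lt(abs(peak_wavelength(s) - 590), 2)
  fw <- half_width(s)
  expect_gte(fw, 65); expect_lte(fw, 75)
  expect_gte(half_width(tpl) - fw, 35)
})

test_that("an unreachable target density errors", {
  expect_error(calibrate_filter(pigment_template(570), 690,
                                filter_spec(560, shape = "ommochrome")),
               "unreachable")
  expect_error(calibrate_filter(pigment_template(570), 560), "red-shift")
})

test_that("a single-opsin model reproduces its template", {
  m <- photoreceptor_model(c("470" = 1))
  s <- coexpression_sensitivity(m, fine_grid())
  expect_equal(s$sensitivity, evaluate_template(pigment_template(470),
                                                fine_grid()),
               tolerance = 1e-5)
})

test_that("a 50/50 blue-green mixture keeps both member peaks high", {
  m <- photoreceptor_model(c("470" = 0.5, "570" = 0.5))
  s <- coexpression_sensitivity(m, fine_grid())
  v <- s$sensitivity
  lam <- fine_grid()
  expect_gte(v[lam == 470], 0.5)
  expect_gte(v[lam == 570], 0.5)
})

test_that("mixtures never narrow below the narrowest member", {
  set.seed(111)
  for (i in 1:10) {
    l1 <- runif(1, 380, 480); l2 <- runif(1, 500, 600)
    w <- runif(1, 0.2, 0.8)
    m <- photoreceptor_model(stats::setNames(c(w, 1 - w), c(l1, l2)))
    fw_mix <- half_width(coexpression_sensitivity(m, fine_grid()))
    fw_members <- c(half_width(pigment_template(l1)),
                    half_width(pigment_template(l2)))
    expect_gte(fw_mix, min(fw_members) - 1e-6)
  }
})

test_that("model invariants are enforced", {
  expect_error(photoreceptor_model(numeric(0)), "at least one")
  expect_error(photoreceptor_model(c("470" = -1, "570" = 2)), "non-negative")
  m <- photoreceptor_model(c("470" = 2, "570" = 6))
  expect_equal(sum(m$weights), 1, tolerance = 1e-9)
})

test_that("mixture_fit recovers pure and mixed generators", {
  sens <- template_sens(470)
  fit <- mixture_fit(sens, c(470, 570))
  expect_lt(abs(fit$weights[["470"]] - 1), 1e-3)
  expect_lt(fit$weights[["570"]], 1e-3)

  grid <- default_grid()
  mixed <- 0.3 * evaluate_template(pigment_template(445), grid) +
    0.7 * evaluate_template(pigment_template(570), grid)
  fit2 <- mixture_fit(spectral_sensitivity(grid, mixed), c(445, 570))
  expect_lt(abs(fit2$weights[["445"]] - 0.3), 0.02)
  expect_lt(abs(fit2$weights[["570"]] - 0.7), 0.02)
})

test_that("NNLS matches a dense simplex-grid oracle", {
  set.seed(121)
  grid <- default_grid()
  for (rep in 1:10) {
    l1 <- round(runif(1, 380, 470)); l2 <- round(runif(1, 520, 600))
    t1 <- evaluate_template(pigment_template(l1), grid)
    t2 <- evaluate_template(pigment_template(l2), grid)
    w_true <- runif(1)
    y <- pmax(w_true * t1 + (1 - w_true) * t2 +
                rnorm(length(grid), 0, 0.02), 0)
    sens <- spectral_sensitivity(grid, y)
    fit <- mixture_fit(sens, c(l1, l2))
    # oracle: weights on a 0.01-step simplex, scale optimal in closed form
    ws <- seq(0, 1, by = 0.01)
    rss <- vapply(ws, function(w) {
      curve <- w * t1 + (1 - w) * t2
      a <- sum(sens$sensitivity * curve) / sum(curve^2)
      sum((sens$sensitivity - a * curve)^2)
    }, numeric(1))
    w_oracle <- ws[which.min(rss)]
    expect_lt(abs(fit$weights[[1]] - w_oracle), 0.015)
    expect_lte(fit$rss, min(rss) + 1e-8)
  }
})

test_that("no plain mixture reproduces the packaged broadband cell", {
  grid <- default_grid()
  bb <- heliconius_models("melpomene")$models$broadband
  sens_bb <- spectral_sensitivity(grid, model_sensitivity(bb, grid))
  mix <- mixture_fit(sens_bb, c(470, 570))
  green <- template_sens(570)
  single <- fit_lambda_max(green)
  expect_gt(mix$rss, single$rss + 0.1)
})

test_that("degenerate mixture inputs error", {
  sens <- template_sens(470)
  expect_error(mixture_fit(sens, numeric(0)), "at least one")
})

test_that("tabulated pigment absorbance is honoured", {
  tab <- data.frame(wavelength_nm = seq(300, 700, 50),
                    absorbance = c(1, 1, 1, 1, 1, 0.8, 0.1, 0, 0))
  f <- filter_spec(shape = "tabulated", density = 1, absorbance_table = tab)
  a <- pigment_absorbance(f, c(300, 650, 700))
  expect_equal(a[1], 1)
  expect_lt(a[3], 0.01)
  expect_error(filter_spec(shape = "tabulated"), "absorbance_table")
})
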