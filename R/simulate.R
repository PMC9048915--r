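# Synthetic intracellular-recording generator: VlogI series plus spectral
# flash responses from configurable photoreceptor cell models.

#' Additive noise model for synthetic recordings
#'
#' @param response_sd SD (mV) of additive Gaussian noise on every
#'   response; negative responses are clipped to 0.
#' @param sensitivity_sd SD (relative units) of additive noise applied
#'   directly to sensitivity curves in direct-sensitivity mode.
#' @param seed Optional integer seed; when set, generation is reproducible.
#' @return Object of class `noise_model`.
#' @export
noise_model <- function(response_sd = 1, sensitivity_sd = 0, seed = NULL) {
  if (response_sd < 0 || sensitivity_sd < 0) stop("noise SDs must be >= 0")
  structure(list(response_sd = response_sd, sensitivity_sd = sensitivity_sd,
                 seed = seed), class = "noise_model")
}

#' Default generator Naka-Rushton parameters
#'
#' Vmax = 60 mV (a healthy large-amplitude cell), n = 1, and K placed so
#' the brightest unattenuated flash (relative flux 1) sits at 90% of Vmax.
#'
#' @param v_max Maximum response (mV).
#' @param n Slope.
#' @param top_fraction Response fraction reached at relative flux 1.
#' @return A [naka_rushton_params()].
#' @export
default_nr_params <- function(v_max = 60, n = 1, top_fraction = 0.9) {
  # V/Vmax = 1/(1 + K^n) = top_fraction  =>  K = ((1-f)/f)^(1/n)
  k <- ((1 - top_fraction) / top_fraction)^(1 / n)
  naka_rushton_params(v_max, k, n)
}

#' A synthetic or recorded cell dataset
#'
#' @param vlogi A [vlogi_curve()].
#' @param spectral A [spectral_flash_series()].
#' @param label Optional cell label.
#' @param truth Optional generating [photoreceptor_model()] (synthetic
#'   data only).
#' @return Object of class `response_recording`.
#' @export
response_recording <- function(vlogi, spectral, label = NA_character_,
                               truth = NULL) {
  stopifnot(inherits(vlogi, "vlogi_curve"),
            inherits(spectral, "spectral_flash_series"))
  structure(list(vlogi = vlogi, spectral = spectral, label = label,
                 truth = truth), class = "response_recording")
}

#' @export
print.response_recording <- function(x, ...) {
  cat(sprintf("response recording%s: %d OD steps, %d spectral flashes\n",
              if (is.na(x$label)) "" else sprintf(" '%s'", x$label),
              length(x$vlogi$od), length(x$spectral$wavelengths)))
  invisible(x)
}

#' Generate one synthetic intracellular recording
#'
#' Emulates the measurement process: a white-light VlogI series over the
#' neutral-density wheel (responses `nr(10^(-OD))` plus noise) and a
#' spectral flash series whose response at each wavelength is
#' `nr(flash_flux * calib(lambda) * S_model(lambda))` plus noise, with
#' negative noisy responses clipped at zero. With zero noise the analysis
#' pipeline recovers the model sensitivity exactly.
#'
#' @param model A [photoreceptor_model()].
#' @param nr Generating [naka_rushton_params()]
#'   (default [default_nr_params()]).
#' @param calib A [flux_calibration()] (default flat on `grid`).
#' @param noise A [noise_model()].
#' @param grid Spectral grid (default [default_grid()]).
#' @param od_steps Neutral-density steps (default 3.5 to 0 by 0.5).
#' @param flash_flux Relative flux of the unattenuated spectral flash
#'   (default 1, i.e. the OD 0 white-light flux).
#' @return A [response_recording()] carrying the generating model as
#'   `truth`.
#' @export
generate_recording <- function(model, nr = default_nr_params(),
                               calib = NULL, noise = noise_model(),
                               grid = default_grid(),
                               od_steps = seq(3.5, 0, by = -0.5),
                               flash_flux = 1) {
  stopifnot(inherits(model, "photoreceptor_model"),
            inherits(nr, "naka_rushton"), inherits(noise, "noise_model"))
  if (is.null(calib)) calib <- flat_calibration(grid)
  stopifnot(inherits(calib, "flux_calibration"))
  if (!isTRUE(all.equal(grid, calib$wavelengths)))
    stop("calibration grid does not match the requested grid")
  if (!is.null(noise$seed)) set.seed(noise$seed)
  v_white <- nr_response(10^(-od_steps), nr)
  s_true <- model_sensitivity(model, grid)
  if (noise$sensitivity_sd > 0) {
    # direct-sensitivity perturbation: cell-to-cell curve variability
    s_true <- pmax(s_true + stats::rnorm(length(s_true), 0,
                                         noise$sensitivity_sd), 0)
    s_true <- s_true / max(s_true)
  }
  v_spec <- nr_response(flash_flux * calib$relative_flux * s_true, nr)
  if (noise$response_sd > 0) {
    v_white <- v_white + stats::rnorm(length(v_white), 0, noise$response_sd)
    v_spec <- v_spec + stats::rnorm(length(v_spec), 0, noise$response_sd)
  }
  v_white <- pmax(v_white, 0)
  v_spec <- pmax(v_spec, 0)
  response_recording(
    vlogi = vlogi_curve(od_steps, v_white, reference_flux = 1),
    spectral = spectral_flash_series(grid, v_spec),
    label = model$label, truth = model)
}

#' Analyse a recording back to a lambda-max fit
#'
#' Convenience wrapper for the standard per-cell pipeline: fit the
#' Naka-Rushton parameters from the VlogI series, derive the relative
#' spectral sensitivity with photon-flux correction, and fit a template.
#'
#' @param recording A [response_recording()].
#' @param calib The [flux_calibration()] the flashes were delivered with.
#' @param family Template family for the fit.
#' @param ... Passed to [fit_lambda_max()].
#' @return List with `nr` (fitted params), `sensitivity`, `fit`
#'   (the [fit_lambda_max()] result).
#' @export
analyze_recording <- function(recording, calib = NULL,
                              family = "govardovskii_a1", ...) {
  stopifnot(inherits(recording, "response_recording"))
  if (is.null(calib)) calib <- flat_calibration(recording$spectral$wavelengths)
  nr_hat <- fit_naka_rushton(recording$vlogi)
  sens <- derive_sensitivity(recording$spectral, nr_hat, calib)
  fit <- suppressWarnings(fit_lambda_max(sens, family = family, ...))
  list(nr = nr_hat, sensitivity = sens, fit = fit)
}

#' Packaged Heliconius species cell models
#'
#' Generative cell models for the photoreceptor classes reported in the
#' adult compound eyes of three Heliconius species: single-opsin UV, blue
#' and green (long-wavelength) cells; the yellow--orange cell built as the
#' species' LW rhodopsin screened by the red (ommochrome) filtering
#' pigment with density calibrated so the filtered peak sits at 590 nm;
#' and the broadband cell built as an equal blue + LW co-expression
#' mixture behind a generic short-wavelength bandpass transmission
#' window (centred 530 nm), the hypothesised mechanism for its broad
#' blue--green sensitivity; a plain two-template mixture cannot
#' reproduce its shape. Class frequencies follow the reported retinal
#' composition
#' (roughly 75% LW-sensitive, 20% blue, 5% UV), with the filtered and
#' broadband cells as subsets of the LW-dominated pool.
#'
#' @param species `"melpomene"`, `"ismenius"` or `"erato"`.
#' @return List with `species`, `models` (named list of
#'   [photoreceptor_model()]s) and `frequencies` (named, sum 1).
#' @export
heliconius_models <- function(species = c("melpomene", "ismenius", "erato")) {
  species <- match.arg(species)
  lw <- switch(species, melpomene = 570, ismenius = 570, erato = 555)
  blue <- switch(species, melpomene = 470, ismenius = 445, erato = 470)
  yo_filter <- calibrate_filter(pigment_template(lw), target_peak = 590,
                                filter = filter_spec(560, shape = "ommochrome"))
  models <- list(
    green = photoreceptor_model(stats::setNames(1, lw), label = "green"),
    blue = photoreceptor_model(stats::setNames(1, blue), label = "blue"),
    yellow_orange = photoreceptor_model(stats::setNames(1, lw),
                                        filter = yo_filter,
                                        label = "yellow_orange"),
    broadband = photoreceptor_model(
      stats::setNames(c(0.5, 0.5), c(blue, lw)),
      filter = filter_spec(530, density = 0.5, shape = "bandpass",
                           short_width = 120),
      label = "broadband"))
  freqs <- c(green = 0.53, blue = 0.18, yellow_orange = 0.20,
             broadband = 0.02)
  if (species == "erato") {
    models$UV1 <- photoreceptor_model(c("355" = 1), label = "UV1")
    models$UV2 <- photoreceptor_model(c("390" = 1), label = "UV2")
    freqs <- c(freqs, UV1 = 0.03, UV2 = 0.04)
    freqs["blue"] <- 0.15
  } else {
    models$UV1 <- photoreceptor_model(c("365" = 1), label = "UV1")
    freqs <- c(freqs, UV1 = 0.05)
    freqs["blue"] <- 0.20
  }
  freqs <- freqs / sum(freqs)
  list(species = species, models = models, frequencies = freqs)
}

#' Generate a synthetic retina dataset
#'
#' Draws cell classes from the species composition and generates one
#' recording per cell, returning the recordings together with a truth
#' table for recovery scoring.
#'
#' @param model_set A species model set as returned by
#'   [heliconius_models()], or any list with `models` and `frequencies`.
#' @param n_cells Number of cells.
#' @param noise A [noise_model()] (its `seed` is ignored here).
#' @param seed Integer seed for the whole dataset.
#' @param calib Optional [flux_calibration()].
#' @param grid Spectral grid.
#' @return List with `recordings` (list of [response_recording()]) and
#'   `truth` (`data.frame` cell, class).
#' @export
generate_retina_dataset <- function(model_set, n_cells,
                                    noise = noise_model(), seed = 1,
                                    calib = NULL, grid = default_grid()) {
  if (n_cells < 1) stop("n_cells must be >= 1")
  stopifnot(is.list(model_set$models), !is.null(model_set$frequencies))
  set.seed(seed)
  classes <- sample_retina(model_set$frequencies, n_cells)
  noise$seed <- NULL  # one seed governs the whole dataset
  recs <- lapply(seq_len(n_cells), function(i)
    generate_recording(model_set$models[[classes[i]]], calib = calib,
                       noise = noise, grid = grid))
  list(recordings = recs,
       truth = data.frame(cell = seq_len(n_cells), class = classes,
                          stringsAsFactors = FALSE))
}

#' A plausible xenon-arc photon-flux calibration
#'
#' Smooth synthetic lamp-plus-filter-set photon flux shape: flux rising
#' from the UV to a broad visible plateau, max-normalized. The real
#' per-filter calibration of any rig is measured, not modelled; this
#' curve exists so tests and simulations can exercise a non-flat
#' correction.
#'
#' @param wavelengths Spectral grid (default [default_grid()]).
#' @return A [flux_calibration()].
#' @export
xenon_calibration <- function(wavelengths = default_grid()) {
  flux <- 0.25 + 0.75 / (1 + exp(-(wavelengths - 380) / 40))
  flux_calibration(wavelengths, flux)
}
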