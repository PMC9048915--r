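# Forward models of non-opsin spectral tuning: photostable screening
# pigments and opsin co-expression mixtures.

#' A screening-pigment filter specification
#'
#' Transmittance is `T(lambda) = 10^(-density * A(lambda))` with `A` the
#' max-normalized pigment absorbance. Three absorbance shapes are
#' available:
#'
#' * `"ommochrome"` (default): asymmetric band peaking at
#'   `pigment_lambda_max` with a broad Gaussian short-wavelength limb
#'   (`short_width`) and a steep long-wavelength cut-off (`long_width`),
#'   emulating an ommochrome granule pigment that absorbs broadly below
#'   its peak and transmits long wavelengths. The default limb widths
#'   (150 nm / 17.7 nm) are a one-time calibration of the shape so that a
#'   570 nm rhodopsin screened at the density reaching a 590 nm peak also
#'   shows the 65--75 nm half-width observed for the yellow--orange cell.
#' * `"template"`: the visual-pigment alpha band of the chosen family
#'   centred at `pigment_lambda_max`.
#' * `"bandpass"`: a transmission window centred at `pigment_lambda_max`
#'   with Gaussian width `short_width`; absorbance is
#'   `1 - exp(-((lambda - centre)/width)^2)`, i.e. the filter transmits a
#'   band and absorbs both flanks (a generic stand-in for the
#'   hypothesised short-wavelength bandpass filtering in broadband
#'   cells).
#' * `"tabulated"`: a user-supplied absorbance table
#'   (`data.frame(wavelength_nm, absorbance)`), interpolated linearly and
#'   max-normalized.
#'
#' @param pigment_lambda_max Pigment absorbance peak (nm, default 560).
#' @param density Peak optical density, >= 0.
#' @param shape Absorbance shape, see above.
#' @param placement `"proximal"` or `"distal"` (metadata).
#' @param short_width,long_width Gaussian widths (nm) of the ommochrome
#'   shape's short and long limbs.
#' @param family Template family for `shape = "template"`.
#' @param absorbance_table Table for `shape = "tabulated"`.
#' @return Object of class `filter_spec`.
#' @export
filter_spec <- function(pigment_lambda_max = 560, density = 1,
                        shape = c("ommochrome", "template", "bandpass",
                                  "tabulated"),
                        placement = c("proximal", "distal"),
                        short_width = 150, long_width = 17.7,
                        family = "govardovskii_a1",
                        absorbance_table = NULL) {
  shape <- match.arg(shape)
  placement <- match.arg(placement)
  if (!is.finite(density) || density < 0) stop("density must be >= 0")
  if (shape == "tabulated") {
    if (is.null(absorbance_table) ||
        !all(c("wavelength_nm", "absorbance") %in% names(absorbance_table)))
      stop("tabulated shape needs an absorbance_table with columns wavelength_nm, absorbance")
    if (any(absorbance_table$absorbance < 0))
      stop("tabulated absorbance must be non-negative")
  }
  structure(list(pigment_lambda_max = pigment_lambda_max, density = density,
                 shape = shape, placement = placement,
                 short_width = short_width, long_width = long_width,
                 family = family, absorbance_table = absorbance_table),
            class = "filter_spec")
}

#' Max-normalized pigment absorbance of a filter
#'
#' @param filter A [filter_spec()].
#' @param wavelengths Wavelengths (nm).
#' @return Relative absorbance in \[0, 1\].
#' @export
pigment_absorbance <- function(filter, wavelengths) {
  stopifnot(inherits(filter, "filter_spec"))
  pk <- filter$pigment_lambda_max
  a <- switch(filter$shape,
    ommochrome = ifelse(
      wavelengths <= pk,
      exp(-((wavelengths - pk) / filter$short_width)^2),
      exp(-((wavelengths - pk) / filter$long_width)^2)),
    template = {
      tpl <- pigment_template(pk, filter$family, include_beta_band = FALSE)
      template_shape(wavelengths, pk, filter$family, FALSE) / tpl$norm
    },
    bandpass = 1 - exp(-((wavelengths - pk) / filter$short_width)^2),
    tabulated = {
      tab <- filter$absorbance_table
      stats::approx(tab$wavelength_nm, tab$absorbance, xout = wavelengths,
                    rule = 2)$y
    })
  a / max(a)
}

#' Filter transmittance
#' @inheritParams pigment_absorbance
#' @return Transmittance in (0, 1\].
#' @export
filter_transmittance <- function(filter, wavelengths)
  10^(-filter$density * pigment_absorbance(filter, wavelengths))

#' Sensitivity of a rhodopsin screened by a photostable filter
#'
#' Pointwise product of the rhodopsin template and the filter
#' transmittance, re-normalized to maximum 1. A short-wavelength-absorbing
#' pigment red-shifts the peak and narrows the curve.
#'
#' @param template A [pigment_template()].
#' @param filter A [filter_spec()].
#' @param wavelengths Evaluation grid (default [default_grid()]).
#' @return A [spectral_sensitivity()].
#' @export
filtered_sensitivity <- function(template, filter,
                                 wavelengths = default_grid()) {
  stopifnot(inherits(template, "pigment_template"),
            inherits(filter, "filter_spec"))
  s <- evaluate_template(template, wavelengths) *
    filter_transmittance(filter, wavelengths)
  spectral_sensitivity(wavelengths, s)
}

#' Calibrate filter density to a target peak wavelength
#'
#' Finds the smallest density whose filtered peak (argmax on a 1 nm grid)
#' is within 1 nm of `target_peak`, by bisection on the density axis. The
#' filtered peak is non-decreasing in density for short-wavelength
#' absorbing pigments, which the bisection relies on.
#'
#' @param template The rhodopsin [pigment_template()] being screened.
#' @param target_peak Desired peak wavelength (nm), >= the unfiltered peak.
#' @param filter A [filter_spec()] whose density is ignored and replaced.
#' @param max_density Upper bound on density (default 10); the target must
#'   be reachable below it.
#' @param tol Bisection tolerance on density (default 1e-4).
#' @return The input `filter` with its calibrated `density`.
#' @export
calibrate_filter <- function(template, target_peak, filter = filter_spec(),
                             max_density = 10, tol = 1e-4) {
  stopifnot(inherits(template, "pigment_template"),
            inherits(filter, "filter_spec"))
  lam <- seq(300, 700, by = 1)
  base <- evaluate_template(template, lam)
  absorb <- pigment_absorbance(filter, lam)
  peak_at <- function(d) lam[which.max(base * 10^(-d * absorb))]
  p0 <- peak_at(0)
  if (target_peak < p0)
    stop("target peak below the unfiltered peak; filtering only red-shifts")
  if (abs(p0 - target_peak) <= 1) {
    filter$density <- 0
    return(filter)
  }
  if (peak_at(max_density) < target_peak - 1)
    stop("target peak unreachable at density <= ", max_density)
  lo <- 0; hi <- max_density
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (peak_at(mid) >= target_peak) hi <- mid else lo <- mid
  }
  if (abs(peak_at(hi) - target_peak) > 1)
    stop("filtered peak jumps past the target: no density lands within 1 nm of ",
         target_peak, " nm")
  filter$density <- hi
  filter
}

#' A generative photoreceptor cell model
#'
#' Mixture of one or more visual-pigment templates (weights sum to 1) with
#' an optional screening filter; drives both forward spectral modelling
#' and the synthetic-recording generator.
#'
#' @param opsins Named numeric vector: names are lambda-max values (nm),
#'   values are non-negative mixture weights (normalized to sum 1).
#' @param filter Optional [filter_spec()].
#' @param label Cell-class label.
#' @param family Template family.
#' @param include_beta_band Passed to [pigment_template()].
#' @return Object of class `photoreceptor_model`.
#' @export
photoreceptor_model <- function(opsins, filter = NULL, label = "cell",
                                family = "govardovskii_a1",
                                include_beta_band = TRUE) {
  if (!length(opsins)) stop("at least one opsin is required")
  w <- as.numeric(opsins)
  lm <- as.numeric(names(opsins))
  if (anyNA(lm)) stop("opsins must be named by their lambda-max in nm")
  if (any(w < 0)) stop("mixture weights must be non-negative")
  if (sum(w) <= 0) stop("mixture weights must not all be zero")
  w <- w / sum(w)
  if (!is.null(filter)) stopifnot(inherits(filter, "filter_spec"))
  structure(list(lambda_max = lm, weights = w, filter = filter,
                 label = label, family = family,
                 include_beta_band = include_beta_band),
            class = "photoreceptor_model")
}

#' @export
print.photoreceptor_model <- function(x, ...) {
  cat(sprintf("photoreceptor model '%s': %s%s\n", x$label,
              paste(sprintf("%g nm (w=%.2f)", x$lambda_max, x$weights),
                    collapse = " + "),
              if (!is.null(x$filter))
                sprintf(" with %s filter (d=%.3g)", x$filter$shape,
                        x$filter$density) else ""))
  invisible(x)
}

#' Model sensitivity curve (unclassed numeric)
#'
#' Weighted sum of member templates, multiplied by the filter
#' transmittance when present, max-normalized.
#'
#' @param model A [photoreceptor_model()].
#' @param wavelengths Wavelengths (nm).
#' @return Numeric relative sensitivity in \[0, 1\].
#' @export
model_sensitivity <- function(model, wavelengths) {
  stopifnot(inherits(model, "photoreceptor_model"))
  s <- numeric(length(wavelengths))
  for (i in seq_along(model$lambda_max)) {
    tpl <- pigment_template(model$lambda_max[i], model$family,
                            model$include_beta_band)
    s <- s + model$weights[i] * evaluate_template(tpl, wavelengths)
  }
  if (!is.null(model$filter))
    s <- s * filter_transmittance(model$filter, wavelengths)
  s / max(s)
}

#' Sensitivity of an opsin co-expression model
#'
#' @param model A [photoreceptor_model()].
#' @param wavelengths Evaluation grid (default [default_grid()]).
#' @return A [spectral_sensitivity()].
#' @export
coexpression_sensitivity <- function(model, wavelengths = default_grid())
  spectral_sensitivity(wavelengths, model_sensitivity(model, wavelengths))

#' Decompose a sensitivity curve into a template mixture
#'
#' Nonnegative least squares over mixture weights of candidate templates
#' (via [pracma::lsqnonneg]); weights are renormalized to sum 1 for
#' reporting, and the residual sum of squares of the NNLS solution is
#' returned. Deterministic.
#'
#' @param sens A [spectral_sensitivity()].
#' @param candidate_lambdas Candidate template peaks (nm).
#' @param family Template family.
#' @param include_beta_band Passed to [pigment_template()].
#' @return List with `weights` (named, sum 1), `raw_weights`, `rss`,
#'   `fitted` (the NNLS-fitted curve).
#' @export
mixture_fit <- function(sens, candidate_lambdas,
                        family = "govardovskii_a1",
                        include_beta_band = TRUE) {
  stopifnot(inherits(sens, "spectral_sensitivity"))
  if (!length(candidate_lambdas)) stop("at least one candidate is required")
  keep <- !is.na(sens$sensitivity)
  y <- sens$sensitivity[keep]
  if (all(y == 0)) stop("all-zero sensitivity cannot be decomposed")
  lam <- sens$wavelengths[keep]
  A <- vapply(candidate_lambdas, function(lmax)
    evaluate_template(pigment_template(lmax, family, include_beta_band), lam),
    numeric(length(lam)))
  A <- matrix(A, nrow = length(lam))
  fit <- pracma::lsqnonneg(A, y)
  w <- fit$x
  fitted <- as.numeric(A %*% w)
  rss <- sum((y - fitted)^2)
  wn <- if (sum(w) > 0) w / sum(w) else w
  names(wn) <- names(w) <- as.character(candidate_lambdas)
  list(weights = wn, raw_weights = w, rss = rss,
       fitted = fitted, wavelengths = lam)
}
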