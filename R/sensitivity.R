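# Per-cell spectral sensitivity: flux correction, inversion, averaging,
# and lambda-max estimation by least-squares template fitting.

#' A spectral flash response series
#'
#' Responses to narrow-band flashes, one per grid wavelength.
#'
#' @param wavelengths Spectral grid (nm); validated with [spectral_grid()].
#' @param response_mv Response amplitudes (mV), non-negative, one per
#'   wavelength.
#' @param flash_duration_ms Flash duration in ms (metadata; default 50).
#' @return Object of class `spectral_flash_series`.
#' @export
spectral_flash_series <- function(wavelengths, response_mv,
                                  flash_duration_ms = 50) {
  spectral_grid(wavelengths)
  if (length(wavelengths) != length(response_mv))
    stop("one response per grid wavelength required")
  if (any(response_mv < 0)) stop("responses must be non-negative")
  structure(list(wavelengths = wavelengths, response_mv = response_mv,
                 flash_duration_ms = flash_duration_ms),
            class = "spectral_flash_series")
}

#' Photon-flux calibration for an interference-filter set
#'
#' Relative photon flux delivered by each filter, max-normalized.
#'
#' @param wavelengths Spectral grid (nm).
#' @param relative_flux Positive relative photon flux per filter.
#' @return Object of class `flux_calibration`.
#' @export
flux_calibration <- function(wavelengths, relative_flux) {
  spectral_grid(wavelengths)
  if (length(wavelengths) != length(relative_flux))
    stop("one flux value per grid wavelength required")
  if (any(relative_flux <= 0)) stop("relative flux must be strictly positive")
  structure(list(wavelengths = wavelengths,
                 relative_flux = relative_flux / max(relative_flux)),
            class = "flux_calibration")
}

#' Flat (constant-flux) calibration
#' @param wavelengths Spectral grid (default [default_grid()]).
#' @return A [flux_calibration()] with unit flux everywhere.
#' @export
flat_calibration <- function(wavelengths = default_grid())
  flux_calibration(wavelengths, rep(1, length(wavelengths)))

#' Normalized relative spectral sensitivity
#'
#' @param wavelengths Spectral grid (nm).
#' @param sensitivity Relative sensitivity per wavelength; renormalized so
#'   the maximum is exactly 1. `NA` marks wavelengths excluded from
#'   derivation (e.g. saturated responses).
#' @param se Standard error per wavelength (0 for single cells).
#' @param n_cells Number of averaged cells (>= 1).
#' @return Object of class `spectral_sensitivity`.
#' @export
spectral_sensitivity <- function(wavelengths, sensitivity, se = 0,
                                 n_cells = 1L) {
  spectral_grid(wavelengths)
  if (length(wavelengths) != length(sensitivity))
    stop("one sensitivity value per grid wavelength required")
  m <- max(sensitivity, na.rm = TRUE)
  if (!is.finite(m) || m <= 0) stop("sensitivity has no positive values")
  se <- rep_len(se, length(wavelengths))
  if (any(se < 0, na.rm = TRUE)) stop("standard errors must be non-negative")
  structure(list(wavelengths = wavelengths, sensitivity = sensitivity / m,
                 se = se, n_cells = as.integer(n_cells)),
            class = "spectral_sensitivity")
}

#' @export
print.spectral_sensitivity <- function(x, ...) {
  cat(sprintf("spectral sensitivity: %d wavelengths (%g-%g nm), peak %g nm, n = %d\n",
              length(x$wavelengths), min(x$wavelengths), max(x$wavelengths),
              peak_wavelength(x), x$n_cells))
  invisible(x)
}

#' @export
as.data.frame.spectral_sensitivity <- function(x, ...) {
  data.frame(wavelength_nm = x$wavelengths, mean = x$sensitivity,
             se = x$se, n = x$n_cells)
}

#' Peak wavelength of a sensitivity curve
#'
#' Argmax after linear interpolation onto a 1 nm grid.
#'
#' @param sens A [spectral_sensitivity()].
#' @return Peak wavelength (nm).
#' @export
peak_wavelength <- function(sens) {
  stopifnot(inherits(sens, "spectral_sensitivity"))
  ok <- !is.na(sens$sensitivity)
  x <- sens$wavelengths[ok]; y <- sens$sensitivity[ok]
  xi <- seq(x[1L], x[length(x)], by = min(1, min(diff(x))))
  yi <- stats::approx(x, y, xout = xi)$y
  xi[which.max(yi)]
}

#' @rdname half_width
#' @export
half_width.spectral_sensitivity <- function(x, ...)
  half_width.default(x$wavelengths, x$sensitivity)

#' Derive relative spectral sensitivity from flash responses
#'
#' Each response is converted to the effective stimulus intensity that
#' produced it by inverting the cell's fitted Naka-Rushton function; the
#' effective intensity is divided by the relative photon flux of that
#' wavelength's filter, and the resulting per-flux sensitivities are
#' max-normalized. Responses above the saturation fraction of `v_max`
#' (including any at or above `v_max` itself, which can occur when the
#' fitted `v_max` underestimates a noisy peak) are excluded (set `NA`)
#' because the inversion error diverges there; with exclusion disabled
#' (`saturation_frac = 1`) a response at or above `v_max` is an error.
#' Non-positive responses map to zero sensitivity.
#'
#' @param flashes A [spectral_flash_series()].
#' @param params The cell's fitted [naka_rushton_params()].
#' @param calib A [flux_calibration()] on the same grid.
#' @param saturation_frac Responses above `saturation_frac * v_max` are
#'   excluded from inversion (default 0.95).
#' @return A [spectral_sensitivity()] with `n_cells = 1` and zero SE.
#' @export
derive_sensitivity <- function(flashes, params, calib,
                               saturation_frac = 0.95) {
  stopifnot(inherits(flashes, "spectral_flash_series"),
            inherits(params, "naka_rushton"),
            inherits(calib, "flux_calibration"))
  if (!isTRUE(all.equal(flashes$wavelengths, calib$wavelengths)))
    stop("calibration grid does not match the flash grid")
  v <- flashes$response_mv
  sat <- v > saturation_frac * params$v_max
  if (saturation_frac >= 1) {
    # no saturation exclusion: responses at or above v_max cannot be
    # inverted at all
    over <- v >= params$v_max
    if (any(over))
      stop("responses at or above v_max at wavelengths: ",
           paste(flashes$wavelengths[over], collapse = ", "))
    sat <- rep(FALSE, length(v))
  }
  s <- numeric(length(v))
  pos <- v > 0 & !sat
  s[pos] <- invert_response(v[pos], params) / calib$relative_flux[pos]
  s[sat] <- NA_real_
  if (all(is.na(s) | s == 0))
    stop("no invertible responses: cannot derive a sensitivity curve")
  spectral_sensitivity(flashes$wavelengths, s)
}

#' Average replicate spectral sensitivities
#'
#' Per-wavelength mean of max-normalized replicates with standard error
#' (sample SD / sqrt(n), computed before re-normalization); the mean curve
#' is then re-normalized to maximum 1.
#'
#' @param cells List of [spectral_sensitivity()] objects on identical grids.
#' @return A [spectral_sensitivity()] with `n_cells = length(cells)`.
#' @export
average_cells <- function(cells) {
  if (!length(cells)) stop("no cells to average")
  stopifnot(all(vapply(cells, inherits, logical(1), "spectral_sensitivity")))
  grid <- cells[[1L]]$wavelengths
  for (cell in cells[-1L])
    if (!isTRUE(all.equal(grid, cell$wavelengths)))
      stop("cells recorded on different spectral grids cannot be averaged")
  mat <- vapply(cells, function(cc) cc$sensitivity,
                numeric(length(grid)))
  mat <- matrix(mat, nrow = length(grid))
  n_eff <- rowSums(!is.na(mat))
  mn <- rowMeans(mat, na.rm = TRUE)
  mn[n_eff == 0L] <- NA_real_
  se <- apply(mat, 1L, function(r) {
    r <- r[!is.na(r)]
    if (length(r) < 2L) return(0)
    stats::sd(r) / sqrt(length(r))
  })
  spectral_sensitivity(grid, mn, se = se, n_cells = length(cells))
}

#' Estimate lambda-max by least-squares template fitting
#'
#' Minimizes the sum of squared differences between the normalized
#' sensitivity curve and a visual-pigment template over candidate peak
#' wavelengths: a 1 nm grid search over `search_bounds` followed by a
#' 0.1 nm local refinement. Ties break toward the lower wavelength. `NA`
#' sensitivities are ignored.
#'
#' @param sens A [spectral_sensitivity()].
#' @param family Template family (see [pigment_template()]).
#' @param search_bounds Numeric length-2 search range in nm
#'   (default `c(300, 700)`).
#' @param include_beta_band Passed to [pigment_template()].
#' @param fit_window Optional half-window (nm): restrict the fitted
#'   wavelengths to within `fit_window` of the empirical peak. `NULL`
#'   (default) fits the full grid.
#' @return Object of class `lambda_max_fit`: fields `lambda_max_hat`,
#'   `family`, `rss`, `fit_window`, `boundary_hit`.
#' @export
fit_lambda_max <- function(sens, family = c("govardovskii_a1", "stavenga1993"),
                           search_bounds = c(300, 700),
                           include_beta_band = TRUE, fit_window = NULL) {
  stopifnot(inherits(sens, "spectral_sensitivity"))
  family <- match.arg(family)
  if (length(search_bounds) != 2L || diff(search_bounds) <= 0)
    stop("search_bounds must be an increasing range")
  keep <- !is.na(sens$sensitivity)
  if (!is.null(fit_window)) {
    pk <- peak_wavelength(sens)
    keep <- keep & abs(sens$wavelengths - pk) <= fit_window
  }
  lam <- sens$wavelengths[keep]
  y <- sens$sensitivity[keep]
  if (length(lam) < 4L) stop("too few usable wavelengths for a template fit")
  rss_at <- function(lmax) {
    tpl <- pigment_template(lmax, family, include_beta_band)
    sum((y - evaluate_template(tpl, lam))^2)
  }
  coarse <- seq(search_bounds[1L], search_bounds[2L], by = 1)
  rss_c <- vapply(coarse, rss_at, numeric(1))
  best <- coarse[which.min(rss_c)]
  fine <- seq(max(search_bounds[1L], best - 1),
              min(search_bounds[2L], best + 1), by = 0.1)
  rss_f <- vapply(fine, rss_at, numeric(1))
  lhat <- fine[which.min(rss_f)]
  boundary <- lhat <= search_bounds[1L] + 0.1 || lhat >= search_bounds[2L] - 0.1
  if (boundary)
    warning("lambda-max fit hit a search boundary at ", lhat, " nm")
  structure(list(lambda_max_hat = lhat, family = family,
                 rss = min(rss_f), fit_window = fit_window,
                 boundary_hit = boundary),
            class = "lambda_max_fit")
}

#' @export
print.lambda_max_fit <- function(x, ...) {
  cat(sprintf("lambda-max fit: %.1f nm (%s, RSS %.4g)\n",
              x$lambda_max_hat, x$family, x$rss))
  invisible(x)
}
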