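# Visual-pigment absorbance templates (nomograms) and shape diagnostics.

#' Validate a spectral grid
#'
#' A spectral grid is a strictly increasing numeric vector of wavelengths in
#' nanometres, restricted to 250--800 nm (the range over which the packaged
#' nomograms are meaningful).
#'
#' @param wavelengths Numeric vector of wavelengths (nm).
#' @return The validated wavelength vector, invisibly unchanged.
#' @export
spectral_grid <- function(wavelengths) {
  if (!is.numeric(wavelengths) || length(wavelengths) < 2L)
    stop("a spectral grid needs at least two numeric wavelengths")
  if (anyNA(wavelengths))
    stop("spectral grid contains NA wavelengths")
  if (any(diff(wavelengths) <= 0))
    stop("spectral grid must be strictly increasing")
  if (any(wavelengths < 250 | wavelengths > 800))
    stop("spectral grid wavelengths must lie within [250, 800] nm")
  wavelengths
}

#' Default measurement grid
#'
#' The 300--700 nm, 10 nm-step grid of the interference-filter set used for
#' spectral flashes.
#'
#' @return Numeric vector, `seq(300, 700, by = 10)`.
#' @export
default_grid <- function() seq(300, 700, by = 10)

template_families <- c("govardovskii_a1", "stavenga1993")

# Raw (unnormalized) alpha + optional beta band absorbance.
# Govardovskii et al. (2000) A1 alpha band with its lambda-max-dependent
# exponent, plus the Gaussian beta band; Stavenga et al. (1993) modified
# log-normal with the a2 = 3*a1^2/8 polynomial closure and a fixed 340 nm
# beta band.
template_shape <- function(wavelengths, lambda_max, family, include_beta_band) {
  if (family == "govardovskii_a1") {
    x <- lambda_max / wavelengths
    a <- 0.8795 + 0.0459 * exp(-(lambda_max - 300)^2 / 11940)
    s <- 1 / (exp(69.7 * (a - x)) + exp(28 * (0.922 - x)) +
                exp(-14.9 * (1.104 - x)) + 0.674)
    if (include_beta_band) {
      lam_beta <- 189 + 0.315 * lambda_max
      b_beta <- -40.5 + 0.195 * lambda_max
      s <- s + 0.26 * exp(-((wavelengths - lam_beta) / b_beta)^2)
    }
  } else {
    a1 <- 6.09
    x <- log10(wavelengths / lambda_max)
    s <- exp(-380 * x^2 * (1 + a1 * x + (3 * a1^2 / 8) * x^2))
    if (include_beta_band) {
      b1 <- 3.59
      xb <- log10(wavelengths / 340)
      s <- s + 0.29 * exp(-247 * xb^2 * (1 + b1 * xb + (3 * b1^2 / 8) * xb^2))
    }
  }
  s
}

#' Construct a visual-pigment template
#'
#' Parametric rhodopsin absorbance curve characterised solely by its
#' wavelength of peak absorbance. Two published template families are
#' available: the Govardovskii et al. (2000) A1 nomogram (default) and the
#' Stavenga, Smits & Hoeve (1993) log-normal nomogram. The combined
#' alpha + beta curve is normalized so its maximum on a dense 0.1 nm grid is
#' exactly 1.
#'
#' @param lambda_max Peak wavelength in nm, within [300, 700].
#' @param family Template family, `"govardovskii_a1"` or `"stavenga1993"`.
#' @param include_beta_band Include the short-wavelength beta band
#'   (default `TRUE`).
#' @return An object of class `pigment_template`.
#' @examples
#' tpl <- pigment_template(570)
#' evaluate_template(tpl, 570)
#' @export
pigment_template <- function(lambda_max,
                             family = c("govardovskii_a1", "stavenga1993"),
                             include_beta_band = TRUE) {
  family <- match.arg(family)
  if (!is.numeric(lambda_max) || length(lambda_max) != 1L || is.na(lambda_max))
    stop("lambda_max must be a single number")
  if (lambda_max < 300 || lambda_max > 700)
    stop("lambda_max outside the template validity range [300, 700] nm")
  # the combined curve's maximum always sits near lambda_max (the beta band
  # amplitude is < 0.3), so a +/- 100 nm window suffices for normalization
  dense <- seq(max(250, lambda_max - 100), min(800, lambda_max + 100), by = 0.1)
  raw <- template_shape(dense, lambda_max, family, include_beta_band)
  norm <- max(raw)
  structure(
    list(lambda_max = lambda_max, family = family,
         include_beta_band = include_beta_band, norm = norm,
         peak = dense[which.max(raw)]),
    class = "pigment_template")
}

#' @export
print.pigment_template <- function(x, ...) {
  cat(sprintf("pigment template: lambda_max = %g nm (%s%s)\n",
              x$lambda_max, x$family,
              if (x$include_beta_band) ", alpha+beta" else ", alpha only"))
  invisible(x)
}

#' Evaluate a visual-pigment template
#'
#' For the default Govardovskii family, whose beta-band position scales
#' with `lambda_max`, the combined curve peaks within 1 nm of
#' `lambda_max` for pigments above ~365 nm (within 1.5 nm for deep-UV
#' pigments, where the beta band merges into the alpha band). The
#' Stavenga 1993 family places its beta band at a fixed 340 nm, so for
#' UV--violet pigments (`lambda_max` below ~420 nm) the combined peak
#' shifts a few nm short of the nominal `lambda_max`; this is a property
#' of that published template, not of the implementation.
#'
#' @param template A [pigment_template()].
#' @param wavelengths Wavelengths (nm) at which to evaluate; validated with
#'   [spectral_grid()] when more than one value is given.
#' @return Relative absorbance in \[0, 1\], one value per wavelength.
#' @export
evaluate_template <- function(template, wavelengths) {
  stopifnot(inherits(template, "pigment_template"))
  if (length(wavelengths) > 1L) spectral_grid(wavelengths)
  template_shape(wavelengths, template$lambda_max, template$family,
                 template$include_beta_band) / template$norm
}

#' Wavelength of the evaluated maximum
#'
#' Argmax of the combined alpha+beta curve on a 0.1 nm grid; within 1 nm of
#' `lambda_max` for all packaged families.
#'
#' @param template A [pigment_template()].
#' @return Peak wavelength (nm).
#' @export
template_peak <- function(template) {
  stopifnot(inherits(template, "pigment_template"))
  template$peak
}

#' Full width at half maximum of a sensitivity curve
#'
#' The curve is re-sampled by linear interpolation onto an internal grid of
#' at most 1 nm spacing; the two half-maximum crossings are located by
#' linear interpolation between bracketing samples and their separation
#' returned. The curve must have an interior maximum and cross half maximum
#' on both sides.
#'
#' @param x A `pigment_template`, a `spectral_sensitivity`, or a numeric
#'   wavelength vector (with `values`).
#' @param ... Passed to methods.
#' @return FWHM in nm.
#' @export
half_width <- function(x, ...) UseMethod("half_width")

#' @rdname half_width
#' @param values Curve values matching `x` when `x` is a wavelength vector.
#' @export
half_width.default <- function(x, values, ...) {
  if (length(x) != length(values))
    stop("wavelengths and values must have equal length")
  ok <- !is.na(values)
  x <- x[ok]; values <- values[ok]
  if (length(x) < 3L) stop("too few points to measure a half-width")
  # internal grid at <= 1 nm
  step <- min(1, min(diff(x)))
  xi <- seq(x[1L], x[length(x)], by = step)
  yi <- stats::approx(x, values, xout = xi)$y
  yi <- yi / max(yi)
  i <- which.max(yi)
  if (i == 1L || i == length(yi))
    stop("curve maximum lies on the grid boundary; FWHM undefined")
  below_lo <- which(yi[seq_len(i)] <= 0.5)
  below_hi <- which(yi[i:length(yi)] <= 0.5)
  if (!length(below_lo))
    stop("half maximum not crossed on the short-wavelength side")
  if (!length(below_hi))
    stop("half maximum not crossed on the long-wavelength side")
  j <- max(below_lo)
  lo <- stats::approx(yi[c(j, j + 1L)], xi[c(j, j + 1L)], xout = 0.5)$y
  j <- i - 1L + min(below_hi)
  hi <- stats::approx(yi[c(j - 1L, j)], xi[c(j - 1L, j)], xout = 0.5)$y
  hi - lo
}

#' @rdname half_width
#' @export
half_width.pigment_template <- function(x, ...) {
  # evaluated over the full validity range so that UV pigments, whose beta
  # band merges into the alpha band, still cross half maximum on both sides
  lam <- seq(250, 800, by = 1)
  half_width.default(lam, evaluate_template(x, lam))
}

#' Export a template curve as a two-column table
#'
#' @param template A [pigment_template()].
#' @param wavelengths Evaluation grid (default [default_grid()]).
#' @return `data.frame` with columns `wavelength_nm`, `relative_sensitivity`.
#' @export
template_curve <- function(template, wavelengths = default_grid()) {
  data.frame(wavelength_nm = wavelengths,
             relative_sensitivity = evaluate_template(template, wavelengths))
}
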