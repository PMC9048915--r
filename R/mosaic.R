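# Photoreceptor classification and ommatidial-type combinatorics.

#' A photoreceptor classification rule
#'
#' Cells are classified by peak wavelength and curve shape (FWHM). A rule
#' matches when the peak lies inside `peak_window` (half-open,
#' `[min, max)`) and the FWHM respects the optional bounds.
#'
#' @param label Class label.
#' @param peak_window Length-2 numeric, nm; use `c(-Inf, Inf)` for a
#'   shape-only rule.
#' @param min_halfwidth,max_halfwidth Optional FWHM bounds (nm).
#' @return Object of class `cell_class_rule`.
#' @export
cell_class_rule <- function(label, peak_window,
                            min_halfwidth = NULL, max_halfwidth = NULL) {
  stopifnot(length(peak_window) == 2L, peak_window[1L] < peak_window[2L])
  structure(list(label = label, peak_window = peak_window,
                 min_halfwidth = min_halfwidth,
                 max_halfwidth = max_halfwidth),
            class = "cell_class_rule")
}

#' Default photoreceptor class rules
#'
#' Broadband cells (FWHM >= 140 nm, any peak) are tested first; the
#' remaining windows bracket the peaks reported for Heliconius
#' photoreceptors: UV (< 410 nm), blue (410--500 nm), green (500--580 nm
#' with FWHM >= 90 nm, the width of an unscreened long-wavelength
#' rhodopsin), and yellow--orange (580--620 nm with FWHM <= 85 nm, the
#' narrowed signature of pigment screening). All thresholds are plain
#' arguments, not constants.
#'
#' @param broadband_min_fwhm,green_min_fwhm,yellow_orange_max_fwhm FWHM
#'   thresholds (nm).
#' @return Ordered list of [cell_class_rule()] objects.
#' @export
default_class_rules <- function(broadband_min_fwhm = 140,
                                green_min_fwhm = 90,
                                yellow_orange_max_fwhm = 85) {
  list(
    cell_class_rule("broadband", c(-Inf, Inf),
                    min_halfwidth = broadband_min_fwhm),
    cell_class_rule("UV", c(-Inf, 410)),
    cell_class_rule("blue", c(410, 500)),
    cell_class_rule("green", c(500, 580), min_halfwidth = green_min_fwhm),
    cell_class_rule("yellow_orange", c(580, 620),
                    max_halfwidth = yellow_orange_max_fwhm))
}

#' Classify a photoreceptor from its spectral sensitivity
#'
#' Applies the rules in order and returns the first match, or
#' `"unclassified"`. Classification is total: degenerate curves (no
#' measurable FWHM) are never an error, and diagnostics (peak, FWHM,
#' best-fit single template and its RSS) are always returned.
#'
#' @param sens A [spectral_sensitivity()].
#' @param rules Ordered list of [cell_class_rule()]s
#'   (default [default_class_rules()]).
#' @param family Template family used for the diagnostic single-template
#'   fit.
#' @return List with `label`, `peak_nm`, `fwhm_nm` (NA if not measurable),
#'   `template_lambda_max`, `template_rss`.
#' @export
classify_cell <- function(sens, rules = default_class_rules(),
                          family = "govardovskii_a1") {
  stopifnot(inherits(sens, "spectral_sensitivity"))
  peak <- tryCatch(peak_wavelength(sens), error = function(e) NA_real_)
  fwhm <- tryCatch(half_width(sens), error = function(e) NA_real_)
  fit <- tryCatch(suppressWarnings(fit_lambda_max(sens, family = family)),
                  error = function(e) NULL)
  label <- "unclassified"
  if (!is.na(peak)) {
    for (rule in rules) {
      if (peak < rule$peak_window[1L] || peak >= rule$peak_window[2L]) next
      if (!is.null(rule$min_halfwidth) &&
          (is.na(fwhm) || fwhm < rule$min_halfwidth)) next
      if (!is.null(rule$max_halfwidth) &&
          (is.na(fwhm) || fwhm > rule$max_halfwidth)) next
      label <- rule$label
      break
    }
  }
  list(label = label, peak_nm = peak, fwhm_nm = fwhm,
       template_lambda_max = if (is.null(fit)) NA_real_ else fit$lambda_max_hat,
       template_rss = if (is.null(fit)) NA_real_ else fit$rss)
}

#' Enumerate ommatidial types from an R1/R2 class inventory
#'
#' An ommatidial type is the unordered pair of cell classes expressed in
#' the R1 and R2 cells, so `k` classes give `k*(k+1)/2` types (pairs with
#' repetition).
#'
#' @param classes Character vector of distinct R1/R2 cell-class labels.
#' @return `data.frame` with columns `r1`, `r2` (one row per unordered
#'   pair, `r1` index <= `r2` index) and attribute `n_types`.
#' @examples
#' enumerate_ommatidial_types(c("UVRh1", "BRh", "BRh+LWRh"))
#' @export
enumerate_ommatidial_types <- function(classes) {
  if (!length(classes)) stop("class inventory is empty")
  classes <- unique(as.character(classes))
  k <- length(classes)
  idx <- which(upper.tri(diag(k), diag = TRUE), arr.ind = TRUE)
  out <- data.frame(r1 = classes[idx[, "row"]], r2 = classes[idx[, "col"]],
                    stringsAsFactors = FALSE)
  out <- out[order(match(out$r1, classes), match(out$r2, classes)), ]
  rownames(out) <- NULL
  attr(out, "n_types") <- nrow(out)
  out
}

#' Sample cell classes from a retinal composition
#'
#' Multinomial draw of cell-class labels, reproducible under a seed. Used
#' to quantify how hard rare classes (e.g. UV cells at 5% of the retina)
#' are to hit by random electrode sampling.
#'
#' @param composition Named numeric vector of class frequencies summing
#'   to 1 (tolerance 1e-6).
#' @param n_cells Number of cells to draw.
#' @param seed Optional integer seed.
#' @return Character vector of `n_cells` class labels.
#' @export
sample_retina <- function(composition, n_cells, seed = NULL) {
  if (is.null(names(composition)) || any(!nzchar(names(composition))))
    stop("composition must be a named frequency vector")
  if (any(composition < 0)) stop("frequencies must be non-negative")
  if (abs(sum(composition) - 1) > 1e-6)
    stop("frequencies must sum to 1 (got ", sum(composition), ")")
  if (!is.null(seed)) set.seed(seed)
  sample(names(composition), size = n_cells, replace = TRUE,
         prob = composition)
}
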