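# File interchange (CSV pairs per cell, calibration tables) and the
# end-to-end analysis pipeline.

# Strict numeric column: rejects rather than coerces (e.g. locale
# comma-decimals), naming the offending rows.
strict_numeric <- function(x, column, file) {
  out <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(out) & !is.na(x) & nzchar(trimws(x)))
  if (length(bad))
    stop(sprintf("non-numeric value '%s' in column '%s' of %s (row %d)",
                 x[bad[1L]], column, file, bad[1L]))
  if (anyNA(out))
    stop(sprintf("missing value in column '%s' of %s", column, file))
  out
}

read_csv_strict <- function(path, columns) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  missing_cols <- setdiff(columns, names(tab))
  if (length(missing_cols))
    stop(sprintf("%s lacks required column(s): %s", path,
                 paste(missing_cols, collapse = ", ")))
  for (cl in columns) tab[[cl]] <- strict_numeric(tab[[cl]], cl, path)
  tab
}

#' Read one cell's recording from a CSV pair
#'
#' The VlogI file has columns `od`, `response_mv`; the spectral file has
#' `wavelength_nm`, `response_mv`. Files are validated strictly: missing
#' or non-numeric cells, duplicate or out-of-range wavelengths, and OD
#' steps outside \[0, 3.5\] are rejected with messages naming the row.
#'
#' @param vlogi_path Path to the VlogI CSV.
#' @param spectral_path Path to the spectral flash CSV.
#' @param label Optional cell label (defaults to the file stem).
#' @return A [response_recording()].
#' @export
read_recording <- function(vlogi_path, spectral_path,
                           label = sub("_?vlogi.*$", "", basename(vlogi_path))) {
  vl <- read_csv_strict(vlogi_path, c("od", "response_mv"))
  sp <- read_csv_strict(spectral_path, c("wavelength_nm", "response_mv"))
  dup <- which(duplicated(sp$wavelength_nm))
  if (length(dup))
    stop(sprintf("duplicate wavelength %g nm in %s (row %d)",
                 sp$wavelength_nm[dup[1L]], spectral_path, dup[1L]))
  # recordings come from the 300-700 nm interference-filter set
  bad <- which(sp$wavelength_nm < 300 | sp$wavelength_nm > 700)
  if (length(bad))
    stop(sprintf("wavelength %g nm outside the 300-700 nm measurement range in %s (row %d)",
                 sp$wavelength_nm[bad[1L]], spectral_path, bad[1L]))
  o <- order(sp$wavelength_nm)
  response_recording(
    vlogi = vlogi_curve(vl$od, vl$response_mv),
    spectral = spectral_flash_series(sp$wavelength_nm[o], sp$response_mv[o]),
    label = label)
}

#' Write a recording to a CSV pair
#' @param recording A [response_recording()].
#' @param vlogi_path,spectral_path Output paths.
#' @return Invisibly, the two paths.
#' @export
write_recording <- function(recording, vlogi_path, spectral_path) {
  stopifnot(inherits(recording, "response_recording"))
  utils::write.csv(data.frame(od = recording$vlogi$od,
                              response_mv = recording$vlogi$response_mv),
                   vlogi_path, row.names = FALSE)
  utils::write.csv(data.frame(wavelength_nm = recording$spectral$wavelengths,
                              response_mv = recording$spectral$response_mv),
                   spectral_path, row.names = FALSE)
  invisible(c(vlogi_path, spectral_path))
}

#' Read a photon-flux calibration CSV
#' @param path CSV with columns `wavelength_nm`, `relative_flux`.
#' @return A [flux_calibration()].
#' @export
read_calibration <- function(path) {
  tab <- read_csv_strict(path, c("wavelength_nm", "relative_flux"))
  o <- order(tab$wavelength_nm)
  flux_calibration(tab$wavelength_nm[o], tab$relative_flux[o])
}

#' Write a calibration CSV
#' @param calib A [flux_calibration()].
#' @param path Output path.
#' @export
write_calibration <- function(calib, path) {
  stopifnot(inherits(calib, "flux_calibration"))
  utils::write.csv(data.frame(wavelength_nm = calib$wavelengths,
                              relative_flux = calib$relative_flux),
                   path, row.names = FALSE)
  invisible(path)
}

#' Write a sensitivity table CSV
#' @param sens A [spectral_sensitivity()].
#' @param path Output path.
#' @export
write_sensitivity <- function(sens, path) {
  utils::write.csv(as.data.frame(sens), path, row.names = FALSE)
  invisible(path)
}

#' Run the full analysis pipeline over a directory of recordings
#'
#' Scans `input_dir` for cell CSV pairs (`<cell>_vlogi.csv` +
#' `<cell>_spectral.csv`), runs the per-cell analysis (Naka-Rushton fit,
#' sensitivity derivation, template fit, classification), averages cells
#' per assigned class, and optionally writes all result tables plus a run
#' log (resolved configuration, seed, config hash) to `out_dir`. Failures
#' are isolated per cell: a bad file yields a row in the error table and
#' the pipeline continues.
#'
#' @param input_dir Directory of recording CSV pairs.
#' @param calibration Path to a calibration CSV, a [flux_calibration()],
#'   or `NULL` for a flat calibration.
#' @param out_dir Optional output directory (created if needed).
#' @param family Template family.
#' @param rules Classification rules (default [default_class_rules()]).
#' @param seed Seed recorded in the log (the analysis itself is
#'   deterministic).
#' @return List with `cells` (per-cell fit table), `classification`,
#'   `class_averages` (named list of [spectral_sensitivity()]),
#'   `lambda_table` (per-class mean fitted lambda-max), `errors`, `log`.
#' @export
run_pipeline <- function(input_dir, calibration = NULL, out_dir = NULL,
                         family = "govardovskii_a1",
                         rules = default_class_rules(), seed = NULL) {
  vl_files <- sort(list.files(input_dir, pattern = "_vlogi\\.csv$",
                              full.names = TRUE))
  cells <- sub("_vlogi\\.csv$", "", basename(vl_files))
  if (is.character(calibration)) calibration <- read_calibration(calibration)
  rows <- list(); errs <- list(); sens_list <- list()
  for (i in seq_along(cells)) {
    cell <- cells[i]
    res <- tryCatch({
      rec <- read_recording(vl_files[i],
                            file.path(input_dir,
                                      paste0(cell, "_spectral.csv")),
                            label = cell)
      calib <- if (is.null(calibration))
        flat_calibration(rec$spectral$wavelengths) else calibration
      ana <- analyze_recording(rec, calib = calib, family = family)
      cls <- classify_cell(ana$sensitivity, rules = rules, family = family)
      list(ana = ana, cls = cls)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      errs[[cell]] <- conditionMessage(res)
      next
    }
    sens_list[[cell]] <- res$ana$sensitivity
    rows[[cell]] <- data.frame(
      cell = cell,
      v_max = res$ana$nr$v_max, k = res$ana$nr$k, n = res$ana$nr$n,
      lambda_max_hat = res$ana$fit$lambda_max_hat,
      fit_rss = res$ana$fit$rss,
      class = res$cls$label, peak_nm = res$cls$peak_nm,
      fwhm_nm = res$cls$fwhm_nm, stringsAsFactors = FALSE)
  }
  cell_tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(cell = character(0))
  rownames(cell_tab) <- NULL
  classes <- unique(cell_tab$class)
  class_averages <- list()
  lambda_rows <- list()
  for (cl in setdiff(classes, "unclassified")) {
    members <- cell_tab$cell[cell_tab$class == cl]
    class_averages[[cl]] <- average_cells(sens_list[members])
    lambda_rows[[cl]] <- data.frame(
      class = cl, n_cells = length(members),
      mean_lambda_max = mean(cell_tab$lambda_max_hat[cell_tab$class == cl]),
      stringsAsFactors = FALSE)
  }
  lambda_table <- if (length(lambda_rows)) do.call(rbind, lambda_rows) else
    data.frame(class = character(0))
  rownames(lambda_table) <- NULL
  config <- list(input_dir = input_dir, family = family, seed = seed,
                 calibration = if (is.null(calibration)) "flat" else "table",
                 n_rules = length(rules))
  log <- list(config = config,
              config_hash = substr(paste(
                as.hexmode(utf8ToInt(jsonlite::toJSON(config,
                                                      auto_unbox = TRUE))),
                collapse = ""), 1L, 40L),
              n_cells = length(cells), n_failed = length(errs))
  out <- list(cells = cell_tab, classification = cell_tab[,
                intersect(c("cell", "class", "peak_nm", "fwhm_nm"),
                          names(cell_tab)), drop = FALSE],
              class_averages = class_averages, lambda_table = lambda_table,
              errors = errs, log = log)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(cell_tab, file.path(out_dir, "cell_fits.csv"),
                     row.names = FALSE)
    utils::write.csv(lambda_table, file.path(out_dir, "lambda_max.csv"),
                     row.names = FALSE)
    for (cl in names(class_averages))
      write_sensitivity(class_averages[[cl]],
                        file.path(out_dir, paste0("class_", cl, ".csv")))
    jsonlite::write_json(log, file.path(out_dir, "run_log.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  if (!length(cells))
    warning("no recording pairs found in ", input_dir)
  out
}
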