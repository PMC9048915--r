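# Naka-Rushton intensity-response model: V/Vmax = I^n / (I^n + K^n).

#' Naka-Rushton parameters
#'
#' @param v_max Maximum response amplitude (mV), > 0.
#' @param k Intensity eliciting half-maximal response, in relative photon
#'   flux units, > 0.
#' @param n Dimensionless exponential slope, > 0.
#' @return Object of class `naka_rushton`.
#' @export
naka_rushton_params <- function(v_max, k, n) {
  if (!all(is.finite(c(v_max, k, n))))
    stop("Naka-Rushton parameters must be finite")
  if (v_max <= 0 || k <= 0 || n <= 0)
    stop("Naka-Rushton parameters must all be positive")
  structure(list(v_max = v_max, k = k, n = n), class = "naka_rushton")
}

#' @export
print.naka_rushton <- function(x, ...) {
  cat(sprintf("Naka-Rushton: Vmax = %.3g mV, K = %.4g, n = %.3g", x$v_max, x$k, x$n))
  if (!is.null(attr(x, "rss"))) cat(sprintf(" (RSS %.4g)", attr(x, "rss")))
  cat("\n")
  invisible(x)
}

#' Forward Naka-Rushton response
#'
#' @param intensity Stimulus intensity in relative photon flux units, >= 0.
#' @param params A [naka_rushton_params()].
#' @return Response amplitude in mV, in \[0, v_max).
#' @export
nr_response <- function(intensity, params) {
  stopifnot(inherits(params, "naka_rushton"))
  if (any(intensity < 0, na.rm = TRUE))
    stop("intensity must be non-negative")
  inten_n <- intensity^params$n
  out <- params$v_max * inten_n / (inten_n + params$k^params$n)
  out[intensity == 0] <- 0
  out
}

#' Invert the Naka-Rushton function to effective intensity
#'
#' I = K * (V / (Vmax - V))^(1/n). The inverse diverges as V approaches
#' Vmax, so responses at or above Vmax are rejected.
#'
#' @param response Response amplitude (mV), strictly inside (0, v_max).
#' @param params A [naka_rushton_params()].
#' @return Effective intensity in the same relative flux units as `k`.
#' @export
invert_response <- function(response, params) {
  stopifnot(inherits(params, "naka_rushton"))
  if (any(response <= 0, na.rm = TRUE))
    stop("response must be strictly positive to invert")
  if (any(response >= params$v_max, na.rm = TRUE))
    stop("response at or above v_max: effective intensity unbounded")
  params$k * (response / (params$v_max - response))^(1 / params$n)
}

#' A response--log-intensity (VlogI) series
#'
#' @param od Neutral-density steps (optical density), within \[0, 3.5\].
#' @param response_mv Response amplitudes (mV), non-negative.
#' @param reference_flux Relative photon flux at OD 0 (default 1). The
#'   stimulus intensity at a step is `reference_flux * 10^(-od)`.
#' @return Object of class `vlogi_curve`.
#' @export
vlogi_curve <- function(od, response_mv, reference_flux = 1) {
  if (length(od) != length(response_mv))
    stop("od and response_mv must have equal length")
  if (any(od < 0 | od > 3.5)) stop("OD steps must lie within [0, 3.5]")
  if (any(response_mv < 0)) stop("responses must be non-negative")
  if (anyDuplicated(od)) stop("duplicate OD steps")
  o <- order(od)
  structure(list(od = od[o], response_mv = response_mv[o],
                 reference_flux = reference_flux),
            class = "vlogi_curve")
}

#' Intensities of a VlogI series
#' @param curve A [vlogi_curve()].
#' @return Relative photon flux per step.
#' @export
vlogi_intensity <- function(curve) {
  stopifnot(inherits(curve, "vlogi_curve"))
  curve$reference_flux * 10^(-curve$od)
}

#' Fit the Naka-Rushton equation to a VlogI series
#'
#' Bounded nonlinear least squares (Levenberg-Marquardt via
#' [minpack.lm::nlsLM]) with a deterministic multi-start over
#' n in \{0.6, 1, 1.5\} and K initialised at the intensity of the step whose
#' response is closest to half the observed maximum. Starts are compared by
#' residual sum of squares, ties broken toward the lowest n. The fit is
#' deterministic given the data and the optional user guess.
#'
#' @param curve A [vlogi_curve()] with at least 4 distinct OD steps spanning
#'   at least 2 OD units.
#' @param initial_guess Optional [naka_rushton_params()] added to the start
#'   set; the returned RSS never exceeds the guess's RSS.
#' @return A [naka_rushton_params()] with attributes `rss` and `converged`.
#' @export
fit_naka_rushton <- function(curve, initial_guess = NULL) {
  stopifnot(inherits(curve, "vlogi_curve"))
  if (length(curve$od) < 4L) stop("need at least 4 distinct OD steps")
  if (diff(range(curve$od)) < 2) stop("OD steps must span at least 2 OD units")
  v <- curve$response_mv
  intensity <- vlogi_intensity(curve)
  vmax_obs <- max(v)
  if (vmax_obs <= 0) stop("flat (all-zero) VlogI curve: fit ill-conditioned")
  if (diff(range(v)) < 0.02 * vmax_obs)
    warning("saturated VlogI curve (all responses within 2% of maximum): fit ill-conditioned")

  k0 <- intensity[which.min(abs(v - vmax_obs / 2))]
  starts <- lapply(c(0.6, 1, 1.5), function(n0)
    c(v_max = vmax_obs * 1.05, k = k0, n = n0))
  if (!is.null(initial_guess)) {
    stopifnot(inherits(initial_guess, "naka_rushton"))
    starts <- c(starts, list(c(v_max = initial_guess$v_max,
                               k = initial_guess$k, n = initial_guess$n)))
  }

  rss_of <- function(p) sum((v - p[1] * intensity^p[3] /
                               (intensity^p[3] + p[2]^p[3]))^2)
  eps <- 1e-8
  best <- NULL
  any_conv <- FALSE
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        v ~ vm * intensity^nn / (intensity^nn + kk^nn),
        data = list(v = v, intensity = intensity),
        start = list(vm = st[["v_max"]], kk = st[["k"]], nn = st[["n"]]),
        lower = c(eps, eps, 0.05), upper = c(10 * vmax_obs, 1e6, 10),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    any_conv <- TRUE
    p <- stats::coef(fit)
    cand <- c(v_max = unname(p[["vm"]]), k = unname(p[["kk"]]),
              n = unname(p[["nn"]]))
    r <- rss_of(cand)
    if (is.null(best) || r < best$rss - 1e-12 ||
        (abs(r - best$rss) <= 1e-12 && cand[["n"]] < best$par[["n"]])) {
      best <- list(par = cand, rss = r)
    }
  }
  if (is.null(best)) {
    # fall back to best start evaluated directly, flagged unconverged
    rs <- vapply(starts, rss_of, numeric(1))
    best <- list(par = starts[[which.min(rs)]], rss = min(rs))
  }
  if (!is.null(initial_guess)) {
    g <- c(v_max = initial_guess$v_max, k = initial_guess$k, n = initial_guess$n)
    if (rss_of(g) < best$rss) best <- list(par = g, rss = rss_of(g))
  }
  out <- naka_rushton_params(best$par[["v_max"]], best$par[["k"]],
                             best$par[["n"]])
  attr(out, "rss") <- best$rss
  attr(out, "converged") <- any_conv
  if (!any_conv)
    warning("Naka-Rushton fit did not converge; returning best start parameters")
  out
}
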