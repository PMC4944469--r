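#' Generalized Von Bertalanffy cumulative elevation
#'
#' Cumulative elevation of maternal energy intake to time `t`:
#' `A * (1 - exp(-k * t))^c`. `A` (MJ) is the asymptote, `k` (1/day) the
#' theoretical rate of intake elevation and `c` a dimensionless exponent
#' controlling the shape of the rise.
#'
#' @param A asymptote, MJ; > 0.
#' @param k rate, 1/day; > 0.
#' @param c shape-controlling exponent; > 0.
#' @param t days since the initial measurement; >= 0.
#' @return MJ (vectorized over `t`).
#' @export
vb_cumulative <- function(A, k, c, t) {
  check_vb_params(A, k, c)
  if (any(t < 0)) stop("`t` must be >= 0", call. = FALSE)
  A * (1 - exp(-k * t))^c
}

#' Rate of intake elevation (extra intake) under the Von Bertalanffy model
#'
#' Derivative of [vb_cumulative()] with respect to time: the intake above
#' the initial rate at day `t`.
#'
#' @inheritParams vb_cumulative
#' @return MJ/day (vectorized over `t`).
#' @export
vb_rate <- function(A, k, c, t) {
  check_vb_params(A, k, c)
  if (any(t < 0)) stop("`t` must be >= 0", call. = FALSE)
  A * c * k * exp(-k * t) * (1 - exp(-k * t))^(c - 1)
}

check_vb_params <- function(A, k, c) {
  if (A <= 0 || k <= 0 || c <= 0) {
    stop("require A > 0, k > 0, c > 0", call. = FALSE)
  }
  invisible(TRUE)
}

#' Characteristics derived from Von Bertalanffy parameters
#'
#' The extra-intake rate `A*c*k*exp(-kt)*(1-exp(-kt))^(c-1)` is maximized
#' at `t = log(c)/k` (natural log; setting its derivative to zero gives
#' `exp(-kt) = 1/c`). Substituting back gives the amplitude
#' `A*k*(1-1/c)^(c-1)` and, through the cumulative curve, the cumulative
#' elevation to peak `A*(1-1/c)^c`. The dimensionless shape statistic
#' `(1-1/c)/log(c)` ties the three together:
#' `cumulative_to_peak = amplitude * time_to_peak * shape`. A shape of 0.5
#' corresponds to a perfectly linear rise (triangular area); > 0.5 to a
#' concave-down (decelerating) and < 0.5 to a concave-up (accelerating)
#' elevation. Only `c > 1` yields an interior peak.
#'
#' @inheritParams vb_cumulative
#' @return list with `time_to_peak` (days), `amplitude` (MJ/day),
#'   `cumulative_to_peak` (MJ) and `shape` (dimensionless).
#' @export
derived_characteristics <- function(A, k, c) {
  check_vb_params(A, k, c)
  if (c <= 1) {
    stop("no interior peak for c <= 1: the extra-intake rate is maximal at t = 0",
         call. = FALSE)
  }
  list(time_to_peak = log(c) / k,
       amplitude = A * k * (1 - 1 / c)^(c - 1),
       cumulative_to_peak = A * (1 - 1 / c)^c,
       shape = (1 - 1 / c) / log(c))
}

#' Normalized root-mean-square error
#'
#' RMSE divided by the range (max - min) of the observations.
#'
#' @param observed,fitted numeric vectors of equal length (>= 2 values).
#' @return fraction; `NA` (with a warning) when the observed range is zero.
#' @export
normalized_rmse <- function(observed, fitted) {
  if (length(observed) < 2 || length(observed) != length(fitted)) {
    stop("need >= 2 paired observations", call. = FALSE)
  }
  rng <- max(observed) - min(observed)
  if (rng == 0) {
    warning("observed range is zero; nRMSE undefined")
    return(NA_real_)
  }
  sqrt(mean((observed - fitted)^2)) / rng
}

#' Cumulative-elevation series of a pattern
#'
#' Rectangle-rule running sum of the excess over the initial rate, on a
#' time axis re-zeroed at the initial measurement. The first point is
#' (0, 0) by construction.
#'
#' @param pattern an [intake_pattern].
#' @return data frame with columns `s` (days since initial measurement),
#'   `cumulative` (MJ) and `extra_rate` (MJ/day, excess over initial rate).
#' @export
cumulative_series <- function(pattern) {
  a <- analysable(pattern)
  dt <- grid_spacing(a$times)
  extra <- a$mei - a$mei[[1]]
  data.frame(s = a$times - a$times[[1]],
             cumulative = cumsum(extra * dt),
             extra_rate = extra)
}

#' Fit the generalized Von Bertalanffy model to one pattern
#'
#' Least-squares fit of `A*(1-exp(-k*s))^c` to the cumulative-elevation
#' series of a pattern (Levenberg-Marquardt with box constraints).
#' Starting values: `A0 = 1.05 * max(cumulative)`, `c0 = 2`,
#' `k0 = log(c0) / t_peak_raw`, with the raw time to peak as the `t_peak`
#' guess. Box constraints: `A` in (0, 10*max cumulative], `k` in (0, 10],
#' `c` in (1, 100] — `c <= 1` gives no interior peak, so the
#' decomposition would be undefined.
#'
#' @param pattern an [intake_pattern], or a data frame with columns `s`
#'   and `cumulative` (as from [cumulative_series()]).
#' @return object of class `vb_fit`: list with `A`, `k`, `c`, `converged`,
#'   `nrmse_cumulative`, `nrmse_rate`, `derived` (see
#'   [derived_characteristics()]), `t_peak_raw_elapsed` and `pattern_id`.
#'   Non-converged fits carry `NA` parameters.
#' @export
fit_vb <- function(pattern) {
  if (inherits(pattern, "intake_pattern")) {
    ser <- cumulative_series(pattern)
    raw_pk <- peak_rate_and_time(pattern)
    t_peak_guess <- raw_pk$time_to_peak - analysable(pattern)$times[[1]]
    id <- pattern$pattern_id
  } else {
    ser <- pattern
    if (is.null(ser$extra_rate)) ser$extra_rate <- NA_real_
    t_peak_guess <- ser$s[which.max(ser$cumulative)]
    id <- NA_character_
  }
  if (nrow(ser) < 3) stop("need >= 3 points to fit", call. = FALSE)
  max_cum <- max(ser$cumulative)
  if (max_cum <= 0) stop("degenerate series: no positive cumulative elevation",
                         call. = FALSE)
  if (t_peak_guess <= 0) t_peak_guess <- max(ser$s) / 2

  start <- list(A = 1.05 * max_cum, k = log(2) / t_peak_guess, c = 2)
  lower <- c(A = 1e-8, k = 1e-8, c = 1 + 1e-6)
  upper <- c(A = 10 * max_cum, k = 10, c = 100)

  fit <- tryCatch(
    minpack.lm::nlsLM(cumulative ~ A * (1 - exp(-k * s))^c,
                      data = ser, start = start,
                      lower = lower, upper = upper,
                      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) NULL)

  if (is.null(fit)) {
    return(structure(list(A = NA_real_, k = NA_real_, c = NA_real_,
                          converged = FALSE,
                          nrmse_cumulative = NA_real_, nrmse_rate = NA_real_,
                          derived = NULL,
                          t_peak_raw_elapsed = t_peak_guess,
                          pattern_id = id),
                     class = "vb_fit"))
  }
  p <- coef(fit)
  der <- derived_characteristics(p[["A"]], p[["k"]], p[["c"]])
  fitted_cum <- vb_cumulative(p[["A"]], p[["k"]], p[["c"]], ser$s)
  nr_cum <- normalized_rmse(ser$cumulative, fitted_cum)
  nr_rate <- if (all(is.finite(ser$extra_rate))) {
    fitted_rate <- vb_rate(p[["A"]], p[["k"]], p[["c"]], ser$s)
    normalized_rmse(ser$extra_rate, fitted_rate)
  } else NA_real_
  structure(list(A = p[["A"]], k = p[["k"]], c = p[["c"]],
                 converged = TRUE,
                 nrmse_cumulative = nr_cum, nrmse_rate = nr_rate,
                 derived = der,
                 t_peak_raw_elapsed = t_peak_guess,
                 pattern_id = id),
            class = "vb_fit")
}

#' @export
print.vb_fit <- function(x, ...) {
  if (!x$converged) {
    cat("<vb_fit> not converged\n")
    return(invisible(x))
  }
  cat(sprintf("<vb_fit> A = %.3g MJ, k = %.3g /day, c = %.3g\n",
              x$A, x$k, x$c))
  cat(sprintf("  time to peak %.2f d, amplitude %.3g MJ/d, shape %.3f; nRMSE(cum) %.1f%%\n",
              x$derived$time_to_peak, x$derived$amplitude,
              x$derived$shape, 100 * x$nrmse_cumulative))
  invisible(x)
}

#' Flag abnormal fits across a cohort
#'
#' For each converged fit, the relative difference
#' `(t_peak_model - t_peak_raw) / t_peak_raw` between the model-derived
#' and the raw time to peak is computed; fits whose `r` falls outside the
#' Tukey fences (Q1 - 1.5 IQR, Q3 + 1.5 IQR) of the cohort distribution
#' are flagged abnormal. With zero IQR and all values identical no fit is
#' flagged. Screening requires at least 4 converged fits; otherwise it is
#' skipped with a warning and nothing is flagged.
#'
#' @param fits list of `vb_fit` objects (non-converged entries are ignored).
#' @return data frame: pattern_id, rel_diff, abnormal, reason.
#' @export
detect_abnormal_fits <- function(fits) {
  conv <- Filter(function(f) isTRUE(f$converged), fits)
  out <- data.frame(
    pattern_id = vapply(conv, function(f) f$pattern_id, character(1)),
    rel_diff = vapply(conv, function(f) {
      (f$derived$time_to_peak - f$t_peak_raw_elapsed) / f$t_peak_raw_elapsed
    }, numeric(1)),
    stringsAsFactors = FALSE)
  if (nrow(out) < 4) {
    warning("fewer than 4 converged fits; abnormal-fit screening skipped")
    out$abnormal <- FALSE
    out$reason <- ""
    return(out)
  }
  q <- quantile(out$rel_diff, c(0.25, 0.75), names = FALSE, type = 7)
  iqr <- q[2] - q[1]
  lo <- q[1] - 1.5 * iqr
  hi <- q[2] + 1.5 * iqr
  out$abnormal <- out$rel_diff < lo | out$rel_diff > hi
  out$reason <- ifelse(out$abnormal,
                       sprintf("time-to-peak rel. diff %.3g outside [%.3g, %.3g]",
                               out$rel_diff, lo, hi),
                       "")
  out
}

#' Fit the Von Bertalanffy model to every pattern and screen the fits
#'
#' @param patterns list of [intake_pattern] objects.
#' @return data frame, one row per pattern: A, k, c, converged, derived
#'   characteristics (time_to_peak etc. in elapsed days), shape, nRMSEs,
#'   abnormal flag and reason.
#' @export
vb_fit_table <- function(patterns) {
  fits <- lapply(patterns, function(p) {
    tryCatch(fit_vb(p), error = function(e) {
      structure(list(A = NA_real_, k = NA_real_, c = NA_real_,
                     converged = FALSE,
                     nrmse_cumulative = NA_real_, nrmse_rate = NA_real_,
                     derived = NULL, t_peak_raw_elapsed = NA_real_,
                     pattern_id = p$pattern_id),
                class = "vb_fit")
    })
  })
  screen <- suppressWarnings(detect_abnormal_fits(fits))
  rows <- lapply(fits, function(f) {
    data.frame(
      pattern_id = f$pattern_id,
      A = f$A, k = f$k, c = f$c,
      converged = f$converged,
      time_to_peak = if (f$converged) f$derived$time_to_peak else NA_real_,
      amplitude = if (f$converged) f$derived$amplitude else NA_real_,
      cumulative_to_peak = if (f$converged) f$derived$cumulative_to_peak else NA_real_,
      shape = if (f$converged) f$derived$shape else NA_real_,
      nrmse_cumulative = f$nrmse_cumulative,
      nrmse_rate = f$nrmse_rate,
      stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab$abnormal <- FALSE
  tab$abnormal_reason <- ""
  m <- match(screen$pattern_id, tab$pattern_id)
  tab$abnormal[m] <- screen$abnormal
  tab$abnormal_reason[m] <- screen$reason
  tab
}
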