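#' Calibration model for sensors with an exponential calibration curve
#'
#' Optical sensors such as plate-embedded dissolved-oxygen spots often relate
#' the measured quantity `y` to the instrument output `x` through an
#' exponential law `x = P + S * exp(alpha * y)` with plateau `P`, span `S`
#' and exponent factor `alpha`. Per-sensor gain differences then act
#' multiplicatively in the log domain `z = ln((x - P) / S)`, which is what
#' the two-step correction ([correct_sensors()]) exploits: `alpha` cancels in
#' the correction itself and is only needed when fitting the curve from
#' multi-level data ([estimate_calibration()]).
#'
#' @param plateau Plateau `P`, in measurement units.
#' @param span Span `S`, in measurement units; must be nonzero.
#' @param window Length-2 numeric, the calibration time window `[t0, t1]`
#'   during which the true value is known and stable. Must cover at least 2
#'   time points of the table it is used with (10 or more in practice).
#' @param alpha Optional exponent factor (per inverse measurement unit).
#' @return A list of class `calibration_model`.
#' @export
calibration_model <- function(plateau, span, window, alpha = NULL) {
  stopifnot(is.numeric(plateau), length(plateau) == 1,
            is.numeric(span), length(span) == 1, span != 0,
            is.numeric(window), length(window) == 2, window[1] < window[2])
  structure(list(plateau = plateau, span = span,
                 window = as.numeric(window), alpha = alpha),
            class = "calibration_model")
}

#' @export
print.calibration_model <- function(x, ...) {
  cat("<calibration_model> x = P + S*exp(alpha*y)\n",
      " P = ", x$plateau, ", S = ", x$span,
      if (!is.null(x$alpha)) paste0(", alpha = ", x$alpha),
      "; window [", x$window[1], ", ", x$window[2], "]\n", sep = "")
  invisible(x)
}

window_rows <- function(table, calib) {
  rows <- which(table$time >= calib$window[1] & table$time <= calib$window[2])
  if (length(rows) < 2)
    stop("calibration window [", calib$window[1], ", ", calib$window[2],
         "] covers fewer than 2 time points", call. = FALSE)
  rows
}

#' Log-domain transform of sensor readings
#'
#' Converts readings to the form in which sensor gain is additive-free:
#' `z = ln((x - P) / S)`. Values at or below the plateau make the transform
#' undefined; the default is a hard error enumerating the offending cells,
#' and `clip_epsilon` opts into clipping `(x - P)/S` from below for
#' exploratory use.
#'
#' @param x Numeric vector, or an [assay table][as_assay_table] (every
#'   measurement column is transformed; time untouched).
#' @param calib A [calibration_model()].
#' @param clip_epsilon `NULL` (error on non-positive arguments) or a small
#'   positive floor such as `1e-9`.
#' @return Same shape as `x`, in log-domain units.
#' @export
to_log_domain <- function(x, calib, clip_epsilon = NULL) {
  if (inherits(x, "data.frame")) {
    z <- tibble::as_tibble(x)
    for (nm in measure_names(x))
      z[[nm]] <- log_arg_checked(x[[nm]], calib, clip_epsilon,
                                 where = paste0("sensor '", nm, "', time "),
                                 times = x$time)
    return(restamp(z, x, value_unit = "log domain"))
  }
  log_arg_checked(x, calib, clip_epsilon)
}

log_arg_checked <- function(x, calib, clip_epsilon, where = "position ",
                            times = seq_along(x)) {
  a <- (x - calib$plateau) / calib$span
  bad <- which(!is.na(a) & a <= 0)
  if (length(bad)) {
    if (is.null(clip_epsilon))
      stop("log-domain transform undefined (reading <= plateau) at: ",
           paste0(where, format(times[utils::head(bad, 10)], trim = TRUE),
                  collapse = "; "),
           if (length(bad) > 10) paste0(" (and ", length(bad) - 10, " more)"),
           call. = FALSE)
    a[bad] <- clip_epsilon
  }
  log(a)
}

from_log_domain <- function(z, calib) calib$plateau + calib$span * exp(z)

#' Per-sensor correction factors from the calibration window
#'
#' For each sensor the mean `m_s` of its log-domain values over the
#' calibration window is computed, together with the plate mean `m_p` (the
#' average of all sensor means). The correction factor of sensor `s` is
#' `m_p / m_s`: rescaling log-domain values by it equalizes per-sensor gain.
#'
#' @inheritParams to_log_domain
#' @param table Assay table of raw readings.
#' @return A tibble of class `correction_factors` with columns `well`, `m_s`
#'   and `factor`, plate mean in attribute `m_p`, window row count in `n`.
#' @export
compute_factors <- function(table, calib, clip_epsilon = NULL) {
  rows <- window_rows(table, calib)
  z <- to_log_domain(table[rows, ], calib, clip_epsilon)
  m_s <- vapply(measure_names(z), function(nm) mean(z[[nm]], na.rm = TRUE),
                numeric(1))
  if (any(!is.finite(m_s)))
    stop("sensor mean not finite for: ",
         paste(names(m_s)[!is.finite(m_s)], collapse = ", "), call. = FALSE)
  if (any(m_s == 0))
    stop("sensor mean is zero (correction factor undefined) for: ",
         paste(names(m_s)[m_s == 0], collapse = ", "), call. = FALSE)
  m_p <- mean(m_s)
  structure(tibble::tibble(well = names(m_s), m_s = unname(m_s),
                           factor = m_p / unname(m_s)),
            class = c("correction_factors", class(tibble::tibble())),
            m_p = m_p, n = length(rows))
}

#' Step 1 of sensor correction: logarithmic recalibration
#'
#' Applies `x' = P + S * exp((m_p / m_s) * z)` elementwise, where `z` is the
#' log-domain reading. Sensors that read identically over the calibration
#' window map to identical corrected series; if all factors are 1 the map is
#' the identity.
#'
#' @inheritParams compute_factors
#' @param factors A [compute_factors()] result for the same table and
#'   calibration; computed on the fly when omitted.
#' @return Corrected `assay_table`.
#' @export
recalibrate <- function(table, calib, factors = NULL, clip_epsilon = NULL) {
  factors <- factors %||% compute_factors(table, calib, clip_epsilon)
  stopifnot(setequal(factors$well, measure_names(table)))
  z <- to_log_domain(table, calib, clip_epsilon)
  out <- tibble::as_tibble(table)
  f <- setNames(factors$factor, factors$well)
  for (nm in measure_names(table))
    out[[nm]] <- from_log_domain(f[[nm]] * z[[nm]], calib)
  restamp(out, table)
}

#' Step 2 of sensor correction: linear normalization to a target value
#'
#' Multiplies each sensor by `target / mean(sensor over the calibration
#' window)`, so that every sensor's window mean equals `target` exactly
#' afterwards. Run this after [recalibrate()]; the order matters.
#'
#' @inheritParams compute_factors
#' @param target Target value in measurement units (e.g. `91.3` % a.s.).
#' @return Normalized `assay_table`.
#' @export
normalize_to_target <- function(table, calib, target) {
  stopifnot(is.numeric(target), length(target) == 1, is.finite(target))
  rows <- window_rows(table, calib)
  out <- tibble::as_tibble(table)
  for (nm in measure_names(table)) {
    m <- mean(table[[nm]][rows], na.rm = TRUE)
    if (!is.finite(m) || m == 0)
      stop("calibration-window mean of sensor '", nm,
           "' is zero or undefined", call. = FALSE)
    out[[nm]] <- table[[nm]] * (target / m)
  }
  restamp(out, table)
}

#' Two-step sensor correction
#'
#' Convenience composition of [compute_factors()], [recalibrate()] and
#' [normalize_to_target()]: logarithmic recalibration equalizes per-sensor
#' gain, linear normalization then sets every sensor's calibration-window
#' mean to the target value.
#'
#' @inheritParams normalize_to_target
#' @inheritParams to_log_domain
#' @return Corrected `assay_table`; the factors used are attached as
#'   attribute `correction_factors`.
#' @examples
#' calib <- calibration_model(plateau = 0, span = 1, window = c(0, 1))
#' tbl <- as_assay_table(data.frame(t = c(0, 1), A = exp(c(2, 2)),
#'                                  B = exp(c(4, 4))))
#' corrected <- correct_sensors(tbl, calib, target = exp(3))
#' @export
correct_sensors <- function(table, calib, target, clip_epsilon = NULL) {
  f <- compute_factors(table, calib, clip_epsilon)
  out <- recalibrate(table, calib, f, clip_epsilon)
  out <- normalize_to_target(out, calib, target)
  attr(out, "correction_factors") <- f
  out
}

#' Estimate the exponential calibration curve from multi-level data
#'
#' Nonlinear least squares for `x = P + S * exp(alpha * y)` given readings at
#' three or more known true values. This is an optional helper: the two-step
#' correction itself only needs `P` and `S` (which normally come from the
#' sensor vendor's calibration sheet), since `alpha` cancels in the
#' correction algebra.
#'
#' @param levels Data frame with columns `true_value` (`y`) and `reading`
#'   (`x`), one row per observation; at least 3 distinct true values.
#' @param window Calibration window stored in the returned model (defaults to
#'   a placeholder `[0, 1]`).
#' @return A [calibration_model()] with `alpha` set, with the fit kept in
#'   attribute `fit`.
#' @export
estimate_calibration <- function(levels, window = c(0, 1)) {
  stopifnot(is.data.frame(levels),
            all(c("true_value", "reading") %in% names(levels)))
  levels <- levels[stats::complete.cases(levels[c("true_value", "reading")]), ]
  if (length(unique(levels$true_value)) < 3)
    stop("need readings at >= 3 distinct true values", call. = FALSE)
  y <- levels$true_value; x <- levels$reading
  # linearized start: guess the plateau just off the data range, then
  # lm(log(x - P0) ~ y) for S and alpha
  dr <- diff(range(x))
  incr <- stats::cor(x, y) >= 0
  P0 <- if (incr) min(x) - 0.05 * max(dr, 1) else max(x) + 0.05 * max(dr, 1)
  lf <- stats::lm(log(abs(x - P0)) ~ y)
  S0 <- if (incr) exp(coef(lf)[[1]]) else -exp(coef(lf)[[1]])
  a0 <- coef(lf)[[2]]
  fit <- tryCatch(
    minpack.lm::nlsLM(reading ~ P + S * exp(alpha * true_value),
                      data = levels,
                      start = list(P = P0, S = S0, alpha = a0),
                      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e)
      stop("calibration fit did not converge (", conditionMessage(e),
           "); enter plateau and span manually", call. = FALSE))
  est <- coef(fit)
  if (abs(est[["alpha"]] * diff(range(y))) < 0.1)
    warning("estimated alpha is ~0: the calibration relationship looks ",
            "linear, not exponential; the fitted plateau/span are degenerate",
            call. = FALSE)
  out <- calibration_model(plateau = est[["P"]], span = est[["S"]],
                           window = window, alpha = est[["alpha"]])
  attr(out, "fit") <- fit
  out
}
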