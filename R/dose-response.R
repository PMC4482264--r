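#' The log-logistic dose-response family
#'
#' Evaluates the `k`-parameter log-logistic model
#' \deqn{f(x) = c + \frac{d - c}{(1 + (x/e)^b)^g}}
#' at doses `x >= 0`. With asymmetry `g = 1` this is the four-parameter
#' log-logistic (equivalently `c + (d - c)/(1 + exp(b(\log x - \log e)))`):
#' `b` the slope, `c` the lower and `d` the upper limit, and `e` the
#' inflection dose — the IC50/EC50 when responses run between `c` and `d`.
#' `x = 0` is handled as the one-sided limit (`d` when `b > 0`, `c` when
#' `b < 0`), so zero-dose controls enter fits without ever taking `log(0)`.
#'
#' The reduced families fix parameters: LL2 has `c = 0, d = 1`; LL3 has
#' `c = 0`; LL5 frees the asymmetry exponent `g > 0`.
#'
#' @param x Dose vector, `x >= 0`.
#' @param b Slope; positive for a response decreasing with dose.
#' @param c,d Lower and upper asymptotes.
#' @param e Inflection dose, `e > 0`.
#' @param g Asymmetry exponent (`1` for the symmetric families).
#' @return Numeric vector of responses.
#' @examples
#' loglogistic(50, b = 1, c = 0, d = 100, e = 50)  # midpoint: 50
#' loglogistic(0, b = 1, c = 0, d = 100, e = 50)   # zero-dose limit: 100
#' @export
loglogistic <- function(x, b, c = 0, d = 1, e, g = 1) {
  stopifnot(all(x >= 0, na.rm = TRUE))
  n <- max(length(x), length(b), length(c), length(d), length(e), length(g))
  x <- rep_len(x, n); b <- rep_len(b, n); e <- rep_len(e, n)
  r <- ifelse(x == 0,
              ifelse(b > 0, 0, ifelse(b < 0, Inf, 1)),
              (x / e)^b)
  c + (d - c) / (1 + r)^g
}

ll_families <- list(
  LL2 = list(free = c("b", "e"),           fixed = c(c = 0, d = 1)),
  LL3 = list(free = c("b", "d", "e"),      fixed = c(c = 0)),
  LL4 = list(free = c("b", "c", "d", "e"), fixed = numeric(0)),
  LL5 = list(free = c("b", "c", "d", "e", "g"), fixed = numeric(0)))

#' Fit a log-logistic dose-response model at one time point
#'
#' Nonlinear least squares (Levenberg–Marquardt) of a [loglogistic()] family
#' to responses observed at a set of doses. Initialization follows the usual
#' heuristic — `c0 = min`, `d0 = max` response, `e0` the dose whose response
#' is nearest the midpoint `(c0 + d0)/2`, `b0 = +1` when response decreases
#' with dose, `-1` otherwise — and can be overridden. `e` is constrained to
#' `(0, 10 * max(dose)]`. Missing responses are dropped pairwise.
#'
#' Non-convergence (or too few usable doses) never throws: the returned fit
#' carries `converged = FALSE`, so time-resolved trajectories continue past
#' bad time points.
#'
#' @param doses Numeric dose vector (zero allowed).
#' @param responses Numeric responses, same length.
#' @param family `"LL2"`, `"LL3"`, `"LL4"` (default) or `"LL5"`.
#' @param init Named list overriding initial values, e.g. `list(e = 60)`.
#' @param time Optional time stamp carried into the result.
#' @return An object of class `dose_response_fit`: estimates, standard errors
#'   (from the Jacobian at the optimum), residual standard error,
#'   convergence flag. [tidy()] and [glance()] methods are provided.
#' @examples
#' d <- c(0, 10, 30, 60, 100, 300)
#' y <- loglogistic(d, b = 2, c = 10, d = 95, e = 60)
#' fit <- fit_dose_response(d, y)
#' coef(fit)[["e"]]
#' @export
fit_dose_response <- function(doses, responses, family = "LL4",
                              init = NULL, time = NA_real_) {
  family <- match.arg(family, names(ll_families))
  fam <- ll_families[[family]]
  stopifnot(length(doses) == length(responses), all(doses >= 0, na.rm = TRUE))
  keep <- !is.na(doses) & !is.na(responses) & is.finite(responses)
  n_dropped <- sum(!keep)
  x <- doses[keep]; y <- responses[keep]
  n_min <- length(fam$free) + 1
  failed <- function(msg) new_drfit(family, fam, est = NULL, se = NULL,
                                    rse = NA_real_, converged = FALSE,
                                    n = length(x), n_dropped = n_dropped,
                                    time = time, message = msg,
                                    doses = x, responses = y)
  if (length(unique(x)) < n_min)
    return(failed(paste0("need >= ", n_min, " distinct doses")))
  if (diff(range(y)) == 0)
    return(failed("degenerate: responses are constant, no dose effect"))
  start <- ll_start(x, y, fam)
  if (!is.null(init)) start[names(init)] <- unlist(init)
  lower <- setNames(rep(-Inf, length(fam$free)), fam$free)
  upper <- setNames(rep(Inf, length(fam$free)), fam$free)
  lower[["e"]] <- 1e-12
  upper[["e"]] <- 10 * max(x)
  if ("g" %in% fam$free) lower[["g"]] <- 1e-6
  fixed <- as.list(fam$fixed)
  fn <- function(p) {
    a <- c(as.list(p), fixed)
    loglogistic(x, b = a$b, c = a$c, d = a$d, e = a$e, g = a$g %||% 1)
  }
  fit <- tryCatch(
    minpack.lm::nls.lm(par = start[fam$free],
                       lower = lower[fam$free], upper = upper[fam$free],
                       fn = function(p) y - fn(p),
                       control = minpack.lm::nls.lm.control(
                         maxiter = 1000, ftol = 1e-8)),
    error = function(e) NULL)
  if (is.null(fit) || !fit$info %in% 1:4)
    return(failed(if (is.null(fit)) "optimizer error" else fit$message))
  est <- coef(fit)
  dof <- length(y) - length(est)
  rse <- sqrt(sum(fit$fvec^2) / max(dof, 1))
  se <- tryCatch(
    setNames(summary(fit)$coefficients[, "Std. Error"], names(est)),
    error = function(e) setNames(rep(NA_real_, length(est)), names(est)))
  if (!all(is.finite(est))) return(failed("non-finite estimates"))
  new_drfit(family, fam, est = est, se = se, rse = rse, converged = TRUE,
            n = length(y), n_dropped = n_dropped, time = time,
            message = fit$message, doses = x, responses = y)
}

ll_start <- function(x, y, fam) {
  c0 <- min(y); d0 <- max(y)
  decreasing <- isTRUE(suppressWarnings(stats::cor(x, y)) < 0)
  mid <- (c0 + d0) / 2
  pos <- x > 0
  e0 <- if (any(pos)) x[pos][which.min(abs(y[pos] - mid))] else 1
  list(b = if (decreasing) 1 else -1, c = c0, d = d0, e = e0, g = 1)
}

new_drfit <- function(family, fam, est, se, rse, converged, n, n_dropped,
                      time, message, doses, responses) {
  full <- c(b = NA_real_, c = NA_real_, d = NA_real_, e = NA_real_)
  if (family == "LL5") full <- c(full, g = NA_real_)
  full[names(fam$fixed)] <- fam$fixed
  se_full <- full * NA_real_
  if (!is.null(est)) {
    full[names(est)] <- est
    se_full[names(se)] <- se
  }
  structure(list(family = family, estimates = full, se = se_full,
                 free = fam$free, rse = rse, converged = converged,
                 n = n, n_dropped = n_dropped, time = time,
                 message = message, doses = doses, responses = responses),
            class = "dose_response_fit")
}

#' @export
coef.dose_response_fit <- function(object, ...) object$estimates

#' @export
print.dose_response_fit <- function(x, ...) {
  cat("<dose_response_fit> ", x$family,
      if (is.finite(x$time)) paste0(" at t = ", signif(x$time, 4)),
      if (!x$converged) "  [NOT CONVERGED]", "\n", sep = "")
  print(round(rbind(estimate = x$estimates, se = x$se), 4))
  cat("residual SE ", signif(x$rse, 4), " on ", x$n, " doses\n", sep = "")
  invisible(x)
}

#' Tidiers for dose-response fits
#'
#' @param x A `dose_response_fit`.
#' @param ... Unused.
#' @return `tidy()`: one row per model parameter (`term`, `estimate`,
#'   `std.error`, `fixed`); `glance()`: a one-row summary.
#' @export
tidy.dose_response_fit <- function(x, ...) {
  tibble::tibble(term = names(x$estimates),
                 estimate = unname(x$estimates),
                 std.error = unname(x$se),
                 fixed = !names(x$estimates) %in% x$free)
}

#' @rdname tidy.dose_response_fit
#' @export
glance.dose_response_fit <- function(x, ...) {
  tibble::tibble(family = x$family, time = x$time,
                 ic50 = unname(x$estimates["e"]),
                 ic50.se = unname(x$se["e"]),
                 sigma = x$rse, n = x$n, n.dropped = x$n_dropped,
                 converged = x$converged)
}

#' Time-resolved IC50: fit every selected time point
#'
#' Fits one log-logistic dose-response curve per selected time point of a
#' time-resolved viability measurement and assembles the fitted inflection
#' parameter `e` — the IC50/EC50 — into a trajectory over time. Doses come
#' from the plate layout; by default each dose's technical replicates are
#' averaged first (pass an [aggregate_replicates()] result, or the raw table
#' with `use_replicates = TRUE` to fit every replicate point).
#'
#' Failed fits are flagged, not fatal: they appear in the trajectory with
#' `converged = FALSE` and neighbouring time points are unaffected.
#'
#' @param table An `aggregated_table` (columns = replicate groups) or a raw
#'   [assay table][as_assay_table] (columns = wells).
#' @param layout A [plate_layout()] with doses on all sample wells.
#' @param family Log-logistic family, see [fit_dose_response()].
#' @param t_min,t_max Time window over which to fit (defaults: whole range).
#' @param stride Fit every `stride`-th time point within the window.
#' @param use_replicates If `TRUE`, fit all replicate wells as individual
#'   points instead of group means.
#' @return A tibble of class `ic50_trajectory` with columns `time`,
#'   `ic50` (the fitted `e`), `se` and `converged`; the full list of
#'   [fit_dose_response()] objects is in attribute `"fits"`.
#' @export
fit_ic50_over_time <- function(table, layout, family = "LL4",
                               t_min = -Inf, t_max = Inf, stride = 1L,
                               use_replicates = FALSE) {
  stopifnot(stride >= 1)
  validate_layout(layout, require_dose = TRUE)
  # columns may be wells (raw/replicate fits) or replicate groups
  # (aggregated or smoothed-aggregated data); recognise either
  mn <- measure_names(table)
  samp <- layout[layout$role == "sample", ]
  if (!use_replicates && !all(mn %in% layout$well) &&
      any(mn %in% samp$group)) {
    dose_by_group <- tapply(samp$dose, samp$group, function(d) {
      u <- unique(d)
      if (length(u) > 1)
        stop("replicate group with several doses", call. = FALSE)
      u
    })
    cols <- intersect(mn, names(dose_by_group))
    doses <- as.numeric(dose_by_group[cols])
  } else {
    samp <- samp[samp$well %in% mn, ]
    if (!nrow(samp))
      stop("no sample wells or groups of the layout found in the table",
           call. = FALSE)
    cols <- samp$well
    doses <- samp$dose
  }
  fam <- ll_families[[match.arg(family, names(ll_families))]]
  if (length(unique(doses)) < length(fam$free) + 1)
    stop("need at least ", length(fam$free) + 1, " distinct doses, have ",
         length(unique(doses)), call. = FALSE)
  rows <- which(table$time >= t_min & table$time <= t_max)
  if (!length(rows)) stop("time window selects no time points", call. = FALSE)
  rows <- rows[seq(1, length(rows), by = stride)]
  resp <- as.matrix(table[cols])
  fits <- lapply(rows, function(i)
    fit_dose_response(doses, resp[i, ], family = family,
                      time = table$time[i]))
  out <- tibble::tibble(
    time = table$time[rows],
    ic50 = vapply(fits, function(f) unname(f$estimates["e"]), numeric(1)),
    se = vapply(fits, function(f) unname(f$se["e"]), numeric(1)),
    converged = vapply(fits, function(f) f$converged, logical(1)))
  structure(out, class = c("ic50_trajectory", class(tibble::tibble())),
            fits = fits, family = family,
            dose_unit = samp$dose_unit[1] %||% "",
            time_unit = time_unit(table))
}

#' @rdname fit_ic50_over_time
#' @param x An `ic50_trajectory`.
#' @param ... Unused.
#' @export
glance.ic50_trajectory <- function(x, ...) {
  ok <- x$converged
  tibble::tibble(n.fits = nrow(x), n.converged = sum(ok),
                 ic50.start = x$ic50[ok][1],
                 ic50.end = rev(x$ic50[ok])[1],
                 time.start = x$time[ok][1],
                 time.end = rev(x$time[ok])[1])
}
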