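#' Normalize all wells to a reference condition
#'
#' At every time point `t` the mean `m_t` of the reference wells is computed
#' and every value is mapped to `x / m_t * M`. The reference-well mean is
#' therefore exactly `M` at every time point afterwards — cell-free medium
#' controls become straight horizontal lines — and the operation is
#' idempotent. Wells with role `reference` define `m_t`; if none exist,
#' `medium_control` wells do.
#'
#' @param table An [assay table][as_assay_table].
#' @param layout A validated [plate_layout()].
#' @param target Target value `M` the reference mean is set to (e.g. `91.3`
#'   % a.s., or `100` for percent viability).
#' @return An `assay_table` of normalized values.
#' @export
normalize_to_reference <- function(table, layout, target) {
  stopifnot(is.numeric(target), length(target) == 1, is.finite(target))
  validate_layout(layout, table)
  ref <- active_wells(layout, "reference")
  if (!length(ref)) ref <- active_wells(layout, "medium_control")
  if (!length(ref))
    stop("layout has no reference or medium_control wells", call. = FALSE)
  m_t <- rowMeans(as.matrix(table[ref]), na.rm = TRUE)
  bad <- which(!is.finite(m_t) | m_t == 0)
  if (length(bad))
    stop("reference mean is zero or undefined at t = ",
         paste(format(table$time[utils::head(bad, 10)], trim = TRUE),
               collapse = ", "), call. = FALSE)
  out <- tibble::as_tibble(table)
  for (nm in measure_names(table))
    out[[nm]] <- table[[nm]] / m_t * target
  restamp(out, table)
}

#' Average technical replicates
#'
#' Computes, for each replicate group of the layout and each time point, the
#' mean and the sample standard deviation (divisor `n - 1`) of the group's
#' wells, excluding missing values pairwise. Excluded wells are ignored.
#'
#' The result is an [assay table][as_assay_table] of group means (one column
#' per replicate group, in layout order) with the matching SD table in
#' attribute `"sd"` and per-group well counts in attribute `"groups"`; use
#' [tidy()][tidy.aggregated_table] for a long view. Groups of size 1 get
#' SD 0 and a warning.
#'
#' @inheritParams normalize_to_reference
#' @return An `assay_table` of class `aggregated_table`.
#' @export
aggregate_replicates <- function(table, layout) {
  validate_layout(layout, table)
  lay <- layout[layout$role != "excluded" & layout$well %in%
                  measure_names(table), ]
  if (!nrow(lay)) stop("layout defines no replicate groups", call. = FALSE)
  groups <- split(lay$well, factor(lay$group, levels = unique(lay$group)))
  if (any(lengths(groups) == 1))
    warning("replicate group(s) of size 1 (SD set to 0): ",
            paste(names(groups)[lengths(groups) == 1], collapse = ", "),
            call. = FALSE)
  mean_tbl <- sd_tbl <- tibble::tibble(time = table$time)
  for (g in names(groups)) {
    m <- as.matrix(table[groups[[g]]])
    n_obs <- rowSums(!is.na(m))
    mu <- rowMeans(m, na.rm = TRUE)
    mu[n_obs == 0] <- NA_real_
    s <- apply(m, 1, sd, na.rm = TRUE)
    s[n_obs == 1] <- 0
    s[n_obs == 0] <- NA_real_
    mean_tbl[[g]] <- mu
    sd_tbl[[g]] <- s
  }
  out <- restamp(mean_tbl, table)
  class(out) <- c("aggregated_table", class(out))
  attr(out, "sd") <- sd_tbl
  attr(out, "groups") <- groups
  out
}

#' @rdname aggregate_replicates
#' @param x An `aggregated_table`.
#' @param ... Unused.
#' @export
tidy.aggregated_table <- function(x, ...) {
  sd_tbl <- attr(x, "sd")
  means <- tidyr::pivot_longer(tibble::as_tibble(x), -"time",
                               names_to = "group", values_to = "mean")
  sds <- tidyr::pivot_longer(sd_tbl, -"time",
                             names_to = "group", values_to = "sd")
  dplyr::left_join(means, sds, by = c("time", "group"))
}

#' Centred moving-average smoothing
#'
#' Replaces each value by the average of the `n` neighbouring data points
#' centred on it. `n` must be odd; `(n - 1)/2` points are lost at each end of
#' the series (strict drop, no padding), and the time vector is trimmed to
#' match.
#'
#' @inheritParams normalize_to_reference
#' @param n Odd window length, `3 <= n <= nrow(table)`.
#' @return A shorter `assay_table` of smoothed values.
#' @examples
#' tbl <- as_assay_table(data.frame(t = 1:5, A = c(1, 2, 3, 4, 5)))
#' smooth_table(tbl, 3)$A  # 2 3 4
#' @export
smooth_table <- function(table, n) {
  stopifnot(is.numeric(n), length(n) == 1, n == round(n))
  if (n %% 2 == 0) stop("smoothing window n must be an odd number",
                        call. = FALSE)
  if (n < 3 || n > nrow(table))
    stop("need 3 <= n <= number of time points", call. = FALSE)
  h <- (n - 1) / 2
  keep <- (h + 1):(nrow(table) - h)
  out <- tibble::tibble(time = table$time[keep])
  for (nm in measure_names(table)) {
    sm <- stats::filter(table[[nm]], rep(1 / n, n), sides = 2)
    out[[nm]] <- as.numeric(sm)[keep]
  }
  restamp(out, table)
}

#' Moving-window linear slope with residual error
#'
#' Fits an ordinary least-squares line through each data point and the `n`
#' points on either side of it (`2n + 1` points total, using the actual time
#' stamps, so irregular sampling is handled), and reports the slope in
#' value-units per time-unit together with the residual standard error
#' `sqrt(SSE / (2n + 1 - 2))` of each local fit. `n` points are lost at each
#' end.
#'
#' The result is an assay-table-like tibble of slopes with the residual table
#' in attribute `"residual"`; [tidy()][tidy.slope_table] gives a long view.
#'
#' @inheritParams normalize_to_reference
#' @param n Half-width of the window (points on each side), `n >= 1`.
#' @return A `slope_table` (also an `assay_table`) of local slopes.
#' @export
windowed_slope <- function(table, n) {
  stopifnot(is.numeric(n), length(n) == 1, n == round(n), n >= 1)
  w <- 2 * n + 1
  if (nrow(table) < w)
    stop("series too short: need at least 2n + 1 = ", w, " time points",
         call. = FALSE)
  t_all <- table$time
  centres <- (n + 1):(nrow(table) - n)
  slope_tbl <- resid_tbl <- tibble::tibble(time = t_all[centres])
  for (nm in measure_names(table)) {
    y_all <- table[[nm]]
    fit <- vapply(centres, function(i) {
      idx <- (i - n):(i + n)
      ols_line(t_all[idx], y_all[idx])
    }, numeric(2))
    slope_tbl[[nm]] <- fit[1, ]
    resid_tbl[[nm]] <- fit[2, ]
  }
  out <- restamp(slope_tbl, table,
                 value_unit = paste0(value_unit(table), "/", time_unit(table)))
  class(out) <- c("slope_table", class(out))
  attr(out, "residual") <- resid_tbl
  out
}

# slope and residual standard error of one OLS window; centred arithmetic
# for numerical stability. NA anywhere in the window -> NA out.
ols_line <- function(t, y) {
  if (anyNA(y) || anyNA(t)) return(c(NA_real_, NA_real_))
  tc <- t - mean(t)
  yc <- y - mean(y)
  sxx <- sum(tc^2)
  m <- sum(tc * yc) / sxx
  sse <- sum((yc - m * tc)^2)
  c(m, sqrt(max(sse, 0) / (length(t) - 2)))
}

#' @rdname windowed_slope
#' @param x A `slope_table`.
#' @param ... Unused.
#' @export
tidy.slope_table <- function(x, ...) {
  res <- attr(x, "residual")
  slopes <- tidyr::pivot_longer(tibble::as_tibble(x), -"time",
                                names_to = "series", values_to = "slope")
  resid <- tidyr::pivot_longer(res, -"time",
                               names_to = "series", values_to = "residual")
  dplyr::left_join(slopes, resid, by = c("time", "series"))
}
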