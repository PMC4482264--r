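#' Basic formatting of assay tables
#'
#' Elementary reshaping applied before any statistics: converting the time
#' unit, excluding leading/trailing time points, shifting the time origin
#' (e.g. to set treatment time to zero) and scaling all values by a fixed
#' factor. All four operate on the table as a whole and commute with column
#' selection.
#'
#' @param table An [assay table][as_assay_table].
#' @param from,to Time units, among `"s"`, `"min"`, `"h"`, `"day"`. `from`
#'   defaults to the table's own unit tag.
#' @return An `assay_table` with the transformation applied.
#' @examples
#' tbl <- as_assay_table(data.frame(t = c(0, 86400), A = c(1, 2)), "s")
#' convert_time_units(tbl, to = "day")$time   # 0 1
#' @name preprocess
NULL

.time_unit_s <- c(s = 1, min = 60, h = 3600, day = 86400)

#' @rdname preprocess
#' @export
convert_time_units <- function(table, to, from = time_unit(table)) {
  if (!from %in% names(.time_unit_s)) stop("unknown time unit '", from, "'")
  if (!to %in% names(.time_unit_s)) stop("unknown time unit '", to, "'")
  out <- table
  out$time <- table$time * (.time_unit_s[[from]] / .time_unit_s[[to]])
  restamp(out, table, time_unit = to)
}

#' @rdname preprocess
#' @param t_min,t_max Closed time interval to keep (in the table's unit).
#' @export
trim_time_range <- function(table, t_min = -Inf, t_max = Inf) {
  stopifnot(t_min < t_max)
  keep <- table$time >= t_min & table$time <= t_max
  if (!any(keep))
    stop("no time points in [", t_min, ", ", t_max, "]", call. = FALSE)
  restamp(table[keep, ], table)
}

#' @rdname preprocess
#' @param offset Amount subtracted from every time stamp; negative results
#'   are allowed (pre-treatment baseline).
#' @export
shift_time_origin <- function(table, offset) {
  stopifnot(is.numeric(offset), length(offset) == 1, is.finite(offset))
  out <- table
  out$time <- table$time - offset
  restamp(out, table)
}

#' @rdname preprocess
#' @param factor Finite nonzero multiplier applied to every measurement.
#' @param value_unit New unit tag after scaling (kept if missing).
#' @export
scale_values <- function(table, factor, value_unit = NULL) {
  stopifnot(is.numeric(factor), length(factor) == 1,
            is.finite(factor), factor != 0)
  out <- dplyr::mutate(tibble::as_tibble(table),
                       dplyr::across(-"time", ~ .x * factor))
  restamp(out, table, value_unit = value_unit)
}
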