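#' Assay tables
#'
#' An assay table holds one time-resolved multi-well measurement: a shared
#' `time` column (strictly increasing, unit-tagged) plus one measurement
#' column per well/sensor. It is an ordinary tibble of class `assay_table`
#' with `time_unit` and `value_unit` attributes, so every dplyr verb works on
#' it; [as_assay_table()] re-validates after arbitrary manipulation.
#'
#' @param x A data frame whose first column is time and remaining columns are
#'   measurements (all numeric).
#' @param time_unit One of `"s"`, `"min"`, `"h"`, `"day"`.
#' @param value_unit Free-text unit tag for the measurements (e.g. `"% a.s."`).
#' @return A validated `assay_table` tibble whose first column is named `time`.
#' @examples
#' tbl <- as_assay_table(data.frame(t = 0:3, A = c(1, 2, 3, 4)),
#'                       time_unit = "min")
#' measure_names(tbl)
#' @export
as_assay_table <- function(x, time_unit = "h", value_unit = "") {
  stopifnot(is.data.frame(x), ncol(x) >= 2)
  x <- tibble::as_tibble(x, .name_repair = "minimal")
  names(x)[1] <- "time"
  validate_assay_table(new_assay_table(x, time_unit, value_unit))
}

new_assay_table <- function(x, time_unit, value_unit) {
  structure(x,
            class = c("assay_table", class(tibble::tibble())),
            time_unit = time_unit, value_unit = value_unit)
}

#' @rdname as_assay_table
#' @export
validate_assay_table <- function(x) {
  stopifnot(inherits(x, "data.frame"), names(x)[1] == "time")
  if (anyDuplicated(names(x)))
    stop("duplicate column names: ",
         paste(unique(names(x)[duplicated(names(x))]), collapse = ", "),
         call. = FALSE)
  if (!is.numeric(x$time) || anyNA(x$time))
    stop("time column must be numeric with no missing values", call. = FALSE)
  bad <- which(diff(x$time) <= 0)
  if (length(bad))
    stop("time must be strictly increasing; offending rows: ",
         paste(utils::head(bad + 1L, 10L), collapse = ", "), call. = FALSE)
  for (nm in measure_names(x))
    if (!is.numeric(x[[nm]]))
      stop("measurement column '", nm, "' is not numeric", call. = FALSE)
  if (!match(time_unit(x), c("s", "min", "h", "day"), nomatch = 0L))
    stop("unknown time unit '", time_unit(x), "'", call. = FALSE)
  x
}

#' @rdname as_assay_table
#' @export
measure_names <- function(x) setdiff(names(x), "time")

#' @rdname as_assay_table
#' @export
time_unit <- function(x) attr(x, "time_unit") %||% "h"

#' @rdname as_assay_table
#' @export
value_unit <- function(x) attr(x, "value_unit") %||% ""

# rebuild an assay_table after a transformation, keeping the unit tags of
# `template` unless overridden
restamp <- function(x, template, time_unit = NULL, value_unit = NULL) {
  new_assay_table(tibble::as_tibble(x),
                  time_unit %||% attr(template, "time_unit"),
                  value_unit %||% attr(template, "value_unit"))
}

#' Read time-resolved assay CSV files
#'
#' Reads one or more CSV files whose first column is the time axis and whose
#' remaining columns are per-well measurements, and merges them into a single
#' [assay table][as_assay_table]. Non-numeric cells become `NA`; duplicate
#' column names and a non-monotone time axis are hard errors. Several files
#' can only be merged when their time vectors agree within `1e-9` (in the
#' input unit).
#'
#' @param paths Character vector of CSV paths.
#' @param sep Field separator (vendor exports vary).
#' @param dec Decimal mark.
#' @param skip Number of lines to skip before the header.
#' @inheritParams as_assay_table
#' @return An `assay_table`.
#' @export
read_assay_csv <- function(paths, sep = ",", dec = ".", skip = 0,
                           time_unit = "h", value_unit = "") {
  stopifnot(length(paths) >= 1, all(file.exists(paths)))
  tabs <- lapply(paths, function(p) {
    raw <- readr::read_delim(
      p, delim = sep, skip = skip, na = c("", "NA", "NaN"),
      locale = readr::locale(decimal_mark = dec),
      col_types = readr::cols(.default = readr::col_character()),
      name_repair = "minimal", progress = FALSE)
    if (anyDuplicated(names(raw)))
      stop("duplicate column names in ", p, ": ",
           paste(unique(names(raw)[duplicated(names(raw))]), collapse = ", "),
           call. = FALSE)
    parsed <- lapply(raw, function(col)
      readr::parse_double(col, na = c("", "NA", "NaN"),
                          locale = readr::locale(decimal_mark = dec)))
    parsed <- lapply(parsed, function(col) { attributes(col) <- NULL; col })
    if (anyNA(parsed[[1]]))
      stop("first (time) column of ", p, " contains non-numeric cells",
           call. = FALSE)
    tibble::as_tibble(parsed, .name_repair = "minimal")
  })
  merged <- tabs[[1]]
  for (tab in tabs[-1]) {
    if (nrow(tab) != nrow(merged) ||
        max(abs(tab[[1]] - merged[[1]])) > 1e-9)
      stop("input files do not share an identical time vector", call. = FALSE)
    merged <- dplyr::bind_cols(merged, tab[-1], .name_repair = "minimal")
  }
  as_assay_table(merged, time_unit = time_unit, value_unit = value_unit)
}

#' Write an assay table to CSV
#'
#' Values are written with shortest round-trip precision, so
#' `read_assay_csv(write_table_csv(tbl, f))` reproduces `tbl` exactly.
#'
#' @param table An `assay_table` (or any data frame).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_table_csv <- function(table, path) {
  readr::write_csv(tibble::as_tibble(table), path, progress = FALSE)
  invisible(path)
}
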