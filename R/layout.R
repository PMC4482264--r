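#' Plate layouts
#'
#' A plate layout maps every measurement column of an assay table to its
#' experimental meaning: a condition label, a replicate group, a role, an
#' optional dose, and plot styling. It mirrors the template a user would fill
#' in next to the raw data and drives replicate averaging, reference
#' normalization and dose-response fitting downstream.
#'
#' Recognised roles:
#' \describe{
#'   \item{`sample`}{a treated (or untreated, dose 0) well entering analysis}
#'   \item{`reference`}{a well whose mean defines reference normalization}
#'   \item{`medium_control`}{cell-free well tracking ambient conditions; also
#'     usable as the normalization reference}
#'   \item{`excluded`}{ignored by every downstream stage}
#' }
#'
#' @param well Character: measurement-column names of the assay table.
#' @param label Condition label shown in legends.
#' @param group Replicate-group key; wells sharing a key are averaged.
#' @param role One of `sample`, `reference`, `medium_control`, `excluded`.
#' @param dose Numeric dose (required for IC50 fitting of sample wells).
#' @param dose_unit Unit of `dose`, e.g. `"uM"`.
#' @param color,linetype,legend Plot styling per well.
#' @return A tibble of class `plate_layout`.
#' @export
plate_layout <- function(well, label = well, group = label, role = "sample",
                         dose = NA_real_, dose_unit = "",
                         color = NA_character_, linetype = "solid",
                         legend = label) {
  out <- tibble::tibble(
    well = as.character(well), label = as.character(label),
    group = as.character(group), role = as.character(role),
    dose = as.numeric(dose), dose_unit = as.character(dose_unit),
    color = as.character(color), linetype = as.character(linetype),
    legend = as.character(legend))
  class(out) <- c("plate_layout", class(tibble::tibble()))
  out
}

layout_roles <- c("sample", "reference", "medium_control", "excluded")

#' Read a plate-layout template
#'
#' The layout file is a plain CSV with one row per measurement column and at
#' least the columns `well` and `role`; `label`, `group`, `dose`, `dose_unit`,
#' `color`, `linetype` and `legend` are optional and filled with defaults.
#'
#' @param path Path to the layout CSV.
#' @return A `plate_layout` tibble.
#' @seealso [validate_layout()] to check a layout against an assay table.
#' @export
read_layout <- function(path) {
  stopifnot(file.exists(path))
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!"well" %in% names(raw))
    stop("layout file must have a 'well' column", call. = FALSE)
  lay <- plate_layout(
    well = raw$well,
    label = raw[["label"]] %||% raw$well,
    group = raw[["group"]] %||% raw[["label"]] %||% raw$well,
    role = raw[["role"]] %||% "sample",
    dose = raw[["dose"]] %||% NA_real_,
    dose_unit = as.character(raw[["dose_unit"]] %||% ""),
    color = as.character(raw[["color"]] %||% NA_character_),
    linetype = as.character(raw[["linetype"]] %||% "solid"),
    legend = as.character(raw[["legend"]] %||% raw[["label"]] %||% raw$well))
  bad <- setdiff(lay$role, layout_roles)
  if (length(bad))
    stop("unknown role(s) in layout: ", paste(bad, collapse = ", "),
         call. = FALSE)
  lay
}

#' Write a plate layout to CSV
#' @param layout A `plate_layout`.
#' @param path Output path.
#' @export
write_layout <- function(layout, path) {
  readr::write_csv(tibble::as_tibble(layout), path, progress = FALSE)
  invisible(path)
}

#' Validate a plate layout against an assay table
#'
#' Checks that the layout and the table describe the same wells (each
#' measurement column appears exactly once), that roles are known, that
#' replicate groups are non-empty, and — when doses are in play — that every
#' non-excluded sample well has one.
#'
#' @param layout A `plate_layout`.
#' @param table An `assay_table` the layout should describe.
#' @param require_dose If `TRUE` (needed before IC50 fitting), a sample well
#'   without a dose is an error.
#' @return `layout`, invisibly re-classed, for piping.
#' @export
validate_layout <- function(layout, table = NULL, require_dose = FALSE) {
  stopifnot(is.data.frame(layout), "well" %in% names(layout))
  if (anyDuplicated(layout$well))
    stop("wells listed more than once in layout: ",
         paste(unique(layout$well[duplicated(layout$well)]), collapse = ", "),
         call. = FALSE)
  bad <- setdiff(layout$role, layout_roles)
  if (length(bad))
    stop("unknown role(s): ", paste(bad, collapse = ", "), call. = FALSE)
  active <- layout$role != "excluded"
  if (any(is.na(layout$group[active]) | layout$group[active] == ""))
    stop("replicate group missing for wells: ",
         paste(layout$well[active & (is.na(layout$group) | layout$group == "")],
               collapse = ", "), call. = FALSE)
  if (!is.null(table)) {
    mn <- measure_names(table)
    missing_in_table <- setdiff(layout$well, mn)
    missing_in_layout <- setdiff(mn, layout$well)
    if (length(missing_in_table) || length(missing_in_layout))
      stop("layout/table mismatch",
           if (length(missing_in_table))
             paste0("; in layout but not table: ",
                    paste(missing_in_table, collapse = ", ")),
           if (length(missing_in_layout))
             paste0("; in table but not layout: ",
                    paste(missing_in_layout, collapse = ", ")),
           call. = FALSE)
  }
  doses_in_play <- require_dose || any(!is.na(layout$dose))
  if (doses_in_play) {
    need <- layout$role == "sample"
    if (any(need & is.na(layout$dose)))
      stop("sample wells without a dose: ",
           paste(layout$well[need & is.na(layout$dose)], collapse = ", "),
           call. = FALSE)
  }
  invisible(layout)
}

# wells taking part in analysis, optionally restricted by role
active_wells <- function(layout, roles = setdiff(layout_roles, "excluded")) {
  layout$well[layout$role %in% roles]
}

# drop excluded wells from a table according to the layout
drop_excluded <- function(table, layout) {
  keep <- c("time", intersect(measure_names(table), active_wells(layout)))
  restamp(table[keep], table)
}
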