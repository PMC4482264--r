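# small in-code fixtures shared across test files

mk_table <- function(..., time = NULL, time_unit = "h", value_unit = "") {
  cols <- list(...)
  time <- time %||% (seq_len(length(cols[[1]])) - 1)
  as_assay_table(tibble::tibble(time = time, !!!cols),
                 time_unit = time_unit, value_unit = value_unit)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# triplicate layout: wells A1..A3 one dose group, B1..B3 another, M1 medium
mk_layout <- function(wells, groups, roles = "sample", doses = NA_real_) {
  plate_layout(well = wells, group = groups, role = roles, dose = doses)
}

# the 13 printed cisplatin concentrations, uM
cisplatin_doses <- c(300, 200, 100, 90, 80, 70, 60, 50, 40, 30, 20, 10, 0)
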