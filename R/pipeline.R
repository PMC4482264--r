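#' Run the whole analysis pipeline from a settings record
#'
#' Executes the configured stages in their legal order — basic formatting
#' (convert, trim, shift, scale), two-step sensor correction, reference
#' normalization, replicate aggregation, smoothing, windowed slope,
#' time-resolved IC50 — writing one CSV per stage, optional plots, the
#' resolved settings and a log into a fresh run directory. Any suffix of the
#' chain can be left unset; a stage whose prerequisite is missing (slope
#' without smoothing) is rejected before any computation. The pipeline is a
#' pure function of its inputs and settings: identical inputs give
#' byte-identical outputs.
#'
#' @param settings An [analysis_settings()] record (or path to a saved one).
#' @param out_dir Run directory to create; must not already exist (outputs
#'   are never overwritten silently).
#' @param table,layout Optional in-memory inputs, overriding
#'   `settings$input`/`settings$layout_path`.
#' @param write_plots Also export per-stage PNG plots.
#' @return Invisibly, a named list of the per-stage results (tables, the
#'   trajectory, paths of everything written).
#' @export
run_pipeline <- function(settings, out_dir, table = NULL, layout = NULL,
                         write_plots = FALSE) {
  if (is.character(settings)) settings <- load_settings(settings)
  stopifnot(inherits(settings, "analysis_settings"))
  if (!is.null(settings$slope) && is.null(settings$smooth))
    stop("illegal stage order: slope requires smoothing first", call. = FALSE)
  if (dir.exists(out_dir))
    stop("run directory '", out_dir, "' already exists", call. = FALSE)
  dir.create(out_dir, recursive = TRUE)
  log_lines <- character(0)
  note <- function(stage, params, tab) {
    log_lines <<- c(log_lines, sprintf(
      "%s | %s | %d rows x %d cols", stage,
      paste(names(params), unlist(lapply(params, format)), sep = "=",
            collapse = ", "),
      nrow(tab), ncol(tab)))
  }
  emit <- function(tab, stage, plot = NULL) {
    write_table_csv(tab, file.path(out_dir, paste0(stage, ".csv")))
    if (write_plots && !is.null(plot))
      export_plot(plot, file.path(out_dir, paste0(stage, ".png")))
  }

  if (is.null(table)) {
    inp <- settings$input
    if (is.null(inp)) stop("no input configured", call. = FALSE)
    table <- read_assay_csv(inp$paths, sep = inp$sep %||% ",",
                            dec = inp$dec %||% ".", skip = inp$skip %||% 0,
                            time_unit = inp$time_unit %||% "h",
                            value_unit = inp$value_unit %||% "")
  }
  if (is.null(layout) && !is.null(settings$layout_path))
    layout <- read_layout(settings$layout_path)
  if (!is.null(layout)) {
    validate_layout(layout, table)
    table <- drop_excluded(table, layout)
  }
  note("input", list(), table)
  out <- list(input = table)

  s <- settings$convert
  if (!is.null(s)) {
    table <- convert_time_units(table, to = s$to,
                                from = s$from %||% time_unit(table))
    note("convert", s, table)
  }
  s <- settings$trim
  if (!is.null(s)) {
    table <- trim_time_range(table, s$t_min %||% -Inf, s$t_max %||% Inf)
    note("trim", s, table)
  }
  s <- settings$shift
  if (!is.null(s)) {
    table <- shift_time_origin(table, s$offset)
    note("shift", s, table)
  }
  s <- settings$scale
  if (!is.null(s)) {
    table <- scale_values(table, s$factor, s$value_unit)
    note("scale", s, table)
  }
  emit(table, "formatted", plot_curves(table, layout))
  out$formatted <- table

  s <- settings$correct
  if (!is.null(s)) {
    calib <- calibration_model(plateau = s$plateau, span = s$span,
                               window = unlist(s$window),
                               alpha = s$alpha)
    table <- correct_sensors(table, calib, target = s$target,
                             clip_epsilon = s$clip_epsilon)
    note("correct", s[c("plateau", "span", "target")], table)
    emit(table, "corrected", plot_curves(table, layout))
    out$corrected <- table
  }
  s <- settings$normalize
  if (!is.null(s)) {
    if (is.null(layout)) stop("normalization needs a layout", call. = FALSE)
    table <- normalize_to_reference(table, layout, target = s$target)
    note("normalize", s, table)
    emit(table, "normalized", plot_curves(table, layout))
    out$normalized <- table
  }
  if (isTRUE(settings$aggregate)) {
    if (is.null(layout)) stop("aggregation needs a layout", call. = FALSE)
    table <- aggregate_replicates(table, layout)
    note("aggregate", list(), table)
    write_table_csv(attr(table, "sd"), file.path(out_dir, "aggregated_sd.csv"))
    emit(table, "aggregated", plot_curves(table, layout))
    out$aggregated <- table
  }
  s <- settings$smooth
  if (!is.null(s)) {
    table <- smooth_table(table, s$n)
    note("smooth", s, table)
    emit(table, "smoothed", plot_curves(table, layout))
    out$smoothed <- table
  }
  s <- settings$slope
  if (!is.null(s)) {
    slopes <- windowed_slope(table, s$n)
    note("slope", s, slopes)
    write_table_csv(attr(slopes, "residual"),
                    file.path(out_dir, "slope_residual.csv"))
    emit(slopes, "slope", plot_curves(slopes, layout))
    out$slope <- slopes
  }
  s <- settings$ic50
  if (!is.null(s)) {
    if (is.null(layout)) stop("IC50 fitting needs a layout", call. = FALSE)
    validate_layout(layout, require_dose = TRUE)
    traj <- fit_ic50_over_time(table, layout,
                               family = s$family %||% "LL4",
                               t_min = s$t_min %||% -Inf,
                               t_max = s$t_max %||% Inf,
                               stride = s$stride %||% 1L,
                               use_replicates = isTRUE(s$use_replicates))
    note("ic50", s, traj)
    write_table_csv(traj, file.path(out_dir, "ic50_trajectory.csv"))
    write_table_csv(trajectory_fits(traj), file.path(out_dir, "ic50_fits.csv"))
    if (write_plots) {
      export_plot(plot_trajectory(traj),
                  file.path(out_dir, "ic50_trajectory.png"))
      export_plot(plot_fit_snapshots(traj),
                  file.path(out_dir, "ic50_snapshots.png"))
    }
    out$ic50 <- traj
  }

  save_settings(settings, file.path(out_dir, "settings.yaml"))
  writeLines(log_lines, file.path(out_dir, "log.txt"))
  out$dir <- out_dir
  invisible(out)
}

#' Per-time-point fit parameters of an IC50 trajectory
#'
#' @param trajectory An [fit_ic50_over_time()] result.
#' @return A tibble with one row per fitted time point: every model
#'   parameter, its standard error, the residual standard error and the
#'   convergence flag.
#' @export
trajectory_fits <- function(trajectory) {
  purrr::map_dfr(attr(trajectory, "fits"), function(f) {
    est <- as.list(setNames(f$estimates, names(f$estimates)))
    ses <- as.list(setNames(f$se, paste0(names(f$se), ".se")))
    tibble::as_tibble(c(list(time = f$time), est, ses,
                        list(rse = f$rse, n = f$n,
                             converged = f$converged)))
  })
}
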