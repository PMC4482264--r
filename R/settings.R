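#' Analysis settings
#'
#' A single serializable record of every tunable parameter of the pipeline,
#' saved next to every output so a run can be reproduced or reused on a
#' similar experiment. Unset stages are `NULL` and are skipped by
#' [run_pipeline()].
#'
#' @param input List with `paths`, `sep`, `dec`, `skip`, `time_unit`,
#'   `value_unit` for [read_assay_csv()].
#' @param layout_path Path of the plate-layout CSV.
#' @param convert List `(from, to)` for [convert_time_units()].
#' @param trim List `(t_min, t_max)` for [trim_time_range()].
#' @param shift List `(offset)` for [shift_time_origin()].
#' @param scale List `(factor, value_unit)` for [scale_values()].
#' @param correct List `(plateau, span, alpha, window, target, clip_epsilon)`
#'   for the two-step sensor correction.
#' @param normalize List `(target)` for [normalize_to_reference()].
#' @param aggregate `TRUE`/`NULL`: aggregate technical replicates.
#' @param smooth List `(n)` for [smooth_table()].
#' @param slope List `(n)` for [windowed_slope()].
#' @param ic50 List `(family, t_min, t_max, stride, use_replicates)` for
#'   [fit_ic50_over_time()].
#' @param seed Integer seed recorded for any stochastic stage.
#' @return A list of class `analysis_settings`.
#' @export
analysis_settings <- function(input = NULL, layout_path = NULL,
                              convert = NULL, trim = NULL, shift = NULL,
                              scale = NULL, correct = NULL, normalize = NULL,
                              aggregate = NULL, smooth = NULL, slope = NULL,
                              ic50 = NULL, seed = NULL) {
  structure(list(input = input, layout_path = layout_path, convert = convert,
                 trim = trim, shift = shift, scale = scale, correct = correct,
                 normalize = normalize, aggregate = aggregate,
                 smooth = smooth, slope = slope, ic50 = ic50, seed = seed),
            class = "analysis_settings")
}

# doubles are written with 17 significant digits so that save/load is the
# identity on IEEE values; integers keep their type through yaml
yaml_num <- function(x) {
  s <- sprintf("%.17g", x)
  ifelse(grepl("[.eE]|^-?[iI]nf|^[nN]a", s), s, paste0(s, ".0"))
}

#' Save and reload analysis settings
#'
#' Settings round-trip losslessly: `load_settings(save_settings(s, f))` is
#' identical to `s` (doubles are serialized with full precision).
#'
#' @param settings An [analysis_settings()] record.
#' @param path A YAML file path.
#' @return `save_settings` returns `path` invisibly; `load_settings` the
#'   restored `analysis_settings`.
#' @export
save_settings <- function(settings, path) {
  stopifnot(inherits(settings, "analysis_settings"))
  txt <- yaml::as.yaml(unclass(settings),
                       handlers = list(numeric = function(x)
                         structure(yaml_num(x), class = "verbatim")))
  writeLines(txt, path)
  invisible(path)
}

#' @rdname save_settings
#' @export
load_settings <- function(path) {
  stopifnot(file.exists(path))
  raw <- yaml::read_yaml(path)
  do.call(analysis_settings, raw[names(formals(analysis_settings))[
    names(formals(analysis_settings)) %in% names(raw)]])
}
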