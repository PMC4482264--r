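#' Simulation configuration for synthetic assay plates
#'
#' Collects every knob of the plate simulator. The defaults emulate a
#' 24-well dissolved-oxygen viability experiment: 24 sensors whose gain in
#' the log domain of the exponential calibration curve varies uniformly by
#' +/- `gain_delta` around 1, additive Gaussian reader noise after the
#' calibration map, 13 doses (300 down to 0 uM) in triplicate plus 3
#' cell-free medium wells, ambient oxygen 91.3 % a.s. with a slow upward
#' drift, 10-minute sampling over 5 days, and a drug whose effective IC50
#' relaxes exponentially from 80 uM at day 2.5 to 30 uM at day 4.7.
#'
#' Sensor miscalibration is multiplicative in the log domain — exactly the
#' error structure logarithmic recalibration inverts — so with zero noise
#' the two-step correction restores true values to machine precision, which
#' is what the correction closure tests exploit.
#'
#' @param n_sensors Sensors on an empty plate.
#' @param gain_delta Half-width of the uniform per-sensor log-domain gain.
#' @param plateau,span,alpha Exponential calibration curve parameters (the
#'   plateau sits below the lowest oxygen level ever simulated).
#' @param noise_sd Reader noise SD in measurement units (% a.s.).
#' @param ambient Ambient oxygen at time zero, % a.s.
#' @param ambient_drift Linear ambient drift, % a.s. per day.
#' @param doses Dose levels, uM; must include 0 for the untreated control.
#' @param replicates Wells per dose.
#' @param n_medium Cell-free medium-control wells.
#' @param dt Sampling interval, day.
#' @param t_end Experiment length, day.
#' @param t_seed,t_medium_change,t_treat Seeding, medium-change and
#'   treatment times, day. Before `t_seed` the wells read ambient oxygen
#'   only: that segment is the calibration window.
#' @param depth_seeding,depth_growth Oxygen drawdown (% a.s.) of untreated
#'   cells at the end of the adhesion phase and at confluence.
#' @param death_slope Log-logistic slope `b` of the dose-death law.
#' @param e_start,e_end,t_e_start,t_e_end,e_floor Programmed IC50 trajectory:
#'   `e(t) = e_floor + A * exp(-k (t - t_treat))` with `A`, `k` solved so
#'   that `e(t_e_start) = e_start` and `e(t_e_end) = e_end`.
#' @param seed Integer seed; fully determines the simulated bytes.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_sensors = 24, gain_delta = 0.05,
                       plateau = 2, span = 100, alpha = 0.035,
                       noise_sd = 0.3,
                       ambient = 91.3, ambient_drift = 0.4,
                       doses = c(300, 200, 100, 90, 80, 70, 60, 50, 40, 30,
                                 20, 10, 0),
                       replicates = 3, n_medium = 3,
                       dt = 10 / 1440, t_end = 5,
                       t_seed = 136 / 1440, t_medium_change = 1.09,
                       t_treat = 2.1,
                       depth_seeding = 25, depth_growth = 40,
                       death_slope = 2,
                       e_start = 80, e_end = 30,
                       t_e_start = 2.5, t_e_end = 4.7, e_floor = 25,
                       seed = 1L) {
  stopifnot(gain_delta >= 0, noise_sd >= 0, length(doses) >= 1,
            span != 0, ambient > plateau)
  structure(as.list(environment()), class = "sim_config")
}

# run code under a seed without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

sensor_gains <- function(config) {
  with_seed(config$seed,
            stats::runif(config$n_sensors,
                         1 - config$gain_delta, 1 + config$gain_delta))
}

# push a matrix of true values through each sensor's miscalibrated
# exponential response: reading = P + S * ((o - P)/S)^gain + noise
read_through_sensors <- function(truth, gains, config, noise_seed) {
  P <- config$plateau; S <- config$span
  if (any(truth <= P))
    stop("true level at or below the calibration plateau", call. = FALSE)
  readings <- sweep(log((truth - P) / S), 2, gains, `*`)
  readings <- P + S * exp(readings)
  if (config$noise_sd > 0)
    readings <- readings + with_seed(noise_seed,
      matrix(stats::rnorm(length(readings), 0, config$noise_sd),
             nrow(readings)))
  readings
}

#' Simulate an empty multi-sensor plate at fixed oxygen levels
#'
#' Emulates the correction validation protocol: an empty plate in an
#' oxygen-controlled incubator stepped through a series of known levels,
#' each held for `points_per_level` samples. Each sensor reads
#' `P + S * ((o - P)/S)^g_s` plus noise, with its own log-domain gain `g_s`.
#'
#' @param config A [sim_config()].
#' @param levels True oxygen levels, % a.s.; the classic protocol is
#'   `c(91.3, 72.1, 48.1, 24.0, 4.8)`. All must exceed the plateau.
#' @param points_per_level Samples held at each level (1-minute interval).
#' @return An `assay_table` (time in minutes) with attributes `gains` and
#'   `levels` (the per-row true level).
#' @export
simulate_empty_plate <- function(config = sim_config(),
                                 levels = c(91.3, 72.1, 48.1, 24.0, 4.8),
                                 points_per_level = 10) {
  stopifnot(points_per_level >= 2)
  if (any(levels <= config$plateau))
    stop("oxygen level at or below the calibration plateau", call. = FALSE)
  gains <- sensor_gains(config)
  true_rows <- rep(levels, each = points_per_level)
  truth <- matrix(true_rows, length(true_rows), config$n_sensors)
  readings <- read_through_sensors(truth, gains, config,
                                   noise_seed = config$seed + 1L)
  out <- tibble::as_tibble(as.data.frame(readings))
  names(out) <- sprintf("S%02d", seq_len(config$n_sensors))
  out <- dplyr::bind_cols(tibble::tibble(time = seq_along(true_rows) - 1),
                          out)
  out <- as_assay_table(out, time_unit = "min", value_unit = "% a.s.")
  attr(out, "gains") <- gains
  attr(out, "levels") <- true_rows
  out
}

# programmed IC50 trajectory e(t): exponential relaxation to a floor,
# anchored at two (time, value) pairs
e_trajectory <- function(config) {
  k <- log((config$e_start - config$e_floor) /
             (config$e_end - config$e_floor)) /
       (config$t_e_end - config$t_e_start)
  A <- (config$e_start - config$e_floor) *
    exp(k * (config$t_e_start - config$t_treat))
  function(t) config$e_floor + A * exp(-k * (t - config$t_treat))
}

# oxygen drawdown of untreated cells over time (phenomenological)
consumption_profile <- function(t, config) {
  depth <- numeric(length(t))
  adhesion <- t >= config$t_seed & t < config$t_medium_change
  depth[adhesion] <- config$depth_seeding *
    (1 - exp(-(t[adhesion] - config$t_seed) / 0.15))
  growth <- t >= config$t_medium_change
  depth[growth] <- config$depth_growth *
    (1 - exp(-(t[growth] - config$t_medium_change) / 0.4))
  depth
}

#' Simulate a full treatment experiment
#'
#' Generates the plate a time-resolved IC50 study produces: seeding dip,
#' medium-change recovery, then dose-dependent divergence after treatment.
#' The viable-cell fraction of a well at dose `x` follows the log-logistic
#' dose-death law `v = 1 / (1 + (x / e(t))^b)` with the programmed,
#' time-varying `e(t)` of the configuration; oxygen is ambient minus the
#' untreated drawdown scaled by `v`. Medium wells track ambient oxygen
#' (with its slow linear drift) only. Every well is read through its own
#' miscalibrated sensor plus noise.
#'
#' @param config A [sim_config()].
#' @param e_fun Optional override for the IC50 trajectory, a function of
#'   time (day) returning `e` in dose units; defaults to the configured
#'   exponential relaxation.
#' @return A list with `table` (the readings, time in days), `layout` (a
#'   [plate_layout()]: triplicate sample groups per dose plus medium
#'   controls), `calibration` (the [calibration_model()] whose window is the
#'   pre-seeding segment), and `truth` (gains, `e_fun`, and the noiseless
#'   true oxygen matrix).
#' @export
simulate_treatment_experiment <- function(config = sim_config(),
                                          e_fun = NULL) {
  stopifnot(length(config$doses) >= 1)
  e_fun <- e_fun %||% e_trajectory(config)
  t <- seq(0, config$t_end, by = config$dt)
  n_wells <- length(config$doses) * config$replicates + config$n_medium
  cfg_wells <- config; cfg_wells$n_sensors <- n_wells
  gains <- sensor_gains(cfg_wells)
  ambient <- config$ambient + config$ambient_drift * t
  depth <- consumption_profile(t, config)
  after <- t >= config$t_treat
  truth <- matrix(0, length(t), n_wells)
  wells <- character(n_wells)
  lay <- list()
  j <- 0
  for (dose in config$doses) for (r in seq_len(config$replicates)) {
    j <- j + 1
    v <- rep(1, length(t))
    v[after] <- loglogistic(dose, b = config$death_slope, c = 0, d = 1,
                            e = e_fun(t[after]))
    truth[, j] <- ambient - depth * v
    wells[j] <- sprintf("D%g_r%d", dose, r)
    lay[[j]] <- data.frame(well = wells[j],
                           label = sprintf("%g uM", dose),
                           group = sprintf("%g uM", dose),
                           role = "sample", dose = dose, dose_unit = "uM")
  }
  for (r in seq_len(config$n_medium)) {
    j <- j + 1
    truth[, j] <- ambient
    wells[j] <- sprintf("MED_r%d", r)
    lay[[j]] <- data.frame(well = wells[j], label = "medium",
                           group = "medium", role = "medium_control",
                           dose = NA_real_, dose_unit = "uM")
  }
  readings <- read_through_sensors(truth, gains, cfg_wells,
                                   noise_seed = config$seed + 2L)
  tab <- tibble::as_tibble(as.data.frame(readings))
  names(tab) <- wells
  tab <- dplyr::bind_cols(tibble::tibble(time = t), tab)
  tab <- as_assay_table(tab, time_unit = "day", value_unit = "% a.s.")
  lay <- dplyr::bind_rows(lay)
  layout <- plate_layout(well = lay$well, label = lay$label,
                         group = lay$group, role = lay$role,
                         dose = lay$dose, dose_unit = lay$dose_unit)
  calib <- calibration_model(plateau = config$plateau, span = config$span,
                             window = c(0, config$t_seed * 0.999),
                             alpha = config$alpha)
  list(table = tab, layout = layout, calibration = calib,
       truth = list(gains = gains, e_fun = e_fun, oxygen = truth,
                    ambient = ambient))
}

#' Simulate a dose-response surface over time
#'
#' Direct input for the dose-response fitter: a table of responses
#' `loglogistic(dose; params(t)) + noise` at each time and dose, bypassing
#' the sensor/plate model. Deterministic per seed.
#'
#' @param times Time vector.
#' @param doses Dose vector; one column per dose.
#' @param params_fun Function of time returning a named list/vector with
#'   `b`, `c`, `d`, `e` (and optionally `g`).
#' @param noise_sd Additive Gaussian noise SD on the responses.
#' @param seed Integer seed.
#' @return A list with `table` (an `assay_table`, one column per dose) and
#'   `layout` (role `sample`, one well per dose).
#' @export
simulate_dose_response_surface <- function(times, doses, params_fun,
                                           noise_sd = 0, seed = 1L) {
  stopifnot(length(doses) >= 1, noise_sd >= 0)
  resp <- vapply(times, function(ti) {
    p <- as.list(params_fun(ti))
    loglogistic(doses, b = p$b, c = p$c, d = p$d, e = p$e, g = p$g %||% 1)
  }, numeric(length(doses)))
  resp <- t(resp)
  if (noise_sd > 0)
    resp <- resp + with_seed(seed,
      matrix(stats::rnorm(length(resp), 0, noise_sd), nrow(resp)))
  tab <- tibble::as_tibble(as.data.frame(resp))
  names(tab) <- sprintf("D%g", doses)
  tab <- dplyr::bind_cols(tibble::tibble(time = times), tab)
  tab <- as_assay_table(tab, time_unit = "day", value_unit = "response")
  layout <- plate_layout(well = sprintf("D%g", doses),
                         label = sprintf("%g", doses),
                         group = sprintf("%g", doses),
                         role = "sample", dose = doses, dose_unit = "uM")
  list(table = tab, layout = layout)
}
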