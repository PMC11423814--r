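## Packaged fixtures, run configuration and synthetic calibration data.

#' Path to a packaged fixture file
#' @param file file name under `extdata/`.
#' @return absolute path.
#' @export
mc_fixture <- function(file) {
  p <- system.file("extdata", file, package = "mechanoclock")
  if (p == "") stop("no packaged fixture named ", file, call. = FALSE)
  p
}

#' Load the packaged baseline parameter tables
#' @return list with `mechano` and `circadian` parameter objects read from
#'   the packaged CSV tables.
#' @export
default_parameter_tables <- function() {
  list(mechano = load_parameter_table(mc_fixture("mechano_params.csv"),
                                      "mechano"),
       circadian = load_parameter_table(mc_fixture("circadian_params.csv"),
                                        "circadian"))
}

#' Load a run configuration
#'
#' JSON with a nested `condition` object (see [load_condition()]) and the
#' module options `n_cells`, `days`, `seed`, `snr`, `halfwidth`,
#' `dt_step`. Unknown keys are rejected.
#'
#' @param path JSON file path.
#' @return list of class `run_config` with defaults filled in.
#' @export
load_run_config <- function(path) {
  cfg <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  defaults <- list(n_cells = 200, days = 3, seed = 1, snr = 5,
                   halfwidth = 0.1, dt_step = 0.02)
  allowed <- c("condition", names(defaults))
  bad <- setdiff(names(cfg), allowed)
  if (length(bad))
    stop("unknown config key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  cond <- if (!is.null(cfg$condition))
    do.call(treatment_condition, as.list(cfg$condition))
  else treatment_condition()
  cfg$condition <- NULL
  out <- modifyList(defaults, cfg)
  out$condition <- cond
  structure(out, class = "run_config")
}

#' Read the packaged (synthetic) calibration summary table
#'
#' The packaged table is a synthetic stand-in for experimentally reported
#' period/amplitude summaries (mean and s.d. per treatment condition); the
#' source measurements are not redistributable, so the values were chosen to
#' reproduce the reported qualitative trends (softer substrates and
#' cytoskeletal inhibition lengthen the period and raise the amplitude).
#'
#' @param path CSV path; defaults to the packaged
#'   `synthetic_calibration_summaries.csv`.
#' @return data frame with columns `label`, `stiffness_kpa`, `y27_um`,
#'   `cytd_um`, `lat_um`, `jas_um`, `period_mean_h`, `period_sd_h`,
#'   `amplitude_mean`, `amplitude_sd`.
#' @export
calibration_summaries <- function(path = NULL) {
  if (is.null(path)) path <- mc_fixture("synthetic_calibration_summaries.csv")
  read.csv(path, stringsAsFactors = FALSE)
}

#' Build calibration datasets from a summary table
#'
#' Runs [reconstruct_experiment()] for each row of a period/amplitude
#' summary table and attaches the treatment condition.
#'
#' @param summaries data frame as from [calibration_summaries()].
#' @param n_samples Monte Carlo draws per condition.
#' @param horizon_h fit horizon (h).
#' @param seed RNG seed.
#' @return list of calibration datasets (each: `condition`, `t_h`, `mu`,
#'   `sd`, `T_exp`, `label`).
#' @export
build_calibration_datasets <- function(summaries, n_samples = 1e5,
                                       horizon_h = 120, seed = 1) {
  lapply(seq_len(nrow(summaries)), function(i) {
    s <- summaries[i, ]
    rec <- reconstruct_experiment(s$period_mean_h, s$period_sd_h,
                                  s$amplitude_mean, s$amplitude_sd,
                                  n_samples = n_samples,
                                  horizon_h = horizon_h, seed = seed + i)
    list(condition = treatment_condition(stiffness_kpa = s$stiffness_kpa,
                                         y27_um = s$y27_um,
                                         cytd_um = s$cytd_um,
                                         lat_um = s$lat_um,
                                         jas_um = s$jas_um),
         t_h = rec$t_h, mu = rec$mu, sd = rec$sd,
         T_exp = s$period_mean_h, label = s$label)
  })
}

#' Generate synthetic calibration datasets at a known ground truth
#'
#' Simulates the model at `theta_true`, normalizes the luciferase trace per
#' condition and wraps it as a calibration dataset with Gaussian noise of
#' standard deviation `noise_sd` added to the mean trace (`noise_sd = 0`
#' returns the model trace exactly, with `sd` set to `sd_floor` so the
#' likelihood stays defined). Enables parameter-recovery tests of the
#' likelihood/MCMC machinery.
#'
#' @param theta_true free-parameter vector (within prior bounds).
#' @param setup a [fit_setup()].
#' @param conditions list of `treatment_condition`s.
#' @param noise_sd additive noise s.d. on the mean trace.
#' @param sd_floor reported s.d. at all points (> 0).
#' @param horizon_h fit horizon (h); hourly grid.
#' @param seed RNG seed.
#' @return list of calibration datasets.
#' @export
generate_synthetic_calibration <- function(theta_true, setup, conditions,
                                           noise_sd = 0, sd_floor = 0.05,
                                           horizon_h = 120, seed = 1) {
  stopifnot(sd_floor > 0, noise_sd >= 0)
  pars <- apply_theta(setup, theta_true)
  ctrl <- simulate_luciferase(pars$mechano, pars$circadian, setup$control,
                              setup$duration, setup$dt_step)
  a_ctrl <- period_amplitude(ctrl$t_h, ctrl$L)$amplitude
  set.seed(seed)
  lapply(conditions, function(cond) {
    traj <- simulate_luciferase(pars$mechano, pars$circadian, cond,
                                setup$duration, setup$dt_step)
    nm <- normalize_model_trace(traj, a_ctrl, horizon_h = horizon_h)
    Tm <- period_amplitude(traj$t_h, traj$L)$period_h
    mu <- nm$L_rel + if (noise_sd > 0)
      rnorm(length(nm$L_rel), sd = noise_sd) else 0
    list(condition = cond, t_h = nm$t_h, mu = mu,
         sd = rep(max(noise_sd, sd_floor), length(nm$t_h)), T_exp = Tm,
         label = "synthetic")
  })
}
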