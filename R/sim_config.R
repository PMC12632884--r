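## Simulation / study configuration.

#' Default simulation configuration
#'
#' Returns the configuration of the synthetic study. Defaults encode the
#' stated world of the validation-simulation regime: 20 simulated
#' participants, 270 sensors, 100 Hz sampling, discrimination patterns on 10%
#' of sensors, temporally autocorrelated Gaussian noise, and a pattern
#' amplitude calibrated once so that held-out-object operation decoding on
#' the synthetic localizer lands ~2% above chance (the weak-decoding regime
#' the analysis pipeline is validated in). Injected replay uses an 80 ms
#' object-to-object lag with operation type, attribute and compound
#' reactivations trailing each location at 30/60/60 ms and, for swap steps
#' only, the post-update face attribute trailing the operation by 120 ms.
#'
#' @param ... overrides of any default field
#' @return list of class `sim_config`
#' @export
sim_config <- function(...) {
  cfg <- list(
    n_participants = 20L,
    n_sensors = 270L,
    fs = 100,
    ar_coefficient = 0.5,
    noise_sd = 1,
    amplitude = 0.106,
    amplitude_objects = 0.45,
    amplitude_faces = 0.2,
    active_fraction = 0.10,
    resp_window_ms = c(50, 500),
    ramp_ms = 100,
    transient_ms = 20,
    lag_means_ms = c(obj_obj = 80, loc_type = 30, loc_attr = 60,
                     loc_op = 60, op_data = 120),
    lag_sds_ms = c(obj_obj = 10, loc_type = 10, loc_attr = 10,
                   loc_op = 10, op_data = 10),
    events_per_trial = 14L,
    replay_direction = "backward",
    chain_source = "correct",
    rsa_pattern_gain = 0.3,
    rsa_pattern_depth = "all",
    rsa_event_window_ms = c(180, 360),
    n_trials = 90L,
    localizer_duration_s = c(functional = 0.8, operation = 1.4),
    behavior = list(base_error = 0.15, error_per_length = 0.08,
                    error_per_op = 0.04, tt_base = 8, tt_per_length = 1.5,
                    tt_per_branch = 1.0, tt_sd = 2, tt_bounds = c(5, 20)),
    max_lag_ms = 200,
    n_shuffles = 1000L,
    lambda = 0.01,
    cv_folds = 8L,
    train_times_ms = NULL,
    seed = 1L
  )
  user <- list(...)
  bad <- setdiff(names(user), names(cfg))
  if (length(bad)) stop("unknown config fields: ", paste(bad, collapse = ", "))
  for (nm in names(user)) cfg[nm] <- list(user[[nm]])
  structure(cfg, class = "sim_config")
}

#' Validate and normalize a configuration
#'
#' Checks every constraint and reports all violations at once, not just the
#' first: the sampling rate must give an integer number of ms per sample, the
#' AR coefficient must be stationary, rates and SDs positive, and no lag may
#' exceed the TDLM lag ceiling.
#'
#' @param cfg a `sim_config` (or plain list of overrides)
#' @return the normalized `sim_config`
#' @export
validate_config <- function(cfg = sim_config()) {
  if (!inherits(cfg, "sim_config")) cfg <- do.call(sim_config, as.list(cfg))
  errs <- character()
  chk <- function(ok, msg) if (!isTRUE(ok)) errs <<- c(errs, msg)
  chk(cfg$fs > 0 && (1000 %% cfg$fs) == 0,
      sprintf("fs=%g must divide 1000 ms into an integer ms-per-sample", cfg$fs))
  chk(abs(cfg$ar_coefficient) < 1, "ar_coefficient must satisfy |ar| < 1")
  chk(cfg$noise_sd > 0, "noise_sd must be positive")
  chk(cfg$amplitude >= 0, "amplitude must be non-negative")
  chk(cfg$active_fraction > 0 && cfg$active_fraction <= 1,
      "active_fraction must be in (0, 1]")
  chk(all(cfg$lag_sds_ms >= 0), "lag SDs must be non-negative")
  chk(all(cfg$lag_means_ms >= 0), "lag means must be non-negative")
  chk(max(cfg$lag_means_ms) <= cfg$max_lag_ms,
      sprintf("lag means above max_lag_ms=%g are not scannable", cfg$max_lag_ms))
  chk(cfg$events_per_trial >= 0, "events_per_trial must be >= 0")
  chk(cfg$replay_direction %in% c("forward", "backward"),
      "replay_direction must be 'forward' or 'backward'")
  chk(cfg$rsa_pattern_depth %in% c("all", "deep", "shallow", "none"),
      "rsa_pattern_depth must be one of all/deep/shallow/none")
  chk(cfg$n_participants >= 1, "n_participants must be >= 1")
  chk(cfg$n_sensors >= 2, "n_sensors must be >= 2")
  if (length(errs)) stop("invalid configuration:\n  - ",
                         paste(errs, collapse = "\n  - "))
  cfg$n_participants <- as.integer(cfg$n_participants)
  cfg$n_sensors <- as.integer(cfg$n_sensors)
  cfg
}

ms_per_sample <- function(cfg) 1000 / cfg$fs

ms_to_samples <- function(ms, fs) as.integer(round(ms / 1000 * fs))
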