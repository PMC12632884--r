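## Synthetic sensor-space MEG generator: per-state multivariate patterns,
## AR(1) noise, localizer runs, and the reasoning run with injected replay
## sequences and a ground-truth injection log.

#' Decodable states of the pattern bank
#'
#' 12 objects, 6 face-attribute values, 2 operation types, 3 operation
#' attributes and 6 compound operations.
#' @return named list of character vectors by state group
#' @export
state_space <- function() {
  list(objects = default_locations(),
       face_values = unlist(face_attributes(), use.names = FALSE),
       op_types = c("swap", "branch"),
       op_attributes = names(face_attributes()),
       operations = operation_table()$op)
}

#' Create a bank of per-state sensor patterns
#'
#' Each decodable state gets a sparse multivariate pattern: Gaussian weights
#' of scale `amplitude` (in noise-SD units) on `round(active_fraction *
#' n_sensors)` sensors drawn independently per state.
#'
#' Stimulus-evoked object and face patterns are far more decodable than
#' abstract operation codes in recordings of this kind; `amplitude_by_group`
#' scales each state group separately (defaults: the base `amplitude` for
#' operation-related states, which is calibrated to the weak ~2%-above-chance
#' operation-decoding regime; stronger object and face patterns calibrated to
#' typical localizer decoding levels).
#'
#' @param n_sensors number of sensors
#' @param active_fraction fraction of sensors carrying each pattern
#' @param amplitude pattern scale in noise-SD units (operation states)
#' @param seed integer seed
#' @param amplitude_by_group optional named list with per-group scales
#'   (`objects`, `face_values`, `op_types`, `op_attributes`, `operations`)
#' @return object of class `pattern_bank`: states x sensors matrix plus meta
#' @export
make_pattern_bank <- function(n_sensors, active_fraction = 0.10,
                              amplitude = 1, seed = 1L,
                              amplitude_by_group = NULL) {
  stopifnot(active_fraction > 0, active_fraction <= 1)
  n_active <- as.integer(round(active_fraction * n_sensors))
  if (n_active < 1L) stop("active_fraction * n_sensors rounds below 1 sensor")
  groups <- state_space()
  amp_of <- function(g) amplitude_by_group[[g]] %||% amplitude
  set.seed(seed)
  states <- unlist(groups, use.names = FALSE)
  P <- matrix(0, length(states), n_sensors,
              dimnames = list(states, NULL))
  for (g in names(groups)) for (s in groups[[g]]) {
    idx <- sample.int(n_sensors, n_active)
    P[s, idx] <- amp_of(g) * stats::rnorm(n_active)
  }
  structure(list(patterns = P, n_sensors = as.integer(n_sensors),
                 active_fraction = active_fraction, amplitude = amplitude,
                 seed = as.integer(seed)),
            class = "pattern_bank")
}

#' Temporally autocorrelated Gaussian sensor noise
#'
#' Order-1 autoregressive noise, independent across sensors, with innovation
#' SD `noise_sd` (stationary variance `noise_sd^2 / (1 - ar^2)`). A burn-in
#' of 100 samples is discarded so the series starts stationary.
#'
#' @param n_sensors,n_samples array dimensions
#' @param ar_coefficient AR(1) coefficient, |ar| < 1
#' @param noise_sd innovation standard deviation
#' @param seed integer seed
#' @return numeric matrix, samples x sensors
#' @export
simulate_noise <- function(n_sensors, n_samples, ar_coefficient = 0.5,
                           noise_sd = 1, seed = 1L) {
  if (abs(ar_coefficient) >= 1) stop("non-stationary ar_coefficient")
  set.seed(seed)
  burn <- 100L
  e <- matrix(stats::rnorm((n_samples + burn) * n_sensors, sd = noise_sd),
              n_samples + burn, n_sensors)
  if (ar_coefficient != 0)
    e <- unclass(stats::filter(e, ar_coefficient, method = "recursive"))
  e[(burn + 1L):(burn + n_samples), , drop = FALSE]
}

## Stimulus-locked response window: flat 1 inside `resp_window_ms`, with
## raised-cosine on/off ramps of `ramp_ms`.
response_window <- function(n_samples, cfg) {
  t_ms <- (seq_len(n_samples) - 1L) * ms_per_sample(cfg)
  w <- numeric(n_samples)
  on <- cfg$resp_window_ms[1L]; off <- cfg$resp_window_ms[2L]
  r <- cfg$ramp_ms
  rising <- t_ms >= on & t_ms < on + r
  plateau <- t_ms >= on + r & t_ms <= off - r
  falling <- t_ms > off - r & t_ms <= off
  w[rising] <- 0.5 * (1 - cos(pi * (t_ms[rising] - on) / r))
  w[plateau] <- 1
  w[falling] <- 0.5 * (1 - cos(pi * (off - t_ms[falling]) / r))
  w
}

## Brief reactivation transient: half-cosine bump, peak-normalized.
transient_kernel <- function(cfg) {
  n <- max(2L, ms_to_samples(cfg$transient_ms, cfg$fs))
  k <- sin(pi * seq_len(n) / (n + 1L))
  k / max(k)
}

#' Default localizer trial schedules
#'
#' The functional localizer presents each of the 12 objects 38 times and each
#' of the 8 faces 11 times, so every face-attribute value appears on 44
#' trials. The operation localizer presents each object 22 times, i.e. 44
#' presentations per operation (each operation is tied to 2 objects).
#'
#' @param run `"functional"` or `"operation"`
#' @param graph a `task_graph`; required for the operation run (to look up
#'   each object's operation)
#' @param seed integer seed for the presentation order
#' @return data.frame schedule, one row per trial
#' @export
default_localizer_schedule <- function(run = c("functional", "operation"),
                                       graph = NULL, seed = 1L) {
  run <- match.arg(run)
  ops <- operation_table()
  if (run == "functional") {
    obj <- data.frame(stim_type = "object",
                      object = rep(default_locations(), each = 38L),
                      face_id = NA_character_, stringsAsFactors = FALSE)
    faces <- all_faces()
    fc <- data.frame(stim_type = "face", object = NA_character_,
                     face_id = rep(vapply(faces, face_id, ""), each = 11L),
                     stringsAsFactors = FALSE)
    sched <- rbind(obj, fc)
    dur <- 0.8
  } else {
    if (is.null(graph)) stop("operation schedule requires a task_graph")
    sched <- data.frame(stim_type = "object",
                        object = rep(graph$locations, each = 22L),
                        face_id = NA_character_, stringsAsFactors = FALSE)
    sched$op <- graph$op_of[sched$object]
    sched$op_type <- ops$op_type[match(sched$op, ops$op)]
    sched$op_attribute <- ops$attribute[match(sched$op, ops$op)]
    dur <- 1.4
  }
  set.seed(derive_seed(seed, paste0("schedule_", run)))
  sched <- sched[sample.int(nrow(sched)), , drop = FALSE]
  sched$trial <- seq_len(nrow(sched))
  sched$duration_s <- dur
  rownames(sched) <- NULL
  sched[, c("trial", "stim_type", setdiff(names(sched),
            c("trial", "stim_type", "duration_s")), "duration_s")]
}

## States embedded on a localizer trial.
schedule_states <- function(row) {
  if (row$stim_type == "face") {
    strsplit(row$face_id, ".", fixed = TRUE)[[1L]]
  } else if (!is.null(row$op) && !is.na(row$op)) {
    c(row$object, row$op_type, row$op_attribute, row$op)
  } else {
    row$object
  }
}

#' Simulate a localizer run
#'
#' Per trial: AR(1) noise plus the scheduled states' patterns, modulated by a
#' stimulus-locked response window (50-500 ms, raised-cosine ramps). On
#' operation-localizer trials the object pattern is accompanied by its
#' operation's type, attribute and compound patterns.
#'
#' @param bank a `pattern_bank`
#' @param schedule a schedule from [default_localizer_schedule()] (or same
#'   shape)
#' @param cfg a `sim_config`
#' @param run run label stored on the result
#' @return `sensor_timeseries`: list with `data` (trials x sensors x samples),
#'   `fs`, `run`, `trial_meta`
#' @export
simulate_localizer <- function(bank, schedule, cfg = sim_config(),
                               run = "functional_localizer") {
  cfg <- validate_config(cfg)
  if (is.null(schedule$op)) schedule$op <- NA_character_
  n_samples <- ms_to_samples(schedule$duration_s[1L] * 1000, cfg$fs)
  w <- response_window(n_samples, cfg)
  X <- array(0, c(nrow(schedule), bank$n_sensors, n_samples))
  for (t in seq_len(nrow(schedule))) {
    states <- schedule_states(schedule[t, ])
    miss <- setdiff(states, rownames(bank$patterns))
    if (length(miss)) stop("schedule states missing from bank: ",
                           paste(miss, collapse = ", "))
    sig <- crossprod(bank$patterns[states, , drop = FALSE],
                     matrix(1, length(states), 1L)) %*% matrix(w, 1L)
    noise <- simulate_noise(bank$n_sensors, n_samples, cfg$ar_coefficient,
                            cfg$noise_sd,
                            derive_seed(cfg$seed, paste0(run, "_noise_", t)))
    X[t, , ] <- t(noise) + sig
  }
  structure(list(data = X, fs = cfg$fs, run = run, trial_meta = schedule),
            class = "sensor_timeseries")
}
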