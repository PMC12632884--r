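## Reasoning-run generator: noise plus injected replay chains with full
## ground-truth logging, plus the simulated behavior model.

op_lookup <- function(op) {
  ops <- operation_table()
  i <- match(op, ops$op)
  list(op = op, op_type = ops$op_type[i], attribute = ops$attribute[i])
}

## Chain of (location, op, input value, output value) for one trial.
## For swaps output is the flipped attribute value; for branches the flip is
## hypothetical (no data update is injected, but input/output are defined).
chain_elements <- function(trial) {
  st <- trial$trace$steps
  lapply(seq_len(nrow(st)), function(k) {
    fb <- face_from_id(st$face_before[k])
    val_in <- fb[[st$attribute[k]]]
    val_out <- setdiff(face_attributes()[[st$attribute[k]]], val_in)
    list(location = st$location[k], op = st$op[k], op_type = st$op_type[k],
         attribute = st$attribute[k], input = val_in, output = val_out)
  })
}

## A deterministic "wrong execution": take the other successor at the first
## branch of the correct path, then continue executing faithfully.
wrong_execution <- function(graph, trial) {
  st <- trial$trace$steps
  b <- which(st$op_type == "branch")[1L]
  if (is.na(b)) return(trial)                 # no branch: nothing to corrupt
  other <- setdiff(unname(graph$succ_branch[[st$location[b]]]), st$nxt[b])
  if (length(other) == 0L || other == graph$end_token) return(trial)
  face <- face_from_id(st$face_before[b])
  tail_tr <- execute_program(graph, other, face)
  steps <- rbind(st[seq_len(b), ], tail_tr$steps)
  steps$nxt[b] <- other
  tr2 <- trial
  tr2$trace <- structure(list(steps = steps, length = nrow(steps),
                              path = steps$location,
                              faces_after = steps$face_after,
                              final_face = tail_tr$final_face),
                         class = "execution_trace")
  tr2$length <- nrow(steps)
  tr2
}

draw_lag_samples <- function(link, cfg, n = 1L) {
  ms <- stats::rnorm(n, cfg$lag_means_ms[[link]], cfg$lag_sds_ms[[link]])
  ms <- pmax(ms, 0)
  pmax(ms_to_samples(ms, cfg$fs), if (link == "obj_obj") 1L else 0L)
}

#' Simulate the reasoning run with injected replay
#'
#' Per trial, AR(1) noise plus `events_per_trial` injected replay events.
#' Each event is a chain of the trial's correct-path location patterns at the
#' object-to-object lag (reversed order when `replay_direction = "backward"`);
#' every location reactivation is trailed by its operation's type, attribute
#' and compound patterns at the configured lags, and on swap steps by the
#' post-update face-attribute ("output") pattern at the operation-to-data lag.
#' Branch steps inject no data update, serving as the built-in control. A
#' sustained path pattern (sum of non-start path-location patterns, scaled by
#' `rsa_pattern_gain`) is added during the final second of each trial and in
#' a short window after each event, carrying the program-similarity signal.
#'
#' All injected content is logged; the run is a pure function of
#' `(bank, trials, cfg)`.
#'
#' @param bank a `pattern_bank`
#' @param trials list of `trial_spec`
#' @param cfg a `sim_config`
#' @param durations_s per-trial reasoning durations in seconds; defaults to
#'   the trials' `thinking_time_s` (or 20 s where unset)
#' @param graph optional `task_graph`, required when
#'   `cfg$chain_source = "incorrect"`
#' @param return_signal also return the noiseless signal component (for
#'   ground-truth reconstruction tests)
#' @return list: `run` (a `sensor_timeseries` whose `data` is a list of
#'   sensors x samples matrices, one per trial) and `log` (injection log
#'   data.frame)
#' @export
simulate_reasoning <- function(bank, trials, cfg = sim_config(),
                               durations_s = NULL, graph = NULL,
                               return_signal = FALSE) {
  cfg <- validate_config(cfg)
  if (is.null(durations_s)) {
    durations_s <- vapply(trials, function(tr)
      if (is.finite(tr$thinking_time_s)) tr$thinking_time_s else 20, 0)
  }
  stopifnot(length(durations_s) == length(trials))
  P <- bank$patterns
  kern <- transient_kernel(cfg)
  log_rows <- list()
  data <- vector("list", length(trials))
  signal <- if (return_signal) vector("list", length(trials)) else NULL

  set.seed(derive_seed(cfg$seed, "reasoning_events"))
  for (t in seq_along(trials)) {
    trial <- trials[[t]]
    if (cfg$chain_source == "incorrect") {
      if (is.null(graph)) stop("chain_source='incorrect' requires the graph")
      trial <- wrong_execution(graph, trial)
    }
    n_samples <- ms_to_samples(durations_s[t] * 1000, cfg$fs)
    sig <- matrix(0, bank$n_sensors, n_samples)
    elems <- chain_elements(trial)
    if (cfg$replay_direction == "backward") elems <- rev(elems)

    add_transient <- function(sample, state, gain = 1) {
      if (sample < 1L || sample > n_samples) return(FALSE)
      idx <- sample:min(n_samples, sample + length(kern) - 1L)
      sig[, idx] <<- sig[, idx] + gain * outer(P[state, ], kern[seq_along(idx)])
      TRUE
    }

    for (ev in seq_len(cfg$events_per_trial)) {
      for (redraw in 1:50) {
        obj_lags <- draw_lag_samples("obj_obj", cfg, length(elems) - 1L)
        offs <- cumsum(c(0L, obj_lags))
        aux <- lapply(elems, function(e) list(
          type = draw_lag_samples("loc_type", cfg),
          attr = draw_lag_samples("loc_attr", cfg),
          op   = draw_lag_samples("loc_op", cfg),
          data = draw_lag_samples("op_data", cfg)))
        span <- max(offs) + max(vapply(aux, function(a) a$op + a$data, 0L)) +
          length(kern)
        if (span < n_samples) break
        if (redraw == 50L) stop("event chain does not fit trial ", t,
                                " (duration too short for configured lags)")
      }
      ## events start no earlier than 1 s into the trial: a replayed path
      ## (and its sustained trace) cannot precede its computation, and the
      ## reasoning-onset epoch must stay free of program structure
      onset_min <- min(ms_to_samples(1000, cfg$fs),
                       max(1L, n_samples - span - 1L))
      t0 <- onset_min + sample.int(max(1L, n_samples - span - onset_min), 1L)
      for (k in seq_along(elems)) {
        e <- elems[[k]]
        tk <- t0 + offs[k]
        put <- function(state, off, kind, anchor_lag) {
          if (add_transient(tk + off, state))
            log_rows[[length(log_rows) + 1L]] <<- data.frame(
              trial = t, event = ev, sample = tk + off, state = state,
              kind = kind, lag_ms = anchor_lag * ms_per_sample(cfg),
              direction = cfg$replay_direction, stringsAsFactors = FALSE)
        }
        put(e$location, 0L, "location", if (k == 1L) 0L else obj_lags[k - 1L])
        put(e$op_type, aux[[k]]$type, "type", aux[[k]]$type)
        put(e$attribute, aux[[k]]$attr, "attribute", aux[[k]]$attr)
        put(e$op, aux[[k]]$op, "operation", aux[[k]]$op)
        if (e$op_type == "swap")
          put(e$output, aux[[k]]$op + aux[[k]]$data, "output", aux[[k]]$data)
      }
      ## post-event program-pattern window (drives replay-aligned RSA)
      pp <- path_pattern(bank, trial, cfg)
      if (!is.null(pp)) {
        w0 <- t0 + ms_to_samples(cfg$rsa_event_window_ms[1L], cfg$fs)
        w1 <- min(n_samples, t0 + ms_to_samples(cfg$rsa_event_window_ms[2L], cfg$fs))
        if (w0 <= w1) {
          sig[, w0:w1] <- sig[, w0:w1] + pp
          log_rows[[length(log_rows) + 1L]] <- data.frame(
            trial = t, event = ev, sample = w0, state = "path_pattern",
            kind = "rsa_event", lag_ms = NA_real_,
            direction = cfg$replay_direction, stringsAsFactors = FALSE)
        }
      }
    }
    ## sustained end-of-trial path pattern
    pp <- path_pattern(bank, trial, cfg)
    if (!is.null(pp)) {
      e0 <- max(1L, n_samples - ms_to_samples(1000, cfg$fs) + 1L)
      sig[, e0:n_samples] <- sig[, e0:n_samples] + pp
      log_rows[[length(log_rows) + 1L]] <- data.frame(
        trial = t, event = NA_integer_, sample = e0, state = "path_pattern",
        kind = "rsa_end", lag_ms = NA_real_, direction = cfg$replay_direction,
        stringsAsFactors = FALSE)
    }
    noise <- t(simulate_noise(bank$n_sensors, n_samples, cfg$ar_coefficient,
                              cfg$noise_sd,
                              derive_seed(cfg$seed, paste0("reasoning_noise_", t))))
    data[[t]] <- noise + sig
    if (return_signal) signal[[t]] <- sig
  }
  log <- if (length(log_rows)) do.call(rbind, log_rows) else
    data.frame(trial = integer(), event = integer(), sample = integer(),
               state = character(), kind = character(), lag_ms = numeric(),
               direction = character())
  run <- structure(list(data = data, fs = cfg$fs, run = "reasoning",
                        trial_meta = trial_table(trials)),
                   class = "sensor_timeseries")
  out <- list(run = run, log = log)
  if (return_signal) out$signal <- signal
  out
}

## Sum of non-start path-location patterns (sensors x 1), restricted by
## cfg$rsa_pattern_depth; NULL when disabled.
path_pattern <- function(bank, trial, cfg) {
  if (cfg$rsa_pattern_depth == "none" || cfg$rsa_pattern_gain == 0) return(NULL)
  path <- trial$trace$path[-1L]
  locs <- switch(cfg$rsa_pattern_depth,
                 all = path, shallow = path[1L], deep = path[-1L])
  if (length(locs) == 0L) return(NULL)
  cfg$rsa_pattern_gain * colSums(bank$patterns[locs, , drop = FALSE])
}

#' Simulate probe responses and thinking times
#'
#' Error probability rises with program length and, for the probe's modality,
#' with the number of branches (object probes) or swaps (face probes).
#' Thinking time rises with length and branch count and is clipped to the
#' task's 5-20 s bounds.
#'
#' @param trials list of `trial_spec`
#' @param cfg a `sim_config` (uses `cfg$behavior`)
#' @param seed integer seed
#' @return data.frame, one row per probe, with per-trial thinking time
#' @export
simulate_behavior <- function(trials, cfg = sim_config(), seed = cfg$seed) {
  b <- cfg$behavior
  set.seed(derive_seed(seed, "behavior"))
  rows <- lapply(trials, function(tr) {
    tt <- b$tt_base + b$tt_per_length * (tr$length - 3L) +
      b$tt_per_branch * tr$n_branches + stats::rnorm(1L, 0, b$tt_sd)
    tt <- min(max(tt, b$tt_bounds[1L]), b$tt_bounds[2L])
    do.call(rbind, lapply(seq_along(tr$probes), function(i) {
      p <- tr$probes[[i]]
      load <- if (p$modality == "object") tr$n_branches else tr$n_swaps
      p_err <- b$base_error + b$error_per_length * (tr$length - 3L) +
        b$error_per_op * load
      p_err <- min(max(p_err, 0), 0.95)
      data.frame(trial_id = tr$trial_id, probe_index = i, q_type = p$q_type,
                 modality = p$modality, is_match = p$is_match,
                 depth_of_probe = p$depth_of_probe,
                 attribute_distance = p$attribute_distance,
                 correct = stats::runif(1L) > p_err, thinking_time_s = tt,
                 stringsAsFactors = FALSE)
    }))
  })
  do.call(rbind, rows)
}
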