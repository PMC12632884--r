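## Study orchestration: one call simulates a multi-participant synthetic
## study, runs the analysis stages, and emits a machine-readable recovery
## report. Plus plain-text dataset serialization and a small CLI.

simulate_participant <- function(cfg, p) {
  pcfg <- cfg
  pcfg$seed <- derive_seed(cfg$seed, paste0("participant_", p))
  graph <- generate_task_graph(derive_seed(pcfg$seed, "graph"))
  trials <- sample_trials(graph, cfg$n_trials, derive_seed(pcfg$seed, "trials"))
  behavior <- simulate_behavior(trials, pcfg, pcfg$seed)
  tt <- behavior$thinking_time_s[match(seq_along(trials), behavior$trial_id)]
  for (t in seq_along(trials)) trials[[t]]$thinking_time_s <- tt[t]
  bank <- make_pattern_bank(cfg$n_sensors, cfg$active_fraction, cfg$amplitude,
                            derive_seed(pcfg$seed, "bank"),
                            amplitude_by_group = list(
                              objects = cfg$amplitude_objects,
                              face_values = cfg$amplitude_faces))
  list(cfg = pcfg, graph = graph, trials = trials, behavior = behavior,
       bank = bank)
}

participant_runs <- function(part) {
  cfg <- part$cfg
  fl <- simulate_localizer(
    part$bank, default_localizer_schedule("functional", seed = cfg$seed),
    cfg, "functional_localizer")
  ol <- simulate_localizer(
    part$bank, default_localizer_schedule("operation", part$graph, cfg$seed),
    cfg, "operation_localizer")
  rs <- simulate_reasoning(part$bank, part$trials, cfg, graph = part$graph)
  list(functional = fl, operation = ol, reasoning = rs$run, log = rs$log)
}

#' Run the full synthetic study
#'
#' Simulates `cfg$n_participants` participants (task graph, trials, behavior,
#' localizers, reasoning run with injected replay), trains decoders, computes
#' reactivation matrices, and runs the requested analysis stages. Returns
#' per-participant results, group-level sequenceness, and a recovery report
#' comparing every injected lag with its recovered peak.
#'
#' Decoder modes: `"trained"` runs the full localizer-decoding path (lasso
#' classifiers, held-out-object application weights). `"template"` applies
#' the pattern bank itself as matched-filter weights, the procedure the
#' validation simulations use for sequence recovery - representations in the
#' reasoning data are defined by the same sensor patterns the generator
#' embeds, so recovery isolates the sequence analyses from decoder-induced
#' artifacts.
#'
#' @param cfg a `sim_config`
#' @param stages analysis stages to run
#' @param n_shuffles permutation count for nulls (scaled down in tests)
#' @param decoders `"trained"` or `"template"` (see Details)
#' @return list of class `study_result` with elements `participants`,
#'   `group`, `report`, `config`
#' @export
run_study <- function(cfg = sim_config(),
                      stages = c("sequenceness", "loc_op", "multistep", "rsa"),
                      n_shuffles = cfg$n_shuffles,
                      decoders = c("trained", "template")) {
  decoders <- match.arg(decoders)
  cfg <- validate_config(cfg)
  parts <- list()
  perms12 <- draw_state_permutations(12L, n_shuffles, derive_seed(cfg$seed, "p12"))
  perms18 <- draw_state_permutations(18L, n_shuffles, derive_seed(cfg$seed, "p18"),
                                     blocks = list(1:12, 13:18))
  for (p in seq_len(cfg$n_participants)) {
    part <- simulate_participant(cfg, p)
    pcfg <- part$cfg
    if (decoders == "trained") {
      runs <- participant_runs(part)
      dec_obj <- train_state_decoders(runs$functional, "objects", pcfg,
                                      times_ms = cfg$train_times_ms)
      dec_face <- train_state_decoders(runs$functional, "face_attributes", pcfg,
                                       times_ms = cfg$train_times_ms)
      dec_op <- train_abstract_decoders(runs$operation, "compound", pcfg,
                                        times_ms = cfg$train_times_ms)
      dec_type <- train_abstract_decoders(runs$operation, "type", pcfg,
                                          times_ms = cfg$train_times_ms)
      dec_attr <- train_abstract_decoders(runs$operation, "attribute", pcfg,
                                          times_ms = cfg$train_times_ms)
      react_obj <- apply_decoders(dec_obj, runs$reasoning)
      react_op <- apply_decoders_heldout(dec_op, runs$reasoning, part$trials)
      react_type <- apply_decoders_heldout(dec_type, runs$reasoning, part$trials)
      react_attr <- apply_decoders_heldout(dec_attr, runs$reasoning, part$trials)
      react_face <- apply_decoders(dec_face, runs$reasoning)
      res <- list(behavior = part$behavior, log = runs$log,
                  decoding = list(object_acc = max(dec_obj$curve$smoothed),
                                  op_acc = max(dec_op$curve$smoothed),
                                  op_chance = dec_op$chance),
                  weights = list(
                    objects = list(W = dec_obj$W, b = dec_obj$b,
                                   states = dec_obj$states),
                    faces = list(W = dec_face$W, b = dec_face$b,
                                 states = dec_face$states),
                    operation = abstract_weights(dec_op)))
    } else {
      rs <- simulate_reasoning(part$bank, part$trials, pcfg, graph = part$graph)
      runs <- list(reasoning = rs$run, log = rs$log)
      tw <- function(states) list(W = part$bank$patterns[states, , drop = FALSE],
                                  b = rep(-2, length(states)), states = states)
      sp <- state_space()
      react_obj <- apply_decoders(tw(sp$objects), runs$reasoning)
      react_op <- apply_decoders(tw(sp$operations), runs$reasoning)
      react_type <- apply_decoders(tw(sp$op_types), runs$reasoning)
      react_attr <- apply_decoders(tw(sp$op_attributes), runs$reasoning)
      react_face <- apply_decoders(tw(sp$face_values), runs$reasoning)
      res <- list(behavior = part$behavior, log = runs$log,
                  weights = list(objects = tw(sp$objects),
                                 faces = tw(sp$face_values),
                                 operation = tw(sp$operations)))
    }
    if ("sequenceness" %in% stages) {
      res$seq_correct <- path_sequenceness(
        react_obj, part$trials, part$graph, c("correct", "incorrect"),
        n_shuffles, pcfg$seed, cfg$max_lag_ms, perms = perms12)
      res$seq_depth <- path_sequenceness(
        react_obj, part$trials, part$graph, c("shallow", "deep"),
        0L, pcfg$seed, cfg$max_lag_ms)
    }
    if ("loc_op" %in% stages) {
      res$loc_op <- loc_op_sequenceness(react_obj, react_op, part$trials,
                                        "operation", n_shuffles, pcfg$seed,
                                        cfg$max_lag_ms, perms = perms18)
      res$loc_type <- loc_op_sequenceness(react_obj, react_type, part$trials,
                                          "type", 0L, pcfg$seed, cfg$max_lag_ms)
      res$loc_attr <- loc_op_sequenceness(react_obj, react_attr, part$trials,
                                          "attribute", 0L, pcfg$seed,
                                          cfg$max_lag_ms)
    }
    if ("multistep" %in% stages) {
      lag_hat <- if (!is.null(res$loc_op))
        res$loc_op$curve$lags_ms[which.max(res$loc_op$curve$forward[, 1L])]
      else cfg$lag_means_ms[["loc_op"]]
      res$ms_swap <- multistep(react_obj, react_op, react_face, part$trials,
                               lag_hat, op_type = "swap", standardize = TRUE)
      res$ms_branch <- multistep(react_obj, react_op, react_face, part$trials,
                                 lag_hat, op_type = "branch", standardize = TRUE)
    }
    if ("rsa" %in% stages) {
      model <- list(program = path_similarity(part$trials, "program"),
                    face_path = path_similarity(part$trials, "face_path"),
                    length_diff = path_similarity(part$trials, "length_diff"))
      res$rsa_start <- list(
        emp = empirical_similarity(runs$reasoning, 1, "onset"), model = model)
      res$rsa_end <- list(
        emp = empirical_similarity(runs$reasoning, 1, "offset"), model = model)
    }
    res$trials <- part$trials
    parts[[p]] <- res
  }

  group <- list()
  if ("sequenceness" %in% stages) {
    g <- group_sequenceness(lapply(parts, function(x) x$seq_correct$curve),
                            lapply(parts, function(x) x$seq_correct$null))
    group$seq_correct <- g
    group$seq_correct$threshold <- list(
      forward = vapply(g$curve$regressors, function(r)
        null_threshold(group$seq_correct$null, r, "forward"), 0),
      backward = vapply(g$curve$regressors, function(r)
        null_threshold(group$seq_correct$null, r, "backward"), 0))
  }
  if ("loc_op" %in% stages) {
    g <- group_sequenceness(lapply(parts, function(x) x$loc_op$curve),
                            lapply(parts, function(x) x$loc_op$null))
    group$loc_op <- g
    group$loc_op$threshold <- null_threshold(g$null, 1L, "forward")
    group$loc_type <- group_sequenceness(
      lapply(parts, function(x) x$loc_type$curve))
    group$loc_attr <- group_sequenceness(
      lapply(parts, function(x) x$loc_attr$curve))
  }
  if ("multistep" %in% stages) {
    group$ms_swap_contrast <- rowMeans(
      sapply(parts, function(x) x$ms_swap$contrast))
    group$ms_branch_contrast <- rowMeans(
      sapply(parts, function(x) x$ms_branch$contrast))
    group$ms_lags_ms <- parts[[1L]]$ms_swap$lags_ms
  }
  report <- recovery_report(cfg, parts, group, stages)
  structure(list(participants = parts, group = group, report = report,
                 config = cfg), class = "study_result")
}

recovery_report <- function(cfg, parts, group, stages) {
  rows <- list()
  add <- function(effect, injected, recovered, threshold, supra) {
    rows[[length(rows) + 1L]] <<- data.frame(
      effect = effect, injected = injected, recovered = recovered,
      threshold = threshold, suprathreshold = supra,
      pass = is.finite(recovered) && abs(recovered - injected) <= 10 + 1e-9,
      stringsAsFactors = FALSE)
  }
  dir_curve <- function(g) if (cfg$replay_direction == "backward")
    g$curve$backward else g$curve$forward
  if (!is.null(group$seq_correct)) {
    cv <- dir_curve(group$seq_correct)[, "correct"]
    thr <- if (cfg$replay_direction == "backward")
      group$seq_correct$threshold$backward[["correct"]]
    else group$seq_correct$threshold$forward[["correct"]]
    add("obj_obj", cfg$lag_means_ms[["obj_obj"]],
        group$seq_correct$curve$lags_ms[which.max(cv)], thr, max(cv) > thr)
  }
  if (!is.null(group$loc_op)) {
    for (nm in c("loc_type", "loc_attr", "loc_op")) {
      g <- group[[switch(nm, loc_type = "loc_type", loc_attr = "loc_attr",
                         loc_op = "loc_op")]]
      cv <- g$curve$forward[, 1L]
      thr <- if (nm == "loc_op") group$loc_op$threshold else NA_real_
      add(nm, cfg$lag_means_ms[[nm]], g$curve$lags_ms[which.max(cv)], thr,
          if (is.na(thr)) NA else max(cv) > thr)
    }
  }
  if (!is.null(group$ms_swap_contrast)) {
    add("op_data", cfg$lag_means_ms[["op_data"]],
        group$ms_lags_ms[which.max(group$ms_swap_contrast)], NA_real_, NA)
  }
  if (!length(rows)) return(data.frame())
  do.call(rbind, rows)
}

#' Serialize a dataset (arrays, tables, metadata) to a plain-text file
#'
#' JSON with full numeric precision; arrays are stored with their dimensions
#' and restored bit-exactly on load. HDF5 is deliberately not used so that
#' datasets remain diff-able text.
#'
#' @param x a (possibly nested) list of arrays, data frames and scalars
#' @param path output file
#' @export
save_dataset <- function(x, path) {
  enc <- function(v) {
    if (is.array(v)) list(.array = list(dim = dim(v), data = as.vector(v)))
    else if (is.data.frame(v)) list(.df = as.list(v))
    else if (is.list(v)) lapply(v, enc)
    else v
  }
  jsonlite::write_json(list(schema_version = 1L, payload = enc(x)), path,
                       digits = I(17), auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' Load a dataset written by [save_dataset()]
#' @param path file path
#' @export
load_dataset <- function(path) {
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e) stop("unreadable dataset (schema 1): ",
                                           conditionMessage(e)))
  if (is.null(obj$schema_version) || obj$schema_version != 1L)
    stop("dataset schema version mismatch (expected 1, got ",
         obj$schema_version %||% "none", ")")
  dec <- function(v) {
    if (is.list(v) && !is.null(v$.array))
      return(array(v$.array$data, v$.array$dim))
    if (is.list(v) && !is.null(v$.df))
      return(as.data.frame(v$.df, stringsAsFactors = FALSE))
    if (is.list(v)) return(lapply(v, dec))
    v
  }
  dec(obj$payload)
}

#' Command-line entry point
#'
#' Subcommands: `simulate` (write a synthetic dataset), `decode` (train
#' localizer decoders for one participant and report accuracies),
#' `sequenceness` (sequence recovery stages + report), `rsa`
#' (similarity-analysis stage), `run-all` (every stage + report), `report`
#' (re-print a saved report). Global flags: `--seed`, `--participants`,
#' `--out`, `--shuffles`, `--sensors`, `--trials`, `--decoders`
#' (trained|template).
#'
#' @param args character vector (defaults to the command line)
#' @export
replay_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0L)
    stop("usage: <simulate|run-all|report> [--seed N] [--participants N] ",
         "[--out PATH] [--shuffles N]")
  cmd <- args[1L]
  opt <- function(flag, default) {
    i <- which(args == flag)
    if (length(i)) args[i + 1L] else default
  }
  seed <- as.integer(opt("--seed", "1"))
  np <- as.integer(opt("--participants", "2"))
  out <- opt("--out", "study_out.json")
  nsh <- as.integer(opt("--shuffles", "200"))
  cfg <- sim_config(seed = seed, n_participants = np,
                    n_sensors = as.integer(opt("--sensors", "270")),
                    n_trials = as.integer(opt("--trials", "90")))
  dec_mode <- opt("--decoders", "trained")
  if (cmd == "simulate") {
    part <- simulate_participant(cfg, 1L)
    runs <- participant_runs(part)
    save_dataset(list(log = runs$log, trials = trial_table(part$trials),
                      behavior = part$behavior), out)
    message("wrote ", out)
  } else if (cmd == "decode") {
    part <- simulate_participant(cfg, 1L)
    runs <- participant_runs(part)
    acc <- list(
      objects = max(train_state_decoders(runs$functional, "objects",
                                         part$cfg)$curve$accuracy),
      faces = max(train_state_decoders(runs$functional, "face_attributes",
                                       part$cfg)$curve$accuracy),
      operations = max(train_abstract_decoders(runs$operation, "compound",
                                               part$cfg)$curve$accuracy))
    save_dataset(list(peak_accuracy = acc), out)
    print(unlist(acc))
    message("wrote ", out)
  } else if (cmd %in% c("sequenceness", "rsa", "run-all")) {
    stages <- switch(cmd,
                     sequenceness = c("sequenceness", "loc_op", "multistep"),
                     rsa = "rsa",
                     `run-all` = c("sequenceness", "loc_op", "multistep", "rsa"))
    res <- run_study(cfg, stages = stages, n_shuffles = nsh,
                     decoders = dec_mode)
    save_dataset(list(report = res$report, config = cfg[
      c("seed", "n_participants", "n_sensors", "amplitude")]), out)
    if (nrow(res$report)) print(res$report)
    message("wrote ", out)
  } else if (cmd == "report") {
    print(load_dataset(out)$report)
  } else stop("unknown subcommand: ", cmd)
  invisible(NULL)
}
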