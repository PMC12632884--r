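## High-level sequenceness analyses: trial-wise path regressors, multi-step
## chains with controls, replay-onset detection, event-locked reactivation,
## and the session-trend regressor.

#' Restrict a reactivation matrix to a subset of states
#' @param react a `reactivation_matrix`
#' @param states states to keep, in order
#' @export
subset_react <- function(react, states) {
  stopifnot(all(states %in% react$states))
  structure(list(mats = lapply(react$mats, function(m)
    m[, states, drop = FALSE]), states = states, fs = react$fs),
    class = "reactivation_matrix")
}

#' Trial-wise theoretical matrix linking path locations to an operation
#' feature
#'
#' Over a combined state space (objects plus the feature's states), marks a
#' transition from every correct-path location to its operation's type,
#' attribute or compound identity.
#'
#' @param trial a `trial_spec`
#' @param states combined state vector (row/col names of the result)
#' @param feature `"type"`, `"attribute"` or `"operation"`
#' @export
loc_feature_matrix <- function(trial, states,
                               feature = c("operation", "type", "attribute")) {
  feature <- match.arg(feature)
  M <- matrix(0, length(states), length(states),
              dimnames = list(states, states))
  st <- trial$trace$steps
  for (k in seq_len(nrow(st))) {
    f <- switch(feature, operation = st$op[k], type = st$op_type[k],
                attribute = st$attribute[k])
    M[st$location[k], f] <- 1
  }
  M
}

#' Path sequenceness with trial-wise theoretical matrices
#'
#' Wraps the two TDLM stages with the requested trial-wise regressors
#' (`correct`, `incorrect`, `shallow`, `deep` - any combination enters one
#' GLM) over the 12 object states, after dropping trials that fail the
#' reactivation-frequency filter.
#'
#' @param react a `reactivation_matrix` containing the object states
#' @param trials list of `trial_spec` aligned with `react$mats`
#' @param graph the `task_graph`
#' @param which character vector of regressors
#' @param n_shuffles permutation count (0 skips the null)
#' @param seed integer seed
#' @param max_lag_ms lag ceiling
#' @param entropy_bounds see [entropy_filter()]
#' @param perms optional shared permutations
#' @return list: `curve`, `null`, `threshold` (per regressor, forward),
#'   `kept`, `drop_fraction`
#' @export
path_sequenceness <- function(react, trials, graph,
                              which = "correct", n_shuffles = 1000L,
                              seed = 1L, max_lag_ms = 200,
                              entropy_bounds = c(0.025, 0.05), perms = NULL) {
  stopifnot(all(which %in% c("correct", "incorrect", "shallow", "deep")))
  ro <- subset_react(react, default_locations())
  keep <- vapply(seq_along(trials), function(t)
    entropy_filter(ro, trials[[t]], entropy_bounds)$keep, TRUE)
  if (!any(keep)) stop("no trials left after reactivation-frequency filter")
  ro$mats <- ro$mats[keep]
  kept_trials <- trials[keep]
  theor <- lapply(kept_trials, function(tr) {
    tm <- transition_matrices(graph, tr)
    lm_ <- path_link_matrices(graph, tr)
    out <- list(correct = tm$correct, incorrect = tm$incorrect,
                shallow = lm_$shallow, deep = lm_$deep)[which]
    out
  })
  emp <- first_stage(ro, max_lag_ms)
  curve <- second_stage(emp, theor)
  out <- list(curve = curve, kept = which(keep),
              drop_fraction = mean(!keep))
  if (n_shuffles > 0L) {
    out$null <- permutation_null(emp, theor, n_shuffles, seed, perms)
    out$threshold <- vapply(curve$regressors, function(r)
      null_threshold(out$null, r, "forward"), 0)
    out$threshold_bwd <- vapply(curve$regressors, function(r)
      null_threshold(out$null, r, "backward"), 0)
  }
  out
}

#' Location-to-operation sequenceness
#'
#' Same machinery over the combined object + operation-feature state space,
#' with trial-wise Location -> Type / Attribute / Operation matrices.
#'
#' @inheritParams path_sequenceness
#' @param react_op reactivations of the feature states
#' @param feature which operation feature links to scan
#' @export
loc_op_sequenceness <- function(react, react_op, trials,
                                feature = c("operation", "type", "attribute"),
                                n_shuffles = 1000L, seed = 1L,
                                max_lag_ms = 200, perms = NULL) {
  feature <- match.arg(feature)
  ro <- subset_react(react, default_locations())
  comb <- bind_reactivations(ro, react_op)
  theor <- lapply(trials, function(tr)
    stats::setNames(list(loc_feature_matrix(tr, comb$states, feature)), feature))
  emp <- first_stage(comb, max_lag_ms, on_deficiency = "ridge")
  curve <- second_stage(emp, theor)
  out <- list(curve = curve)
  if (n_shuffles > 0L) {
    blocks <- list(seq_along(ro$states),
                   length(ro$states) + seq_along(react_op$states))
    out$null <- permutation_null(emp, theor, n_shuffles, seed, perms,
                                 blocks = blocks)
    out$threshold <- null_threshold(out$null, feature, "forward")
  }
  out
}

#' Multi-step TDLM with nested controls
#'
#' Scans the terminal link of a Location -> Operation -> Data chain: for each
#' scanned lag `d`, the data series `y(t)` is regressed on the compound
#' regressor `loc(t - d1 - d) * op(t - d)` while controlling for the location
#' series alone at the cumulative lag (`loc(t - d1 - d)`, a data update
#' "consistent with a missing operation"), the operation series alone
#' (`op(t - d)`), the location at the direct lag (`loc(t - d)`, location
#' followed immediately by data), and a constant. For every swap (or, as
#' control, branch) step the regression is run with the output and with the
#' input attribute-value series as the outcome; the returned contrast is
#' beta(Output) - beta(Input), averaged across steps and trials.
#'
#' When a decoder is weak its probability series hovers around a constant,
#' so the residualized compound regressor has almost no variance and raw
#' per-step betas become ill-conditioned (huge, sign-arbitrary values that
#' dominate averages). `standardize = TRUE` scales every non-constant design
#' column to unit variance, putting step- and trial-level betas on a common
#' scale; the raw product is the default definition.
#'
#' @param react_loc object reactivations
#' @param react_op compound-operation reactivations
#' @param react_data face-attribute-value reactivations
#' @param trials list of `trial_spec`
#' @param loc_op_lag_ms fixed Location -> Operation lag (from prior analysis)
#' @param scan_lags_ms lags scanned for the Operation -> Data link
#' @param op_type restrict to `"swap"` or `"branch"` steps
#' @param standardize scale design columns to unit variance
#' @return list: `lags_ms`, `contrast`, `beta_output`, `beta_input`,
#'   `per_trial` (trials x lags contrast matrix)
#' @export
multistep <- function(react_loc, react_op, react_data, trials,
                      loc_op_lag_ms = 60,
                      scan_lags_ms = seq(10, 200, by = 10),
                      op_type = c("swap", "branch"), standardize = FALSE) {
  op_type <- match.arg(op_type)
  fs <- react_loc$fs
  d1 <- ms_to_samples(loc_op_lag_ms, fs)
  dls <- ms_to_samples(scan_lags_ms, fs)
  n_trials <- length(trials)
  per_trial <- matrix(NA_real_, n_trials, length(dls))
  bo_all <- matrix(NA_real_, n_trials, length(dls))
  bi_all <- matrix(NA_real_, n_trials, length(dls))
  for (t in seq_len(n_trials)) {
    elems <- Filter(function(e) e$op_type == op_type, chain_elements(trials[[t]]))
    if (length(elems) == 0L) next
    L <- react_loc$mats[[t]]; O <- react_op$mats[[t]]; Dm <- react_data$mats[[t]]
    Tn <- nrow(L)
    bo <- matrix(0, length(elems), length(dls)); bi <- bo
    for (ei in seq_along(elems)) {
      e <- elems[[ei]]
      xl <- L[, e$location]; xo <- O[, e$op]
      yo <- Dm[, e$output]; yi <- Dm[, e$input]
      for (j in seq_along(dls)) {
        d <- dls[j]
        t0 <- d1 + d + 1L
        if (t0 >= Tn) stop("cumulative lags exceed trial length")
        idx <- t0:Tn
        comp <- xl[idx - d1 - d] * xo[idx - d]
        D <- cbind(comp, xl[idx - d1 - d], xo[idx - d], xl[idx - d], 1)
        if (standardize)
          D[, 1:4] <- sweep(D[, 1:4], 2L,
                            pmax(apply(D[, 1:4], 2L, stats::sd), 1e-12), `/`)
        q <- qr(D)
        bo[ei, j] <- qr.coef(q, yo[idx])[1L]
        bi[ei, j] <- qr.coef(q, yi[idx])[1L]
      }
    }
    bo_m <- colMeans(bo); bi_m <- colMeans(bi)
    bo_all[t, ] <- bo_m; bi_all[t, ] <- bi_m
    per_trial[t, ] <- bo_m - bi_m
  }
  used <- !is.na(per_trial[, 1L])
  list(lags_ms = scan_lags_ms,
       contrast = colMeans(per_trial[used, , drop = FALSE]),
       beta_output = colMeans(bo_all[used, , drop = FALSE]),
       beta_input = colMeans(bi_all[used, , drop = FALSE]),
       per_trial = per_trial[used, , drop = FALSE])
}

#' Input/output label-shuffle null for the multistep contrast
#'
#' Swapping the input and output series of a trial flips the sign of its
#' contrast, so the null is a per-trial random sign flip.
#'
#' @param per_trial trials x lags contrast matrix from [multistep()]
#' @param n_shuffles number of shuffles
#' @param seed integer seed
#' @return list: `threshold` (max-over-lags 95th percentile), `null` matrix
#' @export
multistep_null <- function(per_trial, n_shuffles = 1000L, seed = 1L) {
  set.seed(derive_seed(seed, "multistep_null"))
  n <- nrow(per_trial)
  null <- t(vapply(seq_len(n_shuffles), function(s)
    colMeans(per_trial * sample(c(-1, 1), n, replace = TRUE)),
    numeric(ncol(per_trial))))
  list(threshold = max(apply(null, 2L, stats::quantile, 0.95, names = FALSE)),
       null = null)
}

#' Detect replay onsets from joint location x lagged operation reactivation
#'
#' For every correct-path step, the joint score is the location probability
#' times the operation probability shifted by `lag_ms`. A null is built by
#' shuffling state identities before multiplication; the threshold is the
#' maximum over time of the per-time 95th percentile of null scores. Events
#' closer than `min_sep_ms` are pruned greedily by score.
#'
#' @param react_loc,react_op reactivation matrices
#' @param trials list of `trial_spec`
#' @param lag_ms the Location -> Operation lag
#' @param n_shuffles identity shuffles for the null
#' @param min_sep_ms minimum separation between retained events
#' @param seed integer seed
#' @return data.frame of events: trial, sample, location, op, score
#' @export
detect_replay_onsets <- function(react_loc, react_op, trials, lag_ms = 60,
                                 n_shuffles = 1000L, min_sep_ms = 200,
                                 seed = 1L) {
  fs <- react_loc$fs
  d <- ms_to_samples(lag_ms, fs)
  if (d < 1L) stop("lag not representable at fs = ", fs)
  min_sep <- ms_to_samples(min_sep_ms, fs)
  objs <- intersect(react_loc$states, default_locations())
  set.seed(derive_seed(seed, "replay_onsets"))
  events <- list()
  for (t in seq_along(trials)) {
    st <- trials[[t]]$trace$steps
    L <- react_loc$mats[[t]]; O <- react_op$mats[[t]]
    Tn <- nrow(L)
    idx <- seq_len(Tn - d)
    score <- sapply(seq_len(nrow(st)), function(k)
      L[idx, st$location[k]] * O[idx + d, st$op[k]])
    ## identity-shuffle null: permute location and operation labels
    null_mat <- matrix(0, length(idx), n_shuffles)
    for (s in seq_len(n_shuffles)) {
      pl <- sample(objs); names(pl) <- objs
      po <- sample(react_op$states); names(po) <- react_op$states
      ns <- sapply(seq_len(nrow(st)), function(k)
        L[idx, pl[[st$location[k]]]] * O[idx + d, po[[st$op[k]]]])
      null_mat[, s] <- rowMeans(ns)
    }
    thr <- max(apply(null_mat, 1L, stats::quantile, 0.95, names = FALSE))
    obs <- rowMeans(as.matrix(score))
    cand <- which(obs > thr)
    if (length(cand)) {
      ord <- cand[order(obs[cand], decreasing = TRUE)]
      keep <- integer()
      for (ti in ord)
        if (!length(keep) || all(abs(keep - ti) >= min_sep))
          keep <- c(keep, ti)
      k_best <- vapply(keep, function(ti)
        which.max(score[ti, , drop = TRUE][seq_len(nrow(st))]), 0L)
      events[[length(events) + 1L]] <- data.frame(
        trial = t, sample = sort(keep),
        location = st$location[k_best[order(keep)]],
        op = st$op[k_best[order(keep)]],
        score = obs[sort(keep)], stringsAsFactors = FALSE)
    }
  }
  if (!length(events))
    return(data.frame(trial = integer(), sample = integer(),
                      location = character(), op = character(),
                      score = numeric()))
  do.call(rbind, events)
}

#' Event-locked input/output reactivation time courses
#'
#' Epochs the trial-specific input and output attribute-value series around
#' each replay event, baseline-subtracts the pre-event mean, averages within
#' trial then across trials, and cluster-tests the output - input difference
#' against an input/output label-flip null (95th percentile, mass-corrected).
#'
#' @param events data.frame from [detect_replay_onsets()]
#' @param react_data face-attribute-value reactivations
#' @param trials list of `trial_spec`
#' @param window_ms epoch window around the event
#' @param n_shuffles label shuffles
#' @param seed integer seed
#' @return list: `time_ms`, `input`, `output`, `diff`, `mask`, `threshold`
#' @export
event_locked_reactivation <- function(events, react_data, trials,
                                      window_ms = c(-100, 400),
                                      n_shuffles = 1000L, seed = 1L) {
  if (nrow(events) == 0L) stop("no events supplied")
  fs <- react_data$fs
  w <- ms_to_samples(window_ms, fs)
  rel <- w[1L]:w[2L]
  base_idx <- which(rel < 0)
  per_trial_in <- list(); per_trial_out <- list()
  for (t in unique(events$trial)) {
    ev <- events[events$trial == t, ]
    st <- trials[[t]]$trace$steps
    elems <- chain_elements(trials[[t]])
    Dm <- react_data$mats[[t]]
    Tn <- nrow(Dm)
    ins <- list(); outs <- list()
    for (i in seq_len(nrow(ev))) {
      k <- match(ev$location[i], st$location)
      if (is.na(k)) next
      s0 <- ev$sample[i]
      if (s0 + w[1L] < 1L || s0 + w[2L] > Tn) next
      yi <- Dm[s0 + rel, elems[[k]]$input]
      yo <- Dm[s0 + rel, elems[[k]]$output]
      ins[[length(ins) + 1L]] <- yi - mean(yi[base_idx])
      outs[[length(outs) + 1L]] <- yo - mean(yo[base_idx])
    }
    if (length(ins)) {
      per_trial_in[[length(per_trial_in) + 1L]] <- Reduce(`+`, ins) / length(ins)
      per_trial_out[[length(per_trial_out) + 1L]] <- Reduce(`+`, outs) / length(outs)
    }
  }
  if (!length(per_trial_in)) stop("window exceeds trial bounds for all events")
  Min <- do.call(rbind, per_trial_in)
  Mout <- do.call(rbind, per_trial_out)
  dmat <- Mout - Min
  obs <- colMeans(dmat)
  set.seed(derive_seed(seed, "event_locked"))
  null_max <- vapply(seq_len(n_shuffles), function(s) {
    flip <- sample(c(-1, 1), nrow(dmat), replace = TRUE)
    max_cluster_mass(colMeans(dmat * flip))
  }, 0)
  thr <- stats::quantile(null_max, 0.95, names = FALSE)
  list(time_ms = rel * 1000 / fs, input = colMeans(Min),
       output = colMeans(Mout), diff = obs,
       mask = cluster_mask(obs, thr), threshold = thr)
}

#' Session trend of a per-trial effect
#'
#' Sliding-window means (window = `window_fraction` of trials, stepped by one
#' trial) regressed on window index; a positive slope indicates increasing
#' effect strength across the session.
#'
#' @param per_trial_effect numeric series, one value per trial in session order
#' @param window_fraction fraction of trials per window
#' @return list: `beta` (slope), `window_means`, `constant` flag
#' @export
session_trend <- function(per_trial_effect, window_fraction = 1 / 3) {
  n <- length(per_trial_effect)
  w <- max(1L, floor(n * window_fraction))
  k <- n - w + 1L
  if (k < 3L) stop("need at least 3 sliding windows")
  means <- vapply(seq_len(k), function(i)
    mean(per_trial_effect[i:(i + w - 1L)]), 0)
  if (stats::sd(means) == 0)
    return(list(beta = 0, window_means = means, constant = TRUE))
  list(beta = unname(stats::coef(stats::lm(means ~ seq_len(k)))[2L]),
       window_means = means, constant = FALSE)
}
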