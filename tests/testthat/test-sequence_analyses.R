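## Multi-step chains, replay-onset detection, and event-locked reactivation
## on directly constructed reactivation series (decoder-independent).

## Reactivation series for trials with injected Location -> Operation -> Data
## chains at exact sample lags.
chain_react <- function(trials, n_samples, d1, d2, n_events, seed,
                        data_kind = "output", fs = 100, noise = 0.02) {
  objs <- default_locations()
  ops <- operation_table()$op
  vals <- unlist(face_attributes(), use.names = FALSE)
  set.seed(seed)
  mk <- function(states) lapply(seq_along(trials), function(t)
    matrix(stats::runif(n_samples * length(states), 0, noise), n_samples,
           length(states), dimnames = list(NULL, states)))
  L <- mk(objs); O <- mk(ops); Dm <- mk(vals)
  ev_rows <- list()
  for (t in seq_along(trials)) {
    elems <- replaytdlm:::chain_elements(trials[[t]])
    for (e in seq_len(n_events)) {
      t0 <- sample.int(n_samples - d1 - d2 - 10L, 1L)
      el <- elems[[sample.int(length(elems), 1L)]]
      L[[t]][t0, el$location] <- 1
      O[[t]][t0 + d1, el$op] <- 1
      if (data_kind != "none")
        Dm[[t]][t0 + d1 + d2, el[[data_kind]]] <- 1
      ev_rows[[length(ev_rows) + 1L]] <- data.frame(
        trial = t, sample = t0, location = el$location, op = el$op)
    }
  }
  as_react <- function(mats, states)
    structure(list(mats = mats, states = states, fs = fs),
              class = "reactivation_matrix")
  list(loc = as_react(L, objs), op = as_react(O, ops),
       data = as_react(Dm, vals), events = do.call(rbind, ev_rows))
}

swap_only <- function(trials) {
  Filter(function(tr) tr$n_swaps > 0, trials)
}

test_that("multistep recovers the injected operation-to-data lag on swaps only", {
  g <- fix_graph()
  trials <- swap_only(fix_trials(16L))[1:9]
  for (t in seq_along(trials)) trials[[t]]$trial_id <- t
  cr <- chain_react(trials, 600, d1 = 6L, d2 = 12L, n_events = 12, seed = 21)
  ms <- multistep(cr$loc, cr$op, cr$data, trials, loc_op_lag_ms = 60,
                  op_type = "swap")
  expect_equal(ms$lags_ms[which.max(ms$contrast)], 120, tolerance = 11)
  expect_gt(max(ms$contrast), 0)

  ## same chains but with the INPUT value injected: contrast goes negative
  cri <- chain_react(trials, 600, 6L, 12L, 12, seed = 22, data_kind = "input")
  msi <- multistep(cri$loc, cri$op, cri$data, trials, 60, op_type = "swap")
  expect_lt(msi$contrast[which.max(abs(msi$contrast))], 0)

  ## no data injections: flat contrast
  cr0 <- chain_react(trials, 600, 6L, 12L, 12, seed = 23, data_kind = "none")
  ms0 <- multistep(cr0$loc, cr0$op, cr0$data, trials, 60, op_type = "swap")
  expect_lt(max(abs(ms0$contrast)), max(ms$contrast) / 3)

  ## input/output flip null calibrates the observed peak
  mn <- multistep_null(ms$per_trial, n_shuffles = 300, seed = 1)
  expect_gt(max(ms$contrast), mn$threshold)
})

test_that("multistep equals a brute-force regression oracle on one trial", {
  g <- fix_graph()
  tr <- swap_only(fix_trials(8L))[[1]]
  tr$trial_id <- 1L
  cr <- chain_react(list(tr), 200, 5L, 8L, 6, seed = 30)
  d1 <- 5L; d <- 10L
  ms <- multistep(cr$loc, cr$op, cr$data, list(tr), loc_op_lag_ms = 50,
                  scan_lags_ms = 100, op_type = "swap")
  elems <- Filter(function(e) e$op_type == "swap",
                  replaytdlm:::chain_elements(tr))
  betas_o <- betas_i <- numeric(length(elems))
  for (i in seq_along(elems)) {
    e <- elems[[i]]
    xl <- cr$loc$mats[[1]][, e$location]; xo <- cr$op$mats[[1]][, e$op]
    idx <- (d1 + d + 1L):200
    D <- cbind(xl[idx - d1 - d] * xo[idx - d], xl[idx - d1 - d], xo[idx - d],
               xl[idx - d], 1)
    betas_o[i] <- (solve(t(D) %*% D) %*% t(D) %*%
                     cr$data$mats[[1]][idx, e$output])[1]
    betas_i[i] <- (solve(t(D) %*% D) %*% t(D) %*%
                     cr$data$mats[[1]][idx, e$input])[1]
  }
  expect_equal(ms$contrast, mean(betas_o) - mean(betas_i), tolerance = 1e-10)
})

test_that("replay onset detection finds injected events and prunes overlaps", {
  g <- fix_graph()
  trials <- fix_trials(6L)[1:3]
  for (t in seq_along(trials)) trials[[t]]$trial_id <- t
  cr <- chain_react(trials, 500, d1 = 6L, d2 = 12L, n_events = 5, seed = 31)
  ev <- detect_replay_onsets(cr$loc, cr$op, trials, lag_ms = 60,
                             n_shuffles = 150, seed = 2)
  expect_gt(nrow(ev), 0)
  ## pruning: no two events within 200 ms in a trial
  for (t in unique(ev$trial)) {
    s <- sort(ev$sample[ev$trial == t])
    if (length(s) > 1) expect_true(all(diff(s) >= 20))
  }
  ## recall: injected events recovered within +/- 2 samples
  hits <- 0
  for (i in seq_len(nrow(cr$events))) {
    e <- cr$events[i, ]
    hits <- hits + any(ev$trial == e$trial & abs(ev$sample - e$sample) <= 2)
  }
  expect_gt(hits / nrow(cr$events), 0.5)

  ## no-injection data: far fewer events
  cr0 <- chain_react(trials, 500, 6L, 12L, 0, seed = 32)
  ev0 <- detect_replay_onsets(cr0$loc, cr0$op, trials, 60,
                              n_shuffles = 150, seed = 2)
  expect_lt(nrow(ev0), nrow(ev) / 2 + 1)
})

test_that("event-locked reactivation shows the output bump at its injected lag", {
  g <- fix_graph()
  trials <- swap_only(fix_trials(16L))[1:8]
  for (t in seq_along(trials)) trials[[t]]$trial_id <- t
  cr <- chain_react(trials, 700, d1 = 6L, d2 = 12L, n_events = 10, seed = 33)
  ## lock to the true injected events (ground truth)
  ev <- cr$events
  ev$score <- 1
  elr <- event_locked_reactivation(ev, cr$data, trials,
                                   window_ms = c(-100, 300),
                                   n_shuffles = 200, seed = 3)
  peak_t <- elr$time_ms[which.max(elr$diff)]
  expect_equal(peak_t, 180, tolerance = 21)   # d1 + d2 = 60 + 120 ms
  expect_true(any(elr$mask))

  ## identical input and output series -> difference identically zero
  same <- cr
  for (t in seq_along(trials)) {
    elems <- replaytdlm:::chain_elements(trials[[t]])
    for (e in elems)
      same$data$mats[[t]][, e$input] <- same$data$mats[[t]][, e$output]
  }
  elr0 <- event_locked_reactivation(ev, same$data, trials,
                                    window_ms = c(-100, 300),
                                    n_shuffles = 100, seed = 3)
  expect_equal(max(abs(elr0$diff)), 0, tolerance = 1e-12)
})
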