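## Shared fixtures, built in code. Heavy objects are memoised per test run.

.fix <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fix[[key]])) .fix[[key]] <- force(expr)
  .fix[[key]]
}

## Small world used across unit tests (cheap, deterministic).
fix_graph <- function() memo("graph", generate_task_graph(seed = 3))

fix_trials <- function(n = 12L) memo(paste0("trials", n), {
  sample_trials(fix_graph(), n, seed = 2)
})

## Reduced-scale config for unit tests (NOT the stated-world defaults).
small_cfg <- function(...) {
  sim_config(n_sensors = 40L, n_trials = 10L, n_participants = 1L,
             cv_folds = 4L, train_times_ms = c(150, 250), seed = 7L, ...)
}

## A reactivation_matrix built directly from per-state impulse series.
## spikes: list of data.frames (sample, state, value) per trial.
make_react <- function(states, n_samples, spikes, fs = 100, base = 0.1) {
  mats <- lapply(spikes, function(sp) {
    m <- matrix(base, n_samples, length(states),
                dimnames = list(NULL, states))
    if (!is.null(sp) && nrow(sp))
      for (i in seq_len(nrow(sp)))
        m[sp$sample[i], sp$state[i]] <- m[sp$sample[i], sp$state[i]] + sp$value[i]
    m
  })
  structure(list(mats = mats, states = states, fs = fs),
            class = "reactivation_matrix")
}

## Gaussian-noise reactivation matrices (null inputs for TDLM).
noise_react <- function(states, n_trials, n_samples, seed, fs = 100) {
  set.seed(seed)
  mats <- lapply(seq_len(n_trials), function(t)
    matrix(stats::runif(n_samples * length(states), 0.05, 0.3),
           n_samples, length(states), dimnames = list(NULL, states)))
  structure(list(mats = mats, states = states, fs = fs),
            class = "reactivation_matrix")
}
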