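## Reduced-scale localizers: 40 sensors, shortened schedules, 2 candidate
## training times - enough to exercise every scheme.

mini_functional <- function(cfg, bank, per_obj = 12L, per_face = 6L) {
  sf <- default_localizer_schedule("functional", seed = cfg$seed)
  keep <- unlist(lapply(split(seq_len(nrow(sf)), sf$stim_type == "face"),
                        function(idx) {
    lab <- ifelse(sf$stim_type[idx] == "face", sf$face_id[idx], sf$object[idx])
    unlist(lapply(split(idx, lab), function(i)
      i[seq_len(min(length(i), ifelse(sf$stim_type[i[1]] == "face",
                                      per_face, per_obj)))]))
  }))
  sch <- sf[sort(keep), ]
  sch$trial <- seq_len(nrow(sch))
  simulate_localizer(bank, sch, cfg, "functional_localizer")
}

mini_operation <- function(cfg, bank, g, per_obj = 8L) {
  so <- default_localizer_schedule("operation", g, seed = cfg$seed)
  keep <- unlist(lapply(split(seq_len(nrow(so)), so$object),
                        function(i) i[seq_len(per_obj)]))
  sch <- so[sort(keep), ]
  sch$trial <- seq_len(nrow(sch))
  simulate_localizer(bank, sch, cfg, "operation_localizer")
}

test_that("state decoders separate high-SNR objects and stay at chance at zero SNR", {
  cfg <- small_cfg()
  g <- fix_graph()
  bank_hi <- make_pattern_bank(cfg$n_sensors, 0.1, 3, 1)
  fl <- mini_functional(cfg, bank_hi)
  dec <- train_state_decoders(fl, "objects", cfg)
  expect_gt(max(dec$curve$accuracy), 0.9)
  ## peak inside the stimulus response window
  expect_gte(dec$peak_time_ms, 50)
  expect_lte(dec$peak_time_ms, 500)
  cm <- confusion_at_peak(dec)
  expect_gt(mean(diag(cm)), 0.9)

  bank0 <- make_pattern_bank(cfg$n_sensors, 0.1, 0, 1)
  fl0 <- mini_functional(cfg, bank0)
  dec0 <- train_state_decoders(fl0, "objects", cfg)
  n_pred <- length(dec0$labels) * length(unique(dec0$curve$time_ms))
  se <- sqrt((1 / 12) * (11 / 12) / n_pred)
  expect_lt(abs(mean(dec0$curve$accuracy) - 1 / 12), 4 * se + 0.02)

  decf <- train_state_decoders(fl0, "face_attributes", cfg)
  expect_lt(abs(mean(decf$curve$accuracy) - 0.5), 0.08)
})

test_that("abstract decoders generalize only when operation codes exist", {
  cfg <- small_cfg()
  g <- fix_graph()
  bank <- make_pattern_bank(cfg$n_sensors, 0.1, 1.5, 1,
                            amplitude_by_group = list(objects = 1.5))
  ol <- mini_operation(cfg, bank, g)
  for (dm in c("type", "attribute", "compound")) {
    dec <- train_abstract_decoders(ol, dm, cfg)
    expect_gt(max(dec$curve$accuracy), dec$chance + 0.15)
    ## structural guard: no object overlap between train and test
    meta <- ol$trial_meta
    for (f in dec$folds)
      expect_length(intersect(meta$object[f$train], meta$object[f$test]), 0L)
  }
  expect_equal(train_abstract_decoders(ol, "type", cfg)$chance, 0.5)
  expect_equal(train_abstract_decoders(ol, "attribute", cfg)$chance, 1 / 3)

  ## object patterns only: operation codes absent -> chance generalization
  bank_obj <- make_pattern_bank(cfg$n_sensors, 0.1, 0, 1,
                                amplitude_by_group = list(objects = 1.5))
  ol_obj <- mini_operation(cfg, bank_obj, g)
  dec_obj <- train_abstract_decoders(ol_obj, "compound", cfg)
  expect_lt(mean(dec_obj$curve$accuracy), dec_obj$chance + 0.08)
})

test_that("apply_decoders: bounds, intercept limit, mismatch error, injections visible", {
  cfg <- small_cfg(events_per_trial = 8L)
  g <- fix_graph()
  trials <- sample_trials(g, 4, seed = 2)
  bank <- make_pattern_bank(cfg$n_sensors, 0.1, 1.5, 1)
  rs <- simulate_reasoning(bank, trials, cfg, durations_s = rep(8, 4))
  W <- list(W = bank$patterns[default_locations(), ], b = rep(-1, 12),
            states = default_locations())
  react <- apply_decoders(W, rs$run)
  expect_true(all(vapply(react$mats, function(m) all(m >= 0 & m <= 1), TRUE)))

  ## zero input -> sigmoid(intercept) everywhere
  zero_run <- rs$run
  zero_run$data <- lapply(zero_run$data, function(m) m * 0)
  rz <- apply_decoders(W, zero_run)
  expect_true(all(abs(rz$mats[[1]] - 1 / (1 + exp(1))) < 1e-12))

  ## at injected location events the location's probability is elevated
  lg <- rs$log[rs$log$kind == "location" & rs$log$trial == 1, ]
  m <- react$mats[[1]]
  hits <- vapply(seq_len(nrow(lg)), function(i)
    m[lg$sample[i] + 1L, lg$state[i]], 0)
  expect_gt(mean(hits > stats::median(m[, 1])), 0.8)

  bad <- list(W = W$W[, 1:10], b = W$b, states = W$states)
  expect_error(apply_decoders(bad, rs$run), "sensor count mismatch")
})

test_that("decoding significance masks strong signal and spares null data", {
  set.seed(11)
  nt <- 60; ntime <- 20
  mk <- function(signal) {
    labels <- rep(letters[1:4], length.out = nt)
    preds <- matrix(sample(letters[1:4], nt * ntime, TRUE), nt, ntime)
    if (signal) for (j in 8:12) {
      hit <- stats::runif(nt) < 0.7
      preds[hit, j] <- labels[hit]
    }
    acc <- colMeans(preds == labels)
    list(predictions = preds, labels = labels,
         curve = data.frame(time_ms = seq_len(ntime), accuracy = acc),
         chance = 0.25)
  }
  sig <- decoding_significance(lapply(1:5, function(i) mk(TRUE)),
                               n_shuffles = 200, seed = 1)
  expect_true(all(sig$mask[9:11]))
  nul <- decoding_significance(lapply(1:5, function(i) mk(FALSE)),
                               n_shuffles = 200, seed = 1)
  expect_lt(sum(nul$mask), 3)
  expect_error(decoding_significance(list(mk(TRUE)), n_shuffles = 10), ">= 100")
})

test_that("peak latency order: constructed order vs shuffled null", {
  peaks <- data.frame(location = rep(100, 10), type = rep(130, 10),
                      attribute = rep(160, 10))
  r <- peak_latency_order(peaks, n_shuffles = 300, seed = 2)
  expect_equal(r$proportion, 1)
  expect_gt(r$proportion, r$threshold)
  ## random latencies: ordered fraction ~ 1/6
  set.seed(3)
  rp <- data.frame(location = stats::runif(300), type = stats::runif(300),
                   attribute = stats::runif(300))
  expect_lt(abs(peak_latency_order(rp, n_shuffles = 100)$proportion - 1 / 6),
            0.07)
})
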