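## Abstract-operation decoders with held-out-object cross-validation, plus
## reactivation matrices, confusion, and permutation significance.

abstract_folds <- function(meta, dimension) {
  ops <- operation_table()
  switch(dimension,
    type = lapply(ops$attribute[!duplicated(ops$attribute)], function(a) {
      list(train = which(meta$op_attribute != a),
           test = which(meta$op_attribute == a), held = a)
    }),
    attribute = lapply(c("swap", "branch"), function(ty) {
      list(train = which(meta$op_type == ty),
           test = which(meta$op_type != ty), held = ty)
    }),
    compound = {
      obj_of <- lapply(split(meta$object, meta$op), unique)
      lapply(1:2, function(d) {
        tr_obj <- vapply(obj_of, function(o) sort(o)[d], "")
        te_obj <- vapply(obj_of, function(o) sort(o)[3L - d], "")
        list(train = which(meta$object %in% tr_obj),
             test = which(meta$object %in% te_obj), held = d)
      })
    },
    stop("unknown dimension"))
}

#' Train abstract operation decoders (held-out-object generalization)
#'
#' Decoders can only perform above chance through codes that generalize
#' across objects: Type classifiers (swap vs branch, chance 1/2) are trained
#' on objects of two attributes and tested on the held-out attribute's
#' objects; Attribute classifiers (shape/limb/hat, chance 1/3) train on one
#' type's objects and test on the other's; compound operation classifiers
#' (chance 1/6) train on one object of each operation and test on the other.
#' All train/test partitions are enumerated; no test object ever contributes
#' a training trial.
#'
#' @param op_localizer operation-localizer `sensor_timeseries`
#' @param dimension `"type"`, `"attribute"` or `"compound"`
#' @param cfg a `sim_config`
#' @param times_ms candidate times (ms post-onset); default 0-500 ms grid
#' @param smooth_sd_ms smoothing SD for peak-picking
#' @return object of class `abstract_decoders` with accuracy `curve`,
#'   held-out `predictions`/`labels`, per-fold weight sets, `chance`
#' @export
train_abstract_decoders <- function(op_localizer,
                                    dimension = c("type", "attribute", "compound"),
                                    cfg = sim_config(), times_ms = NULL,
                                    smooth_sd_ms = 20) {
  dimension <- match.arg(dimension)
  meta <- op_localizer$trial_meta
  if (is.null(meta$op)) stop("operation labels missing from localizer")
  if (any(table(meta$op, meta$object) > 0 &
          rowSums(table(meta$op, meta$object) > 0) < 2))
    stop("each operation needs 2 objects")
  folds <- abstract_folds(meta, dimension)
  for (f in folds) stopifnot(length(intersect(meta$object[f$train],
                                              meta$object[f$test])) == 0L)
  label <- switch(dimension, type = meta$op_type,
                  attribute = meta$op_attribute, compound = meta$op)
  classes <- sort(unique(label))
  tidx <- candidate_times(op_localizer, times_ms)
  t_ms <- (tidx - 1L) * 1000 / op_localizer$fs
  nt <- length(tidx)
  acc <- numeric(nt)
  n_pred <- sum(vapply(folds, function(f) length(f$test), 0L))
  preds <- matrix(NA_character_, n_pred, nt)
  truth <- character(n_pred)
  weights <- vector("list", length(folds))

  for (j in seq_len(nt)) {
    X <- slice_time(op_localizer, tidx[j])
    at <- 0L
    for (fi in seq_along(folds)) {
      f <- folds[[fi]]
      mods <- lapply(classes, function(cl)
        fit_lasso(X[f$train, , drop = FALSE], label[f$train] == cl,
                  cfg$lambda))
      scores <- sapply(mods, function(m) lin_score(X[f$test, , drop = FALSE], m))
      if (length(f$test) == 1L) scores <- matrix(scores, nrow = 1L)
      rows <- at + seq_along(f$test)
      preds[rows, j] <- classes[max.col(scores)]
      truth[rows] <- label[f$test]
      at <- at + length(f$test)
      if (j == 1L) weights[[fi]] <-
        list(W = t(vapply(mods, function(m) m$w, numeric(ncol(X)))),
             b = vapply(mods, function(m) m$b, 0),
             states = classes, held = f$held)
    }
    acc[j] <- mean(preds[, j] == truth)
  }
  sm <- smooth_gauss(acc, smooth_sd_ms, 1000 / op_localizer$fs)
  peak <- which.max(sm)
  ## weights for application: refit per fold at the peak time
  Xp <- slice_time(op_localizer, tidx[peak])
  for (fi in seq_along(folds)) {
    f <- folds[[fi]]
    mods <- lapply(classes, function(cl)
      fit_lasso(Xp[f$train, , drop = FALSE], label[f$train] == cl, cfg$lambda))
    weights[[fi]] <- list(
      W = t(vapply(mods, function(m) m$w, numeric(ncol(Xp)))),
      b = vapply(mods, function(m) m$b, 0), states = classes, held = f$held,
      train_objects = unique(meta$object[f$train]))
    rownames(weights[[fi]]$W) <- classes
  }
  structure(list(dimension = dimension, folds = folds, weights = weights,
                 curve = data.frame(time_ms = t_ms, accuracy = acc,
                                    smoothed = sm),
                 predictions = preds, labels = truth,
                 peak_time_ms = t_ms[peak], chance = 1 / length(classes),
                 fs = op_localizer$fs),
            class = "abstract_decoders")
}

#' Averaged application weights of abstract decoders
#'
#' Mean of the per-fold (held-out-object) weight sets; weights for any state
#' therefore never come from a single object's trials.
#' @param ad an `abstract_decoders`
#' @export
abstract_weights <- function(ad) {
  W <- Reduce(`+`, lapply(ad$weights, `[[`, "W")) / length(ad$weights)
  b <- Reduce(`+`, lapply(ad$weights, `[[`, "b")) / length(ad$weights)
  list(W = W, b = b, states = ad$weights[[1L]]$states)
}

#' Apply abstract decoders with trial-wise held-out-object weights
#'
#' Operation reactivations must not be driven by decoding of the on-path
#' object itself: for every state whose on-path location(s) appear in a
#' fold's training objects, that fold is avoided for the trial (falling back
#' to the across-fold average when no clean fold exists, e.g. when both of an
#' operation's objects lie on the path).
#'
#' @param ad an `abstract_decoders`
#' @param run a `sensor_timeseries`
#' @param trials list of `trial_spec` aligned with the run
#' @return `reactivation_matrix`
#' @export
apply_decoders_heldout <- function(ad, run, trials) {
  classes <- ad$weights[[1L]]$states
  label_col <- switch(ad$dimension, compound = "op", type = "op_type",
                      attribute = "attribute")
  avg <- abstract_weights(ad)
  n_states <- length(classes)
  mats <- vector("list", length(trials))
  for (t in seq_along(trials)) {
    steps <- trials[[t]]$trace$steps
    W <- avg$W; b <- avg$b
    for (ci in seq_len(n_states)) {
      locs <- steps$location[steps[[label_col]] == classes[ci]]
      if (!length(locs)) next
      ok <- which(vapply(ad$weights, function(w)
        !any(locs %in% w$train_objects), TRUE))
      if (length(ok)) {
        W[ci, ] <- ad$weights[[ok[1L]]]$W[ci, ]
        b[ci] <- ad$weights[[ok[1L]]]$b[ci]
      }
    }
    one <- apply_decoders(list(W = W, b = b, states = classes),
                          structure(list(data = run$data[t], fs = run$fs),
                                    class = "sensor_timeseries"))
    mats[[t]] <- one$mats[[1L]]
  }
  structure(list(mats = mats, states = classes, fs = run$fs),
            class = "reactivation_matrix")
}

#' Apply decoder weights to a run, yielding reactivation probabilities
#'
#' Per sample and state, the sigmoid of the linear score. States are
#' independent binomial outputs; rows need not sum to 1.
#'
#' @param weights a `state_decoders`, `abstract_decoders` fold entry, or any
#'   list with `W` (states x sensors), `b`, `states`
#' @param run a `sensor_timeseries`
#' @return `reactivation_matrix`: list `mats` of samples x states matrices
#'   (one per trial), `states`, `fs`
#' @export
apply_decoders <- function(weights, run) {
  if (inherits(weights, "state_decoders"))
    weights <- list(W = weights$W, b = weights$b, states = weights$states)
  if (inherits(weights, "abstract_decoders")) weights <- abstract_weights(weights)
  n_sens <- dim3(run)[2L]
  if (ncol(weights$W) != n_sens)
    stop("sensor count mismatch: weights ", ncol(weights$W), ", run ", n_sens)
  mats <- lapply(seq_len(dim3(run)[1L]), function(t) {
    X <- if (is.array(run$data)) t(run$data[t, , ]) else t(run$data[[t]])
    p <- sigmoid(sweep(X %*% t(weights$W), 2L, weights$b, `+`))
    colnames(p) <- weights$states
    p
  })
  structure(list(mats = mats, states = weights$states, fs = run$fs),
            class = "reactivation_matrix")
}

#' Combine reactivation matrices state-wise
#' @param ... `reactivation_matrix` objects over the same samples
#' @export
bind_reactivations <- function(...) {
  rs <- list(...)
  structure(list(
    mats = lapply(seq_along(rs[[1L]]$mats), function(t)
      do.call(cbind, lapply(rs, function(r) r$mats[[t]]))),
    states = unlist(lapply(rs, `[[`, "states")), fs = rs[[1L]]$fs),
    class = "reactivation_matrix")
}

#' Group-level cluster permutation test for decoding accuracy curves
#'
#' Builds a label-shuffle null per participant from stored held-out
#' predictions, averages shuffled accuracy curves across participants, scores
#' contiguous above-chance clusters by mass, and thresholds observed clusters
#' at the 97.5th percentile of the max-cluster-mass null.
#'
#' @param decoders list of per-participant decoder objects (each with
#'   `predictions`, `labels`, `curve`, `chance`)
#' @param n_shuffles number of label shuffles (>= 100)
#' @param seed integer seed
#' @return list: `mask` (logical per time), `threshold`, observed group curve
#' @export
decoding_significance <- function(decoders, n_shuffles = 1000L, seed = 1L) {
  if (n_shuffles < 100L) stop("n_shuffles must be >= 100")
  chance <- decoders[[1L]]$chance
  obs <- rowMeans(sapply(decoders, function(d) d$curve$accuracy))
  set.seed(derive_seed(seed, "decoding_significance"))
  nt <- length(obs)
  null_max <- numeric(n_shuffles)
  for (s in seq_len(n_shuffles)) {
    gm <- rowMeans(sapply(decoders, function(d) {
      lab <- sample(d$labels)
      colMeans(d$predictions == lab)
    }))
    null_max[s] <- max_cluster_mass(gm - chance)
  }
  thr <- stats::quantile(null_max, 0.975, names = FALSE)
  mask <- cluster_mask(obs - chance, thr)
  list(mask = mask, threshold = thr, group_curve = obs, chance = chance)
}

## mass of the largest contiguous positive run
max_cluster_mass <- function(x) {
  pos <- x > 0
  if (!any(pos)) return(0)
  r <- rle(pos)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  max(vapply(which(r$values), function(i) sum(x[starts[i]:ends[i]]), 0))
}

cluster_mask <- function(x, thr) {
  pos <- x > 0
  mask <- logical(length(x))
  if (!any(pos)) return(mask)
  r <- rle(pos)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (i in which(r$values))
    if (sum(x[starts[i]:ends[i]]) > thr) mask[starts[i]:ends[i]] <- TRUE
  mask
}

#' Object confusion matrix at the peak decoding time
#'
#' @param dec a `state_decoders` for objects
#' @return matrix confusion[true, predicted], rows normalized
#' @export
confusion_at_peak <- function(dec) {
  if (all(is.na(dec$curve$smoothed))) stop("peak undefined (flat curve)")
  j <- which.max(dec$curve$smoothed)
  classes <- sort(unique(dec$labels))
  cm <- table(factor(dec$labels, classes), factor(dec$predictions[, j], classes))
  cm <- unclass(cm) / pmax(rowSums(cm), 1L)
  cm
}

#' Proportion of participants whose peak latencies follow location < type <
#' attribute, against a within-participant shuffle null
#'
#' @param peaks data.frame with per-participant columns `location`, `type`,
#'   `attribute` (peak latencies in ms)
#' @param n_shuffles shuffles of the latency labels within participant
#' @param seed integer seed
#' @return list: observed `proportion`, null `threshold` (97.5th pct)
#' @export
peak_latency_order <- function(peaks, n_shuffles = 1000L, seed = 1L) {
  ordered <- function(m) mean(m[, "location"] < m[, "type"] &
                                m[, "type"] < m[, "attribute"])
  m <- as.matrix(peaks[, c("location", "type", "attribute")])
  obs <- ordered(m)
  set.seed(derive_seed(seed, "latency_order"))
  null <- vapply(seq_len(n_shuffles), function(s) {
    shuf <- t(apply(m, 1L, sample))
    colnames(shuf) <- colnames(m)
    ordered(shuf)
  }, 0)
  list(proportion = obs,
       threshold = stats::quantile(null, 0.975, names = FALSE))
}
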