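## State and abstract-operation decoding with L1-penalized logistic
## regression, cross-validated accuracy curves, and permutation significance.

fit_lasso <- function(X, y, lambda) {
  ## glmnet warns on very small classes; harmless at reduced test scale.
  ## If the penalty zeroes every weight (possible at very low SNR) the
  ## decoder would emit a constant series, so relax lambda until at least
  ## one weight survives.
  repeat {
    fit <- suppressWarnings(
      glmnet::glmnet(X, factor(y), family = "binomial", alpha = 1,
                     lambda = lambda, standardize = TRUE))
    co <- as.numeric(stats::coef(fit))
    if (any(co[-1L] != 0) || lambda < 1e-5) break
    lambda <- lambda / 10
  }
  list(b = co[1L], w = co[-1L])
}

lin_score <- function(X, mod) drop(X %*% mod$w) + mod$b

sigmoid <- function(x) 1 / (1 + exp(-x))

## Gaussian smoothing of a curve sampled every `dt_ms`; sd in ms.
smooth_gauss <- function(x, sd_ms, dt_ms) {
  if (sd_ms <= 0) return(x)
  half <- max(1L, ceiling(3 * sd_ms / dt_ms))
  k <- stats::dnorm(seq(-half, half) * dt_ms, sd = sd_ms)
  k <- k / sum(k)
  n <- length(x)
  xp <- c(rep(x[1L], half), x, rep(x[n], half))
  as.numeric(stats::filter(xp, k, sides = 2))[(half + 1L):(half + n)]
}

stratified_folds <- function(labels, k, seed) {
  set.seed(seed)
  fold <- integer(length(labels))
  for (lv in unique(labels)) {
    idx <- which(labels == lv)
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  fold
}

candidate_times <- function(run, times_ms, max_ms = 500) {
  n_samples <- dim3(run)[3L]
  t_ms <- (seq_len(n_samples) - 1L) * 1000 / run$fs
  if (is.null(times_ms)) which(t_ms >= 0 & t_ms <= max_ms)
  else pmin(n_samples, ms_to_samples(times_ms, run$fs) + 1L)
}

dim3 <- function(run) {
  if (is.array(run$data)) dim(run$data) else
    c(length(run$data), nrow(run$data[[1L]]), ncol(run$data[[1L]]))
}

slice_time <- function(run, tidx) {
  if (is.array(run$data)) run$data[, , tidx] else
    t(vapply(run$data, function(m) m[, tidx], numeric(dim3(run)[2L])))
}

#' Train one-vs-rest state decoders on a localizer
#'
#' For objects, a binomial lasso classifier per object (all other objects as
#' negatives), cross-validated over stratified folds at each candidate time
#' point; the multiclass prediction is the argmax over per-state scores
#' (chance 1/12). For face attributes, pairwise binary classifiers per
#' attribute (chance 1/2). Application weights are refit on all trials at the
#' peak of the (Gaussian-smoothed) accuracy curve.
#'
#' @param localizer a `sensor_timeseries` from [simulate_localizer()]
#' @param states `"objects"` or `"face_attributes"`
#' @param cfg a `sim_config` (uses `lambda`, `cv_folds`, `seed`)
#' @param times_ms candidate training times (ms post-onset); default all
#'   samples in 0-500 ms
#' @param smooth_sd_ms SD of the Gaussian used to smooth the accuracy curve
#'   before peak-picking
#' @return object of class `state_decoders`: weights `W` (states x sensors),
#'   intercepts `b`, accuracy `curve`, held-out `predictions`, `labels`,
#'   `peak_time_ms`, `chance`
#' @export
train_state_decoders <- function(localizer, states = c("objects", "face_attributes"),
                                 cfg = sim_config(), times_ms = NULL,
                                 smooth_sd_ms = 20) {
  states <- match.arg(states)
  meta <- localizer$trial_meta
  tidx <- candidate_times(localizer, times_ms)
  t_ms <- (tidx - 1L) * 1000 / localizer$fs
  if (states == "objects") {
    keep <- which(meta$stim_type == "object")
    labels <- meta$object[keep]
    classes <- default_locations()
    chance <- 1 / length(classes)
  } else {
    keep <- which(meta$stim_type == "face")
    if (length(keep) == 0L) stop("no face trials in localizer")
    fmat <- do.call(rbind, strsplit(meta$face_id[keep], ".", fixed = TRUE))
    colnames(fmat) <- names(face_attributes())
    chance <- 1 / 2
  }
  if (length(keep) < 2L) stop("need at least 2 trials per state")
  folds <- stratified_folds(if (states == "objects") labels else fmat[, 1L],
                            cfg$cv_folds, derive_seed(cfg$seed, "cv_folds"))
  nt <- length(tidx)
  acc <- numeric(nt)
  preds <- matrix(NA_character_, length(keep), nt)

  for (j in seq_len(nt)) {
    X <- slice_time(localizer, tidx[j])[keep, , drop = FALSE]
    for (f in seq_len(max(folds))) {
      tr <- folds != f; te <- folds == f
      if (states == "objects") {
        scores <- sapply(classes, function(cl)
          lin_score(X[te, , drop = FALSE],
                    fit_lasso(X[tr, , drop = FALSE], labels[tr] == cl,
                              cfg$lambda)))
        preds[te, j] <- classes[max.col(scores)]
      } else {
        pv <- matrix(NA_character_, sum(te), 3L,
                     dimnames = list(NULL, colnames(fmat)))
        for (a in colnames(fmat)) {
          v1 <- face_attributes()[[a]][1L]
          mod <- fit_lasso(X[tr, , drop = FALSE], fmat[tr, a] == v1,
                           cfg$lambda)
          pv[, a] <- ifelse(lin_score(X[te, , drop = FALSE], mod) > 0,
                            v1, face_attributes()[[a]][2L])
        }
        preds[te, j] <- apply(pv, 1L, paste, collapse = ".")
      }
    }
    acc[j] <- if (states == "objects") mean(preds[, j] == labels) else
      mean(do.call(rbind, strsplit(preds[, j], ".", fixed = TRUE)) == fmat)
  }
  sm <- smooth_gauss(acc, smooth_sd_ms, 1000 / localizer$fs)
  peak <- which.max(sm)
  ## refit on all trials at the peak for application weights
  Xp <- slice_time(localizer, tidx[peak])[keep, , drop = FALSE]
  if (states == "objects") {
    W <- t(sapply(classes, function(cl) {
      m <- fit_lasso(Xp, labels == cl, cfg$lambda); c(m$b, m$w)
    }))
  } else {
    rows <- list()
    for (a in colnames(fmat)) {
      vals <- face_attributes()[[a]]
      m <- fit_lasso(Xp, fmat[, a] == vals[1L], cfg$lambda)
      rows[[vals[1L]]] <- c(m$b, m$w)
      rows[[vals[2L]]] <- c(-m$b, -m$w)
    }
    W <- do.call(rbind, rows)
  }
  structure(list(W = W[, -1L, drop = FALSE], b = W[, 1L],
                 states = rownames(W), scheme = "cross_validated",
                 curve = data.frame(time_ms = t_ms, accuracy = acc,
                                    smoothed = sm),
                 predictions = preds,
                 labels = if (states == "objects") labels else
                   apply(fmat, 1L, paste, collapse = "."),
                 peak_time_ms = t_ms[peak], chance = chance,
                 fs = localizer$fs),
            class = "state_decoders")
}
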