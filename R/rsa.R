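## Time-resolved GLM representational similarity analysis.

gauss_smooth_rows <- function(M, sd_ms, fs) {
  ## M: sensors x samples; smooth along time (edge-replicated convolution)
  if (sd_ms <= 0) return(M)
  dt_ms <- 1000 / fs
  half <- max(1L, ceiling(3 * sd_ms / dt_ms))
  k <- stats::dnorm(seq(-half, half) * dt_ms, sd = sd_ms)
  k <- k / sum(k)
  X <- t(M)
  n <- nrow(X)
  Xp <- rbind(X[rep(1L, half), , drop = FALSE], X,
              X[rep(n, half), , drop = FALSE])
  sm <- stats::filter(Xp, k, sides = 2)
  t(unclass(sm)[(half + 1L):(half + n), , drop = FALSE])
}

## Extract an aligned epoch (sensors x n samples) from one trial.
epoch_of <- function(m, n, align) {
  Tn <- ncol(m)
  if (n > Tn) stop("epoch longer than trial")
  if (align == "onset") m[, seq_len(n), drop = FALSE]
  else m[, (Tn - n + 1L):Tn, drop = FALSE]
}

#' Time series of trial-by-trial empirical similarity matrices
#'
#' At each time point of an aligned epoch, the Pearson correlation over
#' sensors between every pair of trials' (temporally smoothed) sensor
#' vectors.
#'
#' @param run a `sensor_timeseries` (array or per-trial list data)
#' @param epoch_s epoch length in seconds
#' @param align `"onset"` (reasoning start) or `"offset"` (reasoning end)
#' @param smoothing_ms Gaussian smoothing SD applied along time
#' @return array trials x trials x time, with attribute `time_ms`
#' @export
empirical_similarity <- function(run, epoch_s = 1, align = c("onset", "offset"),
                                 smoothing_ms = 50) {
  align <- match.arg(align)
  n <- ms_to_samples(epoch_s * 1000, run$fs)
  nt <- dim3(run)[1L]
  ep <- lapply(seq_len(nt), function(t) {
    m <- if (is.array(run$data)) run$data[t, , ] else run$data[[t]]
    gauss_smooth_rows(epoch_of(m, n, align), smoothing_ms, run$fs)
  })
  out <- array(NA_real_, c(nt, nt, n))
  for (j in seq_len(n)) {
    X <- t(vapply(ep, function(m) m[, j], numeric(nrow(ep[[1L]]))))
    if (any(apply(X, 1L, stats::sd) == 0))
      stop("zero-variance sensor vector (degenerate trial) at sample ", j)
    out[, , j] <- stats::cor(t(X))
  }
  attr(out, "time_ms") <- (seq_len(n) - 1L) * 1000 / run$fs
  attr(out, "align") <- align
  out
}

ut <- function(M) M[upper.tri(M)]

#' Time-resolved RSA GLM
#'
#' Per time point, OLS of the vectorized (upper triangle, diagonal excluded)
#' empirical similarity on the vectorized model similarity matrices plus a
#' bias term.
#'
#' @param empirical trials x trials x time array from [empirical_similarity()]
#' @param model named list of `similarity_matrix` regressors
#' @param cond_limit abort above this design condition number
#' @return `rsa_timecourse`: data.frame of betas (time x regressors, plus
#'   `bias`), with the design stored as an attribute
#' @export
rsa_glm <- function(empirical, model, cond_limit = 1e8) {
  D <- cbind(bias = 1, vapply(model, ut, numeric(sum(upper.tri(empirical[, , 1L])))))
  colnames(D) <- c("bias", names(model))
  cn <- kappa(D, exact = TRUE)
  if (cn > cond_limit)
    stop("model regressors nearly collinear (condition number ", round(cn), ")")
  q <- qr(D)
  if (q$rank < ncol(D)) stop("collinear model set")
  nt <- dim(empirical)[3L]
  Y <- vapply(seq_len(nt), function(j) ut(empirical[, , j]),
              numeric(nrow(D)))
  B <- qr.coef(q, Y)                       # regressors x time
  tc <- as.data.frame(t(B))
  tc$time_ms <- attr(empirical, "time_ms") %||% (seq_len(nt) - 1L)
  structure(tc, class = c("rsa_timecourse", "data.frame"),
            condition_number = cn)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Group-level cluster permutation test for RSA betas
#'
#' Shuffles the trial correspondence of the neural data (joint row/column
#' permutation of each participant's empirical similarity array), recomputes
#' betas, and thresholds observed clusters of positive group-mean betas by
#' mass at the given percentile of the max-cluster-mass null.
#'
#' @param empiricals list of per-participant empirical similarity arrays
#' @param models list of per-participant model lists (or one shared list)
#' @param regressor name of the regressor under test
#' @param n_shuffles number of shuffles (>= 100)
#' @param prob percentile of the null (0.975 for epoch analyses, 0.95 for
#'   event-locked analyses)
#' @param seed integer seed
#' @return list: `mask`, `threshold`, `group_betas`, `time_ms`
#' @export
rsa_significance <- function(empiricals, models, regressor,
                             n_shuffles = 1000L, prob = 0.975, seed = 1L) {
  if (n_shuffles < 100L) stop("n_shuffles must be >= 100")
  shared <- !is.null(names(models)) || is.matrix(models[[1L]])
  model_of <- function(i) if (shared) models else models[[i]]
  np <- length(empiricals)
  obs <- NULL
  qrs <- vector("list", np)
  for (i in seq_len(np)) {
    tc <- rsa_glm(empiricals[[i]], model_of(i))
    obs <- if (is.null(obs)) tc[[regressor]] else obs + tc[[regressor]]
    D <- cbind(1, vapply(model_of(i), ut,
                         numeric(sum(upper.tri(empiricals[[i]][, , 1L])))))
    colnames(D) <- c("bias", names(model_of(i)))
    qrs[[i]] <- qr(D)
  }
  obs <- obs / np
  k <- match(regressor, c("bias", names(model_of(1L))))
  set.seed(derive_seed(seed, "rsa_significance"))
  nt <- dim(empiricals[[1L]])[3L]
  null_max <- vapply(seq_len(n_shuffles), function(s) {
    gm <- numeric(nt)
    for (i in seq_len(np)) {
      p <- sample.int(dim(empiricals[[i]])[1L])
      Y <- vapply(seq_len(nt), function(j) ut(empiricals[[i]][p, p, j]),
                  numeric(length(qrs[[i]]$qr[, 1L])))
      gm <- gm + qr.coef(qrs[[i]], Y)[k, ]
    }
    max_cluster_mass(gm / np)
  }, 0)
  thr <- stats::quantile(null_max, prob, names = FALSE)
  list(mask = cluster_mask(obs, thr), threshold = thr, group_betas = obs,
       time_ms = attr(empiricals[[1L]], "time_ms") %||% seq_len(nt))
}

#' Replay-aligned RSA with matched control events
#'
#' Neural activity is smoothed, epoched around each trial's replay events and
#' averaged within trial; the RSA GLM then runs per peri-event time point.
#' Control analyses repeat the procedure on randomly sampled time points
#' (matched in count per trial), `n_control_repeats` times, and average the
#' resulting beta time courses.
#'
#' @param events data.frame from [detect_replay_onsets()]
#' @param run the reasoning `sensor_timeseries`
#' @param model named list of similarity matrices over all trials
#' @param window_ms peri-event window
#' @param smoothing_ms smoothing SD
#' @param n_control_repeats control resamples
#' @param seed integer seed
#' @return list: `observed` (`rsa_timecourse`), `control`, `trials_used`,
#'   `time_ms`
#' @export
replay_aligned_rsa <- function(events, run, model, window_ms = c(-100, 500),
                               smoothing_ms = 50, n_control_repeats = 5L,
                               seed = 1L) {
  fs <- run$fs
  w <- ms_to_samples(window_ms, fs)
  rel <- w[1L]:w[2L]
  nt <- dim3(run)[1L]
  smoothed <- lapply(seq_len(nt), function(t) {
    m <- if (is.array(run$data)) run$data[t, , ] else run$data[[t]]
    gauss_smooth_rows(m, smoothing_ms, fs)
  })
  epoch_mean <- function(t, samples) {
    m <- smoothed[[t]]
    ok <- samples[samples + w[1L] >= 1L & samples + w[2L] <= ncol(m)]
    if (!length(ok)) return(NULL)
    Reduce(`+`, lapply(ok, function(s0) m[, s0 + rel, drop = FALSE])) / length(ok)
  }
  obs_ep <- lapply(seq_len(nt), function(t)
    epoch_mean(t, events$sample[events$trial == t]))
  used <- which(!vapply(obs_ep, is.null, TRUE))
  if (length(used) < 3L) stop("too few trials with usable replay events")
  sub_model <- lapply(model, function(M) M[used, used])
  arr_of <- function(eps) {
    a <- array(NA_real_, c(length(used), nrow(eps[[used[1L]]]), length(rel)))
    for (i in seq_along(used)) a[i, , ] <- eps[[used[i]]]
    structure(a, dim = dim(a))
  }
  sim_of <- function(eps) {
    a <- arr_of(eps)
    out <- array(NA_real_, c(length(used), length(used), length(rel)))
    for (j in seq_len(length(rel))) out[, , j] <- stats::cor(t(a[, , j]))
    attr(out, "time_ms") <- rel * 1000 / fs
    out
  }
  observed <- rsa_glm(sim_of(obs_ep), sub_model)
  set.seed(derive_seed(seed, "replay_aligned_controls"))
  ctrl_sum <- NULL
  for (r in seq_len(n_control_repeats)) {
    ctrl_ep <- lapply(seq_len(nt), function(t) {
      n_ev <- sum(events$trial == t)
      if (n_ev == 0L) return(NULL)
      Tn <- ncol(smoothed[[t]])
      lo <- 1L - w[1L]; hi <- Tn - w[2L]
      if (hi < lo) return(NULL)
      epoch_mean(t, sample(lo:hi, n_ev, replace = TRUE))
    })
    for (t in setdiff(seq_len(nt), used)) ctrl_ep[t] <- list(NULL)
    tc <- rsa_glm(sim_of(ctrl_ep), sub_model)
    ctrl_sum <- if (is.null(ctrl_sum)) tc else {
      num <- vapply(tc, is.numeric, TRUE)
      ctrl_sum[num] <- ctrl_sum[num] + tc[num]
      ctrl_sum
    }
  }
  num <- vapply(ctrl_sum, is.numeric, TRUE)
  ctrl_sum[num] <- ctrl_sum[num] / n_control_repeats
  ctrl_sum$time_ms <- observed$time_ms
  list(observed = observed, control = ctrl_sum, trials_used = used,
       time_ms = rel * 1000 / fs)
}
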