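## Temporally delayed linear modeling (TDLM): first-stage lagged transition
## estimation, second-stage regression on theoretical transition structures,
## and state-relabeling permutation nulls.

#' Trial filter based on reactivation frequency
#'
#' A trial is dropped when any correct-path location is almost never
#' reactivated (argmax across object states) during the reasoning period -
#' the trial-wise transition matrices would then hinge on a state that the
#' decoders essentially never see.
#'
#' @param react a `reactivation_matrix` restricted to (or containing) the 12
#'   object states
#' @param trial a `trial_spec`
#' @param bounds reactivation-frequency band; a trial is dropped below the
#'   lower bound
#' @return list: `keep` (logical), `freqs` (named per path location)
#' @export
entropy_filter <- function(react, trial, bounds = c(0.025, 0.05)) {
  objs <- intersect(react$states, default_locations())
  m <- react$mats[[trial$trial_id]][, objs, drop = FALSE]
  am <- objs[max.col(m)]
  freqs <- vapply(unique(trial$trace$path), function(l) mean(am == l), 0)
  list(keep = all(freqs >= bounds[1L]), freqs = freqs)
}

#' First-stage TDLM: empirical lagged transition matrices
#'
#' For every lag up to `max_lag_ms`, each state's reactivation series at
#' `t + lag` is regressed (with intercept) on all states' series at `t`,
#' giving a lag-resolved states x states coefficient matrix per trial.
#'
#' With `method = "ols"` (the definition of the method) the lag-d matrix is
#' the multivariate regression coefficient matrix; with `method =
#' "covariance"` it is the centered lagged cross-covariance, which carries an
#' exact time-reversal antisymmetry (reversing time transposes every lag's
#' matrix, hence exactly exchanges forward and backward second-stage betas -
#' under OLS the exchange holds only up to finite-sample error).
#'
#' Binary dimensions decoded with a single classifier yield exactly
#' complementary probability series (p and 1-p), which are collinear with the
#' intercept; `on_deficiency = "ridge"` resolves such designs with a tiny
#' ridge penalty instead of raising.
#'
#' @param react a `reactivation_matrix`
#' @param max_lag_ms lag ceiling in ms (default 200)
#' @param method `"ols"` (default) or `"covariance"`
#' @param on_deficiency `"error"` (default) or `"ridge"`
#' @return `empirical_transitions`: per-trial array lags x states x states
#' @export
first_stage <- function(react, max_lag_ms = 200, method = c("ols", "covariance"),
                        on_deficiency = c("error", "ridge")) {
  method <- match.arg(method)
  on_deficiency <- match.arg(on_deficiency)
  lags <- seq_len(ms_to_samples(max_lag_ms, react$fs))
  S <- length(react$states)
  tensors <- lapply(react$mats, function(X) {
    Tn <- nrow(X)
    if (Tn <= max(lags) + S + 1L)
      stop("trial too short for requested lags")
    emp <- array(NA_real_, c(length(lags), S, S))
    for (d in lags) {
      if (method == "ols") {
        D <- cbind(1, X[1:(Tn - d), , drop = FALSE])
        co <- qr.coef(qr(D), X[(d + 1L):Tn, , drop = FALSE])
        if (anyNA(co)) {
          if (on_deficiency == "error")
            stop("rank-deficient design (constant reactivation series)")
          A <- crossprod(D) + 1e-6 * diag(ncol(D))
          co <- solve(A, crossprod(D, X[(d + 1L):Tn, , drop = FALSE]))
        }
        emp[d, , ] <- co[-1L, , drop = FALSE]
      } else {
        X0 <- scale(X[1:(Tn - d), , drop = FALSE], scale = FALSE)
        Xd <- scale(X[(d + 1L):Tn, , drop = FALSE], scale = FALSE)
        emp[d, , ] <- crossprod(X0, Xd) / (Tn - d - 1L)
      }
    }
    emp
  })
  structure(list(tensors = tensors, states = react$states,
                 lags_ms = lags * 1000 / react$fs, fs = react$fs),
            class = "empirical_transitions")
}

## Vectorized empirical matrices: S^2 x n_lags per trial (column-major vec).
vec_tensors <- function(emp) {
  lapply(emp$tensors, function(a)
    vapply(seq_len(dim(a)[1L]), function(d) as.vector(a[d, , ]),
           numeric(dim(a)[2L]^2)))
}

## Second-stage design for one trial's theoretical matrices (named list).
stage2_design <- function(theor, S) {
  cols <- list()
  for (nm in names(theor)) {
    cols[[paste0(nm, "_fwd")]] <- as.vector(theor[[nm]])
    cols[[paste0(nm, "_bwd")]] <- as.vector(t(theor[[nm]]))
  }
  cols[["self"]] <- as.vector(diag(S))
  cols[["const"]] <- rep(1, S * S)
  D <- do.call(cbind, cols)
  q <- qr(D)
  if (q$rank < ncol(D))
    stop("collinear theoretical regressor set (is a matrix symmetric?)")
  q
}

## Per-trial second-stage betas for all lags at once: regressors x lags.
stage2_betas <- function(qrD, Y) qr.coef(qrD, Y)

#' Second-stage TDLM: sequenceness curves
#'
#' Per lag and trial, the vectorized empirical transition matrix is regressed
#' on each theoretical matrix (forward), its transpose (backward), the
#' identity (self-transitions) and a constant. Betas are averaged across
#' trials; a neighboring-lag-averaged variant is included.
#'
#' @param emp `empirical_transitions` from [first_stage()]
#' @param theoretical either a named list of theoretical matrices (shared by
#'   all trials) or a list of such named lists, one per trial
#' @return `sequenceness_curve`: `lags_ms`, `forward`/`backward` (lags x
#'   regressors), smoothed variants, and per-trial beta arrays
#' @export
second_stage <- function(emp, theoretical) {
  n_trials <- length(emp$tensors)
  per_trial <- !is.null(names(theoretical[[1L]])) &&
    is.list(theoretical[[1L]]) && !is.matrix(theoretical[[1L]])
  theor_of <- function(t) if (per_trial) theoretical[[t]] else theoretical
  if (per_trial && length(theoretical) != n_trials)
    stop("per-trial theoretical list must match trial count")
  S <- length(emp$states)
  Y <- vec_tensors(emp)
  K <- length(theor_of(1L))
  rnames <- names(theor_of(1L))
  nl <- length(emp$lags_ms)
  fwd <- array(0, c(n_trials, nl, K)); bwd <- fwd
  for (t in seq_len(n_trials)) {
    B <- stage2_betas(stage2_design(theor_of(t), S), Y[[t]])
    for (k in seq_len(K)) {
      fwd[t, , k] <- B[2L * k - 1L, ]
      bwd[t, , k] <- B[2L * k, ]
    }
  }
  mk <- function(a) {
    m <- apply(a, c(2L, 3L), mean)
    dimnames(m) <- list(NULL, rnames)
    m
  }
  structure(list(lags_ms = emp$lags_ms,
                 forward = mk(fwd), backward = mk(bwd),
                 forward_avg = lag_average(mk(fwd)),
                 backward_avg = lag_average(mk(bwd)),
                 per_trial_forward = fwd, per_trial_backward = bwd,
                 regressors = rnames),
            class = "sequenceness_curve")
}

## mean of each neighboring lag pair (power-pooling variant)
lag_average <- function(m) {
  n <- nrow(m)
  out <- m
  for (i in seq_len(n))
    out[i, ] <- colMeans(m[max(1L, i - 1L):min(n, i + 1L), , drop = FALSE])
  out
}

#' State-relabeling permutation null for sequenceness
#'
#' Each shuffle draws one random permutation of state identities (identity
#' excluded) and applies it coherently to every trial's theoretical
#' matrices before recomputing second-stage betas; shuffled betas are
#' averaged across trials. The corrected threshold is the maximum over lags
#' of the per-lag 95th percentile of the shuffle means.
#'
#' For theoretical matrices over a single domain (e.g. 12 objects) the
#' permutation acts on all states. For bipartite matrices (locations linking
#' to operation features) pass `blocks` so each domain's identities are
#' permuted among themselves: the relabeled indicator then stays inside the
#' location-to-feature block and the null is not inflated by unrelated
#' (e.g. object-to-object) empirical structure.
#'
#' @param emp `empirical_transitions`
#' @param theoretical as in [second_stage()]
#' @param n_shuffles number of shuffles
#' @param seed integer seed
#' @param perms optional list of permutations (for sharing across
#'   participants at group level)
#' @param blocks optional list of disjoint state-index vectors to permute
#'   within (default: one block of all states)
#' @return `null_distribution`: arrays `forward`/`backward` of shape
#'   n_shuffles x lags x regressors, plus the permutations used
#' @export
permutation_null <- function(emp, theoretical, n_shuffles = 1000L, seed = 1L,
                             perms = NULL, blocks = NULL) {
  S <- length(emp$states)
  if (is.null(perms)) perms <- draw_state_permutations(S, n_shuffles, seed, blocks)
  n_trials <- length(emp$tensors)
  per_trial <- !is.null(names(theoretical[[1L]])) &&
    is.list(theoretical[[1L]]) && !is.matrix(theoretical[[1L]])
  theor_of <- function(t) if (per_trial) theoretical[[t]] else theoretical
  Y <- vec_tensors(emp)
  K <- length(theor_of(1L))
  nl <- length(emp$lags_ms)
  fwd <- array(0, c(length(perms), nl, K)); bwd <- fwd
  for (s in seq_along(perms)) {
    p <- perms[[s]]
    tf <- array(0, c(nl, K)); tb <- tf
    for (t in seq_len(n_trials)) {
      th <- lapply(theor_of(t), function(M) M[p, p])
      B <- stage2_betas(stage2_design(th, S), Y[[t]])
      for (k in seq_len(K)) {
        tf[, k] <- tf[, k] + B[2L * k - 1L, ]
        tb[, k] <- tb[, k] + B[2L * k, ]
      }
    }
    fwd[s, , ] <- tf / n_trials
    bwd[s, , ] <- tb / n_trials
  }
  structure(list(forward = fwd, backward = bwd, perms = perms,
                 lags_ms = emp$lags_ms, regressors = names(theor_of(1L))),
            class = "null_distribution")
}

#' Draw non-identity state permutations
#' @param S number of states
#' @param n number of permutations
#' @param seed integer seed
#' @param blocks optional list of disjoint index vectors permuted within
#' @export
draw_state_permutations <- function(S, n, seed, blocks = NULL) {
  if (is.null(blocks)) blocks <- list(seq_len(S))
  n_distinct <- prod(vapply(blocks, function(b) factorial(length(b)), 0)) - 1
  if (n_distinct < 1) stop("no non-identity permutation exists")
  if (n_distinct < n && S <= 8 && length(blocks) == 1L) {
    ## small state spaces: exhaustive minus identity, recycled if needed
    all_p <- all_permutations(S)
    all_p <- all_p[!vapply(all_p, function(p) all(p == seq_len(S)), TRUE)]
    return(all_p[((seq_len(n) - 1L) %% length(all_p)) + 1L])
  }
  set.seed(derive_seed(seed, "state_perms"))
  out <- vector("list", n)
  i <- 1L
  while (i <= n) {
    p <- seq_len(S)
    for (b in blocks) p[b] <- b[sample.int(length(b))]
    if (all(p == seq_len(S)) && n_distinct > n) next
    out[[i]] <- p
    i <- i + 1L
  }
  out
}

all_permutations <- function(S) {
  if (S == 1L) return(list(1L))
  sub <- all_permutations(S - 1L)
  out <- list()
  for (p in sub) for (pos in seq_len(S)) {
    out[[length(out) + 1L]] <- append(p, S, after = pos - 1L)
  }
  out
}

#' Multiple-comparison-corrected threshold from a null distribution
#'
#' The maximum null beta across lags is taken within each shuffle and the
#' threshold is the `prob` percentile of that max distribution - the
#' max-statistic correction that controls the family-wise rate over the
#' tested lags (taking instead the maximum over lags of per-lag percentiles
#' under-corrects badly when lag curves are weakly correlated; the
#' calibration tests check the <= 5% family-wise rate directly).
#'
#' @param null a `null_distribution`
#' @param regressor regressor name or index
#' @param direction `"forward"` or `"backward"`
#' @param prob percentile (default 0.95)
#' @param averaged use neighboring-lag-averaged null curves
#' @export
null_threshold <- function(null, regressor = 1L, direction = "forward",
                           prob = 0.95, averaged = FALSE) {
  if (is.character(regressor)) regressor <- match(regressor, null$regressors)
  a <- null[[direction]][, , regressor, drop = FALSE]
  m <- matrix(a, dim(a)[1L], dim(a)[2L])
  if (averaged) m <- t(apply(m, 1L, function(r)
    lag_average(matrix(r, ncol = 1L))[, 1L]))
  stats::quantile(apply(m, 1L, max), probs = prob, names = FALSE)
}

#' Average sequenceness curves and nulls across participants
#'
#' Null distributions must have been computed with shared permutations.
#' @param curves list of `sequenceness_curve`
#' @param nulls list of `null_distribution`
#' @return list with group `curve` (forward/backward matrices) and group
#'   `null` (a `null_distribution`)
#' @export
group_sequenceness <- function(curves, nulls = NULL) {
  avg <- function(field, lst) Reduce(`+`, lapply(lst, `[[`, field)) / length(lst)
  curve <- list(lags_ms = curves[[1L]]$lags_ms,
                forward = avg("forward", curves),
                backward = avg("backward", curves),
                regressors = curves[[1L]]$regressors)
  curve$forward_avg <- lag_average(curve$forward)
  curve$backward_avg <- lag_average(curve$backward)
  out <- list(curve = curve)
  if (!is.null(nulls)) {
    out$null <- structure(list(forward = avg("forward", nulls),
                               backward = avg("backward", nulls),
                               lags_ms = nulls[[1L]]$lags_ms,
                               regressors = nulls[[1L]]$regressors),
                          class = "null_distribution")
  }
  out
}

#' Z-score a sequenceness value against its null
#' @param value observed beta(s)
#' @param null_values vector of null betas at the same lag(s)
#' @export
zscore_vs_null <- function(value, null_values) {
  (value - mean(null_values)) / stats::sd(null_values)
}
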