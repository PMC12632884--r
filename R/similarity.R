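## Path-derived model matrices: trial-by-trial similarity regressors and
## trial-wise theoretical transition matrices.

#' Trial-by-trial path similarity matrix
#'
#' Position-dependent ("program") or position-independent ("object") overlap
#' of correct-path locations between trials, the on-screen start location
#' always excluded. `shallow` counts overlap of the first off-screen location
#' only, `deep` of all later locations; `face_path` is the position-dependent
#' overlap of the face states traversed; `length_diff` the absolute path
#' length difference.
#'
#' Variable-length paths are aligned by comparing first with first, last with
#' last, and middle elements pairwise in order, ignoring the unmatched middle
#' slot (`alignment = "flex"`, default). With `alignment = "strict"` elements
#' are compared position by position up to the shorter length.
#'
#' @param trials list of `trial_spec` sharing one graph
#' @param mode one of `"program"`, `"object"`, `"shallow"`, `"deep"`,
#'   `"face_path"`, `"length_diff"`
#' @param alignment `"flex"` or `"strict"`
#' @return symmetric numeric matrix with class `similarity_matrix`
#' @export
path_similarity <- function(trials, mode = c("program", "object", "shallow",
                                             "deep", "face_path", "length_diff"),
                            alignment = c("flex", "strict")) {
  mode <- match.arg(mode)
  alignment <- match.arg(alignment)
  if (length(trials) == 0L) stop("empty trial list")
  n <- length(trials)
  seqs <- lapply(trials, function(tr) {
    switch(mode,
      program = , object = , shallow = , deep = tr$trace$path[-1L],
      face_path = tr$trace$faces_after,
      length_diff = tr$length)
  })
  S <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in i:n) {
    a <- seqs[[i]]; b <- seqs[[j]]
    v <- switch(mode,
      program   = aligned_matches(a, b, alignment),
      face_path = aligned_matches(a, b, alignment),
      object    = multiset_overlap(a, b),
      shallow   = as.numeric(a[1L] == b[1L]),
      deep      = aligned_matches(a[-1L], b[-1L], alignment),
      length_diff = abs(a - b))
    S[i, j] <- S[j, i] <- v
  }
  structure(S, mode = mode, class = c("similarity_matrix", "matrix", "array"))
}

## first<->first, last<->last, middles pairwise in order
aligned_matches <- function(a, b, alignment = "flex") {
  la <- length(a); lb <- length(b)
  if (la == 0L || lb == 0L) return(0)
  if (alignment == "strict" || la == lb) {
    m <- min(la, lb)
    return(sum(a[seq_len(m)] == b[seq_len(m)]))
  }
  if (min(la, lb) == 1L) return(as.numeric(a[la] == b[lb]))
  m <- as.numeric(a[1L] == b[1L]) + as.numeric(a[la] == b[lb])
  ma <- a[-c(1L, la)]; mb <- b[-c(1L, lb)]
  k <- min(length(ma), length(mb))
  if (k > 0L) m <- m + sum(ma[seq_len(k)] == mb[seq_len(k)])
  m
}

multiset_overlap <- function(a, b) {
  ta <- table(a); tb <- table(b)
  common <- intersect(names(ta), names(tb))
  sum(pmin(ta[common], tb[common]))
}

#' Trial-wise correct and incorrect transition matrices
#'
#' The correct matrix marks each consecutive pair of the trial's correct
#' path (END excluded); the incorrect matrix marks every other
#' location-to-location edge of the graph. The two are disjoint by
#' construction.
#'
#' @param graph a `task_graph`
#' @param trial a `trial_spec`
#' @return list with binary matrices `correct` and `incorrect`
#' @export
transition_matrices <- function(graph, trial) {
  A <- graph_edges(graph)
  C <- A * 0L
  path <- trial$trace$path
  if (length(path) > 1L)
    for (k in seq_len(length(path) - 1L)) C[path[k], path[k + 1L]] <- 1L
  list(correct = C, incorrect = A - C)
}

#' Shallow/deep split of the correct-path transition matrix
#'
#' The shallow matrix holds the first link (start to its association), the
#' deep matrix all later links.
#' @inheritParams transition_matrices
#' @return list with binary matrices `shallow` and `deep`
#' @export
path_link_matrices <- function(graph, trial) {
  A <- graph_edges(graph) * 0L
  Sh <- A; Dp <- A
  path <- trial$trace$path
  if (length(path) > 1L) Sh[path[1L], path[2L]] <- 1L
  if (length(path) > 2L)
    for (k in 2:(length(path) - 1L)) Dp[path[k], path[k + 1L]] <- 1L
  list(shallow = Sh, deep = Dp)
}

#' Behavioral summary of a simulated (or observed) session
#'
#' Interaction effects with program content (branch/swap counts) are computed
#' within trials of identical program length and then averaged across lengths,
#' so they are not confounded by length itself.
#'
#' @param trials list of `trial_spec`
#' @param responses data.frame with one row per probe: `trial_id`, `q_type`,
#'   `modality`, `depth_of_probe`, `attribute_distance`, `correct` (logical),
#'   `thinking_time_s`
#' @return list of summary tables (see Details)
#' @details Components: `by_question` (accuracy by question type x modality),
#'   `by_length` (accuracy and thinking time by program length),
#'   `branch_effect_path_object` and `swap_effect_face` (within-length OLS
#'   slopes averaged across lengths), `branch_effect_thinking_time`,
#'   `depth_effect` (PATH-object accept accuracy shallow vs deep), and
#'   `attr_distance_effect` (END-face accuracy by attribute distance).
#' @export
behavioral_summary <- function(trials, responses) {
  tt <- trial_table(trials)
  d <- merge(responses, tt[, c("trial_id", "length", "n_branches", "n_swaps")],
             by = "trial_id")
  lengths <- sort(unique(tt$length))
  for (L in lengths)
    if (!any(d$length == L)) stop("no responses for program length ", L)

  acc <- function(x) mean(x$correct)
  by_question <- stats::aggregate(correct ~ q_type + modality, d, mean)

  by_length <- merge(
    stats::aggregate(correct ~ length, d, mean),
    stats::aggregate(thinking_time_s ~ trial_id + length,
                     d, mean)[, c("length", "thinking_time_s")] |>
      (\(x) stats::aggregate(thinking_time_s ~ length, x, mean))(),
    by = "length")

  within_length_slope <- function(sub, xvar, yvar) {
    slopes <- vapply(lengths, function(L) {
      s <- sub[sub$length == L, ]
      if (nrow(s) < 2L || stats::var(s[[xvar]]) == 0) return(NA_real_)
      unname(stats::coef(stats::lm(s[[yvar]] ~ s[[xvar]]))[2L])
    }, numeric(1))
    mean(slopes, na.rm = TRUE)
  }

  po <- d[d$q_type == "PATH" & d$modality == "object", ]
  fa <- d[d$modality == "face", ]
  per_trial <- stats::aggregate(thinking_time_s ~ trial_id + length + n_branches,
                                d, mean)

  depth <- d[d$q_type == "PATH" & d$modality == "object" & d$is_match, ]
  depth_effect <- if (nrow(depth) > 0L)
    stats::aggregate(correct ~ depth_of_probe, depth, mean) else NULL

  ef <- d[d$q_type == "END" & d$modality == "face", ]
  attr_distance_effect <- if (nrow(ef) > 0L)
    stats::aggregate(correct ~ attribute_distance, ef, mean) else NULL

  list(by_question = by_question,
       by_length = by_length,
       branch_effect_path_object = within_length_slope(po, "n_branches", "correct"),
       swap_effect_face = within_length_slope(fa, "n_swaps", "correct"),
       branch_effect_thinking_time =
         within_length_slope(per_trial, "n_branches", "thinking_time_s"),
       depth_effect = depth_effect,
       attr_distance_effect = attr_distance_effect)
}
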