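## Trial sampling and probe generation for the reasoning task.

#' Sample reasoning-task trials
#'
#' Draws `(start location, start face)` pairs whose correct path length lies
#' in the graph's `length_set` (by default with replacement, forbidding an
#' immediate repeat of the same pair, emulating a session of ~90 trials over
#' ~42 unique paths). Each trial carries its execution trace and two probe
#' questions.
#'
#' @param graph a `task_graph`
#' @param n_trials number of trials
#' @param seed integer seed
#' @param replace sample pairs with replacement (default TRUE)
#' @return list of `trial_spec` objects
#' @export
sample_trials <- function(graph, n_trials, seed, replace = TRUE) {
  stopifnot(inherits(graph, "task_graph"), n_trials >= 1L)
  adm <- graph$admissible[graph$admissible$length %in% graph$length_set, ]
  if (nrow(adm) < 2L) stop("fewer than 2 admissible (start, face) pairs")
  if (!replace && nrow(adm) < n_trials)
    stop("only ", nrow(adm), " admissible pairs for ", n_trials,
         " trials without replacement")
  set.seed(derive_seed(seed, "sample_trials"))
  if (replace) {
    idx <- integer(n_trials)
    idx[1L] <- sample.int(nrow(adm), 1L)
    for (t in seq_len(n_trials)[-1L]) {
      repeat {
        k <- sample.int(nrow(adm), 1L)
        if (k != idx[t - 1L]) break
      }
      idx[t] <- k
    }
  } else {
    idx <- sample.int(nrow(adm), n_trials)
  }
  faces <- all_faces()
  face_by_id <- stats::setNames(faces, vapply(faces, face_id, ""))
  lapply(seq_len(n_trials), function(t) {
    start <- adm$start[idx[t]]
    face <- face_by_id[[adm$face[idx[t]]]]
    trace <- execute_program(graph, start, face)
    tr <- structure(list(
      trial_id = t, start_location = start, start_face = face,
      trace = trace, length = trace$length,
      n_branches = sum(trace$steps$op_type == "branch"),
      n_swaps = sum(trace$steps$op_type == "swap"),
      thinking_time_s = NA_real_), class = "trial_spec")
    tr$probes <- generate_probes(tr, derive_seed(seed, paste0("probes", t)))
    tr
  })
}

#' Generate the two probe questions of a trial
#'
#' One END and one PATH question in randomized order, sharing a randomly
#' chosen modality (object or face); the probe stimulus matches the correct
#' path with probability 0.5. PATH probes are tagged with the depth of the
#' probed path element (shallow = first location after the start, deep =
#' later); face probes are tagged with the attribute (Hamming) distance of
#' the probe face from the correct face.
#'
#' @param trial a `trial_spec`
#' @param seed integer seed
#' @return list of two `probe_question` lists
#' @export
generate_probes <- function(trial, seed) {
  stopifnot(inherits(trial, "trial_spec"))
  set.seed(seed)
  modality <- sample(c("object", "face"), 1L)
  path <- trial$trace$path
  faces_after <- trial$trace$faces_after
  L <- trial$length

  make_probe <- function(q_type) {
    is_match <- stats::runif(1L) < 0.5
    if (q_type == "END") {
      depth <- "end"
      correct_obj <- path[L]
      correct_face <- faces_after[L]
    } else {
      ## element encountered before the final step, start (on screen) excluded
      elig <- if (L > 2L) 2:(L - 1L) else 2L
      pos <- if (length(elig) == 1L) elig else sample(elig, 1L)
      depth <- if (pos == 2L) "shallow" else "deep"
      correct_obj <- path[pos]
      correct_face <- faces_after[pos - 1L] # face on arrival at position pos
    }
    if (modality == "object") {
      stim <- if (is_match) correct_obj else
        sample(setdiff(default_locations(), correct_obj), 1L)
      dist <- NA_integer_
    } else {
      cf <- face_from_id(correct_face)
      if (is_match) {
        stim <- correct_face
        dist <- 0L
      } else {
        dist <- sample(1:3, 1L)
        flip <- sample(names(face_attributes()), dist)
        f <- cf
        for (a in flip) f <- flip_attribute(f, a)
        stim <- face_id(f)
      }
    }
    list(q_type = q_type, modality = modality, probe_stimulus = stim,
         is_match = is_match,
         correct_response = if (is_match) "accept" else "reject",
         depth_of_probe = depth, attribute_distance = dist)
  }

  probes <- lapply(c("END", "PATH"), make_probe)
  probes[sample(2L)]
}

face_from_id <- function(id) {
  v <- strsplit(id, ".", fixed = TRUE)[[1L]]
  face_state(v[1L], v[2L], v[3L])
}

#' Trial table as a data.frame
#'
#' One row per trial with path, counts and probe fields; convenient for CSV
#' export and behavioral joins.
#' @param trials list of `trial_spec`
#' @export
trial_table <- function(trials) {
  do.call(rbind, lapply(trials, function(tr) {
    data.frame(trial_id = tr$trial_id, start_location = tr$start_location,
               start_face = face_id(tr$start_face), length = tr$length,
               n_branches = tr$n_branches, n_swaps = tr$n_swaps,
               path = paste(tr$trace$path, collapse = ";"),
               thinking_time_s = tr$thinking_time_s,
               stringsAsFactors = FALSE)
  }))
}
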