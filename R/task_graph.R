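## Task graph generation and deterministic program execution.

END_TOKEN <- "END"

#' Generate a valid task graph
#'
#' Builds a directed graph of `n_locations` program locations plus one END
#' token. Each of the six operations is assigned to exactly two locations;
#' swap locations have one successor, branch locations have two successors
#' keyed by the values of the operation's attribute (distinct, at most one of
#' which is END). Generation is seeded rejection sampling over a random
#' location ordering: successors always point "down" the ordering (or to END),
#' which guarantees termination; candidate graphs are accepted only if
#' exhaustive execution of all (start, face) pairs terminates within
#' `max_depth` steps and traces of every length in `length_set` exist.
#'
#' @param seed integer seed; the same seed reproduces the same graph
#' @param n_locations number of program locations (default 12)
#' @param length_set admissible correct-path lengths for sampled trials
#' @param max_depth maximum number of operations any execution may take
#' @param max_attempts bound on rejection-sampling attempts
#' @return an object of class `task_graph`
#' @export
generate_task_graph <- function(seed, n_locations = 12L, length_set = c(3L, 4L),
                                max_depth = 8L, max_attempts = 2000L) {
  stopifnot(n_locations %% 2L == 0L, n_locations >= 4L)
  ops <- operation_table()
  if (n_locations != 2L * nrow(ops))
    stop("n_locations must equal twice the number of operations (12)")
  locs <- default_locations()[seq_len(n_locations)]

  set.seed(seed)
  for (attempt in seq_len(max_attempts)) {
    g <- try(build_candidate_graph(locs, ops, max_depth), silent = TRUE)
    if (inherits(g, "try-error")) next
    chk <- check_graph(g, length_set, max_depth)
    if (isTRUE(chk$ok)) {
      g$length_set <- as.integer(length_set)
      g$seed <- as.integer(seed)
      g$admissible <- chk$admissible
      return(g)
    }
  }
  stop("no valid task graph found within ", max_attempts,
       " attempts; parameters are over-constrained")
}

## One candidate: random rank order; successors must have higher rank or END.
build_candidate_graph <- function(locs, ops, max_depth) {
  n <- length(locs)
  order_locs <- sample(locs)                      # rank 1 .. n
  rank <- stats::setNames(seq_len(n), order_locs)

  ## branch locations need two distinct successors, at most one END:
  ## the last rank only has END available, so branches sit at ranks <= n - 1
  branch_ranks <- sample(seq_len(n - 1L), nrow(ops))
  is_branch_rank <- seq_len(n) %in% branch_ranks

  op_assign <- character(n)
  names(op_assign) <- order_locs
  op_assign[is_branch_rank]  <- sample(rep(ops$op[ops$op_type == "branch"], 2L))
  op_assign[!is_branch_rank] <- sample(rep(ops$op[ops$op_type == "swap"], 2L))

  succ_swap <- list()
  succ_branch <- list()
  for (r in seq_len(n)) {
    loc <- order_locs[r]
    cands <- c(order_locs[rank > r], END_TOKEN)
    op <- op_assign[[loc]]
    attr <- ops$attribute[ops$op == op]
    if (startsWith(op, "swap")) {
      succ_swap[[loc]] <- sample(cands, 1L)
    } else {
      if (length(cands) < 2L) stop("no room for branch successors")
      targets <- sample(cands, 2L)
      vals <- face_attributes()[[attr]]
      succ_branch[[loc]] <- stats::setNames(targets, vals)
    }
  }
  structure(list(locations = locs, end_token = END_TOKEN,
                 op_of = op_assign[locs], succ_swap = succ_swap,
                 succ_branch = succ_branch, max_depth = as.integer(max_depth)),
            class = "task_graph")
}

## Exhaustive execution over all (start, face) pairs; returns admissible table.
check_graph <- function(graph, length_set, max_depth) {
  faces <- all_faces()
  rows <- list()
  for (s in graph$locations) for (f in faces) {
    tr <- try(execute_program(graph, s, f), silent = TRUE)
    if (inherits(tr, "try-error")) return(list(ok = FALSE))
    rows[[length(rows) + 1L]] <- data.frame(
      start = s, face = face_id(f), length = tr$length,
      stringsAsFactors = FALSE)
  }
  adm <- do.call(rbind, rows)
  ok <- all(length_set %in% adm$length)
  list(ok = ok, admissible = adm)
}

#' Execute a program deterministically
#'
#' Starting at `start` with face `face`, repeatedly applies the operation of
#' the current location: a swap flips the operation's attribute and moves to
#' the single successor; a branch leaves the face unchanged and moves to the
#' successor keyed by the current value of the operation's attribute.
#'
#' @param graph a `task_graph`
#' @param start a location of `graph`
#' @param face a `face_state`
#' @return an `execution_trace`: list with `steps` (data.frame), `length`,
#'   `path` (locations visited, in order), and the final face
#' @export
execute_program <- function(graph, start, face) {
  stopifnot(inherits(graph, "task_graph"), start %in% graph$locations)
  ops <- operation_table()
  loc <- start
  steps <- list()
  for (k in seq_len(graph$max_depth + 1L)) {
    if (k > graph$max_depth)
      stop("execution exceeded max_depth = ", graph$max_depth,
           " without reaching END (invalid graph)")
    op <- graph$op_of[[loc]]
    i <- match(op, ops$op)
    attr <- ops$attribute[i]
    face_before <- face
    if (ops$op_type[i] == "swap") {
      face <- flip_attribute(face, attr)
      nxt <- graph$succ_swap[[loc]]
    } else {
      nxt <- graph$succ_branch[[loc]][[face[[attr]]]]
    }
    steps[[k]] <- data.frame(
      location = loc, op = op, op_type = ops$op_type[i], attribute = attr,
      face_before = face_id(face_before), face_after = face_id(face),
      nxt = nxt, stringsAsFactors = FALSE)
    if (nxt == graph$end_token) break
    loc <- nxt
  }
  steps <- do.call(rbind, steps)
  structure(list(steps = steps, length = nrow(steps), path = steps$location,
                 faces_after = steps$face_after, final_face = face),
            class = "execution_trace")
}

#' All location-to-location edges of a graph
#'
#' @param graph a `task_graph`
#' @return binary adjacency matrix over locations (END edges excluded)
#' @export
graph_edges <- function(graph) {
  n <- length(graph$locations)
  A <- matrix(0L, n, n, dimnames = list(graph$locations, graph$locations))
  for (loc in graph$locations) {
    tg <- if (startsWith(graph$op_of[[loc]], "swap")) graph$succ_swap[[loc]]
          else unname(graph$succ_branch[[loc]])
    for (t in tg) if (t != graph$end_token) A[loc, t] <- 1L
  }
  A
}

#' @export
print.task_graph <- function(x, ...) {
  cat("task_graph:", length(x$locations), "locations + END, seed", x$seed, "\n")
  cat("  operations:", paste(unique(x$op_of), collapse = ", "), "\n")
  invisible(x)
}
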