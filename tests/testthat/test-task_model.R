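test_that("graph generation is deterministic and satisfies the combinatorics", {
  g1 <- generate_task_graph(seed = 0)
  g2 <- generate_task_graph(seed = 0)
  expect_identical(g1[c("op_of", "succ_swap", "succ_branch")],
                   g2[c("op_of", "succ_swap", "succ_branch")])

  for (seed in c(0, 3, 11)) {
    g <- generate_task_graph(seed = seed)
    expect_length(g$locations, 12L)
    expect_identical(g$end_token, "END")
    ops <- operation_table()
    counts <- table(g$op_of)
    expect_setequal(names(counts), ops$op)
    expect_true(all(counts == 2L))
    is_swap <- startsWith(unname(g$op_of), "swap")
    expect_identical(sum(is_swap), 6L)
    ## swap out-degree 1, branch out-degree 2 (distinct, at most one END)
    for (loc in g$locations) {
      if (startsWith(g$op_of[[loc]], "swap")) {
        expect_length(g$succ_swap[[loc]], 1L)
      } else {
        tg <- g$succ_branch[[loc]]
        expect_length(tg, 2L)
        expect_false(anyDuplicated(tg) > 0)
        expect_lte(sum(tg == "END"), 1L)
      }
    }
  }
})

test_that("all 96 (start, face) executions terminate and respect face algebra", {
  g <- fix_graph()
  faces <- all_faces()
  expect_length(faces, 8L)
  n_pairs <- 0L
  for (s in g$locations) for (f in faces) {
    tr <- execute_program(g, s, f)
    n_pairs <- n_pairs + 1L
    expect_lte(tr$length, g$max_depth)
    expect_identical(tr$steps$nxt[tr$length], "END")
    for (k in seq_len(tr$length)) {
      fb <- replaytdlm:::face_from_id(tr$steps$face_before[k])
      fa <- replaytdlm:::face_from_id(tr$steps$face_after[k])
      if (tr$steps$op_type[k] == "swap") {
        expect_identical(face_distance(fb, fa), 1L)
        expect_false(fb[[tr$steps$attribute[k]]] == fa[[tr$steps$attribute[k]]])
      } else {
        expect_identical(face_distance(fb, fa), 0L)
      }
    }
  }
  expect_identical(n_pairs, 96L)
  ## double swap restores the attribute
  f <- face_state("round", "hands", "crown")
  expect_identical(flip_attribute(flip_attribute(f, "hat"), "hat"), f)
})

test_that("trial sampling respects the length set, seeds, and repetition rule", {
  g <- fix_graph()
  tr <- sample_trials(g, 90, seed = 1)
  expect_length(tr, 90L)
  expect_true(all(vapply(tr, `[[`, 0L, "length") %in% c(3L, 4L)))
  tr2 <- sample_trials(g, 90, seed = 1)
  expect_identical(trial_table(tr), trial_table(tr2))
  ## no immediate (start, face) repeats
  key <- vapply(tr, function(t) paste(t$start_location, face_id(t$start_face)), "")
  expect_false(any(key[-1] == key[-length(key)]))
  ## both lengths occur over a large sample
  big <- sample_trials(g, 600, seed = 4)
  expect_setequal(unique(vapply(big, `[[`, 0L, "length")), c(3L, 4L))
})

test_that("probes: structure, match rate, and attribute distances", {
  g <- fix_graph()
  trials <- sample_trials(g, 300, seed = 5)
  match_flags <- logical(0)
  for (tr in trials) {
    p <- tr$probes
    expect_setequal(vapply(p, `[[`, "", "q_type"), c("END", "PATH"))
    expect_identical(p[[1]]$modality, p[[2]]$modality)
    for (q in p) {
      expect_identical(q$correct_response,
                       if (q$is_match) "accept" else "reject")
      match_flags <- c(match_flags, q$is_match)
      if (q$modality == "face") {
        if (q$is_match) expect_identical(q$attribute_distance, 0L)
        else expect_true(q$attribute_distance %in% 1:3)
        if (q$q_type == "END") {
          d <- face_distance(replaytdlm:::face_from_id(q$probe_stimulus),
                             tr$trace$final_face)
          expect_identical(d, as.integer(q$attribute_distance))
        }
      }
      if (q$q_type == "PATH")
        expect_true(q$depth_of_probe %in% c("shallow", "deep"))
    }
  }
  expect_lt(abs(mean(match_flags) - 0.5), 0.05)
})

test_that("path similarity matches the worked example and its orderings", {
  ## position-dependent vs position-independent overlap on reversed paths
  a <- c("Anchor", "Elephant", "Broccoli")
  b <- c("Broccoli", "Elephant", "Anchor")
  expect_equal(replaytdlm:::aligned_matches(a, b), 1)
  expect_equal(replaytdlm:::multiset_overlap(a, b), 3)

  trials <- fix_trials(15L)
  S_prog <- path_similarity(trials, "program")
  S_obj <- path_similarity(trials, "object")
  S_sh <- path_similarity(trials, "shallow")
  S_dp <- path_similarity(trials, "deep")
  expect_true(isSymmetric(unclass(S_prog)))
  expect_true(all(S_prog <= S_obj + 1e-12))
  ## self-similarity counts the whole non-start path
  for (i in seq_along(trials))
    expect_equal(S_prog[i, i], trials[[i]]$length - 1)
  ## shallow + deep decompose program similarity under flex alignment
  expect_equal(S_sh + S_dp, unclass(S_prog), ignore_attr = TRUE)
  expect_error(path_similarity(list(), "program"), "empty")
})

test_that("transition matrices are disjoint and exhaust graph edges", {
  g <- fix_graph()
  trials <- fix_trials(15L)
  A <- graph_edges(g)
  for (tr in trials) {
    tm <- transition_matrices(g, tr)
    expect_identical(sum(tm$correct), tr$length - 1L)
    expect_true(all(tm$correct * tm$incorrect == 0))
    expect_identical(sum(tm$correct) + sum(tm$incorrect), sum(A))
    lm_ <- path_link_matrices(g, tr)
    expect_identical(lm_$shallow + lm_$deep, tm$correct)
  }
})

test_that("behavioral summary: perfect, chance, and length-sensitive agents", {
  g <- fix_graph()
  trials <- sample_trials(g, 400, seed = 6)
  cfg0 <- sim_config(behavior = list(base_error = 0, error_per_length = 0,
                                     error_per_op = 0, tt_base = 8,
                                     tt_per_length = 1.5, tt_per_branch = 1,
                                     tt_sd = 2, tt_bounds = c(5, 20)))
  resp0 <- simulate_behavior(trials, cfg0, seed = 1)
  s0 <- behavioral_summary(trials, resp0)
  expect_true(all(s0$by_question$correct == 1))

  cfgc <- sim_config(behavior = list(base_error = 0.5, error_per_length = 0,
                                     error_per_op = 0, tt_base = 8,
                                     tt_per_length = 1.5, tt_per_branch = 1,
                                     tt_sd = 2, tt_bounds = c(5, 20)))
  respc <- simulate_behavior(trials, cfgc, seed = 1)
  sc <- behavioral_summary(trials, respc)
  expect_true(all(abs(sc$by_question$correct - 0.5) < 0.08))

  ## default agent: accuracy decreases and thinking time increases with length
  resp <- simulate_behavior(trials, sim_config(), seed = 2)
  s <- behavioral_summary(trials, resp)
  bl <- s$by_length[order(s$by_length$length), ]
  expect_true(all(diff(bl$correct) < 0))
  expect_true(all(diff(bl$thinking_time_s) > 0))
})
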