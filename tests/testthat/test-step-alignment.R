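test_that("step_matrix holds per-step Tanimoto coefficients", {
  m <- list(c("f:C-O", "c:H-O"), c("i:C-C"), c("f:C-N"))
  e <- make_entry("E", m)
  M <- step_matrix(e, e)
  expect_identical(dim(M), c(3L, 3L))
  expect_identical(diag(M), rep(1, 3))
  # disjoint steps give an all-zero matrix
  e2 <- make_entry("F", list(c("f:O-P"), c("d:H-S")))
  expect_true(all(step_matrix(e, e2) == 0))
  # 2x1 case computed by hand: each one-change step vs the two-change union
  m1 <- make_entry("G", list(c("f:C-O"), c("c:H-O")))
  m2 <- make_entry("H", list(c("f:C-O", "c:H-O")))
  expect_equal(step_matrix(m1, m2), matrix(c(0.5, 0.5), ncol = 1L))
  expect_error(step_matrix(list(), m), "empty mechanism")
  # empty steps score 0 and are flagged
  w <- make_entry("W", list(c("f:C-O"), character()))
  expect_message(Mw <- step_matrix(w, w), "no bond changes")
  expect_identical(Mw[2L, ], c(0, 0))
})

test_that("global_align solves hand-checked matrices", {
  a1 <- global_align(matrix(1))
  expect_identical(a1$score, 1)
  expect_identical(a1$matched, matrix(c(1L, 1L), ncol = 2L,
                                      dimnames = list(NULL, c("i", "j"))))
  a2 <- global_align(diag(2))
  expect_identical(a2$score, 2)
  expect_identical(unname(a2$matched), matrix(c(1L, 2L, 1L, 2L), ncol = 2L))
  a3 <- global_align(matrix(c(0.5, 0.3, 0.2, 0.9), 2))
  expect_equal(a3$score, 1.4)
  expect_identical(unname(a3$matched), matrix(c(1L, 2L, 1L, 2L), ncol = 2L))
  # zero-valued matches are dropped from the path
  a4 <- global_align(matrix(0, 2, 2))
  expect_identical(a4$score, 0)
  expect_identical(nrow(a4$matched), 0L)
})

test_that("global_align matches the brute-force oracle and stays monotone", {
  set.seed(31)
  for (k in 1:150) {
    n1 <- sample(5, 1L)
    n2 <- sample(5, 1L)
    M <- matrix(round(runif(n1 * n2), 3), n1, n2)
    aln <- global_align(M)
    expect_equal(aln$score, brute_force_best_matching(M), tolerance = 1e-9)
    if (nrow(aln$matched) > 1L) {
      expect_true(all(diff(aln$matched[, 1L]) > 0))
      expect_true(all(diff(aln$matched[, 2L]) > 0))
    }
    # the matched path accounts for the whole score
    path_sum <- sum(M[aln$matched])
    expect_equal(path_sum, aln$score, tolerance = 1e-9)
  }
})

test_that("mechanistic Tanimoto and its size bound follow the formulas", {
  expect_identical(mechanistic_tanimoto(4, 4, 4), 1)
  expect_identical(mechanistic_tanimoto(0, 3, 7), 0)
  expect_equal(mechanistic_tanimoto(1.4, 2, 2), 1.4 / 2.6)
  expect_error(mechanistic_tanimoto(3.5, 3, 9), "outside")

  expect_equal(max_possible_mechanistic(3, 9), 1 / 3)
  expect_identical(max_possible_mechanistic(5, 5), 1)
  expect_equal(max_possible_mechanistic(1, 3), 1 / 3)
  # monotone increasing in S at fixed sizes
  s_grid <- seq(0, 3, by = 0.5)
  vals <- vapply(s_grid, mechanistic_tanimoto, 0, n1 = 3, n2 = 8)
  expect_true(all(diff(vals) > 0))
})

test_that("rotations enumerate cyclic shifts that compose modulo n", {
  e <- make_entry("R", list(c("f:C-O"), c("c:H-O"), c("i:C-C")))
  rots <- rotations(e)
  expect_length(rots, 3L)
  expect_identical(rots[["0"]], e$mechanism)
  expect_identical(unclass(rots[["1"]][[1L]]$changes), "c:H-O")
  expect_identical(unclass(rots[["2"]][[1L]]$changes), "i:C-C")
  # single-step mechanism rotates to itself only
  expect_length(rotations(make_entry("S", list("f:C-O"))), 1L)
  # composing offsets 1 then 2 returns the original order (mod 3)
  r1 <- mechsim:::.rotate_mechanism(e$mechanism, 1L)
  r12 <- mechsim:::.rotate_mechanism(r1, 2L)
  expect_identical(lapply(r12, `[[`, "changes"),
                   lapply(e$mechanism, `[[`, "changes"))
})

test_that("find_identical_steps detects forward and reversed identity", {
  e <- make_entry("E", list(c("f:C-O"), c("c:H-O"), c("i:C-C")))
  self <- find_identical_steps(e, e)
  fwd <- self[self$direction == "forward", ]
  expect_identical(fwd$i, fwd$j)
  expect_identical(nrow(fwd), 3L)
  # full reversal: anti-diagonal hits in the reversed direction
  r <- reverse_entry(e)
  rev_hits <- find_identical_steps(e, r)
  rev_hits <- rev_hits[rev_hits$direction == "reversed", ]
  expect_identical(rev_hits$j, 4L - rev_hits$i)
  expect_identical(nrow(rev_hits), 3L)
  # disjoint chemistry: nothing
  f <- make_entry("F", list(c("f:O-P"), c("d:H-S")))
  expect_identical(nrow(find_identical_steps(e, f)), 0L)
})

test_that("local_align finds the best block under the mismatch offset", {
  expect_identical(local_align(matrix(0, 3, 3))$score, 0)
  M <- matrix(0, 3, 3)
  M[2, 2] <- 1
  a <- local_align(M, mismatch_offset = 0.5)
  expect_equal(a$score, 0.5)
  expect_identical(unname(a$matched), matrix(c(2L, 2L), ncol = 2L))
  b <- local_align(diag(4), mismatch_offset = 0.5)
  expect_equal(b$score, 2)
  expect_identical(unname(b$matched),
                   matrix(c(1:4, 1:4), ncol = 2L))
})

test_that("compare_pair: self, reversed and single-shared-step cases", {
  set.seed(41)
  e <- random_test_entry("E", 4)
  self <- compare_pair(e, e)
  expect_identical(self$overall_raw, 1)
  expect_identical(self$mechanistic_raw, 1)
  expect_identical(self$best_direction, "forward")

  rev <- compare_pair(e, reverse_entry(e))
  expect_identical(rev$overall_raw, 1)
  expect_identical(rev$mechanistic_raw, 1)
  expect_identical(rev$best_direction, "reversed")

  # two 3-step mechanisms sharing exactly one identical step
  a <- make_entry("A", list(c("f:C-O"), c("c:H-N"), c("i:C-C")))
  b <- make_entry("B", list(c("f:O-P"), c("c:H-N"), c("d:O-S")))
  ab <- compare_pair(a, b)
  expect_equal(ab$mechanistic_raw, 1 / 5)
  expect_identical(nrow(ab$identical_steps_in_alignment), 1L)
  expect_identical(ab$identical_steps_in_alignment$i, 2L)
  expect_identical(ab$identical_steps_in_alignment$j, 2L)
})

test_that("compare_pair is symmetric and invariant under double reversal", {
  set.seed(42)
  for (k in 1:40) {
    e1 <- random_test_entry("E1")
    e2 <- random_test_entry("E2")
    c12 <- compare_pair(e1, e2)
    expect_scores_equal(c12, compare_pair(e2, e1))
    expect_scores_equal(c12, compare_pair(reverse_entry(e1),
                                          reverse_entry(e2)))
    # identical steps on the winning alignment are identical steps
    ia <- c12$identical_steps_in_alignment
    all_ids <- c12$identical_steps_all
    if (nrow(ia) > 0L) {
      key <- paste(ia$i, ia$j, ia$direction)
      expect_true(all(key %in%
                        paste(all_ids$i, all_ids$j, all_ids$direction)))
    }
    # bounds
    n <- c12$n_steps
    expect_lte(c12$mechanistic_raw,
               max_possible_mechanistic(n[1L], n[2L]) + 1e-12)
    expect_lte(c12$mechanistic_normalized, 1 + 1e-12)
  }
})

test_that("enabling rotations never decreases the mechanistic score", {
  set.seed(43)
  for (k in 1:20) {
    e1 <- random_test_entry("E1")
    e2 <- random_test_entry("E2")
    e1$permutation_allowed <- TRUE
    e2$permutation_allowed <- TRUE
    none <- compare_pair(e1, e2, rotations = "none")
    wl <- compare_pair(e1, e2, rotations = "whitelist")
    all_r <- compare_pair(e1, e2, rotations = "all")
    expect_gte(wl$mechanistic_raw, none$mechanistic_raw - 1e-12)
    expect_gte(all_r$mechanistic_raw, wl$mechanistic_raw - 1e-12)
  }
  # a rotated copy of a permutation-allowed mechanism is recovered exactly
  steps <- list(c("f:H-O"), c("c:C-O"), c("i:C-C"), c("f:C-N"))
  a <- make_entry("A", steps, perm = TRUE)
  b <- make_entry("B", steps[c(2:4, 1L)], perm = TRUE)
  expect_lt(compare_pair(a, b, rotations = "none")$mechanistic_raw, 1)
  expect_identical(compare_pair(a, b)$mechanistic_raw, 1)
})
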