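# Shared helpers: compact constructors, random generators and independent
# oracles used across the suite.

# all canonical (kind, bond) tokens over a small repertoire
all_tokens <- function(bonds = c("C-O", "H-O", "C-C", "C-N", "H-N", "O-P")) {
  as.vector(outer(c("f", "c", "i", "d"), bonds, paste, sep = ":"))
}

random_token_set <- function(max_size = 6, bonds = NULL) {
  pool <- if (is.null(bonds)) all_tokens() else all_tokens(bonds)
  sample(pool, sample.int(max_size, 1L))
}

# quick entry builder: steps given as character vectors of tokens
make_entry <- function(id, steps, ec = "1.1.1.1", sf = "1.10.10.10",
                       overall = NULL, perm = FALSE) {
  mech <- lapply(seq_along(steps), function(k) {
    mechanistic_step(k, steps[[k]])
  })
  if (is.null(overall)) overall <- derive_overall(mech)
  reaction_entry(id, ec, sf, overall = overall, mechanism = mech,
                 permutation_allowed = perm)
}

random_test_entry <- function(id = "RND", n_steps = sample(2:6, 1L)) {
  repeat {
    steps <- replicate(n_steps, random_token_set(4), simplify = FALSE)
    mech <- lapply(seq_along(steps), function(k) {
      mechanistic_step(k, steps[[k]])
    })
    if (length(derive_overall(mech)) > 0L) {
      return(make_entry(id, steps))
    }
  }
}

# Independent oracle for the global step alignment: memoized exhaustive
# maximisation over all monotone (non-crossing) matchings. Shares no code
# with the Needleman-Wunsch implementation.
brute_force_best_matching <- function(M) {
  n1 <- nrow(M)
  n2 <- ncol(M)
  memo <- array(NA_real_, dim = c(n1 + 1L, n2 + 1L))
  rec <- function(i, j) {
    if (i > n1 || j > n2) return(0)
    if (!is.na(memo[i, j])) return(memo[i, j])
    v <- max(rec(i + 1L, j), rec(i, j + 1L), M[i, j] + rec(i + 1L, j + 1L))
    memo[i, j] <<- v
    v
  }
  rec(1L, 1L)
}

expect_scores_equal <- function(c1, c2, tol = 1e-12) {
  expect_equal(c1$overall_raw, c2$overall_raw, tolerance = tol)
  expect_equal(c1$overall_normalized, c2$overall_normalized,
               tolerance = tol)
  expect_equal(c1$mechanistic_raw, c2$mechanistic_raw, tolerance = tol)
  expect_equal(c1$mechanistic_normalized, c2$mechanistic_normalized,
               tolerance = tol)
}
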