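test_that("metrics_at counts the confusion matrix with >= as positive", {
  m <- metrics_at(c(0.9, 0.8), c(0.1, 0.2), 0.5)
  expect_identical(c(m$tp, m$fp, m$tn, m$fn), c(2L, 0L, 2L, 0L))
  expect_identical(m$f_measure, 1)
  expect_identical(m$mcc, 1)
  # cutoff 0: everything positive, recall 1
  m0 <- metrics_at(c(0.9, 0.8), c(0.1, 0.2), 0)
  expect_identical(m0$recall, 1)
  expect_identical(m0$fp, 2L)
  # enrichment is tpr/fpr on exact counts
  m1 <- metrics_at(c(0.9, 0.9, 0.1, 0.1), rep(c(0.9, 0.1), c(1, 19)), 0.5)
  expect_equal(m1$tpr, 0.5)
  expect_equal(m1$fpr, 0.05)
  expect_equal(m1$enrichment, 10)
  expect_error(metrics_at(numeric(), c(1), 0.5), "non-empty")
})

test_that("metrics_at conserves totals across all cutoffs", {
  set.seed(51)
  ds <- runif(40)
  bg <- runif(100)
  for (ct in c(-1, sort(unique(c(ds, bg))), 2)) {
    m <- metrics_at(ds, bg, ct)
    expect_identical(m$tp + m$fn, 40L)
    expect_identical(m$fp + m$tn, 100L)
  }
})

test_that("mcc follows the formula with the zero-factor convention", {
  expect_identical(mcc(2, 0, 2, 0), 1)
  expect_identical(mcc(0, 2, 0, 2), -1)
  expect_identical(mcc(1, 1, 1, 1), 0)
  expect_identical(mcc(0, 0, 5, 5), 0)
})

test_that("optimal_f_cutoff agrees with an independent sorted scan", {
  opt <- optimal_f_cutoff(c(0.9, 0.8), c(0.1, 0.2))
  expect_identical(opt$cutoff, 0.8)
  expect_identical(opt$metrics$f_measure, 1)
  # single dataset score above all background
  opt2 <- optimal_f_cutoff(0.7, c(0.1, 0.2, 0.3))
  expect_identical(opt2$cutoff, 0.7)
  expect_identical(opt2$metrics$f_measure, 1)
  # interleaved scores cannot be perfectly separated
  opt3 <- optimal_f_cutoff(c(0.2, 0.4, 0.6), c(0.3, 0.5, 0.7))
  expect_lt(opt3$metrics$f_measure, 1)
  # oracle: direct scan computing F from sorted counts, independent code
  set.seed(52)
  for (k in 1:20) {
    ds <- round(runif(30), 2)
    bg <- round(runif(60), 2)
    cand <- sort(unique(c(ds, bg)))
    f_vals <- vapply(cand, function(ct) {
      tp <- sum(ds >= ct)
      fp <- sum(bg >= ct)
      p <- if (tp + fp == 0) 0 else tp / (tp + fp)
      r <- tp / length(ds)
      if (p + r == 0) 0 else 2 * p * r / (p + r)
    }, 0)
    best_f <- max(f_vals)
    opt_k <- optimal_f_cutoff(ds, bg)
    expect_equal(opt_k$metrics$f_measure, best_f, tolerance = 1e-12)
    expect_identical(opt_k$cutoff, cand[which.max(f_vals)])
  }
})

test_that("significance_cutoff returns the smallest sufficiently rare score", {
  bg <- seq(0, 0.99, by = 0.01)
  expect_equal(significance_cutoff(bg, 0.05), 0.96)
  expect_equal(significance_cutoff(bg, 1), 0)
  expect_error(significance_cutoff(rep(0.5, 10), 0.05), "degenerate")
  expect_error(significance_cutoff(bg, 0), "alpha")
  # definition check: fewer than alpha of the background at or above it
  set.seed(53)
  sc <- runif(500)
  s <- significance_cutoff(sc, 0.05)
  expect_lt(mean(sc >= s), 0.05)
  smaller <- sort(unique(sc[sc < s]))
  if (length(smaller) > 0L) {
    expect_gte(mean(sc >= max(smaller)), 0.05)
  }
})

test_that("similarity_labels applies the two-tier scheme", {
  labs <- similarity_labels(c(0.9, 0.6, 0.1), 0.8, 0.5)
  expect_identical(labs,
                   c("highly_similar", "distantly_similar", "non_similar"))
})

test_that("roc_curve is monotone, anchored and trapezium-integrated", {
  r <- roc_curve(1, 0)
  expect_identical(r$points$fpr, c(0, 0, 1, 1))
  expect_identical(r$points$tpr, c(0, 1, 1, 1))
  expect_identical(r$auc, 1)
  # perfectly separated
  expect_identical(roc_curve(c(0.8, 0.9), c(0.1, 0.2))$auc, 1)
  set.seed(54)
  ds <- runif(50)
  bg <- runif(80)
  rr <- roc_curve(ds, bg)
  expect_true(all(diff(rr$points$fpr) >= 0))
  expect_true(all(diff(rr$points$tpr) >= 0))
  expect_identical(rr$points$fpr[1L], 0)
  expect_identical(utils::tail(rr$points$tpr, 1L), 1)
  expect_gte(rr$auc, 0)
  expect_lte(rr$auc, 1)
  # oracle: AUC equals the Mann-Whitney statistic on the same samples
  u <- mean(outer(ds, bg, ">") + 0.5 * outer(ds, bg, "=="))
  expect_equal(rr$auc, u, tolerance = 1e-9)
})

test_that("repetitions_needed is the ceiling of -ln(p)/f", {
  expect_identical(repetitions_needed(0.01, 0.01), 461L)
  expect_identical(repetitions_needed(exp(-1), 1), 1L)
  expect_identical(repetitions_needed(0.05, 0.01), 300L)
  expect_error(repetitions_needed(0, 0.01), "p must")
  expect_error(repetitions_needed(0.01, 0), "f must")
})

test_that("analog_pairs collapses homologs within sub-subclasses", {
  mk <- function(id, ec, sf) make_entry(id, list("f:C-O"), ec = ec, sf = sf)
  # 3 entries, same sub-subclass, disjoint superfamilies: 3 pairs
  e3 <- list(mk("a", "1.1.1.1", "1.1.1.1"), mk("b", "1.1.1.2", "2.2.2.2"),
             mk("c", "1.1.1.3", "3.3.3.3"))
  expect_identical(nrow(analog_pairs(e3, seed = 1)), 3L)
  # 2 entries sharing a superfamily collapse to one survivor: 0 pairs
  e2 <- list(mk("a", "1.1.1.1", "1.1.1.1"), mk("b", "1.1.1.2", "1.1.1.1"))
  expect_identical(nrow(analog_pairs(e2, seed = 1)), 0L)
  # 4 entries, two sharing a superfamily: 3 survivors -> 3 pairs
  e4 <- c(e3, list(mk("d", "1.1.1.4", "1.1.1.1")))
  pr <- analog_pairs(e4, seed = 1)
  expect_identical(nrow(pr), 3L)
  # entries without superfamilies are excluded with a warning
  e_na <- c(e3, list(mk("x", "1.1.1.5", character())))
  expect_warning(pr2 <- analog_pairs(e_na, seed = 1), "without superfamily")
  expect_identical(nrow(pr2), 3L)
})

test_that("build_background output is certifiably non-redundant", {
  set.seed(55)
  cfg <- generator_config()
  # construct a pool with deliberate functional and structural overlaps
  pool <- lapply(1:40, function(i) {
    make_entry(sprintf("P%02d", i), list(c("f:C-O"), c("c:H-O")),
               ec = sprintf("%d.%d.%d.%d", i %% 3 + 1, i %% 5 + 1,
                            i %% 7 + 1, i),
               sf = sprintf("%d.10.%d.10", i %% 4 + 1, i %% 6 + 1))
  })
  bg <- build_background(pool, seed = 9)
  expect_gt(length(bg), 1L)
  ssc <- vapply(bg, ec_sub_subclass, "")
  expect_false(anyDuplicated(ssc) > 0L)
  for (i in seq_along(bg)) {
    for (j in seq_len(i - 1L)) {
      expect_length(intersect(bg[[i]]$superfamilies,
                              bg[[j]]$superfamilies), 0L)
    }
  }
  # pairwise-unrelated input is fully retained
  disjoint <- lapply(1:5, function(i) {
    make_entry(sprintf("D%d", i), list("f:C-O"),
               ec = sprintf("%d.1.1.1", i), sf = sprintf("%d.1.1.1", i))
  })
  expect_length(build_background(disjoint, seed = 1), 5L)
  # two entries in the same sub-subclass: exactly one survives
  same <- list(make_entry("a", list("f:C-O"), ec = "1.1.1.1", sf = "1.1.1.1"),
               make_entry("b", list("f:C-O"), ec = "1.1.1.2", sf = "2.2.2.2"))
  expect_length(build_background(same, seed = 1), 1L)
})

test_that("min_domain_combinations finds the minimal survivor count", {
  mk <- function(id, sf) make_entry(id, list("f:C-O"), ec = "1.1.1.1",
                                    sf = sf)
  # chain A-B homologous, B-C homologous, A-C not: picking B first gives 1
  chain <- list(mk("A", "s1"), mk("B", c("s1", "s2")), mk("C", "s2"))
  expect_identical(unname(min_domain_combinations(chain, 100, seed = 2)),
                   1L)
  # all homologous: always 1
  homo <- list(mk("A", "s1"), mk("B", "s1"), mk("C", "s1"))
  expect_identical(unname(min_domain_combinations(homo, 10, seed = 2)), 1L)
  # all pairwise non-homologous: always n
  free <- list(mk("A", "s1"), mk("B", "s2"), mk("C", "s3"))
  expect_identical(unname(min_domain_combinations(free, 10, seed = 2)), 3L)
})

test_that("injected separation is recovered by both cutoffs", {
  set.seed(56)
  bg <- runif(400, 0, 0.4)
  ds <- runif(60, 0.6, 1)
  ana <- similarity_analysis(ds, bg)
  expect_gt(ana$f_cutoff, max(bg) - 1e-12)
  expect_lte(ana$f_cutoff, min(ds))
  expect_gt(ana$sig_cutoff, 0.4 * 0.9)
  expect_identical(ana$n_significant, 60L)
  expect_identical(ana$auc, 1)
})
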