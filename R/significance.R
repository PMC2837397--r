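# Dataset/background construction and classification statistics: confusion
# matrices per cutoff, F-measure and MCC cutoff optimisation, empirical
# significance thresholds, enrichment, ROC/AUC, and the repeated random
# selection machinery for non-homologous subsets.

#' Matthews correlation coefficient
#'
#' `(tp*tn - fp*fn) / sqrt((tp+fp)(tp+fn)(tn+fp)(tn+fn))`, with the
#' convention that the coefficient is 0 whenever any factor of the
#' denominator is 0.
#'
#' @param tp,fp,tn,fn Non-negative confusion-matrix counts.
#' @return Numeric in `[-1, 1]`.
#' @export
mcc <- function(tp, fp, tn, fn) {
  stopifnot(tp >= 0, fp >= 0, tn >= 0, fn >= 0)
  denom <- as.numeric(tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (denom == 0) return(0)
  (as.numeric(tp) * tn - as.numeric(fp) * fn) / sqrt(denom)
}

#' Confusion matrix and derived statistics at one cutoff
#'
#' Scores at or above the cutoff are positive calls ("equal or higher", the
#' convention of the empirical significance definition, applied uniformly).
#' Dataset pairs are the positive class, background pairs the negative
#' class: `tp`/`fn` partition the dataset scores, `fp`/`tn` the background
#' scores. Ratios with zero denominator (0/0) are reported as 0 and flagged.
#'
#' @param dataset_scores,background_scores Non-empty numeric vectors.
#' @param cutoff Similarity cutoff.
#' @return A list of class `"threshold_metrics"`: counts, `precision`,
#'   `recall`, `f_measure`, `mcc`, `tpr`, `fpr`, `enrichment` (tpr/fpr) and
#'   an `undefined` character vector naming flagged ratios.
#' @export
metrics_at <- function(dataset_scores, background_scores, cutoff) {
  if (length(dataset_scores) == 0L || length(background_scores) == 0L) {
    stop("dataset and background score sets must be non-empty",
         call. = FALSE)
  }
  tp <- sum(dataset_scores >= cutoff)
  fn <- length(dataset_scores) - tp
  fp <- sum(background_scores >= cutoff)
  tn <- length(background_scores) - fp
  undefined <- character()
  ratio <- function(num, den, name) {
    if (den == 0) {
      if (num == 0) {
        undefined <<- c(undefined, name)
        return(0)
      }
      return(Inf)
    }
    num / den
  }
  precision <- ratio(tp, tp + fp, "precision")
  recall <- tp / (tp + fn)
  f_measure <- if (precision + recall == 0) {
    undefined <- c(undefined, "f_measure")
    0
  } else {
    2 * precision * recall / (precision + recall)
  }
  tpr <- recall
  fpr <- fp / (fp + tn)
  enrichment <- ratio(tpr, fpr, "enrichment")
  structure(
    list(cutoff = cutoff, tp = tp, fp = fp, tn = tn, fn = fn,
         precision = precision, recall = recall, f_measure = f_measure,
         mcc = mcc(tp, fp, tn, fn), tpr = tpr, fpr = fpr,
         enrichment = enrichment, undefined = undefined),
    class = "threshold_metrics"
  )
}

#' @export
print.threshold_metrics <- function(x, ...) {
  cat("<threshold_metrics> cutoff", format(x$cutoff, digits = 4),
      sprintf("tp=%d fp=%d tn=%d fn=%d", x$tp, x$fp, x$tn, x$fn),
      sprintf("P=%.4f R=%.4f F=%.4f MCC=%.4f", x$precision, x$recall,
              x$f_measure, x$mcc), "\n")
  invisible(x)
}

# Candidate cutoffs: the union of observed scores. Tanimoto-type scores are
# rationals with small denominators, so the observed values are the only
# places the confusion matrix can change.
.candidate_cutoffs <- function(dataset_scores, background_scores) {
  sort(unique(c(dataset_scores, background_scores)))
}

#' Threshold metrics at every candidate cutoff
#'
#' @inheritParams metrics_at
#' @return Data frame with one row per candidate cutoff (union of observed
#'   scores, ascending).
#' @export
threshold_table <- function(dataset_scores, background_scores) {
  cuts <- .candidate_cutoffs(dataset_scores, background_scores)
  do.call(rbind, lapply(cuts, function(ct) {
    m <- metrics_at(dataset_scores, background_scores, ct)
    data.frame(cutoff = m$cutoff, tp = m$tp, fp = m$fp, tn = m$tn,
               fn = m$fn, precision = m$precision, recall = m$recall,
               f_measure = m$f_measure, mcc = m$mcc, tpr = m$tpr,
               fpr = m$fpr, enrichment = m$enrichment)
  }))
}

#' Cutoff that maximizes the F-measure
#'
#' Scans the union of observed scores and returns the cutoff with maximal
#' F-measure (harmonic mean of precision and recall). Ties are broken
#' toward the lowest cutoff, i.e. maximal recall at equal F.
#'
#' @inheritParams metrics_at
#' @return List with `cutoff` and `metrics` (the [metrics_at()] result).
#' @export
optimal_f_cutoff <- function(dataset_scores, background_scores) {
  cuts <- .candidate_cutoffs(dataset_scores, background_scores)
  best <- NULL
  for (ct in cuts) {
    m <- metrics_at(dataset_scores, background_scores, ct)
    if (is.null(best) || m$f_measure > best$metrics$f_measure + 1e-12) {
      best <- list(cutoff = ct, metrics = m)
    }
  }
  best
}

#' Empirical significance cutoff from a background distribution
#'
#' The smallest observed score s such that strictly fewer than
#' `alpha * 100` percent of background pairs score equal or higher than s.
#' A dataset pair scoring at or above s is then significant at level
#' `alpha`.
#'
#' @param background_scores Non-empty numeric vector of null scores.
#' @param alpha Significance level in (0, 1]; default 0.05.
#' @return The cutoff score.
#' @export
significance_cutoff <- function(background_scores, alpha = 0.05) {
  if (length(background_scores) == 0L) {
    stop("background score set must be non-empty", call. = FALSE)
  }
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha > 1) {
    stop("alpha must lie in (0, 1]", call. = FALSE)
  }
  if (alpha == 1) return(min(background_scores))
  cand <- sort(unique(background_scores))
  n <- length(background_scores)
  for (s in cand) {
    if (sum(background_scores >= s) / n < alpha) return(s)
  }
  stop("degenerate background: no observed score is exceeded by fewer ",
       "than ", alpha * 100, "% of background pairs", call. = FALSE)
}

#' Two-tier similarity labels
#'
#' Pairs at or above the F-measure-optimal cutoff are `"highly_similar"`,
#' pairs between the significance cutoff and the F-optimal cutoff are
#' `"distantly_similar"`, the rest `"non_similar"`.
#'
#' @param scores Numeric vector of pair scores.
#' @param f_cutoff F-measure-optimal cutoff.
#' @param sig_cutoff Significance cutoff (must not exceed `f_cutoff`
#'   for the tiers to be meaningful; no check is enforced).
#' @return Character vector of labels.
#' @export
similarity_labels <- function(scores, f_cutoff, sig_cutoff) {
  ifelse(scores >= f_cutoff, "highly_similar",
         ifelse(scores >= sig_cutoff, "distantly_similar", "non_similar"))
}

#' ROC curve and trapezium-rule AUC
#'
#' Sweeps the cutoff from above the largest observed score down to below
#' the smallest, recording (false positive rate, true positive rate) at
#' each candidate; the curve is anchored at (0,0) and (1,1) and the area
#' under it computed by the trapezium rule.
#'
#' @inheritParams metrics_at
#' @return List of class `"roc_result"` with `points` (data frame of
#'   `fpr`, `tpr`, `cutoff`) and `auc`.
#' @export
roc_curve <- function(dataset_scores, background_scores) {
  if (length(dataset_scores) == 0L || length(background_scores) == 0L) {
    stop("dataset and background score sets must be non-empty",
         call. = FALSE)
  }
  cuts <- c(Inf, rev(.candidate_cutoffs(dataset_scores, background_scores)),
            -Inf)
  nd <- length(dataset_scores)
  nb <- length(background_scores)
  tpr <- vapply(cuts, function(ct) sum(dataset_scores >= ct) / nd, 0)
  fpr <- vapply(cuts, function(ct) sum(background_scores >= ct) / nb, 0)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1L) + utils::tail(tpr, -1L)) / 2)
  structure(
    list(points = data.frame(fpr = fpr, tpr = tpr, cutoff = cuts),
         auc = auc),
    class = "roc_result"
  )
}

#' @export
print.roc_result <- function(x, ...) {
  cat("<roc_result>", nrow(x$points), "points, AUC =",
      format(x$auc, digits = 4), "\n")
  invisible(x)
}

#' Repetitions needed for repeated random selection
#'
#' For a randomised selection whose best outcome is found by a fraction `f`
#' of all selection orders, about `-ln(p)/f` independent repetitions reduce
#' the probability of missing the best outcome to `p`. With p = f = 0.01
#' this gives 461 repetitions.
#'
#' @param p Miss probability, in (0, 1).
#' @param f Fraction of selections producing the best outcome, in (0, 1].
#' @return Integer count (ceiling of the approximation).
#' @export
repetitions_needed <- function(p, f) {
  if (!is.numeric(p) || length(p) != 1L || p <= 0 || p >= 1) {
    stop("p must lie in (0, 1)", call. = FALSE)
  }
  if (!is.numeric(f) || length(f) != 1L || f <= 0 || f > 1) {
    stop("f must lie in (0, 1]", call. = FALSE)
  }
  as.integer(ceiling(-log(p) / f))
}

# One round of homolog collapsing: iteratively pick a random entry, keep
# it, and drop every remaining entry sharing at least one superfamily code
# with the kept one. Returns indices of the survivors.
.collapse_homologs <- function(superfam_list) {
  pool <- seq_along(superfam_list)
  kept <- integer()
  while (length(pool) > 0L) {
    pick <- pool[sample.int(length(pool), 1L)]
    kept <- c(kept, pick)
    sf <- superfam_list[[pick]]
    pool <- pool[pool != pick]
    if (length(sf) > 0L && length(pool) > 0L) {
      share <- vapply(superfam_list[pool],
                      function(x) length(intersect(x, sf)) > 0L, TRUE)
      pool <- pool[!share]
    }
  }
  sort(kept)
}

#' Functional-analog pairs within EC sub-subclasses
#'
#' Groups entries by EC sub-subclass, collapses structural homologs within
#' each group to a single randomly chosen representative (entries sharing
#' any superfamily code are reduced to one, iteratively), and returns all
#' within-group unordered pairs of the survivors: pairs of enzymes with the
#' same reaction chemistry but no detectable common ancestry.
#'
#' @param entries List of [reaction_entry()]s with EC and superfamily
#'   annotations. Entries without superfamily codes are excluded with a
#'   warning (homology cannot be assessed for them).
#' @param seed Integer seed for the random representative selection.
#' @return Data frame with columns `id_1`, `id_2`, `sub_subclass`.
#' @export
analog_pairs <- function(entries, seed) {
  set.seed(seed)
  has_sf <- vapply(entries, function(e) length(e$superfamilies) > 0L, TRUE)
  if (any(!has_sf)) {
    warning(sum(!has_sf), " entr(ies) without superfamily codes excluded ",
            "from analog-pair construction", call. = FALSE)
    entries <- entries[has_sf]
  }
  ssc <- vapply(entries, ec_sub_subclass, "")
  out <- list()
  for (grp in unique(ssc)) {
    members <- entries[ssc == grp]
    if (length(members) < 2L) next
    kept <- .collapse_homologs(lapply(members, `[[`, "superfamilies"))
    if (length(kept) < 2L) next
    ids <- sort(vapply(members[kept], `[[`, "", "id"))
    pr <- t(utils::combn(ids, 2L))
    out[[length(out) + 1L]] <- data.frame(
      id_1 = pr[, 1L], id_2 = pr[, 2L], sub_subclass = grp,
      stringsAsFactors = FALSE)
  }
  if (length(out) == 0L) {
    return(data.frame(id_1 = character(), id_2 = character(),
                      sub_subclass = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Assemble a non-redundant background set
#'
#' Iterative uniform random selection: each pick keeps one entry and
#' removes every remaining entry in the same EC sub-subclass (functional
#' analogs) or sharing at least one superfamily code (structural homologs),
#' until the pool is exhausted. The survivors are pairwise unrelated by
#' both function and structure, so their pairwise similarities form a null
#' distribution in which similarity arises only from the limited repertoire
#' of bond types in catalysis.
#'
#' @param entries List of [reaction_entry()]s (typically excluding the
#'   analog dataset's members).
#' @param seed Integer seed.
#' @return List of surviving `reaction_entry`s, in input order.
#' @export
build_background <- function(entries, seed) {
  set.seed(seed)
  ssc <- vapply(entries, ec_sub_subclass, "")
  sfs <- lapply(entries, `[[`, "superfamilies")
  pool <- seq_along(entries)
  kept <- integer()
  while (length(pool) > 0L) {
    pick <- pool[sample.int(length(pool), 1L)]
    kept <- c(kept, pick)
    pool <- pool[pool != pick]
    if (length(pool) > 0L) {
      related <- ssc[pool] == ssc[pick] |
        vapply(sfs[pool],
               function(x) length(intersect(x, sfs[[pick]])) > 0L, TRUE)
      pool <- pool[!related]
    }
  }
  entries[sort(kept)]
}

#' Minimum number of non-homologous domain combinations per sub-subclass
#'
#' Repeats the random homolog-collapsing selection many times for each EC
#' sub-subclass and reports the minimum survivor count observed, i.e. the
#' smallest number of distinct structural solutions compatible with the
#' homology relations. With the default 500 repetitions the chance of
#' missing the optimum is below 1% when at least 1% of selection orders
#' attain it (see [repetitions_needed()]).
#'
#' @param entries List of [reaction_entry()]s.
#' @param repetitions Number of random selections per sub-subclass
#'   (default 500).
#' @param seed Integer seed.
#' @return Named integer vector: minimum survivor count per sub-subclass.
#' @export
min_domain_combinations <- function(entries, repetitions = 500, seed) {
  stopifnot(repetitions >= 1)
  set.seed(seed)
  ssc <- vapply(entries, ec_sub_subclass, "")
  groups <- unique(ssc)
  out <- integer(length(groups))
  names(out) <- groups
  for (g in groups) {
    sfl <- lapply(entries[ssc == g], `[[`, "superfamilies")
    out[g] <- min(vapply(seq_len(repetitions),
                         function(k) length(.collapse_homologs(sfl)), 0L))
  }
  out
}

#' Full significance summary for one score type
#'
#' Convenience wrapper combining the cutoff optimisation, empirical
#' significance threshold, significant-pair count and ROC/AUC for one pair
#' of score distributions.
#'
#' @inheritParams metrics_at
#' @param alpha Significance level (default 0.05).
#' @return List with `f_cutoff`, `f_metrics`, `sig_cutoff`,
#'   `n_significant` (dataset pairs at or above `sig_cutoff`), `roc`,
#'   `auc` and `labels`.
#' @export
similarity_analysis <- function(dataset_scores, background_scores,
                                alpha = 0.05) {
  opt <- optimal_f_cutoff(dataset_scores, background_scores)
  sig <- significance_cutoff(background_scores, alpha)
  roc <- roc_curve(dataset_scores, background_scores)
  list(
    f_cutoff = opt$cutoff,
    f_metrics = opt$metrics,
    sig_cutoff = sig,
    n_significant = sum(dataset_scores >= sig),
    roc = roc,
    auc = roc$auc,
    labels = similarity_labels(dataset_scores, opt$cutoff, sig)
  )
}
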