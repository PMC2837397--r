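# Full pairwise comparison of two reaction entries: direction- and
# rotation-maximised overall and mechanistic similarity, with identical-step
# bookkeeping.

#' Compare two reaction entries
#'
#' Computes every similarity the framework defines for one pair of enzymes:
#'
#' * overall similarity: Tanimoto coefficient between the overall
#'   bond-change sets, maximised over the two reaction directions (the
#'   second entry's changes inverted for the reverse direction);
#' * mechanistic similarity: mechanistic Tanimoto of the best global step
#'   alignment, maximised over direction and, where admitted, circular
#'   permutations of either mechanism;
#' * normalized variants of both, dividing by the maximum score attainable
#'   given the set sizes / step counts;
#' * all identical step pairs (forward and reversed) and the subset of them
#'   lying on the winning global alignment.
#'
#' Reaction direction is searched because enzyme catalysis is microscopically
#' reversible: the mechanism read backwards describes the same enzyme. The
#' mechanistic direction is searched independently of the overall direction,
#' and both winners are reported. Ties are resolved deterministically in
#' favour of the forward direction and the smallest rotation offsets.
#'
#' @param e1,e2 [reaction_entry()]s. Spontaneous steps are stripped
#'   internally (see [strip_spontaneous()]).
#' @param rotations Circular-permutation policy: `"whitelist"` (default;
#'   rotate only entries whose `permutation_allowed` flag is set), `"none"`,
#'   or `"all"` (exhaustive search for both entries).
#' @return A list of class `"pair_comparison"`; see the fields in the
#'   examples and [pairwise_table()].
#' @examples
#' e <- reaction_entry("R1", "3.1.3.1", "3.40.720.10",
#'                     overall = c("c:O-P", "f:H-O"),
#'                     mechanism = list(c("c:O-P"), c("f:H-O")))
#' cmp <- compare_pair(e, e)
#' cmp$overall_raw        # 1
#' cmp$mechanistic_raw    # 1
#' @export
compare_pair <- function(e1, e2,
                         rotations = c("whitelist", "none", "all")) {
  stopifnot(inherits(e1, "reaction_entry"), inherits(e2, "reaction_entry"))
  rotations <- match.arg(rotations)
  e1 <- strip_spontaneous(e1)
  e2 <- strip_spontaneous(e2)

  eps <- 1e-12

  ## ---- overall similarity, direction-maximised -------------------------
  o1 <- unclass(e1$overall)
  o2 <- unclass(e2$overall)
  if (length(o1) == 0L && length(o2) == 0L) {
    stop("both entries have change-free overall reactions ('", e1$id,
         "', '", e2$id, "'); overall similarity undefined", call. = FALSE)
  }
  t_fwd <- .tanimoto_raw(o1, o2)
  t_rev <- .tanimoto_raw(o1, unclass(reverse_changes(o2)))
  if (t_rev > t_fwd + eps) {
    overall_raw <- t_rev
    overall_direction <- "reversed"
  } else {
    overall_raw <- t_fwd
    overall_direction <- "forward"
  }
  if (length(o1) == 0L || length(o2) == 0L) {
    warning("entry '", if (length(o1) == 0L) e1$id else e2$id,
            "' has a change-free overall reaction; normalized overall ",
            "similarity undefined", call. = FALSE)
    overall_norm <- NA_real_
  } else {
    overall_norm <- normalize_similarity(overall_raw, length(o1), length(o2))
  }

  ## ---- mechanistic similarity, direction x rotation maximised ----------
  m1 <- e1$mechanism
  m2 <- e2$mechanism
  if (length(m1) == 0L || length(m2) == 0L) {
    stop("entry with empty mechanism ('",
         if (length(m1) == 0L) e1$id else e2$id,
         "'); mechanistic comparison impossible", call. = FALSE)
  }
  n1 <- length(m1)
  n2 <- length(m2)
  offs1 <- .rotation_offsets(e1, n1, rotations)
  offs2 <- .rotation_offsets(e2, n2, rotations)

  best <- NULL
  for (direction in c("forward", "reversed")) {
    m2_dir <- if (direction == "reversed") .reverse_mechanism(m2) else m2
    for (r1 in offs1) {
      m1_rot <- .rotate_mechanism(m1, r1)
      for (r2 in offs2) {
        m2_rot <- .rotate_mechanism(m2_dir, r2)
        M <- suppressMessages(step_matrix(m1_rot, m2_rot))
        aln <- global_align(M)
        score <- mechanistic_tanimoto(aln$score, n1, n2)
        if (is.null(best) || score > best$score + eps) {
          best <- list(score = score, direction = direction,
                       r1 = r1, r2 = r2, alignment = aln, M = M)
        }
      }
    }
  }
  mech_raw <- best$score
  mech_norm <- normalize_similarity(mech_raw, n1, n2)

  ## ---- identical steps -------------------------------------------------
  identical_all <- find_identical_steps(m1, m2)
  identical_in_aln <- .identical_on_alignment(best, n1, n2)

  structure(
    list(id_1 = e1$id, id_2 = e2$id, ec_1 = e1$ec, ec_2 = e2$ec,
         overall_raw = overall_raw, overall_normalized = overall_norm,
         mechanistic_raw = mech_raw, mechanistic_normalized = mech_norm,
         overall_direction = overall_direction,
         best_direction = best$direction,
         best_rotations = c(best$r1, best$r2),
         n_steps = c(n1, n2),
         alignment = best$alignment,
         identical_steps_all = identical_all,
         identical_steps_in_alignment = identical_in_aln),
    class = "pair_comparison"
  )
}

.rotation_offsets <- function(entry, n, policy) {
  allowed <- switch(policy,
                    none = FALSE,
                    all = TRUE,
                    whitelist = entry$permutation_allowed)
  if (allowed) 0:(n - 1L) else 0L
}

# Map the winning alignment's matched pairs back to the original step
# numbering and keep those whose cell similarity is exactly 1.
.identical_on_alignment <- function(best, n1, n2) {
  matched <- best$alignment$matched
  out <- data.frame(i = integer(), j = integer(),
                    direction = character(), stringsAsFactors = FALSE)
  if (nrow(matched) == 0L) return(out)
  for (k in seq_len(nrow(matched))) {
    i <- matched[k, 1L]
    j <- matched[k, 2L]
    if (abs(best$M[i, j] - 1) > 1e-12) next
    i_orig <- (i - 1L + best$r1) %% n1 + 1L
    j_dir <- (j - 1L + best$r2) %% n2 + 1L
    j_orig <- if (best$direction == "reversed") n2 + 1L - j_dir else j_dir
    out <- rbind(out, data.frame(i = i_orig, j = j_orig,
                                 direction = best$direction,
                                 stringsAsFactors = FALSE))
  }
  out
}

#' @export
print.pair_comparison <- function(x, ...) {
  fmt <- function(v) formatC(v, digits = 4, format = "f")
  cat("<pair_comparison> ", x$id_1, " (", x$ec_1, ") vs ", x$id_2,
      " (", x$ec_2, ")\n",
      "  overall:     raw ", fmt(x$overall_raw), "  normalized ",
      fmt(x$overall_normalized), "  direction ", x$overall_direction, "\n",
      "  mechanistic: raw ", fmt(x$mechanistic_raw), "  normalized ",
      fmt(x$mechanistic_normalized), "  direction ", x$best_direction,
      "  rotations ", x$best_rotations[1L], "/", x$best_rotations[2L], "\n",
      "  identical steps: ", nrow(x$identical_steps_all), " total, ",
      nrow(x$identical_steps_in_alignment), " on the best alignment\n",
      sep = "")
  if (nrow(x$alignment$matched) > 0L) {
    cat("  aligned steps: ",
        paste0(x$alignment$matched[, 1L], "~", x$alignment$matched[, 2L],
               collapse = " "), "\n", sep = "")
  }
  invisible(x)
}

#' Compare many pairs of reaction entries
#'
#' Applies [compare_pair()] to a list of index pairs, or to all unordered
#' pairs of `entries` when `pairs` is omitted.
#'
#' @param entries Named or unnamed list of [reaction_entry()]s.
#' @param pairs Optional two-column matrix (or data frame) of entry indices
#'   or ids; default: all unordered pairs.
#' @param rotations Passed to [compare_pair()].
#' @return List of `"pair_comparison"` objects.
#' @export
compare_all <- function(entries, pairs = NULL,
                        rotations = c("whitelist", "none", "all")) {
  rotations <- match.arg(rotations)
  ids <- vapply(entries, `[[`, "", "id")
  if (is.null(pairs)) {
    if (length(entries) < 2L) return(list())
    pairs <- t(utils::combn(length(entries), 2L))
  }
  pairs <- as.matrix(pairs)
  if (is.character(pairs)) {
    pairs <- matrix(match(pairs, ids), ncol = 2L)
    if (anyNA(pairs)) stop("unknown entry id in pairs", call. = FALSE)
  }
  lapply(seq_len(nrow(pairs)), function(k) {
    compare_pair(entries[[pairs[k, 1L]]], entries[[pairs[k, 2L]]],
                 rotations = rotations)
  })
}

#' Tabulate pair comparisons
#'
#' Flattens a list of `"pair_comparison"` objects into a data frame with one
#' row per pair, sorted by id pair for deterministic output.
#'
#' @param results List of `"pair_comparison"` objects.
#' @return Data frame with score, direction, rotation and identical-step
#'   columns.
#' @export
pairwise_table <- function(results) {
  if (length(results) == 0L) {
    return(data.frame(
      id_1 = character(), id_2 = character(), ec_1 = character(),
      ec_2 = character(), overall_raw = numeric(),
      overall_norm = numeric(), mech_raw = numeric(), mech_norm = numeric(),
      overall_direction = character(), direction = character(),
      rotation_1 = integer(), rotation_2 = integer(),
      n_identical_steps_all = integer(),
      n_identical_steps_in_alignment = integer(),
      stringsAsFactors = FALSE))
  }
  df <- do.call(rbind, lapply(results, function(x) {
    data.frame(
      id_1 = x$id_1, id_2 = x$id_2, ec_1 = x$ec_1, ec_2 = x$ec_2,
      overall_raw = x$overall_raw, overall_norm = x$overall_normalized,
      mech_raw = x$mechanistic_raw, mech_norm = x$mechanistic_normalized,
      overall_direction = x$overall_direction,
      direction = x$best_direction,
      rotation_1 = x$best_rotations[1L], rotation_2 = x$best_rotations[2L],
      n_identical_steps_all = nrow(x$identical_steps_all),
      n_identical_steps_in_alignment =
        nrow(x$identical_steps_in_alignment),
      stringsAsFactors = FALSE)
  }))
  df[order(df$id_1, df$id_2), , drop = FALSE]
}
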