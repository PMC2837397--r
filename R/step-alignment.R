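# Mechanism-level comparison: per-step similarity matrix, global alignment
# with unpenalised gaps, mechanistic Tanimoto, local alignment, circular
# permutations, and identical-step detection.

.mech_steps <- function(m) {
  if (inherits(m, "reaction_entry")) m$mechanism else m
}

#' Step-by-step similarity matrix between two mechanisms
#'
#' Cell `(i, j)` holds the Tanimoto coefficient between the bond-change set
#' of step i of the first mechanism and step j of the second. Steps with
#' empty change sets score 0 against everything (flagged with a message),
#' so that the alignment machinery never divides by zero.
#'
#' @param m1,m2 Mechanisms: lists of [mechanistic_step()]s or
#'   [reaction_entry()]s (their mechanisms are used). Spontaneous steps are
#'   expected to have been removed already.
#' @return Numeric matrix of dimension `length(m1) x length(m2)`.
#' @export
step_matrix <- function(m1, m2) {
  s1 <- .mech_steps(m1)
  s2 <- .mech_steps(m2)
  if (length(s1) == 0L || length(s2) == 0L) {
    stop("cannot build a step similarity matrix for an empty mechanism",
         call. = FALSE)
  }
  c1 <- lapply(s1, function(s) unclass(s$changes))
  c2 <- lapply(s2, function(s) unclass(s$changes))
  empty1 <- vapply(c1, length, 0L) == 0L
  empty2 <- vapply(c2, length, 0L) == 0L
  if (any(empty1) || any(empty2)) {
    message("mechanistic step(s) with no bond changes score 0 ",
            "against all steps")
  }
  M <- matrix(0, nrow = length(c1), ncol = length(c2))
  for (i in seq_along(c1)) {
    if (empty1[i]) next
    for (j in seq_along(c2)) {
      if (empty2[j]) next
      M[i, j] <- .tanimoto_raw(c1[[i]], c2[[j]])
    }
  }
  M
}

#' Global alignment of mechanistic steps (unpenalised gaps)
#'
#' Needleman-Wunsch dynamic programming over a step-similarity matrix with
#' zero gap-opening and gap-extension penalties:
#' `H(i,j) = max(H(i-1,j-1) + M(i,j), H(i-1,j), H(i,j-1))`.
#' Gaps are free because there is no model for how insertion or deletion of
#' mechanistic steps should be penalised. The optimal score is unique; the
#' path may not be, so traceback ties are broken deterministically
#' (diagonal, then up, then left). Matched pairs whose cell value is 0 carry
#' no similarity and are dropped from `matched`.
#'
#' @param M Step-similarity matrix from [step_matrix()].
#' @return List of class `"step_alignment"` with elements `score` (the
#'   optimal total similarity), `matched` (two-column matrix of aligned step
#'   index pairs, strictly increasing in both columns) and `mode = "global"`.
#' @export
global_align <- function(M) {
  stopifnot(is.matrix(M), all(M >= -1e-12), all(M <= 1 + 1e-12))
  n1 <- nrow(M)
  n2 <- ncol(M)
  H <- matrix(0, n1 + 1L, n2 + 1L)
  for (i in seq_len(n1)) {
    for (j in seq_len(n2)) {
      H[i + 1L, j + 1L] <- max(H[i, j] + M[i, j], H[i, j + 1L], H[i + 1L, j])
    }
  }
  # traceback, diagonal preferred, then up, then left
  i <- n1
  j <- n2
  pairs <- NULL
  eps <- 1e-12
  while (i > 0L && j > 0L) {
    h <- H[i + 1L, j + 1L]
    if (abs(h - (H[i, j] + M[i, j])) < eps) {
      if (M[i, j] > eps) pairs <- rbind(c(i, j), pairs)
      i <- i - 1L
      j <- j - 1L
    } else if (abs(h - H[i, j + 1L]) < eps) {
      i <- i - 1L
    } else {
      j <- j - 1L
    }
  }
  if (is.null(pairs)) pairs <- matrix(integer(), ncol = 2L)
  colnames(pairs) <- c("i", "j")
  structure(list(score = H[n1 + 1L, n2 + 1L], matched = pairs,
                 mode = "global"),
            class = "step_alignment")
}

#' @export
print.step_alignment <- function(x, ...) {
  cat("<step_alignment:", x$mode, "> score", format(x$score, digits = 6),
      "with", nrow(x$matched), "matched step pair(s)\n")
  if (nrow(x$matched) > 0L) {
    cat(paste0("  ", x$matched[, 1L], " ~ ", x$matched[, 2L]), sep = "\n")
  }
  invisible(x)
}

#' Mechanistic Tanimoto coefficient from an alignment score
#'
#' Treats the global alignment score S as the "shared" part of the two
#' mechanisms and their step counts as set sizes: `S / (n1 + n2 - S)`.
#' Equals 1 only for two identical mechanisms aligned perfectly.
#'
#' @param S Global alignment score, in `[0, min(n1, n2)]`.
#' @param n1,n2 Step counts of the two mechanisms.
#' @return Numeric similarity in `[0, 1]`.
#' @export
mechanistic_tanimoto <- function(S, n1, n2) {
  .check_cardinality(n1)
  .check_cardinality(n2)
  if (S < -1e-12 || S > min(n1, n2) + 1e-12) {
    stop("alignment score ", S, " outside [0, min(n1, n2)] for step counts ",
         n1, ", ", n2, call. = FALSE)
  }
  S / (n1 + n2 - S)
}

#' Maximum attainable mechanistic similarity for two step counts
#'
#' If every step of the shorter mechanism were identical to a step of the
#' longer one, the alignment score would be `m = min(n1, n2)` and the
#' mechanistic Tanimoto `m / (n1 + n2 - m)`. Used as the divisor for the
#' normalized mechanistic similarity, so that mechanisms differing mainly
#' in step count (e.g. a 3-step vs a 9-step route to the same chemistry)
#' are not penalised for the length mismatch itself.
#'
#' @param n1,n2 Positive step counts.
#' @return Numeric bound in `(0, 1]`.
#' @export
max_possible_mechanistic <- function(n1, n2) {
  .check_cardinality(n1)
  .check_cardinality(n2)
  m <- min(n1, n2)
  m / (n1 + n2 - m)
}

#' All circular permutations of a mechanism
#'
#' An n-step mechanism has n rotations (offsets 0 to n-1); offset r starts
#' the sequence at original step r+1 while preserving the internal order.
#' Offset 0 is the original mechanism.
#'
#' @param m A mechanism (list of [mechanistic_step()]s or a
#'   [reaction_entry()]).
#' @return List of mechanisms, one per offset, named by offset.
#' @export
rotations <- function(m) {
  steps <- .mech_steps(m)
  n <- length(steps)
  if (n == 0L) stop("cannot rotate an empty mechanism", call. = FALSE)
  out <- lapply(0:(n - 1L), function(r) .rotate_mechanism(steps, r))
  names(out) <- as.character(0:(n - 1L))
  out
}

.rotate_mechanism <- function(steps, offset) {
  n <- length(steps)
  offset <- offset %% n
  if (offset == 0L) return(steps)
  idx <- c((offset + 1L):n, 1L:offset)
  lapply(seq_len(n), function(k) {
    s <- steps[[idx[k]]]
    mechanistic_step(k, s$changes, s$spontaneous)
  })
}

#' Find all identical step pairs between two mechanisms
#'
#' Enumerates every pair of steps whose bond-change sets are identical
#' (Tanimoto coefficient exactly 1), both with the mechanisms as given
#' (forward) and with the second mechanism reversed (step order reversed and
#' bond changes inverted). Step indices always refer to the mechanisms as
#' given; empty steps are never reported.
#'
#' @param m1,m2 Mechanisms or [reaction_entry()]s.
#' @return Data frame with columns `i`, `j`, `direction`
#'   (`"forward"`/`"reversed"`); zero rows if no identical pairs exist.
#' @export
find_identical_steps <- function(m1, m2) {
  s1 <- .mech_steps(m1)
  s2 <- .mech_steps(m2)
  n2 <- length(s2)
  hits <- list()
  scan <- function(steps2, direction) {
    for (i in seq_along(s1)) {
      a <- unclass(s1[[i]]$changes)
      if (length(a) == 0L) next
      for (j in seq_along(steps2)) {
        b <- unclass(steps2[[j]]$changes)
        if (length(b) == 0L) next
        if (length(a) == length(b) && all(a == b)) {
          j_orig <- if (direction == "reversed") n2 + 1L - j else j
          hits[[length(hits) + 1L]] <<- data.frame(
            i = i, j = j_orig, direction = direction,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  scan(s2, "forward")
  scan(.reverse_mechanism(s2), "reversed")
  if (length(hits) == 0L) {
    return(data.frame(i = integer(), j = integer(),
                      direction = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, hits)
}

#' Local alignment of mechanistic steps (Smith-Waterman)
#'
#' Standard local dynamic programming on shifted scores
#' `s(i,j) = M(i,j) - mismatch_offset` with a floor at zero:
#' `H(i,j) = max(0, H(i-1,j-1) + s(i,j), H(i-1,j) - gap, H(i,j-1) - gap)`.
#' The default offset of 0.5 makes a dissimilar step pair (Tc below 0.5)
#' terminate a block while an isolated identical step still stands out;
#' gaps are free, consistent with the global alignment.
#'
#' @param M Step-similarity matrix.
#' @param mismatch_offset Subtracted from every cell before the DP
#'   (default 0.5).
#' @param gap_penalty Penalty per gap move (default 0).
#' @return A `"step_alignment"` with `mode = "local"`: the best-scoring
#'   block's score and its matched pairs (diagonal moves with positive
#'   shifted score).
#' @export
local_align <- function(M, mismatch_offset = 0.5, gap_penalty = 0) {
  stopifnot(is.matrix(M), mismatch_offset >= 0, gap_penalty >= 0)
  n1 <- nrow(M)
  n2 <- ncol(M)
  s <- M - mismatch_offset
  H <- matrix(0, n1 + 1L, n2 + 1L)
  best <- 0
  best_ij <- c(0L, 0L)
  for (i in seq_len(n1)) {
    for (j in seq_len(n2)) {
      h <- max(0, H[i, j] + s[i, j],
               H[i, j + 1L] - gap_penalty, H[i + 1L, j] - gap_penalty)
      H[i + 1L, j + 1L] <- h
      if (h > best + 1e-12) {
        best <- h
        best_ij <- c(i, j)
      }
    }
  }
  pairs <- matrix(integer(), ncol = 2L)
  if (best > 0) {
    i <- best_ij[1L]
    j <- best_ij[2L]
    eps <- 1e-12
    while (i > 0L && j > 0L && H[i + 1L, j + 1L] > eps) {
      h <- H[i + 1L, j + 1L]
      if (abs(h - (H[i, j] + s[i, j])) < eps) {
        if (s[i, j] > eps) pairs <- rbind(c(i, j), pairs)
        i <- i - 1L
        j <- j - 1L
      } else if (abs(h - (H[i, j + 1L] - gap_penalty)) < eps) {
        i <- i - 1L
      } else {
        j <- j - 1L
      }
    }
  }
  colnames(pairs) <- c("i", "j")
  structure(list(score = best, matched = pairs, mode = "local"),
            class = "step_alignment")
}
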