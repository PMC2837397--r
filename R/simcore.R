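# Set-level similarity: Tanimoto coefficient, the maximum coefficient
# attainable for two set sizes, and size-normalized similarity.

#' Tanimoto coefficient between two bond-change sets
#'
#' `|A n B| / |A u B|`. Symmetric; 1 exactly when the sets are equal and
#' non-empty; 0 when they are disjoint. Two empty sets have no defined
#' similarity (change-free reactions are excluded upstream) and raise an
#' error.
#'
#' @param a,b Bond-change sets ([bond_change_set()] or token vectors).
#' @return Numeric similarity in `[0, 1]`.
#' @export
tanimoto <- function(a, b) {
  a <- unclass(.as_change_set(a))
  b <- unclass(.as_change_set(b))
  if (length(a) == 0L && length(b) == 0L) {
    stop("Tanimoto similarity of two empty bond-change sets is undefined",
         call. = FALSE)
  }
  n_int <- length(intersect(a, b))
  n_int / (length(a) + length(b) - n_int)
}

# fast path for internal callers holding already-canonical token vectors
.tanimoto_raw <- function(a, b) {
  n_int <- sum(a %in% b)
  n_int / (length(a) + length(b) - n_int)
}

#' Maximum attainable Tanimoto coefficient for two set sizes
#'
#' If the smaller set were entirely contained in the larger, the Tanimoto
#' coefficient would be `min / (min + max - min) = min/max`; no pair of sets
#' with these cardinalities can score higher. Two overall reactions with
#' three and five bond changes, for instance, can reach at most
#' 0.6000 = 3/(3+5-3). Used as the divisor for size-normalized similarity.
#'
#' @param n_a,n_b Positive set cardinalities.
#' @return Numeric bound in `(0, 1]`; 1 iff `n_a == n_b`.
#' @export
max_possible_tanimoto <- function(n_a, n_b) {
  .check_cardinality(n_a)
  .check_cardinality(n_b)
  m <- min(n_a, n_b)
  m / (n_a + n_b - m)
}

.check_cardinality <- function(n) {
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 1 ||
      n != as.integer(n)) {
    stop("set cardinality must be a positive integer, got: ", deparse(n),
         call. = FALSE)
  }
}

#' Size-normalized similarity score
#'
#' Divides a raw Tanimoto-type score by the maximum score attainable given
#' the two set sizes, so that a perfect subset relation scores 1 regardless
#' of the size mismatch. Reactions (or mechanisms) differing mainly in how
#' many changes (or steps) they contain are thereby not penalized for the
#' size difference itself.
#'
#' @param score Raw similarity in `[0, max_possible_tanimoto(n_a, n_b)]`.
#' @param n_a,n_b The two set cardinalities.
#' @return Normalized score in `[score, 1]`.
#' @export
normalize_similarity <- function(score, n_a, n_b) {
  max_tc <- max_possible_tanimoto(n_a, n_b)
  if (score < 0 || score > max_tc + 1e-12) {
    stop("raw score ", score, " exceeds the maximum attainable similarity ",
         max_tc, " for sizes ", n_a, " and ", n_b, call. = FALSE)
  }
  min(score / max_tc, 1)
}
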