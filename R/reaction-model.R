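# Canonical representation of bond changes, mechanistic steps and reaction
# entries, plus the preprocessing rules applied before any similarity
# computation (stereochemistry records, spontaneous steps, reversal).

# Periodic-table element symbols accepted in bond descriptors.
.ELEMENTS <- c(
  "H", "He", "Li", "Be", "B", "C", "N", "O", "F", "Ne", "Na", "Mg", "Al",
  "Si", "P", "S", "Cl", "Ar", "K", "Ca", "Sc", "Ti", "V", "Cr", "Mn", "Fe",
  "Co", "Ni", "Cu", "Zn", "Ga", "Ge", "As", "Se", "Br", "Kr", "Rb", "Sr",
  "Y", "Zr", "Nb", "Mo", "Tc", "Ru", "Rh", "Pd", "Ag", "Cd", "In", "Sn",
  "Sb", "Te", "I", "Xe", "Cs", "Ba", "La", "Ce", "Pr", "Nd", "Pm", "Sm",
  "Eu", "Gd", "Tb", "Dy", "Ho", "Er", "Tm", "Yb", "Lu", "Hf", "Ta", "W",
  "Re", "Os", "Ir", "Pt", "Au", "Hg", "Tl", "Pb", "Bi", "Po", "At", "Rn",
  "Fr", "Ra", "Ac", "Th", "Pa", "U", "Np", "Pu"
)

# Bond-change kinds: f = formed, c = cleaved, i = order increased,
# d = order decreased. "involved" (stereochemistry) is accepted on input
# only and stripped by strip_stereo().
.KINDS <- c("f", "c", "i", "d")
.KIND_NAMES <- c(
  formed = "f", cleaved = "c",
  order_increased = "i", order_decreased = "d"
)
.REVERSE_KIND <- c(f = "c", c = "f", i = "d", d = "i")

#' Canonicalize a chemical bond as an unordered element pair
#'
#' Bonds carry no direction: a C-O bond and an O-C bond are the same bond.
#' The canonical form orders the two element symbols lexicographically, so
#' every downstream set operation can compare bonds as plain strings.
#'
#' @param e1,e2 Element symbols (e.g. `"C"`, `"O"`, `"Cl"`).
#' @return Character vector of length 2 with the symbols in canonical order.
#' @examples
#' canonicalize_bond("O", "C")   # c("C", "O")
#' canonicalize_bond("Cl", "C")  # c("C", "Cl")
#' @export
canonicalize_bond <- function(e1, e2) {
  for (e in c(e1, e2)) {
    if (!is.character(e) || length(e) != 1L || is.na(e) || !nzchar(e)) {
      stop("bond element symbol must be a non-empty string, got: ",
           deparse(e), call. = FALSE)
    }
    if (!e %in% .ELEMENTS) {
      stop("unknown element symbol: '", e, "'", call. = FALSE)
    }
  }
  sort(c(e1, e2), method = "radix")
}

#' Construct a single bond change
#'
#' A bond change is the atom of all similarity computation here: a kind
#' (formed, cleaved, order increased, order decreased) attached to an
#' unordered element pair. Atom types are not differentiated beyond the
#' element symbol, so e.g. an aromatic and an aliphatic carbon are identical.
#'
#' @param kind One of `"f"`, `"c"`, `"i"`, `"d"` or the long names
#'   `"formed"`, `"cleaved"`, `"order_increased"`, `"order_decreased"`.
#' @param e1,e2 Element symbols of the bond.
#' @return A canonical token string of the form `"f:C-O"`.
#' @export
bond_change <- function(kind, e1, e2) {
  k <- .normalize_kind(kind)
  b <- canonicalize_bond(e1, e2)
  paste0(k, ":", b[1L], "-", b[2L])
}

.normalize_kind <- function(kind) {
  if (!is.character(kind) || length(kind) != 1L || is.na(kind)) {
    stop("bond-change kind must be a single string", call. = FALSE)
  }
  if (kind %in% .KINDS) return(kind)
  if (kind %in% names(.KIND_NAMES)) return(unname(.KIND_NAMES[kind]))
  stop("unknown bond-change kind token: '", kind, "'", call. = FALSE)
}

# Parse a change token like "f:C-O" (or "involved:C-C") into its parts.
.parse_change_token <- function(token) {
  m <- regmatches(token, regexec("^([A-Za-z_]+):([A-Za-z]+)-([A-Za-z]+)$",
                                 token))[[1L]]
  if (length(m) != 4L) {
    stop("malformed bond-change token: '", token,
         "' (expected 'kind:El1-El2')", call. = FALSE)
  }
  list(kind = m[2L], e1 = m[3L], e2 = m[4L])
}

#' Construct a set of bond changes
#'
#' Collections of bond changes are sets, not multisets: repeated identical
#' changes are merged (with a warning) because the Tanimoto formulation
#' counts each distinct change once.
#'
#' @param tokens Character vector of change tokens (`"f:C-O"` style), long
#'   or short kind names accepted. May be empty.
#' @return Sorted character vector of canonical tokens, class
#'   `"bond_change_set"`.
#' @export
bond_change_set <- function(tokens = character()) {
  if (length(tokens) == 0L) {
    return(structure(character(), class = "bond_change_set"))
  }
  parsed <- lapply(tokens, .parse_change_token)
  canon <- vapply(parsed, function(p) bond_change(p$kind, p$e1, p$e2), "")
  if (anyDuplicated(canon)) {
    warning("duplicate bond changes merged: ",
            paste(unique(canon[duplicated(canon)]), collapse = ", "),
            call. = FALSE)
    canon <- unique(canon)
  }
  structure(sort(canon, method = "radix"), class = "bond_change_set")
}

.as_change_set <- function(x) {
  if (inherits(x, "bond_change_set")) return(x)
  bond_change_set(x)
}

#' @export
print.bond_change_set <- function(x, ...) {
  if (length(x) == 0L) {
    cat("<bond_change_set: empty>\n")
  } else {
    cat("<bond_change_set>", paste(unclass(x), collapse = " "), "\n")
  }
  invisible(x)
}

#' Invert a set of bond changes (reaction reversal)
#'
#' Running a reaction backwards turns each bond formation into a cleavage
#' and each order increase into a decrease, and vice versa. The operation
#' is an involution: applying it twice restores the input.
#'
#' @param changes A [bond_change_set()] (or character vector of tokens).
#' @return A `bond_change_set` of the same size with kinds swapped.
#' @export
reverse_changes <- function(changes) {
  changes <- .as_change_set(changes)
  if (length(changes) == 0L) return(changes)
  kinds <- substr(changes, 1L, 1L)
  bonds <- substring(changes, 3L)
  out <- paste0(.REVERSE_KIND[kinds], ":", bonds)
  structure(sort(out, method = "radix"), class = "bond_change_set")
}

#' Drop stereochemistry-only records from raw bond-change input
#'
#' Source databases annotate a fifth record kind, "bonds involved": bonds
#' that change stereochemistry during the overall reaction. Stereochemistry
#' changes are always the net result of elementary formations, cleavages and
#' order changes, so these records carry no independent information and are
#' removed (curated inputs are expected to already contain the elementary
#' replacements).
#'
#' @param raw_tokens Character vector of change tokens; the kind `"involved"`
#'   is accepted here and only here.
#' @return A [bond_change_set()] of the remaining elementary changes.
#' @export
strip_stereo <- function(raw_tokens) {
  if (length(raw_tokens) == 0L) return(bond_change_set())
  parsed <- lapply(raw_tokens, .parse_change_token)
  kinds <- vapply(parsed, `[[`, "", "kind")
  stereo <- kinds == "involved"
  bad <- !stereo & !kinds %in% c(.KINDS, names(.KIND_NAMES))
  if (any(bad)) {
    stop("unknown bond-change kind token: '", kinds[bad][1L], "'",
         call. = FALSE)
  }
  if (any(stereo)) {
    warning(sum(stereo), " stereochemistry-only ('involved') record(s) ",
            "removed", call. = FALSE)
  }
  kept <- raw_tokens[!stereo]
  suppressWarnings(bond_change_set(kept))
}

#' Construct one mechanistic step
#'
#' @param index 1-based position of the step within its mechanism.
#' @param changes Bond changes of the step (tokens or [bond_change_set()]).
#' @param spontaneous Whether the step proceeds without enzyme catalysis
#'   (such steps are excluded from similarity calculations).
#' @return A list of class `"mechanistic_step"`.
#' @export
mechanistic_step <- function(index, changes = character(),
                             spontaneous = FALSE) {
  stopifnot(is.numeric(index), length(index) == 1L, index >= 1,
            index == as.integer(index),
            is.logical(spontaneous), length(spontaneous) == 1L)
  structure(
    list(index = as.integer(index), changes = .as_change_set(changes),
         spontaneous = spontaneous),
    class = "mechanistic_step"
  )
}

#' Construct a reaction entry
#'
#' A reaction entry bundles everything needed to compare two enzymes: the
#' identifier, the 4-level EC code (the first three components form the
#' sub-subclass, conventionally read as the reaction chemistry), the
#' structural superfamily codes used to detect homology, the overall
#' reaction as a set of bond changes, and the ordered mechanism.
#'
#' @param id Identifier string (e.g. `"M0044"`).
#' @param ec EC code with exactly four dot-separated components.
#' @param superfamilies Character vector of structural-superfamily codes
#'   (CATH-style strings); may be empty.
#' @param overall Overall bond-change set (tokens or [bond_change_set()]).
#'   May be empty, in which case the entry is flagged change-free.
#' @param mechanism List of [mechanistic_step()]s, or a list of character
#'   vectors of tokens (then taken as non-spontaneous steps in order).
#' @param permutation_allowed Whether circular permutation of the step
#'   sequence is admissible for this mechanism (curated whitelist).
#' @return A list of class `"reaction_entry"`.
#' @export
reaction_entry <- function(id, ec, superfamilies = character(),
                           overall = character(), mechanism = list(),
                           permutation_allowed = FALSE) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  ec_parts <- strsplit(ec, ".", fixed = TRUE)[[1L]]
  if (length(ec_parts) != 4L || !all(nzchar(ec_parts))) {
    stop("EC code must have exactly 4 dot-separated components, got '",
         ec, "'", call. = FALSE)
  }
  steps <- vector("list", length(mechanism))
  for (k in seq_along(mechanism)) {
    s <- mechanism[[k]]
    if (inherits(s, "mechanistic_step")) {
      if (s$index != k) {
        stop("mechanism step indices must be consecutive from 1; step ", k,
             " carries index ", s$index, call. = FALSE)
      }
      steps[[k]] <- s
    } else {
      steps[[k]] <- mechanistic_step(k, s)
    }
  }
  structure(
    list(id = id, ec = ec,
         superfamilies = sort(unique(as.character(superfamilies))),
         overall = .as_change_set(overall),
         mechanism = steps,
         permutation_allowed = isTRUE(permutation_allowed)),
    class = "reaction_entry"
  )
}

#' @export
print.reaction_entry <- function(x, ...) {
  cat("<reaction_entry>", x$id, " EC:", x$ec,
      " superfamilies:", length(x$superfamilies),
      "\n  overall: ", length(x$overall), " bond change(s)",
      "\n  mechanism: ", length(x$mechanism), " step(s)",
      if (any(vapply(x$mechanism, `[[`, TRUE, "spontaneous")))
        " (includes spontaneous)" else "",
      if (x$permutation_allowed) "\n  circular permutation allowed" else "",
      "\n", sep = "")
  invisible(x)
}

#' EC sub-subclass (first three EC components) of an entry or code
#' @param ec An EC code string or a `reaction_entry`.
#' @return The sub-subclass string, e.g. `"3.1.3"`.
#' @export
ec_sub_subclass <- function(ec) {
  if (inherits(ec, "reaction_entry")) ec <- ec$ec
  paste(strsplit(ec, ".", fixed = TRUE)[[1L]][1:3], collapse = ".")
}

#' Remove spontaneous steps and re-annotate the overall reaction
#'
#' Non-enzymatic steps (spontaneous substrate formation or product release)
#' obscure the similarity of the catalysed chemistry, so they are removed
#' from the mechanism before comparison, and the overall reaction is
#' re-annotated to exclude the bond changes occurring in them. A change
#' appearing in both a spontaneous and a non-spontaneous step is still
#' removed from the overall set (conservative; a message flags it).
#'
#' @param entry A [reaction_entry()].
#' @return The entry with spontaneous steps dropped and steps re-indexed.
#' @export
strip_spontaneous <- function(entry) {
  stopifnot(inherits(entry, "reaction_entry"))
  spont <- vapply(entry$mechanism, `[[`, TRUE, "spontaneous")
  if (!any(spont)) return(entry)
  if (all(spont)) {
    stop("entry '", entry$id, "': all mechanistic steps are spontaneous; ",
         "no mechanism left to compare", call. = FALSE)
  }
  removed <- unique(unlist(lapply(entry$mechanism[spont],
                                  function(s) unclass(s$changes))))
  kept_steps <- entry$mechanism[!spont]
  shared <- intersect(
    removed,
    unique(unlist(lapply(kept_steps, function(s) unclass(s$changes))))
  )
  if (length(shared) > 0L) {
    message("entry '", entry$id, "': change(s) ",
            paste(shared, collapse = ", "),
            " occur in both spontaneous and catalysed steps; ",
            "removed from the overall reaction")
  }
  entry$overall <- structure(setdiff(unclass(entry$overall), removed),
                             class = "bond_change_set")
  entry$mechanism <- lapply(seq_along(kept_steps), function(k) {
    s <- kept_steps[[k]]
    s$index <- k
    s
  })
  entry
}

# Reverse a mechanism: step order reversed, bond changes inverted.
.reverse_mechanism <- function(steps) {
  n <- length(steps)
  lapply(seq_len(n), function(k) {
    s <- steps[[n + 1L - k]]
    mechanistic_step(k, reverse_changes(s$changes), s$spontaneous)
  })
}

#' Reverse a reaction entry
#'
#' Produces the entry as it would read in the opposite reaction direction:
#' the overall bond changes inverted, the mechanism's step order reversed
#' and every step's bond changes inverted.
#'
#' @param entry A [reaction_entry()].
#' @return The reversed `reaction_entry`.
#' @export
reverse_entry <- function(entry) {
  stopifnot(inherits(entry, "reaction_entry"))
  entry$overall <- reverse_changes(entry$overall)
  entry$mechanism <- .reverse_mechanism(entry$mechanism)
  entry
}
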