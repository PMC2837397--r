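# Seeded synthetic-reaction generator: random entries, perturbed analogs
# and non-redundant background ensembles, so the whole pipeline is testable
# without any external data.

#' Configuration for the synthetic-reaction generator
#'
#' The default bond repertoire is weighted toward the bond types most common
#' in enzyme catalysis (O-H, C-O, N-H, C-C, C-N, C-H, P-O in decreasing
#' order, plus a tail of rarer bonds), formations and cleavages are four
#' times as likely as order changes, and mechanisms have 2-8 steps of 1-5
#' bond changes each -- the shape of curated catalytic mechanisms.
#'
#' @param repertoire Data frame with columns `bond` (canonical `"El1-El2"`
#'   strings) and `weight` (positive sampling weights).
#' @param n_steps Integer range (length 2) of steps per mechanism.
#' @param changes_per_step Integer range (length 2) of bond changes per
#'   step.
#' @param p_insert,p_delete,p_swap Per-step perturbation rates used by
#'   [perturbed_analog()].
#' @param kind_weights Sampling weights for the change kinds f, c, i, d.
#' @return List of class `"generator_config"`.
#' @export
generator_config <- function(
    repertoire = data.frame(
      bond = c("H-O", "C-O", "H-N", "C-C", "C-N", "C-H", "O-P",
               "C-S", "H-S", "N-O", "C-Cl", "O-S"),
      weight = c(10, 9, 8, 7, 6, 5, 4, 2, 2, 1, 1, 1),
      stringsAsFactors = FALSE),
    n_steps = c(2L, 8L),
    changes_per_step = c(1L, 5L),
    p_insert = 0.1, p_delete = 0.1, p_swap = 0.1,
    kind_weights = c(f = 4, c = 4, i = 1, d = 1)) {
  stopifnot(is.data.frame(repertoire),
            all(c("bond", "weight") %in% names(repertoire)),
            nrow(repertoire) >= 1L, all(repertoire$weight > 0),
            length(n_steps) == 2L, n_steps[1L] >= 1L,
            n_steps[2L] >= n_steps[1L],
            length(changes_per_step) == 2L, changes_per_step[1L] >= 1L,
            changes_per_step[2L] >= changes_per_step[1L],
            p_insert >= 0, p_insert <= 1, p_delete >= 0, p_delete <= 1,
            p_swap >= 0, p_swap <= 1,
            all(names(kind_weights) == c("f", "c", "i", "d")),
            all(kind_weights > 0))
  # validate bonds once so generated tokens always parse
  for (b in repertoire$bond) {
    parts <- strsplit(b, "-", fixed = TRUE)[[1L]]
    if (length(parts) != 2L) {
      stop("repertoire bond '", b, "' is not of the form 'El1-El2'",
           call. = FALSE)
    }
    canon <- canonicalize_bond(parts[1L], parts[2L])
    if (!identical(parts, canon)) {
      stop("repertoire bond '", b, "' is not in canonical order ('",
           paste(canon, collapse = "-"), "')", call. = FALSE)
    }
  }
  structure(
    list(repertoire = repertoire, n_steps = as.integer(n_steps),
         changes_per_step = as.integer(changes_per_step),
         p_insert = p_insert, p_delete = p_delete, p_swap = p_swap,
         kind_weights = kind_weights),
    class = "generator_config"
  )
}

# Sample one set of distinct bond-change tokens from the repertoire.
.sample_change_set <- function(cfg, size) {
  combos <- as.vector(outer(names(cfg$kind_weights), cfg$repertoire$bond,
                            paste, sep = ":"))
  if (size > length(combos)) {
    stop("repertoire too small to draw ", size, " distinct bond changes",
         call. = FALSE)
  }
  w <- as.vector(outer(unname(cfg$kind_weights), cfg$repertoire$weight))
  sample(combos, size, prob = w)
}

.sample_range <- function(range) {
  if (range[1L] == range[2L]) range[1L]
  else sample(range[1L]:range[2L], 1L)
}

#' Derive an overall reaction from a mechanism by net-change cancellation
#'
#' The overall reaction is the union of the step bond changes with
#' transient events cancelled: a formation and a cleavage of the same bond
#' leave no net change (the intermediate bond exists only transiently), and
#' likewise an order increase cancels an order decrease. Counts are netted
#' per bond, so e.g. two formations and one cleavage leave one formation.
#'
#' @param mechanism List of [mechanistic_step()]s (or a
#'   [reaction_entry()]).
#' @return A [bond_change_set()]; may be empty (change-free reaction).
#' @export
derive_overall <- function(mechanism) {
  steps <- .mech_steps(mechanism)
  all_changes <- unlist(lapply(steps, function(s) unclass(s$changes)))
  if (length(all_changes) == 0L) return(bond_change_set())
  kinds <- substr(all_changes, 1L, 1L)
  bonds <- substring(all_changes, 3L)
  out <- character()
  for (b in unique(bonds)) {
    net_form <- sum(kinds == "f" & bonds == b) - sum(kinds == "c" & bonds == b)
    net_incr <- sum(kinds == "i" & bonds == b) - sum(kinds == "d" & bonds == b)
    if (net_form > 0L) out <- c(out, paste0("f:", b))
    if (net_form < 0L) out <- c(out, paste0("c:", b))
    if (net_incr > 0L) out <- c(out, paste0("i:", b))
    if (net_incr < 0L) out <- c(out, paste0("d:", b))
  }
  bond_change_set(out)
}

#' Generate one random reaction entry
#'
#' Samples a mechanism of random length with random per-step change sets
#' from the configured repertoire and derives the overall reaction by
#' net-change cancellation ([derive_overall()]). Deterministic under
#' `set.seed()`; a change-free overall reaction is flagged with a warning.
#'
#' @param cfg A [generator_config()].
#' @param id,ec,superfamilies Annotations for the entry.
#' @param permutation_allowed Passed through to [reaction_entry()].
#' @return A [reaction_entry()].
#' @export
random_entry <- function(cfg, id, ec, superfamilies = character(),
                         permutation_allowed = FALSE) {
  stopifnot(inherits(cfg, "generator_config"))
  n <- .sample_range(cfg$n_steps)
  mech <- lapply(seq_len(n), function(k) {
    mechanistic_step(k, .sample_change_set(
      cfg, .sample_range(cfg$changes_per_step)))
  })
  overall <- derive_overall(mech)
  if (length(overall) == 0L) {
    warning("generated entry '", id, "' is change-free: all bond changes ",
            "cancel in the overall reaction", call. = FALSE)
  }
  reaction_entry(id, ec, superfamilies, overall = overall,
                 mechanism = mech,
                 permutation_allowed = permutation_allowed)
}

#' Perturb an entry into a synthetic functional analog
#'
#' Copies an entry under a new identity and applies controlled
#' perturbations to its mechanism: step deletions, insertions of fresh
#' random steps, and within-step bond-change swaps, each at the configured
#' per-step rate (or at exact counts when given). The overall reaction is
#' re-derived from the perturbed mechanism, and the applied perturbation
#' counts are recorded in the `"perturbations"` attribute as ground truth.
#'
#' @param entry A [reaction_entry()].
#' @param cfg A [generator_config()] providing rates and the repertoire.
#' @param id Identifier of the analog (default: `<id>_analog`).
#' @param superfamilies Superfamily codes of the analog (an analog is
#'   non-homologous, so these should differ from the parent's).
#' @param n_delete,n_insert,n_swap Optional exact perturbation counts
#'   overriding the stochastic rates.
#' @return A [reaction_entry()] with attribute `"perturbations"`.
#' @export
perturbed_analog <- function(entry, cfg, id = paste0(entry$id, "_analog"),
                             superfamilies = entry$superfamilies,
                             n_delete = NULL, n_insert = NULL,
                             n_swap = NULL) {
  stopifnot(inherits(entry, "reaction_entry"),
            inherits(cfg, "generator_config"))
  steps <- lapply(entry$mechanism, function(s) unclass(s$changes))
  n <- length(steps)

  # deletions (always leave at least one step)
  if (is.null(n_delete)) n_delete <- stats::rbinom(1L, n, cfg$p_delete)
  n_delete <- min(n_delete, n - 1L)
  if (n_delete > 0L) {
    steps <- steps[-sample.int(length(steps), n_delete)]
  }

  # insertions of fresh random steps at random positions
  if (is.null(n_insert)) {
    n_insert <- stats::rbinom(1L, length(steps), cfg$p_insert)
  }
  if (n_insert > 0L) {
    for (k in seq_len(n_insert)) {
      new_step <- .sample_change_set(
        cfg, .sample_range(cfg$changes_per_step))
      pos <- sample.int(length(steps) + 1L, 1L)
      steps <- append(steps, list(new_step), after = pos - 1L)
    }
  }

  # swaps: replace one change of a step with a fresh one not already there
  if (is.null(n_swap)) n_swap <- stats::rbinom(1L, length(steps), cfg$p_swap)
  n_swap <- min(n_swap, length(steps))
  if (n_swap > 0L) {
    for (k in sample.int(length(steps), n_swap)) {
      s <- steps[[k]]
      repl <- .sample_change_set(cfg, 1L)
      if (repl %in% s) next
      s[sample.int(length(s), 1L)] <- repl
      steps[[k]] <- s
    }
  }

  mech <- lapply(seq_along(steps), function(k) mechanistic_step(k, steps[[k]]))
  out <- reaction_entry(id, entry$ec, superfamilies,
                        overall = derive_overall(mech), mechanism = mech,
                        permutation_allowed = entry$permutation_allowed)
  attr(out, "perturbations") <- c(deleted = n_delete, inserted = n_insert,
                                  swapped = n_swap)
  out
}

#' Generate a non-redundant background ensemble
#'
#' Produces `k` entries with pairwise-distinct EC sub-subclasses and
#' superfamily codes and independently sampled chemistry: a synthetic null
#' in which any similarity arises only from the limited bond-type
#' repertoire. Change-free entries are resampled (mirroring the removal of
#' reactions without bond changes from empirical backgrounds).
#'
#' @param cfg A [generator_config()].
#' @param k Number of entries (>= 2).
#' @param seed Integer seed.
#' @return List of `k` [reaction_entry()]s.
#' @export
background_ensemble <- function(cfg, k, seed) {
  stopifnot(k >= 2L)
  set.seed(seed)
  lapply(seq_len(k), function(i) {
    repeat {
      e <- withCallingHandlers(
        random_entry(cfg, sprintf("B%04d", i),
                     sprintf("%d.%d.%d.%d", (i - 1L) %% 6L + 1L, i, i, 1L),
                     sprintf("9.%d.%d.10", i, i)),
        warning = function(w) invokeRestart("muffleWarning"))
      if (length(e$overall) > 0L) return(e)
    }
  })
}

#' Generate synthetic functional-analog pairs
#'
#' Each pair is a random entry plus a perturbed copy carrying the same EC
#' code but a different superfamily: a synthetic convergent pair whose
#' ground-truth relationship is known. Change-free parents are resampled.
#'
#' @param cfg A [generator_config()] (its perturbation rates apply).
#' @param n_pairs Number of pairs.
#' @param seed Integer seed.
#' @return List of `n_pairs` lists, each with elements `a` and `b`.
#' @export
analog_ensemble <- function(cfg, n_pairs, seed) {
  stopifnot(n_pairs >= 1L)
  set.seed(seed)
  lapply(seq_len(n_pairs), function(i) {
    repeat {
      a <- withCallingHandlers(
        random_entry(cfg, sprintf("A%04da", i),
                     sprintf("%d.%d.%d.%d", (i - 1L) %% 6L + 1L, i, i, 1L),
                     sprintf("1.%d.%d.10", i, i)),
        warning = function(w) invokeRestart("muffleWarning"))
      if (length(a$overall) == 0L) next
      b <- perturbed_analog(a, cfg, id = sprintf("A%04db", i),
                            superfamilies = sprintf("2.%d.%d.10", i, i))
      if (length(b$overall) > 0L) return(list(a = a, b = b))
    }
  })
}
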