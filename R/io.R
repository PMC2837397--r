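# Readers and writers for the reaction schema (JSON and TSV) and for the
# pairwise result table.

.KIND_IN <- c(f = "f", c = "c", i = "i", d = "d",
              formed = "f", cleaved = "c",
              order_increased = "i", order_decreased = "d",
              involved = "involved")

# Convert one JSON change record ({"kind": "f", "bond": ["C","O"]}) to a
# raw token; "involved" is preserved for strip_stereo to handle.
.json_change_token <- function(rec) {
  kind <- rec$kind
  if (is.null(kind) || !kind %in% names(.KIND_IN)) {
    stop("unknown bond-change kind token: '", kind, "'", call. = FALSE)
  }
  bond <- unlist(rec$bond)
  if (length(bond) != 2L) {
    stop("bond must list exactly two element symbols, got: ",
         paste(bond, collapse = ","), call. = FALSE)
  }
  paste0(.KIND_IN[[kind]], ":", bond[1L], "-", bond[2L])
}

.tsv_change_tokens <- function(field) {
  if (is.na(field) || !nzchar(field)) return(character())
  strsplit(field, ";", fixed = TRUE)[[1L]]
}

#' Read reaction entries from a JSON or TSV file
#'
#' JSON files hold an array of entry objects
#' (`{"id", "ec", "superfamilies", "overall", "mechanism",
#' "permutation_allowed"}` with changes as `{"kind", "bond"}` records);
#' TSV files hold one row per overall reaction or step with a
#' semicolon-joined change list such as `"f:C-O;c:H-O"`. Kinds are the
#' letters f (formed), c (cleaved), i (order increased), d (order
#' decreased); the stereochemistry kind `"involved"` is accepted on input
#' and stripped with a warning. Entries are validated and canonicalized;
#' duplicate ids are an error. A per-file summary is reported.
#'
#' @param path Path to a `.json` or `.tsv` file.
#' @param format `"auto"` (by extension), `"json"` or `"tsv"`.
#' @return List of [reaction_entry()]s.
#' @export
read_reactions <- function(path, format = c("auto", "json", "tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json"
              else "tsv"
  }
  entries <- if (format == "json") .read_json(path) else .read_tsv(path)
  ids <- vapply(entries, `[[`, "", "id")
  if (anyDuplicated(ids)) {
    stop("duplicate entry id(s) in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "),
         call. = FALSE)
  }
  n_steps <- sum(vapply(entries, function(e) length(e$mechanism), 0L))
  n_free <- sum(vapply(entries, function(e) length(e$overall) == 0L, TRUE))
  message("read ", length(entries), " entr(ies), ", n_steps, " step(s), ",
          n_free, " change-free overall reaction(s) from ", path)
  entries
}

.read_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(raw, function(rec) {
    for (field in c("id", "ec")) {
      if (is.null(rec[[field]])) {
        stop("record missing '", field, "' in JSON input", call. = FALSE)
      }
    }
    overall <- strip_stereo(
      vapply(rec$overall, .json_change_token, ""))
    mech <- lapply(seq_along(rec$mechanism), function(k) {
      s <- rec$mechanism[[k]]
      idx <- if (is.null(s$index)) k else s$index
      if (idx != k) {
        stop("entry '", rec$id, "': step indices must be consecutive ",
             "from 1", call. = FALSE)
      }
      mechanistic_step(
        k,
        strip_stereo(vapply(s$changes, .json_change_token, "")),
        isTRUE(s$spontaneous))
    })
    reaction_entry(rec$id, rec$ec,
                   unlist(rec$superfamilies),
                   overall = overall, mechanism = mech,
                   permutation_allowed = isTRUE(rec$permutation_allowed))
  })
}

.read_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  need <- c("id", "ec", "superfamilies", "part", "spontaneous",
            "permutation_allowed", "changes")
  if (!all(need %in% names(df))) {
    stop("TSV input must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  lapply(unique(df$id), function(one_id) {
    rows <- df[df$id == one_id, , drop = FALSE]
    ov <- rows[rows$part == "overall", , drop = FALSE]
    if (nrow(ov) > 1L) {
      stop("entry '", one_id, "': more than one 'overall' row",
           call. = FALSE)
    }
    overall <- if (nrow(ov) == 1L) {
      strip_stereo(.tsv_change_tokens(ov$changes))
    } else bond_change_set()
    st <- rows[rows$part != "overall", , drop = FALSE]
    idx <- as.integer(st$part)
    if (nrow(st) > 0L &&
        (anyNA(idx) || !identical(sort(idx), seq_len(nrow(st))))) {
      stop("entry '", one_id, "': step rows must be numbered consecutively ",
           "from 1", call. = FALSE)
    }
    st <- st[order(idx), , drop = FALSE]
    mech <- lapply(seq_len(nrow(st)), function(k) {
      mechanistic_step(
        k, strip_stereo(.tsv_change_tokens(st$changes[k])),
        st$spontaneous[k] %in% c("1", "true", "TRUE"))
    })
    sfs <- rows$superfamilies[1L]
    sfs <- if (is.na(sfs) || !nzchar(sfs)) character()
           else strsplit(sfs, ",", fixed = TRUE)[[1L]]
    reaction_entry(one_id, rows$ec[1L], sfs, overall = overall,
                   mechanism = mech,
                   permutation_allowed =
                     rows$permutation_allowed[1L] %in%
                       c("1", "true", "TRUE"))
  })
}

.change_to_json <- function(token) {
  p <- .parse_change_token(token)
  list(kind = p$kind, bond = c(p$e1, p$e2))
}

#' Write reaction entries to a JSON file
#'
#' Inverse of [read_reactions()]: a read/write round trip reproduces the
#' canonical entries bit-exactly.
#'
#' @param entries List of [reaction_entry()]s.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_reactions <- function(entries, path) {
  recs <- lapply(entries, function(e) {
    list(
      id = e$id, ec = e$ec,
      superfamilies = as.list(e$superfamilies),
      overall = lapply(unclass(e$overall), .change_to_json),
      mechanism = lapply(e$mechanism, function(s) {
        list(index = s$index, spontaneous = s$spontaneous,
             changes = lapply(unclass(s$changes), .change_to_json))
      }),
      permutation_allowed = e$permutation_allowed)
  })
  jsonlite::write_json(recs, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' Write a pairwise comparison table as TSV
#'
#' One row per compared pair, sorted by id pair for deterministic,
#' byte-reproducible output. Scores are printed at the configured decimal
#' precision (default 4); the file is tab-separated, UTF-8, unquoted.
#'
#' @param results List of `"pair_comparison"` objects.
#' @param path Output path.
#' @param labels Optional character vector of similarity labels, parallel
#'   to `results` (see [similarity_labels()]).
#' @param precision Decimal places for scores (default 4).
#' @return The path, invisibly.
#' @export
write_pairwise <- function(results, path, labels = NULL, precision = 4) {
  df <- pairwise_table(results)
  if (!is.null(labels)) {
    stopifnot(length(labels) == length(results))
    ord <- order(vapply(results, `[[`, "", "id_1"),
                 vapply(results, `[[`, "", "id_2"))
    df$label <- labels[ord]
  } else if (nrow(df) > 0L) {
    df$label <- ""
  } else {
    df$label <- character()
  }
  for (col in c("overall_raw", "overall_norm", "mech_raw", "mech_norm")) {
    df[[col]] <- formatC(df[[col]], digits = precision, format = "f")
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
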