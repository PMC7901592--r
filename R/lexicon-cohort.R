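#' Build an expanded concept lexicon from annotated candidates
#'
#' Starting from seed terms for each clinical concept, adds every returned
#' candidate whose (by default consensus) semantic label is "synonym", from
#' any embedding source. Terms are stored case-folded with underscore and
#' hyphen delimiters normalised to spaces, and each learned term records
#' the sources that proposed it.
#'
#' @param seed_concepts Named list: concept name -> character vector of
#'   seed terms. The concept's query terms must appear among the
#'   annotations' `query` values for synonyms to be learned (concepts with
#'   no annotated queries simply keep their seeds).
#' @param annotations Annotation tibble (`query`, `returned`, `source`,
#'   `annotator`, `label`). Every annotated query term must belong to some
#'   concept's seed set.
#' @param rule `"consensus"` (default): a candidate is a synonym when its
#'   consensus label is synonym; `"any"`: when any annotator labeled it
#'   synonym.
#' @return A `lexicon`: tibble with columns `concept`, `term`, `tag`
#'   (`"seed"` or `"learned"`) and `sources` (comma-separated contributing
#'   source names; empty for seeds).
#' @export
build_expanded_lexicon <- function(seed_concepts, annotations = NULL,
                                   rule = c("consensus", "any")) {
  rule <- match.arg(rule)
  if (length(seed_concepts) == 0 || is.null(names(seed_concepts))) {
    stop("`seed_concepts` must be a named list of concept -> seed terms",
         call. = FALSE)
  }
  seed_rows <- tibble::tibble(
    concept = rep(names(seed_concepts), lengths(seed_concepts)),
    term = normalize_term_key(unlist(seed_concepts, use.names = FALSE)),
    tag = "seed",
    sources = ""
  )
  if (any(!nzchar(seed_rows$term))) {
    stop("seed terms must be non-empty", call. = FALSE)
  }

  learned_rows <- NULL
  if (!is.null(annotations) && nrow(annotations) > 0) {
    assert_annotations(annotations)
    # map query surface forms back to their concept
    query_concept <- stats::setNames(
      rep(names(seed_concepts), lengths(seed_concepts)),
      normalize_term_key(unlist(seed_concepts, use.names = FALSE))
    )
    ann_concept <- query_concept[normalize_term_key(annotations$query)]
    if (anyNA(ann_concept)) {
      unknown <- unique(annotations$query[is.na(ann_concept)])
      stop(sprintf("annotations reference query terms outside the seed concepts: %s",
                   paste(utils::head(unknown, 5), collapse = ", ")), call. = FALSE)
    }
    syn <- if (rule == "consensus") {
      cons <- consensus_labels(annotations)
      cons_concept <- query_concept[normalize_term_key(cons$query)]
      cons[cons$label == "synonym", c("returned", "source")] |>
        dplyr::mutate(concept = cons_concept[cons$label == "synonym"])
    } else {
      tibble::tibble(
        returned = annotations$returned[annotations$label == "synonym"],
        source = annotations$source[annotations$label == "synonym"],
        concept = ann_concept[annotations$label == "synonym"]
      )
    }
    if (nrow(syn) > 0) {
      syn$term <- normalize_term_key(syn$returned)
      learned_rows <- syn |>
        dplyr::group_by(.data$concept, .data$term) |>
        dplyr::summarise(
          sources = paste(sort(unique(.data$source)), collapse = ","),
          .groups = "drop"
        ) |>
        dplyr::mutate(tag = "learned")
      # seeds take precedence over identical learned surface forms
      seed_key <- paste(seed_rows$concept, seed_rows$term, sep = "\r")
      learned_key <- paste(learned_rows$concept, learned_rows$term, sep = "\r")
      learned_rows <- learned_rows[!learned_key %in% seed_key,
                                   c("concept", "term", "tag", "sources")]
    }
  }

  lex <- dplyr::bind_rows(seed_rows, learned_rows)
  lex <- lex[order(lex$concept, lex$tag != "seed", lex$term), ]
  structure(lex, class = c("lexicon", class(lex)))
}

#' Terms of a lexicon for one concept
#'
#' @param lexicon A lexicon tibble.
#' @param concept Concept name.
#' @return Character vector of terms (seeds and learned).
#' @export
lexicon_terms <- function(lexicon, concept) {
  lexicon$term[lexicon$concept == concept]
}

#' Read / write lexicons
#'
#' Lexicons travel as tab-separated files with the header
#' `concept, term, tag, sources`.
#'
#' @param lexicon A lexicon tibble.
#' @param path File path.
#' @return `path` (write) or a lexicon (read).
#' @export
write_lexicon <- function(lexicon, path) {
  write_tsv_utf8(as.data.frame(lexicon[, c("concept", "term", "tag", "sources")]),
                 path)
}

#' @rdname write_lexicon
#' @export
read_lexicon <- function(path) {
  lex <- read_tsv_utf8(path, colClasses = "character")
  required <- c("concept", "term", "tag", "sources")
  if (!all(required %in% names(lex))) {
    stop("lexicon file must have columns concept, term, tag, sources",
         call. = FALSE)
  }
  lex$sources[is.na(lex$sources)] <- ""
  structure(lex, class = c("lexicon", class(lex)))
}

# word-boundary-safe regex for one lexicon term: case-insensitive, hyphen /
# underscore / single-space delimiter variants all match; underscore counts
# as a boundary character too, so "cough" never matches inside "coughing"
# or "dry_coughs"
term_pattern <- function(term) {
  tokens <- strsplit(normalize_term_key(term), " ", fixed = TRUE)[[1]]
  body <- paste(vapply(tokens, rex_escape, ""), collapse = "[ _-]")
  paste0("(?<![[:alnum:]])", body, "(?![[:alnum:]])")
}

rex_escape <- function(x) gsub("([][.\\\\|(){}^$*+?])", "\\\\\\1", x, perl = TRUE)

#' Match lexicon terms in patient notes
#'
#' A patient is positive for a concept when any of their notes contains
#' any of the concept's lexicon terms as a case-insensitive,
#' word-boundary-delimited contiguous phrase. Multi-word terms match
#' across single spaces only, and hyphen/underscore spellings of the
#' term's delimiters also match ("dry cough", "dry-cough", "dry_cough").
#' No stemming and no negation handling is applied: "coughing" does not
#' match "cough", and "no fever" still matches "fever".
#'
#' @param notes Tibble of patient notes with columns `patient_id`,
#'   `cohort`, `note_text`. A patient may have several rows; identical
#'   duplicated (patient_id, note_text) rows are rejected.
#' @param lexicon A lexicon tibble (see [build_expanded_lexicon()]).
#' @return Long tibble with one row per (patient, concept): columns
#'   `patient_id`, `cohort`, `concept`, `matched` (logical).
#' @export
match_features <- function(notes, lexicon) {
  required <- c("patient_id", "cohort", "note_text")
  if (!all(required %in% names(notes))) {
    stop("`notes` must have columns patient_id, cohort, note_text", call. = FALSE)
  }
  if (nrow(lexicon) == 0) stop("`lexicon` is empty", call. = FALSE)
  if (any(!nzchar(notes$patient_id) | is.na(notes$patient_id))) {
    stop("patient_id must be non-empty", call. = FALSE)
  }
  dup <- duplicated(paste(notes$patient_id, notes$note_text, sep = "\r"))
  if (any(dup)) {
    stop(sprintf("duplicate (patient, note) rows for patient(s): %s",
                 paste(unique(notes$patient_id[dup]), collapse = ", ")),
         call. = FALSE)
  }
  cohort_of <- notes$cohort[!duplicated(notes$patient_id)]
  names(cohort_of) <- notes$patient_id[!duplicated(notes$patient_id)]
  n_cohorts <- tapply(notes$cohort, notes$patient_id,
                      function(x) length(unique(x)))
  if (any(n_cohorts > 1)) {
    stop("each patient must belong to exactly one cohort", call. = FALSE)
  }

  concepts <- unique(lexicon$concept)
  patients <- names(cohort_of)
  text <- ifelse(is.na(notes$note_text), "", tolower(notes$note_text))

  out <- vector("list", length(concepts))
  for (ci in seq_along(concepts)) {
    terms <- lexicon_terms(lexicon, concepts[ci])
    pattern <- paste(vapply(terms, term_pattern, ""), collapse = "|")
    note_hit <- grepl(pattern, text, perl = TRUE)
    pat_hit <- as.vector(tapply(note_hit, notes$patient_id, any)[patients])
    out[[ci]] <- tibble::tibble(
      patient_id = patients,
      cohort = unname(cohort_of[patients]),
      concept = concepts[ci],
      matched = unname(pat_hit)
    )
  }
  dplyr::bind_rows(out)
}

#' Per-cohort feature-documentation proportions
#'
#' For each (cohort, concept), the fraction of the cohort's patients with
#' the concept documented in at least one note. The exact fraction is
#' reported together with its numerator and denominator; `proportion` is
#' additionally rounded to two decimals in [write_proportions()].
#'
#' @param match_table Output of [match_features()].
#' @return Tibble with columns `cohort`, `concept`, `numerator`,
#'   `denominator`, `proportion`.
#' @export
feature_proportions <- function(match_table) {
  required <- c("patient_id", "cohort", "concept", "matched")
  if (!all(required %in% names(match_table))) {
    stop("`match_table` must come from match_features()", call. = FALSE)
  }
  sizes <- match_table |>
    dplyr::distinct(.data$patient_id, .data$cohort) |>
    dplyr::count(.data$cohort, name = "denominator")
  if (any(sizes$denominator == 0)) stop("empty cohort", call. = FALSE)
  match_table |>
    dplyr::group_by(.data$cohort, .data$concept) |>
    dplyr::summarise(numerator = sum(.data$matched), .groups = "drop") |>
    dplyr::left_join(sizes, by = "cohort") |>
    dplyr::mutate(proportion = .data$numerator / .data$denominator)
}

#' @rdname feature_proportions
#' @param proportions Output of [feature_proportions()].
#' @param path Output path; proportions are written to two decimals
#'   alongside their exact numerator and denominator.
#' @export
write_proportions <- function(proportions, path) {
  out <- as.data.frame(proportions)
  out$proportion <- sprintf("%.2f", out$proportion)
  write_tsv_utf8(out, path)
}

#' Severity-group flags per patient
#'
#' Applies a severity-group map (see [severity_group_map()]) to a patient
#' feature match table. Group rules: `"any"` flags the group when at least
#' one listed feature matched, `"all"` when all did, `"anchor_any"` when
#' the anchor feature matched together with at least one listed feature.
#' A patient may satisfy several groups; all satisfied groups are flagged.
#'
#' @param match_table Output of [match_features()].
#' @param map Severity-group map; defaults to [severity_group_map()].
#' @return Tibble with `patient_id`, `cohort` and one logical column per
#'   severity group.
#' @export
severity_rollup <- function(match_table, map = severity_group_map()) {
  needed <- unique(unlist(lapply(map, function(g) c(g$anchor, g$features))))
  have <- unique(match_table$concept)
  missing <- setdiff(needed, have)
  if (length(missing) > 0) {
    stop(sprintf("severity map references feature(s) absent from the match table: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  wide <- match_table |>
    tidyr::pivot_wider(
      id_cols = c("patient_id", "cohort"),
      names_from = "concept", values_from = "matched"
    )
  flags <- wide[, c("patient_id", "cohort")]
  for (grp in names(map)) {
    g <- map[[grp]]
    feat <- as.matrix(wide[, g$features, drop = FALSE])
    flags[[grp]] <- switch(
      g$rule,
      any = apply(feat, 1, any),
      all = apply(feat, 1, all),
      anchor_any = wide[[g$anchor]] & apply(feat, 1, any),
      stop(sprintf("unknown severity rule '%s'", g$rule), call. = FALSE)
    )
  }
  flags
}

#' Read / write patient note tables
#'
#' Notes travel as tab-separated files with the header
#' `patient_id, cohort, note_text`.
#'
#' @param notes Notes tibble.
#' @param path File path.
#' @return `path` (write) or a notes tibble (read).
#' @export
write_notes <- function(notes, path) {
  write_tsv_utf8(as.data.frame(notes[, c("patient_id", "cohort", "note_text")]),
                 path)
}

#' @rdname write_notes
#' @export
read_notes <- function(path) {
  read_tsv_utf8(path, colClasses = "character")
}
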