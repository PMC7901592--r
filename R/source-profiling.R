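#' Cross-source frequency weights for returned terms
#'
#' For every unique term returned by any source for one query, counts the
#' number of sources whose top-k list contains the term at any rank, and
#' divides by the total number of sources queried. With S sources the
#' weight is bounded between 1/S (returned by a single source) and 1.0
#' (returned by every source); with the seven standard sources the lower
#' bound is 0.14 to two decimals. The weight is the size scale used when
#' candidate terms are rendered as a word cloud.
#'
#' Term identity across sources is delimiter-insensitive: keys are
#' case-folded and underscore, hyphen and space are treated as the same
#' separator, so "dry_cough" and "dry-cough" count as the same term. The
#' reported `term` column carries the first surface form seen.
#'
#' @param top_k_lists Named list of per-source candidate tibbles for one
#'   query (see [query_sources()]).
#' @return A tibble with columns `term`, `source_count`, `total_sources`
#'   and `weight`, sorted by decreasing weight then term.
#' @export
frequency_weights <- function(top_k_lists) {
  s_total <- length(top_k_lists)
  if (s_total < 1) stop("at least one source list is required", call. = FALSE)
  per_source <- lapply(top_k_lists, function(lst) {
    tibble::tibble(
      key = unique(normalize_term_key(lst$returned)),
      surface = lst$returned[!duplicated(normalize_term_key(lst$returned))]
    )
  })
  all_terms <- dplyr::bind_rows(per_source)
  counts <- table(all_terms$key)
  first_surface <- all_terms$surface[!duplicated(all_terms$key)]
  names(first_surface) <- all_terms$key[!duplicated(all_terms$key)]
  out <- tibble::tibble(
    term = unname(first_surface[names(counts)]),
    source_count = as.integer(counts),
    total_sources = s_total,
    weight = as.integer(counts) / s_total
  )
  out[order(-out$weight, out$term), ]
}

#' Consensus semantic label for one annotated item
#'
#' Reconciles multiple annotators' labels for one (query, returned,
#' source) item into a single label by majority vote. Ties are broken by a
#' fixed documented priority order (synonym first, then negation,
#' hypernym, hyponym, symptom/sign, disease/disorder, qualifier,
#' anatomical location, therapeutic, other) and flagged.
#'
#' @param labels Character vector of one or more annotator labels for the
#'   same item.
#' @return The consensus label, with logical attribute `"tie"` indicating
#'   whether the majority was tied.
#' @export
#' @examples
#' consensus_label(c("synonym", "synonym", "hypernym"))
consensus_label <- function(labels) {
  if (length(labels) == 0) stop("at least one label is required", call. = FALSE)
  assert_semantic_labels(labels)
  priority <- c(
    "synonym", "negation", "hypernym", "hyponym", "symptom_sign",
    "disease_disorder", "qualifier", "anatomical_location", "therapeutic",
    "other"
  )
  counts <- table(factor(labels, levels = priority))
  top <- names(counts)[counts == max(counts)]
  winner <- top[order(match(top, priority))][1]
  structure(winner, tie = length(top) > 1)
}

#' Consensus labels for every annotated item
#'
#' @param annotations Annotation tibble (columns `query`, `returned`,
#'   `source`, `annotator`, `label`).
#' @return Tibble with one row per (query, returned, source) item:
#'   columns `query`, `returned`, `source`, `label` (the consensus) and
#'   `tie`.
#' @export
consensus_labels <- function(annotations) {
  assert_annotations(annotations)
  annotations |>
    dplyr::group_by(.data$query, .data$returned, .data$source) |>
    dplyr::summarise(
      label = {
        cl <- consensus_label(.data$label)
        as.character(cl)
      },
      tie = attr(consensus_label(.data$label), "tie"),
      .groups = "drop"
    )
}

#' Distribution of semantic types among returned candidates
#'
#' For each (source, query) pair, counts how many of the source's top-k
#' candidates carry each consensus semantic label. Counts conserve the
#' number of labeled candidates per (source, query); comparing the
#' per-source distributions reveals construction-driven patterns, e.g.
#' character-unit sources returning more synonyms.
#'
#' @param annotations Annotation tibble covering every candidate.
#' @param top_k_lists Either a single candidates tibble (several queries /
#'   sources bound together) or a list of per-source candidate tibbles.
#' @return Tibble with columns `source`, `query`, one count column per
#'   semantic type, and `tie_count` (candidates whose consensus was tied).
#' @export
semantic_type_distribution <- function(annotations, top_k_lists) {
  candidates <- if (is.data.frame(top_k_lists)) top_k_lists
                else dplyr::bind_rows(top_k_lists)
  cons <- consensus_labels(annotations)
  merged <- dplyr::left_join(
    candidates[, c("source", "query", "returned")], cons,
    by = c("source", "query", "returned")
  )
  if (anyNA(merged$label)) {
    miss <- merged[is.na(merged$label), ]
    stop(sprintf(
      "candidates without annotation: %s",
      paste(utils::head(
        paste(miss$source, miss$query, miss$returned, sep = " | "), 5
      ), collapse = "; ")
    ), call. = FALSE)
  }
  merged$label <- factor(merged$label, levels = semantic_types())
  counts <- merged |>
    dplyr::group_by(.data$source, .data$query) |>
    dplyr::summarise(
      tie_count = sum(.data$tie),
      counts = list(table(.data$label)),
      .groups = "drop"
    )
  wide <- do.call(rbind, lapply(counts$counts, as.integer))
  colnames(wide) <- semantic_types()
  dplyr::bind_cols(
    counts[, c("source", "query")],
    tibble::as_tibble(as.data.frame(wide)),
    counts[, "tie_count"]
  )
}

#' Mean count of a semantic type over a source group
#'
#' Averages a semantic type's per-(source, query) candidate count over all
#' queries and all sources in the named group — e.g. the mean number of
#' synonym-labeled candidates per query returned by character-unit versus
#' token-unit sources. Reported to two decimal places.
#'
#' @param distributions Output of [semantic_type_distribution()].
#' @param source_group Character vector of source names to average over.
#' @param type One semantic type.
#' @return The mean count, rounded to 2 dp.
#' @export
mean_type_count <- function(distributions, source_group, type) {
  if (length(source_group) == 0) {
    stop("`source_group` must name at least one source", call. = FALSE)
  }
  assert_semantic_labels(type, "type")
  missing <- setdiff(source_group, unique(distributions$source))
  if (length(missing) > 0) {
    stop(sprintf("source(s) absent from distributions: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  sub <- distributions[distributions$source %in% source_group, , drop = FALSE]
  round(mean(sub[[type]]), 2)
}

#' Modifier contrasts in semantic-type counts
#'
#' For each admitted (unmodified, modified) query-term pair, compares the
#' mean per-source count of each semantic type between the modified and
#' the unmodified variant — e.g. whether "dry cough" returns more
#' qualifier-labeled candidates than "cough". Only the packaged variant
#' pairs (or an explicit `pairs` table of the same shape) are admitted.
#'
#' @param distributions Output of [semantic_type_distribution()].
#' @param pairs Tibble with columns `unmodified` and `modified`; defaults
#'   to [modifier_pairs()].
#' @param types Semantic types to contrast; defaults to all ten.
#' @return Tibble with columns `unmodified`, `modified`, `type`,
#'   `mean_modified`, `mean_unmodified` (each to 2 dp) and `difference`.
#' @export
modifier_contrast <- function(distributions, pairs = modifier_pairs(),
                              types = semantic_types()) {
  assert_semantic_labels(types, "types")
  present <- unique(distributions$query)
  out <- list()
  for (i in seq_len(nrow(pairs))) {
    un <- pairs$unmodified[i]
    mo <- pairs$modified[i]
    for (variant in c(un, mo)) {
      if (!variant %in% present) {
        stop(sprintf("variant '%s' of pair ('%s', '%s') missing from distributions",
                     variant, un, mo), call. = FALSE)
      }
    }
    d_un <- distributions[distributions$query == un, , drop = FALSE]
    d_mo <- distributions[distributions$query == mo, , drop = FALSE]
    for (ty in types) {
      m_mo <- round(mean(d_mo[[ty]]), 2)
      m_un <- round(mean(d_un[[ty]]), 2)
      out[[length(out) + 1L]] <- tibble::tibble(
        unmodified = un, modified = mo, type = ty,
        mean_modified = m_mo, mean_unmodified = m_un,
        difference = m_mo - m_un
      )
    }
  }
  dplyr::bind_rows(out)
}

#' Size of the full annotation grid
#'
#' Number of annotation cells produced when every (candidate rank, query
#' term, source, annotator) combination is labeled: k x number of query
#' terms x number of sources x number of annotators. Each argument may be
#' given as a count or as a vector of the things themselves.
#'
#' @param query_terms Query terms (vector) or their count.
#' @param sources Sources (vector/list) or their count.
#' @param k Candidates per (query, source) list.
#' @param annotators Annotator ids (vector) or their count.
#' @return Integer grid size.
#' @export
#' @examples
#' annotation_grid_size(query_terms = 24, sources = 7, k = 20, annotators = 3)
annotation_grid_size <- function(query_terms, sources, k, annotators) {
  as_count <- function(x, arg) {
    n <- if (is.numeric(x) && length(x) == 1L) x else length(x)
    if (is.na(n) || n < 1 || n != as.integer(n)) {
      stop(sprintf("`%s` must be a positive count or a non-empty vector", arg),
           call. = FALSE)
    }
    as.integer(n)
  }
  as_count(k, "k") * as_count(query_terms, "query_terms") *
    as_count(sources, "sources") * as_count(annotators, "annotators")
}

#' Export profiling tables
#'
#' Writes frequency weights, semantic-type distributions and modifier
#' contrasts as tab-separated files.
#'
#' @param x Table to write (output of [frequency_weights()],
#'   [semantic_type_distribution()] or [modifier_contrast()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profile_table <- function(x, path) {
  num <- vapply(x, is.double, TRUE)
  x[num] <- lapply(x[num], function(col) sprintf("%.6f", col))
  write_tsv_utf8(as.data.frame(x), path)
}
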