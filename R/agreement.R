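#' Cohen's kappa over a closed label set
#'
#' Chance-corrected agreement between two raters:
#' kappa = (p_o - p_e) / (1 - p_e), where p_o is the observed fraction of
#' items on which the raters agree and p_e the agreement expected by chance
#' from the two raters' marginal label frequencies. The statistic is
#' computed over the full closed label set, so unobserved labels simply
#' contribute zero marginals.
#'
#' In the degenerate case p_e = 1 (both raters use a single, identical
#' marginal concentrated on one label) the ratio is undefined; the
#' convention used here returns 1 when the raters agree everywhere and 0
#' otherwise, so single-label strata with perfect agreement remain
#' reportable.
#'
#' @param labels_a,labels_b Equal-length character vectors of labels, one
#'   per item, aligned by position.
#' @param label_set Closed label set; defaults to the ten semantic types.
#' @return Kappa in \[-1, 1\].
#' @export
#' @examples
#' cohen_kappa(c("synonym", "synonym", "negation", "other"),
#'             c("synonym", "negation", "negation", "other"))
cohen_kappa <- function(labels_a, labels_b, label_set = semantic_types()) {
  n <- length(labels_a)
  if (n == 0 || length(labels_b) != n) {
    stop("`labels_a` and `labels_b` must be non-empty and of equal length",
         call. = FALSE)
  }
  labels_a <- as.character(labels_a)
  labels_b <- as.character(labels_b)
  bad <- setdiff(unique(c(labels_a, labels_b)), label_set)
  if (length(bad) > 0) {
    stop(sprintf("labels outside the label set: %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  p_o <- mean(labels_a == labels_b)
  ma <- table(factor(labels_a, levels = label_set)) / n
  mb <- table(factor(labels_b, levels = label_set)) / n
  p_e <- sum(as.numeric(ma) * as.numeric(mb))
  if (p_e >= 1 - .Machine$double.eps^0.5) {
    return(if (p_o == 1) 1 else 0)
  }
  (p_o - p_e) / (1 - p_e)
}

# validate an annotation table and fail on duplicate (item, annotator) rows
assert_annotations <- function(annotations) {
  required <- c("query", "returned", "source", "annotator", "label")
  missing <- setdiff(required, names(annotations))
  if (length(missing) > 0) {
    stop(sprintf("annotation table lacks column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  assert_semantic_labels(annotations$label, "annotations$label")
  key <- paste(annotations$query, annotations$returned, annotations$source,
               annotations$annotator, sep = "\r")
  if (anyDuplicated(key)) {
    dups <- unique(key[duplicated(key)])
    stop(sprintf(
      "duplicate (query, returned, source, annotator) annotation rows: %s",
      paste(utils::head(gsub("\r", " | ", dups), 5), collapse = "; ")
    ), call. = FALSE)
  }
  invisible(TRUE)
}

# align one annotator pair on (query, returned, source) items; errors if an
# item was labeled by only one of the two
align_pair <- function(annotations, annotator_a, annotator_b) {
  a <- annotations[annotations$annotator == annotator_a, , drop = FALSE]
  b <- annotations[annotations$annotator == annotator_b, , drop = FALSE]
  key_a <- paste(a$query, a$returned, a$source, sep = "\r")
  key_b <- paste(b$query, b$returned, b$source, sep = "\r")
  only_a <- setdiff(key_a, key_b)
  only_b <- setdiff(key_b, key_a)
  if (length(only_a) > 0 || length(only_b) > 0) {
    stop(sprintf(
      "items labeled by only one annotator of pair (%s, %s): %s",
      annotator_a, annotator_b,
      paste(utils::head(gsub("\r", " | ", c(only_a, only_b)), 5), collapse = "; ")
    ), call. = FALSE)
  }
  idx <- match(key_a, key_b)
  tibble::tibble(
    query = a$query,
    returned = a$returned,
    source = a$source,
    label_a = a$label,
    label_b = b$label[idx]
  )
}

#' Pairwise interannotator agreement by stratum
#'
#' Computes Cohen's kappa for every unordered annotator pair within each
#' stratum: either the clinical category of the query term (symptom,
#' finding, disorder) or the query term itself. Items are aligned between
#' the two annotators of a pair on the (query, returned, source) key; every
#' evaluated item must be labeled by both annotators of the pair.
#'
#' @param annotations Annotation tibble with columns `query`, `returned`,
#'   `source`, `annotator`, `label`.
#' @param strata `"by_category"` or `"by_query_term"`.
#' @param categories Named character vector mapping query terms to
#'   categories (required for `"by_category"`); defaults to the packaged
#'   seed-term category assignment.
#' @param label_set Closed label set for the kappa computation.
#' @return A tibble with one row per (annotator pair, stratum): columns
#'   `annotator_a`, `annotator_b`, `stratum`, `kappa`, `item_count` and a
#'   list-column `confusion` holding the pair's label-by-label count
#'   matrix (rows: first annotator, columns: second).
#' @export
pairwise_agreement <- function(annotations,
                               strata = c("by_category", "by_query_term"),
                               categories = query_term_categories(),
                               label_set = semantic_types()) {
  strata <- match.arg(strata)
  assert_annotations(annotations)
  annotators <- sort(unique(annotations$annotator))
  if (length(annotators) < 2) {
    stop("at least two annotators are required", call. = FALSE)
  }

  if (strata == "by_category") {
    unknown <- setdiff(unique(annotations$query), names(categories))
    if (length(unknown) > 0) {
      stop(sprintf("query terms without category assignment: %s",
                   paste(unknown, collapse = ", ")), call. = FALSE)
    }
    stratum_of <- unname(categories[annotations$query])
  } else {
    stratum_of <- annotations$query
  }

  pairs <- utils::combn(annotators, 2, simplify = FALSE)
  out <- list()
  for (pr in pairs) {
    for (st in unique(stratum_of)) {
      sub <- annotations[stratum_of == st, , drop = FALSE]
      aligned <- align_pair(sub, pr[1], pr[2])
      conf <- table(
        factor(aligned$label_a, levels = label_set),
        factor(aligned$label_b, levels = label_set)
      )
      out[[length(out) + 1L]] <- tibble::tibble(
        annotator_a = pr[1],
        annotator_b = pr[2],
        stratum = st,
        kappa = cohen_kappa(aligned$label_a, aligned$label_b, label_set),
        item_count = nrow(aligned),
        confusion = list(unclass(conf))
      )
    }
  }
  dplyr::bind_rows(out)
}

#' Disagreement matrix for one annotator pair
#'
#' Counts, over all items labeled by both annotators, how often the first
#' annotator assigned label r while the second assigned label c. The
#' diagonal holds agreements; off-diagonal mass shows which semantic
#' classes the pair systematically confuses (the content of a pairwise
#' disagreement heat map). The diagonal sum divided by the total equals
#' the observed agreement p_o entering Cohen's kappa.
#'
#' @inheritParams pairwise_agreement
#' @param pair Character vector of two annotator ids; the first indexes
#'   rows of the result.
#' @return Integer matrix with `label_set` rows and columns.
#' @export
disagreement_matrix <- function(annotations, pair, label_set = semantic_types()) {
  if (length(pair) != 2 || pair[1] == pair[2]) {
    stop("`pair` must name two distinct annotators", call. = FALSE)
  }
  assert_annotations(annotations)
  aligned <- align_pair(annotations, pair[1], pair[2])
  m <- table(
    factor(aligned$label_a, levels = label_set),
    factor(aligned$label_b, levels = label_set)
  )
  m <- unclass(m)
  names(dimnames(m)) <- pair
  m
}

#' Read / write annotation tables
#'
#' Annotations travel as tab-separated files with the header
#' `query, returned, source, annotator, label`.
#'
#' @param annotations Annotation tibble.
#' @param path File path.
#' @return `path` (write) or an annotation tibble (read).
#' @export
write_annotations <- function(annotations, path) {
  assert_annotations(annotations)
  write_tsv_utf8(
    annotations[, c("query", "returned", "source", "annotator", "label")],
    path
  )
}

#' @rdname write_annotations
#' @export
read_annotations <- function(path) {
  ann <- read_tsv_utf8(path, colClasses = "character")
  assert_annotations(ann)
  ann
}
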