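#' Cosine similarity between two vectors
#'
#' Standard inner product over the product of Euclidean norms. Values lie
#' in \[-1, 1\] up to floating-point rounding; 1 means identical direction.
#'
#' @param u,v Numeric vectors of equal length with non-zero norm.
#' @return Cosine similarity as a double.
#' @export
#' @examples
#' cosine_similarity(c(1, 0), c(1, 1))  # 1/sqrt(2)
cosine_similarity <- function(u, v) {
  if (length(u) != length(v)) {
    stop("`u` and `v` must have equal length", call. = FALSE)
  }
  nu <- sqrt(sum(u^2))
  nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) {
    stop("cosine similarity is undefined for zero-norm vectors", call. = FALSE)
  }
  min(max(sum(u * v) / (nu * nv), -1), 1)
}

# cosines of one query vector against every row of the source matrix
source_cosines <- function(source, qvec) {
  vecs <- source$vectors
  norms <- sqrt(rowSums(vecs^2))
  if (any(norms == 0)) {
    stop(sprintf("source '%s' contains zero-norm vectors: %s",
                 source$name,
                 paste(utils::head(rownames(vecs)[norms == 0], 5), collapse = ", ")),
         call. = FALSE)
  }
  qn <- sqrt(sum(qvec^2))
  if (qn == 0) stop("query vector has zero norm", call. = FALSE)
  cs <- as.vector(vecs %*% qvec) / unname(norms * qn)
  pmin(pmax(cs, -1), 1)
}

# resolve a query term to (vector, probed keys); key_then_average falls back
# to the unweighted mean of constituent-token vectors
resolve_query <- function(source, query, phrase_strategy) {
  probed <- normalize_query(query, source)
  if (length(probed) > 0) {
    return(list(vector = source$vectors[probed[1], ], probed = probed))
  }
  if (phrase_strategy == "key_only") {
    stop(sprintf("query '%s' has no vocabulary key in source '%s'",
                 query, source$name), call. = FALSE)
  }
  tokens <- strsplit(trimws(query), "[ \t]+")[[1]]
  token_keys <- lapply(tokens, function(tok) normalize_query(tok, source))
  missing <- tokens[lengths(token_keys) == 0]
  if (length(missing) > 0) {
    stop(sprintf(
      "query '%s' unresolvable in source '%s': token(s) %s not in vocabulary",
      query, source$name, paste(sQuote(missing), collapse = ", ")
    ), call. = FALSE)
  }
  token_mat <- do.call(rbind, lapply(token_keys, function(k) source$vectors[k[1], ]))
  list(vector = colMeans(token_mat), probed = unlist(token_keys))
}

#' Top-k nearest vocabulary terms by cosine similarity
#'
#' Ranks a source's whole vocabulary by cosine similarity to the query and
#' returns the k most similar terms. All vocabulary keys the query
#' normalises to are excluded from the candidates (so case or delimiter
#' variants of the query never return themselves). Ties in cosine are
#' broken lexicographically on the returned key.
#'
#' Multi-word queries with no whole-phrase vocabulary key are handled
#' according to `phrase_strategy`: `"key_then_average"` (default) falls
#' back to querying with the unweighted mean of the constituent-token
#' vectors, while `"key_only"` errors.
#'
#' @param source An [embedding_source()].
#' @param query Query term (string).
#' @param k Number of neighbours to return (default 20). If k exceeds the
#'   number of available candidates the full ranked list is returned.
#' @param phrase_strategy `"key_then_average"` or `"key_only"`.
#' @return A tibble of ranked candidates with columns `query`, `returned`,
#'   `cosine`, `rank`, `source`.
#' @export
top_k_neighbors <- function(source, query, k = 20,
                            phrase_strategy = c("key_then_average", "key_only")) {
  stopifnot(inherits(source, "embedding_source"))
  phrase_strategy <- match.arg(phrase_strategy)
  if (!is.numeric(k) || length(k) != 1L || k < 1) {
    stop("`k` must be a positive integer", call. = FALSE)
  }
  res <- resolve_query(source, query, phrase_strategy)
  cs <- source_cosines(source, res$vector)
  keys <- vocabulary(source)
  keep <- !(keys %in% res$probed)
  keys <- keys[keep]
  cs <- cs[keep]
  ord <- order(-cs, keys)
  take <- utils::head(ord, min(k, length(ord)))
  tibble::tibble(
    query = query,
    returned = keys[take],
    cosine = cs[take],
    rank = seq_along(take),
    source = source$name
  )
}

#' Query several sources for the same term
#'
#' @param sources Named list of [embedding_source()] objects.
#' @param query Query term.
#' @inheritParams top_k_neighbors
#' @param skip_unresolvable If `TRUE` (default), sources where the query
#'   cannot be resolved are dropped with a warning instead of erroring.
#' @return Named list of candidate tibbles, one per source that resolved
#'   the query.
#' @export
query_sources <- function(sources, query, k = 20,
                          phrase_strategy = c("key_then_average", "key_only"),
                          skip_unresolvable = TRUE) {
  phrase_strategy <- match.arg(phrase_strategy)
  out <- list()
  for (src in sources) {
    lst <- tryCatch(
      top_k_neighbors(src, query, k = k, phrase_strategy = phrase_strategy),
      error = function(e) {
        if (!skip_unresolvable) stop(e)
        warning(conditionMessage(e), call. = FALSE)
        NULL
      }
    )
    if (!is.null(lst)) out[[src$name]] <- lst
  }
  out
}

#' Cross-source cosine record for one returned term
#'
#' For a term retrieved for some query, reports the cosine similarity that
#' each source assigned it in its own top-k list. A source whose top-k list
#' does not contain the term receives the sentinel value -1, marking the
#' term as absent from (or not top-ranked in) that source.
#'
#' @param term Returned term to look up.
#' @param top_k_lists Named list of per-source candidate tibbles for a
#'   common query, as produced by [top_k_neighbors()] or [query_sources()].
#' @return A tibble with one row per source: columns `term`, `source`,
#'   `cosine` (the source's cosine, or exactly -1 when absent) and
#'   `present`.
#' @export
cross_source_cosines <- function(term, top_k_lists) {
  if (length(top_k_lists) == 0) {
    return(tibble::tibble(term = character(0), source = character(0),
                          cosine = numeric(0), present = logical(0)))
  }
  src_names <- names(top_k_lists) %||%
    vapply(top_k_lists, function(l) l$source[1], "")
  rows <- lapply(seq_along(top_k_lists), function(i) {
    lst <- top_k_lists[[i]]
    hit <- match(term, lst$returned)
    tibble::tibble(
      term = term,
      source = src_names[i],
      cosine = if (is.na(hit)) -1 else lst$cosine[hit],
      present = !is.na(hit)
    )
  })
  dplyr::bind_rows(rows)
}

#' Write / read candidate lists
#'
#' Candidate lists are exchanged as tab-separated files with header
#' `query, returned, cosine, rank, source`; cosines are written with six
#' decimal places.
#'
#' @param candidates Tibble of ranked candidates (possibly several queries
#'   and sources bound together).
#' @param path Output path.
#' @return `path` (write) or a candidates tibble (read).
#' @export
write_candidates <- function(candidates, path) {
  out <- data.frame(
    query = candidates$query,
    returned = candidates$returned,
    cosine = sprintf("%.6f", candidates$cosine),
    rank = candidates$rank,
    source = candidates$source,
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_candidates
#' @export
read_candidates <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          colClasses = c(
                            query = "character", returned = "character",
                            cosine = "numeric", rank = "integer",
                            source = "character"
                          ), fileEncoding = "UTF-8")
  tibble::as_tibble(df)
}
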