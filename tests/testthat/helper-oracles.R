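# Independent oracles and small fixture builders used across the suite.

# brute-force ranked cosine list: plain loop, no shared code with
# top_k_neighbors beyond arithmetic
brute_force_neighbors <- function(vectors, query_key, k) {
  q <- vectors[query_key, ]
  keys <- setdiff(rownames(vectors), query_key)
  cs <- vapply(keys, function(key) {
    v <- vectors[key, ]
    sum(q * v) / (sqrt(sum(q^2)) * sqrt(sum(v^2)))
  }, numeric(1))
  ord <- order(-cs, keys)
  data.frame(
    returned = keys[ord][seq_len(min(k, length(ord)))],
    cosine = unname(cs[ord][seq_len(min(k, length(ord)))]),
    stringsAsFactors = FALSE
  )
}

# contingency-table kappa written as explicit double loops over the label
# set; independent of cohen_kappa's vectorised marginals
brute_force_kappa <- function(a, b, label_set) {
  n <- length(a)
  conf <- matrix(0, length(label_set), length(label_set),
                 dimnames = list(label_set, label_set))
  for (i in seq_len(n)) conf[a[i], b[i]] <- conf[a[i], b[i]] + 1
  p_o <- sum(diag(conf)) / n
  p_e <- 0
  for (l in label_set) p_e <- p_e + sum(conf[l, ]) / n * sum(conf[, l]) / n
  if (p_e >= 1 - 1e-12) return(if (p_o == 1) 1 else 0)
  (p_o - p_e) / (1 - p_e)
}

# tiny embedding source from a named list of vectors
make_source <- function(vectors, name = "test",
                        case_policy = "lowercase",
                        phrase_policy = "unigram_only") {
  m <- do.call(rbind, vectors)
  rownames(m) <- names(vectors)
  embedding_source(name, m, case_policy = case_policy,
                   phrase_policy = phrase_policy)
}

# annotation tibble from parallel label vectors, one item per position
make_annotations <- function(..., query = "fever", source = "src1") {
  annotators <- list(...)
  n <- length(annotators[[1]])
  dplyr::bind_rows(lapply(names(annotators), function(a) {
    tibble::tibble(
      query = query,
      returned = sprintf("cand_%03d", seq_len(n)),
      source = source,
      annotator = a,
      label = annotators[[a]]
    )
  }))
}

# non-overlapping toy lexicon used by matching / prevalence tests: no term
# shares a token with another concept's terms
toy_lexicon <- function() {
  build_expanded_lexicon(list(
    fever = c("fever", "pyrexia", "febrile"),
    hypoxia = c("hypoxia", "hypoxemia"),
    malaise = "malaise",
    headache = "headache",
    chills = "chills"
  ))
}
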