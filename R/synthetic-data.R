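# run code under a private RNG seed, restoring the caller's RNG state
with_rng_seed <- function(seed, code) {
  genv <- globalenv()
  old <- if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
    get(".Random.seed", envir = genv)
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
        rm(".Random.seed", envir = genv)
      }
    } else {
      assign(".Random.seed", old, envir = genv)
    }
  })
  set.seed(seed)
  force(code)
}

unit_vector <- function(v) v / sqrt(sum(v^2))

# unit vector orthogonal to u, from a standard-normal draw by Gram-Schmidt
orthogonal_unit <- function(u, max_attempts = 1000) {
  d <- length(u)
  for (i in seq_len(max_attempts)) {
    r <- stats::rnorm(d)
    r <- r - sum(r * u) * u
    nr <- sqrt(sum(r^2))
    if (nr > 1e-8) return(r / nr)
  }
  stop("failed to construct an orthogonal complement; dimension too small",
       call. = FALSE)
}

#' Configuration for a synthetic embedding space
#'
#' Describes an embedding space with planted structure: for each seed
#' concept a cluster of synonyms at a high target cosine to the seed, a
#' ring of related terms at a lower target cosine, and a pool of
#' distractors near-orthogonal to every seed. The separation emulates what
#' is observed in real embedding sources, where true lexical variants sit
#' at high cosine with low variability while merely related terms sit
#' lower.
#'
#' @param seed_terms Character vector of seed concept phrases (non-empty,
#'   unique after case/delimiter normalisation).
#' @param dimension Embedding dimension (>= 2).
#' @param synonyms_per_seed,related_per_seed,distractor_count Non-negative
#'   counts of planted terms.
#' @param target_cos_synonym Target cosine between a seed and its synonyms,
#'   in (0, 1]; default 0.9.
#' @param target_cos_related Target cosine between a seed and its related
#'   terms, in \[0, 1); default 0.4. Must be below `target_cos_synonym`.
#' @param cos_jitter Half-width of the uniform jitter applied to each
#'   planted cosine (>= 0); default 0.05.
#' @param rng_seed Integer seed making generation fully reproducible.
#' @return A `synth_embedding_config` list.
#' @export
synth_embedding_config <- function(seed_terms,
                                   dimension = 50,
                                   synonyms_per_seed = 5,
                                   related_per_seed = 5,
                                   distractor_count = 100,
                                   target_cos_synonym = 0.9,
                                   target_cos_related = 0.4,
                                   cos_jitter = 0.05,
                                   rng_seed = 1L) {
  if (!is.character(seed_terms) || length(seed_terms) == 0 ||
      any(!nzchar(trimws(seed_terms)))) {
    stop("`seed_terms` must be non-empty strings", call. = FALSE)
  }
  if (anyDuplicated(normalize_term_key(seed_terms))) {
    stop("seed terms must be unique after normalization", call. = FALSE)
  }
  if (dimension < 2) stop("`dimension` must be at least 2", call. = FALSE)
  if (synonyms_per_seed < 0 || related_per_seed < 0 || distractor_count < 0) {
    stop("planted counts must be non-negative", call. = FALSE)
  }
  if (!(target_cos_synonym > 0 && target_cos_synonym <= 1)) {
    stop("`target_cos_synonym` must lie in (0, 1]", call. = FALSE)
  }
  if (!(target_cos_related >= 0 && target_cos_related < 1)) {
    stop("`target_cos_related` must lie in [0, 1)", call. = FALSE)
  }
  if (target_cos_synonym <= target_cos_related) {
    stop("`target_cos_synonym` must exceed `target_cos_related`", call. = FALSE)
  }
  if (cos_jitter < 0) stop("`cos_jitter` must be non-negative", call. = FALSE)
  structure(
    list(
      seed_terms = seed_terms,
      dimension = as.integer(dimension),
      synonyms_per_seed = as.integer(synonyms_per_seed),
      related_per_seed = as.integer(related_per_seed),
      distractor_count = as.integer(distractor_count),
      target_cos_synonym = target_cos_synonym,
      target_cos_related = target_cos_related,
      cos_jitter = cos_jitter,
      rng_seed = as.integer(rng_seed)
    ),
    class = "synth_embedding_config"
  )
}

#' Generate an embedding space with planted synonym structure
#'
#' Builds a vocabulary of seeds, synonyms, related terms and distractors
#' with controlled cosine geometry. Each planted vector v for seed
#' direction u is constructed as v = c u + sqrt(1 - c^2) r with r a unit
#' vector orthogonal to u (Gram-Schmidt of a standard-normal draw) and c
#' the target cosine plus uniform jitter, so the intended angle is exact
#' up to the jitter. Seeds and distractors are drawn by check-and-resample
#' until every |cosine| to (other) seeds is at most 0.3, capped at 1000
#' attempts.
#'
#' @param config A [synth_embedding_config()].
#' @param name Source name for the generated [embedding_source()].
#' @param source_tag Optional short tag appended to related-term and
#'   distractor names (not synonyms), so that several sources generated
#'   from the same seeds share their synonym vocabulary but keep
#'   idiosyncratic remainder vocabularies, as real independently trained
#'   sources do.
#' @return List with `source` (an [embedding_source()]) and `truth`, a
#'   tibble with columns `term`, `role` (`"seed"`, `"synonym"`,
#'   `"related"`, `"distractor"`), `seed` (the anchor seed term, `NA` for
#'   distractors) and `target_cosine` (the intended cosine to the anchor
#'   before jitter, `NA` for seeds and distractors).
#' @export
generate_embedding_space <- function(config, name = "synthetic", source_tag = NULL) {
  stopifnot(inherits(config, "synth_embedding_config"))
  with_rng_seed(config$rng_seed, {
    d <- config$dimension
    n_seeds <- length(config$seed_terms)
    seed_keys <- gsub("[ \t]+", "_", tolower(config$seed_terms))
    tag <- if (is.null(source_tag)) "" else paste0("_", source_tag)

    seed_mat <- matrix(NA_real_, n_seeds, d)
    for (i in seq_len(n_seeds)) {
      ok <- FALSE
      for (attempt in seq_len(1000)) {
        v <- unit_vector(stats::rnorm(d))
        if (i == 1 ||
            max(abs(seed_mat[seq_len(i - 1), , drop = FALSE] %*% v)) <= 0.3) {
          seed_mat[i, ] <- v
          ok <- TRUE
          break
        }
      }
      if (!ok) {
        stop(sprintf(
          "could not place seed %d with |cos| <= 0.3 to earlier seeds in dimension %d",
          i, d
        ), call. = FALSE)
      }
    }

    keys <- seed_keys
    vecs <- seed_mat
    truth <- tibble::tibble(
      term = seed_keys, role = "seed",
      seed = config$seed_terms, target_cosine = NA_real_
    )

    plant <- function(count, target, suffix, role, name_tag) {
      for (i in seq_len(n_seeds)) {
        u <- seed_mat[i, ]
        for (j in seq_len(count)) {
          cos_t <- target + stats::runif(1, -config$cos_jitter, config$cos_jitter)
          cos_t <- min(max(cos_t, -1), 1)
          r <- orthogonal_unit(u)
          v <- cos_t * u + sqrt(1 - cos_t^2) * r
          keys <<- c(keys, paste0(seed_keys[i], "_", suffix, j, name_tag))
          vecs <<- rbind(vecs, v)
          truth <<- dplyr::bind_rows(truth, tibble::tibble(
            term = keys[length(keys)], role = role,
            seed = config$seed_terms[i], target_cosine = target
          ))
        }
      }
    }
    # synonyms are lexical variants of the seed and recur across sources,
    # so they are never source-tagged; related terms and distractors are
    plant(config$synonyms_per_seed, config$target_cos_synonym, "syn",
          "synonym", name_tag = "")
    plant(config$related_per_seed, config$target_cos_related, "rel",
          "related", name_tag = tag)

    for (j in seq_len(config$distractor_count)) {
      ok <- FALSE
      for (attempt in seq_len(1000)) {
        v <- unit_vector(stats::rnorm(d))
        if (max(abs(seed_mat %*% v)) <= 0.3) {
          ok <- TRUE
          break
        }
      }
      if (!ok) {
        stop(sprintf(
          "could not place distractor %d with |cos| <= 0.3 to all seeds in dimension %d",
          j, d
        ), call. = FALSE)
      }
      keys <- c(keys, sprintf("filler_%04d%s", j, tag))
      vecs <- rbind(vecs, v)
      truth <- dplyr::bind_rows(truth, tibble::tibble(
        term = keys[length(keys)], role = "distractor",
        seed = NA_character_, target_cosine = NA_real_
      ))
    }

    if (anyDuplicated(normalize_term_key(keys))) {
      stop("duplicate vocabulary term after normalization", call. = FALSE)
    }
    rownames(vecs) <- keys
    list(
      source = embedding_source(
        name = name, vectors = vecs,
        unit = "token", case_policy = "lowercase",
        phrase_policy = "multiword_keys",
        metadata = list(synthetic = TRUE, rng_seed = config$rng_seed)
      ),
      truth = truth
    )
  })
}

#' Write a planted-truth table
#'
#' @param truth Truth tibble from [generate_embedding_space()].
#' @param path Output path (tab-separated with header).
#' @return `path`, invisibly.
#' @export
write_truth_table <- function(truth, path) {
  write_tsv_utf8(as.data.frame(truth), path)
}

#' Configuration for a synthetic annotation set
#'
#' Describes a multi-annotator labeling process with controlled agreement:
#' each item carries a latent reference label drawn from `base_labels`;
#' each annotator independently copies the reference with probability
#' `agreement_prob` and otherwise draws a label from the confusion-kernel
#' row of the reference label.
#'
#' @param item_count Number of annotated items (> 0).
#' @param annotator_ids At least two annotator ids.
#' @param base_labels Named probability vector over the ten semantic types
#'   (missing names get probability 0); default uniform.
#' @param agreement_prob Probability in \[0, 1\] that an annotator copies
#'   the reference label; default 0.8.
#' @param confusion_kernel Row-stochastic 10 x 10 matrix (rows and columns
#'   named by the semantic types): the error distribution given each
#'   reference label. Default: uniform over the nine non-reference labels.
#' @param rng_seed Integer RNG seed.
#' @return A `synth_annotation_config` list.
#' @export
synth_annotation_config <- function(item_count,
                                    annotator_ids = c("A1", "A2", "A3"),
                                    base_labels = NULL,
                                    agreement_prob = 0.8,
                                    confusion_kernel = NULL,
                                    rng_seed = 1L) {
  labels <- semantic_types()
  if (item_count < 1) stop("`item_count` must be positive", call. = FALSE)
  if (length(annotator_ids) < 2 || anyDuplicated(annotator_ids)) {
    stop("at least two distinct annotator ids are required", call. = FALSE)
  }
  if (!(agreement_prob >= 0 && agreement_prob <= 1)) {
    stop("`agreement_prob` must lie in [0, 1]", call. = FALSE)
  }
  if (is.null(base_labels)) {
    base_labels <- stats::setNames(rep(1 / length(labels), length(labels)), labels)
  }
  assert_semantic_labels(names(base_labels), "base_labels")
  full_base <- stats::setNames(rep(0, length(labels)), labels)
  full_base[names(base_labels)] <- base_labels
  if (any(full_base < 0) || abs(sum(full_base) - 1) > 1e-9) {
    stop("`base_labels` must be a probability distribution", call. = FALSE)
  }
  if (is.null(confusion_kernel)) {
    confusion_kernel <- matrix(
      1 / (length(labels) - 1), length(labels), length(labels),
      dimnames = list(labels, labels)
    )
    diag(confusion_kernel) <- 0
  }
  if (!all(dim(confusion_kernel) == length(labels)) ||
      is.null(rownames(confusion_kernel)) ||
      !setequal(rownames(confusion_kernel), labels) ||
      !setequal(colnames(confusion_kernel), labels)) {
    stop("`confusion_kernel` must be a 10 x 10 matrix named by the semantic types",
         call. = FALSE)
  }
  confusion_kernel <- confusion_kernel[labels, labels]
  if (any(confusion_kernel < 0) ||
      any(abs(rowSums(confusion_kernel) - 1) > 1e-9)) {
    stop("`confusion_kernel` rows must sum to 1 (tolerance 1e-9)", call. = FALSE)
  }
  structure(
    list(
      item_count = as.integer(item_count),
      annotator_ids = as.character(annotator_ids),
      base_labels = full_base,
      agreement_prob = agreement_prob,
      confusion_kernel = confusion_kernel,
      rng_seed = as.integer(rng_seed)
    ),
    class = "synth_annotation_config"
  )
}

#' Generate a synthetic multi-annotator annotation set
#'
#' @param config A [synth_annotation_config()].
#' @param queries Query terms to cycle the items over (default one
#'   synthetic concept).
#' @param sources Source names to cycle the items over.
#' @return List with `annotations` (tibble with columns `query`,
#'   `returned`, `source`, `annotator`, `label`; one row per item x
#'   annotator) and `reference` (tibble of the latent reference label per
#'   item).
#' @export
generate_annotation_set <- function(config,
                                    queries = "concept_1",
                                    sources = "synthetic_source") {
  stopifnot(inherits(config, "synth_annotation_config"))
  labels <- semantic_types()
  with_rng_seed(config$rng_seed, {
    n <- config$item_count
    items <- tibble::tibble(
      query = rep_len(queries, n),
      returned = sprintf("cand_%05d", seq_len(n)),
      source = rep_len(sources, n)
    )
    reference <- sample(labels, n, replace = TRUE, prob = config$base_labels)
    ann <- list()
    for (a in config$annotator_ids) {
      copy <- stats::runif(n) < config$agreement_prob
      lab <- reference
      for (i in which(!copy)) {
        lab[i] <- sample(labels, 1, prob = config$confusion_kernel[reference[i], ])
      }
      ann[[a]] <- dplyr::bind_cols(items, tibble::tibble(annotator = a, label = lab))
    }
    list(
      annotations = dplyr::bind_rows(ann)[, c("query", "returned", "source",
                                              "annotator", "label")],
      reference = dplyr::bind_cols(items, tibble::tibble(label = reference))
    )
  })
}

#' Closed-form expected agreement for the synthetic annotation process
#'
#' Enumerates the joint label distribution of two annotators under the
#' generating process of [generate_annotation_set()] (conditional on the
#' reference label, annotators are independent with
#' P(l | r) = a 1\[l = r\] + (1 - a) K\[r, l\]) and returns the expected
#' observed agreement, chance agreement and Cohen kappa.
#'
#' @param config A [synth_annotation_config()].
#' @return List with `p_o`, `p_e` and `kappa`.
#' @export
expected_pairwise_agreement <- function(config) {
  stopifnot(inherits(config, "synth_annotation_config"))
  labels <- semantic_types()
  a <- config$agreement_prob
  K <- config$confusion_kernel
  pi_r <- config$base_labels[labels]
  # P(l | r) for each reference label r
  P <- (1 - a) * K
  diag(P) <- diag(P) + a
  p_o <- sum(pi_r * rowSums(P^2))
  marg <- as.numeric(t(P) %*% pi_r)
  p_e <- sum(marg^2)
  kappa <- if (p_e >= 1 - 1e-12) {
    if (p_o >= 1 - 1e-12) 1 else 0
  } else {
    (p_o - p_e) / (1 - p_e)
  }
  list(p_o = p_o, p_e = p_e, kappa = kappa)
}

#' Configuration for a synthetic note corpus
#'
#' Describes per-cohort patient populations and, for each cohort, the
#' probability that each clinical concept is documented for a patient. A
#' documented concept is realised by embedding one of the concept's
#' lexicon terms verbatim at a word boundary of one of the patient's
#' notes; all remaining text is filler drawn from a vocabulary disjoint
#' from the lexicon.
#'
#' @param cohorts Named integer vector: cohort name -> patient count
#'   (names unique, counts positive).
#' @param concept_prevalence Named list: cohort -> named numeric vector of
#'   per-concept documentation probabilities in \[0, 1\]. Cohorts listed
#'   here must appear in `cohorts`.
#' @param filler_vocabulary Character vector of lowercase filler words;
#'   default is a packaged list of non-clinical words. Must not collide
#'   with any lexicon term or any token of a multi-word lexicon term
#'   (checked at generation time).
#' @param notes_per_patient Notes per patient (default 3).
#' @param words_per_note Filler words per note (default 20).
#' @param rng_seed Integer RNG seed.
#' @return A `synth_cohort_config` list.
#' @export
synth_cohort_config <- function(cohorts,
                                concept_prevalence,
                                filler_vocabulary = default_filler_vocabulary(),
                                notes_per_patient = 3,
                                words_per_note = 20,
                                rng_seed = 1L) {
  if (is.null(names(cohorts)) || anyDuplicated(names(cohorts)) ||
      any(cohorts < 1)) {
    stop("`cohorts` must be a named vector of positive patient counts with unique names",
         call. = FALSE)
  }
  unknown <- setdiff(names(concept_prevalence), names(cohorts))
  if (length(unknown) > 0) {
    stop(sprintf("prevalence given for unknown cohort(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  for (co in names(concept_prevalence)) {
    p <- concept_prevalence[[co]]
    if (is.null(names(p)) || any(p < 0 | p > 1)) {
      stop(sprintf("prevalences for cohort '%s' must be named and lie in [0, 1]", co),
           call. = FALSE)
    }
  }
  if (notes_per_patient < 1) stop("`notes_per_patient` must be positive", call. = FALSE)
  structure(
    list(
      cohorts = cohorts,
      concept_prevalence = concept_prevalence,
      filler_vocabulary = tolower(filler_vocabulary),
      notes_per_patient = as.integer(notes_per_patient),
      words_per_note = as.integer(words_per_note),
      rng_seed = as.integer(rng_seed)
    ),
    class = "synth_cohort_config"
  )
}

#' Default filler vocabulary for synthetic notes
#'
#' Lowercase non-clinical words used as background text; chosen to share
#' no token with the packaged seed-concept lexicons.
#'
#' @return Character vector of filler words.
#' @export
default_filler_vocabulary <- function() {
  c(
    "the", "and", "was", "were", "with", "for", "noted", "stable", "today",
    "morning", "evening", "plan", "continue", "home", "family", "diet",
    "activity", "ambulating", "tolerated", "well", "daily", "status",
    "arrival", "discharge", "followup", "clinic", "visit", "routine",
    "reviewed", "discussed", "improved", "unchanged", "baseline", "monitor",
    "labs", "ordered", "pending", "results", "within", "normal", "limits",
    "seen", "examined", "alert", "oriented", "resting", "comfortable"
  )
}

#' Generate a synthetic per-cohort note corpus
#'
#' For each patient and each concept with a configured prevalence in the
#' patient's cohort, a Bernoulli draw decides whether the concept is
#' documented; if so, one uniformly chosen lexicon term for the concept is
#' inserted verbatim at a uniformly chosen word boundary of a uniformly
#' chosen note. Filler text never contains a lexicon term (the filler
#' vocabulary is checked against every lexicon term and every token of
#' multi-word terms, and generation errors on collision), so feature
#' matching recovers exactly the planted concepts.
#'
#' @param config A [synth_cohort_config()].
#' @param lexicon A lexicon tibble (see [build_expanded_lexicon()])
#'   containing every concept named in the config's prevalences.
#' @return List with `notes` (tibble: `patient_id`, `cohort`,
#'   `note_text`) and `truth` (tibble: `patient_id`, `cohort`, `concept`,
#'   `planted`).
#' @export
generate_cohort_notes <- function(config, lexicon) {
  stopifnot(inherits(config, "synth_cohort_config"))
  concepts_needed <- unique(unlist(lapply(config$concept_prevalence, names)))
  missing <- setdiff(concepts_needed, unique(lexicon$concept))
  if (length(missing) > 0) {
    stop(sprintf("concept(s) missing from lexicon: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  lex_terms <- normalize_term_key(lexicon$term)
  lex_tokens <- unique(unlist(strsplit(lex_terms, " ", fixed = TRUE)))
  clash <- intersect(config$filler_vocabulary, union(lex_terms, lex_tokens))
  if (length(clash) > 0) {
    stop(sprintf("filler vocabulary overlaps lexicon terms/tokens: %s",
                 paste(clash, collapse = ", ")), call. = FALSE)
  }

  with_rng_seed(config$rng_seed, {
    notes_out <- list()
    truth_out <- list()
    for (co in names(config$cohorts)) {
      n_pat <- config$cohorts[[co]]
      prev <- config$concept_prevalence[[co]] %||% numeric(0)
      for (p in seq_len(n_pat)) {
        pid <- sprintf("%s_%05d", gsub("[^[:alnum:]]+", "_", co), p)
        note_words <- lapply(seq_len(config$notes_per_patient), function(i) {
          sample(config$filler_vocabulary, config$words_per_note, replace = TRUE)
        })
        planted <- stats::setNames(logical(length(prev)), names(prev))
        for (concept in names(prev)) {
          if (stats::runif(1) < prev[[concept]]) {
            planted[[concept]] <- TRUE
            terms <- lexicon_terms(lexicon, concept)
            term <- terms[sample.int(length(terms), 1)]
            ni <- sample.int(config$notes_per_patient, 1)
            pos <- sample.int(length(note_words[[ni]]) + 1L, 1) - 1L
            note_words[[ni]] <- append(note_words[[ni]], term, after = pos)
          }
        }
        notes_out[[length(notes_out) + 1L]] <- tibble::tibble(
          patient_id = pid,
          cohort = co,
          note_text = vapply(note_words, paste, "", collapse = " ")
        )
        if (length(prev) > 0) {
          truth_out[[length(truth_out) + 1L]] <- tibble::tibble(
            patient_id = pid, cohort = co,
            concept = names(prev), planted = unname(planted)
          )
        }
      }
    }
    list(
      notes = dplyr::bind_rows(notes_out),
      truth = dplyr::bind_rows(truth_out)
    )
  })
}
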