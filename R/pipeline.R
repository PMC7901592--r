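#' Default pipeline configuration
#'
#' Assembles the configuration for the packaged end-to-end synthetic
#' demonstration: seven synthetic embedding sources generated from the
#' packaged seed-term lists (two character-unit sources sharing their
#' synonym vocabulary with the five token-unit ones), top-20 retrieval,
#' three annotators at a controlled agreement probability, lexicon
#' expansion, and three patient cohorts (pneumonia, ARDS, COVID-19) with
#' planted per-concept documentation prevalences.
#'
#' @param out_dir Output directory for stage artifacts.
#' @param rng_seed Master seed; every stage derives its own sub-seed from
#'   it, so a full rerun with the same seed is byte-identical.
#' @param overrides Named list of fields to override.
#' @return A `pipeline_config` list.
#' @export
default_pipeline_config <- function(out_dir = tempfile("embedlex_run_"),
                                    rng_seed = 1L,
                                    overrides = list()) {
  seed_lists <- seed_term_lists()
  source_names <- c(
    "w2v_pubmed", "w2v_wiki_pubmed", "w2v_abstracts", "w2v_clinical",
    "ft_char_extrinsic", "ft_char_intrinsic", "glove_web"
  )
  cfg <- list(
    out_dir = out_dir,
    rng_seed = as.integer(rng_seed),
    seed_lists = seed_lists,
    k = 20,
    phrase_strategy = "key_then_average",
    source_names = source_names,
    source_units = stats::setNames(
      c("token", "token", "token", "token", "character", "character", "token"),
      source_names
    ),
    embedding_dimension = 50,
    # character-unit sources return far more lexical variants of the query
    # than token-unit sources do; the planted synonym counts mirror that
    synonyms_per_seed = stats::setNames(c(3, 3, 2, 3, 7, 7, 2), source_names),
    related_per_seed = 5,
    distractor_count = 60,
    target_cos_synonym = 0.9,
    target_cos_related = 0.4,
    cos_jitter = 0.05,
    annotator_ids = c("A1", "A2", "A3"),
    agreement_prob = 0.9,
    consensus_rule = "consensus",
    severity_map = severity_group_map(),
    cohorts = c(pneumonia = 150, ARDS = 150, "COVID-19" = 150),
    concept_prevalence = default_concept_prevalence(),
    notes_per_patient = 3,
    verbose = FALSE
  )
  cfg[names(overrides)] <- overrides
  structure(cfg, class = "pipeline_config")
}

#' Default planted per-cohort concept prevalences
#'
#' Documentation probabilities for clinical-feature concepts in the three
#' synthetic cohorts. The prominent features (fever, cough, shortness of
#' breath, hypoxia, dry cough) use cohort-level proportions in the ranges
#' reported for real pneumonia/ARDS/COVID-19 discharge-summary cohorts;
#' the remaining features use modest background rates shared across
#' cohorts.
#'
#' @return Named list: cohort -> named prevalence vector.
#' @export
default_concept_prevalence <- function() {
  background <- c(
    "sore throat" = 0.10, "malaise" = 0.08, "headache" = 0.12,
    "muscle pain" = 0.10, "nasal congestion" = 0.06, "dyspnea" = 0.30,
    "respiratory distress" = 0.20, "tachypnea" = 0.15
  )
  list(
    pneumonia = c(
      fever = 0.61, cough = 0.41, "shortness of breath" = 0.40,
      hypoxia = 0.51, "dry cough" = 0.05, background
    ),
    ARDS = c(
      fever = 0.84, cough = 0.55, "shortness of breath" = 0.59,
      hypoxia = 0.56, "dry cough" = 0.03, background
    ),
    "COVID-19" = c(
      fever = 0.75, cough = 0.48, "shortness of breath" = 0.50,
      hypoxia = 0.54, "dry cough" = 0.07, background
    )
  )
}

#' Read a pipeline configuration file
#'
#' Reads a YAML or JSON file of configuration overrides and merges it
#' into [default_pipeline_config()]. Scalar and vector fields override
#' directly; `seed_lists`, `cohorts` and `concept_prevalence` replace the
#' defaults wholesale when given.
#'
#' @param path YAML (`.yml`/`.yaml`) or JSON file.
#' @param out_dir,rng_seed Defaults forwarded to
#'   [default_pipeline_config()] unless the file overrides them.
#' @return A `pipeline_config` list.
#' @export
read_pipeline_config <- function(path, out_dir = tempfile("embedlex_run_"),
                                 rng_seed = 1L) {
  ext <- tolower(tools::file_ext(path))
  overrides <- if (ext %in% c("yml", "yaml")) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  if (!is.null(overrides$k)) overrides$k <- as.integer(overrides$k)
  if (!is.null(overrides$cohorts)) {
    overrides$cohorts <- vapply(overrides$cohorts, as.integer, 1L)
  }
  if (!is.null(overrides$concept_prevalence)) {
    overrides$concept_prevalence <- lapply(overrides$concept_prevalence, unlist)
  }
  default_pipeline_config(out_dir = out_dir, rng_seed = rng_seed,
                          overrides = overrides)
}

pipeline_stages <- function() {
  c("simulate", "query", "agree", "profile", "lexicon", "cohort")
}

stage_prerequisites <- function() {
  list(
    simulate = character(0),
    query = "registry.yaml",
    agree = c("candidates.tsv", "truth.tsv"),
    profile = c("candidates.tsv", "annotations.tsv"),
    lexicon = "annotations.tsv",
    cohort = "lexicon.tsv"
  )
}

pipeline_log <- function(config, ...) {
  if (isTRUE(config$verbose)) message(sprintf(...))
}

# Reference semantic label for a candidate, relative to the query it was
# returned for: a planted synonym of the queried concept is a synonym, a
# related term of the queried concept is another symptom/sign, anything
# anchored to a different concept (its seed, synonyms or related terms) is
# a distinct clinical term (disease_disorder), and distractors are other.
role_reference_label <- function(role, anchor_seed, query) {
  same <- !is.na(anchor_seed) &
    normalize_term_key(anchor_seed) == normalize_term_key(query)
  ifelse(role == "distractor", "other",
    ifelse(same,
      ifelse(role == "synonym", "synonym", "symptom_sign"),
      "disease_disorder"
    )
  )
}

# per-stage deterministic sub-seed, derived from the master seed
stage_seed <- function(config, stage, i = 0L) {
  (config$rng_seed * 1009L + match(stage, pipeline_stages()) * 101L + i) %% 2147483647L
}

#' Run the lexicon-development pipeline
#'
#' Executes the requested stages in order, writing each stage's tabular
#' artifacts to `config$out_dir` and finally a `manifest.json` recording
#' the stages run, the key parameters, the master seed and an MD5
#' checksum of every artifact. All randomness is derived from the master
#' seed, so rerunning the same configuration reproduces byte-identical
#' tabular outputs.
#'
#' Stages: `simulate` (generate the seven synthetic sources, their truth
#' tables and a source registry), `query` (top-k retrieval for every seed
#' term against every source), `agree` (synthetic annotator labels over
#' the retrieved candidates plus agreement reports and disagreement
#' matrices), `profile` (frequency weights, semantic-type distributions,
#' group mean counts, modifier contrasts), `lexicon` (expanded concept
#' lexicon), `cohort` (synthetic notes, feature matching, per-cohort
#' proportions, severity roll-up).
#'
#' @param config A `pipeline_config` (see [default_pipeline_config()]).
#' @param stages Character vector of stages, or `"all"`.
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config = default_pipeline_config(), stages = "all") {
  stopifnot(inherits(config, "pipeline_config"))
  if (identical(stages, "all")) stages <- pipeline_stages()
  unknown <- setdiff(stages, pipeline_stages())
  if (length(unknown) > 0) {
    stop(sprintf("unknown stage(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  }
  stages <- pipeline_stages()[pipeline_stages() %in% stages]
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  prereq <- stage_prerequisites()
  provider <- c(
    "registry.yaml" = "simulate", "truth.tsv" = "simulate",
    "candidates.tsv" = "query", "annotations.tsv" = "agree",
    "lexicon.tsv" = "lexicon"
  )
  for (st in stages) {
    for (artifact in prereq[[st]]) {
      if (!file.exists(file.path(config$out_dir, artifact)) &&
          !provider[[artifact]] %in% stages) {
        stop(sprintf(
          "stage '%s' needs %s; run stage '%s' first",
          st, artifact, provider[[artifact]]
        ), call. = FALSE)
      }
    }
    pipeline_log(config, "running stage: %s", st)
    switch(st,
      simulate = stage_simulate(config),
      query = stage_query(config),
      agree = stage_agree(config),
      profile = stage_profile(config),
      lexicon = stage_lexicon(config),
      cohort = stage_cohort(config)
    )
  }

  files <- sort(setdiff(list.files(config$out_dir), "manifest.json"))
  manifest <- list(
    stages = stages,
    rng_seed = config$rng_seed,
    parameters = list(
      k = config$k,
      phrase_strategy = config$phrase_strategy,
      agreement_prob = config$agreement_prob,
      consensus_rule = config$consensus_rule,
      cohorts = as.list(config$cohorts)
    ),
    artifacts = as.list(tools::md5sum(file.path(config$out_dir, files)) |>
                          stats::setNames(files))
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

stage_simulate <- function(config) {
  all_seeds <- unlist(config$seed_lists, use.names = FALSE)
  registry <- list()
  truth_all <- list()
  for (i in seq_along(config$source_names)) {
    nm <- config$source_names[i]
    synth_cfg <- synth_embedding_config(
      seed_terms = all_seeds,
      dimension = config$embedding_dimension,
      synonyms_per_seed = if (length(config$synonyms_per_seed) > 1) {
        config$synonyms_per_seed[[nm]]
      } else {
        config$synonyms_per_seed
      },
      related_per_seed = config$related_per_seed,
      distractor_count = config$distractor_count,
      target_cos_synonym = config$target_cos_synonym,
      target_cos_related = config$target_cos_related,
      cos_jitter = config$cos_jitter,
      rng_seed = stage_seed(config, "simulate", i)
    )
    space <- generate_embedding_space(synth_cfg, name = nm, source_tag = nm)
    emb_file <- paste0(nm, ".vec")
    write_embedding(space$source, file.path(config$out_dir, emb_file),
                    dialect = "word2vec_text")
    truth_all[[nm]] <- dplyr::mutate(space$truth, source = nm)
    registry[[i]] <- list(
      name = nm, path = emb_file, dialect = "word2vec_text",
      unit = unname(config$source_units[nm]),
      case_policy = "lowercase", phrase_policy = "multiword_keys"
    )
  }
  write_truth_table(dplyr::bind_rows(truth_all),
                    file.path(config$out_dir, "truth.tsv"))
  yaml::write_yaml(list(sources = registry),
                   file.path(config$out_dir, "registry.yaml"))
}

stage_query <- function(config) {
  registry <- read_source_registry(file.path(config$out_dir, "registry.yaml"))
  sources <- load_sources(registry)
  all_seeds <- unlist(config$seed_lists, use.names = FALSE)
  out <- list()
  for (q in all_seeds) {
    lists <- query_sources(sources, q, k = config$k,
                           phrase_strategy = config$phrase_strategy)
    out[[q]] <- dplyr::bind_rows(lists)
  }
  write_candidates(dplyr::bind_rows(out),
                   file.path(config$out_dir, "candidates.tsv"))
}

stage_agree <- function(config) {
  candidates <- read_candidates(file.path(config$out_dir, "candidates.tsv"))
  truth <- read_tsv_utf8(file.path(config$out_dir, "truth.tsv"))
  ref <- truth[match(paste(candidates$returned, candidates$source),
                     paste(truth$term, truth$source)), ]
  if (anyNA(ref$role)) {
    stop("candidate term missing from the truth table", call. = FALSE)
  }
  reference <- role_reference_label(ref$role, ref$seed, candidates$query)

  labels <- semantic_types()
  kernel <- matrix(1 / (length(labels) - 1), length(labels), length(labels),
                   dimnames = list(labels, labels))
  diag(kernel) <- 0
  ann <- with_rng_seed(stage_seed(config, "agree"), {
    out <- list()
    n <- nrow(candidates)
    for (a in config$annotator_ids) {
      copy <- stats::runif(n) < config$agreement_prob
      lab <- reference
      for (i in which(!copy)) {
        lab[i] <- sample(labels, 1, prob = kernel[reference[i], ])
      }
      out[[a]] <- tibble::tibble(
        query = candidates$query, returned = candidates$returned,
        source = candidates$source, annotator = a, label = lab
      )
    }
    dplyr::bind_rows(out)
  })
  write_annotations(ann, file.path(config$out_dir, "annotations.tsv"))

  categories <- query_term_categories(config$seed_lists)
  by_cat <- pairwise_agreement(ann, "by_category", categories = categories)
  by_query <- pairwise_agreement(ann, "by_query_term")
  drop_conf <- function(x) {
    x$kappa <- sprintf("%.4f", x$kappa)
    as.data.frame(x[, c("annotator_a", "annotator_b", "stratum", "kappa",
                        "item_count")])
  }
  write_tsv_utf8(drop_conf(by_cat),
                 file.path(config$out_dir, "agreement_by_category.tsv"))
  write_tsv_utf8(drop_conf(by_query),
                 file.path(config$out_dir, "agreement_by_query.tsv"))

  pairs <- utils::combn(sort(unique(config$annotator_ids)), 2, simplify = FALSE)
  for (pr in pairs) {
    m <- disagreement_matrix(ann, pr)
    utils::write.csv(m, file.path(
      config$out_dir, sprintf("disagreement_%s_%s.csv", pr[1], pr[2])
    ))
  }
}

stage_profile <- function(config) {
  candidates <- read_candidates(file.path(config$out_dir, "candidates.tsv"))
  ann <- read_annotations(file.path(config$out_dir, "annotations.tsv"))

  weights <- list()
  for (q in unique(candidates$query)) {
    sub <- candidates[candidates$query == q, ]
    lists <- split(sub, sub$source)
    w <- frequency_weights(lists)
    w$query <- q
    weights[[q]] <- w[, c("query", "term", "source_count", "total_sources",
                          "weight")]
  }
  write_profile_table(dplyr::bind_rows(weights),
                      file.path(config$out_dir, "weights.tsv"))

  dist <- semantic_type_distribution(ann, candidates)
  write_tsv_utf8(as.data.frame(dist), file.path(config$out_dir,
                                                "distributions.tsv"))

  char_sources <- names(config$source_units)[config$source_units == "character"]
  token_sources <- names(config$source_units)[config$source_units == "token"]
  groups <- tibble::tibble(
    group = c("character_unit", "token_unit"),
    mean_synonym_count = c(
      mean_type_count(dist, char_sources, "synonym"),
      mean_type_count(dist, token_sources, "synonym")
    )
  )
  write_tsv_utf8(as.data.frame(groups),
                 file.path(config$out_dir, "mean_synonym_counts.tsv"))

  contrasts <- modifier_contrast(dist, pairs = modifier_pairs())
  write_tsv_utf8(as.data.frame(contrasts),
                 file.path(config$out_dir, "contrasts.tsv"))
}

stage_lexicon <- function(config) {
  ann <- read_annotations(file.path(config$out_dir, "annotations.tsv"))
  seeds <- unlist(config$seed_lists, use.names = FALSE)
  seed_concepts <- stats::setNames(as.list(seeds), seeds)
  lex <- build_expanded_lexicon(seed_concepts, ann,
                                rule = config$consensus_rule)
  write_lexicon(lex, file.path(config$out_dir, "lexicon.tsv"))
}

stage_cohort <- function(config) {
  lex <- read_lexicon(file.path(config$out_dir, "lexicon.tsv"))
  cohort_cfg <- synth_cohort_config(
    cohorts = config$cohorts,
    concept_prevalence = config$concept_prevalence,
    notes_per_patient = config$notes_per_patient,
    rng_seed = stage_seed(config, "cohort")
  )
  corpus <- generate_cohort_notes(cohort_cfg, lex)
  write_notes(corpus$notes, file.path(config$out_dir, "notes.tsv"))
  matches <- match_features(corpus$notes, lex)
  write_tsv_utf8(as.data.frame(matches), file.path(config$out_dir,
                                                   "matches.tsv"))
  props <- feature_proportions(matches)
  write_proportions(props, file.path(config$out_dir, "proportions.tsv"))
  sev <- severity_rollup(matches, config$severity_map)
  write_tsv_utf8(as.data.frame(sev), file.path(config$out_dir, "severity.tsv"))
}
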