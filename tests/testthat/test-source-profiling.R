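fake_list <- function(source, terms, query = "fever") {
  tibble::tibble(
    query = query, returned = terms,
    cosine = seq(0.9, by = -0.01, length.out = length(terms)),
    rank = seq_along(terms), source = source
  )
}

test_that("frequency weights count sources at any rank and hit the bounds", {
  lists <- lapply(sprintf("s%d", 1:7), function(s) {
    fake_list(s, c("pyrexia", paste0("term_", s)))
  })
  names(lists) <- sprintf("s%d", 1:7)
  w <- frequency_weights(lists)
  expect_equal(w$weight[w$term == "pyrexia"], 1.0)
  expect_equal(round(w$weight[w$term == "term_s1"], 2), 0.14)
  expect_equal(w$source_count[w$term == "pyrexia"], 7L)
  expect_true(all(w$source_count <= w$total_sources))

  # 3 of 7 sources
  lists37 <- lapply(sprintf("s%d", 1:7), function(s) {
    fake_list(s, if (s %in% c("s1", "s2", "s3")) c("febrile", "x") else "x")
  })
  w37 <- frequency_weights(lists37)
  expect_equal(w37$weight[w37$term == "febrile"], 3 / 7, tolerance = 1e-12)

  # single-source run: every weight is exactly 1
  w1 <- frequency_weights(lists[1])
  expect_true(all(w1$weight == 1))
})

test_that("frequency weights unify delimiter and case variants across sources", {
  lists <- list(
    s1 = fake_list("s1", "dry_cough"),
    s2 = fake_list("s2", "dry-cough"),
    s3 = fake_list("s3", "Dry Cough")
  )
  w <- frequency_weights(lists)
  expect_identical(nrow(w), 1L)
  expect_identical(w$source_count, 3L)
})

test_that("consensus labeling is majority with documented priority ties", {
  expect_identical(as.character(consensus_label(c("synonym", "synonym", "hypernym"))),
                   "synonym")
  expect_false(attr(consensus_label(c("synonym", "synonym", "hypernym")), "tie"))
  three_way <- consensus_label(c("synonym", "hypernym", "other"))
  expect_identical(as.character(three_way), "synonym")
  expect_true(attr(three_way, "tie"))
  # priority also decides non-synonym ties deterministically
  hh <- consensus_label(c("hyponym", "hypernym"))
  expect_identical(as.character(hh), "hypernym")
  expect_true(attr(hh, "tie"))
  expect_identical(as.character(consensus_label("therapeutic")), "therapeutic")
})

test_that("semantic-type distributions conserve candidate counts", {
  cands <- dplyr::bind_rows(
    fake_list("s1", c("cand_001", "cand_002", "cand_003")),
    fake_list("s2", c("cand_001", "cand_002"))
  )
  ann <- dplyr::bind_rows(
    make_annotations(A1 = c("synonym", "synonym", "other"),
                     A2 = c("synonym", "hypernym", "other"),
                     A3 = c("synonym", "synonym", "qualifier"), source = "s1"),
    make_annotations(A1 = c("synonym", "negation"),
                     A2 = c("synonym", "negation"),
                     A3 = c("synonym", "negation"), source = "s2")
  )
  dist <- semantic_type_distribution(ann, cands)
  expect_identical(nrow(dist), 2L)
  type_cols <- semantic_types()
  expect_equal(unname(rowSums(dist[, type_cols])), c(3, 2))
  s1 <- dist[dist$source == "s1", ]
  expect_identical(s1$synonym, 2L)
  expect_identical(s1$other, 1L)
  expect_identical(s1$tie_count, 0L)

  # an unlabeled candidate is an error naming it
  expect_error(
    semantic_type_distribution(ann, dplyr::bind_rows(cands, fake_list("s1", "mystery"))),
    "mystery"
  )
})

test_that("distributions read back the planted reference mix exactly", {
  cfg <- synth_annotation_config(
    item_count = 120, agreement_prob = 1.0,
    base_labels = c(synonym = 0.5, hypernym = 0.3, other = 0.2),
    rng_seed = 5
  )
  aset <- generate_annotation_set(cfg, queries = "fever", sources = "s1")
  cands <- tibble::tibble(
    query = aset$reference$query, returned = aset$reference$returned,
    cosine = 0.5, rank = seq_len(nrow(aset$reference)),
    source = aset$reference$source
  )
  dist <- semantic_type_distribution(aset$annotations, cands)
  planted <- table(factor(aset$reference$label, levels = semantic_types()))
  expect_identical(as.integer(dist[1, semantic_types()]),
                   as.integer(planted))
})

test_that("mean type counts average over (source, query) cells", {
  dist <- tibble::tibble(
    source = c("s1", "s2", "s1", "s2"),
    query = c("fever", "fever", "cough", "cough")
  )
  for (ty in semantic_types()) dist[[ty]] <- 0L
  dist$synonym <- c(6L, 8L, 5L, 9L)
  expect_equal(mean_type_count(dist, c("s1", "s2"), "synonym"), 7.0)
  expect_equal(mean_type_count(dist, "s1", "synonym"), 5.5)
  # invariant to row order
  expect_equal(mean_type_count(dist[sample.int(4), ], c("s1", "s2"), "synonym"), 7.0)
  expect_error(mean_type_count(dist, character(0), "synonym"), "at least one")
  expect_error(mean_type_count(dist, "s9", "synonym"), "absent")
})

test_that("a fixture averaging 7.2 synonyms per query recovers 7.2", {
  # two character-unit sources x five queries with synonym counts
  # summing to 72 over 10 cells
  counts <- c(7L, 8L, 6L, 9L, 7L, 7L, 8L, 6L, 7L, 7L)
  stopifnot(sum(counts) == 72L)
  dist <- tibble::tibble(
    source = rep(c("char1", "char2"), each = 5),
    query = rep(sprintf("q%d", 1:5), 2)
  )
  for (ty in semantic_types()) dist[[ty]] <- 0L
  dist$synonym <- counts
  expect_identical(mean_type_count(dist, c("char1", "char2"), "synonym"), 7.2)
})

test_that("modifier contrasts compare variant means and demand both variants", {
  dist <- tibble::tibble(
    source = rep(c("s1", "s2"), each = 2),
    query = rep(c("cough", "dry cough"), 2)
  )
  for (ty in semantic_types()) dist[[ty]] <- 0L
  dist$qualifier <- c(1L, 4L, 1L, 4L)
  pairs <- tibble::tibble(unmodified = "cough", modified = "dry cough")
  con <- modifier_contrast(dist, pairs, types = "qualifier")
  expect_equal(con$mean_modified, 4.0)
  expect_equal(con$mean_unmodified, 1.0)
  expect_equal(con$difference, 3.0)

  # identical distributions give zero difference for every type
  dist$qualifier <- 2L
  con0 <- modifier_contrast(dist, pairs)
  expect_true(all(con0$difference == 0))
  expect_identical(nrow(con0), length(semantic_types()))

  expect_error(
    modifier_contrast(dist, tibble::tibble(unmodified = "fever",
                                           modified = "high fever")),
    "missing from distributions"
  )
})

test_that("the annotation grid multiplies counts or vector lengths", {
  expect_identical(annotation_grid_size(query_terms = 1, sources = 1,
                                        k = 1, annotators = 1), 1L)
  expect_identical(
    annotation_grid_size(query_terms = sprintf("q%d", 1:25), sources = 7,
                         k = 20, annotators = c("A1", "A2", "A3")),
    10500L
  )
  expect_error(annotation_grid_size(0, 7, 20, 3), "positive")
})
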