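#' The ten-class semantic annotation scheme
#'
#' Candidate terms returned by an embedding query are annotated with one of
#' ten semantic classes describing their relation to the queried clinical
#' concept: a negation of it, a synonym (lexical variant with the same
#' meaning), an unrelated symptom/sign, an unrelated disease/disorder, a
#' hyponym (more specific) or hypernym (broader) of it, a non-clinical
#' qualifier, an anatomical location, a therapeutic (drug, therapy or
#' procedure), or other. The label set is closed: every annotation must use
#' one of these ten labels, and agreement statistics are computed over the
#' full set even when some labels are unobserved.
#'
#' @return Character vector of the ten semantic-type labels, in canonical
#'   order.
#' @seealso [semantic_type_colors()] for the display colours conventionally
#'   attached to each class.
#' @export
#' @examples
#' semantic_types()
semantic_types <- function() {
  c(
    "negation", "synonym", "symptom_sign", "disease_disorder",
    "hyponym", "hypernym", "qualifier", "anatomical_location",
    "therapeutic", "other"
  )
}

#' Display colours for the semantic classes
#'
#' @return Named character vector mapping each semantic type to its
#'   conventional display colour.
#' @export
semantic_type_colors <- function() {
  c(
    negation = "black",
    synonym = "green",
    symptom_sign = "yellow",
    disease_disorder = "blue",
    hyponym = "lightred",
    hypernym = "darkred",
    qualifier = "teal",
    anatomical_location = "orange",
    therapeutic = "purple",
    other = "grey"
  )
}

assert_semantic_labels <- function(labels, arg = "labels") {
  bad <- setdiff(unique(as.character(labels)), semantic_types())
  if (length(bad) > 0) {
    stop(
      sprintf(
        "`%s` contains labels outside the semantic-type scheme: %s",
        arg, paste(bad, collapse = ", ")
      ),
      call. = FALSE
    )
  }
  invisible(TRUE)
}

#' Seed clinical concept terms by category
#'
#' The COVID-19-related seed concepts used to query embedding sources,
#' grouped into the three clinical categories: symptoms, findings and
#' disorders. These seed lists also define the category assignment used when
#' agreement is stratified by category.
#'
#' @return Named list with elements `symptom`, `finding` and `disorder`,
#'   each a character vector of query terms.
#' @export
#' @examples
#' lengths(seed_term_lists())
seed_term_lists <- function() {
  list(
    symptom = c(
      "fever", "high fever", "cough", "wet cough", "dry cough",
      "congestion", "nasal congestion", "pain", "chest pain", "muscle pain",
      "shortness of breath", "dyspnea", "tachypnea", "malaise", "headache",
      "sore throat"
    ),
    finding = c(
      "hypoxia", "opacities", "bilateral opacities", "infiltrates",
      "lung infiltrates"
    ),
    disorder = c(
      "ARDS", "respiratory distress", "acute respiratory distress syndrome",
      "pneumonia"
    )
  )
}

#' Category lookup for query terms
#'
#' @param seed_lists Named list of category -> terms, as returned by
#'   [seed_term_lists()].
#' @return Named character vector mapping each query term to its category.
#' @export
query_term_categories <- function(seed_lists = seed_term_lists()) {
  stats::setNames(
    rep(names(seed_lists), lengths(seed_lists)),
    unlist(seed_lists, use.names = FALSE)
  )
}

#' Modified/unmodified query-term pairs
#'
#' Query terms that occur both bare and with a modifier (a qualifier or an
#' anatomical adjective), used to contrast the semantic types returned for
#' modified versus unmodified queries.
#'
#' @return A tibble with columns `category`, `unmodified` and `modified`;
#'   one row per (unmodified, modified) variant pair.
#' @export
modifier_pairs <- function() {
  tibble::tribble(
    ~category, ~unmodified, ~modified,
    "symptom", "fever", "high fever",
    "symptom", "cough", "wet cough",
    "symptom", "cough", "dry cough",
    "symptom", "congestion", "nasal congestion",
    "symptom", "pain", "chest pain",
    "symptom", "pain", "muscle pain",
    "finding", "opacities", "bilateral opacities",
    "finding", "infiltrates", "lung infiltrates",
    "disorder", "ARDS", "respiratory distress",
    "disorder", "ARDS", "acute respiratory distress syndrome"
  )
}

#' Respiratory illness severity groups and their clinical features
#'
#' Maps each severity group to the clinical-feature concepts that
#' characterise it, together with the rule combining them:
#' \describe{
#'   \item{mild illness}{any one of fever, cough, sore throat, malaise,
#'     headache, muscle pain, nasal congestion.}
#'   \item{moderate pneumonia}{cough AND shortness of breath.}
#'   \item{severe pneumonia/ARDS}{fever AND at least one of dyspnea,
#'     respiratory distress, tachypnea, hypoxia.}
#' }
#' The severe rule reads an ambiguous prose description as an anchor
#' conjunction (fever) with a disjunction over the associated respiratory
#' features; the rule field makes the reading explicit and overridable.
#'
#' @return Named list of groups. Each group is a list with fields
#'   `features` (character vector of concept names), `rule` (one of
#'   `"any"`, `"all"`, `"anchor_any"`) and, for `"anchor_any"`, `anchor`
#'   (the concept that must always be present).
#' @export
severity_group_map <- function() {
  list(
    "mild illness" = list(
      features = c(
        "fever", "cough", "sore throat", "malaise", "headache",
        "muscle pain", "nasal congestion"
      ),
      rule = "any"
    ),
    "moderate pneumonia" = list(
      features = c("cough", "shortness of breath"),
      rule = "all"
    ),
    "severe pneumonia/ARDS" = list(
      anchor = "fever",
      features = c("dyspnea", "respiratory distress", "tachypnea", "hypoxia"),
      rule = "anchor_any"
    )
  )
}
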