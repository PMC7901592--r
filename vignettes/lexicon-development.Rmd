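---
title: "Developing clinical concept lexicons from word-embedding sources"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Developing clinical concept lexicons from word-embedding sources}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(embedlex)
```

## The problem

Extracting COVID-19-related clinical information from free-text notes starts
with a lexicon: for each clinical concept (fever, dry cough, hypoxia, ...),
the set of surface terms that express it in text. Public word embeddings —
vector spaces trained on PubMed, clinical notes, Wikipedia or web crawls —
offer a cheap way to expand a seed lexicon: terms whose vectors sit close to
a seed term's vector (by cosine similarity) are candidate synonyms. But the
candidates returned depend heavily on how each embedding source was built
(token vs character units, case folding, phrase keys), and most candidates
are not synonyms at all: they are hypernyms, qualifiers, co-occurring
symptoms, negations, or noise.

`embedlex` implements the full pipeline around that observation:

1. load embedding sources in their standard file dialects, with per-source
   construction metadata driving query normalisation;
2. rank each source's vocabulary by cosine similarity to seed concepts and
   keep the top k (default 20) candidates;
3. have multiple annotators classify each candidate into a closed ten-class
   semantic scheme, and quantify their reliability with pairwise Cohen
   kappa and disagreement matrices;
4. profile candidates across sources: cross-source frequency weights (the
   word-cloud scale), cosine ranges with a −1 sentinel for absence,
   per-source semantic-type distributions, and modified-vs-unmodified query
   contrasts;
5. fold consensus-labeled synonyms into an expanded lexicon, match it
   against patient notes with word-boundary semantics, and report
   per-cohort feature-documentation proportions and severity-group
   roll-ups.

Because the real inputs of such a study (proprietary embedding downloads,
annotation tables, hospital notes) are not redistributable, the package
ships a first-class synthetic-data module that generates all three with
known ground truth, so every stage is testable end to end.

## Retrieval model

For a query $q$ and vocabulary vectors $v_i$, candidates are ranked by
cosine similarity $\cos(q, v_i) = \langle q, v_i\rangle / (\lVert q\rVert\,
\lVert v_i\rVert)$, computed in double precision with per-source norms; ties
are broken lexicographically on the returned key so rankings are
deterministic. Every vocabulary key the query normalises to (case and
delimiter variants) is excluded from the candidate list, preventing trivial
self-returns.

Query normalisation follows each source's construction: case-folding only
for lowercase-built sources, and phrase probing in the order
underscore-joined, hyphen-joined, verbatim — underscore being the dominant
phrase-key convention in public releases. Multi-word queries with no phrase
key fall back (under the default `key_then_average` strategy) to the
unweighted mean of the constituent-token vectors; runs record the strategy
used, since released sources do not document how phrases should be probed.
Out-of-vocabulary tokens are a hard error naming the failing token.

## Agreement model

Annotators label each (query, returned term, source) item with one of ten
semantic types (negation, synonym, symptom/sign, disease/disorder, hyponym,
hypernym, qualifier, anatomical location, therapeutic, other). Reliability
is pairwise Cohen kappa, $\kappa = (p_o - p_e)/(1 - p_e)$, computed over the
full closed label set even when a stratum never uses some labels — the
instrument, not the observed data, defines the label space. The degenerate
case $p_e = 1$ returns 1 when observed agreement is perfect and 0 otherwise,
keeping single-label strata reportable. Strata are either the query term or
its clinical category; categories come from the seed-list assignment, never
from the annotations. Duplicate (item, annotator) rows and items labeled by
only one annotator of a pair are hard errors: silent fixes hide data
problems.

Consensus labels (used for distributions and lexicon building) are majority
votes with a fixed documented priority order for ties (synonym first), and
every tie is flagged in the output. Majority-with-priority was chosen
because it is deterministic and auditable; an `"any"` rule (any annotator
said synonym) is available for lexicon building where recall matters more.

## Cross-source profiling

A returned term's frequency weight is (number of sources whose top-k list
contains it, at any rank) / (number of sources); with seven sources it
ranges from 0.14 to 1.0 and is the size scale of the word-cloud view. Term
identity across sources is case-folded and delimiter-insensitive
(underscore = hyphen = space), because the same concept surfaces as
`dry_cough` or `dry-cough` depending on the corpus. A term absent from a
source's list carries the sentinel value −1 in cross-source cosine records,
distinguishing absence from genuine low similarity. Group mean counts
(e.g. mean synonyms per query for character-unit vs token-unit sources) and
modifier contrasts (qualifier counts for "dry cough" vs "cough") are plain
means over (source, query) cells, reported to two decimals.

## Matching semantics

A patient is positive for a concept when any of their notes contains any
lexicon term as a case-insensitive, word-boundary-delimited contiguous
phrase; multi-word terms match across single spaces, and hyphen/underscore
spellings of the internal delimiters also match. There is no stemming and no
negation, severity or temporality handling — contextualisation is a separate
downstream problem, and proportions computed here count documentation, not
assertion. One consequence worth knowing: nested terms legitimately
cross-match ("...dry cough..." documents both "dry cough" and "cough"), so
a nested concept's proportion is a superset count, exactly as keyword
matching behaves on real notes.

## The synthetic-data module

The generators define the package's study conditions:

* **Embedding spaces.** Each seed direction is a random unit vector,
  re-drawn until $|\cos| \le 0.3$ against every earlier seed (the same
  check-and-resample rule, capped at 1000 attempts, used for distractors);
  this makes planted-structure recovery a construction guarantee rather
  than a property of a lucky draw. A planted vector at target cosine $c$
  to seed $u$ is $v = c\,u + \sqrt{1 - c^2}\,r$, with $r$ an exact
  Gram–Schmidt orthogonal complement of a normal draw. Defaults — cosine
  0.9 for synonyms, 0.4 for related terms, jitter 0.05, distractors within
  ±0.3 of orthogonal — keep the synonym band (≥ 0.85) strictly above
  everything else, so the top-$m$ neighbours of each seed are exactly its
  $m$ planted synonyms. Synonym names are shared across sources generated
  from the same seeds, while related/distractor names can carry a
  per-source tag: sources then share lexical variants but keep
  idiosyncratic remainder vocabularies, which is what makes cross-source
  frequency weights span their full range.
* **Annotations.** Each item has a latent reference label from a base
  distribution; each annotator copies it with probability $a$ and
  otherwise draws from the reference label's confusion-kernel row. The
  closed-form expected kappa under this process (enumerating the joint
  label-pair distribution) is exposed as `expected_pairwise_agreement()`
  and is what the Monte-Carlo tests check against. The pipeline default
  $a = 0.9$ yields kappas in the high-agreement range reported for trained
  clinical annotators.
* **Note corpora.** Filler text is lowercase words drawn from a vocabulary
  checked to share no term — and no token of a multi-word term — with the
  lexicon; the check is deliberately stricter than "no whole-term overlap"
  so that adjacent filler words can never concatenate into a multi-word
  lexicon phrase. Planted concepts insert a uniformly chosen lexicon term
  at a word boundary of a uniformly chosen note. Matching therefore
  recovers planted prevalence exactly up to binomial noise when concepts'
  term sets are token-disjoint; with nested concepts (the packaged seed
  lists) recovered proportions are inflated for the enclosing concept, as
  on real notes.

What passing on synthetic data does **not** show: robustness to
misspellings, inflection ("coughing"), negated mentions, templated note
structure, or embedding spaces whose similarity structure is not cleanly
separated — real sources return morphological noise and polysemous terms
that the planted geometry does not emulate.

## Pipeline and reproducibility

`run_pipeline()` executes the stages simulate → query → agree → profile →
lexicon → cohort, each reading only the tabular artifacts of its
predecessors and writing tab-separated outputs plus a JSON manifest with
MD5 checksums. All randomness derives from one master seed through fixed
per-stage offsets, so a rerun with the same configuration is byte-identical
— the manifest checksums are the determinism contract. Default problem
sizes (seven sources of ~500-term vocabularies at dimension 50, top-20
retrieval over 25 queries, three annotators, three cohorts of 150 patients)
were chosen so a complete run takes seconds on a laptop while every
downstream table is densely populated; all are configuration fields.

In the pipeline's `agree` stage, reference labels are assigned relative to
the query: a planted synonym of a *different* concept that strays into a
query's top-20 is a distinct clinical term (disease/disorder), not a
synonym. The character-unit sources plant 7 synonyms per seed versus 2–3
for token-unit sources, reproducing the qualitative contrast that
character-based embeddings return far more lexical variants of the query.
Default cohort prevalences for the prominent features (fever 0.61–0.84,
cough 0.41–0.55, shortness of breath 0.40–0.59, hypoxia 0.51–0.56, dry
cough 0.03–0.07 across the pneumonia/ARDS/COVID-19 cohorts) sit in the
ranges reported for real discharge-summary cohorts; background features use
modest shared rates.

## Numerical and degenerate-input choices

* Cosines are clamped into [−1, 1] after division to absorb rounding;
  zero-norm vectors are an error, never silently 0.
* Text serialisation writes 8 significant digits; the binary dialect
  stores 32-bit floats — round-trips are exact on vocabulary and order,
  and ≤ 1e−6 per component on values.
* Duplicate keys in embedding files keep the first occurrence with a
  warning (tolerant loading); duplicate annotation rows are an error
  (data integrity).
* Empty note text is allowed and matches nothing; empty cohorts are an
  error.
* The severe-illness rule is read as fever AND at least one of dyspnea,
  respiratory distress, tachypnea, hypoxia; the group map carries the rule
  explicitly (`any` / `all` / `anchor_any`) so the reading is overridable.

## Worked example

```{r, eval = FALSE}
cfg <- default_pipeline_config(out_dir = "run", rng_seed = 1)
manifest <- run_pipeline(cfg, "all")

read_lexicon(file.path("run", "lexicon.tsv")) |> head()
utils::read.delim(file.path("run", "proportions.tsv")) |>
  subset(concept == "fever")
```

## Known limitations

Matching is surface-level keyword matching; no UMLS normalisation, no
subword inference for out-of-vocabulary terms, no approximate-neighbour
indexing (unnecessary at 25 queries x 7 sources), and no rendering of word
clouds beyond exporting the weight table. The synthetic annotators err
uniformly by default; real disagreement is structured (hypernym/hyponym
confusions), which the confusion kernel can encode but the defaults do not.
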