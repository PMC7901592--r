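#' Construct an embedding source
#'
#' An `embedding_source` bundles a vocabulary-to-vector map with the
#' construction metadata needed to query it correctly: whether the model was
#' trained on tokens or characters, whether its vocabulary is lowercased,
#' and whether it contains multi-word keys. Downstream query normalisation
#' consults this metadata so that, for example, a lowercase source is probed
#' with case-folded forms.
#'
#' @param name Source name (non-empty string).
#' @param vectors Numeric matrix, one row per vocabulary key; rownames are
#'   the vocabulary. All entries must be finite, keys unique and non-empty.
#' @param unit Training unit: `"token"` or `"character"`.
#' @param case_policy `"lowercase"` or `"mixed"`.
#' @param phrase_policy `"unigram_only"` or `"multiword_keys"`.
#' @param metadata Optional named list of free-form provenance notes
#'   (training corpus, context window, algorithm, ...).
#' @return An object of class `embedding_source`.
#' @export
#' @examples
#' m <- matrix(c(1, 0, 0, 1), 2, byrow = TRUE,
#'             dimnames = list(c("fever", "cough"), NULL))
#' src <- embedding_source("demo", m)
#' src
embedding_source <- function(name, vectors,
                             unit = c("token", "character"),
                             case_policy = c("lowercase", "mixed"),
                             phrase_policy = c("unigram_only", "multiword_keys"),
                             metadata = list()) {
  unit <- match.arg(unit)
  case_policy <- match.arg(case_policy)
  phrase_policy <- match.arg(phrase_policy)
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    stop("`name` must be a non-empty string", call. = FALSE)
  }
  if (!is.matrix(vectors) || !is.numeric(vectors)) {
    stop("`vectors` must be a numeric matrix with one row per key", call. = FALSE)
  }
  keys <- rownames(vectors)
  if (is.null(keys) && nrow(vectors) > 0) {
    stop("`vectors` must carry vocabulary keys as rownames", call. = FALSE)
  }
  if (anyDuplicated(keys)) {
    stop(
      sprintf("duplicate vocabulary keys: %s",
              paste(unique(keys[duplicated(keys)]), collapse = ", ")),
      call. = FALSE
    )
  }
  if (nrow(vectors) > 0 && any(!nzchar(keys))) {
    stop("vocabulary keys must be non-empty strings", call. = FALSE)
  }
  if (ncol(vectors) < 1L) {
    stop("embedding dimension must be at least 1", call. = FALSE)
  }
  if (nrow(vectors) > 0 && !all(is.finite(vectors))) {
    stop("all vector components must be finite", call. = FALSE)
  }
  storage.mode(vectors) <- "double"
  structure(
    list(
      name = name,
      vectors = vectors,
      unit = unit,
      case_policy = case_policy,
      phrase_policy = phrase_policy,
      metadata = metadata
    ),
    class = "embedding_source"
  )
}

#' @export
print.embedding_source <- function(x, ...) {
  cat(sprintf(
    "<embedding_source> %s: %d keys x %d dims (%s unit, %s case, %s)\n",
    x$name, nrow(x$vectors), ncol(x$vectors),
    x$unit, x$case_policy,
    if (x$phrase_policy == "multiword_keys") "multi-word keys" else "unigrams only"
  ))
  invisible(x)
}

#' @export
dim.embedding_source <- function(x) dim(x$vectors)

#' Vocabulary of an embedding source
#'
#' @param source An [embedding_source()].
#' @return Character vector of vocabulary keys in storage order.
#' @export
vocabulary <- function(source) {
  stopifnot(inherits(source, "embedding_source"))
  rownames(source$vectors) %||% character(0)
}

embedding_dialects <- function() {
  c("word2vec_text", "word2vec_binary", "glove_text", "fasttext_vec")
}

#' Read an embedding file
#'
#' Parses one of the standard embedding file dialects into an
#' [embedding_source()]:
#' \describe{
#'   \item{word2vec_text, fasttext_vec}{first line `"<count> <dim>"`, then
#'     one `key v1 ... vdim` row per term. The declared count must match the
#'     number of rows.}
#'   \item{glove_text}{no header; the dimension is inferred from the first
#'     row and enforced on every subsequent row.}
#'   \item{word2vec_binary}{ASCII header line `"<count> <dim>"`, then for
#'     each term the key bytes, a single space, and `dim` little-endian
#'     32-bit floats.}
#' }
#' Files are decoded as UTF-8; invalid byte sequences are replaced and a
#' warning logged. If a key occurs twice the first occurrence wins, with a
#' warning.
#'
#' @param path Path to the embedding file.
#' @param dialect One of `"word2vec_text"`, `"word2vec_binary"`,
#'   `"glove_text"`, `"fasttext_vec"`.
#' @param name Source name; defaults to the file name without extension.
#' @inheritParams embedding_source
#' @return An [embedding_source()].
#' @export
read_embedding <- function(path,
                           dialect = c("word2vec_text", "word2vec_binary",
                                       "glove_text", "fasttext_vec"),
                           name = NULL,
                           unit = "token",
                           case_policy = "lowercase",
                           phrase_policy = "unigram_only",
                           metadata = list()) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) {
    stop(sprintf("embedding file not found: %s", path), call. = FALSE)
  }
  name <- name %||% tools::file_path_sans_ext(basename(path))

  parsed <- if (dialect == "word2vec_binary") {
    read_w2v_binary(path)
  } else {
    read_embedding_text(path, headered = dialect %in% c("word2vec_text", "fasttext_vec"))
  }
  embedding_source(
    name = name, vectors = parsed,
    unit = unit, case_policy = case_policy,
    phrase_policy = phrase_policy, metadata = metadata
  )
}

read_embedding_text <- function(path, headered) {
  con <- file(path, open = "rt", encoding = "UTF-8")
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  if (any(validEnc(lines) == FALSE)) {
    warning("invalid UTF-8 byte sequences replaced while reading ", path,
            call. = FALSE)
    lines <- iconv(lines, from = "UTF-8", to = "UTF-8", sub = "�")
  }
  # real-world files occasionally end with a blank trailing line
  if (length(lines) > 0 && !nzchar(lines[length(lines)])) {
    lines <- lines[-length(lines)]
  }

  declared <- NULL
  dim_declared <- NULL
  offset <- 0L
  if (headered) {
    if (length(lines) == 0) {
      stop("empty file: expected a 'count dim' header at line 1", call. = FALSE)
    }
    header <- strsplit(trimws(lines[1]), "[ \t]+")[[1]]
    hdr <- suppressWarnings(as.integer(header))
    if (length(hdr) != 2L || anyNA(hdr) || any(hdr < 0)) {
      stop(sprintf("line 1: malformed header '%s' (expected '<count> <dim>')",
                   lines[1]), call. = FALSE)
    }
    declared <- hdr[1]
    dim_declared <- hdr[2]
    offset <- 1L
    if (length(lines) - 1L != declared) {
      stop(sprintf(
        "header at line 1 declares %d rows but file has %d (last data line %d)",
        declared, length(lines) - 1L, length(lines)
      ), call. = FALSE)
    }
  }

  rows <- if (length(lines) > offset) lines[(offset + 1L):length(lines)] else character(0)
  n <- length(rows)
  if (n == 0) {
    d <- dim_declared %||% 1L
    return(matrix(numeric(0), nrow = 0, ncol = max(d, 1L)))
  }

  keys <- character(n)
  first_fields <- strsplit(trimws(rows[1]), "[ \t]+")[[1]]
  d <- dim_declared %||% (length(first_fields) - 1L)
  if (d < 1L) {
    stop(sprintf("line %d: row has no vector components", 1L + offset),
         call. = FALSE)
  }
  vecs <- matrix(NA_real_, nrow = n, ncol = d)
  for (i in seq_len(n)) {
    fields <- strsplit(trimws(rows[i]), "[ \t]+")[[1]]
    lineno <- i + offset
    if (length(fields) != d + 1L) {
      stop(sprintf("line %d: expected %d fields (key + %d components), found %d",
                   lineno, d + 1L, d, length(fields)), call. = FALSE)
    }
    vals <- suppressWarnings(as.numeric(fields[-1]))
    if (anyNA(vals)) {
      stop(sprintf("line %d: non-numeric vector component '%s'",
                   lineno, fields[-1][which(is.na(vals))[1]]), call. = FALSE)
    }
    keys[i] <- fields[1]
    vecs[i, ] <- vals
  }
  dedupe_rows(vecs, keys)
}

dedupe_rows <- function(vecs, keys) {
  dup <- duplicated(keys)
  if (any(dup)) {
    warning(sprintf("duplicate keys (first occurrence kept): %s",
                    paste(unique(keys[dup]), collapse = ", ")), call. = FALSE)
    vecs <- vecs[!dup, , drop = FALSE]
    keys <- keys[!dup]
  }
  rownames(vecs) <- keys
  vecs
}

read_w2v_binary <- function(path) {
  con <- file(path, open = "rb")
  on.exit(close(con))
  header_bytes <- raw(0)
  repeat {
    b <- readBin(con, "raw", n = 1L)
    if (length(b) == 0) {
      stop("unexpected end of file while reading binary header", call. = FALSE)
    }
    if (b == as.raw(0x0A)) break
    header_bytes <- c(header_bytes, b)
  }
  header <- strsplit(trimws(rawToChar(header_bytes)), "[ \t]+")[[1]]
  hdr <- suppressWarnings(as.integer(header))
  if (length(hdr) != 2L || anyNA(hdr) || any(hdr < 0)) {
    stop(sprintf("malformed binary header '%s' (expected '<count> <dim>')",
                 rawToChar(header_bytes)), call. = FALSE)
  }
  n <- hdr[1]
  d <- hdr[2]
  keys <- character(n)
  vecs <- matrix(NA_real_, nrow = n, ncol = max(d, 1L))
  for (i in seq_len(n)) {
    key_bytes <- raw(0)
    repeat {
      b <- readBin(con, "raw", n = 1L)
      if (length(b) == 0) {
        stop(sprintf("unexpected end of file in entry %d of %d", i, n),
             call. = FALSE)
      }
      if (b == as.raw(0x20)) break
      if (b == as.raw(0x0A) && length(key_bytes) == 0) next  # tolerate leading newlines
      key_bytes <- c(key_bytes, b)
    }
    key <- rawToChar(key_bytes)
    Encoding(key) <- "UTF-8"
    if (!validEnc(key)) {
      warning("invalid UTF-8 in binary key replaced", call. = FALSE)
      key <- iconv(key, from = "UTF-8", to = "UTF-8", sub = "�")
    }
    vals <- readBin(con, "numeric", n = d, size = 4L, endian = "little")
    if (length(vals) != d) {
      stop(sprintf("entry %d ('%s'): expected %d float components, found %d",
                   i, key, d, length(vals)), call. = FALSE)
    }
    keys[i] <- key
    vecs[i, ] <- vals
  }
  dedupe_rows(vecs, keys)
}

#' Write an embedding source to file
#'
#' Serialises an [embedding_source()] in one of the dialects understood by
#' [read_embedding()]. Round-tripping preserves the vocabulary and its
#' order exactly, and vector components to text-serialisation precision
#' (text dialects write 6 significant digits; the binary dialect stores
#' 32-bit floats).
#'
#' @inheritParams read_embedding
#' @param source An [embedding_source()].
#' @return `path`, invisibly.
#' @export
write_embedding <- function(source, path,
                            dialect = c("word2vec_text", "word2vec_binary",
                                        "glove_text", "fasttext_vec")) {
  stopifnot(inherits(source, "embedding_source"))
  dialect <- match.arg(dialect)
  keys <- vocabulary(source)
  vecs <- source$vectors
  d <- ncol(vecs)

  if (dialect == "word2vec_binary") {
    con <- file(path, open = "wb")
    on.exit(close(con))
    writeBin(charToRaw(sprintf("%d %d\n", length(keys), d)), con)
    for (i in seq_along(keys)) {
      writeBin(c(charToRaw(enc2utf8(keys[i])), as.raw(0x20)), con)
      writeBin(vecs[i, ], con, size = 4L, endian = "little")
    }
    return(invisible(path))
  }

  rows <- character(0)
  if (length(keys) > 0) {
    comp <- apply(vecs, 1, function(v) paste(formatC(v, format = "g", digits = 8),
                                             collapse = " "))
    rows <- paste(keys, comp)
  }
  if (dialect %in% c("word2vec_text", "fasttext_vec")) {
    rows <- c(sprintf("%d %d", length(keys), d), rows)
  }
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(rows, con)
  invisible(path)
}

#' Normalise a query term against a source's conventions
#'
#' Returns, in priority order, the vocabulary keys under which a query term
#' should be probed in a given source: the term is case-folded when the
#' source was built lowercase, and multi-word terms are probed as
#' underscore-joined, then hyphen-joined, then verbatim forms. Only forms
#' actually present in the vocabulary are returned; an empty result means
#' the term is out of vocabulary.
#'
#' @param term Query term (non-empty string).
#' @param source An [embedding_source()].
#' @return Character vector of matching vocabulary keys (possibly empty),
#'   in probe-priority order.
#' @export
#' @examples
#' m <- matrix(rnorm(4), 2, dimnames = list(c("dry_cough", "fever"), NULL))
#' src <- embedding_source("demo", m, phrase_policy = "multiword_keys")
#' normalize_query("Dry Cough", src)
normalize_query <- function(term, source) {
  stopifnot(inherits(source, "embedding_source"))
  if (!is.character(term) || length(term) != 1L || !nzchar(trimws(term))) {
    stop("`term` must be a non-empty string", call. = FALSE)
  }
  term <- trimws(term)
  if (source$case_policy == "lowercase") term <- tolower(term)
  forms <- unique(c(
    gsub("[ \t]+", "_", term),
    gsub("[ \t]+", "-", term),
    term
  ))
  forms[forms %in% vocabulary(source)]
}

#' Read a source-registry configuration
#'
#' A registry is a YAML or JSON file listing embedding sources with their
#' paths, dialects and construction metadata, mirroring how a catalogue of
#' public embedding releases is described (name, training unit, case
#' policy, n-gram range, file location).
#'
#' @param path Path to a YAML (`.yml`/`.yaml`) or JSON registry file with a
#'   top-level `sources` list; each entry needs `name`, `path`, `dialect`
#'   and may give `unit`, `case_policy`, `phrase_policy` and free-form
#'   metadata fields.
#' @param base_dir Directory against which relative `path` entries are
#'   resolved; defaults to the registry file's directory.
#' @return List of source descriptors (named lists).
#' @export
read_source_registry <- function(path, base_dir = dirname(path)) {
  ext <- tolower(tools::file_ext(path))
  reg <- if (ext %in% c("yml", "yaml")) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = FALSE)
  }
  sources <- reg$sources %||% reg
  if (length(sources) == 0) stop("registry lists no sources", call. = FALSE)
  lapply(sources, function(s) {
    for (field in c("name", "path", "dialect")) {
      if (is.null(s[[field]])) {
        stop(sprintf("registry entry missing required field '%s'", field),
             call. = FALSE)
      }
    }
    if (!file.path_is_absolute(s$path)) s$path <- file.path(base_dir, s$path)
    s
  })
}

file.path_is_absolute <- function(p) grepl("^(/|[A-Za-z]:[/\\\\])", p)

#' Load every source named in a registry
#'
#' @param registry List of source descriptors from [read_source_registry()].
#' @return Named list of [embedding_source()] objects.
#' @export
load_sources <- function(registry) {
  sources <- lapply(registry, function(s) {
    read_embedding(
      s$path,
      dialect = s$dialect,
      name = s$name,
      unit = s$unit %||% "token",
      case_policy = s$case_policy %||% "lowercase",
      phrase_policy = s$phrase_policy %||% "unigram_only",
      metadata = s$metadata %||% list()
    )
  })
  stats::setNames(sources, vapply(registry, `[[`, "", "name"))
}
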