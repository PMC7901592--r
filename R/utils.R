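`%||%` <- function(x, y) if (is.null(x)) y else x

# cross-source term identity: case-folded, with underscore/hyphen/space
# treated as the same delimiter
normalize_term_key <- function(term) {
  gsub("[ _\\-]+", " ", tolower(trimws(term)))
}

write_tsv_utf8 <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

read_tsv_utf8 <- function(path, colClasses = NA) {
  tibble::as_tibble(
    utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                      colClasses = colClasses, fileEncoding = "UTF-8")
  )
}
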