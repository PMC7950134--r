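#' Read a protein variant substitution table
#'
#' Variants are single- or multi-residue substitutions on a canonical
#' sequence, in the UniProt convention: 1-based inclusive residue positions,
#' `ref`/`alt` of equal length. Insertions and deletions are unsupported.
#'
#' @param path TSV with columns `accession`, `position`, `ref`, `alt`,
#'   `variant_id` (e.g. `VAR_000652`).
#' @return a `data.frame` of validated variant records (class
#'   `variant_table`).
#' @export
read_variant_table <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character")
  req <- c("accession", "position", "ref", "alt", "variant_id")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols)) {
    stop_named("variant file lacks column(s): %s", paste(missing_cols, collapse = ", "))
  }
  df$position <- as.integer(df$position)
  variant_table(df)
}

#' Construct a validated variant table
#'
#' @param df `data.frame` with columns `accession`, `position` (integer,
#'   1-based), `ref`, `alt`, `variant_id`.
#' @return `df` with class `variant_table`.
#' @export
variant_table <- function(df) {
  if (nrow(df)) {
    df$ref <- toupper(as.character(df$ref))
    df$alt <- toupper(as.character(df$alt))
    if (any(is.na(df$position)) || any(df$position < 1L)) {
      stop_named("variant position must be an integer >= 1 (record %s)",
                 df$variant_id[which(is.na(df$position) | df$position < 1L)[1]])
    }
    bad_len <- nchar(df$ref) != nchar(df$alt) | nchar(df$ref) < 1L
    if (any(bad_len)) {
      stop_named("ref/alt length mismatch in record %s (ref '%s', alt '%s'): substitutions only",
                 df$variant_id[bad_len][1], df$ref[bad_len][1], df$alt[bad_len][1])
    }
    bad_aa <- !grepl("^[ACDEFGHIKLMNPQRSTVWY]+$", df$ref) |
      !grepl("^[ACDEFGHIKLMNPQRSTVWY]+$", df$alt)
    if (any(bad_aa)) {
      stop_named("non-amino-acid residue in record %s", df$variant_id[bad_aa][1])
    }
  }
  rownames(df) <- NULL
  class(df) <- c("variant_table", "data.frame")
  df
}
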