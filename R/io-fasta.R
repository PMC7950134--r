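#' Read protein sequences from FASTA
#'
#' Sequences are normalized to uppercase. Empty sequences and duplicate
#' headers are rejected.
#'
#' @param path FASTA file.
#' @return `data.frame` with columns `header` (full description line, without
#'   the leading `>`) and `sequence`.
#' @export
read_fasta <- function(path) {
  aas <- Biostrings::readAAStringSet(path)
  headers <- names(aas)
  seqs <- toupper(as.character(aas))
  if (anyDuplicated(headers)) {
    stop_named("header collision in FASTA: %s", headers[duplicated(headers)][1])
  }
  if (any(nchar(seqs) == 0L)) {
    stop_named("empty sequence for header: %s", headers[nchar(seqs) == 0L][1])
  }
  data.frame(header = headers, sequence = unname(seqs), stringsAsFactors = FALSE)
}

#' Write protein sequences to FASTA
#'
#' `write_fasta` then [read_fasta()] is an identity on valid records.
#'
#' @param records `data.frame` with columns `header` and `sequence`.
#' @param path output file.
#' @return `records`, invisibly.
#' @export
write_fasta <- function(records, path) {
  if (!all(c("header", "sequence") %in% names(records))) {
    stop_named("records must have 'header' and 'sequence' columns")
  }
  if (anyDuplicated(records$header)) {
    stop_named("header collision in FASTA records: %s",
               records$header[duplicated(records$header)][1])
  }
  seqs <- toupper(as.character(records$sequence))
  if (any(nchar(seqs) == 0L)) stop_named("refusing to write empty sequence")
  aas <- Biostrings::AAStringSet(seqs)
  names(aas) <- records$header
  Biostrings::writeXStringSet(aas, path, width = 60L)
  invisible(records)
}

#' Headers for variant sequence FASTA records
#'
#' Variant sequences are written with `"<accession>|<variant_id>"` appended
#' to the canonical header fields, so a variant database is distinguishable
#' from the canonical one while remaining parseable by standard tools.
#'
#' @param canonical_header the canonical record's header line.
#' @param accession protein accession.
#' @param variant_id variant identifier (e.g. `VAR_000652`).
#' @return character header line.
#' @export
variant_fasta_header <- function(canonical_header, accession, variant_id) {
  sprintf("%s %s|%s", canonical_header, accession, variant_id)
}
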