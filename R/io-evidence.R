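#' Peptide identification evidence
#'
#' Binary peptide-by-sample identification calls with gene / allele / variant
#' site labels — a long-format stand-in for search-engine peptide evidence.
#'
#' @param peptides `data.frame` with columns `peptide_sequence`, `gene_id`,
#'   `protein_accession`, `allele_id`, `variant_site` (1-based integer or
#'   `NA`); one row per (peptide, allele).
#' @param presence logical matrix, rows matching `peptides`, columns named by
#'   sample id; `TRUE` = identified in that sample.
#' @param annotations sample annotation table covering every presence column.
#' @return an object of class `evidence_table` with elements `peptides`,
#'   `presence` and `samples`.
#' @export
evidence_table <- function(peptides, presence, annotations) {
  req <- c("peptide_sequence", "gene_id", "protein_accession", "allele_id", "variant_site")
  missing_cols <- setdiff(req, names(peptides))
  if (length(missing_cols)) {
    stop_named("peptides table lacks column(s): %s", paste(missing_cols, collapse = ", "))
  }
  peptides$peptide_sequence <- toupper(as.character(peptides$peptide_sequence))
  bad <- !grepl("^[ACDEFGHIKLMNPQRSTVWY]+$", peptides$peptide_sequence)
  if (any(bad)) {
    stop_named("peptide sequence with illegal characters: %s", peptides$peptide_sequence[which(bad)[1]])
  }
  peptides$variant_site <- as.integer(peptides$variant_site)
  key <- paste(peptides$peptide_sequence, peptides$allele_id, sep = "\r")
  if (anyDuplicated(key)) {
    stop_named("duplicate (peptide_sequence, allele_id) row: %s",
               sub("\r", " / ", key[duplicated(key)][1]))
  }
  if (!is.matrix(presence) || !is.logical(presence)) stop_named("presence must be a logical matrix")
  if (nrow(presence) != nrow(peptides)) stop_named("presence rows must match peptides rows")
  ann <- validate_annotations(annotations)
  unknown <- setdiff(colnames(presence), ann$sample_id)
  if (length(unknown)) {
    stop_named("evidence references unknown sample(s): %s", paste(unknown, collapse = ", "))
  }
  # complete to the full annotated sample set; unreferenced samples default to FALSE
  full <- matrix(FALSE, nrow(presence), nrow(ann), dimnames = list(NULL, ann$sample_id))
  if (ncol(presence) && nrow(presence)) full[, colnames(presence)] <- presence
  rownames(peptides) <- NULL
  structure(list(peptides = peptides[req], presence = full, samples = ann),
            class = "evidence_table")
}

#' @export
print.evidence_table <- function(x, ...) {
  cat(sprintf("evidence_table: %d peptide rows x %d samples, %d genes\n",
              nrow(x$peptides), ncol(x$presence), length(unique(x$peptides$gene_id))))
  invisible(x)
}

#' Read long-format peptide evidence
#'
#' Expects a TSV with columns `peptide_sequence`, `gene_id`,
#' `protein_accession`, `allele_id`, `variant_site`, `sample_id`,
#' `identified` (0/1). Absent (peptide, sample) combinations default to
#' not-identified. Conflicting duplicate rows are rejected.
#'
#' @param path TSV path.
#' @param annotations optional annotation table defining the full cohort
#'   sample set; if `NULL`, annotations are reconstructed from the canonical
#'   `"<individual>_TP<k>"` sample ids found in the file.
#' @return an [evidence_table()].
#' @export
read_evidence_table <- function(path, annotations = NULL) {
  long <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                            na.strings = c("", "NA"))
  req <- c("peptide_sequence", "gene_id", "protein_accession", "allele_id",
           "variant_site", "sample_id", "identified")
  missing_cols <- setdiff(req, names(long))
  if (length(missing_cols)) {
    stop_named("evidence file lacks column(s): %s", paste(missing_cols, collapse = ", "))
  }
  if (nrow(long) && !all(long$identified %in% c(0L, 1L))) {
    stop_named("identified values must be 0 or 1 (found: %s)",
               paste(unique(long$identified[!long$identified %in% c(0L, 1L)]), collapse = ", "))
  }
  dupkey <- paste(long$peptide_sequence, long$allele_id, long$sample_id, sep = "\r")
  if (anyDuplicated(dupkey)) {
    dups <- long[dupkey %in% dupkey[duplicated(dupkey)], , drop = FALSE]
    conflict <- stats::aggregate(identified ~ peptide_sequence + allele_id + sample_id,
                                 dups, function(z) length(unique(z)))
    if (any(conflict$identified > 1L)) {
      stop_named("conflicting duplicate evidence rows for peptide %s in sample %s",
                 conflict$peptide_sequence[conflict$identified > 1L][1],
                 conflict$sample_id[conflict$identified > 1L][1])
    }
    long <- long[!duplicated(dupkey), , drop = FALSE]
  }
  if (is.null(annotations)) {
    annotations <- annotations_from_sample_ids(unique(long$sample_id))
  }
  ann <- validate_annotations(annotations)
  pep <- unique(long[, c("peptide_sequence", "gene_id", "protein_accession",
                         "allele_id", "variant_site")])
  pepkey <- paste(pep$peptide_sequence, pep$allele_id, sep = "\r")
  if (anyDuplicated(pepkey)) {
    stop_named("inconsistent labels across rows of peptide %s",
               pep$peptide_sequence[duplicated(pepkey)][1])
  }
  presence <- matrix(FALSE, nrow(pep), nrow(ann), dimnames = list(NULL, ann$sample_id))
  if (nrow(long)) {
    ri <- match(paste(long$peptide_sequence, long$allele_id, sep = "\r"), pepkey)
    ci <- match(long$sample_id, ann$sample_id)
    if (anyNA(ci)) {
      stop_named("evidence references unknown sample(s): %s",
                 paste(unique(long$sample_id[is.na(ci)]), collapse = ", "))
    }
    presence[cbind(ri, ci)] <- long$identified == 1L
  }
  evidence_table(pep, presence, ann)
}

#' Write peptide evidence in long format
#'
#' Only identified (`TRUE`) cells and one `identified = 0` row per peptide
#' for samples where it was never seen are not distinguished: the full dense
#' long table is written so the roundtrip is lossless.
#'
#' @param x an [evidence_table()].
#' @param path output TSV path.
#' @return `x`, invisibly.
#' @export
write_evidence_table <- function(x, path) {
  stopifnot(inherits(x, "evidence_table"))
  n_pep <- nrow(x$peptides)
  n_smp <- ncol(x$presence)
  long <- data.frame(
    x$peptides[rep(seq_len(n_pep), each = n_smp), , drop = FALSE],
    sample_id = rep(colnames(x$presence), times = n_pep),
    identified = as.integer(t(x$presence)),
    stringsAsFactors = FALSE
  )
  utils::write.table(long, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
  invisible(x)
}

# reconstruct annotations from canonical "<individual>_TP<k>" ids
annotations_from_sample_ids <- function(sample_ids) {
  m <- regmatches(sample_ids, regexec("^(.+)_TP([0-9]+)$", sample_ids))
  bad <- vapply(m, length, 1L) != 3L
  if (any(bad)) {
    stop_named("sample id not in canonical '<individual>_TP<k>' form: %s",
               sample_ids[bad][1])
  }
  data.frame(
    sample_id = sample_ids,
    individual_id = vapply(m, `[`, "", 2L),
    timepoint = as.integer(vapply(m, `[`, "", 3L)),
    stringsAsFactors = FALSE
  )
}
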