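#' Protein intensity matrix with sample annotations
#'
#' The central quantitative container: a proteins x samples matrix of
#' linear-scale intensities (positive reals, `NA` for missing) tied to a
#' sample annotation table (`sample_id`, `individual_id`, `timepoint`).
#'
#' @param values numeric matrix, proteins in rows (rownames = accessions),
#'   samples in columns (colnames = sample ids). All non-missing values must
#'   be positive.
#' @param annotations sample annotation `data.frame`; every matrix column
#'   must be annotated. Column order of `values` is preserved.
#' @return an object of class `intensity_matrix` with elements `values`
#'   (the matrix) and `samples` (the annotation rows, in column order).
#' @export
intensity_matrix <- function(values, annotations) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop_named("values must be a numeric matrix")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop_named("values must have protein rownames and sample colnames")
  }
  if (anyDuplicated(rownames(values))) {
    stop_named("duplicate protein id(s): %s",
               paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  }
  if (anyDuplicated(colnames(values))) {
    stop_named("duplicate sample column(s): %s",
               paste(unique(colnames(values)[duplicated(colnames(values))]), collapse = ", "))
  }
  ann <- validate_annotations(annotations)
  unknown <- setdiff(colnames(values), ann$sample_id)
  if (length(unknown)) {
    stop_named("sample column(s) absent from annotations: %s", paste(unknown, collapse = ", "))
  }
  bad <- which(!is.na(values) & values <= 0, arr.ind = TRUE)
  if (nrow(bad)) {
    stop_named("non-positive intensity at protein %s, sample %s",
               rownames(values)[bad[1, 1]], colnames(values)[bad[1, 2]])
  }
  samples <- ann[match(colnames(values), ann$sample_id), , drop = FALSE]
  rownames(samples) <- NULL
  structure(list(values = values, samples = samples), class = "intensity_matrix")
}

#' @export
dim.intensity_matrix <- function(x) dim(x$values)

#' @export
print.intensity_matrix <- function(x, ...) {
  cat(sprintf("intensity_matrix: %d proteins x %d samples (%d individuals, %s missing)\n",
              nrow(x$values), ncol(x$values),
              length(unique(x$samples$individual_id)),
              sprintf("%.1f%%", 100 * mean(is.na(x$values)))))
  invisible(x)
}

#' Read an intensity matrix and its sample annotations
#'
#' The matrix file is TSV with a `protein_id` first column and one column per
#' sample; missing cells are empty or `"NA"`. The annotation file is TSV with
#' columns `sample_id`, `individual_id`, `timepoint` and is authoritative:
#' every matrix column must appear in it.
#'
#' @param path_matrix,path_annotations paths to the two TSV files.
#' @return an [intensity_matrix()].
#' @export
read_intensity_matrix <- function(path_matrix, path_annotations) {
  raw <- utils::read.delim(path_matrix, check.names = FALSE, na.strings = c("", "NA"),
                           stringsAsFactors = FALSE)
  if (ncol(raw) < 2L) stop_named("matrix file must have a protein id column plus sample columns")
  prot <- as.character(raw[[1L]])
  vals <- as.matrix(raw[, -1L, drop = FALSE])
  storage.mode(vals) <- "double"
  rownames(vals) <- prot
  ann <- utils::read.delim(path_annotations, check.names = FALSE, stringsAsFactors = FALSE)
  intensity_matrix(vals, ann)
}

#' Write an intensity matrix and its sample annotations
#'
#' Missing values are written as `"NA"`. `write` then `read` is lossless.
#'
#' @param x an [intensity_matrix()].
#' @param path_matrix,path_annotations output TSV paths.
#' @return `x`, invisibly.
#' @export
write_intensity_matrix <- function(x, path_matrix, path_annotations) {
  stopifnot(inherits(x, "intensity_matrix"))
  df <- data.frame(protein_id = rownames(x$values), x$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path_matrix, sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
  utils::write.table(x$samples, path_annotations, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(x)
}

#' Subset an intensity matrix
#'
#' @param x an [intensity_matrix()].
#' @param proteins,samples optional character vectors of protein ids /
#'   sample ids to keep (order preserved as given).
#' @return an [intensity_matrix()].
#' @export
subset_intensity <- function(x, proteins = NULL, samples = NULL) {
  stopifnot(inherits(x, "intensity_matrix"))
  v <- x$values
  if (!is.null(proteins)) {
    unknown <- setdiff(proteins, rownames(v))
    if (length(unknown)) stop_named("unknown protein id(s): %s", paste(unknown, collapse = ", "))
    v <- v[proteins, , drop = FALSE]
  }
  if (!is.null(samples)) {
    unknown <- setdiff(samples, colnames(v))
    if (length(unknown)) stop_named("unknown sample id(s): %s", paste(unknown, collapse = ", "))
    v <- v[, samples, drop = FALSE]
  }
  intensity_matrix(v, x$samples)
}
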