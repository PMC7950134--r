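#' Canonical sample identifiers
#'
#' Samples in a longitudinal cohort are keyed by an individual identifier and
#' a time point, rendered canonically as `"<individual>_TP<timepoint>"`. The
#' annotation table is always authoritative; the string form is a display and
#' file convention only.
#'
#' @param individual_id character vector of individual identifiers.
#' @param timepoint integer vector of time points (1-based).
#' @return character vector of canonical sample ids.
#' @examples
#' sample_key("I01", 3) # "I01_TP3"
#' @export
sample_key <- function(individual_id, timepoint) {
  tp <- as.integer(timepoint)
  if (any(is.na(tp)) || any(tp < 1L)) {
    stop_named("timepoint must be an integer >= 1")
  }
  sprintf("%s_TP%d", as.character(individual_id), tp)
}

#' Build a sample annotation table
#'
#' @param individual_id,timepoint vectors of equal length (recycled by
#'   `data.frame`); one row per sample.
#' @param sample_id optional explicit sample ids; defaults to the canonical
#'   `"<individual>_TP<k>"` form.
#' @return a `data.frame` with columns `sample_id`, `individual_id`,
#'   `timepoint`; `(individual_id, timepoint)` pairs must be unique.
#' @export
sample_annotations <- function(individual_id, timepoint, sample_id = NULL) {
  ann <- data.frame(
    sample_id = if (is.null(sample_id)) sample_key(individual_id, timepoint) else as.character(sample_id),
    individual_id = as.character(individual_id),
    timepoint = as.integer(timepoint),
    stringsAsFactors = FALSE
  )
  validate_annotations(ann)
}

validate_annotations <- function(ann) {
  req <- c("sample_id", "individual_id", "timepoint")
  missing_cols <- setdiff(req, names(ann))
  if (length(missing_cols)) {
    stop_named("annotation table lacks column(s): %s", paste(missing_cols, collapse = ", "))
  }
  ann$sample_id <- as.character(ann$sample_id)
  ann$individual_id <- as.character(ann$individual_id)
  ann$timepoint <- as.integer(ann$timepoint)
  if (any(is.na(ann$timepoint)) || any(ann$timepoint < 1L)) {
    stop_named("annotation timepoints must be integers >= 1")
  }
  if (anyDuplicated(ann$sample_id)) {
    stop_named("duplicate sample_id in annotations: %s",
               paste(unique(ann$sample_id[duplicated(ann$sample_id)]), collapse = ", "))
  }
  key <- paste(ann$individual_id, ann$timepoint, sep = "\r")
  if (anyDuplicated(key)) {
    stop_named("duplicate (individual_id, timepoint) pair in annotations")
  }
  rownames(ann) <- NULL
  ann[req]
}
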