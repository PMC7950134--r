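#' Log10-transform an intensity matrix
#'
#' Plasma protein intensities span orders of magnitude; correlations are
#' computed on log10 intensities by default. Missing stays missing.
#'
#' @param x an [intensity_matrix()] or numeric matrix of positive values.
#' @return object of the same shape with log10 values. For an
#'   `intensity_matrix` input the result is a plain numeric matrix (log
#'   values are not valid linear intensities) with the annotations attached
#'   as attribute `samples`.
#' @export
log_transform <- function(x) {
  v <- if (inherits(x, "intensity_matrix")) x$values else x
  if (any(!is.na(v) & v <= 0)) {
    bad <- which(!is.na(v) & v <= 0, arr.ind = TRUE)
    stop_named("non-positive intensity cannot be log-transformed (row %d, col %d)",
               bad[1, 1], bad[1, 2])
  }
  out <- log10(v)
  if (inherits(x, "intensity_matrix")) attr(out, "samples") <- x$samples
  out
}

panel_protein_ids <- function(panel) {
  if (inherits(panel, "protein_panel")) panel$protein_ids else as.character(panel)
}

# log-scale panel-restricted value matrix (proteins x samples)
panel_values <- function(x, panel, log10_scale = TRUE) {
  ids <- panel_protein_ids(panel)
  unknown <- setdiff(ids, rownames(x$values))
  if (length(unknown)) stop_named("panel protein(s) not in matrix: %s", paste(unknown, collapse = ", "))
  v <- x$values[ids, , drop = FALSE]
  if (log10_scale) log10(v) else v
}

#' Pearson correlation of two samples on a protein panel
#'
#' Computed on log10 intensities restricted to panel proteins non-missing in
#' both samples (pairwise-complete). With fewer than `min_overlap` shared
#' proteins the correlation is undefined and reported as `NA`.
#'
#' @param x an [intensity_matrix()].
#' @param sample_a,sample_b sample ids.
#' @param panel a `protein_panel` or character vector of protein ids.
#' @param min_overlap minimum number of shared non-missing panel proteins
#'   (default 20).
#' @param log10_scale correlate log10 (default) or linear intensities.
#' @return list with `r` (numeric or `NA`) and `n_overlap` (integer).
#' @export
pearson_on_panel <- function(x, sample_a, sample_b, panel,
                             min_overlap = 20L, log10_scale = TRUE) {
  stopifnot(inherits(x, "intensity_matrix"))
  unknown <- setdiff(c(sample_a, sample_b), colnames(x$values))
  if (length(unknown)) stop_named("unknown sample id(s): %s", paste(unknown, collapse = ", "))
  v <- panel_values(x, panel, log10_scale)
  a <- v[, sample_a]
  b <- v[, sample_b]
  ok <- !is.na(a) & !is.na(b)
  n <- sum(ok)
  if (n < min_overlap) return(list(r = NA_real_, n_overlap = n))
  list(r = stats::cor(a[ok], b[ok]), n_overlap = n)
}

#' All-pairs sample correlation matrix on a protein panel
#'
#' For `n` samples there are `n(n-1)/2` informative (unordered off-diagonal)
#' correlation values; the diagonal is exactly 1.
#'
#' @inheritParams pearson_on_panel
#' @return a `correlation_matrix`: list with `r` (symmetric matrix, unit
#'   diagonal, `NA` where overlap < `min_overlap`), `n_overlap` (pairwise
#'   counts) and `samples` (annotations in matrix order).
#' @export
correlation_matrix <- function(x, panel, min_overlap = 20L, log10_scale = TRUE) {
  stopifnot(inherits(x, "intensity_matrix"))
  if (ncol(x$values) < 2L) stop_named("need at least 2 samples")
  if (!length(panel_protein_ids(panel))) stop_named("protein panel is empty")
  v <- panel_values(x, panel, log10_scale)
  obs <- !is.na(v)
  n_overlap <- crossprod(obs)
  suppressWarnings(r <- stats::cor(v, use = "pairwise.complete.obs"))
  r[n_overlap < min_overlap] <- NA_real_
  diag(r) <- 1
  structure(list(r = r, n_overlap = n_overlap, samples = x$samples),
            class = "correlation_matrix")
}

#' @export
print.correlation_matrix <- function(x, ...) {
  n <- ncol(x$r)
  cat(sprintf("correlation_matrix: %d samples, %d unordered pairwise values\n",
              n, n_informative_pairs(x)))
  invisible(x)
}

#' Number of informative pairwise values in a correlation matrix
#'
#' @param cm a [correlation_matrix()].
#' @return `n(n-1)/2` for `n` samples.
#' @export
n_informative_pairs <- function(cm) {
  n <- ncol(cm$r)
  n * (n - 1L) / 2L
}

#' Write a correlation matrix as TSV
#'
#' @param cm a [correlation_matrix()].
#' @param path output TSV.
#' @export
write_correlation_matrix <- function(cm, path) {
  df <- data.frame(sample_id = colnames(cm$r), cm$r, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
  invisible(cm)
}

#' Assign blinded samples to individuals by correlation
#'
#' One sample per individual at `reference_timepoint` serves as reference;
#' every other sample is a query, ranked against all references by Pearson
#' correlation of panel proteins (descending). The predicted individual is
#' the owner of the top-ranked reference. Score ties are broken
#' lexicographically by individual id and flagged ambiguous. Individuals
#' lacking the reference time point are excluded from the reference set with
#' a warning; their queries are still evaluated (truth then unrankable).
#'
#' @inheritParams pearson_on_panel
#' @param reference_timepoint time point of the reference samples (default 1).
#' @return an `assignment_result`: list with `assignments` (per query:
#'   truth, prediction, score, `correct`, `rank_of_truth`, `ambiguous`),
#'   `scores` (query x reference correlation matrix), `references`
#'   (annotation rows) and `summary` (see [evaluate_assignment()]).
#' @export
assign_by_correlation <- function(x, panel, reference_timepoint = 1L,
                                  min_overlap = 20L, log10_scale = TRUE) {
  stopifnot(inherits(x, "intensity_matrix"))
  cm <- correlation_matrix(x, panel, min_overlap = min_overlap, log10_scale = log10_scale)
  assign_from_scores(cm$r, x$samples, reference_timepoint, score_label = "r")
}

# shared ranking logic for correlation scores and allele match scores.
# score_matrix: full sample x sample (correlation) or query x reference.
assign_from_scores <- function(score_matrix, samples, reference_timepoint,
                               score_label = "score", ties_incorrect = FALSE) {
  reference_timepoint <- as.integer(reference_timepoint)
  is_ref <- samples$timepoint == reference_timepoint
  inds <- unique(samples$individual_id)
  no_ref <- setdiff(inds, samples$individual_id[is_ref])
  if (length(no_ref)) {
    warning(sprintf("individual(s) without a reference sample at TP%d: %s",
                    reference_timepoint, paste(no_ref, collapse = ", ")), call. = FALSE)
  }
  refs <- samples[is_ref, , drop = FALSE]
  if (!nrow(refs)) stop_named("no reference samples at timepoint %d", reference_timepoint)
  queries <- samples[!is_ref, , drop = FALSE]
  # score rows = queries, cols = references
  sc <- score_matrix[queries$sample_id, refs$sample_id, drop = FALSE]
  ref_ind <- refs$individual_id
  per_query <- lapply(seq_len(nrow(queries)), function(qi) {
    s <- sc[qi, ]
    ord <- order(-s, ref_ind, na.last = TRUE)
    top <- ord[1L]
    ambiguous <- length(ord) > 1L && !is.na(s[top]) && !is.na(s[ord[2L]]) &&
      s[top] == s[ord[2L]]
    truth <- queries$individual_id[qi]
    rank_truth <- match(truth, ref_ind[ord])
    predicted <- ref_ind[top]
    correct <- !is.na(s[top]) && predicted == truth && !(ambiguous && ties_incorrect)
    data.frame(sample_id = queries$sample_id[qi], individual_id = truth,
               timepoint = queries$timepoint[qi], predicted_individual = predicted,
               score = unname(s[top]), correct = correct,
               rank_of_truth = rank_truth, ambiguous = ambiguous,
               stringsAsFactors = FALSE)
  })
  assignments <- do.call(rbind, per_query)
  rownames(assignments) <- NULL
  res <- structure(list(assignments = assignments, scores = sc, references = refs,
                        score_label = score_label, summary = NULL),
                   class = "assignment_result")
  res$summary <- evaluate_assignment(res)
  res
}

#' Summarize an assignment result
#'
#' @param result an `assignment_result` from [assign_by_correlation()] (or
#'   the allele-matching equivalent).
#' @return list with `n_queries`, `n_correct`, `error_rate_percent` (one
#'   decimal, half-up), `percent_correct`, `rank_of_truth_distribution`, and
#'   the median intra- vs inter-individual score.
#' @export
evaluate_assignment <- function(result) {
  stopifnot(inherits(result, "assignment_result"))
  a <- result$assignments
  if (!nrow(a)) stop_named("assignment result has no queries")
  n_queries <- nrow(a)
  n_correct <- sum(a$correct)
  truth_by_row <- matrix(a$individual_id, nrow(a), ncol(result$scores))
  ref_by_col <- matrix(result$references$individual_id, nrow(a), ncol(result$scores), byrow = TRUE)
  intra <- result$scores[truth_by_row == ref_by_col]
  inter <- result$scores[truth_by_row != ref_by_col]
  list(
    n_queries = n_queries,
    n_correct = n_correct,
    error_rate_percent = round_half_up(100 * (1 - n_correct / n_queries), 1),
    percent_correct = round_half_up(100 * n_correct / n_queries, 1),
    rank_of_truth_distribution = table(factor(a$rank_of_truth,
                                              levels = seq_len(ncol(result$scores)))),
    median_intra = median_or_na(intra),
    median_inter = median_or_na(inter)
  )
}

#' @export
print.assignment_result <- function(x, ...) {
  s <- x$summary
  cat(sprintf("assignment_result: %d/%d queries correct (error rate %.1f%%)\n",
              s$n_correct, s$n_queries, s$error_rate_percent))
  cat(sprintf("  median intra-individual %s = %.3f, inter = %.3f\n",
              x$score_label, s$median_intra, s$median_inter))
  invisible(x)
}
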