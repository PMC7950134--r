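#' Present/absent call vectors on an allele panel
#'
#' One boolean call per panel group per sample, in panel order. By default a
#' group never observed in a sample is called "absent" (present/absent
#' framing admits no third state); `strict = TRUE` instead marks calls for
#' peptides with no evidence rows at all as `NA` so they can be skipped in
#' scoring.
#'
#' @param evidence an [evidence_table()].
#' @param panel an `allele_panel` (or `peptide_groups`).
#' @param strict treat never-observed panel groups as missing rather than
#'   absent (default `FALSE`).
#' @return logical matrix, samples x panel groups.
#' @export
presence_vectors <- function(evidence, panel, strict = FALSE) {
  groups <- if (inherits(panel, "allele_panel")) {
    structure(list(groups = panel$groups, members = panel$members),
              class = "peptide_groups")
  } else panel
  stopifnot(inherits(groups, "peptide_groups"))
  pres <- t(group_presence(groups, evidence))
  if (strict) {
    evkey <- paste(evidence$peptides$peptide_sequence, evidence$peptides$allele_id, sep = "\r")
    observed <- vapply(seq_len(nrow(groups$groups)), function(g) {
      keys <- paste(groups$members[[g]], groups$groups$allele_id[g], sep = "\r")
      any(keys %in% evkey)
    }, TRUE)
    pres[, !observed] <- NA
  }
  pres
}

#' Number of matching present/absent calls between two samples
#'
#' The count of panel positions where two call vectors agree (both present or
#' both absent); equals panel size minus the Hamming distance. Positions with
#' a missing call in either vector are skipped.
#'
#' @param vector_a,vector_b logical vectors of equal length in the same panel
#'   order.
#' @return integer match score in `[0, length(vector_a)]`.
#' @export
match_score <- function(vector_a, vector_b) {
  if (length(vector_a) != length(vector_b)) {
    stop_named("call vectors differ in length (%d vs %d)",
               length(vector_a), length(vector_b))
  }
  sum(vector_a == vector_b, na.rm = TRUE)
}

#' Assign blinded samples to individuals by allele matching
#'
#' Scores every non-reference sample against each individual's reference
#' sample (at `reference_timepoint`) by the number of matching present/absent
#' variant-peptide calls, predicting the individual with the maximum score.
#' Tied top scores are flagged ambiguous and counted incorrect
#' (conservative). Queries whose calls are all missing (strict mode) are
#' excluded with a warning.
#'
#' @param evidence an [evidence_table()].
#' @param panel an `allele_panel`.
#' @param reference_timepoint reference time point (default 1).
#' @param strict see [presence_vectors()].
#' @return an `assignment_result` (see [assign_by_correlation()]); `scores`
#'   holds the full query x reference match-score table (the heat-map
#'   layout).
#' @export
assign_by_matches <- function(evidence, panel, reference_timepoint = 1L,
                              strict = FALSE) {
  stopifnot(inherits(evidence, "evidence_table"))
  calls <- presence_vectors(evidence, panel, strict = strict)
  samples <- evidence$samples
  if (strict) {
    all_missing <- rowSums(!is.na(calls)) == 0L
    if (any(all_missing)) {
      warning(sprintf("excluding query sample(s) with all-missing calls: %s",
                      paste(rownames(calls)[all_missing], collapse = ", ")), call. = FALSE)
      keep <- !all_missing | samples$timepoint == as.integer(reference_timepoint)
      calls <- calls[keep, , drop = FALSE]
      samples <- samples[keep, , drop = FALSE]
    }
  }
  # pairwise agreement counts via 0/1 matrix algebra (NA-safe)
  m <- calls * 1L
  m[is.na(m)] <- NA_integer_
  p <- m
  q <- 1L - m
  p[is.na(p)] <- 0L
  q[is.na(q)] <- 0L
  scores <- p %*% t(p) + q %*% t(q)
  dimnames(scores) <- list(rownames(calls), rownames(calls))
  res <- assign_from_scores(scores, samples, reference_timepoint,
                            score_label = "matches", ties_incorrect = TRUE)
  res$calls <- calls
  res
}

#' Summarize an allele-matching assignment
#'
#' @param result an `assignment_result` from [assign_by_matches()].
#' @return list with `percent_correct` (one decimal), `n_correct`,
#'   `n_queries`, per-individual accuracy, and median within- vs
#'   between-individual match scores.
#' @export
evaluate_allele_assignment <- function(result) {
  stopifnot(inherits(result, "assignment_result"))
  s <- evaluate_assignment(result)
  a <- result$assignments
  per_ind <- vapply(split(a$correct, a$individual_id), mean, 0)
  c(s, list(per_individual_accuracy = per_ind))
}
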