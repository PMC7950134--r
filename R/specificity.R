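#' Parameters for individual-specific protein selection
#'
#' A protein is "individual-specific" when its level in a participant is more
#' than `fold_threshold`-fold different from the population median for at
#' least a `participant_fraction` share of participants, while staying stable
#' within a person (coefficient of variation over time below `cv_threshold`).
#'
#' @param fold_threshold symmetric fold-change threshold (> 1). Default 1.5.
#' @param participant_fraction minimum fraction of participants that must
#'   deviate, in (0, 1]. Default 0.25.
#' @param cv_threshold upper bound on the median within-participant CV
#'   (linear scale), in (0, 1). Default 0.20.
#' @param min_quantified_fraction proteins quantified in fewer than this
#'   fraction of samples are excluded before evaluation (unstable medians).
#'   Default 0.5.
#' @return a `specificity_params` list.
#' @export
specificity_params <- function(fold_threshold = 1.5, participant_fraction = 0.25,
                               cv_threshold = 0.20, min_quantified_fraction = 0.5) {
  if (!is_scalar_number(fold_threshold) || fold_threshold <= 1) {
    stop_named("fold_threshold must be a number > 1")
  }
  if (!is_scalar_number(participant_fraction) || participant_fraction <= 0 || participant_fraction > 1) {
    stop_named("participant_fraction must be in (0, 1]")
  }
  if (!is_scalar_number(cv_threshold) || cv_threshold <= 0 || cv_threshold >= 1) {
    stop_named("cv_threshold must be in (0, 1)")
  }
  structure(list(fold_threshold = fold_threshold,
                 participant_fraction = participant_fraction,
                 cv_threshold = cv_threshold,
                 min_quantified_fraction = min_quantified_fraction),
            class = "specificity_params")
}

#' Per-participant level of one protein
#'
#' The level of a protein "in a participant" is the median of that
#' participant's non-missing intensities across time points.
#'
#' @param x an [intensity_matrix()].
#' @param protein protein id.
#' @return named numeric vector, one entry per individual (`NA` when the
#'   individual has no observation).
#' @export
participant_levels <- function(x, protein) {
  stopifnot(inherits(x, "intensity_matrix"))
  if (!protein %in% rownames(x$values)) stop_named("unknown protein id: %s", protein)
  v <- x$values[protein, ]
  inds <- unique(x$samples$individual_id)
  out <- vapply(inds, function(i) median_or_na(v[x$samples$individual_id == i]), 0)
  names(out) <- inds
  out
}

#' Within-participant coefficient of variation
#'
#' Sample standard deviation divided by mean, on linear-scale intensities
#' across one individual's time points. Undefined (`NA`) with fewer than two
#' non-missing observations.
#'
#' @param x an [intensity_matrix()].
#' @param protein protein id.
#' @param individual individual id.
#' @return non-negative number, or `NA`.
#' @export
within_cv <- function(x, protein, individual) {
  stopifnot(inherits(x, "intensity_matrix"))
  if (!protein %in% rownames(x$values)) stop_named("unknown protein id: %s", protein)
  v <- x$values[protein, x$samples$individual_id == individual]
  v <- v[!is.na(v)]
  if (length(v) < 2L) return(NA_real_)
  stats::sd(v) / mean(v)
}

#' Select individual-specific proteins
#'
#' Evaluates every sufficiently quantified protein against both criteria:
#' (a) the fraction of individuals whose per-participant level deviates from
#' the population median (the median of per-participant levels) by a
#' symmetric ratio `max(level/median, median/level)` greater than
#' `fold_threshold` is at least `participant_fraction`; and (b) the median
#' across individuals of the within-participant CV is below `cv_threshold`.
#'
#' @param x an [intensity_matrix()].
#' @param params a [specificity_params()].
#' @return a `protein_panel`: list with `protein_ids` (the selected set, in
#'   matrix order), `stats` (per evaluated protein: `fraction_deviating`,
#'   `median_within_cv`, `selected`) and `params`.
#' @export
select_individual_specific <- function(x, params = specificity_params()) {
  stopifnot(inherits(x, "intensity_matrix"), inherits(params, "specificity_params"))
  vals <- x$values
  inds <- unique(x$samples$individual_id)
  ind_of <- x$samples$individual_id
  n_smp <- ncol(vals)
  stats_rows <- lapply(rownames(vals), function(p) {
    v <- vals[p, ]
    if (n_smp == 0L || mean(!is.na(v)) < params$min_quantified_fraction) return(NULL)
    levels <- vapply(inds, function(i) median_or_na(v[ind_of == i]), 0)
    levels <- levels[!is.na(levels)]
    if (length(levels) < 2L) return(NULL)
    popmed <- stats::median(levels)
    ratio <- pmax(levels / popmed, popmed / levels)
    frac <- mean(ratio > params$fold_threshold)
    cvs <- vapply(inds, function(i) {
      w <- v[ind_of == i]
      w <- w[!is.na(w)]
      if (length(w) < 2L) NA_real_ else stats::sd(w) / mean(w)
    }, 0)
    med_cv <- median_or_na(cvs)
    data.frame(protein_id = p, fraction_deviating = frac, median_within_cv = med_cv,
               selected = frac >= params$participant_fraction &&
                 !is.na(med_cv) && med_cv < params$cv_threshold,
               stringsAsFactors = FALSE)
  })
  stats_df <- do.call(rbind, stats_rows)
  if (is.null(stats_df)) {
    stats_df <- data.frame(protein_id = character(), fraction_deviating = numeric(),
                           median_within_cv = numeric(), selected = logical(),
                           stringsAsFactors = FALSE)
  }
  rownames(stats_df) <- NULL
  structure(list(protein_ids = stats_df$protein_id[stats_df$selected],
                 stats = stats_df, params = params),
            class = "protein_panel")
}

#' @export
print.protein_panel <- function(x, ...) {
  cat(sprintf("protein_panel: %d of %d evaluated proteins selected as individual-specific\n",
              length(x$protein_ids), nrow(x$stats)))
  invisible(x)
}

#' Write / read a protein panel as JSON
#'
#' @param panel a `protein_panel`.
#' @param path JSON path.
#' @return the panel, invisibly (write) or reconstructed (read).
#' @export
write_protein_panel <- function(panel, path) {
  stopifnot(inherits(panel, "protein_panel"))
  jsonlite::write_json(
    list(protein_ids = panel$protein_ids, stats = panel$stats,
         params = unclass(panel$params)),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(panel)
}

#' @rdname write_protein_panel
#' @export
read_protein_panel <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  params <- do.call(specificity_params, obj$params)
  structure(list(protein_ids = as.character(obj$protein_ids),
                 stats = as.data.frame(obj$stats), params = params),
            class = "protein_panel")
}

#' Screen for incidental marker spikes
#'
#' Flags every (sample, marker) whose intensity exceeds `fold_threshold`
#' times that individual's own median level of the marker — the signature of
#' e.g. an acute-phase response at a single time point.
#'
#' @param x an [intensity_matrix()].
#' @param marker_proteins character vector of marker protein ids.
#' @param fold_threshold fold-over-personal-median required to flag (> 1).
#' @return `data.frame` of flags: `sample_id`, `individual_id`, `timepoint`,
#'   `marker_protein`, `fold_over_personal_median`.
#' @export
flag_marker_spikes <- function(x, marker_proteins, fold_threshold = 5) {
  stopifnot(inherits(x, "intensity_matrix"))
  if (!is_scalar_number(fold_threshold) || fold_threshold <= 1) {
    stop_named("fold_threshold must be a number > 1")
  }
  unknown <- setdiff(marker_proteins, rownames(x$values))
  if (length(unknown)) stop_named("unknown marker protein(s): %s", paste(unknown, collapse = ", "))
  flags <- list()
  for (m in marker_proteins) {
    v <- x$values[m, ]
    for (i in unique(x$samples$individual_id)) {
      sel <- x$samples$individual_id == i
      med <- median_or_na(v[sel])
      if (is.na(med)) next
      fold <- v[sel] / med
      hit <- which(!is.na(fold) & fold > fold_threshold)
      if (length(hit)) {
        smp <- x$samples[sel, , drop = FALSE][hit, , drop = FALSE]
        flags[[length(flags) + 1L]] <- data.frame(
          sample_id = smp$sample_id, individual_id = smp$individual_id,
          timepoint = smp$timepoint, marker_protein = m,
          fold_over_personal_median = unname(fold[hit]), stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(flags)) {
    return(data.frame(sample_id = character(), individual_id = character(),
                      timepoint = integer(), marker_protein = character(),
                      fold_over_personal_median = numeric(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, flags)
  rownames(out) <- NULL
  out
}
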