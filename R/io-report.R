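#' Write a machine- and human-readable report bundle
#'
#' Serializes assignment results, panels and marker flags into one JSON file
#' (all scores, ranks and per-stage panel counts) plus a TSV summary with
#' percentages formatted to one decimal place.
#'
#' @param results named list; recognized elements: `correlation_assignment`
#'   and/or `allele_assignment` (`assignment_result`), `protein_panel`,
#'   `allele_panel`, `marker_flags` (data.frame).
#' @param path output path for the JSON report; the TSV summary is written
#'   next to it with extension `.tsv`.
#' @return list of the two output paths, invisibly.
#' @export
write_report <- function(results, path) {
  json <- list()
  summary_rows <- list()
  add_row <- function(section, metric, value) {
    summary_rows[[length(summary_rows) + 1L]] <<-
      data.frame(section = section, metric = metric, value = as.character(value),
                 stringsAsFactors = FALSE)
  }
  pct <- function(x) sprintf("%.1f", round_half_up(x, 1))
  for (nm in intersect(c("correlation_assignment", "allele_assignment"), names(results))) {
    res <- results[[nm]]
    stopifnot(inherits(res, "assignment_result"))
    s <- res$summary
    json[[nm]] <- list(
      assignments = res$assignments,
      scores = as.data.frame(res$scores),
      references = res$references,
      summary = list(n_queries = s$n_queries, n_correct = s$n_correct,
                     error_rate_percent = s$error_rate_percent,
                     percent_correct = s$percent_correct,
                     median_intra = s$median_intra, median_inter = s$median_inter))
    add_row(nm, "n_queries", s$n_queries)
    add_row(nm, "n_correct", s$n_correct)
    add_row(nm, "error_rate_percent", pct(s$error_rate_percent))
    add_row(nm, "percent_correct", pct(s$percent_correct))
  }
  if (!is.null(results$protein_panel)) {
    p <- results$protein_panel
    json$protein_panel <- list(protein_ids = p$protein_ids, stats = p$stats,
                               params = unclass(p$params))
    add_row("protein_panel", "n_selected", length(p$protein_ids))
    add_row("protein_panel", "n_evaluated", nrow(p$stats))
  }
  if (!is.null(results$allele_panel)) {
    p <- results$allele_panel
    json$allele_panel <- list(groups = p$groups,
                              stage_counts = as.list(p$stage_counts),
                              params = unclass(p$params))
    for (st in names(p$stage_counts)) {
      add_row("allele_panel", paste0("stage_", st), p$stage_counts[[st]])
    }
  }
  if (!is.null(results$marker_flags)) {
    json$marker_flags <- results$marker_flags
    add_row("marker_screen", "n_flags", nrow(results$marker_flags))
  }
  jsonlite::write_json(json, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows")
  tsv_path <- sub("\\.json$", ".tsv", path)
  if (identical(tsv_path, path)) tsv_path <- paste0(path, ".tsv")
  summary_df <- if (length(summary_rows)) do.call(rbind, summary_rows) else
    data.frame(section = character(), metric = character(), value = character())
  utils::write.table(summary_df, tsv_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(json = path, tsv = tsv_path))
}
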