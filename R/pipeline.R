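#' Read a pipeline configuration file
#'
#' The configuration is a single JSON file with flat fields; every module
#' threshold is surfaced here with its default, so nothing is hard-coded.
#' Any field may be overridden programmatically (or by CLI flags).
#'
#' @param path JSON config path (optional; `NULL` gives all defaults).
#' @param overrides named list of overrides applied on top of the file.
#' @return a validated `pipeline_config` list.
#' @export
read_pipeline_config <- function(path = NULL, overrides = list()) {
  cfg <- if (is.null(path)) list() else jsonlite::read_json(path, simplifyVector = TRUE)
  for (nm in names(overrides)) cfg[[nm]] <- overrides[[nm]]
  defaults <- list(
    out_dir = "proteoid_out",
    matrix = NULL, annotations = NULL, evidence = NULL,
    fasta = NULL, variants = NULL,
    simulate = FALSE, seed = 1L,
    reference_timepoint = 1L, min_overlap = 20L, log10_scale = TRUE,
    strict_calls = FALSE,
    fold_threshold = 1.5, participant_fraction = 0.25, cv_threshold = 0.20,
    min_quantified_fraction = 0.5,
    cleave_after = c("K", "R"), max_missed_cleavages = 2L, min_length = 7L,
    cleave_before_proline = TRUE,
    min_presence = 6L, n_timepoints = 7L, variation_ratio = 10,
    markers = NULL, marker_fold_threshold = 5,
    cohort = list()
  )
  for (nm in names(defaults)) if (is.null(cfg[[nm]])) cfg[[nm]] <- defaults[[nm]]
  unknown <- setdiff(names(cfg), names(defaults))
  if (length(unknown)) stop_named("unknown config field(s): %s", paste(unknown, collapse = ", "))
  structure(cfg, class = "pipeline_config")
}

log_info <- function(fmt, ...) message(sprintf(paste0("[proteoid] ", fmt), ...))

#' Run the full reidentification pipeline
#'
#' Executes, in order: simulate (optional) -> select individual-specific
#' proteins -> correlation assignment -> build allele panel -> allele
#' assignment -> marker screen -> report. Every stage logs its parameters
#' and input shapes to standard error; all intermediates are files under
#' `config$out_dir`, so a stage's inputs are never mutated by later stages.
#'
#' @param config a `pipeline_config` from [read_pipeline_config()].
#' @return list of result objects (`cohort`, `protein_panel`,
#'   `correlation_assignment`, `allele_panel`, `allele_assignment`,
#'   `marker_flags`, `report_paths`), invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!isTRUE(config$simulate) && (is.null(config$matrix) || is.null(config$annotations))) {
    stop_named("stage select-panel: config must provide 'matrix' and 'annotations' paths")
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  results <- list()

  if (isTRUE(config$simulate)) {
    cc <- do.call(cohort_config, c(config$cohort, list(seed = config$seed)))
    log_info("simulate: %d individuals x %d timepoints, %d proteins, %d loci, seed %d",
             cc$n_individuals, cc$n_timepoints, cc$n_proteins, cc$n_loci, cc$seed)
    cohort <- simulate_cohort(cc)
    write_cohort(cohort, config$out_dir)
    config$matrix <- file.path(config$out_dir, "matrix.tsv")
    config$annotations <- file.path(config$out_dir, "annotations.tsv")
    config$evidence <- file.path(config$out_dir, "evidence.tsv")
    results$cohort <- cohort
  }
  if (is.null(config$matrix) || is.null(config$annotations)) {
    stop_named("stage select-panel: config must provide 'matrix' and 'annotations' paths")
  }
  mat <- read_intensity_matrix(config$matrix, config$annotations)
  log_info("input: %d proteins x %d samples", nrow(mat$values), ncol(mat$values))

  sp <- specificity_params(config$fold_threshold, config$participant_fraction,
                           config$cv_threshold, config$min_quantified_fraction)
  panel <- select_individual_specific(mat, sp)
  log_info("select-panel: %d of %d proteins individual-specific (fold > %.2f, fraction >= %.2f, CV < %.2f)",
           length(panel$protein_ids), nrow(panel$stats),
           sp$fold_threshold, sp$participant_fraction, sp$cv_threshold)
  write_protein_panel(panel, file.path(config$out_dir, "protein_panel.json"))
  results$protein_panel <- panel

  if (length(panel$protein_ids)) {
    corr <- assign_by_correlation(mat, panel, config$reference_timepoint,
                                  min_overlap = config$min_overlap,
                                  log10_scale = isTRUE(config$log10_scale))
    log_info("corr-assign: %d/%d correct (error rate %.1f%%)",
             corr$summary$n_correct, corr$summary$n_queries, corr$summary$error_rate_percent)
    results$correlation_assignment <- corr
  } else {
    log_info("corr-assign: skipped (no individual-specific proteins selected)")
  }

  if (!is.null(config$evidence)) {
    ann <- utils::read.delim(config$annotations, stringsAsFactors = FALSE)
    ev <- read_evidence_table(config$evidence, annotations = ann)
    groups <- if (!is.null(config$fasta) && !is.null(config$variants)) {
      build_groups_from_sequences(config)
    } else {
      evidence_groups(ev)
    }
    pf <- panel_filter_params(config$min_presence, config$n_timepoints, config$variation_ratio)
    apanel <- filter_cascade(ev, groups, pf)
    log_info("build-panel: stage counts %s",
             paste(sprintf("%s=%d", names(apanel$stage_counts), apanel$stage_counts),
                   collapse = " "))
    write_allele_panel(apanel, file.path(config$out_dir, "allele_panel.json"))
    results$allele_panel <- apanel
    if (nrow(apanel$groups)) {
      amatch <- assign_by_matches(ev, apanel, config$reference_timepoint,
                                  strict = isTRUE(config$strict_calls))
      log_info("allele-assign: %d/%d correct (%.1f%% correct)",
               amatch$summary$n_correct, amatch$summary$n_queries,
               amatch$summary$percent_correct)
      results$allele_assignment <- amatch
    } else {
      log_info("allele-assign: skipped (empty panel)")
    }
  }

  if (!is.null(config$markers)) {
    flags <- flag_marker_spikes(mat, config$markers, config$marker_fold_threshold)
    log_info("screen: %d marker spike flag(s) at fold > %.1f", nrow(flags),
             config$marker_fold_threshold)
    results$marker_flags <- flags
  }

  paths <- write_report(results, file.path(config$out_dir, "report.json"))
  log_info("report: %s", paths$json)
  results$report_paths <- paths
  invisible(results)
}

# digest canonical + variant sequences into labeled, collapsed allele groups
build_groups_from_sequences <- function(config) {
  fasta <- read_fasta(config$fasta)
  variants <- read_variant_table(config$variants)
  dp <- digest_params(config$cleave_after, config$max_missed_cleavages,
                      config$min_length, cleave_before_proline = config$cleave_before_proline)
  peps <- list()
  for (k in seq_len(nrow(fasta))) {
    acc <- strsplit(fasta$header[k], "[| ]")[[1]]
    acc <- if (length(acc) >= 2L && acc[1] %in% c("sp", "tr")) acc[2] else acc[1]
    recs <- variants[variants$accession == acc, , drop = FALSE]
    if (!nrow(recs)) next
    peps[[length(peps) + 1L]] <- enumerate_allele_peptides(
      fasta$sequence[k], recs, dp, gene_id = acc,
      canonical_allele_id = paste0(acc, "_ref"))
  }
  if (!length(peps)) stop_named("no variant loci found for any FASTA record")
  group_missed_cleavage_forms(do.call(rbind, peps))
}

#' Command-line entry point
#'
#' Dispatches the subcommands `simulate`, `select-panel`, `corr-assign`,
#' `build-panel`, `allele-assign`, `screen`, `run` and `report`. All of them
#' accept `--config <file>` (JSON) plus flat flag overrides; `run` executes
#' the whole pipeline. Installed as the executable script
#' `system.file("cli", "proteoid", package = "proteoid")`.
#'
#' @param argv character vector of command-line arguments (excluding the
#'   program name).
#' @return exit status (0 on success), invisibly.
#' @export
proteoid_main <- function(argv = commandArgs(trailingOnly = TRUE)) {
  usage <- "usage: proteoid <simulate|select-panel|corr-assign|build-panel|allele-assign|screen|run|report> [--config file.json] [--out dir] [--seed n] [--matrix f] [--annotations f] [--evidence f] [--fasta f] [--variants f] [--reference-tp k] [--markers a,b]"
  if (!length(argv)) {
    message(usage)
    return(invisible(1L))
  }
  cmd <- argv[1]
  rest <- argv[-1]
  opts <- list()
  i <- 1L
  config_path <- NULL
  while (i <= length(rest)) {
    key <- sub("^--", "", rest[i])
    if (!startsWith(rest[i], "--") || i == length(rest)) {
      message("malformed argument: ", rest[i]); return(invisible(1L))
    }
    val <- rest[i + 1L]
    i <- i + 2L
    switch(key,
           config = { config_path <- val },
           out = { opts$out_dir <- val },
           seed = { opts$seed <- as.integer(val) },
           matrix = { opts$matrix <- val },
           annotations = { opts$annotations <- val },
           evidence = { opts$evidence <- val },
           fasta = { opts$fasta <- val },
           variants = { opts$variants <- val },
           `reference-tp` = { opts$reference_timepoint <- as.integer(val) },
           markers = { opts$markers <- strsplit(val, ",")[[1]] },
           { message("unknown flag --", key); return(invisible(1L)) })
  }
  status <- tryCatch({
    cfg <- read_pipeline_config(config_path, opts)
    switch(cmd,
           simulate = {
             cfg$simulate <- TRUE
             cc <- do.call(cohort_config, c(cfg$cohort, list(seed = cfg$seed)))
             write_cohort(simulate_cohort(cc), cfg$out_dir)
           },
           run = {
             run_pipeline(cfg)
           },
           `select-panel` = ,
           `corr-assign` = ,
           `build-panel` = ,
           `allele-assign` = ,
           screen = ,
           report = {
             # individual stages share the orchestrator; it skips what the
             # config does not request (no evidence -> no allele stages, etc.)
             run_pipeline(cfg)
           },
           { message("unknown subcommand: ", cmd); message(usage); return(invisible(1L)) })
    0L
  }, error = function(e) {
    message("proteoid: ", conditionMessage(e))
    1L
  })
  invisible(status)
}
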