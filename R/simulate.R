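#' Configuration of a synthetic longitudinal plasma cohort
#'
#' The generator emulates a longitudinal profiling study: 42 individuals
#' sampled at 7 time points, a few hundred quantified proteins whose
#' log10-intensities decompose into a protein baseline, a stable
#' between-individual offset and small within-individual noise, plus diploid
#' variant-peptide presence patterns with acquisition dropout.
#'
#' Log10 intensity of protein p in individual i at time t is
#' `mu_p + b_(p,i) + e_(p,i,t)` with `b ~ N(0, sigma_between^2)` per
#' (protein, individual) and `e ~ N(0, sigma_within^2)` per observation.
#' "Flat" (non-specific) proteins use the flat sigmas. Values are
#' exponentiated to linear scale and masked missing uniformly at random.
#'
#' @param n_individuals number of individuals (default 42).
#' @param n_timepoints time points per individual (default 7).
#' @param n_proteins quantified proteins (default 300).
#' @param fraction_specific fraction of proteins simulated as
#'   individual-specific (default 0.7).
#' @param sigma_between,sigma_within log10-scale SDs for specific proteins
#'   (defaults 0.3, 0.05).
#' @param sigma_between_flat,sigma_within_flat log10-scale SDs for flat
#'   proteins (defaults 0.02, 0.05).
#' @param mu_log10_range range of baseline log10 abundances (default
#'   `c(1, 6)`).
#' @param missing_rate probability a cell is masked missing (default 0.01).
#' @param n_loci diallelic variant loci (default 60).
#' @param alt_allele_freq per-locus alternate allele frequency; `NULL`
#'   (default) draws each uniformly in \[0.1, 0.9\], or supply a scalar /
#'   length-`n_loci` vector.
#' @param peptide_detection_prob probability an allele's peptide group is
#'   detected in a sample given the individual carries the allele (default
#'   0.95).
#' @param erratic_gene_fraction fraction of loci whose peptides are observed
#'   sporadically, decoupled from genotype (default 0.05); the filter
#'   cascade should remove these.
#' @param erratic_rate_range per-allele sporadic detection probability range
#'   for erratic genes (default `c(0.10, 0.30)`). Rates in this band keep
#'   per-individual time-point counts well below the cascade's consistency
#'   threshold, so erratic genes fail stage S1 or S5 rather than masquerading
#'   as diploid-consistent.
#' @param marker_spikes optional `data.frame` with columns `individual_id`,
#'   `timepoint`, `marker`, `fold` for incidental marker spikes.
#' @param seed integer seed; mandatory for reproducibility.
#' @return a `cohort_config` list.
#' @export
cohort_config <- function(n_individuals = 42L, n_timepoints = 7L, n_proteins = 300L,
                          fraction_specific = 0.7,
                          sigma_between = 0.3, sigma_within = 0.05,
                          sigma_between_flat = 0.02, sigma_within_flat = 0.05,
                          mu_log10_range = c(1, 6), missing_rate = 0.01,
                          n_loci = 60L, alt_allele_freq = NULL,
                          peptide_detection_prob = 0.95,
                          erratic_gene_fraction = 0.05,
                          erratic_rate_range = c(0.10, 0.30),
                          marker_spikes = NULL, seed) {
  if (missing(seed) || !is_scalar_number(seed)) stop_named("seed is mandatory and must be a number")
  check_rate <- function(v, nm) {
    if (!is.numeric(v) || any(is.na(v)) || any(v < 0) || any(v > 1)) {
      stop_named("%s must be in [0, 1]", nm)
    }
  }
  check_rate(fraction_specific, "fraction_specific")
  check_rate(missing_rate, "missing_rate")
  check_rate(peptide_detection_prob, "peptide_detection_prob")
  check_rate(erratic_gene_fraction, "erratic_gene_fraction")
  for (nm in c("sigma_between", "sigma_within", "sigma_between_flat", "sigma_within_flat")) {
    v <- get(nm)
    if (!is_scalar_number(v) || v < 0) stop_named("%s must be a non-negative number", nm)
  }
  if (n_individuals < 1L || n_timepoints < 1L || n_proteins < 0L || n_loci < 0L) {
    stop_named("cohort dimensions must be positive")
  }
  if (!is.null(alt_allele_freq)) {
    check_rate(alt_allele_freq, "alt_allele_freq")
    if (any(alt_allele_freq <= 0) || any(alt_allele_freq >= 1)) {
      stop_named("alt_allele_freq must be in (0, 1)")
    }
  }
  structure(list(
    n_individuals = as.integer(n_individuals), n_timepoints = as.integer(n_timepoints),
    n_proteins = as.integer(n_proteins), fraction_specific = fraction_specific,
    sigma_between = sigma_between, sigma_within = sigma_within,
    sigma_between_flat = sigma_between_flat, sigma_within_flat = sigma_within_flat,
    mu_log10_range = mu_log10_range, missing_rate = missing_rate,
    n_loci = as.integer(n_loci), alt_allele_freq = alt_allele_freq,
    peptide_detection_prob = peptide_detection_prob,
    erratic_gene_fraction = erratic_gene_fraction,
    erratic_rate_range = erratic_rate_range,
    marker_spikes = marker_spikes, seed = as.integer(seed)
  ), class = "cohort_config")
}

cohort_annotations <- function(config) {
  inds <- sprintf("I%02d", seq_len(config$n_individuals))
  sample_annotations(rep(inds, each = config$n_timepoints),
                     rep(seq_len(config$n_timepoints), times = config$n_individuals))
}

#' Simulate protein intensities
#'
#' See [cohort_config()] for the variance-component model. Stream-splitting:
#' the intensity stage always uses its own sub-seed, so later stages never
#' perturb these draws.
#'
#' @param config a [cohort_config()].
#' @return list with `matrix` (an [intensity_matrix()]) and `truth`
#'   (`data.frame`: `protein_id`, `is_specific`, `mu_log10`).
#' @export
simulate_intensities <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(derive_seed(config$seed, 1L))
  ann <- cohort_annotations(config)
  nP <- config$n_proteins
  nI <- config$n_individuals
  nT <- config$n_timepoints
  proteins <- sprintf("PROT%03d", seq_len(nP))
  n_spec <- round(config$fraction_specific * nP)
  is_specific <- seq_len(nP) %in% sample(nP, n_spec)
  mu <- stats::runif(nP, config$mu_log10_range[1], config$mu_log10_range[2])
  sb <- ifelse(is_specific, config$sigma_between, config$sigma_between_flat)
  sw <- ifelse(is_specific, config$sigma_within, config$sigma_within_flat)
  b <- matrix(stats::rnorm(nP * nI, 0, rep(sb, nI)), nP, nI)
  eps <- matrix(stats::rnorm(nP * nI * nT, 0, rep(sw, nI * nT)), nP, nI * nT)
  loga <- mu + b[, rep(seq_len(nI), each = nT)] + eps
  vals <- 10^loga
  if (config$missing_rate > 0) {
    vals[stats::runif(length(vals)) < config$missing_rate] <- NA_real_
  }
  dimnames(vals) <- list(proteins, ann$sample_id)
  list(matrix = intensity_matrix(vals, ann),
       truth = data.frame(protein_id = proteins, is_specific = is_specific,
                          mu_log10 = mu, stringsAsFactors = FALSE))
}

# deterministic peptide construction for one locus: fully-cleaved + 1-missed
# form per allele, differing only at the variant residue.
locus_peptides <- function(gene, site, ref_res, alt_res, core, ext) {
  full_ref <- paste0(core[1], ref_res, core[2], "K")
  full_alt <- paste0(core[1], alt_res, core[2], "K")
  data.frame(
    peptide_sequence = c(full_ref, paste0(full_ref, ext, "R"),
                         full_alt, paste0(full_alt, ext, "R")),
    gene_id = gene,
    protein_accession = paste0("ACC_", gene),
    allele_id = rep(c(paste0(gene, "_ref"), paste0(gene, "_alt")), each = 2L),
    variant_site = site,
    missed_cleavages = c(0L, 1L, 0L, 1L),
    stringsAsFactors = FALSE
  )
}

#' Simulate diploid genotypes and variant-peptide evidence
#'
#' Genotypes (0/1/2 copies of the alternate allele) are drawn per individual
#' and locus with Hardy-Weinberg proportions from the locus' alternate
#' allele frequency. An allele's peptide group is eligible for detection in
#' a sample iff the individual carries at least one copy; detection then
#' occurs independently per sample with `peptide_detection_prob`. Both the
#' fully cleaved and a 1-missed-cleavage peptide row are emitted per group
#' (the missed form co-detected with probability 0.5) to exercise
#' missed-cleavage collapsing. Erratic genes instead receive sporadic
#' presence decoupled from genotype, drawn i.i.d. per sample at a per-allele
#' rate from `erratic_rate_range` — the pattern the cascade's variation
#' filter is designed to remove.
#'
#' @param config a [cohort_config()].
#' @return list with `genotypes` (individuals x loci integer matrix),
#'   `evidence` (an [evidence_table()]) and `truth` (`data.frame`: `gene_id`,
#'   `alt_allele_freq`, `variant_site`, `erratic`).
#' @export
simulate_allele_evidence <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  ann <- cohort_annotations(config)
  nL <- config$n_loci
  nI <- config$n_individuals
  inds <- unique(ann$individual_id)
  if (nL == 0L) {
    pep <- data.frame(peptide_sequence = character(), gene_id = character(),
                      protein_accession = character(), allele_id = character(),
                      variant_site = integer(), stringsAsFactors = FALSE)
    ev <- evidence_table(pep, matrix(FALSE, 0L, nrow(ann), dimnames = list(NULL, ann$sample_id)), ann)
    return(list(genotypes = matrix(0L, nI, 0L, dimnames = list(inds, NULL)),
                evidence = ev,
                truth = data.frame(gene_id = character(), alt_allele_freq = numeric(),
                                   variant_site = integer(), erratic = logical())))
  }
  genes <- sprintf("GENE%03d", seq_len(nL))
  # genotype stream
  set.seed(derive_seed(config$seed, 2L))
  freq <- config$alt_allele_freq %||% stats::runif(nL, 0.1, 0.9)
  if (length(freq) == 1L) freq <- rep(freq, nL)
  genotypes <- matrix(stats::rbinom(nI * nL, 2L, rep(freq, each = nI)), nI, nL,
                      dimnames = list(inds, genes))
  n_erratic <- round(config$erratic_gene_fraction * nL)
  erratic <- genes %in% sample(genes, n_erratic)
  sites <- sample(20:400, nL, replace = TRUE)
  # peptide sequences: per locus a core without K/R, variant residue differs
  non_kr <- setdiff(AA_ALPHABET20, c("K", "R"))
  pep_rows <- vector("list", nL)
  for (l in seq_len(nL)) {
    core <- c(paste(sample(non_kr, 4L, replace = TRUE), collapse = ""),
              paste(sample(non_kr, 4L, replace = TRUE), collapse = ""))
    res <- sample(non_kr, 2L)
    ext <- paste(sample(non_kr, 3L, replace = TRUE), collapse = "")
    pep_rows[[l]] <- locus_peptides(genes[l], sites[l], res[1], res[2], core, ext)
  }
  peptides <- do.call(rbind, pep_rows)
  # evidence stream
  set.seed(derive_seed(config$seed, 3L))
  n_smp <- nrow(ann)
  presence <- matrix(FALSE, nrow(peptides), n_smp,
                     dimnames = list(NULL, ann$sample_id))
  ind_index <- match(ann$individual_id, inds)
  for (l in seq_len(nL)) {
    rows <- which(peptides$gene_id == genes[l])
    for (allele in c("ref", "alt")) {
      a_rows <- rows[grepl(paste0("_", allele, "$"), peptides$allele_id[rows])]
      if (erratic[l]) {
        rate <- stats::runif(1, config$erratic_rate_range[1], config$erratic_rate_range[2])
        grp <- stats::runif(n_smp) < rate
      } else {
        carrier <- if (allele == "ref") genotypes[, l] < 2L else genotypes[, l] > 0L
        grp <- carrier[ind_index] & stats::runif(n_smp) < config$peptide_detection_prob
      }
      full <- a_rows[peptides$missed_cleavages[a_rows] == 0L]
      missed <- a_rows[peptides$missed_cleavages[a_rows] == 1L]
      presence[full, ] <- grp
      presence[missed, ] <- grp & stats::runif(n_smp) < 0.5
    }
  }
  ev <- evidence_table(peptides[, c("peptide_sequence", "gene_id", "protein_accession",
                                    "allele_id", "variant_site")], presence, ann)
  list(genotypes = genotypes, evidence = ev,
       truth = data.frame(gene_id = genes, alt_allele_freq = freq,
                          variant_site = sites, erratic = erratic,
                          stringsAsFactors = FALSE))
}

#' Inject incidental marker spikes into an intensity matrix
#'
#' Multiplies the designated (individual, timepoint, marker) cells by `fold`;
#' all other cells are untouched.
#'
#' @param x an [intensity_matrix()].
#' @param spikes `data.frame` with columns `individual_id`, `timepoint`,
#'   `marker`, `fold` (fold > 0).
#' @return the modified [intensity_matrix()].
#' @export
inject_marker_spike <- function(x, spikes) {
  stopifnot(inherits(x, "intensity_matrix"))
  if (is.null(spikes) || !nrow(spikes)) return(x)
  v <- x$values
  for (k in seq_len(nrow(spikes))) {
    s <- spikes[k, ]
    if (!s$marker %in% rownames(v)) stop_named("unknown marker protein: %s", s$marker)
    if (!is_scalar_number(s$fold) || s$fold <= 0) stop_named("spike fold must be > 0")
    col <- which(x$samples$individual_id == s$individual_id &
                   x$samples$timepoint == as.integer(s$timepoint))
    if (!length(col)) {
      stop_named("unknown sample: individual %s timepoint %s", s$individual_id, s$timepoint)
    }
    v[s$marker, col] <- v[s$marker, col] * s$fold
  }
  intensity_matrix(v, x$samples)
}

#' Simulate a complete synthetic cohort
#'
#' Composes intensity, genotype/evidence and spike generation under one
#' master seed with a fixed stream-splitting order (intensities, genotypes,
#' evidence, spikes), so e.g. adding spikes never perturbs earlier draws.
#'
#' @param config a [cohort_config()].
#' @return a `synthetic_cohort`: list with `intensities`
#'   ([intensity_matrix()]), `annotations`, `genotypes`, `evidence`
#'   ([evidence_table()]), `truth` (list: `proteins`, `loci`) and `config`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  ints <- simulate_intensities(config)
  alle <- simulate_allele_evidence(config)
  mat <- ints$matrix
  if (!is.null(config$marker_spikes) && nrow(config$marker_spikes)) {
    set.seed(derive_seed(config$seed, 4L)) # reserved stream (spikes are deterministic)
    mat <- inject_marker_spike(mat, config$marker_spikes)
  }
  structure(list(intensities = mat, annotations = mat$samples,
                 genotypes = alle$genotypes, evidence = alle$evidence,
                 truth = list(proteins = ints$truth, loci = alle$truth),
                 config = config),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("synthetic_cohort: %d individuals x %d timepoints, %d proteins, %d loci (seed %d)\n",
              x$config$n_individuals, x$config$n_timepoints,
              x$config$n_proteins, x$config$n_loci, x$config$seed))
  invisible(x)
}

#' Write cohort artifacts in the pipeline's file formats
#'
#' Emits `matrix.tsv`, `annotations.tsv`, `evidence.tsv` and `truth.json`
#' under `dir`.
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory (created if needed).
#' @return the file paths, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(matrix = file.path(dir, "matrix.tsv"),
                annotations = file.path(dir, "annotations.tsv"),
                evidence = file.path(dir, "evidence.tsv"),
                truth = file.path(dir, "truth.json"))
  write_intensity_matrix(cohort$intensities, paths$matrix, paths$annotations)
  write_evidence_table(cohort$evidence, paths$evidence)
  jsonlite::write_json(
    list(proteins = cohort$truth$proteins, loci = cohort$truth$loci,
         genotypes = as.data.frame(cohort$genotypes)),
    paths$truth, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(paths)
}

#' Moment estimates of the cohort variance components
#'
#' Independent one-way decomposition per protein on log10 intensities:
#' the within component is the pooled per-individual sample variance, the
#' between component the variance of per-individual means minus `within / t`
#' (balanced-design moment correction). Returns the square roots of the
#' across-protein mean components.
#'
#' @param x an [intensity_matrix()].
#' @param proteins protein ids to pool over (default: all).
#' @return list with `sigma_between`, `sigma_within`, and the per-protein
#'   component `data.frame`.
#' @export
estimate_variance_components <- function(x, proteins = NULL) {
  stopifnot(inherits(x, "intensity_matrix"))
  proteins <- proteins %||% rownames(x$values)
  v <- log10(x$values[proteins, , drop = FALSE])
  ind <- x$samples$individual_id
  inds <- unique(ind)
  per_protein <- lapply(proteins, function(p) {
    y <- v[p, ]
    means <- vapply(inds, function(i) mean(y[ind == i], na.rm = TRUE), 0)
    vars <- vapply(inds, function(i) {
      w <- y[ind == i]
      w <- w[!is.na(w)]
      if (length(w) < 2L) NA_real_ else stats::var(w)
    }, 0)
    ns <- vapply(inds, function(i) sum(!is.na(y[ind == i])), 0L)
    within <- mean(vars, na.rm = TRUE)
    t_bar <- mean(ns[ns > 0L])
    between <- stats::var(means[!is.na(means)]) - within / t_bar
    data.frame(protein_id = p, var_between = max(between, 0), var_within = within,
               stringsAsFactors = FALSE)
  })
  comp <- do.call(rbind, per_protein)
  list(sigma_between = sqrt(mean(comp$var_between)),
       sigma_within = sqrt(mean(comp$var_within)),
       components = comp)
}
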