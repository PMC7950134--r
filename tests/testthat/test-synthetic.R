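small_config <- function(seed = 1, ...) {
  cohort_config(n_individuals = 8, n_timepoints = 4, n_proteins = 40,
                n_loci = 12, seed = seed, ...)
}

test_that("configuration validates fields individually and requires a seed", {
  expect_error(cohort_config(), "seed")
  expect_error(cohort_config(missing_rate = 1.5, seed = 1), "missing_rate")
  expect_error(cohort_config(sigma_between = -1, seed = 1), "sigma_between")
  expect_error(cohort_config(alt_allele_freq = 0, seed = 1), "alt_allele_freq")
})

test_that("intensity simulation is deterministic and degenerates correctly", {
  cc <- small_config(seed = 42)
  a <- simulate_intensities(cc)
  b <- simulate_intensities(cc)
  expect_identical(a$matrix$values, b$matrix$values) # bit-identical rerun
  expect_identical(a$truth, b$truth)

  # all sigmas zero, no missingness -> every protein constant at 10^mu
  cc0 <- small_config(seed = 7, sigma_between = 0, sigma_within = 0,
                      sigma_between_flat = 0, sigma_within_flat = 0, missing_rate = 0)
  z <- simulate_intensities(cc0)
  expect_equal(unname(apply(z$matrix$values, 1, function(r) diff(range(r)))),
               rep(0, 40))
  expect_equal(unname(z$matrix$values[, 1]), 10^z$truth$mu_log10)
})

test_that("simulated between-individual variance dominates for specific proteins", {
  cc <- cohort_config(n_individuals = 20, n_timepoints = 5, n_proteins = 100,
                      n_loci = 0, seed = 3)
  sim <- simulate_intensities(cc)
  comp <- estimate_variance_components(sim$matrix)$components
  spec_ids <- sim$truth$protein_id[sim$truth$is_specific]
  frac_dominant <- mean(comp$var_between[comp$protein_id %in% spec_ids] >
                          comp$var_within[comp$protein_id %in% spec_ids])
  expect_gte(frac_dominant, 0.95)
})

test_that("allele evidence respects genotypes and Hardy-Weinberg sampling", {
  cc <- small_config(seed = 9, erratic_gene_fraction = 0)
  sim <- simulate_allele_evidence(cc)
  ev <- sim$evidence
  # no alternate-allele peptide is ever detected in a non-carrier
  for (l in seq_len(cc$n_loci)) {
    gene <- sim$truth$gene_id[l]
    alt_rows <- which(ev$peptides$gene_id == gene &
                        grepl("_alt$", ev$peptides$allele_id))
    noncarriers <- rownames(sim$genotypes)[sim$genotypes[, gene] == 0L]
    cols <- ev$samples$sample_id[ev$samples$individual_id %in% noncarriers]
    expect_false(any(ev$presence[alt_rows, cols]))
  }
  # detection_prob 1, no erratic genes -> presence equals carriage at all TPs
  cc1 <- small_config(seed = 9, erratic_gene_fraction = 0, peptide_detection_prob = 1)
  sim1 <- simulate_allele_evidence(cc1)
  g <- evidence_groups(sim1$evidence)
  gp <- group_presence(g, sim1$evidence)
  for (k in seq_len(nrow(g$groups))) {
    gene <- g$groups$gene_id[k]
    carrier <- if (grepl("_ref$", g$groups$allele_id[k])) {
      sim1$genotypes[, gene] < 2L
    } else sim1$genotypes[, gene] > 0L
    expect_identical(unname(gp[k, ]),
                     unname(carrier[sim1$evidence$samples$individual_id]))
  }
  # genotype frequencies within 3 SE of exact Hardy-Weinberg proportions
  cc_hw <- cohort_config(n_individuals = 1000, n_timepoints = 2, n_proteins = 0,
                         n_loci = 1, alt_allele_freq = 0.5,
                         erratic_gene_fraction = 0, seed = 11)
  gt <- simulate_allele_evidence(cc_hw)$genotypes
  counts <- table(factor(gt[, 1], levels = 0:2))
  expected <- c(0.25, 0.5, 0.25) * 1000
  se <- sqrt(1000 * c(0.25, 0.5, 0.25) * (1 - c(0.25, 0.5, 0.25)))
  expect_true(all(abs(counts - expected) <= 3 * se))
})

test_that("marker spikes multiply only the designated cells", {
  cc <- small_config(seed = 5, missing_rate = 0)
  m <- simulate_intensities(cc)$matrix
  spikes <- data.frame(individual_id = c("I01", "I03"), timepoint = c(2L, 4L),
                       marker = c("PROT001", "PROT002"), fold = c(10, 8),
                       stringsAsFactors = FALSE)
  m2 <- inject_marker_spike(m, spikes)
  delta <- m2$values / m$values
  expect_equal(unname(delta["PROT001", "I01_TP2"]), 10)
  expect_equal(unname(delta["PROT002", "I03_TP4"]), 8)
  expect_equal(sum(delta != 1), 2L) # no cross-talk
  # fold 1 -> unchanged
  expect_identical(inject_marker_spike(m, transform(spikes, fold = 1))$values, m$values)
  expect_error(inject_marker_spike(m, data.frame(individual_id = "I01", timepoint = 2L,
                                                 marker = "NOPE", fold = 2)), "NOPE")

  # closed loop with the screen: threshold 5 recovers exactly the 10-fold spike
  flags <- flag_marker_spikes(m2, "PROT001", 5)
  expect_identical(flags$sample_id, "I01_TP2")
})

test_that("cohort orchestration is seed-stable and stream-split", {
  cc <- small_config(seed = 31)
  a <- simulate_cohort(cc)
  b <- simulate_cohort(cc)
  expect_identical(a$intensities$values, b$intensities$values)
  expect_identical(a$genotypes, b$genotypes)
  expect_identical(a$evidence$presence, b$evidence$presence)
  # adding spikes never perturbs earlier draws
  cc_spiked <- small_config(seed = 31, missing_rate = 0,
                            marker_spikes = data.frame(individual_id = "I01",
                                                       timepoint = 1L,
                                                       marker = "PROT003", fold = 6))
  cc_plain <- small_config(seed = 31, missing_rate = 0)
  s <- simulate_cohort(cc_spiked)
  p <- simulate_cohort(cc_plain)
  expect_identical(s$genotypes, p$genotypes)
  expect_identical(s$evidence$presence, p$evidence$presence)
  untouched <- setdiff(rownames(p$intensities$values), "PROT003")
  expect_identical(s$intensities$values[untouched, ], p$intensities$values[untouched, ])

  # default design emits 42 x 7 = 294 samples
  ann <- proteoid:::cohort_annotations(cohort_config(seed = 1))
  expect_equal(nrow(ann), 294L)
})

test_that("a cohort without specific proteins yields at most a 5% panel", {
  cc <- cohort_config(n_individuals = 20, n_timepoints = 5, n_proteins = 100,
                      fraction_specific = 0, n_loci = 0, seed = 13)
  sim <- simulate_intensities(cc)
  panel <- select_individual_specific(sim$matrix)
  expect_lte(length(panel$protein_ids), 5L)
})
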