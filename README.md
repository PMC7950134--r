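# proteoid

Reidentification analysis for longitudinal blood plasma proteomes.

Clinical proteomics samples are blinded and pseudonymized, yet the plasma
proteome itself is identifying. `proteoid` quantifies that privacy risk (and,
conversely, supports sample-swap detection) along the two routes a mass
spectrometry readout offers:

1. **Protein levels.** Many plasma proteins are *individual-specific*: their
   level in a participant differs from the population median by more than
   1.5-fold for at least a quarter of participants, while staying stable
   within a person (coefficient of variation < 20% over time). Correlating a
   blinded sample's individual-specific protein vector (Pearson *r* on log10
   intensities) against one reference sample per individual re-links it to
   its donor.
2. **Allelic information.** Coding SNPs produce single-amino-acid-variant
   (SAAV) tryptic peptides. After in-silico digestion of canonical and
   variant sequences (cleavage after K/R, ≤ 2 missed cleavages, ≥ 7
   residues), allele-discriminating peptides are filtered through a
   five-stage evidence cascade (consistent presence in ≥ 6 of 7 time points
   in some individual; not always/never identified; counterpart allele
   present; missed-cleavage forms collapsed; erratically observed genes
   discarded when total identifications exceed 10× the consistent ones).
   Samples are then matched by counting agreeing present/absent calls —
   panel size minus Hamming distance.

A seeded synthetic-cohort generator (42 individuals × 7 time points, 300
proteins with dominant between-individual variance, 60 diallelic loci with
Hardy–Weinberg genotypes and acquisition dropout) makes the whole pipeline
testable offline. See `vignette("reidentification-methods")` for the model,
its assumptions and its limits.

## Worked example

```r
library(proteoid)

cohort <- simulate_cohort(cohort_config(seed = 7))
cohort
#> synthetic_cohort: 42 individuals x 7 timepoints, 300 proteins, 60 loci (seed 7)

## route 1: individual-specific protein levels
panel <- select_individual_specific(cohort$intensities)
panel
#> protein_panel: 210 of 300 evaluated proteins selected as individual-specific
assign_by_correlation(cohort$intensities, panel, reference_timepoint = 1)
#> assignment_result: 252/252 queries correct (error rate 0.0%)
#>   median intra-individual r = 0.999, inter = 0.959

## route 2: variant-peptide allele matching
apanel <- filter_cascade(cohort$evidence, evidence_groups(cohort$evidence))
apanel
#> allele_panel: 114 groups after cascade (stage counts: S1=114, S2=114, S3=114, S4=114, S5=114)
assign_by_matches(cohort$evidence, apanel, reference_timepoint = 1)
#> assignment_result: 252/252 queries correct (error rate 0.0%)
#>   median intra-individual matches = 106.000, inter = 74.000

## incidental-finding screen: a 12-fold acute-phase spike at one time point
spiked <- inject_marker_spike(cohort$intensities,
  data.frame(individual_id = "I07", timepoint = 4, marker = "PROT010", fold = 12))
flag_marker_spikes(spiked, "PROT010", fold_threshold = 5)
#>   sample_id individual_id timepoint marker_protein fold_over_personal_median
#> 1   I07_TP4           I07         4        PROT010                  10.94674
```

Reading the numbers: all 210 planted individual-specific proteins are
recovered; every one of the 252 blinded queries (42 individuals × 6
non-reference time points) is re-linked to its donor by both routes; the
intra-individual correlation/match medians sit well above the
inter-individual ones (0.999 vs 0.959; 106 vs 74 of 114 panel calls), which
is exactly the separation that makes reidentification work; and the screen
pinpoints the one spiked (sample, marker) cell. On real cohorts the same
functions consume TSV/FASTA inputs via `read_intensity_matrix()`,
`read_evidence_table()`, `read_fasta()` and `read_variant_table()`, or the
bundled CLI (`inst/cli/proteoid`) with subcommands `simulate`,
`select-panel`, `corr-assign`, `build-panel`, `allele-assign`, `screen`,
`run` and `report`.

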