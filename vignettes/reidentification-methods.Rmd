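---
title: "Methods: reidentifying individuals from plasma proteome profiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: reidentifying individuals from plasma proteome profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(proteoid)
```

## The problem

Blinded, pseudonymized samples from a longitudinal plasma proteomics study
can often be re-linked to their donors, because the plasma proteome carries
two independent identifying signals:

1. **Individual-specific protein levels.** Many plasma proteins vary far
   more between people than within one person over time (driven by genetics
   — pQTLs, copy-number effects such as the apolipoprotein(a) Kringle
   repeats — and by stable lifestyle factors). A vector of such protein
   levels acts as a quantitative fingerprint.
2. **Variant (SAAV) peptides.** Coding SNPs change single residues in
   tryptic peptides. Whether the reference- and alternate-allele forms of
   such a peptide are observed in a sample reads out the donor's genotype
   at that locus, one bit at a time.

`proteoid` implements both reidentification routes as a tested pipeline and
ships a synthetic-cohort generator so that every stage is exercisable
without access to any real study data.

## Individual-specific proteins

A protein is *individual-specific* when it simultaneously

- deviates between people: the fraction of participants whose level differs
  from the population median by a symmetric ratio
  $\max(\ell_i/m,\; m/\ell_i) > f$ is at least $q$, and
- is stable within a person: the median across participants of the
  within-participant coefficient of variation
  $\mathrm{CV}_i = s_i/\bar{x}_i$ (linear scale, across time points) is
  below $c$.

Defaults are $f = 1.5$, $q = 0.25$, $c = 0.20$.

Aggregation choices the criterion itself does not pin down, and how we
resolved them:

- the level of a protein "in a participant" is the **median** of that
  participant's non-missing intensities over time, and the population
  median is the median of those per-participant levels — medians for
  robustness against single-time-point spikes;
- the CV criterion is applied to the **median CV across all individuals**,
  not only the deviating ones, so that a protein that is unstable in most
  people cannot qualify through a few quiet carriers;
- CVs are computed on **linear** intensities (the conventional scale for
  CV) while correlations use log10 (below);
- proteins quantified in fewer than 50% of samples are excluded before
  evaluation (`min_quantified_fraction`), because medians over a handful of
  observations are unstable. This threshold is exposed, not hard-coded.

All four choices make the filter strictly monotone in its thresholds
(raising $f$ or $q$, or lowering $c$, can only shrink the panel), which the
test suite verifies property-style.

## Correlation-based assignment

Samples are compared by the Pearson correlation of their
individual-specific protein values, computed on **log10** intensities:
plasma intensities span five orders of magnitude, and on the linear scale a
single abundant protein would dominate the covariance. A linear-scale mode
remains available behind `log10_scale = FALSE`.

Missing values are handled by pairwise-complete deletion with a minimum
overlap of 20 panel proteins (`min_overlap`); below that the correlation is
reported as undefined rather than noisy.

For assignment, one sample per individual at a designated *reference time
point* (the first, by default) is the gallery; every other sample is a
query ranked against all references by $r$. The predicted donor is the
owner of the top-ranked reference. Exact score ties — which essentially
never occur with continuous scores — are broken lexicographically by
individual id and flagged `ambiguous`. Error rates are rounded half-up to
one decimal (so 1 error in 252 queries prints as 0.4%).

## The variant-peptide panel

Allele-discriminating peptides are derived from a canonical sequence plus a
table of substitution variants (UniProt-style 1-based positions, equal
length `ref`/`alt`; indels are out of scope). Each allele sequence is
digested independently; since substitutions preserve length, peptide
coordinates remain comparable across alleles, which also handles
substitutions that create or destroy a K/R cleavage site. A fragment is
reported when it covers the variant site and differs from the
same-coordinate stretch of every other allele at that locus.

Digestion defaults mirror a trypsin + LysC search: cleavage C-terminal to
K/R, up to two missed cleavages, minimum length seven residues. Cleavage
before proline is **enabled** by default (LysC cleaves K–P, and Trypsin/P
rules match the trypsin+LysC protease combination); a strict no-cleavage-
before-proline mode is available. No upper length bound is applied by
default.

### The filter cascade

Observed evidence is filtered in five ordered stages, each a pure filter
whose surviving count is recorded:

| stage | rule |
|-------|------|
| S1 | keep groups present in ≥ `min_presence` of `n_timepoints` time points in ≥ 1 individual (defaults 6 of 7) |
| S2 | drop groups identified in every sample or in none |
| S3 | keep groups with a counterpart group from another allele of the same gene at the same variant site |
| S4 | missed-cleavage collapsing (bookkeeping: groups are already collapsed) |
| S5 | drop every allele of a gene whose total identification count exceeds `variation_ratio` (default 10) times its *consistent* count |

Missed-cleavage forms of one allele site carry identical information, so
they are collapsed into a single group whose presence in a sample is the
logical OR of its members ("counted once"). S3's "overlapping peptide from
another allele" is interpreted geometrically: a group of a *different*
allele of the same gene covering the same variant site, and the
counterpart must itself still be alive after S2 — the cascade is applied
strictly in order.

S5's accounting: `total` is the number of sample-level identifications of
the gene's groups study-wide; `consistent` is the subset contributed by
(group, individual) pairs in which the group was seen `min_presence` to
`n_timepoints` times. A gene dominated by scattered one-off
identifications (e.g. `total = 50`, `consistent = 4` with ratio 10: 50 >
40) is discarded entirely — both alleles — since its detection pattern
cannot be trusted as a genotype readout.

## Present/absent matching

Each sample's call vector holds one boolean per panel group. The match
score between two samples is the number of agreeing positions (panel size
minus Hamming distance). A group never observed in a sample is called
*absent* by default — the present/absent framing admits no third state; a
`strict` mode instead marks never-observed groups as missing and skips
them. Queries are assigned to the reference with the maximal score; ties
are counted **incorrect** (conservative), unlike the correlation route
where a tie merely flags ambiguity — integer scores can genuinely tie.

## The synthetic cohort

The generator states a world matching the design the analysis assumes: 42
individuals × 7 time points, 300 proteins, 60 diallelic loci.

- **Intensities.** $\log_{10} x_{p,i,t} = \mu_p + b_{p,i} +
  \varepsilon_{p,i,t}$ with $\mu_p \sim U(1, 6)$, $b \sim N(0,
  \sigma_b^2)$ per (protein, individual) and $\varepsilon \sim N(0,
  \sigma_w^2)$ per observation. Specific proteins use $\sigma_b = 0.3$,
  $\sigma_w = 0.05$; flat proteins $\sigma_b = 0.02$, $\sigma_w = 0.05$.
  The study this emulates reports no quantitative variance components —
  these defaults are artifact choices set to reproduce the *qualitative*
  signature (intra-individual correlations well above inter-individual
  ones) and are labeled as such. 70% of proteins are specific, 1% of cells
  missing uniformly at random. There is no longitudinal drift term by
  default: intervention effects are out of scope.
- **Genotypes.** Hardy–Weinberg sampling from per-locus alternate-allele
  frequencies drawn uniformly in [0.1, 0.9] — the simplest population
  model.
- **Evidence.** An allele's peptide group is eligible for detection in a
  sample iff the individual carries ≥ 1 copy; detection then occurs with
  probability 0.95 independently per sample (emulating data-dependent
  acquisition dropout). Both the fully cleaved and a 1-missed-cleavage
  peptide row are emitted per group so the collapsing rule is exercised.
- **Erratic genes.** 5% of loci are planted as erratically observed:
  presence is drawn i.i.d. per sample at a per-allele rate from
  [0.10, 0.30], decoupled from genotype. An alternative construction —
  shuffling a genotype-faithful pattern across samples — was rejected
  because shuffling a high-fill pattern (e.g. a near-universal reference
  allele) leaves per-individual consistency nearly intact, and the cascade
  then rightly keeps it; sporadic low-rate presence is what the variation
  filter is designed to reject. Analysis of the S5 predicate shows rates
  ≤ 0.3 keep the chance of an erratic allele accumulating two
  coincidentally consistent individuals (and thereby slipping past S5)
  negligible; depending on the drawn rate an erratic gene may instead
  already fail S1, so tests assert removal by the cascade as a whole and
  that S5 rejects only erratic genes.
- **Determinism.** One master seed is split into fixed streams
  (intensities, genotypes, evidence, spikes), so adding marker spikes never
  perturbs earlier draws and identical configs are bit-identical.

What a green test on this cohort does **not** establish: real plasma data
adds correlated protein modules, intensity-dependent (not uniform)
missingness, batch effects, search-engine identification errors and linkage
between loci. Synthetic accuracies are therefore upper bounds on, not
estimates of, real-data performance; the package asserts only qualitative
signatures (accuracy thresholds, intra > inter medians, monotone
degradation with noise and dropout) that the real study also exhibits.

## Numerical choices

- Percentages are rounded half away from zero to one decimal.
- Pearson correlations use pairwise-complete observations; `min_overlap`
  (default 20) guards against high-variance estimates from few shared
  proteins.
- Variance components are recovered by a balanced one-way moment
  decomposition (within = pooled per-individual variance, between =
  variance of individual means minus within/$t$), clamped at zero.
- Degenerate inputs: proteins with all-missing individuals, individuals
  with single observations (CV undefined), empty panels and header-only
  evidence files are all defined no-error paths; see the reference pages.

## Known limitations

- Insertion/deletion and splice variants are unsupported (substitutions
  only).
- No likelihood-ratio forensic match statistics or population
  allele-frequency calibration; scores are raw agreement counts.
- No peptide detectability/ionization modeling — a real allele peptide can
  be systematically invisible, which present/absent matching then
  misreads as homozygosity.
- MaxQuant-native file parsing is out of scope; evidence enters as a
  long-format TSV.
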