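vt_row <- function(pos, ref, alt, id = "VAR_1", acc = "P1") {
  data.frame(accession = acc, position = pos, ref = ref, alt = alt,
             variant_id = id, stringsAsFactors = FALSE)
}

test_that("substitutions replace residues in place and validate the reference", {
  out <- apply_substitutions("ACDEFGHIK", vt_row(5, "F", "L"))
  expect_identical(out$sequence, "ACDELGHIK")
  # alt == ref is the identity
  expect_identical(apply_substitutions("ACDEFGHIK", vt_row(5, "F", "F"))$sequence,
                   "ACDEFGHIK")
  # reference mismatch names accession, position and residues
  expect_error(apply_substitutions("ACDEFGHIK", vt_row(5, "W", "L")),
               "P1.*position 5.*'W'.*'F'")
  # multi-residue substitution, length preserved
  out2 <- apply_substitutions("ACDEFGHIK", vt_row(3, "DE", "NQ", "VAR_2"))
  expect_identical(out2$sequence, "ACNQFGHIK")
  expect_equal(nchar(out2$sequence), 9L)
})

test_that("allele peptide enumeration reports discriminating coverage of the site", {
  # C -> S inside an 8-mer tryptic peptide: exactly one peptide per allele at
  # 0 missed cleavages, differing at one residue
  canon <- "AAAKTTCTTTTKGGGR"
  rec <- vt_row(7, "C", "S")
  peps <- enumerate_allele_peptides(canon, rec, digest_params(max_missed_cleavages = 0),
                                    gene_id = "G1")
  expect_equal(nrow(peps), 2L)
  expect_setequal(peps$allele_id, c("ref", "VAR_1"))
  expect_setequal(peps$sequence, c("TTCTTTTK", "TTSTTTTK"))
  expect_true(all(peps$start <= peps$variant_site & peps$variant_site <= peps$end))
  expect_true(all(peps$missed_cleavages == 0L))

  # variant in a leading fragment shorter than min_length -> nothing reportable
  short <- enumerate_allele_peptides("AMKTTTTTTTK", vt_row(2, "M", "L"),
                                     digest_params(max_missed_cleavages = 0), "G1")
  expect_equal(nrow(short), 0L)

  # K -> R at a cleavage site: alleles differ only at the C-terminal residue,
  # both reported (per-allele digestion keeps coordinates comparable)
  canon2 <- "TTTTTTTKGGGGGGGR"
  peps2 <- enumerate_allele_peptides(canon2, vt_row(8, "K", "R"),
                                     digest_params(max_missed_cleavages = 0), "G1")
  expect_setequal(peps2$sequence[peps2$allele_id == "ref"], "TTTTTTTK")
  expect_setequal(peps2$sequence[peps2$allele_id == "VAR_1"], "TTTTTTTR")
})

test_that("missed-cleavage forms collapse into one group per allele site", {
  peps <- data.frame(
    sequence = c("TTCTTTTK", "TTCTTTTKGGGR", "TTSTTTTK"),
    gene_id = "G1", allele_id = c("ref", "ref", "VAR_1"),
    variant_site = 7L, stringsAsFactors = FALSE)
  g <- group_missed_cleavage_forms(peps)
  expect_equal(nrow(g$groups), 2L) # two alleles of one gene -> 2 groups
  expect_equal(g$groups$n_members[g$groups$allele_id == "ref"], 2L)
  # no shared sites -> group count equals input count
  distinct <- peps; distinct$allele_id <- c("a", "b", "c")
  expect_equal(nrow(group_missed_cleavage_forms(distinct)$groups), 3L)
})

test_that("group presence is the OR of member peptide presences", {
  ann <- annotations_from_ids(sprintf("A_TP%d", 1:4))
  peptides <- data.frame(
    peptide_sequence = c("TTCTTTTK", "TTCTTTTKGGGR"),
    gene_id = "G1", protein_accession = "P1", allele_id = "ref",
    variant_site = 7L, stringsAsFactors = FALSE)
  presence <- rbind(c(TRUE, FALSE, FALSE, FALSE),
                    c(FALSE, TRUE, FALSE, FALSE))
  colnames(presence) <- ann$sample_id
  ev <- make_evidence(peptides, presence, ann)
  g <- evidence_groups(ev)
  gp <- group_presence(g, ev)
  expect_identical(unname(gp[1, ]), c(TRUE, TRUE, FALSE, FALSE))
})

# build a two-allele evidence set where per-individual time point counts are
# given directly: counts[[allele]] is a named vector individual -> #TPs present
cascade_evidence <- function(counts, n_ind = 25L, n_tp = 7L, site = 7L,
                             scattered = list()) {
  inds <- sprintf("I%02d", seq_len(n_ind))
  ann <- annotations_from_ids(as.vector(t(outer(inds, seq_len(n_tp),
                                                function(i, t) sprintf("%s_TP%d", i, t)))))
  peptides <- data.frame(
    peptide_sequence = c("TTCTTTTK", "TTSTTTTK"),
    gene_id = "G1", protein_accession = "P1",
    allele_id = c("G1_ref", "G1_alt"), variant_site = site,
    stringsAsFactors = FALSE)
  presence <- matrix(FALSE, 2L, nrow(ann), dimnames = list(NULL, ann$sample_id))
  for (a in seq_along(counts)) {
    for (ind in names(counts[[a]])) {
      k <- counts[[a]][[ind]]
      if (k > 0) presence[a, sprintf("%s_TP%d", ind, seq_len(k))] <- TRUE
    }
  }
  make_evidence(peptides, presence, ann)
}

test_that("cascade stages implement the stated predicates in order", {
  # group present 6/7 TPs in one individual, absent elsewhere, with a
  # counterpart allele group -> survives S1-S3
  ev <- cascade_evidence(list(G1_ref = c(I01 = 6), G1_alt = c(I02 = 6)))
  panel <- filter_cascade(ev, evidence_groups(ev), panel_filter_params())
  expect_identical(unname(panel$stage_counts), c(2L, 2L, 2L, 2L, 2L))
  expect_equal(nrow(panel$groups), 2L)

  # group present in every sample -> dropped at S2
  ev2 <- cascade_evidence(list(G1_ref = setNames(rep(7, 25), sprintf("I%02d", 1:25)),
                               G1_alt = c(I01 = 6)))
  panel2 <- filter_cascade(ev2, evidence_groups(ev2))
  expect_identical(panel2$drop_stage[["G1|G1_ref|7"]], "S2")
  # losing its only counterpart kills the alt group at S3
  expect_identical(panel2$drop_stage[["G1|G1_alt|7"]], "S3")
  expect_equal(nrow(panel2$groups), 0L)

  # group never passing the per-individual presence requirement dies at S1
  ev3 <- cascade_evidence(list(G1_ref = c(I01 = 3), G1_alt = c(I02 = 6)))
  panel3 <- filter_cascade(ev3, evidence_groups(ev3))
  expect_identical(panel3$drop_stage[["G1|G1_ref|7"]], "S1")
})

test_that("S5 drops genes whose identifications are dominated by inconsistent ones", {
  # the gene's groups are seen 50 times study-wide but only 4 of those fall in
  # consistent individuals (count within [min_presence, n_timepoints]);
  # 50 > 10 x 4 -> both alleles dropped at S5
  scattered_ref <- setNames(c(2, rep(1, 23)), sprintf("I%02d", 1:24)) # I01 consistent with 2
  scattered_alt <- setNames(c(2, rep(1, 23)), sprintf("I%02d", c(2, setdiff(1:25, 2)[1:23])))
  ev <- cascade_evidence(list(G1_ref = scattered_ref, G1_alt = scattered_alt))
  params <- panel_filter_params(min_presence = 2, n_timepoints = 7, variation_ratio = 10)
  panel <- filter_cascade(ev, evidence_groups(ev), params)
  gs <- panel$gene_stats
  expect_equal(gs$total, 50)       # 25 + 25 identifications
  expect_equal(gs$consistent, 4)   # 2 + 2 inside consistent individuals
  expect_true(gs$dropped)
  expect_identical(unname(panel$drop_stage), c("S5", "S5"))
  expect_equal(nrow(panel$groups), 0L)

  # a consistent gene with the same totals split differently survives
  ok_ref <- setNames(rep(5, 5), sprintf("I%02d", 1:5))
  ok_alt <- setNames(rep(5, 5), sprintf("I%02d", 6:10))
  ev_ok <- cascade_evidence(list(G1_ref = ok_ref, G1_alt = ok_alt))
  panel_ok <- filter_cascade(ev_ok, evidence_groups(ev_ok), params)
  expect_equal(nrow(panel_ok$groups), 2L)
})

test_that("cascade is a pure, threshold-monotone filter", {
  set.seed(99)
  cc <- cohort_config(n_individuals = 12, n_timepoints = 7, n_proteins = 0,
                      n_loci = 25, erratic_gene_fraction = 0.12, seed = 99)
  sim <- simulate_allele_evidence(cc)
  g <- evidence_groups(sim$evidence)
  base <- filter_cascade(sim$evidence, g, panel_filter_params())
  expect_true(all(base$groups$group_id %in% g$groups$group_id))
  expect_true(all(diff(base$stage_counts) <= 0))
  # raising min_presence or lowering variation_ratio never grows the panel
  stricter1 <- filter_cascade(sim$evidence, g, panel_filter_params(min_presence = 7))
  stricter2 <- filter_cascade(sim$evidence, g, panel_filter_params(variation_ratio = 2))
  expect_true(all(stricter1$groups$group_id %in% base$groups$group_id))
  expect_true(all(stricter2$groups$group_id %in% base$groups$group_id))
})
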