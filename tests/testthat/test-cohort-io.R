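test_that("intensity matrix TSV roundtrip is lossless and validates", {
  v <- matrix(c(10, 20, NA, 40), 2, 2,
              dimnames = list(c("P1", "P2"), c("A_TP1", "A_TP2")))
  x <- tiny_matrix(v)
  expect_equal(sum(is.na(x$values)), 1L)

  tmp_m <- withr::local_tempfile(fileext = ".tsv")
  tmp_a <- withr::local_tempfile(fileext = ".tsv")
  write_intensity_matrix(x, tmp_m, tmp_a)
  y <- read_intensity_matrix(tmp_m, tmp_a)
  expect_identical(y$values, x$values)
  expect_identical(y$samples, x$samples)

  # unannotated column named in the error
  ann <- annotations_from_ids(c("A_TP1", "A_TP2"))
  v2 <- v; colnames(v2) <- c("A_TP1", "X_TP9")
  expect_error(intensity_matrix(v2, ann), "X_TP9")
  # duplicate protein id
  v3 <- v; rownames(v3) <- c("P1", "P1")
  expect_error(intensity_matrix(v3, ann), "duplicate protein")
  # non-positive intensity names the cell
  v4 <- v; v4[2, 1] <- -1
  expect_error(intensity_matrix(v4, ann), "P2.*A_TP1")
})

test_that("evidence table long-format parsing, defaults and validation", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  header <- "peptide_sequence\tgene_id\tprotein_accession\tallele_id\tvariant_site\tsample_id\tidentified"
  rows <- sprintf("ACDEFGHK\tG1\tP1\tG1_ref\t10\tA_TP%d\t1", c(1, 3, 5))
  writeLines(c(header, rows), tmp)
  ann <- annotations_from_ids(sprintf("A_TP%d", 1:7))
  ev <- read_evidence_table(tmp, ann)
  expect_equal(sum(ev$presence), 3L)
  expect_equal(ncol(ev$presence), 7L) # absent combinations default to FALSE
  expect_true(all(ev$presence[1, c("A_TP1", "A_TP3", "A_TP5")]))

  # conflicting duplicate rows rejected
  writeLines(c(header,
               "ACDEFGHK\tG1\tP1\tG1_ref\t10\tA_TP1\t1",
               "ACDEFGHK\tG1\tP1\tG1_ref\t10\tA_TP1\t0"), tmp)
  expect_error(read_evidence_table(tmp, ann), "conflicting duplicate")

  # identified outside {0,1}
  writeLines(c(header, "ACDEFGHK\tG1\tP1\tG1_ref\t10\tA_TP1\t2"), tmp)
  expect_error(read_evidence_table(tmp, ann), "0 or 1")

  # illegal sequence characters
  writeLines(c(header, "ACDEFGHX1\tG1\tP1\tG1_ref\t10\tA_TP1\t1"), tmp)
  expect_error(read_evidence_table(tmp, ann), "illegal characters")

  # header-only file -> empty table, no error
  writeLines(header, tmp)
  ev0 <- read_evidence_table(tmp, ann)
  expect_equal(nrow(ev0$peptides), 0L)

  # roundtrip
  writeLines(c(header, rows), tmp)
  ev <- read_evidence_table(tmp, ann)
  tmp2 <- withr::local_tempfile(fileext = ".tsv")
  write_evidence_table(ev, tmp2)
  ev2 <- read_evidence_table(tmp2, ann)
  expect_identical(ev2$presence, ev$presence)
  expect_identical(ev2$peptides, ev$peptides)
})

test_that("variant table parsing validates substitution records", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("accession\tposition\tref\talt\tvariant_id",
               "P02649\t130\tC\tR\tVAR_000652"), tmp)
  vt <- read_variant_table(tmp)
  expect_equal(nrow(vt), 1L)
  expect_identical(vt$accession, "P02649")
  expect_identical(vt$position, 130L)
  expect_identical(vt$ref, "C")
  expect_identical(vt$alt, "R")
  expect_identical(vt$variant_id, "VAR_000652")

  writeLines(c("accession\tposition\tref\talt\tvariant_id",
               "P02649\t130\tCD\tR\tVAR_1"), tmp)
  expect_error(read_variant_table(tmp), "substitutions only")

  writeLines("accession\tposition\tref\talt\tvariant_id", tmp)
  expect_equal(nrow(read_variant_table(tmp)), 0L)
})

test_that("FASTA roundtrip, normalization and validation", {
  tmp <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">sp|P1|T", "ACDEFGH"), tmp)
  fa <- read_fasta(tmp)
  expect_equal(nrow(fa), 1L)
  expect_equal(nchar(fa$sequence), 7L)

  writeLines(c(">p1", "acdefgh"), tmp)
  expect_identical(read_fasta(tmp)$sequence, "ACDEFGH")

  recs <- data.frame(header = c("sp|P1|A desc", "sp|P2|B", "sp|P3|C"),
                     sequence = c("ACDEFGHIK", "MKWVTFR", "PEPTIDEK"),
                     stringsAsFactors = FALSE)
  write_fasta(recs, tmp)
  expect_identical(read_fasta(tmp), recs)

  expect_error(write_fasta(data.frame(header = c("a", "a"), sequence = c("AC", "DE")), tmp),
               "collision")
  expect_identical(variant_fasta_header("sp|P1|A desc", "P1", "VAR_9"),
                   "sp|P1|A desc P1|VAR_9")
})

test_that("report bundle carries one-decimal percentages and stage counts in order", {
  # evaluation with exactly one misassignment among 252 queries -> "0.4"
  n <- 252L
  refs <- data.frame(sample_id = sprintf("I%03d_TP1", 1:42),
                     individual_id = sprintf("I%03d", 1:42), timepoint = 1L)
  truth <- rep(sprintf("I%03d", 1:42), each = 6L)
  assignments <- data.frame(
    sample_id = sprintf("%s_TP%d", truth, rep(2:7, times = 42L)),
    individual_id = truth, timepoint = rep(2:7, times = 42L),
    predicted_individual = c("I002", truth[-1]), # one misassignment
    score = 0.99, correct = c(FALSE, rep(TRUE, n - 1L)),
    rank_of_truth = c(2L, rep(1L, n - 1L)), ambiguous = FALSE,
    stringsAsFactors = FALSE)
  scores <- matrix(0.9, n, 42L, dimnames = list(assignments$sample_id, refs$sample_id))
  res <- structure(list(assignments = assignments, scores = scores,
                        references = refs, score_label = "r", summary = NULL),
                   class = "assignment_result")
  res$summary <- evaluate_assignment(res)
  expect_equal(res$summary$error_rate_percent, 0.4)

  stage_counts <- c(S1 = 83L, S2 = 83L, S3 = 83L, S4 = 67L, S5 = 53L)
  panel <- structure(list(groups = data.frame(group_id = "g", gene_id = "G",
                                              allele_id = "a", variant_site = 1L,
                                              n_members = 1L),
                          members = list(g = "PEPTIDEK"),
                          stage_counts = stage_counts,
                          params = panel_filter_params()),
                     class = "allele_panel")
  tmp <- withr::local_tempfile(fileext = ".json")
  paths <- write_report(list(correlation_assignment = res, allele_panel = panel), tmp)
  js <- jsonlite::read_json(paths$json, simplifyVector = TRUE)
  expect_equal(js$correlation_assignment$summary$error_rate_percent, 0.4)
  expect_identical(unlist(js$allele_panel$stage_counts),
                   c(S1 = 83L, S2 = 83L, S3 = 83L, S4 = 67L, S5 = 53L))
  summary_tsv <- read.delim(paths$tsv, stringsAsFactors = FALSE, colClasses = "character")
  expect_identical(summary_tsv$value[summary_tsv$metric == "error_rate_percent"], "0.4")

  # empty result set -> valid report with zero rows
  paths0 <- write_report(list(), withr::local_tempfile(fileext = ".json"))
  expect_equal(nrow(read.delim(paths0$tsv)), 0L)
})

test_that("sample keys render canonically and annotations enforce uniqueness", {
  expect_identical(sample_key("I01", 3), "I01_TP3")
  expect_error(sample_key("I01", 0), ">= 1")
  expect_error(sample_annotations(c("A", "A"), c(1, 1)), "duplicate")
})
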