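#' Apply substitution variants to a canonical sequence
#'
#' Each variant record replaces `ref` by `alt` (equal length) at its 1-based
#' position, producing one variant sequence per record. The canonical residue
#' at the position must match `ref`.
#'
#' @param canonical_sequence uppercase amino-acid string.
#' @param variant_records a [variant_table()] (or data.frame with the same
#'   columns) for this protein.
#' @return `data.frame` with columns `variant_id`, `position`, `sequence`.
#' @export
apply_substitutions <- function(canonical_sequence, variant_records) {
  canonical_sequence <- toupper(canonical_sequence)
  variant_records <- variant_table(as.data.frame(variant_records))
  out <- lapply(seq_len(nrow(variant_records)), function(i) {
    rec <- variant_records[i, ]
    len <- nchar(rec$ref)
    found <- substr(canonical_sequence, rec$position, rec$position + len - 1L)
    if (found != rec$ref) {
      stop_named("reference mismatch for %s at %s position %d: expected '%s', found '%s'",
                 rec$variant_id, rec$accession, rec$position, rec$ref, found)
    }
    seq <- canonical_sequence
    substr(seq, rec$position, rec$position + len - 1L) <- rec$alt
    data.frame(variant_id = rec$variant_id, position = rec$position,
               sequence = seq, stringsAsFactors = FALSE)
  })
  if (!length(out)) {
    return(data.frame(variant_id = character(), position = integer(),
                      sequence = character(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Enumerate allele-discriminating peptides for one protein
#'
#' Each variant record defines a locus with a canonical and an alternate
#' allele (multiple records at the same position form a multi-allelic
#' locus). Every allele sequence is digested independently; because
#' substitutions preserve length, peptide coordinates remain comparable
#' across alleles. A digest fragment is reported when it covers the variant
#' site and its sequence differs from the same-coordinate stretch of every
#' other allele at that locus — i.e. observing the peptide identifies the
#' allele. Substitutions that create or destroy a K/R cleavage site are
#' handled naturally by the per-allele digestion.
#'
#' @param canonical_sequence uppercase amino-acid string.
#' @param variant_records a [variant_table()] for this protein.
#' @param params a [digest_params()].
#' @param gene_id gene symbol used to label peptides.
#' @param canonical_allele_id allele label for the canonical sequence
#'   (default `"ref"`).
#' @return `data.frame` of allele peptides: `sequence`, `gene_id`,
#'   `allele_id`, `variant_site`, `start`, `end`, `missed_cleavages`, with
#'   `start <= variant_site <= end`.
#' @export
enumerate_allele_peptides <- function(canonical_sequence, variant_records,
                                      params = digest_params(), gene_id = "GENE",
                                      canonical_allele_id = "ref") {
  canonical_sequence <- toupper(canonical_sequence)
  variants <- apply_substitutions(canonical_sequence, variant_records)
  empty <- data.frame(sequence = character(), gene_id = character(),
                      allele_id = character(), variant_site = integer(),
                      start = integer(), end = integer(),
                      missed_cleavages = integer(), stringsAsFactors = FALSE)
  if (!nrow(variants)) return(empty)
  out <- list()
  for (site in unique(variants$position)) {
    at_site <- variants[variants$position == site, , drop = FALSE]
    alleles <- c(stats::setNames(list(canonical_sequence), canonical_allele_id),
                 stats::setNames(as.list(at_site$sequence), at_site$variant_id))
    for (a in names(alleles)) {
      frags <- tryptic_digest(alleles[[a]], params)
      frags <- frags[frags$start <= site & frags$end >= site, , drop = FALSE]
      if (!nrow(frags)) next
      others <- alleles[setdiff(names(alleles), a)]
      discrim <- vapply(seq_len(nrow(frags)), function(k) {
        all(vapply(others, function(o) {
          substr(o, frags$start[k], frags$end[k]) != frags$sequence[k]
        }, TRUE))
      }, TRUE)
      frags <- frags[discrim, , drop = FALSE]
      if (nrow(frags)) {
        out[[length(out) + 1L]] <- data.frame(
          sequence = frags$sequence, gene_id = gene_id, allele_id = a,
          variant_site = as.integer(site), start = frags$start, end = frags$end,
          missed_cleavages = frags$missed_cleavages, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Collapse missed-cleavage forms into allele groups
#'
#' Peptides retaining an internal K/R carry the same allele information as
#' their fully cleaved form, so all peptides sharing
#' `(gene_id, allele_id, variant_site)` merge into one group. Group presence
#' in a sample is the logical OR of member presences — each allele is only
#' counted once per sample.
#'
#' @param peptides `data.frame` of labeled allele peptides (from
#'   [enumerate_allele_peptides()] or the `peptides` slot of an
#'   [evidence_table()]); needs columns `sequence` (or `peptide_sequence`),
#'   `gene_id`, `allele_id`, `variant_site`.
#' @return a `peptide_groups` object: list with `groups` (one row per group:
#'   `group_id`, `gene_id`, `allele_id`, `variant_site`, `n_members`) and
#'   `members` (named list of member peptide sequences per group).
#' @export
group_missed_cleavage_forms <- function(peptides) {
  peptides <- as.data.frame(peptides)
  if ("peptide_sequence" %in% names(peptides) && !"sequence" %in% names(peptides)) {
    peptides$sequence <- peptides$peptide_sequence
  }
  req <- c("sequence", "gene_id", "allele_id", "variant_site")
  missing_cols <- setdiff(req, names(peptides))
  if (length(missing_cols)) {
    stop_named("peptides lack column(s): %s", paste(missing_cols, collapse = ", "))
  }
  gid <- paste(peptides$gene_id, peptides$allele_id, peptides$variant_site, sep = "|")
  ord <- !duplicated(gid)
  groups <- data.frame(group_id = gid[ord], gene_id = peptides$gene_id[ord],
                       allele_id = peptides$allele_id[ord],
                       variant_site = as.integer(peptides$variant_site[ord]),
                       stringsAsFactors = FALSE)
  members <- split(peptides$sequence, factor(gid, levels = groups$group_id))
  members <- lapply(members, unique)
  groups$n_members <- vapply(members, length, 1L)
  rownames(groups) <- NULL
  structure(list(groups = groups, members = members), class = "peptide_groups")
}

#' @export
print.peptide_groups <- function(x, ...) {
  cat(sprintf("peptide_groups: %d groups (%d genes), %d member peptides\n",
              nrow(x$groups), length(unique(x$groups$gene_id)),
              sum(x$groups$n_members)))
  invisible(x)
}

#' Derive allele groups directly from evidence labels
#'
#' Convenience for evidence that already carries gene / allele / variant-site
#' labels (e.g. synthetic cohorts): equivalent to
#' `group_missed_cleavage_forms(evidence$peptides)`.
#'
#' @param evidence an [evidence_table()].
#' @return a `peptide_groups` object.
#' @export
evidence_groups <- function(evidence) {
  stopifnot(inherits(evidence, "evidence_table"))
  group_missed_cleavage_forms(evidence$peptides)
}

#' Group-level presence matrix
#'
#' @param groups a `peptide_groups` object.
#' @param evidence an [evidence_table()]. Member peptides are matched on
#'   `(sequence, allele_id)`; members without evidence rows contribute
#'   nothing (never observed).
#' @return logical matrix, groups x samples (group presence = OR of member
#'   presences).
#' @export
group_presence <- function(groups, evidence) {
  stopifnot(inherits(groups, "peptide_groups"), inherits(evidence, "evidence_table"))
  evkey <- paste(evidence$peptides$peptide_sequence, evidence$peptides$allele_id, sep = "\r")
  pres <- matrix(FALSE, nrow(groups$groups), ncol(evidence$presence),
                 dimnames = list(groups$groups$group_id, colnames(evidence$presence)))
  for (g in seq_len(nrow(groups$groups))) {
    keys <- paste(groups$members[[g]], groups$groups$allele_id[g], sep = "\r")
    rows <- match(keys, evkey)
    rows <- rows[!is.na(rows)]
    if (length(rows)) {
      pres[g, ] <- colSums(evidence$presence[rows, , drop = FALSE]) > 0L
    }
  }
  pres
}

#' Parameters for the allele-panel filter cascade
#'
#' @param min_presence minimum number of time points (out of `n_timepoints`)
#'   in which a group must be seen within at least one individual (default
#'   6).
#' @param n_timepoints time points per individual (default 7).
#' @param variation_ratio a gene is discarded when its total identification
#'   count exceeds `variation_ratio` times its consistent count (default 10).
#' @return a `panel_filter_params` list.
#' @export
panel_filter_params <- function(min_presence = 6L, n_timepoints = 7L,
                                variation_ratio = 10) {
  min_presence <- as.integer(min_presence)
  n_timepoints <- as.integer(n_timepoints)
  if (min_presence < 1L || min_presence > n_timepoints) {
    stop_named("min_presence must satisfy 1 <= min_presence <= n_timepoints")
  }
  if (!is_scalar_number(variation_ratio) || variation_ratio <= 0) {
    stop_named("variation_ratio must be a positive number")
  }
  structure(list(min_presence = min_presence, n_timepoints = n_timepoints,
                 variation_ratio = variation_ratio), class = "panel_filter_params")
}

#' Filter cascade producing the allele-matching panel
#'
#' Applies five stages in order, recording the surviving group count after
#' each:
#' \describe{
#'   \item{S1}{keep groups present in at least `min_presence` of
#'     `n_timepoints` time points within at least one individual;}
#'   \item{S2}{drop groups identified in every sample or in none (no
#'     discriminating information);}
#'   \item{S3}{keep groups with at least one counterpart group from another
#'     allele of the same gene covering the same variant site;}
#'   \item{S4}{missed-cleavage collapsing — already reflected in the groups,
#'     counted here for stage bookkeeping;}
#'   \item{S5}{per gene, let `total` be the number of sample-level
#'     identifications of its groups study-wide and `consistent` the
#'     identifications contributed by (group, individual) pairs seen
#'     `min_presence`..`n_timepoints` times; when
#'     `total > variation_ratio * consistent`, all alleles of the gene are
#'     dropped (erratically observed genes).}
#' }
#'
#' @param evidence an [evidence_table()] whose samples carry individual and
#'   time-point annotations.
#' @param groups a `peptide_groups` object (see
#'   [group_missed_cleavage_forms()] / [evidence_groups()]).
#' @param params a [panel_filter_params()].
#' @return an `allele_panel`: list with `groups` (surviving group rows),
#'   `members`, `stage_counts` (named S1..S5, non-increasing), `drop_stage`
#'   (per input group: stage name or `NA` if retained), `gene_stats` (S5
#'   accounting) and `params`.
#' @export
filter_cascade <- function(evidence, groups, params = panel_filter_params()) {
  stopifnot(inherits(evidence, "evidence_table"), inherits(groups, "peptide_groups"),
            inherits(params, "panel_filter_params"))
  pres <- group_presence(groups, evidence)
  ann <- evidence$samples
  g <- groups$groups
  inds <- unique(ann$individual_id)
  # per-group, per-individual count of time points present
  ind_counts <- vapply(inds, function(i) {
    rowSums(pres[, ann$individual_id == i, drop = FALSE])
  }, numeric(nrow(g)))
  if (nrow(g) == 1L) ind_counts <- matrix(ind_counts, nrow = 1L, dimnames = list(g$group_id, inds))
  alive <- rep(TRUE, nrow(g))
  drop_stage <- rep(NA_character_, nrow(g))
  mark <- function(alive, keep, stage) {
    dropped <- alive & !keep
    drop_stage[dropped] <<- stage
    alive & keep
  }
  # S1: >= min_presence of n_timepoints in >= 1 individual
  s1 <- apply(ind_counts, 1L, max) >= params$min_presence
  alive <- mark(alive, s1, "S1")
  counts <- c(S1 = sum(alive))
  # S2: drop always- or never-identified groups
  n_pres <- rowSums(pres)
  s2 <- n_pres > 0L & n_pres < ncol(pres)
  alive <- mark(alive, s2, "S2")
  counts <- c(counts, S2 = sum(alive))
  # S3: counterpart group from another allele, same gene and variant site
  locus <- paste(g$gene_id, g$variant_site, sep = "|")
  s3 <- vapply(seq_len(nrow(g)), function(k) {
    any(alive & locus == locus[k] & g$allele_id != g$allele_id[k])
  }, TRUE)
  alive <- mark(alive, s3, "S3")
  counts <- c(counts, S3 = sum(alive))
  # S4: collapsing bookkeeping (groups already collapsed)
  counts <- c(counts, S4 = sum(alive))
  # S5: gene-level variation filter on current survivors
  gene_stats <- NULL
  if (any(alive)) {
    total_by_group <- rowSums(pres)
    consistent_mask <- ind_counts >= params$min_presence & ind_counts <= params$n_timepoints
    consistent_by_group <- rowSums(ind_counts * consistent_mask)
    gene_stats <- stats::aggregate(
      cbind(total = total_by_group[alive], consistent = consistent_by_group[alive]),
      by = list(gene_id = g$gene_id[alive]), FUN = sum)
    gene_stats$dropped <- gene_stats$total > params$variation_ratio * gene_stats$consistent
    bad_genes <- gene_stats$gene_id[gene_stats$dropped]
    s5 <- !(g$gene_id %in% bad_genes)
    alive <- mark(alive, s5, "S5")
  }
  counts <- c(counts, S5 = sum(alive))
  structure(list(groups = g[alive, , drop = FALSE],
                 members = groups$members[alive],
                 stage_counts = counts,
                 drop_stage = stats::setNames(drop_stage, g$group_id),
                 gene_stats = gene_stats,
                 params = params),
            class = "allele_panel")
}

#' @export
print.allele_panel <- function(x, ...) {
  cat(sprintf("allele_panel: %d groups after cascade (stage counts: %s)\n",
              nrow(x$groups), paste(sprintf("%s=%d", names(x$stage_counts), x$stage_counts),
                                    collapse = ", ")))
  invisible(x)
}

#' Write / read an allele panel as JSON
#'
#' @param panel an `allele_panel`.
#' @param path JSON path.
#' @export
write_allele_panel <- function(panel, path) {
  stopifnot(inherits(panel, "allele_panel"))
  jsonlite::write_json(
    list(groups = panel$groups,
         members = panel$members,
         stage_counts = as.list(panel$stage_counts),
         params = unclass(panel$params)),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(panel)
}

#' @rdname write_allele_panel
#' @export
read_allele_panel <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  groups <- as.data.frame(obj$groups)
  members <- lapply(obj$members, as.character)
  params <- do.call(panel_filter_params, obj$params)
  structure(list(groups = groups, members = members[groups$group_id],
                 stage_counts = unlist(obj$stage_counts),
                 drop_stage = NULL, gene_stats = NULL, params = params),
            class = "allele_panel")
}
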