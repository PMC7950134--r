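# fixtures and independent oracles used across test files

# tiny intensity matrix from a proteins x samples value matrix; annotations
# derived from canonical "<ind>_TP<k>" column names
tiny_matrix <- function(values) {
  intensity_matrix(values, annotations_from_ids(colnames(values)))
}

annotations_from_ids <- function(ids) {
  m <- regmatches(ids, regexec("^(.+)_TP([0-9]+)$", ids))
  data.frame(sample_id = ids,
             individual_id = vapply(m, `[`, "", 2L),
             timepoint = as.integer(vapply(m, `[`, "", 3L)),
             stringsAsFactors = FALSE)
}

# random cohort-shaped matrix: one row per protein, samples = inds x tps
random_matrix <- function(n_prot, n_ind, n_tp, missing_rate = 0) {
  inds <- sprintf("A%02d", seq_len(n_ind))
  ids <- as.vector(vapply(inds, function(i) sprintf("%s_TP%d", i, seq_len(n_tp)),
                          character(n_tp)))
  v <- matrix(10^stats::runif(n_prot * length(ids), 1, 4), n_prot, length(ids),
              dimnames = list(sprintf("P%03d", seq_len(n_prot)), ids))
  if (missing_rate > 0) v[stats::runif(length(v)) < missing_rate] <- NA
  tiny_matrix(v)
}

# evidence table built directly from a labeled peptide table + presence matrix
make_evidence <- function(peptides, presence, annotations) {
  evidence_table(peptides, presence, annotations)
}

random_aa_sequence <- function(n, alphabet = strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

## ---- independent oracles -------------------------------------------------

# brute-force digest: every substring with valid tryptic termini, at most
# max_missed internal cleavage sites, and length within bounds
oracle_digest <- function(sequence, cleave_after = c("K", "R"),
                          max_missed = 2L, min_length = 7L,
                          cleave_before_proline = TRUE) {
  aa <- strsplit(sequence, "")[[1]]
  n <- length(aa)
  is_site <- function(i) { # cut between residue i and i+1
    i >= 1L && i < n && aa[i] %in% cleave_after &&
      (cleave_before_proline || aa[i + 1L] != "P")
  }
  out <- list()
  for (s in seq_len(n)) {
    for (e in s:n) {
      if (e - s + 1L < min_length) next
      if (!(s == 1L || is_site(s - 1L))) next
      if (!(e == n || is_site(e))) next
      internal <- if (e > s) sum(vapply(s:(e - 1L), is_site, TRUE)) else 0L
      if (internal > max_missed) next
      out[[length(out) + 1L]] <- data.frame(
        sequence = paste(aa[s:e], collapse = ""), start = s, end = e,
        missed_cleavages = internal, stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(sequence = character(), start = integer(), end = integer(),
                      missed_cleavages = integer(), stringsAsFactors = FALSE))
  }
  df <- do.call(rbind, out)
  df[order(df$start, df$missed_cleavages), , drop = FALSE]
}

# brute-force Pearson via the definition
oracle_pearson <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  dx <- x - mean(x); dy <- y - mean(y)
  sum(dx * dy) / sqrt(sum(dx^2) * sum(dy^2))
}

oracle_hamming <- function(a, b) sum(a != b)

# independent re-derivation of the individual-specific selection criteria
oracle_select <- function(x, fold = 1.5, frac = 0.25, cv = 0.20, min_q = 0.5) {
  vals <- x$values
  ind <- x$samples$individual_id
  inds <- unique(ind)
  selected <- character()
  for (p in rownames(vals)) {
    v <- vals[p, ]
    if (mean(!is.na(v)) < min_q) next
    lv <- sapply(inds, function(i) {
      w <- v[ind == i]; w <- w[!is.na(w)]
      if (!length(w)) NA_real_ else stats::median(w)
    })
    lv <- lv[!is.na(lv)]
    if (length(lv) < 2) next
    pm <- stats::median(lv)
    dev <- mean(pmax(lv / pm, pm / lv) > fold)
    cvs <- sapply(inds, function(i) {
      w <- v[ind == i]; w <- w[!is.na(w)]
      if (length(w) < 2) NA_real_ else stats::sd(w) / mean(w)
    })
    cvs <- cvs[!is.na(cvs)]
    if (!length(cvs)) next
    if (dev >= frac && stats::median(cvs) < cv) selected <- c(selected, p)
  }
  selected
}
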