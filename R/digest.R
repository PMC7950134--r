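#' In-silico digestion parameters
#'
#' Defaults mirror a trypsin + LysC search: cleavage C-terminal to lysine and
#' arginine, up to two missed cleavages, minimum peptide length seven.
#'
#' @param cleave_after residues after which the backbone is cut (default
#'   `c("K", "R")`).
#' @param max_missed_cleavages maximum internal uncut K/R sites (default 2).
#' @param min_length minimum peptide length in residues (default 7).
#' @param max_length optional maximum length (`Inf` = none).
#' @param cleave_before_proline if `TRUE` (default) cleavage also occurs when
#'   the following residue is proline (Trypsin/P-style, matching LysC's
#'   ability to cut K-P); set `FALSE` for strict trypsin rules.
#' @return a `digest_params` list.
#' @export
digest_params <- function(cleave_after = c("K", "R"), max_missed_cleavages = 2L,
                          min_length = 7L, max_length = Inf,
                          cleave_before_proline = TRUE) {
  if (!length(cleave_after) || !all(cleave_after %in% AA_ALPHABET20)) {
    stop_named("cleave_after must be a set of amino-acid residues")
  }
  if (max_missed_cleavages < 0L) stop_named("max_missed_cleavages must be >= 0")
  if (min_length < 1L) stop_named("min_length must be >= 1")
  structure(list(cleave_after = toupper(cleave_after),
                 max_missed_cleavages = as.integer(max_missed_cleavages),
                 min_length = as.integer(min_length),
                 max_length = max_length,
                 cleave_before_proline = isTRUE(cleave_before_proline)),
            class = "digest_params")
}

# 1-based positions i such that a cut occurs between residue i and i+1
cleavage_positions <- function(sequence, params) {
  aa <- strsplit(sequence, "")[[1]]
  n <- length(aa)
  if (n < 2L) return(integer())
  pos <- which(aa[-n] %in% params$cleave_after)
  if (!params$cleave_before_proline) pos <- pos[aa[pos + 1L] != "P"]
  pos
}

#' Tryptic in-silico digestion
#'
#' Cuts after every cleavage residue (see [digest_params()]) and emits every
#' fragment spanning at most `max_missed_cleavages` internal cut sites with
#' length at least `min_length`. Coordinates are 1-based inclusive on the
#' input sequence.
#'
#' @param sequence uppercase amino-acid string.
#' @param params a [digest_params()].
#' @return `data.frame` with columns `sequence`, `start`, `end`,
#'   `missed_cleavages`, ordered by `start` then `missed_cleavages`.
#' @export
tryptic_digest <- function(sequence, params = digest_params()) {
  sequence <- toupper(sequence)
  if (!nchar(sequence)) stop_named("cannot digest an empty sequence")
  if (!grepl("^[ACDEFGHIKLMNPQRSTVWY]+$", sequence)) {
    stop_named("sequence contains non-amino-acid characters")
  }
  n <- nchar(sequence)
  bounds <- c(0L, cleavage_positions(sequence, params), n)
  n_seg <- length(bounds) - 1L
  out <- vector("list", n_seg * (params$max_missed_cleavages + 1L))
  k <- 0L
  for (i in seq_len(n_seg)) {
    jmax <- min(i + params$max_missed_cleavages, n_seg)
    for (j in i:jmax) {
      s <- bounds[i] + 1L
      e <- bounds[j + 1L]
      len <- e - s + 1L
      if (len < params$min_length || len > params$max_length) next
      k <- k + 1L
      out[[k]] <- list(sequence = substr(sequence, s, e), start = s, end = e,
                       missed_cleavages = j - i)
    }
  }
  if (k == 0L) {
    return(data.frame(sequence = character(), start = integer(), end = integer(),
                      missed_cleavages = integer(), stringsAsFactors = FALSE))
  }
  out <- out[seq_len(k)]
  df <- data.frame(
    sequence = vapply(out, `[[`, "", "sequence"),
    start = vapply(out, `[[`, 1L, "start"),
    end = vapply(out, `[[`, 1L, "end"),
    missed_cleavages = vapply(out, `[[`, 1L, "missed_cleavages"),
    stringsAsFactors = FALSE
  )
  df[order(df$start, df$missed_cleavages), , drop = FALSE] -> df
  rownames(df) <- NULL
  df
}
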