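# Per-column amino-acid frequencies (the logo-plot layer) and conservation
# scores: Shannon entropy of the non-gap column distribution, z-scored across
# columns so the average score is 0 with SD 1, lower = more conserved.

#' Per-column amino-acid frequencies (logo-plot layer)
#'
#' Frequencies are computed over non-gap residues per column; the gap
#' fraction is recorded separately. Characters outside the 20 standard amino
#' acids are treated as missing.
#'
#' @param bundle An [msa_bundle()] (or a plain character alignment matrix).
#' @return A list with `freq` (20 x n_columns matrix, columns named by
#'   reference position when available), `gap_fraction`, and `n_scored`
#'   (non-gap residues per column).
#' @export
column_frequencies <- function(bundle) {
  m <- if (inherits(bundle, "msa_bundle")) bundle$protein else as.matrix(bundle)
  pos <- if (inherits(bundle, "msa_bundle")) bundle$positions else
    seq_len(ncol(m))
  n_col <- ncol(m)
  freq <- matrix(0, length(AA20), n_col, dimnames = list(AA20, pos))
  n_scored <- integer(n_col)
  for (j in seq_len(n_col)) {
    obs <- m[, j]
    obs <- obs[obs %in% AA20]
    n_scored[j] <- length(obs)
    if (length(obs) > 0L) {
      tab <- table(factor(obs, levels = AA20))
      freq[, j] <- as.numeric(tab) / length(obs)
    }
  }
  list(freq = freq, gap_fraction = 1 - n_scored / nrow(m),
       n_scored = n_scored, positions = pos)
}

shannon_entropy <- function(p) {
  p <- p[p > 0]
  if (length(p) == 0L) return(NA_real_)
  -sum(p * log2(p))
}

#' Normalized per-column conservation scores
#'
#' Raw variability is the Shannon entropy (bits) of each column's non-gap
#' amino-acid distribution. Scores are the z-scores of that variability
#' across scored columns using the population SD, so that the average score
#' over all residues is 0 with a standard deviation of 1 and lower scores
#' mean more conserved positions; fully invariant columns (entropy 0) get the
#' column-minimum score.
#'
#' @param bundle An [msa_bundle()] or alignment matrix.
#' @return A data.frame (`site_table` layer) with `position`, `entropy`,
#'   `conservation`, `gap_fraction`. Columns with no scorable residue carry
#'   `NA` and are excluded from the normalization.
#' @export
conservation_scores <- function(bundle) {
  cf <- column_frequencies(bundle)
  ent <- apply(cf$freq, 2L, shannon_entropy)
  ent[cf$n_scored == 0L] <- NA_real_
  scored <- !is.na(ent)
  if (sum(scored) < 2L) {
    stop("need >= 2 scored columns to normalize conservation", call. = FALSE)
  }
  mu <- mean(ent[scored])
  sdev <- sqrt(mean((ent[scored] - mu)^2))   # population SD
  if (sdev == 0) {
    stop(paste("all columns have identical variability",
               sprintf("(entropy %.4g); conservation z-scores undefined", mu)),
         call. = FALSE)
  }
  data.frame(position = cf$positions,
             entropy = ent,
             conservation = (ent - mu) / sdev,
             gap_fraction = cf$gap_fraction,
             row.names = NULL)
}
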