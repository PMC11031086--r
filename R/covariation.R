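# Column-pair covariation: plug-in mutual information over jointly non-gap
# rows, the average-product correction (APC), and the dual-threshold calling
# rule combining MI with conservation scores.

#' Mutual information between all alignment column pairs
#'
#' For each unordered pair `(i, j)` (`i < j`), MI (bits) is computed from the
#' joint residue counts over rows that are non-gap in both columns; pairs
#' whose joint coverage falls below `min_coverage` of the alignment rows (or
#' below 2 rows) are left unscored (`NA`). The average-product correction
#' `mi_apc = mi - mean_i * mean_j / mean_all` removes background covariation
#' from shared conservation/phylogeny.
#'
#' @param bundle An [msa_bundle()] or alignment matrix.
#' @param min_coverage Minimum fraction of rows jointly non-gap (default 0.5).
#' @return A `pair_table` data.frame with `i`, `j` (reference positions),
#'   `mi_raw`, `mi_apc`, `n_rows`.
#' @export
mutual_information <- function(bundle, min_coverage = 0.5) {
  m <- if (inherits(bundle, "msa_bundle")) bundle$protein else as.matrix(bundle)
  pos <- if (inherits(bundle, "msa_bundle")) bundle$positions else
    seq_len(ncol(m))
  n_col <- ncol(m)
  if (n_col < 3L) stop("need >= 3 columns for APC-corrected MI", call. = FALSE)
  n_row <- nrow(m)
  ok <- matrix(m %in% AA20, n_row, n_col)
  min_rows <- max(2L, ceiling(min_coverage * n_row))
  idx <- t(utils::combn(n_col, 2L))
  mi <- rep(NA_real_, nrow(idx))
  nr <- integer(nrow(idx))
  for (k in seq_len(nrow(idx))) {
    i <- idx[k, 1L]; j <- idx[k, 2L]
    rows <- ok[, i] & ok[, j]
    nr[k] <- sum(rows)
    if (nr[k] < min_rows) next
    tab <- table(m[rows, i], m[rows, j])
    pj <- tab / nr[k]
    pi_ <- rowSums(pj); pj_ <- colSums(pj)
    nz <- pj > 0
    mi[k] <- sum(pj[nz] * log2(pj[nz] / outer(pi_, pj_)[nz]))
  }
  out <- data.frame(i = pos[idx[, 1L]], j = pos[idx[, 2L]],
                    mi_raw = mi, mi_apc = NA_real_, n_rows = nr)
  out$mi_apc <- apc_correct(idx, mi, n_col)
  class(out) <- c("pair_table", "data.frame")
  out
}

# Average-product correction given pair indices and raw MI values.
apc_correct <- function(idx, mi, n_col) {
  scored <- !is.na(mi)
  if (!any(scored)) return(rep(NA_real_, length(mi)))
  col_sum <- numeric(n_col)
  col_n <- numeric(n_col)
  for (k in which(scored)) {
    for (c_ in idx[k, ]) {
      col_sum[c_] <- col_sum[c_] + mi[k]
      col_n[c_] <- col_n[c_] + 1
    }
  }
  col_mean <- ifelse(col_n > 0, col_sum / col_n, NA_real_)
  mean_all <- mean(mi[scored])
  apc <- rep(NA_real_, length(mi))
  if (mean_all != 0) {
    apc[scored] <- mi[scored] -
      col_mean[idx[scored, 1L]] * col_mean[idx[scored, 2L]] / mean_all
  } else {
    apc[scored] <- mi[scored]
  }
  apc
}

#' Covariation calling criteria
#'
#' The dual-threshold rule: a pair covaries if its MI exceeds `mi_lo` and
#' both members have conservation below `cons_lo`, or if MI exceeds `mi_hi`
#' and both members are below `cons_hi`. At most `select_fraction` of all
#' possible pairs are retained (top MI first).
#'
#' @param mi_lo,cons_lo Low-MI rule: MI > 4 with both conservations < -0.5.
#' @param mi_hi,cons_hi High-MI rule: MI > 8 with both conservations < -0.3.
#' @param select_fraction Cap on the called fraction of all pairs (0.005).
#' @return A list of class `covariation_criteria`.
#' @export
covariation_criteria <- function(mi_lo = 4, cons_lo = -0.5,
                                 mi_hi = 8, cons_hi = -0.3,
                                 select_fraction = 0.005) {
  stopifnot(mi_lo < mi_hi, cons_lo < cons_hi,
            select_fraction > 0, select_fraction <= 1)
  structure(list(mi_lo = mi_lo, cons_lo = cons_lo, mi_hi = mi_hi,
                 cons_hi = cons_hi, select_fraction = select_fraction),
            class = "covariation_criteria")
}

#' Call covarying residue pairs with the dual-threshold rule
#'
#' A pair is called when `MI > mi_lo` and both residues have conservation
#' `< cons_lo` (low-MI rule), or `MI > mi_hi` and both `< cons_hi` (high-MI
#' rule); inequalities are strict. If more than `select_fraction` of all
#' possible pairs pass, only the top `floor(select_fraction * n_pairs)` by MI
#' are kept (ties broken by lexicographic pair order). Pairs lacking an MI or
#' a member conservation score are left uncalled.
#'
#' @param pairs A `pair_table` from [mutual_information()] (columns `i`, `j`
#'   and an MI column).
#' @param sites A site table with `position` and `conservation` (e.g. from
#'   [conservation_scores()]).
#' @param criteria A [covariation_criteria()].
#' @param mi_column Which MI column drives the rule: `"mi_raw"` (default) or
#'   `"mi_apc"`.
#' @param cap Apply the `select_fraction` cap (default `TRUE`); with
#'   `cap = FALSE` the fraction is only reported.
#' @return The pair table with `covary_call` (logical) and `rule_fired`
#'   (`"low_MI_rule"`, `"high_MI_rule"`, `"none"`) columns; the called
#'   fraction is attached as attribute `called_fraction`.
#' @export
call_covariation <- function(pairs, sites, criteria = covariation_criteria(),
                             mi_column = c("mi_raw", "mi_apc"), cap = TRUE) {
  mi_column <- match.arg(mi_column)
  stopifnot(all(c("i", "j", mi_column) %in% names(pairs)),
            all(c("position", "conservation") %in% names(sites)))
  mi <- pairs[[mi_column]]
  cons <- sites$conservation[match(pairs$i, sites$position)]
  cons_j <- sites$conservation[match(pairs$j, sites$position)]
  scorable <- !is.na(mi) & !is.na(cons) & !is.na(cons_j)
  low <- scorable & mi > criteria$mi_lo &
    cons < criteria$cons_lo & cons_j < criteria$cons_lo
  high <- scorable & mi > criteria$mi_hi &
    cons < criteria$cons_hi & cons_j < criteria$cons_hi
  call <- low | high
  if (cap) {
    n_max <- floor(criteria$select_fraction * nrow(pairs))
    if (sum(call) > n_max) {
      cand <- which(call)
      ord <- cand[order(-mi[cand], pairs$i[cand], pairs$j[cand])]
      call[] <- FALSE
      call[ord[seq_len(n_max)]] <- TRUE
    }
  }
  pairs$covary_call <- call
  pairs$rule_fired <- ifelse(call & low, "low_MI_rule",
                             ifelse(call & high, "high_MI_rule", "none"))
  attr(pairs, "called_fraction") <- sum(call) / nrow(pairs)
  pairs
}
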