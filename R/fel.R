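# Per-site dN/dS analysis in the FEL (fixed effects likelihood) style:
# global nuisance parameters (kappa, tree scale, optionally a shared omega)
# are fitted once on the whole codon alignment, then each site gets its own
# synonymous rate alpha and nonsynonymous rate beta by maximum likelihood,
# with a chi-square(1) likelihood-ratio test of the neutral constraint
# beta = alpha. Sites with beta < alpha and p < 0.1 are flagged as evolving
# under purifying selection.

# Integer codon states (1..61, NA for gaps/ambiguity) for the bundle's codon
# layer, rows ordered to match the tree tips.
codon_tipstates <- function(bundle) {
  if (is.null(bundle$codon)) stop("bundle has no codon layer", call. = FALSE)
  if (is.null(bundle$tree)) stop("bundle has no tree", call. = FALSE)
  sc <- codon_cache()$sc
  m <- bundle$codon[bundle$tree$tip.label, , drop = FALSE]
  states <- matrix(sc$index[m], nrow(m), ncol(m))
  rownames(states) <- rownames(m)
  states
}

#' Fit global MG94 nuisance parameters on a codon alignment
#'
#' Maximizes the whole-alignment likelihood under the equal-frequency MG94
#' model with a single transition/transversion ratio `kappa`, a single
#' branch-length scale applied to the input tree, and either a fixed neutral
#' omega (`free_omega = FALSE`, the FEL nuisance fit) or one shared free
#' omega (`free_omega = TRUE`, a global dN/dS estimate). The optimizer start
#' is deterministic (`kappa = 2`, `scale = 1`, `omega = 1`).
#'
#' @param bundle An [msa_bundle()] with codon layer and tree.
#' @param free_omega Also estimate a single shared dN/dS ratio.
#' @return A list with `kappa`, `scale`, `omega`, `loglik`, `convergence`.
#' @export
fit_global_kappa_and_scale <- function(bundle, free_omega = FALSE) {
  states <- codon_tipstates(bundle)
  topo <- tree_topology(bundle$tree)
  if (sum(topo$tree$edge.length) <= 0) {
    stop("tree has zero total branch length; parameters unidentifiable",
         call. = FALSE)
  }
  freq <- rep(1 / 61, 61)
  negll <- function(par) {
    kappa <- exp(par[1L]); scale <- exp(par[2L])
    omega <- if (free_omega) exp(par[3L]) else 1
    eig <- mg94_eigen(alpha = 1, beta = omega, kappa = kappa)
    pm <- edge_pmats(topo, eig, scale = scale)
    ll <- sum(pruning_loglik(topo, states, pm, freq))
    if (!is.finite(ll)) {
      stop("non-finite codon likelihood (kappa=", signif(kappa, 4),
           ", scale=", signif(scale, 4), ")", call. = FALSE)
    }
    -ll
  }
  start <- if (free_omega) c(log(2), 0, 0) else c(log(2), 0)
  fit <- stats::optim(start, negll, method = "Nelder-Mead",
                      control = list(maxit = 1000, reltol = 1e-10))
  list(kappa = exp(fit$par[1L]), scale = exp(fit$par[2L]),
       omega = if (free_omega) exp(fit$par[3L]) else 1,
       loglik = -fit$value, convergence = fit$convergence)
}

# Log-likelihood of one site under site rates (alpha, beta).
fel_site_loglik <- function(topo, site_states, kappa, scale, alpha, beta) {
  eig <- mg94_eigen(alpha = alpha, beta = beta, kappa = kappa)
  pm <- edge_pmats(topo, eig, scale = scale)
  sum(pruning_loglik(topo, matrix(site_states, ncol = 1L), pm,
                     rep(1 / 61, 61)))
}

#' Per-site FEL likelihood-ratio test of selection
#'
#' The alternative model fits site-specific synonymous (`alpha`) and
#' nonsynonymous (`beta`) rates by ML; the null constrains `beta = alpha`.
#' `lrt_stat = 2 (lnL_alt - lnL_null)` is referred to the chi-square(1) upper
#' tail. A site is flagged as under purifying selection when `beta < alpha`
#' and `p < p_threshold` (default 0.1).
#'
#' @param bundle An [msa_bundle()] with codon layer and tree.
#' @param site Codon column index (1-based within the alignment).
#' @param kappa,scale Global nuisance parameters from
#'   [fit_global_kappa_and_scale()].
#' @param p_threshold Significance level for the purifying flag.
#' @return A one-row data.frame: `site`, `position`, `alpha`, `beta`,
#'   `omega`, `lrt_stat`, `p_value`, `purifying_flag`. Invariant sites return
#'   `NA` estimates with `p = 1` and no flag.
#' @export
fel_site_test <- function(bundle, site, kappa, scale, p_threshold = 0.1) {
  states <- codon_tipstates(bundle)[, site]
  pos <- if (!is.null(bundle$positions)) bundle$positions[site] else site
  row <- function(alpha, beta, lrt, p) {
    data.frame(site = site, position = pos, alpha = alpha, beta = beta,
               omega = ifelse(is.na(alpha) | alpha == 0, NA_real_,
                              beta / alpha),
               lrt_stat = lrt, p_value = p,
               purifying_flag = isTRUE(beta < alpha) && p < p_threshold)
  }
  obs <- unique(states[!is.na(states)])
  if (length(obs) <= 1L) {
    return(row(NA_real_, NA_real_, NA_real_, 1))
  }
  topo <- tree_topology(bundle$tree)
  lo <- -9; hi <- 4   # log-rate bounds
  alt <- stats::optim(c(0, 0), function(p) {
    -fel_site_loglik(topo, states, kappa, scale, exp(p[1L]), exp(p[2L]))
  }, method = "L-BFGS-B", lower = lo, upper = hi)
  null <- stats::optimize(function(p) {
    -fel_site_loglik(topo, states, kappa, scale, exp(p), exp(p))
  }, interval = c(lo, hi), tol = 1e-8)
  lrt <- max(0, 2 * (null$objective - alt$value))
  p <- stats::pchisq(lrt, df = 1, lower.tail = FALSE)
  row(exp(alt$par[1L]), exp(alt$par[2L]), lrt, p)
}

#' Run the FEL test over many sites
#'
#' Convenience wrapper: fits (or accepts) the global nuisance parameters and
#' applies [fel_site_test()] to each requested codon column.
#'
#' @param bundle An [msa_bundle()] with codon layer and tree.
#' @param sites Codon column indices (default: all).
#' @param global Optional result of [fit_global_kappa_and_scale()]; fitted
#'   when missing.
#' @param p_threshold Significance level for the purifying flag.
#' @return A data.frame with one [fel_site_test()] row per site.
#' @export
fel_scan <- function(bundle, sites = NULL, global = NULL, p_threshold = 0.1) {
  if (is.null(global)) global <- fit_global_kappa_and_scale(bundle)
  sites <- sites %||% seq_len(ncol(bundle$codon))
  do.call(rbind, lapply(sites, function(s) {
    fel_site_test(bundle, s, global$kappa, global$scale, p_threshold)
  }))
}

#' Deterministic covariation fixture with a known 0.5% called fraction
#'
#' Builds a 401-position site table and complete pair table in which exactly
#' 401 of the C(401,2) = 80,200 possible pairs satisfy the dual-threshold
#' covariation rule: positions 1-58 have conservation -1.0 (the rest 0.0),
#' and the first 401 lexicographic pairs among positions 1-58 carry MI 9.0
#' (all other pairs 0.1). There is no randomness; the fixture is identical
#' across runs.
#'
#' @return A list with `sites` (position, conservation) and `pairs`
#'   (`pair_table` with `i`, `j`, `mi_raw`, `mi_apc`).
#' @export
make_covariation_fixture <- function() {
  n_pos <- 401L
  n_cons <- 58L
  sites <- data.frame(position = seq_len(n_pos),
                      conservation = c(rep(-1.0, n_cons),
                                       rep(0.0, n_pos - n_cons)))
  idx <- t(utils::combn(n_pos, 2L))
  i <- idx[, 1L]; j <- idx[, 2L]
  # lexicographic rank of (i, j) among the C(58, 2) pairs within 1..58
  in_block <- j <= n_cons
  rank <- ifelse(in_block,
                 (i - 1L) * n_cons - (i * (i - 1L)) %/% 2L + (j - i),
                 NA_integer_)
  mi <- ifelse(in_block & rank <= 401L, 9.0, 0.1)
  pairs <- data.frame(i = i, j = j, mi_raw = mi, mi_apc = mi)
  class(pairs) <- c("pair_table", "data.frame")
  list(sites = sites, pairs = pairs)
}
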