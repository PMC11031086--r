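# Amino-acid substitution models and marginal ancestral sequence
# reconstruction. The JTT empirical model (exchangeabilities and equilibrium
# frequencies taken from phangorn) is the default for real alignments; the
# symmetric Poisson model (equal rates, equal frequencies) serves toy
# examples and hand-checkable tests.

#' Amino-acid substitution model
#'
#' Builds a reversible 20-state rate matrix normalized to one expected
#' substitution per unit branch length, together with the similarity-
#' transformed symmetric eigendecomposition used for transition
#' probabilities.
#'
#' @param kind `"poisson"` (equal exchangeabilities and frequencies) or
#'   `"jtt"` (Jones-Taylor-Thornton empirical model).
#' @return A list of class `aa_model` with `states`, `Q`, `freq`, and the
#'   decomposition pieces.
#' @export
aa_model <- function(kind = c("jtt", "poisson")) {
  kind <- match.arg(kind)
  if (kind == "poisson") {
    s <- matrix(1, 20L, 20L)
    freq <- rep(1 / 20, 20L)
  } else {
    jtt <- utils::getFromNamespace(".JTT", "phangorn")
    s <- matrix(0, 20L, 20L)
    s[lower.tri(s)] <- jtt$Q
    s <- s + t(s)
    # phangorn orders states by its amino-acid alphabet; remap to AA20
    phang_order <- toupper(names(jtt$bf))
    perm <- match(AA20, phang_order)
    stopifnot(!anyNA(perm))
    s <- s[perm, perm]
    freq <- as.numeric(jtt$bf)[perm]
    freq <- freq / sum(freq)
  }
  q <- s * rep(freq, each = 20L)   # Q_ij = s_ij * pi_j
  diag(q) <- 0
  q <- q / sum(freq * rowSums(q))  # mean rate 1
  diag(q) <- -rowSums(q)
  # reversible Q diagonalized via B = D^{1/2} Q D^{-1/2} (symmetric)
  d <- sqrt(freq)
  b <- q * (d %o% (1 / d))
  e <- eigen((b + t(b)) / 2, symmetric = TRUE)
  structure(list(kind = kind, states = AA20, Q = q, freq = freq,
                 vectors = e$vectors, values = e$values, d = d),
            class = "aa_model")
}

# P(t) for an aa_model (rows: from-state).
aa_prob_matrix <- function(model, t) {
  inner <- model$vectors %*% (exp(model$values * t) * t(model$vectors))
  p <- (1 / model$d) * inner * rep(model$d, each = 20L)
  p[p < 0] <- 0
  p
}

aa_tipstates <- function(bundle) {
  if (is.null(bundle$tree)) stop("bundle has no tree", call. = FALSE)
  m <- bundle$protein[bundle$tree$tip.label, , drop = FALSE]
  states <- matrix(match(m, AA20), nrow(m), ncol(m))
  rownames(states) <- rownames(m)
  states
}

# Resolve a node reference: ape node number, internal node label, or "root".
resolve_node <- function(tree, node_id) {
  n_tip <- length(tree$tip.label)
  if (identical(node_id, "root")) return(n_tip + 1L)
  if (is.numeric(node_id)) {
    node <- as.integer(node_id)
    if (node < 1L || node > n_tip + tree$Nnode) {
      stop(sprintf("node %d not in tree (1..%d)", node, n_tip + tree$Nnode),
           call. = FALSE)
    }
    return(node)
  }
  if (!is.null(tree$node.label)) {
    hit <- match(node_id, tree$node.label)
    if (!is.na(hit)) return(n_tip + hit)
  }
  hit <- match(node_id, tree$tip.label)
  if (!is.na(hit)) return(hit)
  stop(sprintf("node '%s' not found in tree", node_id), call. = FALSE)
}

#' Most recent common ancestor node of a set of tips
#'
#' @param bundle An [msa_bundle()] with a tree.
#' @param tips Character vector of two or more tip labels.
#' @return The ape node number of the MRCA.
#' @export
mrca_node <- function(bundle, tips) {
  stopifnot(inherits(bundle, "msa_bundle"), !is.null(bundle$tree))
  ape::getMRCA(bundle$tree, tips)
}

#' Marginal ancestral sequence reconstruction at a tree node
#'
#' Computes, per alignment column, the marginal posterior distribution over
#' amino acids at the requested node via two-pass pruning: conditional
#' likelihoods are propagated from the tips, combined with the complementary
#' (rest-of-tree) message, and normalized. Gaps are treated as missing data
#' (uniform tip message). The MAP state per site is reported with its
#' posterior; exact ties are broken alphabetically and flagged.
#'
#' @param bundle An [msa_bundle()] with protein layer and tree.
#' @param node_id Node: ape node number, internal node label, or `"root"`.
#' @param model An [aa_model()] (default JTT, the standard choice for
#'   ortholog alignments).
#' @return A list of class `ancestral_reconstruction` with `node` (ape
#'   number), `posterior` (20 x n_sites matrix, columns sum to 1),
#'   `map_sequence` (character vector), `map_posterior`, `tie_flag`.
#' @export
marginal_ancestral_reconstruction <- function(bundle, node_id = "root",
                                              model = aa_model("jtt")) {
  stopifnot(inherits(bundle, "msa_bundle"), inherits(model, "aa_model"))
  node <- resolve_node(bundle$tree, node_id)
  topo <- tree_topology(bundle$tree)
  states <- aa_tipstates(bundle)
  pm <- lapply(topo$tree$edge.length, function(t) aa_prob_matrix(model, t))
  up_res <- pruning_up(topo, states, pm)
  down <- pruning_down(topo, up_res, pm, model$freq)
  post <- up_res$up[[node]] * down[[node]]
  post <- sweep(post, 2L, colSums(post), "/")
  rownames(post) <- AA20
  map_idx <- integer(ncol(post))
  tie <- logical(ncol(post))
  for (s in seq_len(ncol(post))) {
    best <- which(post[, s] >= max(post[, s]) - 1e-12)
    map_idx[s] <- best[1L]            # AA20 is alphabetical
    tie[s] <- length(best) > 1L
  }
  structure(
    list(node = node,
         posterior = post,
         map_sequence = AA20[map_idx],
         map_posterior = post[cbind(map_idx, seq_len(ncol(post)))],
         tie_flag = tie,
         positions = bundle$positions),
    class = "ancestral_reconstruction"
  )
}

#' @export
print.ancestral_reconstruction <- function(x, ...) {
  cat(sprintf("<ancestral_reconstruction> node %d, %d sites\nMAP: %s\n",
              x$node, length(x$map_sequence),
              paste(x$map_sequence, collapse = "")))
  invisible(x)
}

#' Write an ancestral reconstruction (FASTA + per-site posterior TSV)
#'
#' @param asr An `ancestral_reconstruction`.
#' @param fasta_file,posterior_file Output paths (`NULL` skips).
#' @param name Sequence name used in the FASTA record.
#' @export
write_reconstruction <- function(asr, fasta_file = NULL,
                                 posterior_file = NULL,
                                 name = paste0("node", asr$node)) {
  if (!is.null(fasta_file)) {
    con <- file(fasta_file, "wb")
    writeLines(c(paste0(">", name), paste(asr$map_sequence, collapse = "")),
               con)
    close(con)
  }
  if (!is.null(posterior_file)) {
    df <- data.frame(position = asr$positions %||%
                       seq_along(asr$map_sequence),
                     map_state = asr$map_sequence,
                     map_posterior = asr$map_posterior,
                     tie = asr$tie_flag,
                     t(asr$posterior), check.names = FALSE)
    utils::write.table(df, posterior_file, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(asr)
}
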