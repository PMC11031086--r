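# Felsenstein pruning over an arbitrary state space, shared by the codon
# likelihood machinery (global MG94 fit, per-site FEL) and the amino-acid
# ancestral reconstruction. Conditional likelihoods are carried as
# (n_states x n_sites) matrices with per-node rescaling to avoid underflow.

# Children-of lists and a postorder node sequence for an ape phylo tree.
tree_topology <- function(tree) {
  if (is.null(tree$edge.length)) {
    stop("tree has no branch lengths", call. = FALSE)
  }
  tr <- stats::reorder(tree, "postorder")
  n_tip <- length(tr$tip.label)
  n_node <- tr$Nnode
  kids <- vector("list", n_tip + n_node)
  for (k in seq_len(nrow(tr$edge))) {
    p <- tr$edge[k, 1L]
    kids[[p]] <- c(kids[[p]], k)     # edge indices, postorder-sorted
  }
  list(tree = tr, n_tip = n_tip, n_node = n_node,
       root = n_tip + 1L, kids = kids,
       node_order = unique(tr$edge[, 1L]))  # internal nodes, postorder
}

# One-hot (or all-ones for NA) tip conditional likelihoods.
tip_likelihood <- function(states, n_states) {
  n_sites <- length(states)
  m <- matrix(0, n_states, n_sites)
  miss <- is.na(states)
  if (any(!miss)) {
    m[cbind(states[!miss], which(!miss))] <- 1
  }
  m[, miss] <- 1
  m
}

# Upward pass. `tipstates`: integer matrix (n_tip x n_sites), rows in
# tree$tip.label order, NA = missing. `pmats`: list of transition matrices,
# one per edge of the postorder tree. Returns per-node conditional
# likelihoods, per-edge messages, and the per-site log scaling total.
pruning_up <- function(topo, tipstates, pmats) {
  n_states <- nrow(pmats[[1L]])
  n_sites <- ncol(tipstates)
  up <- vector("list", topo$n_tip + topo$n_node)
  msg <- vector("list", nrow(topo$tree$edge))
  logscale <- numeric(n_sites)
  for (i in seq_len(topo$n_tip)) {
    up[[i]] <- tip_likelihood(tipstates[i, ], n_states)
  }
  for (node in topo$node_order) {
    acc <- 1
    for (k in topo$kids[[node]]) {
      child <- topo$tree$edge[k, 2L]
      msg[[k]] <- pmats[[k]] %*% up[[child]]
      acc <- acc * msg[[k]]
    }
    sc <- apply(acc, 2L, max)
    sc[sc <= 0] <- 1
    up[[node]] <- sweep(acc, 2L, sc, "/")
    logscale <- logscale + log(sc)
  }
  list(up = up, msg = msg, logscale = logscale)
}

# Per-site log-likelihoods at the root under equilibrium frequencies `freq`.
pruning_loglik <- function(topo, tipstates, pmats, freq) {
  res <- pruning_up(topo, tipstates, pmats)
  site_l <- colSums(res$up[[topo$root]] * freq)
  log(site_l) + res$logscale
}

# Transition matrices for every edge, caching by branch length (edge lengths
# are often shared, e.g. ultrametric or simulated trees).
edge_pmats <- function(topo, eig, scale = 1) {
  lens <- topo$tree$edge.length * scale
  key <- as.character(signif(lens, 12))
  cache <- new.env(parent = emptyenv())
  lapply(seq_along(lens), function(k) {
    if (is.null(cache[[key[k]]])) {
      cache[[key[k]]] <- prob_matrix(eig, lens[k])
    }
    cache[[key[k]]]
  })
}

# Downward (outside) messages for every node: the likelihood contribution of
# everything outside the subtree below each node, with the root holding the
# equilibrium frequencies. Used for marginal ancestral posteriors:
# posterior(node) = normalize(up[node] * down[node]).
pruning_down <- function(topo, up_res, pmats, freq) {
  n_states <- length(freq)
  n_nodes <- topo$n_tip + topo$n_node
  n_sites <- ncol(up_res$up[[1L]])
  down <- vector("list", n_nodes)
  down[[topo$root]] <- matrix(freq, n_states, n_sites)
  # visit internal nodes root-first (reverse postorder)
  for (node in rev(topo$node_order)) {
    ks <- topo$kids[[node]]
    for (k in ks) {
      child <- topo$tree$edge[k, 2L]
      g <- down[[node]]
      for (s in ks) {
        if (s != k) g <- g * up_res$msg[[s]]
      }
      d <- crossprod(pmats[[k]], g)     # t(P) %*% g
      sc <- apply(d, 2L, max)
      sc[sc <= 0] <- 1
      down[[child]] <- sweep(d, 2L, sc, "/")
    }
  }
  down
}
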