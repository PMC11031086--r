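# Seeded sequence-evolution simulators: protein alignments with planted
# conserved columns and perfectly covarying column pairs (a shared latent
# character relabelled between the two columns), and codon alignments under
# the MG94 model with site-specific omega — the ground truth for the
# conservation, covariation and FEL machinery.

# Edges of `tree` ordered root-first (parents before children).
preorder_edges <- function(tree) {
  if (is.null(tree$edge.length)) {
    stop("tree has no branch lengths", call. = FALSE)
  }
  tr <- stats::reorder(tree, "cladewise")
  tr
}

#' Simulate a protein alignment with planted site classes
#'
#' Sites evolve independently along the tree according to their class:
#' `conserved` sites have rate ~0 (invariant), `neutral` sites evolve under
#' the symmetric 20-state Poisson model at rate 1, and each `covary:<k>`
#' label (which must appear at exactly two sites) evolves as one joint
#' neutral character whose states are copied to both columns through a
#' random state relabelling — perfect covariation with high mutual
#' information.
#'
#' @param tree An `ape::phylo` tree (or Newick string) with branch lengths;
#'   >= 3 tips.
#' @param site_classes Character vector: `"conserved"`, `"neutral"`, or
#'   `"covary:<k>"`.
#' @param seed Integer seed.
#' @param ref_id,ref_offset Reference settings for the returned bundle.
#' @return An [msa_bundle()] (protein layer + tree) with attribute
#'   `site_classes`.
#' @export
gen_protein_msa <- function(tree, site_classes, seed = 1L,
                            ref_id = NULL, ref_offset = 48L) {
  if (is.character(tree)) tree <- parse_newick(tree)
  if (length(tree$tip.label) < 3L) stop("need >= 3 tree tips", call. = FALSE)
  cls <- as.character(site_classes)
  pair_ids <- sub("^covary:", "", cls[startsWith(cls, "covary:")])
  if (length(pair_ids) > 0L && any(table(pair_ids) != 2L)) {
    stop("every covary:<k> label must appear at exactly two sites",
         call. = FALSE)
  }
  ok <- cls %in% c("conserved", "neutral") | startsWith(cls, "covary:")
  if (!all(ok)) {
    stop("site classes must be conserved, neutral or covary:<k>",
         call. = FALSE)
  }
  # primary sites: everything except the second member of each covary pair
  second <- logical(length(cls))
  for (k in unique(pair_ids)) {
    second[which(cls == paste0("covary:", k))[2L]] <- TRUE
  }
  primary <- which(!second)
  rate <- ifelse(cls[primary] == "conserved", 0, 1)

  tr <- preorder_edges(tree)
  n_tip <- length(tr$tip.label)
  n_nodes <- n_tip + tr$Nnode
  states <- matrix(NA_integer_, n_nodes, length(primary))
  states[n_tip + 1L, ] <- with_stream(
    seed, "msa_root", sample.int(20L, length(primary), replace = TRUE))
  with_stream(seed, "msa_paths", {
    for (e in seq_len(nrow(tr$edge))) {
      par <- tr$edge[e, 1L]; child <- tr$edge[e, 2L]
      t_e <- tr$edge.length[e]
      p_same <- 1 / 20 + (19 / 20) * exp(-20 / 19 * t_e * rate)
      cur <- states[par, ]
      change <- stats::runif(length(primary)) > p_same
      nxt <- cur
      if (any(change)) {
        # resample uniformly among the 19 other states
        u <- sample.int(19L, sum(change), replace = TRUE)
        nxt[change] <- ifelse(u < cur[change], u, u + 1L)
      }
      states[child, ] <- nxt
    }
  })
  aln <- matrix("-", n_tip, length(cls),
                dimnames = list(tr$tip.label, NULL))
  aln[, primary] <- AA20[states[seq_len(n_tip), , drop = FALSE]]
  for (k in unique(pair_ids)) {
    cols <- which(cls == paste0("covary:", k))
    perm <- with_stream(seed, paste0("msa_pair_", k), sample.int(20L))
    first_col <- match(cols[1L], primary)
    aln[, cols[2L]] <- AA20[perm[states[seq_len(n_tip), first_col]]]
  }
  b <- msa_bundle(aln, tree = tree, ref_id = ref_id %||% tr$tip.label[1L],
                  ref_offset = ref_offset)
  attr(b, "site_classes") <- cls
  b
}

#' Simulate a codon alignment under MG94 with site-specific omega
#'
#' Sites evolve independently on the given tree under the equal-frequency
#' MG94 model ([mg94_q()]) with a global `kappa` and per-site `omega`
#' (`alpha = 1`, `beta = omega`). Branch lengths are in expected neutral
#' substitutions per codon. Emits both the codon layer and its protein
#' translation.
#'
#' @param tree An `ape::phylo` tree (or Newick string) with branch lengths.
#' @param omegas Numeric vector of per-site dN/dS values (>= 0), one per
#'   codon site.
#' @param kappa Transition/transversion ratio (>= 0).
#' @param seed Integer seed.
#' @param ref_id,ref_offset Reference settings for the returned bundle.
#' @return An [msa_bundle()] (protein + codon layers + tree) with attribute
#'   `omegas`.
#' @export
gen_codon_alignment <- function(tree, omegas, kappa = 2, seed = 1L,
                                ref_id = NULL, ref_offset = 48L) {
  if (is.character(tree)) tree <- parse_newick(tree)
  omegas <- as.numeric(omegas)
  if (any(omegas < 0) || any(!is.finite(omegas))) {
    stop("omegas must be finite and >= 0", call. = FALSE)
  }
  if (kappa < 0) stop("kappa must be >= 0", call. = FALSE)
  tr <- preorder_edges(tree)
  n_tip <- length(tr$tip.label)
  n_sites <- length(omegas)
  n_nodes <- n_tip + tr$Nnode
  sc <- codon_cache()$sc

  eigs <- lapply(unique(omegas), function(w) {
    mg94_eigen(alpha = 1, beta = w, kappa = kappa)
  })
  names(eigs) <- as.character(unique(omegas))
  states <- matrix(NA_integer_, n_nodes, n_sites)
  states[n_tip + 1L, ] <- with_stream(
    seed, "codon_root", sample.int(61L, n_sites, replace = TRUE))
  with_stream(seed, "codon_paths", {
    for (e in seq_len(nrow(tr$edge))) {
      par <- tr$edge[e, 1L]; child <- tr$edge[e, 2L]
      t_e <- tr$edge.length[e]
      nxt <- integer(n_sites)
      for (w in unique(omegas)) {
        cols <- which(omegas == w)
        p <- prob_matrix(eigs[[as.character(w)]], t_e)
        cur <- states[par, cols]
        for (s in unique(cur)) {
          here <- cols[cur == s]
          nxt[here] <- sample.int(61L, length(here), replace = TRUE,
                                  prob = p[s, ])
        }
      }
      states[child, ] <- nxt
    }
  })
  tip_states <- states[seq_len(n_tip), , drop = FALSE]
  codon <- matrix(sc$codons[tip_states], n_tip, n_sites,
                  dimnames = list(tr$tip.label, NULL))
  protein <- matrix(sc$aa[tip_states], n_tip, n_sites,
                    dimnames = list(tr$tip.label, NULL))
  b <- msa_bundle(protein, codon = codon, tree = tree,
                  ref_id = ref_id %||% tr$tip.label[1L],
                  ref_offset = ref_offset)
  attr(b, "omegas") <- omegas
  b
}

#' Symmetric bifurcating test tree
#'
#' A balanced tree over `2^k` tips with every branch the given length —
#' the standard shape for simulation-recovery tests.
#'
#' @param n_tips Number of tips (a power of two).
#' @param branch_length Length of every branch.
#' @return An `ape::phylo` tree with tips `t1..tn`.
#' @export
symmetric_tree <- function(n_tips = 16L, branch_length = 0.1) {
  k <- log2(n_tips)
  if (k != round(k)) stop("n_tips must be a power of two", call. = FALSE)
  newick <- "t"
  for (d in seq_len(k)) {
    newick <- sprintf("(%s,%s)", newick, newick)
  }
  tree <- ape::read.tree(text = paste0(newick, ";"))
  tree$tip.label <- paste0("t", seq_len(n_tips))
  tree$edge.length <- rep(branch_length, nrow(tree$edge))
  tree
}
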