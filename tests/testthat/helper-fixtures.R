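# Shared fixtures built in code: tiny trees and alignments used across tests.

tree3 <- function(bl = c(0.2, 0.3, 0.1)) {
  tr <- ape::read.tree(text = "(a:0.2,b:0.3,c:0.1);")
  tr$edge.length <- bl
  tr
}

# A small hand-written protein alignment (5 sequences, 6 columns) with a
# reference insertion at column 3.
toy_protein_msa <- function() {
  m <- rbind(
    mouse = c("K", "A", "-", "L", "V", "D"),
    rat   = c("K", "A", "P", "L", "V", "D"),
    human = c("K", "S", "P", "I", "V", "E"),
    cow   = c("K", "S", "-", "I", "A", "E"),
    frog  = c("K", "T", "-", "L", "A", "-")
  )
  msa_bundle(m, ref_id = "mouse", ref_offset = 48L)
}

# Brute-force mutual information from joint counts (independent oracle).
mi_oracle <- function(x, y) {
  keep <- x %in% coreceptR:::AA20 & y %in% coreceptR:::AA20
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  mi <- 0
  for (a in unique(x)) for (b in unique(y)) {
    pab <- sum(x == a & y == b) / n
    if (pab > 0) {
      mi <- mi + pab * log2(pab / (sum(x == a) / n * sum(y == b) / n))
    }
  }
  mi
}

# Brute-force codon site likelihood on a 3-taxon star: exhaustive sum over
# the single internal node's 61 states (independent oracle for pruning).
codon_lik_oracle_3taxon <- function(tree, tip_states, alpha, beta, kappa,
                                    scale = 1) {
  P <- lapply(tree$edge.length * scale, function(t) {
    coreceptR:::prob_matrix(coreceptR:::mg94_eigen(alpha, beta, kappa), t)
  })
  tot <- 0
  for (r in 1:61) {
    p <- 1 / 61
    for (k in seq_len(nrow(tree$edge))) {
      tip <- tree$edge[k, 2L]
      s <- tip_states[tip]
      p <- p * if (is.na(s)) 1 else P[[k]][r, s]
    }
    tot <- tot + p
  }
  log(tot)
}
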