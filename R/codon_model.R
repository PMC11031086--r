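# MG94-style codon model over the 61 sense codons of the standard genetic
# code, with equal codon frequencies (1/61). Single-nucleotide changes occur
# at rate alpha (synonymous) or beta (nonsynonymous), times kappa for
# transitions; multi-nucleotide changes have rate 0. With equal frequencies
# the rate matrix is symmetric, so transition probabilities come from a real
# symmetric eigendecomposition.

NUC <- c("T", "C", "A", "G")

# Standard genetic code in TCAG order (NCBI translation table 1).
GENETIC_CODE_STR <- "FFLLSSSSYY**CC*WLLLLPPPPHHQQRRRRIIIMTTTTNNKKSSRRVVVVAAAADDEEGGGG"

#' The 61 sense codons and their amino-acid translations
#'
#' @return A list with `codons` (character 61), `aa` (character 61, one-letter
#'   amino acids), and `index` (named lookup codon -> 1..61).
#' @export
sense_codons <- function() {
  b1 <- rep(NUC, each = 16L)
  b2 <- rep(rep(NUC, each = 4L), 4L)
  b3 <- rep(NUC, 16L)
  codons <- paste0(b1, b2, b3)
  aa <- strsplit(GENETIC_CODE_STR, "")[[1]]
  keep <- aa != "*"
  codons <- codons[keep]
  aa <- aa[keep]
  idx <- seq_along(codons)
  names(idx) <- codons
  list(codons = codons, aa = aa, index = idx)
}

#' Translate codons to one-letter amino acids
#'
#' @param codons Character vector of 3-letter codons (`---` and codons with
#'   ambiguity characters translate to `-`).
#' @return Character vector of amino acids.
#' @export
translate_codons <- function(codons) {
  sc <- codon_cache()$sc
  out <- rep("-", length(codons))
  hit <- match(toupper(codons), sc$codons)
  out[!is.na(hit)] <- sc$aa[hit[!is.na(hit)]]
  out
}

# Lazily built masks shared by simulator and estimator.
.codon_env <- new.env(parent = emptyenv())

codon_cache <- function() {
  if (is.null(.codon_env$sc)) {
    sc <- sense_codons()
    n <- length(sc$codons)
    splits <- strsplit(sc$codons, "")
    bmat <- do.call(rbind, splits)           # 61 x 3 nucleotides
    one_nt <- matrix(FALSE, n, n)
    is_ts <- matrix(FALSE, n, n)             # transition at the differing site
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        d <- which(bmat[i, ] != bmat[j, ])
        if (length(d) == 1L) {
          one_nt[i, j] <- one_nt[j, i] <- TRUE
          pair <- sort(c(bmat[i, d], bmat[j, d]))
          ts <- identical(pair, c("A", "G")) || identical(pair, c("C", "T"))
          is_ts[i, j] <- is_ts[j, i] <- ts
        }
      }
    }
    syn <- outer(sc$aa, sc$aa, "==") & one_nt
    .codon_env$sc <- sc
    .codon_env$one_nt <- one_nt
    .codon_env$is_ts <- is_ts
    .codon_env$syn <- syn
    .codon_env$nonsyn <- one_nt & !syn
  }
  as.list(.codon_env)
}

#' MG94 rate matrix with site rates alpha (dS) and beta (dN)
#'
#' Builds the 61 x 61 generator with equal codon frequencies. The matrix is
#' normalized so that the expected substitution rate equals 1 when
#' `alpha = beta = 1` at the given `kappa`; branch lengths are therefore in
#' units of expected neutral substitutions per codon, and `alpha`/`beta`
#' multiply the synonymous/nonsynonymous parts.
#'
#' @param alpha Synonymous rate multiplier (>= 0).
#' @param beta Nonsynonymous rate multiplier (>= 0).
#' @param kappa Transition/transversion rate ratio (>= 0).
#' @return A 61 x 61 rate matrix (rows sum to 0).
#' @export
mg94_q <- function(alpha = 1, beta = 1, kappa = 2) {
  if (alpha < 0 || beta < 0 || kappa < 0) {
    stop("alpha, beta and kappa must be >= 0", call. = FALSE)
  }
  cc <- codon_cache()
  w <- ifelse(cc$is_ts, kappa, 1)
  qs <- cc$syn * w
  qn <- cc$nonsyn * w
  norm <- sum(qs + qn) / 61            # mean rate at alpha = beta = 1
  q <- (alpha * qs + beta * qn) / norm
  diag(q) <- -rowSums(q)
  q
}

# Symmetric eigendecomposition of an MG94 generator; P(t) = E exp(L t) E'.
mg94_eigen <- function(alpha = 1, beta = 1, kappa = 2) {
  e <- eigen(mg94_q(alpha, beta, kappa), symmetric = TRUE)
  list(vectors = e$vectors, values = e$values)
}

# Transition probability matrix from a symmetric eigendecomposition.
# Tiny negative entries from roundoff are clamped to 0.
prob_matrix <- function(eig, t) {
  p <- eig$vectors %*% (exp(eig$values * t) * t(eig$vectors))
  p[p < 0] <- 0
  p
}
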