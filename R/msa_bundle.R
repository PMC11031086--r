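# The MsaBundle container: a protein alignment, an optional codon alignment
# consistent with it by translation, a phylogenetic tree with branch lengths,
# and a reference-sequence numbering map (by convention the mouse reference,
# with the alignment edited to start at residue 48).

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Construct an alignment bundle
#'
#' @param protein Character matrix of aligned one-letter amino acids
#'   (rows = sequences, named; `-` = gap).
#' @param codon Optional character matrix of aligned 3-letter codons with the
#'   same dimensions as `protein` (`---` = gap); must translate to `protein`.
#' @param tree An `ape::phylo` tree (or Newick string) whose tip labels match
#'   the alignment row names.
#' @param ref_id Reference sequence name for column numbering (default: first
#'   row).
#' @param ref_offset Residue number of the first alignment column in
#'   reference coordinates (default 48, the first consistently aligned
#'   residue of the mouse reference).
#' @return An object of class `msa_bundle` with a `positions` vector
#'   (reference numbering per column; `NA` until
#'   [strip_nonreference_columns()] establishes the map when the reference
#'   contains gaps).
#' @export
msa_bundle <- function(protein, codon = NULL, tree = NULL,
                       ref_id = rownames(protein)[1L], ref_offset = 48L) {
  protein <- as.matrix(protein)
  if (is.null(rownames(protein))) {
    stop("protein alignment rows must be named", call. = FALSE)
  }
  protein[] <- toupper(protein)
  if (!is.null(codon)) {
    codon <- as.matrix(codon)
    codon[] <- toupper(codon)
    if (!all(dim(codon) == dim(protein))) {
      stop("codon alignment must have one codon column per protein column",
           call. = FALSE)
    }
    tr <- apply(codon, 2L, translate_codons)
    mismatch <- tr != protein & protein != "-" & tr != "-"
    if (any(mismatch)) {
      stop("codon alignment does not translate to the protein alignment",
           call. = FALSE)
    }
  }
  if (is.character(tree)) tree <- parse_newick(tree)
  if (!is.null(tree)) {
    if (!inherits(tree, "phylo")) stop("tree must be a phylo object",
                                       call. = FALSE)
    if (!all(rownames(protein) %in% tree$tip.label) ||
        !all(tree$tip.label %in% rownames(protein))) {
      stop("tree tip labels and alignment row names must match",
           call. = FALSE)
    }
  }
  if (!ref_id %in% rownames(protein)) {
    stop(sprintf("reference sequence '%s' not found in alignment", ref_id),
         call. = FALSE)
  }
  ref_has_gaps <- any(protein[ref_id, ] == "-")
  positions <- if (ref_has_gaps) {
    rep(NA_integer_, ncol(protein))
  } else {
    ref_offset + seq_len(ncol(protein)) - 1L
  }
  structure(
    list(protein = protein, codon = codon, tree = tree, ref_id = ref_id,
         ref_offset = as.integer(ref_offset), positions = positions),
    class = "msa_bundle"
  )
}

#' @export
print.msa_bundle <- function(x, ...) {
  cat(sprintf(
    "<msa_bundle> %d sequences x %d columns%s%s; ref %s (offset %d)\n",
    nrow(x$protein), ncol(x$protein),
    if (!is.null(x$codon)) " (+codon layer)" else "",
    if (!is.null(x$tree)) " (+tree)" else "",
    x$ref_id, x$ref_offset))
  invisible(x)
}

#' Remove alignment columns that are insertions relative to the reference
#'
#' Columns where the reference sequence has a gap are dropped so that the
#' remaining columns carry consecutive reference residue numbers starting at
#' `ref_offset`. The codon layer, if present, is trimmed in register.
#'
#' @param bundle An [msa_bundle()].
#' @return The bundle with reference-gap columns removed and `positions` set.
#' @export
strip_nonreference_columns <- function(bundle) {
  stopifnot(inherits(bundle, "msa_bundle"))
  keep <- bundle$protein[bundle$ref_id, ] != "-"
  if (!any(keep)) stop("reference sequence is all gaps", call. = FALSE)
  bundle$protein <- bundle$protein[, keep, drop = FALSE]
  if (!is.null(bundle$codon)) {
    bundle$codon <- bundle$codon[, keep, drop = FALSE]
  }
  bundle$positions <- bundle$ref_offset + seq_len(sum(keep)) - 1L
  bundle
}

# FASTA I/O (via ape) -------------------------------------------------------

read_fasta_matrix <- function(path, type = c("AA", "DNA")) {
  type <- match.arg(type)
  x <- ape::read.FASTA(path, type = type)
  m <- toupper(do.call(rbind, as.character(x)))
  rownames(m) <- names(x)
  m
}

#' Read an alignment bundle from FASTA / Newick files
#'
#' @param protein_fasta Path to the aligned protein FASTA.
#' @param codon_fasta Optional path to the aligned nucleotide (codon) FASTA;
#'   sequence lengths must be 3x the protein alignment length.
#' @param tree_file Optional path to a Newick tree.
#' @inheritParams msa_bundle
#' @return An [msa_bundle()].
#' @export
read_msa_bundle <- function(protein_fasta, codon_fasta = NULL,
                            tree_file = NULL, ref_id = NULL,
                            ref_offset = 48L) {
  prot <- read_fasta_matrix(protein_fasta, "AA")
  codon <- NULL
  if (!is.null(codon_fasta)) {
    nt <- read_fasta_matrix(codon_fasta, "DNA")
    if (ncol(nt) != 3L * ncol(prot)) {
      stop("codon FASTA length must be 3x the protein alignment length",
           call. = FALSE)
    }
    nt <- nt[rownames(prot), , drop = FALSE]
    codon <- vapply(seq_len(ncol(prot)), function(j) {
      apply(nt[, (3L * j - 2L):(3L * j), drop = FALSE], 1L, paste0,
            collapse = "")
    }, character(nrow(prot)))
    if (!is.matrix(codon)) codon <- matrix(codon, nrow = nrow(prot))
    rownames(codon) <- rownames(prot)
  }
  tree <- if (!is.null(tree_file)) ape::read.tree(tree_file) else NULL
  msa_bundle(prot, codon = codon, tree = tree,
             ref_id = ref_id %||% rownames(prot)[1L],
             ref_offset = ref_offset)
}

#' Write an alignment bundle to FASTA / Newick files
#'
#' @param bundle An [msa_bundle()].
#' @param protein_fasta,codon_fasta,tree_file Output paths (`NULL` skips a
#'   layer).
#' @return The bundle, invisibly.
#' @export
write_msa_bundle <- function(bundle, protein_fasta = NULL, codon_fasta = NULL,
                             tree_file = NULL) {
  stopifnot(inherits(bundle, "msa_bundle"))
  write_seq <- function(m, path) {
    seqs <- apply(m, 1L, paste0, collapse = "")
    con <- file(path, "wb")  # binary mode: byte-identical across platforms
    on.exit(close(con))
    writeLines(paste0(">", names(seqs), "\n", seqs), con, sep = "\n")
  }
  if (!is.null(protein_fasta)) write_seq(bundle$protein, protein_fasta)
  if (!is.null(codon_fasta)) {
    if (is.null(bundle$codon)) stop("bundle has no codon layer", call. = FALSE)
    write_seq(bundle$codon, codon_fasta)
  }
  if (!is.null(tree_file)) {
    if (is.null(bundle$tree)) stop("bundle has no tree", call. = FALSE)
    ape::write.tree(bundle$tree, file = tree_file)
  }
  invisible(bundle)
}
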