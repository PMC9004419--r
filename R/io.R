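# Alignment and tree input.

#' Construct an amino-acid alignment object
#'
#' @param x Character matrix (rows = taxa, columns = sites) of one-letter
#'   codes, or a named character vector of sequences.
#' @return An object of class `aa_alignment`: list with `matrix` (uppercase
#'   character matrix), `taxa`, `n_sites`, and `analyzable`, a logical mask of
#'   sites containing only the 20 standard residues (no gaps, no ambiguity
#'   codes).
#' @export
aa_alignment <- function(x) {
  if (is.character(x) && !is.matrix(x)) {
    if (is.null(names(x))) stop("sequences must be named")
    lens <- nchar(x)
    if (length(unique(lens)) != 1L) stop("sequences have unequal lengths")
    x <- do.call(rbind, strsplit(x, ""))
    rownames(x) <- names(lens)
  }
  stopifnot(is.matrix(x), is.character(x))
  if (nrow(x) < 1L || ncol(x) < 1L) stop("empty alignment")
  x <- toupper(x)
  taxa <- rownames(x)
  if (is.null(taxa)) stop("alignment rows must be named by taxon")
  if (anyDuplicated(taxa)) stop("duplicate taxon labels in alignment")
  ok <- matrix(x %in% aa_alphabet(), nrow(x), ncol(x))
  structure(list(matrix = x, taxa = taxa, n_sites = ncol(x),
                 analyzable = apply(ok, 2L, all)),
            class = "aa_alignment")
}

#' Read an amino-acid alignment from a FASTA file
#'
#' Sites containing a gap (`-`, `.`) or any non-standard character (`X`, `B`,
#' `Z`, `U`, `O`, `?`, ...) are flagged as non-analyzable and excluded from
#' all downstream computations.
#'
#' @param path Path to a FASTA file of aligned amino-acid sequences.
#' @return An `aa_alignment` object.
#' @export
read_alignment <- function(path) {
  if (!file.exists(path)) stop("alignment file not found: ", path)
  seqs <- suppressWarnings(ape::read.FASTA(path, type = "AA"))
  if (is.null(seqs) || length(seqs) == 0L) stop("empty FASTA file: ", path)
  lens <- lengths(seqs)
  if (length(unique(lens)) != 1L) {
    stop("sequences have unequal lengths (", paste(unique(lens), collapse = ", "),
         "); is this an alignment?")
  }
  aa_alignment(as.character(as.matrix(seqs)))
}

#' @export
print.aa_alignment <- function(x, ...) {
  cat("Amino-acid alignment:", length(x$taxa), "taxa x", x$n_sites, "sites (",
      sum(x$analyzable), "analyzable )\n")
  invisible(x)
}

#' Read a rooted phylogeny with branch lengths from a Newick file
#'
#' The tree is honored as rooted at the file's root node. Branches are
#' indexed deterministically in preorder from the root (the row order of
#' `$edge` after cladewise reordering), so that branch-level outputs are
#' reproducible. Signed property changes depend on this orientation; all
#' sites of a family share the same tree, so compensation statistics are
#' orientation-consistent.
#'
#' @param path Newick file path, or an `ape::phylo` object.
#' @param alignment Optional `aa_alignment`; taxon sets are checked to match.
#' @return An `ape::phylo` object in cladewise (preorder) edge order.
#' @export
read_tree <- function(path, alignment = NULL) {
  tree <- if (inherits(path, "phylo")) path else ape::read.tree(path)
  if (is.null(tree)) stop("could not parse Newick file: ", path)
  if (is.null(tree$edge.length) || anyNA(tree$edge.length)) {
    stop("tree has missing branch lengths")
  }
  if (any(tree$edge.length < 0)) stop("negative branch length in tree")
  if (anyDuplicated(tree$tip.label)) {
    stop("duplicate leaf label(s): ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "))
  }
  tree <- stats::reorder(tree, "cladewise")
  if (!is.null(alignment)) {
    miss_tree <- setdiff(alignment$taxa, tree$tip.label)
    miss_aln <- setdiff(tree$tip.label, alignment$taxa)
    if (length(miss_tree) || length(miss_aln)) {
      stop("taxon mismatch between tree and alignment; missing from tree: [",
           paste(miss_tree, collapse = ", "), "]; missing from alignment: [",
           paste(miss_aln, collapse = ", "), "]")
    }
  }
  tree
}

#' Number of branches of a phylogeny
#'
#' @param tree An `ape::phylo` object.
#' @return Number of branches (nodes minus one for a rooted tree).
#' @export
n_branches <- function(tree) nrow(tree$edge)
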