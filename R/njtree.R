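# Neighbor-joining trees from consensus/element sequences, with bootstrap
# support from alignment-column resampling. The multiple alignment is
# consensus-anchored (each sequence pairwise-aligned to the longest input),
# which preserves column homology for ~100 bp SINEs with a known parent
# without a progressive-alignment dependency.

#' Neighbor joining from a distance matrix
#'
#' Classic Saitou-Nei agglomeration (via \code{ape::nj}) with negative
#' branch lengths clamped to zero.
#'
#' @param d a \code{dist} or symmetric matrix.
#' @return an unrooted \code{phylo}.
#' @export
njTree <- function(d) {
  tr <- ape::nj(as.dist(d))
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

# anchor-based alignment matrix: rows = sequences, columns = anchor
# positions of the longest input
.anchorAlignment <- function(seqs) {
  anchorIdx <- which.max(Biostrings::width(seqs))
  anchor <- as.character(seqs[[anchorIdx]])
  M <- .projectOnConsensus(seqs, anchor)
  rownames(M) <- names(seqs)
  M
}

# pairwise p-distance over shared non-gap columns
.pDistance <- function(M) {
  n <- nrow(M)
  d <- matrix(0, n, n, dimnames = list(rownames(M), rownames(M)))
  base <- M %in% c("A", "C", "G", "T")
  dim(base) <- dim(M)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      shared <- base[i, ] & base[j, ]
      ns <- sum(shared)
      d[i, j] <- d[j, i] <-
        if (ns == 0) 1 else sum(M[i, shared] != M[j, shared]) / ns
    }
  }
  d
}

#' Build a neighbor-joining tree with bootstrap support
#'
#' Sequences are anchor-aligned to the longest input, pairwise p-distances
#' are computed over shared non-gap columns, and the NJ tree is built.
#' Bootstrap replicates resample alignment columns with replacement;
#' node labels carry the percentage of replicates containing each internal
#' bipartition. Deterministic given \code{seed}.
#'
#' @param seqs named \code{DNAStringSet} (at least 3).
#' @param bootstrap number of bootstrap replicates (0 to skip).
#' @param seed RNG seed for resampling.
#' @return a \code{phylo} with \code{node.label} support percentages (the
#'   root label is empty).
#' @export
buildNJTree <- function(seqs, bootstrap = 100, seed = 1L) {
  if (length(seqs) < 3L) .stopf("need at least 3 sequences")
  M <- .anchorAlignment(seqs)
  tr <- njTree(.pDistance(M))
  if (bootstrap > 0 && length(seqs) > 3L) {
    set.seed(seed)
    boots <- vector("list", bootstrap)
    for (b in seq_len(bootstrap)) {
      cols <- sample.int(ncol(M), ncol(M), replace = TRUE)
      boots[[b]] <- njTree(.pDistance(M[, cols, drop = FALSE]))
    }
    cl <- ape::prop.clades(tr, boots, rooted = FALSE)
    cl[is.na(cl)] <- 0
    tr$node.label <- c("", round(100 * cl[-1] / bootstrap))
  } else if (bootstrap > 0) {
    tr$node.label <- rep("", tr$Nnode)
  }
  tr
}

#' Newick string for a tree
#'
#' @param tree a \code{phylo}.
#' @param file optional path.
#' @return the Newick string, invisibly when writing to file.
#' @export
writeNewick <- function(tree, file = NULL) {
  txt <- ape::write.tree(tree)
  if (!is.null(file)) { writeLines(txt, file); return(invisible(txt)) }
  txt
}
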