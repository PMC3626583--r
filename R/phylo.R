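#' Amino-acid p-distance with pairwise gap deletion
#'
#' Proportion of differing sites over the sites where neither sequence has a
#' gap (`-`, `.`, `?` or `X` treated as missing), computed for every pair of
#' an alignment.
#'
#' @param aln Named character vector, `AAStringSet` or character matrix of
#'   equal-length aligned sequences.
#' @return A `dist` object.
#' @export
aa_p_distance <- function(aln) {
  m <- aln_matrix(aln)
  n <- nrow(m)
  gap <- m %in% c("-", ".", "?", "X")
  dim(gap) <- dim(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ok <- !gap[i, ] & !gap[j, ]
      if (!any(ok)) abort("sequence pair with no shared ungapped sites.")
      d[i, j] <- d[j, i] <- mean(m[i, ok] != m[j, ok])
    }
  }
  stats::as.dist(d)
}

aln_matrix <- function(aln) {
  if (inherits(aln, "AAStringSet") || inherits(aln, "XStringSet")) {
    aln <- setNames(as.character(aln), names(aln))
  }
  if (is.matrix(aln)) return(aln)
  if (length(unique(nchar(aln))) != 1) {
    abort("sequences must be aligned to equal length.")
  }
  m <- do.call(rbind, strsplit(aln, ""))
  rownames(m) <- names(aln)
  m
}

#' Neighbor-joining tree of NB-domain peptides with bootstrap support
#'
#' Saitou-Nei neighbor joining (via [ape::nj()]) on amino-acid p-distances
#' with pairwise gap deletion; negative branch lengths are clamped to zero.
#' Bootstrap support is the percentage of `n_bootstrap` column-resampled
#' replicates containing each internal bipartition of the tree, computed
#' with a fixed seed so supports are reproducible.
#'
#' @param aln Aligned peptides (named character vector, `AAStringSet` or
#'   character matrix), at least 3 sequences.
#' @param n_bootstrap Bootstrap replicates (default 1000; 0 skips
#'   bootstrapping).
#' @param seed Integer seed for the column resampling.
#' @return An [ape::phylo] tree of class `cucumap_tree` with internal-node
#'   `node.label` support values in \[0, 100\] and attribute `n_bootstrap`.
#' @export
nj_tree <- function(aln, n_bootstrap = 1000, seed = 1) {
  m <- aln_matrix(aln)
  if (nrow(m) < 3) abort("need at least 3 sequences for a tree.")
  build <- function(mm) {
    tr <- ape::nj(aa_p_distance(mm))
    tr$edge.length[tr$edge.length < 0] <- 0
    tr
  }
  tree <- build(m)
  if (n_bootstrap > 0) {
    set.seed(seed)
    reps <- vector("list", n_bootstrap)
    for (b in seq_len(n_bootstrap)) {
      reps[[b]] <- build(m[, sample.int(ncol(m), replace = TRUE), drop = FALSE])
    }
    counts <- ape::prop.clades(tree, reps, rooted = FALSE)
    counts[is.na(counts)] <- 0
    tree$node.label <- round(100 * counts / n_bootstrap, 1)
  }
  attr(tree, "n_bootstrap") <- n_bootstrap
  class(tree) <- c("cucumap_tree", class(tree))
  tree
}

#' Bootstrap support for a clade
#'
#' @param tree A [nj_tree()] result.
#' @param leaves Character vector of leaf labels forming the clade (as a
#'   bipartition of the unrooted tree).
#' @return Support percentage, or `NA` if the bipartition is not an edge of
#'   the tree.
#' @export
clade_support <- function(tree, leaves) {
  if (is.null(tree$node.label)) return(NA_real_)
  parts <- ape::prop.part(tree)
  labs <- attr(parts, "labels")
  target <- sort(match(leaves, labs))
  comp <- sort(setdiff(seq_along(labs), target))
  for (k in seq_along(parts)) {
    pp <- sort(parts[[k]])
    if (identical(pp, target) || identical(pp, comp)) {
      return(as.numeric(tree$node.label[k]))
    }
  }
  NA_real_
}
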