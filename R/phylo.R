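# Distance computation and neighbour-joining trees from presence/absence
# indel matrices, with unrooted "clan" grouping tests.  No outgroup is
# available within the system, so clans -- groups separable by removing
# one edge of the unrooted tree -- replace rooted monophyly.

#' Pairwise sample distances from an indel matrix
#'
#' Hamming distance (number of loci with differing presence; default) or
#' Jaccard distance over presence.  Requires a filtered matrix: coverage
#' in all individuals is what makes shared absence informative.
#'
#' @param x a filtered `indel_matrix`.
#' @param method `"hamming"` or `"jaccard"`.
#' @param partition optionally restrict to `"background"` or
#'   `"supergene"` loci.
#' @return A [stats::dist] over samples.
#' @export
indel_distances <- function(x, method = c("hamming", "jaccard"),
                            partition = NULL) {
  stopifnot(inherits(x, "indel_matrix"))
  method <- match.arg(method)
  v <- x$values
  if (!is.null(partition)) {
    partition <- match.arg(partition, c("background", "supergene"))
    v <- v[x$loci$partition == partition, , drop = FALSE]
  }
  if (any(!x$covered)) stop("matrix has uncovered cells; filter first")
  if (method == "hamming") dist(t(v), method = "manhattan")
  else dist(t(v), method = "binary")
}

#' Neighbour-joining tree and grouping test from indel distances
#'
#' Infers an unrooted neighbour-joining tree (closed-form for exactly
#' three samples) and tests whether each species (background partition)
#' or each supergene-variant class (supergene partition) forms a clan.
#' All-zero distances yield a star tree and an indeterminate (`NA`)
#' grouping.
#'
#' @param x a filtered `indel_matrix`.
#' @param partition `"background"` or `"supergene"`: which loci to use
#'   and which grouping (species vs variant) to test.
#' @param method distance method, see [indel_distances()].
#' @return Object of class `indel_tree`: `tree` (an [ape::phylo]),
#'   `newick`, `partition`, and `grouping` (data.frame `group`,
#'   `grouping`, `is_clan`).
#' @export
infer_indel_tree <- function(x, partition = c("background", "supergene"),
                             method = "hamming") {
  stopifnot(inherits(x, "indel_matrix"))
  partition <- match.arg(partition)
  d <- indel_distances(x, method, partition)
  n <- attr(d, "Size")
  if (n < 3) stop("need at least 3 samples")
  labels <- attr(d, "Labels")
  degenerate <- all(d == 0)
  if (degenerate) {
    tree <- ape::stree(n, type = "star", tip.label = labels)
    tree$edge.length <- rep(0, nrow(tree$edge))
  } else if (n == 3) {
    # unique unrooted 3-leaf topology; branch lengths in closed form
    m <- as.matrix(d)
    bl <- c((m[1, 2] + m[1, 3] - m[2, 3]) / 2,
            (m[1, 2] + m[2, 3] - m[1, 3]) / 2,
            (m[1, 3] + m[2, 3] - m[1, 2]) / 2)
    tree <- ape::stree(3, type = "star", tip.label = labels)
    tree$edge.length <- pmax(0, bl)
  } else {
    tree <- ape::nj(d)
  }
  grouping_var <- if (partition == "background") "species" else "variant"
  groups <- unique(x$samples[[grouping_var]])
  grouping <- data.frame(
    group = groups, grouping = grouping_var,
    is_clan = vapply(groups, function(g) {
      if (degenerate) return(NA)
      tips <- x$samples$sample[x$samples[[grouping_var]] == g]
      is_clan(tree, tips)
    }, logical(1)), stringsAsFactors = FALSE, row.names = NULL)
  structure(list(tree = tree, newick = ape::write.tree(tree),
                 partition = partition, grouping = grouping),
            class = "indel_tree")
}

#' @export
print.indel_tree <- function(x, ...) {
  cat("indel_tree (", x$partition, "):", x$newick, "\n")
  print(x$grouping)
  invisible(x)
}

#' Test whether a tip set forms a clan on an unrooted tree
#'
#' A clan is a group of leaves separable from all others by removing a
#' single edge -- the unrooted analogue of monophyly.  Implemented by
#' rooting at a tip outside the group and testing monophyly.
#'
#' @param tree an [ape::phylo].
#' @param tips tip labels of the candidate clan.
#' @return Logical.
#' @export
is_clan <- function(tree, tips) {
  nt <- length(tree$tip.label)
  k <- length(tips)
  stopifnot(all(tips %in% tree$tip.label))
  if (k <= 1 || k >= nt - 1) return(TRUE)
  out <- setdiff(tree$tip.label, tips)[1]
  rooted <- ape::root(tree, outgroup = out, resolve.root = TRUE)
  ape::is.monophyletic(rooted, tips)
}
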