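#' Clade indicator matrix over the edges of a tree
#'
#' For each edge, marks which tips lie on its child side.  This is the
#' workhorse behind both the bipartition listing and the expected-GSM kernel:
#' a mutation on edge d under the infinite sites model gives one allele to
#' exactly the tips indicated in column d.
#'
#' @param tree A `"phylo"` object.
#' @return A 0/1 matrix of dimension N x E (tips in `tree$tip.label` order,
#'   columns in `tree$edge` row order), with tip labels as row names.
#' @keywords internal
clade_indicator <- function(tree) {
  n <- length(tree$tip.label)
  po <- stats::reorder(tree, "postorder")
  ne <- nrow(po$edge)
  below <- vector("list", max(po$edge))
  for (i in seq_len(n)) below[[i]] <- i
  Z <- matrix(0, n, ne)
  for (k in seq_len(ne)) {
    child <- po$edge[k, 2L]
    parent <- po$edge[k, 1L]
    tips <- below[[child]]
    Z[tips, k] <- 1
    below[[parent]] <- c(below[[parent]], tips)
  }
  # restore the original edge ordering of `tree`
  key <- function(e) paste(e[, 1L], e[, 2L])
  perm <- match(key(tree$edge), key(po$edge))
  Z <- Z[, perm, drop = FALSE]
  rownames(Z) <- tree$tip.label
  Z
}

#' Edge-induced bipartitions of an unrooted tree
#'
#' Cutting any edge of an unrooted tree splits the leaves into two nonempty
#' sets.  Under the infinite sites model a mutation on that edge gives the
#' minor allele to the smaller side (`c1`) and the major allele to the larger
#' side (`c0`).  When the two sides are the same size the expected GSM is
#' provably unaffected by the choice, so the tie is broken deterministically:
#' `c1` is the side containing the lexicographically smallest leaf label.
#'
#' Rooted input is unrooted first (the two root edges induce the same split;
#' merging them is the equivalent treatment).
#'
#' @param tree A `"phylo"` object with at least 2 leaves.
#' @return A list with one element per edge of the unrooted tree, each a list
#'   with components `edge` (edge index), `length` (branch length), `c0` and
#'   `c1` (character vectors of leaf labels, `|c0| >= |c1|`).
#' @examples
#' bp <- tree_bipartitions(parse_newick("(A:1,B:1,(C:1,D:1):1);"))
#' length(bp)  # 2N - 3 = 5
#' @export
tree_bipartitions <- function(tree) {
  tree <- unroot_tree(tree)
  labs <- tree$tip.label
  Z <- clade_indicator(tree)
  lapply(seq_len(ncol(Z)), function(k) {
    inside <- labs[Z[, k] == 1]
    outside <- labs[Z[, k] == 0]
    if (length(inside) < length(outside)) {
      c1 <- inside; c0 <- outside
    } else if (length(inside) > length(outside)) {
      c1 <- outside; c0 <- inside
    } else {
      small <- min(labs)
      if (small %in% inside) { c1 <- inside; c0 <- outside }
      else { c1 <- outside; c0 <- inside }
    }
    list(edge = k, length = tree$edge.length[k], c0 = sort(c0), c1 = sort(c1))
  })
}

#' Patristic distance between two leaves
#'
#' The sum of branch lengths along the unique path between two leaves.
#'
#' @param tree A `"phylo"` object.
#' @param i,j Leaf labels.
#' @return A nonnegative scalar; `d(i, i) = 0` and the measure is symmetric.
#' @seealso [patristic_matrix()] for all pairs at once.
#' @export
patristic_distance <- function(tree, i, j) {
  D <- patristic_matrix(tree)
  for (lab in c(i, j))
    if (!lab %in% rownames(D)) stop("unknown leaf label: ", lab)
  D[i, j]
}

#' All pairwise patristic distances
#'
#' @param tree A `"phylo"` object.
#' @return An N x N symmetric matrix of path-length distances with leaf
#'   labels as dimnames.
#' @export
patristic_matrix <- function(tree) {
  validate_tree(tree)
  D <- ape::dist.nodes(tree)[seq_along(tree$tip.label), seq_along(tree$tip.label)]
  dimnames(D) <- list(tree$tip.label, tree$tip.label)
  D
}

#' Shared root path of a pair of leaves
#'
#' On a rooted tree, the branch length between the root and the most recent
#' common ancestor (MRCA) of leaves `i` and `j`.  Pairs whose MRCA is the
#' root share nothing (0); for `i == j` the MRCA is the leaf itself, so the
#' full root-to-leaf depth is returned.
#'
#' @param tree A rooted `"phylo"` object.
#' @param i,j Leaf labels.
#' @return A nonnegative scalar.
#' @export
shared_root_path <- function(tree, i, j) {
  validate_tree(tree)
  if (!ape::is.rooted(tree))
    stop("shared_root_path needs a rooted tree; supply one or root the input first")
  labs <- tree$tip.label
  for (lab in c(i, j))
    if (!lab %in% labs) stop("unknown leaf label: ", lab)
  depths <- ape::node.depth.edgelength(tree)
  ii <- match(i, labs); jj <- match(j, labs)
  node <- if (ii == jj) ii else ape::getMRCA(tree, c(ii, jj))
  depths[node]
}
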