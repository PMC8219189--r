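#' Parse a Newick string into a phylogenetic tree
#'
#' Thin wrapper around [ape::read.tree()] that adds the validation the
#' similarity kernels rely on: unique leaf labels, at least two leaves, and a
#' branch length on every non-root edge.  Internal node labels are ignored and
#' square-bracket comments are stripped (the standard Newick dialect).
#'
#' @param text A single Newick string, terminated by `;`.
#' @return An object of class `"phylo"` (see [ape::read.tree()]).  Rootedness
#'   follows the top-level arity: two children at the outermost level give a
#'   rooted tree, three or more an unrooted one.
#' @examples
#' tr <- parse_newick("(A:1,B:1,(C:1,D:1):1);")
#' ape::is.rooted(tr)   # FALSE: trifurcating base
#' @export
parse_newick <- function(text) {
  if (!is.character(text) || length(text) != 1L)
    stop("'text' must be a single Newick string")
  tree <- tryCatch(suppressWarnings(ape::read.tree(text = text)),
                   error = function(e) stop("Newick parse error: ",
                                            conditionMessage(e), call. = FALSE))
  if (is.null(tree)) stop("Newick parse error: could not read a tree from the string")
  validate_tree(tree)
  tree
}

#' Validate the structural invariants of a phylogenetic tree
#'
#' @param tree A `"phylo"` object.
#' @return `tree`, invisibly, if valid; otherwise an error naming the problem.
#' @keywords internal
validate_tree <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a \"phylo\" object")
  n <- length(tree$tip.label)
  if (n < 2L) stop("tree must have at least 2 leaves, got ", n)
  dup <- tree$tip.label[duplicated(tree$tip.label)]
  if (length(dup))
    stop("duplicate leaf label(s): ", paste(unique(dup), collapse = ", "))
  if (is.null(tree$edge.length))
    stop("tree has no branch lengths")
  bad <- which(!is.finite(tree$edge.length))
  if (length(bad)) {
    child <- tree$edge[bad[1L], 2L]
    lab <- if (child <= n) tree$tip.label[child] else paste0("internal node ", child)
    stop("missing branch length on the edge above '", lab, "'")
  }
  if (any(tree$edge.length < 0))
    stop("negative branch length(s) present")
  invisible(tree)
}

#' Total branch length of a tree
#'
#' @param tree A `"phylo"` object with branch lengths.
#' @return The sum of all branch lengths (written |T| in the method's
#'   weighting), a nonnegative scalar.
#' @export
total_branch_length <- function(tree) {
  validate_tree(tree)
  sum(tree$edge.length)
}

#' Unroot a tree, merging the two root edges
#'
#' A rooted binary tree has a degree-2 root whose two incident edges cut the
#' leaf set identically; unrooting merges them into one edge carrying the sum
#' of their lengths, so the edge count drops from 2N-2 to 2N-3 while total
#' branch length and all patristic distances are preserved.  Already-unrooted
#' input is returned unchanged, as is the 2-leaf tree (its two edges already
#' induce the single possible bipartition).
#'
#' @param tree A `"phylo"` object.
#' @return An unrooted `"phylo"` object with the same leaves and total length.
#' @export
unroot_tree <- function(tree) {
  validate_tree(tree)
  if (length(tree$tip.label) == 2L || !ape::is.rooted(tree)) return(tree)
  ape::unroot(tree)
}

#' Read a set of trees sharing one leaf set
#'
#' Reads either a multi-line Newick file (one tree per line) or a NEXUS trees
#' block, such as the posterior samples written by BEAST/BEAST2.  NEXUS
#' `Translate` tables are honoured, so numeric tip codes are resolved to taxon
#' names.  All trees must carry the same leaf-label set; a mismatch is an
#' error naming the first offending tree.
#'
#' @param path Path to the tree file.
#' @param format `"newick"` or `"nexus"`.
#' @return A list of `"phylo"` objects in file order.
#' @export
read_tree_set <- function(path, format = c("newick", "nexus")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  trees <- suppressWarnings(switch(format,
    newick = ape::read.tree(path),
    nexus  = ape::read.nexus(path)))
  if (is.null(trees)) stop("no trees could be read from ", path)
  if (inherits(trees, "phylo")) trees <- list(trees)
  if (inherits(trees, "multiPhylo"))
    trees <- ape::.uncompressTipLabel(trees)   # shared-label storage -> per tree
  trees <- unclass(trees)  # multiPhylo -> plain list
  if (length(trees) == 0L) stop("no trees could be read from ", path)
  ref <- sort(trees[[1L]]$tip.label)
  for (k in seq_along(trees)) {
    validate_tree(trees[[k]])
    if (!identical(sort(trees[[k]]$tip.label), ref))
      stop("tree ", k, " has a different leaf-label set from tree 1")
  }
  trees
}
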