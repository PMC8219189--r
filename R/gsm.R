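#' Construct a similarity-matrix object
#'
#' @param K Numeric symmetric matrix with taxon labels as dimnames.
#' @param kind One of `"expected"`, `"empirical"`, `"gaussian"`, `"mds"`.
#' @return `K` with class `"gsm"` and a `kind` attribute.
#' @keywords internal
new_gsm <- function(K, kind = c("expected", "empirical", "gaussian", "mds")) {
  kind <- match.arg(kind)
  stopifnot(is.matrix(K), nrow(K) == ncol(K), !is.null(rownames(K)))
  K <- (K + t(K)) / 2            # kill floating-point asymmetry
  colnames(K) <- rownames(K)
  attr(K, "kind") <- kind
  class(K) <- c("gsm", class(K))
  K
}

#' @export
print.gsm <- function(x, ...) {
  n <- nrow(x)
  cat(sprintf("Similarity matrix (kind: %s), %d taxa\n", attr(x, "kind"), n))
  m <- min(n, 6L)
  print(round(unclass(x)[seq_len(m), seq_len(m), drop = FALSE], 4), ...)
  if (n > m) cat("... (", n, "x", n, " total)\n", sep = "")
  invisible(x)
}

#' @export
as.matrix.gsm <- function(x, ...) {
  attr(x, "kind") <- NULL
  class(x) <- "matrix"
  unclass(x)
}

#' Expected genetic similarity matrix from a phylogeny
#'
#' Computes the expectation of the standardized-genotype similarity matrix
#' conditioned on a tree, under the infinite sites model with a constant
#' neutral mutation rate.  A mutation falling on edge d (probability
#' proportional to its branch length) splits the leaves into the edge's
#' bipartition; the matrix is the branch-length-weighted sum over all edges of
#' the outer product of the standardized allele indicator:
#' \deqn{K^T = \sum_d \frac{|e_d|}{|T|} z_d z_d',\qquad
#'       z_{d,i} = \frac{[i \in c_1(d)] - \mu_d}{\sigma_d},}
#' with \eqn{\mu_d} the minor-allele frequency of the split and
#' \eqn{\sigma_d^2 = \mu_d(1-\mu_d)} its Bernoulli variance.  Row sums are 0
#' and the trace equals the number of leaves, matching the empirical GSM
#' under the population-variance convention.  The result is invariant to
#' rescaling all branch lengths (the weights are relative) and to which side
#' of an even split carries the minor allele.
#'
#' Rooted input is unrooted first: the two root edges induce the same
#' bipartition, and merging them leaves the weighted sum unchanged.
#'
#' @param tree A `"phylo"` object with at least 2 leaves and positive total
#'   branch length.
#' @return A `"gsm"` object of kind `"expected"` (N x N, labels from the tree).
#' @examples
#' expected_gsm(parse_newick("(A:1,B:2);"))             # [[1,-1],[-1,1]]
#' expected_gsm(parse_newick("(A:1,B:1,(C:1,D:1):1);")) # K_AB = -1/15
#' @export
expected_gsm <- function(tree) {
  validate_tree(tree)
  tree <- unroot_tree(tree)
  n <- length(tree$tip.label)
  tot <- sum(tree$edge.length)
  if (tot <= 0) stop("total branch length must be positive")
  Z <- clade_indicator(tree)
  w <- tree$edge.length / tot
  p <- colSums(Z) / n
  X <- sweep(sweep(Z, 2L, p, `-`), 2L, sqrt(p * (1 - p)), `/`)
  K <- tcrossprod(sweep(X, 2L, w, `*`), X)
  dimnames(K) <- list(tree$tip.label, tree$tip.label)
  new_gsm(K, "expected")
}

#' Empirical genetic similarity matrix from genotypes
#'
#' The standard normalized inner product of binary haploid genotypes:
#' \deqn{K^G_{ij} = \frac1M \sum_m \frac{(G_{im}-\mu_m)(G_{jm}-\mu_m)}{\sigma_m^2},}
#' with \eqn{\mu_m} the column mean and \eqn{\sigma_m^2 = \mu_m(1-\mu_m)} the
#' population (divide-by-N) column variance.  This convention makes the trace
#' exactly N and every row sum exactly 0, so the matrix is directly comparable
#' to [expected_gsm()].  The result is invariant to flipping any column's
#' allele coding and to permuting columns.
#'
#' @param G An N x M matrix (or data frame) of 0/1 genotypes, taxa in rows,
#'   loci in columns, with taxon labels as row names.
#' @return A `"gsm"` object of kind `"empirical"`.
#' @export
empirical_gsm <- function(G) {
  G <- as.matrix(G)
  storage.mode(G) <- "double"
  if (is.null(rownames(G))) rownames(G) <- paste0("t", seq_len(nrow(G)))
  if (nrow(G) < 2L) stop("need at least 2 taxa")
  if (ncol(G) < 1L) stop("need at least 1 locus")
  if (anyNA(G) || !all(G %in% c(0, 1)))
    stop("genotype matrix must contain only 0/1 entries")
  mu <- colMeans(G)
  mono <- which(mu == 0 | mu == 1)
  if (length(mono)) {
    nm <- colnames(G)[mono[1L]]
    if (is.null(nm) || is.na(nm)) nm <- as.character(mono[1L])
    stop("monomorphic column: ", nm,
         " (constant loci carry no similarity information)")
  }
  X <- sweep(sweep(G, 2L, mu, `-`), 2L, sqrt(mu * (1 - mu)), `/`)
  K <- tcrossprod(X) / ncol(G)
  new_gsm(K, "empirical")
}

#' Gaussian patristic-distance similarity
#'
#' Converts patristic distances to similarities with a Gaussian-type kernel
#' \eqn{K^S_{ij} = \exp(-\lambda d_{ij} / |T|)}, where \eqn{d_{ij}} is the
#' path length between leaves i and j and \eqn{|T|} the total branch length.
#' The bandwidth \eqn{\lambda} controls the decay; \eqn{\lambda = 0} gives
#' the degenerate all-ones matrix.
#'
#' @param tree A `"phylo"` object with positive total branch length.
#' @param lambda Nonnegative bandwidth (default 1).
#' @return A `"gsm"` object of kind `"gaussian"`: entries in (0, 1],
#'   diagonal 1.
#' @export
gaussian_similarity <- function(tree, lambda = 1) {
  if (length(lambda) != 1L || !is.finite(lambda) || lambda < 0)
    stop("'lambda' must be a single nonnegative number")
  tot <- total_branch_length(tree)
  if (tot <= 0) stop("total branch length must be positive")
  D <- patristic_matrix(tree)
  new_gsm(exp(-lambda * D / tot), "gaussian")
}

#' Shared root-path similarity
#'
#' The tree kernel used by MDS-based population-structure corrections: the
#' similarity of a pair of leaves is the branch length shared between the
#' root and their most recent common ancestor.  Diagonal entries are the
#' root-to-leaf depths; pairs whose MRCA is the root have similarity 0.  The
#' matrix is left unnormalized (raw branch-length units).
#'
#' @param tree A rooted `"phylo"` object.
#' @return A `"gsm"` object of kind `"mds"`.
#' @export
mds_similarity <- function(tree) {
  validate_tree(tree)
  if (!ape::is.rooted(tree))
    stop("mds_similarity needs a rooted tree; supply one or root the input first")
  n <- length(tree$tip.label)
  depths <- ape::node.depth.edgelength(tree)
  A <- ape::mrca(tree)               # N x N matrix of MRCA node numbers
  K <- matrix(depths[A], n, n, dimnames = list(tree$tip.label, tree$tip.label))
  diag(K) <- depths[seq_len(n)]      # MRCA(i, i) = i
  new_gsm(K, "mds")
}
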