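#' Simulate a Kingman coalescent tree
#'
#' Generates a rooted binary tree for `n_taxa` haploid samples under the
#' neutral, constant-population-size coalescent: while k lineages remain, a
#' waiting time is drawn from Exponential(rate k(k-1)/2) and a uniformly
#' random pair of lineages merges.  Branch lengths are in units of 2N
#' generations (N the effective population size), so for two samples the
#' expected tree height is 1 and for n samples the expected total branch
#' length is \eqn{2 \sum_{k=1}^{n-1} 1/k}.
#'
#' @param n_taxa Number of leaves (>= 2); labelled `t1 ... tn`.
#' @param seed Optional integer seed; if supplied the draw is reproducible.
#' @return A rooted binary `"phylo"` object with `2 n_taxa - 2` edges.
#' @examples
#' tr <- simulate_coalescent_tree(10, seed = 1)
#' ape::is.rooted(tr)
#' @export
simulate_coalescent_tree <- function(n_taxa, seed = NULL) {
  if (length(n_taxa) != 1L || n_taxa < 2L) stop("'n_taxa' must be an integer >= 2")
  n_taxa <- as.integer(n_taxa)
  if (!is.null(seed)) set.seed(seed)
  sub <- paste0("t", seq_len(n_taxa))   # newick fragment per active lineage
  height <- numeric(n_taxa)
  t_now <- 0
  k <- n_taxa
  while (k > 1L) {
    t_now <- t_now + stats::rexp(1L, rate = k * (k - 1L) / 2)
    pair <- sample.int(k, 2L)
    i <- pair[1L]; j <- pair[2L]
    merged <- sprintf("(%s:%.12g,%s:%.12g)",
                      sub[i], t_now - height[i], sub[j], t_now - height[j])
    keep <- setdiff(seq_len(k), c(i, j))
    sub <- c(sub[keep], merged)
    height <- c(height[keep], t_now)
    k <- k - 1L
  }
  ape::read.tree(text = paste0(sub, ";"))
}

#' Simulate infinite-sites genotypes on a tree
#'
#' Places mutations on the tree one locus at a time: each mutation falls on
#' edge d with probability \eqn{|e_d|/|T|} (its relative branch length), and
#' the resulting biallelic column gives one allele to every leaf on the
#' child side of that edge and the other allele to the rest.  Columns are
#' recoded so that 1 marks the minor allele (ties left as placed).  Because
#' each edge separates two nonempty leaf sets, no column is ever
#' monomorphic.
#'
#' Two mutation modes mirror the usual coalescent-simulator interfaces:
#' a fixed number of segregating sites `n_loci`, or a population-scaled
#' mutation rate `theta` (\eqn{\theta = 2N\mu}, matching branch lengths in
#' units of 2N generations) under which the number of sites is
#' Poisson(\eqn{\theta |T| / 2}).
#'
#' @param tree A `"phylo"` object with positive total branch length.
#' @param n_loci Number of segregating sites (fixed-sites mode, >= 1).
#' @param theta Population-scaled mutation rate (rate mode, > 0).  Supply
#'   exactly one of `n_loci` or `theta`.
#' @param seed Optional integer seed.
#' @return An N x `M` 0/1 matrix with taxon row names and columns `m1 ...`;
#'   in rate mode `M` is random and may be 0.
#' @export
simulate_genotypes <- function(tree, n_loci = NULL, theta = NULL, seed = NULL) {
  validate_tree(tree)
  tot <- sum(tree$edge.length)
  if (tot <= 0) stop("total branch length must be positive")
  if (is.null(n_loci) == is.null(theta))
    stop("supply exactly one of 'n_loci' or 'theta'")
  if (!is.null(seed)) set.seed(seed)
  if (!is.null(theta)) {
    if (theta <= 0) stop("'theta' must be positive")
    m <- stats::rpois(1L, theta * tot / 2)
  } else {
    if (n_loci < 1L) stop("'n_loci' must be >= 1")
    m <- as.integer(n_loci)
  }
  Z <- clade_indicator(tree)
  n <- nrow(Z)
  if (m == 0L) {
    G <- matrix(numeric(0), n, 0L, dimnames = list(tree$tip.label, NULL))
    return(G)
  }
  edges <- sample.int(ncol(Z), m, replace = TRUE, prob = tree$edge.length / tot)
  G <- Z[, edges, drop = FALSE]
  flip <- colSums(G) > n / 2
  G[, flip] <- 1 - G[, flip, drop = FALSE]
  dimnames(G) <- list(tree$tip.label, paste0("m", seq_len(m)))
  G
}
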