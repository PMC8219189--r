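# Independent brute-force oracles used to check the vectorized kernels.
# They deliberately share no code with the package internals: bipartition
# membership comes from phangorn::Descendants and the sums are literal loops.

naive_expected_gsm <- function(tree) {
  if (ape::is.rooted(tree) && length(tree$tip.label) > 2L)
    tree <- ape::unroot(tree)
  n <- length(tree$tip.label)
  tot <- sum(tree$edge.length)
  K <- matrix(0, n, n, dimnames = list(tree$tip.label, tree$tip.label))
  desc <- phangorn::Descendants(tree, tree$edge[, 2L], "tips")
  for (d in seq_len(nrow(tree$edge))) {
    g <- rep(0, n)
    g[desc[[d]]] <- 1
    if (sum(g) > n / 2) g <- 1 - g     # minor allele on the smaller side
    mu <- mean(g)
    s2 <- mu * (1 - mu)
    for (i in seq_len(n)) for (j in seq_len(n))
      K[i, j] <- K[i, j] +
        tree$edge.length[d] / tot * (g[i] - mu) * (g[j] - mu) / s2
  }
  K
}

naive_empirical_gsm <- function(G) {
  n <- nrow(G)
  m <- ncol(G)
  K <- matrix(0, n, n, dimnames = list(rownames(G), rownames(G)))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    acc <- 0
    for (l in seq_len(m)) {
      mu <- mean(G[, l])
      s2 <- mean((G[, l] - mu)^2)      # population variance
      acc <- acc + (G[i, l] - mu) * (G[j, l] - mu) / s2
    }
    K[i, j] <- acc / m
  }
  K
}

# Random tree with branch lengths, independent of the package's simulator.
random_test_tree <- function(n) {
  tr <- ape::rtree(n)
  tr$edge.length <- stats::runif(nrow(tr$edge), 0.05, 2)
  tr
}
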