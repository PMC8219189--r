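#' Consistency study: empirical vs expected GSM on simulated data
#'
#' For each replicate, simulates a coalescent tree, simulates `n_loci`
#' infinite-sites genotypes on it, and computes the entrywise differences
#' between the empirical GSM (from the genotypes) and the expected GSM (from
#' the tree).  Differences are pooled over the upper triangle (including the
#' diagonal by default) across all replicates and summarised by mean,
#' standard deviation and the 2.5/25/50/75/97.5% quantiles.  Since the
#' expected GSM is the conditional expectation of the empirical one, the
#' pooled mean is ~0 and the spread shrinks as `n_loci` grows.
#'
#' @param n_trees Number of replicate trees.
#' @param n_taxa Leaves per tree.
#' @param n_loci Segregating sites simulated per tree.
#' @param seed Optional integer seed governing the whole study.
#' @param include_diagonal Pool diagonal entries too? (default TRUE).
#' @param keep_differences Keep the pooled difference vector in the result?
#' @return An object of class `"diff_summary"`: design sizes plus `mean`,
#'   `sd`, `quantiles`, `n_entries` (and `differences` if kept).
#' @export
consistency_study <- function(n_trees, n_taxa, n_loci, seed = NULL,
                              include_diagonal = TRUE,
                              keep_differences = FALSE) {
  stopifnot(n_trees >= 1L, n_taxa >= 2L, n_loci >= 1L)
  if (!is.null(seed)) set.seed(seed)
  diffs <- vector("list", n_trees)
  for (r in seq_len(n_trees)) {
    tree <- simulate_coalescent_tree(n_taxa)
    G <- simulate_genotypes(tree, n_loci = n_loci)
    D <- as.matrix(empirical_gsm(G)) - as.matrix(expected_gsm(tree))
    diffs[[r]] <- D[upper.tri(D, diag = include_diagonal)]
  }
  pooled <- unlist(diffs, use.names = FALSE)
  out <- list(n_taxa = n_taxa, n_loci = n_loci, n_trees = n_trees,
              mean = mean(pooled), sd = stats::sd(pooled),
              quantiles = stats::quantile(pooled,
                                          c(0.025, 0.25, 0.5, 0.75, 0.975)),
              n_entries = length(pooled),
              include_diagonal = include_diagonal)
  if (keep_differences) out$differences <- pooled
  structure(out, class = "diff_summary")
}

#' @export
print.diff_summary <- function(x, ...) {
  cat(sprintf(
    "Entrywise K^G - K^T differences: %d trees, %d taxa, %d loci (%d entries)\n",
    x$n_trees, x$n_taxa, x$n_loci, x$n_entries))
  print(round(c(mean = x$mean, SD = x$sd, x$quantiles), 4))
  invisible(x)
}

#' Turn a difference summary into a one-row table
#'
#' @param x A `"diff_summary"`.
#' @param ... Unused.
#' @return A one-row data frame with columns `n_taxa`, `mean`, `sd`, `q2.5`,
#'   `q25`, `q50`, `q75`, `q97.5`.
#' @export
as.data.frame.diff_summary <- function(x, ...) {
  data.frame(n_taxa = x$n_taxa, mean = x$mean, sd = x$sd,
             q2.5 = x$quantiles[[1L]], q25 = x$quantiles[[2L]],
             q50 = x$quantiles[[3L]], q75 = x$quantiles[[4L]],
             q97.5 = x$quantiles[[5L]])
}

#' Comparison study: empirical GSM vs three tree kernels
#'
#' Simulates replicate rooted coalescent trees with infinite-sites genotypes
#' and compares the empirical GSM against the expected GSM, the Gaussian
#' patristic-distance similarity (bandwidth `lambda`), and the shared
#' root-path (MDS-approach) similarity.  The expected and Gaussian kernels
#' are computed on the unrooted form; the root-path kernel uses the
#' simulated root.  Upper-triangle entries (including the diagonal by
#' default, the same pooling convention as [consistency_study()]) are pooled
#' across all replicates and each comparison is scored by the Pearson
#' correlation with the empirical entries, alongside mean/SD of the
#' differences.
#'
#' @param n_trees Number of replicate trees.
#' @param n_taxa Leaves per tree.
#' @param n_loci Segregating sites per tree.
#' @param lambda Bandwidth for the Gaussian kernel.
#' @param seed Optional integer seed.
#' @param include_diagonal Pool diagonal entries too? (default TRUE).
#' @return An object of class `"comparison_study"` with elements
#'   `correlations` (named: `expected`, `gaussian`, `mds`),
#'   `difference_summary` (mean/SD per comparison) and the design sizes.
#' @export
comparison_study <- function(n_trees = 100L, n_taxa = 20L, n_loci = 1000L,
                             lambda = 1, seed = NULL,
                             include_diagonal = TRUE) {
  stopifnot(n_trees >= 1L, n_taxa >= 3L, n_loci >= 1L, lambda > 0)
  if (!is.null(seed)) set.seed(seed)
  acc <- list(empirical = list(), expected = list(), gaussian = list(),
              mds = list())
  ut <- function(M) M[upper.tri(M, diag = include_diagonal)]
  for (r in seq_len(n_trees)) {
    tree <- simulate_coalescent_tree(n_taxa)
    G <- simulate_genotypes(tree, n_loci = n_loci)
    lab <- tree$tip.label
    al <- function(K) as.matrix(K)[lab, lab]
    acc$empirical[[r]] <- ut(al(empirical_gsm(G)))
    acc$expected[[r]] <- ut(al(expected_gsm(tree)))
    acc$gaussian[[r]] <- ut(al(gaussian_similarity(tree, lambda)))
    acc$mds[[r]] <- ut(al(mds_similarity(tree)))
  }
  pooled <- lapply(acc, unlist, use.names = FALSE)
  comps <- c("expected", "gaussian", "mds")
  cors <- vapply(comps, function(k)
    stats::cor(pooled$empirical, pooled[[k]]), numeric(1))
  dsum <- t(vapply(comps, function(k) {
    d <- pooled$empirical - pooled[[k]]
    c(mean = mean(d), sd = stats::sd(d))
  }, numeric(2)))
  structure(list(correlations = cors,
                 difference_summary = as.data.frame(dsum),
                 n_trees = n_trees, n_taxa = n_taxa, n_loci = n_loci,
                 lambda = lambda, n_entries = length(pooled$empirical)),
            class = "comparison_study")
}

#' @export
print.comparison_study <- function(x, ...) {
  cat(sprintf(
    "Kernel comparison vs empirical GSM: %d trees, %d taxa, %d loci\n",
    x$n_trees, x$n_taxa, x$n_loci))
  cat("Pearson correlations (pooled off-diagonal entries):\n")
  print(round(x$correlations, 3))
  cat("Differences (empirical - kernel):\n")
  print(round(x$difference_summary, 4))
  invisible(x)
}

#' Per-entry GSM uncertainty over a tree ensemble
#'
#' Applies [expected_gsm()] to every tree of an ensemble (e.g. a thinned
#' posterior sample from Bayesian tree inference) and summarises each matrix
#' entry by its mean and equal-tailed 95% interval across trees.  Trees must
#' share one leaf-label set; entries are aligned by label.
#'
#' @param trees A list of `"phylo"` objects (>= 2) with identical leaf sets.
#' @param prob Interval mass (default 0.95).
#' @return An object of class `"gsm_ensemble"` with matrices `mean`, `lower`,
#'   `upper` and the tree count `n_trees`.
#' @export
ensemble_gsm <- function(trees, prob = 0.95) {
  if (!is.list(trees) || length(trees) < 2L)
    stop("need a list of at least 2 trees")
  lab <- sort(trees[[1L]]$tip.label)
  n <- length(lab)
  arr <- array(NA_real_, c(n, n, length(trees)))
  for (k in seq_along(trees)) {
    if (!setequal(trees[[k]]$tip.label, lab))
      stop("tree ", k, " has a different leaf-label set from tree 1")
    arr[, , k] <- as.matrix(expected_gsm(trees[[k]]))[lab, lab]
  }
  alpha <- (1 - prob) / 2
  qs <- apply(arr, c(1, 2), stats::quantile, probs = c(alpha, 1 - alpha))
  dn <- list(lab, lab)
  structure(list(mean = matrix(apply(arr, c(1, 2), mean), n, n, dimnames = dn),
                 lower = matrix(qs[1L, , ], n, n, dimnames = dn),
                 upper = matrix(qs[2L, , ], n, n, dimnames = dn),
                 n_trees = length(trees), prob = prob),
            class = "gsm_ensemble")
}

#' @export
print.gsm_ensemble <- function(x, ...) {
  cat(sprintf("Expected-GSM ensemble over %d trees, %d taxa\n",
              x$n_trees, nrow(x$mean)))
  cat("Posterior mean (leading entries):\n")
  m <- min(nrow(x$mean), 5L)
  print(round(x$mean[seq_len(m), seq_len(m)], 3))
  invisible(x)
}
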