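#' Gibbs sampler for variance components and narrow-sense heritability
#'
#' Fits the single-component animal model
#' \deqn{y = b + e,\quad b \sim N(0, \sigma_g^2 K),\quad e \sim N(0, \sigma_e^2 I)}
#' to a standardized phenotype vector, with K a fixed genetic similarity
#' matrix (typically [expected_gsm()]), and samples the posterior of
#' \eqn{(\sigma_g^2, \sigma_e^2)} by Gibbs sampling under independent
#' Inverse-Gamma(`prior_shape`, `prior_rate`) priors.  Narrow-sense
#' heritability \eqn{h^2 = \sigma_g^2 / (\sigma_g^2 + \sigma_e^2)} is derived
#' per draw.
#'
#' Expected GSMs have zero row sums, so K is singular (the all-ones vector is
#' in its null space).  The genetic effect is therefore sampled in the column
#' space of K: with the spectral decomposition \eqn{K = U \Lambda U'}
#' restricted to eigenvalues above `tol` times the largest, \eqn{b = U a}
#' with \eqn{a \sim N(0, \sigma_g^2 \Lambda)}.  Because U has orthonormal
#' columns the full conditional of `a` factorizes over coordinates, making
#' each sweep O(n) after one eigendecomposition.
#'
#' @param y Named numeric phenotype vector; names must match the labels of
#'   `K` (same set; `y` is re-ordered to match).  Standardized to mean 0,
#'   variance 1 before inference.
#' @param K Symmetric positive semidefinite similarity matrix with taxon
#'   labels as dimnames (a `"gsm"` or plain matrix).
#' @param n_iter Total Gibbs iterations (default 10000).
#' @param burn_in Iterations discarded from the front (default 5000).
#' @param seed Optional integer seed for a reproducible chain.
#' @param prior_shape,prior_rate Inverse-Gamma hyperparameters for both
#'   variance components (default 0.001, 0.001: weakly informative).
#' @param tol Relative eigenvalue cutoff for the column space of K.
#' @return An object of class `"h2_fit"`: post-burn-in draws of
#'   \eqn{\sigma_g^2, \sigma_e^2, h^2} plus the posterior-mean genetic
#'   effects, with `print`, `summary`, `coef`, `fitted`, `residuals` and
#'   `plot` methods.
#' @export
gibbs_h2 <- function(y, K, n_iter = 10000L, burn_in = 5000L, seed = NULL,
                     prior_shape = 0.001, prior_rate = 0.001, tol = 1e-10) {
  K <- as.matrix(K)
  if (!isSymmetric(K, tol = 1e-8)) stop("K must be symmetric")
  n <- nrow(K)
  if (length(y) != n) stop("length(y) != nrow(K)")
  if (!is.null(names(y)) && !is.null(rownames(K))) {
    if (!setequal(names(y), rownames(K)))
      stop("phenotype labels do not match the similarity matrix labels")
    y <- y[rownames(K)]
  }
  if (n_iter <= burn_in || burn_in < 0) stop("need n_iter > burn_in >= 0")
  s <- stats::sd(y) * sqrt((n - 1) / n)
  if (s == 0) stop("phenotype has zero variance; cannot standardize")
  y <- (y - mean(y)) / s
  if (!is.null(seed)) set.seed(seed)

  ee <- eigen((K + t(K)) / 2, symmetric = TRUE)
  keep <- ee$values > tol * max(ee$values)
  if (!any(keep)) stop("K has no positive eigenvalues; not a valid covariance")
  lam <- ee$values[keep]
  U <- ee$vectors[, keep, drop = FALSE]
  r <- length(lam)
  uty <- drop(crossprod(U, y))

  n_keep <- n_iter - burn_in
  sg2 <- se2 <- numeric(n_keep)
  b_sum <- numeric(n)
  sigma_g2 <- sigma_e2 <- 1
  for (it in seq_len(n_iter)) {
    prec <- 1 / sigma_e2 + 1 / (sigma_g2 * lam)
    a <- stats::rnorm(r, mean = (uty / sigma_e2) / prec, sd = sqrt(1 / prec))
    sigma_g2 <- 1 / stats::rgamma(1L, shape = prior_shape + r / 2,
                                  rate = prior_rate + sum(a^2 / lam) / 2)
    resid <- y - drop(U %*% a)
    sigma_e2 <- 1 / stats::rgamma(1L, shape = prior_shape + n / 2,
                                  rate = prior_rate + sum(resid^2) / 2)
    if (it > burn_in) {
      j <- it - burn_in
      sg2[j] <- sigma_g2
      se2[j] <- sigma_e2
      b_sum <- b_sum + (y - resid)
    }
  }
  out <- variance_posterior(sg2, se2, burn_in = burn_in, seed = seed)
  out$n <- n
  out$rank <- r
  out$y <- y
  out$b_hat <- stats::setNames(b_sum / n_keep, rownames(K))
  out$prior <- c(shape = prior_shape, rate = prior_rate)
  out
}

#' Bundle variance-component draws into a posterior object
#'
#' Low-level constructor used by [gibbs_h2()]; also handy for summarising
#' draws produced elsewhere.
#'
#' @param sigma_g2,sigma_e2 Equal-length vectors of positive draws.
#' @param burn_in Number of iterations that were discarded before these
#'   draws (bookkeeping only).
#' @param seed Seed used to generate the chain, if any.
#' @return An object of class `"h2_fit"` with a `draws` data frame holding
#'   `iter`, `sigma_g2`, `sigma_e2` and the per-draw `h2`.
#' @export
variance_posterior <- function(sigma_g2, sigma_e2, burn_in = 0L, seed = NULL) {
  stopifnot(length(sigma_g2) == length(sigma_e2), length(sigma_g2) >= 1L,
            all(sigma_g2 > 0), all(sigma_e2 > 0))
  draws <- data.frame(iter = burn_in + seq_along(sigma_g2),
                      sigma_g2 = sigma_g2, sigma_e2 = sigma_e2,
                      h2 = sigma_g2 / (sigma_g2 + sigma_e2))
  structure(list(draws = draws, n_iter = burn_in + nrow(draws),
                 burn_in = burn_in, seed = seed),
            class = "h2_fit")
}

#' Summarise a variance-component posterior
#'
#' Posterior means and equal-tailed 95% credible intervals for
#' \eqn{\sigma_g^2}, \eqn{\sigma_e^2} and \eqn{h^2}.  Heritability is
#' summarised from the per-draw ratios, not the ratio of the means.
#'
#' @param object An `"h2_fit"`.
#' @param prob Credible-interval mass (default 0.95).
#' @param ... Unused.
#' @return A data frame with rows `sigma_g2`, `sigma_e2`, `h2` and columns
#'   `mean`, `lower`, `upper`.
#' @export
summary.h2_fit <- function(object, prob = 0.95, ...) {
  d <- object$draws
  if (nrow(d) < 1L) stop("empty posterior")
  alpha <- (1 - prob) / 2
  stat <- function(x) c(mean = mean(x),
                        lower = unname(stats::quantile(x, alpha)),
                        upper = unname(stats::quantile(x, 1 - alpha)))
  out <- as.data.frame(rbind(sigma_g2 = stat(d$sigma_g2),
                             sigma_e2 = stat(d$sigma_e2),
                             h2 = stat(d$h2)))
  class(out) <- c("summary.h2_fit", class(out))
  out
}

#' @export
print.summary.h2_fit <- function(x, digits = 3L, ...) {
  cat("Posterior summaries (mean and 95% credible interval):\n")
  for (p in rownames(x))
    cat(sprintf("  %-9s %.*f (%.*f, %.*f)\n", p,
                digits, x[p, "mean"], digits, x[p, "lower"],
                digits, x[p, "upper"]))
  invisible(x)
}

#' @export
print.h2_fit <- function(x, ...) {
  cat("Variance-component LMM fit (Gibbs sampling)\n")
  cat(sprintf("  %d stored draws (%d iterations, %d burn-in)\n",
              nrow(x$draws), x$n_iter, x$burn_in))
  print(summary(x))
  invisible(x)
}

#' @export
coef.h2_fit <- function(object, ...) {
  d <- object$draws
  c(sigma_g2 = mean(d$sigma_g2), sigma_e2 = mean(d$sigma_e2), h2 = mean(d$h2))
}

#' @export
fitted.h2_fit <- function(object, ...) {
  if (is.null(object$b_hat)) stop("no fitted genetic effects stored")
  object$b_hat
}

#' @export
residuals.h2_fit <- function(object, ...) {
  if (is.null(object$y)) stop("no data stored")
  object$y - object$b_hat
}

#' @export
plot.h2_fit <- function(x, ...) {
  d <- x$draws
  op <- graphics::par(mfrow = c(1, 3))
  on.exit(graphics::par(op))
  graphics::plot(d$iter, d$sigma_g2, type = "l", xlab = "iteration",
                 ylab = expression(sigma[g]^2), main = "trace")
  graphics::plot(d$iter, d$sigma_e2, type = "l", xlab = "iteration",
                 ylab = expression(sigma[e]^2), main = "trace")
  graphics::hist(d$h2, breaks = 40, xlab = expression(h^2),
                 main = "posterior", freq = FALSE)
  invisible(x)
}

#' Simulate a phenotype from the variance-component model
#'
#' Draws \eqn{y = b + e} with \eqn{b \sim N(0, \sigma_g^2 K)} (sampled in the
#' column space of K) and \eqn{e \sim N(0, \sigma_e^2 I)}.  Used for
#' parameter-recovery checks of [gibbs_h2()].
#'
#' @param K Symmetric PSD similarity matrix with taxon labels.
#' @param sigma_g2,sigma_e2 True variance components.
#' @param seed Optional integer seed.
#' @param tol Relative eigenvalue cutoff, as in [gibbs_h2()].
#' @return A named numeric vector of phenotypes.
#' @export
simulate_lmm_phenotype <- function(K, sigma_g2, sigma_e2, seed = NULL,
                                   tol = 1e-10) {
  K <- as.matrix(K)
  if (!is.null(seed)) set.seed(seed)
  ee <- eigen((K + t(K)) / 2, symmetric = TRUE)
  keep <- ee$values > tol * max(ee$values)
  lam <- ee$values[keep]
  U <- ee$vectors[, keep, drop = FALSE]
  b <- drop(U %*% (sqrt(sigma_g2 * lam) * stats::rnorm(length(lam))))
  y <- b + stats::rnorm(nrow(K), sd = sqrt(sigma_e2))
  stats::setNames(y, rownames(K))
}
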