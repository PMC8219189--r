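---
title: "Expected genetic similarity matrices from phylogenies: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Expected genetic similarity matrices from phylogenies: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phylogsm)
```

## The model

The empirical genetic similarity matrix (GSM) of $N$ haploid taxa genotyped
at $M$ biallelic loci is the standardized inner product

$$K^G_{ij} = \frac{1}{M}\sum_{m=1}^{M}
  \frac{(G_{im}-\mu_m)(G_{jm}-\mu_m)}{\sigma_m^2},$$

where $G_{im}\in\{0,1\}$ marks the minor allele, $\mu_m$ is the column mean
and $\sigma_m^2$ its variance. `phylogsm` computes the expectation of this
matrix conditioned on a phylogeny, under three assumptions:

* **infinite sites**: every mutation hits a fresh locus, so each variant is
  biallelic and maps to exactly one edge of the tree;
* **neutrality with a constant mutation rate**: the locus of a random
  variant falls on edge $d$ with probability $|e_d|/|T|$, the edge's share
  of the total branch length;
* **no recombination**: one tree describes every locus (appropriate at the
  species level or for clonal organisms).

Cutting edge $d$ of the *unrooted* tree splits the leaves into a bipartition
$(c_0, c_1)$ with $|c_0|\ge|c_1|$; a mutation there gives the minor allele
to $c_1$. Writing $G^d_i = \mathbb{1}[i \in c_1]$, $\mu_d = |c_1|/N$ and
$\sigma_d^2 = \mu_d(1-\mu_d)$, the expectation becomes a finite sum over
edges:

$$K^T_{ij} = \sum_d \frac{|e_d|}{|T|}
  \frac{(G^d_i-\mu_d)(G^d_j-\mu_d)}{\sigma_d^2}.$$

`expected_gsm()` evaluates this as $Z W Z^\top$ for the $N\times E$ matrix
$Z$ of column-standardized split indicators and $W$ the diagonal of relative
branch lengths — one pass over the edges plus one matrix product, $O(NE +
N^2E)$ worst case and far cheaper in BLAS practice. The test suite checks
this vectorized form against a literal per-edge triple loop (an independent
implementation built on a different tree traversal) to $10^{-12}$.

Two structural identities follow from the construction and are enforced to
$10^{-9}$ in the tests: every row of $K^T$ sums to 0 (each standardized
indicator has mean zero) and $\mathrm{trace}(K^T) = N$ (each edge
contributes $N$ to the trace and the weights sum to 1). The same identities
hold exactly for `empirical_gsm()` because it uses the *population*
(divide-by-$N$) variance $\sigma_m^2 = \mu_m(1-\mu_m)$; the sample-variance
convention would break the correspondence between the two matrices.

### Conventions and degenerate inputs

* **Even splits.** When $|c_0| = |c_1|$ the summand is provably unchanged by
  swapping the labels, so any rule works; `tree_bipartitions()` puts the
  side containing the lexicographically smallest leaf label into $c_1$,
  keeping output deterministic.
* **Rooted input.** The two edges incident to a degree-2 root induce the
  same bipartition; `expected_gsm()` unroots first (merging them, summing
  their lengths), which leaves the weighted sum unchanged.
* **Zero-length edges** are kept and contribute weight 0; only $|T| = 0$ is
  an error.
* **Scale invariance.** Multiplying all branch lengths by $c > 0$ leaves
  $K^T$ unchanged — only relative branch lengths matter, so trees dated in
  years, generations or substitutions give the same matrix.
* **Monomorphic genotype columns** are an error, not silently dropped:
  infinite-sites data cannot contain them, so their presence signals an
  upstream filtering problem the user should see.
* **Polytomies** are accepted (the edge sum does not require a binary
  tree); binary-only checks are reserved for the simulator's output.

## Comparator kernels

Two other tree-derived similarity measures are provided for comparison:

* `gaussian_similarity()`: $K^S_{ij} = \exp(-\lambda d_{ij}/|T|)$ with
  $d_{ij}$ the patristic distance. The bandwidth $\lambda$ (dimensionless,
  since the distance is normalized by $|T|$) defaults to 1 — a neutral
  choice that puts the exponent on the unit scale of relative path length —
  and is exposed as an argument because there is no canonical value.
* `mds_similarity()`: the shared root-path kernel used by MDS-based
  population-structure corrections — the branch length from the root to the
  pair's MRCA, with root-to-leaf depths on the diagonal. It requires a
  rooted tree and is left in raw branch-length units: the Pearson
  correlations used to score kernels are location/scale-free, so a
  normalization would not change any reported comparison.

Neither kernel integrates over mutation placements, which is why both track
the empirical GSM less closely than $K^T$ does (see
`comparison_study()`).

## The coalescent / infinite-sites simulator

`simulate_coalescent_tree()` implements the neutral constant-size Kingman
coalescent: with $k$ lineages, wait $\mathrm{Exp}(k(k-1)/2)$ and merge a
uniform pair. Time is measured in units of $2N_e$ generations, so the
population-scaled mutation rate is $\theta = 2N_e\mu$ and rate-mode
genotypes draw $\mathrm{Poisson}(\theta|T|/2)$ segregating sites.
`simulate_genotypes()` places each site on an edge with probability
$|e_d|/|T|$ and assigns the derived allele to the clade below it, then
recodes so 1 is the minor allele (exactly the conditional distribution a
standard coalescent simulator produces given the number of segregating
sites). One seed governs a whole replicate, making every study table
reproducible bit for bit.

The simulator emulates the data-generating process the expected GSM is
derived under — which is precisely what makes it the right validation
instrument and an incomplete model of real data. It has no recombination,
no demography, no selection, no genotyping error and no homoplasy, so
passing tests demonstrate internal consistency of the method, not
robustness to violations of its assumptions.

## Study drivers and pooling conventions

`consistency_study()` simulates replicate (tree, genotypes) pairs and pools
entrywise differences $K^G_{ij} - K^T_{ij}$ across replicates, reporting
mean, SD and the 2.5/25/50/75/97.5% quantiles. Differences are pooled over
the **upper triangle including the diagonal**, across trees rather than
per tree. The diagonal is genuine signal here — $K^G_{ii}$ varies around
$K^T_{ii}$ exactly as the off-diagonal entries do, and diagonal deviations
matter to downstream variance-component models — so the default includes
it; `include_diagonal = FALSE` is available, and at $M = 1000$ loci the
choice moves the pooled SD by well under the replicate-to-replicate noise.
`comparison_study()` applies the same pooling convention when correlating
each kernel's entries with the empirical GSM's, so the two drivers report
on identical entry sets.

Because $K^T$ is the conditional expectation of $K^G$, the pooled mean is
zero up to floating point (both matrices have trace $N$ and zero row sums),
and the pooled SD shrinks like $M^{-1/2}$: the tests assert the SD at
$M = 30{,}000$ is below the SD at $M = 10$ ($N = 50$, 20 replicates each),
and the consistency study reproduces a near-constant SD across $N = 10$ to
$300$ taxa at $M = 1000$.

`ensemble_gsm()` maps `expected_gsm()` over a set of trees with a common
leaf set (e.g. a thinned posterior sample from Bayesian tree inference) and
returns entrywise means and equal-tailed 95% intervals — a direct
uncertainty statement about each similarity entry under tree uncertainty.

## The heritability model

`gibbs_h2()` fits the standard single-component animal model
$y = b + e$, $b \sim N(0, \sigma_g^2 K)$, $e \sim N(0, \sigma_e^2 I)$,
on phenotypes standardized to mean 0 and (population) variance 1; no fixed
effects beyond that centering are included. Narrow-sense heritability is
the per-draw ratio $h^2 = \sigma_g^2/(\sigma_g^2+\sigma_e^2)$, and
summaries report means and equal-tailed 95% intervals of the stored draws
(never the ratio of means). Defaults are 10,000 iterations with the first
5,000 discarded.

Design choices where the model leaves room:

* **Priors.** Independent Inverse-Gamma(0.001, 0.001) on both variance
  components — the standard weakly-informative conjugate choice, exposed
  via `prior_shape`/`prior_rate` so sensitivity can be checked rather than
  hidden.
* **Singular K.** An expected GSM satisfies $K\mathbf{1} = 0$, so $K$ is
  singular. The genetic effect is sampled in the column space of $K$:
  eigenvalues below $10^{-10}$ of the largest are dropped and
  $b = U a$ with $a \sim N(0, \sigma_g^2\Lambda)$ on the retained
  eigenpairs. Since $U$ has orthonormal columns, the full conditional of
  $a$ factorizes coordinate-wise, so a sweep costs $O(n)$ after one
  eigendecomposition.
* **Blocking.** The sampler alternates $a \mid \cdot$,
  $\sigma_g^2 \mid a$, $\sigma_e^2 \mid y, a$ — all closed-form
  conditionals.
* **Mixing caveat.** When $K \propto I$ the likelihood identifies only
  $\sigma_g^2 + \sigma_e^2$ and a single chain executes a slow random walk
  along the $h^2$ direction; the exchangeability of the two components
  still centers the posterior at $h^2 = 1/2$, which the tests verify by
  averaging over independent chains. Structured similarity matrices (any
  real tree) identify the ratio and mix well.

Calibration is checked by simulation: phenotypes drawn from the model on a
200-leaf coalescent-tree GSM with true $h^2 = 2/3$ are refit in 50 seeded
replicates, and the 95% credible interval is required to cover the truth in
at least 90% of them.

## Problem sizes and runtime choices

The shipped tests run the structural invariants on 100 simulated trees each
at $N \in \{5, 20, 50\}$, the consistency study at $N \in \{10, 100, 300\}$
with 100 trees and 1000 loci, the kernel comparison at $N = 20$ with 100
trees, the convergence trend at $N = 50$ with 20 replicates of
$M \in \{10, 30{,}000\}$, and the coverage study at $n = 200$ with chains
of 3,000 iterations. These sizes make the whole suite run in about a
minute on one core while keeping every Monte Carlo tolerance at three or
more standard errors; all drivers accept larger values unchanged.

## Known limitations

* Haploid 0/1 genotypes only; no diploid dosage coding.
* No recombination: a single tree must describe all loci. For recombining
  samples an ancestral-recombination-graph extension (averaging expected
  GSMs over marginal trees) is the natural path but is not implemented.
* The expected GSM assumes the supplied tree is correct; uncertainty is
  addressed only by ensembling over candidate trees.
* The LMM has no fixed-effect design matrix and a single genetic component;
  multi-trait (coheritability) models are out of scope.
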