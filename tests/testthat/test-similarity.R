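test_that("expected GSM matches hand-worked and brute-force values", {
  # 2 leaves: single bipartition, mu = 1/2, standardized product is +/-1
  K2 <- expected_gsm(parse_newick("(A:3,B:0.5);"))
  expect_equal(as.matrix(K2), matrix(c(1, -1, -1, 1), 2, 2,
                                     dimnames = list(c("A", "B"), c("A", "B"))))

  # quartet with five unit edges, topology AB|CD
  tq <- parse_newick("(A:1,B:1,(C:1,D:1):1);")
  K <- expected_gsm(tq)
  expect_equal(diag(unclass(K)), c(A = 1, B = 1, C = 1, D = 1))
  expect_equal(K["A", "B"], -1 / 15)
  expect_equal(K["C", "D"], -1 / 15)
  expect_equal(K["A", "C"], -7 / 15)
  expect_equal(as.matrix(K), naive_expected_gsm(tq), tolerance = 1e-12)
})

test_that("expected GSM equals the literal per-edge loop on random trees", {
  set.seed(7)
  for (rep in 1:12) {
    tr <- random_test_tree(sample(4:20, 1L))
    K <- as.matrix(expected_gsm(tr))
    expect_equal(K, naive_expected_gsm(tr), tolerance = 1e-12)
  }
  # coalescent trees exercise the rooted-input path too
  for (rep in 1:3) {
    tr <- simulate_coalescent_tree(12)
    expect_equal(as.matrix(expected_gsm(tr)), naive_expected_gsm(tr),
                 tolerance = 1e-12)
  }
})

test_that("expected GSM has zero row sums, trace N, and scale invariance", {
  set.seed(8)
  for (n in c(5L, 20L, 50L)) {
    tr <- simulate_coalescent_tree(n)
    K <- as.matrix(expected_gsm(tr))
    expect_lt(max(abs(rowSums(K))), 1e-9)
    expect_equal(sum(diag(K)), n, tolerance = 1e-9)
    scaled <- tr
    scaled$edge.length <- tr$edge.length * 37.5
    expect_equal(as.matrix(expected_gsm(scaled)), K, tolerance = 1e-12)
  }
  expect_error(expected_gsm(structure(list(), class = "phylo")), "phylo|leaves")
  zero <- parse_newick("(A:0,B:0);")
  expect_error(expected_gsm(zero), "positive")
})

test_that("even splits are invariant to the minor-allele assignment", {
  # contribution of an even split computed with both orientations
  g <- c(1, 1, 0, 0)
  mu <- mean(g)
  expect_equal(outer(g - mu, g - mu) / (mu * (1 - mu)),
               outer((1 - g) - mu, (1 - g) - mu) / (mu * (1 - mu)))
  # and end to end: relabelling the leaves across an even split leaves K unchanged
  tq <- parse_newick("(A:1,B:1,(C:1,D:1):1);")
  sw <- parse_newick("(C:1,D:1,(A:1,B:1):1);")
  lab <- c("A", "B", "C", "D")
  expect_equal(as.matrix(expected_gsm(tq))[lab, lab],
               as.matrix(expected_gsm(sw))[lab, lab], tolerance = 1e-12)
})

test_that("empirical GSM matches direct evaluation and its invariances", {
  G1 <- matrix(c(1, 0, 0, 0), 4, 1,
               dimnames = list(paste0("s", 1:4), "m1"))
  K <- empirical_gsm(G1)
  expect_equal(K["s1", "s1"], 3)
  expect_equal(K["s1", "s2"], -1)
  expect_equal(K["s2", "s3"], 1 / 3)
  expect_equal(as.matrix(K), naive_empirical_gsm(G1), tolerance = 1e-12)

  set.seed(9)
  tr <- simulate_coalescent_tree(8)
  G <- simulate_genotypes(tr, n_loci = 40)
  K <- as.matrix(empirical_gsm(G))
  expect_equal(K, naive_empirical_gsm(G), tolerance = 1e-12)
  expect_lt(max(abs(rowSums(K))), 1e-9)
  expect_equal(sum(diag(K)), nrow(G), tolerance = 1e-9)

  flipped <- G
  flipped[, 3L] <- 1 - flipped[, 3L]
  expect_equal(as.matrix(empirical_gsm(flipped)), K, tolerance = 1e-12)
  expect_equal(as.matrix(empirical_gsm(G[, sample(ncol(G))])), K,
               tolerance = 1e-12)

  mono <- cbind(G, bad = 1)
  expect_error(empirical_gsm(mono), "monomorphic column: bad")
  G[1, 1] <- 2
  expect_error(empirical_gsm(G), "0/1")
})

test_that("Gaussian similarity is a unit-diagonal kernel of relative distance", {
  tq <- parse_newick("(A:1,B:1,(C:1,D:1):1);")
  K <- gaussian_similarity(tq, lambda = 1)
  expect_equal(diag(unclass(K)), c(A = 1, B = 1, C = 1, D = 1))
  expect_equal(K["A", "B"], exp(-2 / 5))
  expect_equal(K["A", "C"], exp(-3 / 5))
  expect_true(all(unclass(K) > 0 & unclass(K) <= 1))
  expect_equal(unique(as.vector(as.matrix(gaussian_similarity(tq, 0)))), 1)
  expect_error(gaussian_similarity(tq, -1), "nonnegative")
})

test_that("shared root-path similarity reflects MRCA depths", {
  tr <- parse_newick("((A:1,B:1):2,C:3);")
  K <- mds_similarity(tr)
  expect_equal(K["A", "B"], 2)
  expect_equal(K["A", "C"], 0)
  expect_equal(diag(unclass(K)), c(A = 3, B = 3, C = 3))

  # ultrametric coalescent tree: diagonal equals the tree height
  tr2 <- simulate_coalescent_tree(6, seed = 5)
  h <- max(ape::node.depth.edgelength(tr2))
  expect_equal(unname(diag(as.matrix(mds_similarity(tr2)))), rep(h, 6),
               tolerance = 1e-10)

  # all leaves hang straight off the root: every off-diagonal MRCA is the root
  star <- parse_newick("(A:1,B:2);")
  Ks <- mds_similarity(star)
  expect_equal(Ks["A", "B"], 0)
  expect_equal(diag(unclass(Ks)), c(A = 1, B = 2))
  expect_error(mds_similarity(unroot_tree(parse_newick("((A:1,B:1):1,(C:1,D:1):1);"))),
               "rooted")
})
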