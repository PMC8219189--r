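test_that("Newick parsing infers rootedness and validates structure", {
  t2 <- parse_newick("(A:1,B:1);")
  expect_equal(length(t2$tip.label), 2L)
  expect_equal(total_branch_length(t2), 2)

  tq_rooted <- parse_newick("((A:1,B:1):1,(C:1,D:1):1);")
  expect_true(ape::is.rooted(tq_rooted))
  expect_equal(nrow(tq_rooted$edge), 6L)   # 2N - 2

  tq_unrooted <- parse_newick("(A:1,B:1,(C:1,D:1):1);")
  expect_false(ape::is.rooted(tq_unrooted))
  expect_equal(nrow(tq_unrooted$edge), 5L) # 2N - 3

  expect_error(parse_newick("(A:1,A:1);"), "duplicate")
  expect_error(parse_newick("(A:1,B);"), "branch length")
  expect_error(parse_newick("not a tree"), "parse")
})

test_that("unrooting merges the root edges and preserves structure", {
  tr <- parse_newick("((A:1,B:1):0.5,C:0.5);")
  u <- unroot_tree(tr)
  expect_false(ape::is.rooted(u))
  expect_equal(nrow(u$edge), 3L)
  expect_equal(patristic_distance(u, "A", "C"), 2)  # C edge now 0.5 + 0.5
  expect_equal(total_branch_length(u), total_branch_length(tr))

  # patristic distances are untouched by unrooting
  big <- random_test_tree(12)
  ub <- unroot_tree(big)
  expect_equal(patristic_matrix(ub)[big$tip.label, big$tip.label],
               patristic_matrix(big))
  # idempotence
  expect_equal(unroot_tree(u), u)
})

test_that("bipartitions enumerate one split per edge with the tie rule", {
  bp2 <- tree_bipartitions(parse_newick("(A:1,B:1);"))
  expect_length(bp2, 2L)  # 2-leaf tree: both edges induce {A}|{B}
  expect_true(all(vapply(bp2, function(b)
    setequal(c(b$c0, b$c1), c("A", "B")), logical(1))))

  bp <- tree_bipartitions(parse_newick("(A:1,B:1,(C:1,D:1):1);"))
  expect_length(bp, 5L)
  sizes <- t(vapply(bp, function(b) c(length(b$c0), length(b$c1)), numeric(2)))
  expect_true(all(sizes[, 1L] >= sizes[, 2L]))
  even <- bp[[which(sizes[, 1L] == 2 & sizes[, 2L] == 2)]]
  expect_true("A" %in% even$c1)        # tie: c1 holds the smallest label

  for (n in c(5L, 13L, 20L)) {
    tr <- random_test_tree(n)
    expect_length(tree_bipartitions(tr), 2L * n - 3L)
  }
})

test_that("patristic distances sum path lengths and obey the four-point condition", {
  expect_equal(patristic_distance(parse_newick("(A:1,B:3);"), "A", "A"), 0)
  expect_equal(patristic_distance(parse_newick("(A:1,B:3);"), "A", "B"), 4)
  tq <- parse_newick("((A:1,B:1):1,(C:1,D:1):0);")
  expect_equal(patristic_distance(tq, "A", "C"), 3)
  expect_error(patristic_distance(tq, "A", "Z"), "unknown leaf")

  set.seed(42)
  for (rep in 1:5) {
    D <- patristic_matrix(random_test_tree(8))
    expect_equal(D, t(D))
    quad <- sample(rownames(D), 4L)
    s <- c(D[quad[1], quad[2]] + D[quad[3], quad[4]],
           D[quad[1], quad[3]] + D[quad[2], quad[4]],
           D[quad[1], quad[4]] + D[quad[2], quad[3]])
    expect_lt(max(s) - sort(s, decreasing = TRUE)[2L], 1e-10)
  }
})

test_that("shared root path measures root-to-MRCA length", {
  tr <- parse_newick("((A:1,B:1):2,C:3);")
  expect_equal(shared_root_path(tr, "A", "B"), 2)
  expect_equal(shared_root_path(tr, "A", "C"), 0)
  expect_equal(shared_root_path(tr, "A", "A"), 3)
  expect_error(shared_root_path(unroot_tree(parse_newick("((A:1,B:1):1,(C:1,D:1):1);")),
                                "A", "B"), "rooted")
  expect_error(shared_root_path(tr, "A", "Z"), "unknown leaf")
})

test_that("tree sets are read from Newick lists and NEXUS with translation", {
  nwk <- tempfile(fileext = ".nwk")
  writeLines(c("((A:1,B:1):0.5,C:0.5);",
               "((A:2,C:1):0.5,B:0.5);",
               "((B:1,C:1):1,A:1);"), nwk)
  trees <- read_tree_set(nwk, "newick")
  expect_length(trees, 3L)
  expect_true(all(vapply(trees, function(t)
    setequal(t$tip.label, c("A", "B", "C")), logical(1))))

  nex <- tempfile(fileext = ".nex")
  writeLines(c("#NEXUS",
               "BEGIN TREES;",
               "  TRANSLATE",
               "    1 A,",
               "    2 B,",
               "    3 C;",
               "  TREE tree1 = ((1:1,2:1):0.5,3:0.5);",
               "  TREE tree2 = ((1:1,3:1):0.5,2:0.5);",
               "END;"), nex)
  ntrees <- read_tree_set(nex, "nexus")
  expect_length(ntrees, 2L)
  expect_setequal(ntrees[[1L]]$tip.label, c("A", "B", "C"))

  empty <- tempfile()
  writeLines(character(0), empty)
  expect_error(read_tree_set(empty, "newick"))

  mism <- tempfile(fileext = ".nwk")
  writeLines(c("((A:1,B:1):0.5,C:0.5);", "((A:1,B:1):0.5,D:0.5);"), mism)
  expect_error(read_tree_set(mism, "newick"), "tree 2")
})

test_that("write/parse round trip preserves topology, labels and lengths", {
  tr <- random_test_tree(10)
  back <- parse_newick(ape::write.tree(tr, digits = 12))
  expect_setequal(back$tip.label, tr$tip.label)
  expect_equal(patristic_matrix(back)[tr$tip.label, tr$tip.label],
               patristic_matrix(tr), tolerance = 1e-10)
})
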