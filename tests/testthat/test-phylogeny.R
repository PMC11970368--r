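named_matrix <- function(v, nm) {
  matrix(v, length(nm), length(nm), dimnames = list(nm, nm))
}

test_that("NJ recovers the additive four-taxon tree exactly", {
  D <- named_matrix(c(0, 5, 7, 8,
                      5, 0, 8, 9,
                      7, 8, 0, 9,
                      8, 9, 9, 0), c("A", "B", "C", "D"))
  tr <- nj_tree(D)
  expect_s3_class(tr, "phylo")
  expect_setequal(tree_bipartitions(tr), "3,4")   # AB|CD split
  expect_equal(sort(tr$edge.length), c(1, 2, 3, 4, 5))
  co <- ape::cophenetic.phylo(tr)[rownames(D), colnames(D)]
  expect_equal(co, D, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("three taxa join at a trifurcation with closed-form lengths", {
  D <- named_matrix(c(0, 3, 5,
                      3, 0, 6,
                      5, 6, 0), c("x", "y", "z"))
  tr <- nj_tree(D)
  expect_equal(tr$Nnode, 1L)
  lens <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(unname(lens[c("x", "y", "z")]), c(1, 2, 4))
})

test_that("NJ topology is invariant to taxon order and respects preconditions", {
  set.seed(5)
  rt <- ape::rtree(9)
  D <- ape::cophenetic.phylo(rt)
  tr1 <- nj_tree(D)
  perm <- sample(rownames(D))
  tr2 <- nj_tree(D[perm, perm])
  expect_identical(tree_bipartitions(tr1), tree_bipartitions(tr2))

  expect_error(nj_tree(D[1:2, 1:2]), "at least 3")
  Dna <- D; Dna[1, 2] <- Dna[2, 1] <- NA
  expect_error(nj_tree(Dna), "undefined")
})

test_that("NJ is consistent on random additive matrices", {
  set.seed(101)
  for (k in 1:30) {
    n <- sample(5:20, 1)
    rt <- ape::rtree(n)                       # positive branch lengths
    D <- ape::cophenetic.phylo(rt)
    D <- D[sort(rownames(D)), sort(rownames(D))]
    tr <- nj_tree(D)
    expect_identical(tree_bipartitions(tr),
                     tree_bipartitions(ape::unroot(rt)))
    co <- ape::cophenetic.phylo(tr)[rownames(D), colnames(D)]
    expect_lt(max(abs(co - D)), 1e-9)
  }
})

test_that("UPGMA solves the textbook three-taxon case and is ultrametric", {
  D <- named_matrix(c(0, 2, 4,
                      2, 0, 4,
                      4, 4, 0), c("A", "B", "C"))
  tr <- upgma_tree(D)
  expect_equal(write_newick(tr, decimals = 0), "((A:1,B:1):1,C:2);")
  set.seed(33)
  M <- as.matrix(dist(matrix(rnorm(60), 10)))
  dimnames(M) <- list(paste0("s", 1:10), paste0("s", 1:10))
  u <- upgma_tree(M)
  depths <- ape::node.depth.edgelength(u)[seq_len(10)]
  expect_lt(diff(range(depths)), 1e-9)
})

test_that("UPGMA agrees with average-linkage hclust on random matrices", {
  set.seed(77)
  for (k in 1:10) {
    n <- sample(5:10, 1)
    M <- as.matrix(dist(matrix(rnorm(n * 4), n)))
    dimnames(M) <- list(paste0("s", seq_len(n)), paste0("s", seq_len(n)))
    u <- upgma_tree(M)
    h <- hclust(as.dist(M), method = "average")
    co <- ape::cophenetic.phylo(u)[rownames(M), colnames(M)]
    hc <- stats::cophenetic(h)
    expect_equal(co, as.matrix(hc)[rownames(M), colnames(M)],
                 tolerance = 1e-9, ignore_attr = TRUE)
  }
})

test_that("UPGMA recovers random ultrametric trees exactly", {
  set.seed(55)
  for (k in 1:30) {
    n <- sample(5:20, 1)
    rt <- ape::rcoal(n)
    D <- ape::cophenetic.phylo(rt)
    D <- D[sort(rownames(D)), sort(rownames(D))]
    u <- upgma_tree(D)
    co <- ape::cophenetic.phylo(u)[rownames(D), colnames(D)]
    expect_lt(max(abs(co - D)), 1e-9)
  }
})

test_that("Newick writing follows the grammar and round-trips", {
  D <- named_matrix(c(0, 3, 5,
                      3, 0, 6,
                      5, 6, 0), c("A", "B", "C"))
  tr <- nj_tree(D)
  txt <- write_newick(tr)
  expect_match(txt, "^\\(.*\\);$")
  expect_equal(txt, "(A:1.000000,B:2.000000,C:4.000000);")
  back <- parse_newick(txt)
  expect_identical(sort(back$tip.label), c("A", "B", "C"))
  expect_equal(sort(back$edge.length), sort(tr$edge.length))

  # support labels sit after the closing parenthesis
  cons <- parse_newick("((A,B)87:0.5,C,D);")
  expect_true("87" %in% cons$node.label)

  # quoted names with spaces survive a round trip
  q <- parse_newick("('tax one':1,'tax two':2,'it''s':3);")
  expect_setequal(q$tip.label, c("tax one", "tax two", "it's"))
  expect_identical(sort(parse_newick(write_newick(q))$tip.label),
                   sort(q$tip.label))
})

test_that("malformed Newick is rejected", {
  expect_error(parse_newick("(A,B),C;"), "trailing|expected")
  expect_error(parse_newick("(A,(B,C);"), "parenthes|expected")
  expect_error(parse_newick("(A,B)"), "expected ';'")
})

test_that("random trees survive a write/parse round trip", {
  set.seed(9)
  for (k in 1:10) {
    rt <- ape::rtree(sample(4:12, 1))
    txt <- write_newick(rt, decimals = 6)
    back <- parse_newick(txt)
    expect_identical(tree_bipartitions(back), tree_bipartitions(rt))
    expect_equal(sort(back$edge.length), sort(round(rt$edge.length, 6)),
                 tolerance = 1e-9)
  }
})

test_that("majority consensus counts bipartitions and labels supports", {
  t_ab <- parse_newick("((A,B),(C,D));")
  t_ac <- parse_newick("((A,C),(B,D));")
  trees <- c(rep(list(t_ab), 6), rep(list(t_ac), 4))
  cons <- majority_consensus(trees)
  expect_identical(tree_bipartitions(cons), tree_bipartitions(t_ab))
  expect_true("60" %in% cons$node.label)
  expect_false(any(cons$node.label == "40"))

  unanimous <- majority_consensus(rep(list(t_ab), 10))
  labs <- unanimous$node.label[nzchar(unanimous$node.label)]
  expect_true(all(labs == "100"))

  t_other <- parse_newick("((A,B),(C,E));")
  expect_error(majority_consensus(list(t_ab, t_other)), "D|E")
})

test_that("consensus supports stay above the threshold and splits are compatible", {
  set.seed(13)
  base <- ape::rtree(8)
  trees <- lapply(1:9, function(i) {
    if (i <= 6) base else ape::rtree(8, tip.label = base$tip.label)
  })
  cons <- majority_consensus(trees)
  labs <- as.numeric(cons$node.label[nzchar(cons$node.label)])
  expect_true(all(labs > 50 & labs <= 100))
  # compatibility: the splits nest, so they form a valid tree already
  expect_s3_class(cons, "phylo")
  expect_identical(sort(cons$tip.label), sort(base$tip.label))
})
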