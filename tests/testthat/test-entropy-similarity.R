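# Von Neumann entropy closed forms and bounds; similarity metrics and the
# within/between test.

test_that("entropy matches closed forms on canonical small graphs", {
  # single isolated node (read back from a zero-edge file to construct it)
  f <- tempfile()
  single <- buildNetwork(data.frame(sample_id = character(),
                                    genome_a = character(), pos_a = numeric(),
                                    genome_b = character(), pos_b = numeric()))
  g1 <- igraph::make_empty_graph(1, directed = FALSE)
  igraph::V(g1)$name <- "a"
  oneNode <- new("HGTNetwork", sampleId = "s", graph = g1)
  expect_equal(vonNeumannEntropy(oneNode), 0, tolerance = 1e-15)
  expect_equal(vonNeumannEntropy(makeNet("a", "b")), 0.25, tolerance = 1e-15)
  expect_equal(vonNeumannEntropy(makeNet(c("a", "b"), c("b", "c"))), 5 / 9,
               tolerance = 1e-15)
  expect_equal(vonNeumannEntropy(starNet("h", letters[1:4])), 0.76,
               tolerance = 1e-15)
  expect_error(vonNeumannEntropy(single), class = "hgtnet_undefined_entropy")
})

test_that("entropy ignores event multiplicity and respects the 1 - 1/|V| bound", {
  weighted <- makeNet(c("a", "b"), c("b", "c"), weight = c(7, 2))
  expect_equal(vonNeumannEntropy(weighted), 5 / 9)
  set.seed(21)
  for (i in 1:10) {
    net <- sampleScaleFreeNetwork(80, 2.5)
    V <- networkSize(net)
    expect_lt(vonNeumannEntropy(net), 1 - 1 / V)
    expect_gt(vonNeumannEntropy(net), 0)
  }
})

test_that("node Jaccard handles identity, disjointness, counting and errors", {
  nAB <- cliqueNet(c("A", "B", "C"))
  expect_equal(nodeJaccard(nAB, nAB), 1)
  expect_equal(nodeJaccard(nAB, cliqueNet(c("X", "Y", "Z"))), 0)
  expect_equal(nodeJaccard(nAB, cliqueNet(c("B", "C", "D"))), 0.5)
  empty <- buildNetwork(data.frame(sample_id = character(),
                                   genome_a = character(), pos_a = numeric(),
                                   genome_b = character(), pos_b = numeric()))
  expect_error(nodeJaccard(empty, empty),
               class = "hgtnet_undefined_similarity")
  # triangle-compatible bound J(a,c) >= J(a,b) + J(b,c) - 1 on fixture triples
  set.seed(22)
  pool <- sprintf("g%02d", 1:20)
  for (i in 1:20) {
    tri <- replicate(3, cliqueNet(sample(pool, 8)), simplify = FALSE)
    expect_gte(nodeJaccard(tri[[1]], tri[[3]]) + 1e-12,
               nodeJaccard(tri[[1]], tri[[2]]) +
                 nodeJaccard(tri[[2]], tri[[3]]) - 1)
  }
})

test_that("topology correlations: identity, rank reversal, oracle agreement", {
  set.seed(23)
  net <- sampleScaleFreeNetwork(60, 2.5)
  for (p in c("degree", "pagerank", "clustering_coefficient")) {
    r <- tryCatch(topologyCorrelation(net, net, p),
                  hgtnet_undefined_correlation = function(e) NA)
    if (!is.na(r)) expect_equal(r, 1)
  }
  # exact rank reversal of shared-node degrees -> -1
  a <- makeNet(c("h", "h", "h", "m"), c("x1", "x2", "m", "t"))
  # in b, reverse: t gets the high degree, h the low one
  b <- makeNet(c("t", "t", "t", "m"), c("y1", "y2", "m", "h"))
  expect_equal(topologyCorrelation(a, b, "degree"), -1)
  # fewer than 3 shared nodes
  expect_error(topologyCorrelation(cliqueNet(c("A", "B", "q")),
                                   cliqueNet(c("A", "B", "r")), "degree"),
               class = "hgtnet_insufficient_overlap")
  # agreement with a from-first-principles Spearman on shared values
  set.seed(24)
  core <- sprintf("c%02d", 1:30)
  mk <- function(extra) {
    pairs <- rbind(t(combn(core[1:10], 2)),
                   cbind(sample(core, 40, TRUE), sample(extra, 40, TRUE)))
    pairs <- pairs[pairs[, 1] != pairs[, 2], ]
    buildNetwork(eventsFromPairs(unique(pairs)))
  }
  na <- mk(sprintf("a%02d", 1:15)); nb <- mk(sprintf("b%02d", 1:15))
  shared <- intersect(networkNodes(na), networkNodes(nb))
  da <- igraph::degree(networkGraph(na))[shared]
  db <- igraph::degree(networkGraph(nb))[shared]
  expect_equal(topologyCorrelation(na, nb, "degree"),
               bruteSpearman(da, db), tolerance = 1e-9)
})

test_that("combined similarity multiplies Jaccard and degree correlation", {
  net <- sampleScaleFreeNetwork(60, 2.5)
  same <- combinedSimilarity(net, net)
  expect_equal(as.numeric(same), 1)
  expect_false(attr(same, "degenerate"))
  disjoint <- combinedSimilarity(cliqueNet(c("A", "B", "C")),
                                 cliqueNet(c("X", "Y", "Z")))
  expect_equal(as.numeric(disjoint), 0)
  expect_true(attr(disjoint, "degenerate"))
  # constructed product check: value equals jaccard * degree correlation
  a <- makeNet(c("h", "h", "h", "m"), c("x1", "x2", "m", "t"))
  b <- makeNet(c("t", "t", "t", "m"), c("y1", "y2", "m", "h"))
  expect_equal(as.numeric(combinedSimilarity(a, b)),
               nodeJaccard(a, b) * topologyCorrelation(a, b, "degree"))
})

test_that("similarity metrics are symmetric in their arguments", {
  set.seed(25)
  pool <- sprintf("g%02d", 1:30)
  n1 <- cliqueNet(sample(pool, 12)); n2 <- cliqueNet(sample(pool, 12))
  expect_equal(nodeJaccard(n1, n2), nodeJaccard(n2, n1))
  expect_equal(as.numeric(combinedSimilarity(n1, n2)),
               as.numeric(combinedSimilarity(n2, n1)))
})

test_that("within/between testing matches the direct t formula", {
  same <- withinBetweenTest(c(0.5, 0.6, 0.7), c(0.5, 0.6, 0.7))
  expect_equal(same$tStatistic, 0)
  expect_equal(same$pValue, 1)
  set.seed(26)
  within <- 0.9 + runif(10, -0.01, 0.01)
  between <- 0.1 + runif(10, -0.01, 0.01)
  r <- withinBetweenTest(within, between)
  oracle <- bruteT(within, between)
  expect_equal(r$tStatistic, oracle$t, tolerance = 1e-9)
  expect_equal(r$pValue, oracle$p, tolerance = 1e-9)
  expect_lt(r$pValue, 1e-6)
  expect_lt(r$pGreater, r$pValue)
  expect_error(withinBetweenTest(0.5, c(0.1, 0.2)),
               class = "hgtnet_insufficient_data")
})
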