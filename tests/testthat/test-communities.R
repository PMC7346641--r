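# Leiden communities, HCC clustering, bias-corrected labels, composition.

test_that("community detection separates two bridged cliques and partitions nodes", {
  left <- sprintf("L%d", 1:5); right <- sprintf("R%d", 1:5)
  ev <- rbind(eventsFromPairs(t(combn(left, 2))),
              eventsFromPairs(t(combn(right, 2))),
              eventsFromPairs(matrix(c("L1", "R1"), 1, 2)))
  net <- buildNetwork(ev)
  cm <- detectCommunities(net, seed = 7)
  # a partition: every node exactly once
  expect_setequal(cm$genome, networkNodes(net))
  expect_equal(nrow(cm), networkSize(net))
  # exactly the two cliques (oracle: exhaustive 2-block modularity check)
  expect_equal(length(unique(cm$community)), 2L)
  blocks <- split(cm$genome, cm$community)
  expect_true(setequal(blocks[[1]], left) || setequal(blocks[[1]], right))
  g <- networkGraph(net)
  planted <- ifelse(networkNodes(net) %in% left, 1L, 2L)
  qPlanted <- igraph::modularity(g, planted, weights = igraph::E(g)$weight)
  nodes <- networkNodes(net)
  for (i in 1:200) {  # random 2-block partitions never beat the planted one
    rnd <- sample(1:2, length(nodes), replace = TRUE)
    expect_lte(igraph::modularity(g, rnd, weights = igraph::E(g)$weight),
               qPlanted + 1e-12)
  }
})

test_that("a single clique stays one community and detection is deterministic", {
  net <- cliqueNet(sprintf("n%d", 1:6))
  cm <- detectCommunities(net, seed = 3)
  expect_equal(length(unique(cm$community)), 1L)
  set.seed(99)  # perturb global RNG state; the seed argument must win
  cm2 <- detectCommunities(net, seed = 3)
  expect_identical(cm, cm2)
  big <- sampleScaleFreeNetwork(120, 2.5, sampleId = "s")
  expect_identical(detectCommunities(big, seed = 11),
                   detectCommunities(big, seed = 11))
  empty <- buildNetwork(data.frame(sample_id = character(),
                                   genome_a = character(), pos_a = numeric(),
                                   genome_b = character(), pos_b = numeric()))
  expect_error(detectCommunities(empty), class = "hgtnet_validation_error")
})

test_that("community clustering groups identical sets and respects the size gate", {
  # 10 identical communities -> one cluster of 10
  ct <- do.call(rbind, lapply(1:10, function(i)
    data.frame(sample_id = paste0("s", i), community = 1L,
               genome = letters[1:5])))
  cc <- clusterCommunities(ct)
  expect_equal(unique(cc$cluster), 1L)
  expect_equal(nrow(cc), 10L)
  # two families, within-Jaccard 1, across 0 -> exactly 2 clusters
  ct2 <- do.call(rbind, lapply(1:10, function(i)
    data.frame(sample_id = paste0("s", i), community = 1L,
               genome = if (i <= 5) letters[1:6] else LETTERS[1:6])))
  cc2 <- clusterCommunities(ct2)
  expect_equal(sort(unique(cc2$cluster)), c(1L, 2L))
  expect_equal(as.vector(table(cc2$cluster)), c(5L, 5L))
  # a singleton community far from everything goes to the unclustered pool
  ct3 <- rbind(ct2, data.frame(sample_id = "lone", community = 1L,
                               genome = c("qq", "ww", "ee")))
  cc3 <- clusterCommunities(ct3)
  expect_equal(cc3$cluster[cc3$sample_id == "lone"], 0L)
  expect_error(clusterCommunities(ct[1:5, ]),
               class = "hgtnet_insufficient_data")
})

test_that("community cluster assignment is invariant to input row order", {
  set.seed(31)
  fams <- list(letters[1:6], LETTERS[1:6], sprintf("z%d", 1:6))
  ct <- do.call(rbind, lapply(1:12, function(i)
    data.frame(sample_id = paste0("s", i), community = 1L,
               genome = sample(fams[[1 + (i %% 3)]]))))
  key <- function(cc) {
    cc <- cc[order(cc$sample_id, cc$community), ]
    split(cc$sample_id, cc$cluster)
  }
  cc1 <- clusterCommunities(ct)
  cc2 <- clusterCommunities(ct[sample(nrow(ct)), ])
  expect_identical(key(cc1), key(cc2))
})

test_that("planted motif families are recovered with high agreement", {
  set.seed(32)
  motifs <- lapply(1:5, function(m) sprintf("M%d_%02d", m, 1:8))
  rows <- list()
  truth <- integer(0)
  for (m in 1:5) for (i in 1:20) {
    # jitter: drop one member, add one stray genome
    members <- c(sample(motifs[[m]], 7), sprintf("stray%03d", sample(999, 1)))
    rows[[length(rows) + 1]] <- data.frame(
      sample_id = sprintf("s%d_%d", m, i), community = 1L, genome = members)
    truth <- c(truth, m)
  }
  ct <- do.call(rbind, rows)
  cc <- clusterCommunities(ct, maxDistance = 0.6, minSize = 2)
  assigned <- cc$cluster[match(sprintf("s%d_%d", rep(1:5, each = 20),
                                       rep(1:20, 5)), cc$sample_id)]
  ari <- bruteARI(truth, assigned)
  if (requireNamespace("mclust", quietly = TRUE))
    expect_equal(ari, mclust::adjustedRandIndex(truth, assigned),
                 tolerance = 1e-12)
  expect_gte(ari, 0.9)
})

test_that("bias-corrected labeling follows COUNT/num with ties ambiguous", {
  num <- c(`Non-IBD` = 38, IBD = 109)
  expect_identical(labelCluster(c(`Non-IBD` = 10, IBD = 20), num), "Non-IBD")
  expect_identical(labelCluster(c(`Non-IBD` = 0, IBD = 5), num), "IBD")
  # exact tie -> ambiguous
  expect_identical(labelCluster(c(A = 2, B = 4), c(A = 10, B = 20)),
                   "ambiguous")
  # scale invariance over a small integer grid
  for (cA in 0:6) for (cB in 0:6) {
    if (cA + cB == 0) next
    l1 <- labelCluster(c(A = cA, B = cB), c(A = 2, B = 5))
    l3 <- labelCluster(c(A = 3 * cA, B = 3 * cB), c(A = 6, B = 15))
    expect_identical(l1, l3)
  }
  expect_error(labelCluster(c(A = 0, B = 0), c(A = 1, B = 1)),
               class = "hgtnet_validation_error")
  expect_error(labelCluster(c(A = 1), c(A = 3)),
               class = "hgtnet_parameter_error")
})

test_that("composition profiles count genomes with multiplicity and sum to 1", {
  tax <- tinyTaxonomy()
  p <- clusterComposition(c("gA", "gA", "gC", "gB"), tax, "phylum")
  expect_equal(unname(p["Proteobacteria"]), 0.75)
  expect_equal(unname(p["Bacteroidetes"]), 0.25)
  expect_equal(sum(p), 1)
  expect_equal(unname(clusterComposition("gD", tax, "phylum")), 1)
  err <- tryCatch(clusterComposition(c("gA", "gZ"), tax), error = identity)
  expect_s3_class(err, "hgtnet_taxonomy_error")
  expect_match(conditionMessage(err), "gZ")
})

test_that("composition comparisons match the direct t formula with 0 for absent taxa", {
  mkProfiles <- function(fracs)
    lapply(fracs, function(f) setNames(c(f, 1 - f),
                                       c("Proteobacteria", "Firmicutes")))
  same <- compareCompositions(mkProfiles(c(0.4, 0.5, 0.6)),
                              mkProfiles(c(0.4, 0.5, 0.6)),
                              "Proteobacteria")
  expect_equal(same$pValue, 1)
  expect_equal(same$tStatistic, 0)
  set.seed(33)
  a <- 0.7 + runif(10, -0.02, 0.02); b <- 0.1 + runif(10, -0.02, 0.02)
  r <- compareCompositions(mkProfiles(a), mkProfiles(b), "Proteobacteria")
  oracle <- bruteT(a, b)
  expect_equal(r$tStatistic, oracle$t, tolerance = 1e-9)
  expect_lt(r$pValue, 1e-6)
  expect_identical(r$direction, "A>B")
  # absent taxon counts as fraction 0 on that side
  onlyF <- lapply(1:3, function(i) c(Firmicutes = 1))
  r2 <- compareCompositions(mkProfiles(c(0.5, 0.6, 0.7)), onlyF,
                            "Proteobacteria")
  expect_equal(r2$meanB, 0)
})

test_that("full HCC wrapper labels clusters and profiles composition", {
  tax <- tinyTaxonomy()
  ct <- do.call(rbind, lapply(1:8, function(i)
    data.frame(sample_id = paste0("s", i), community = 1L,
               genome = if (i <= 4) c("gA", "gC") else c("gB", "gD"))))
  meta <- data.frame(sample_id = paste0("s", 1:8),
                     individual = paste0("i", 1:8),
                     group = rep(c("IBD", "Non-IBD"), each = 4),
                     time_point = "t1")
  hcc <- communityClusters(ct, meta, tax)
  expect_equal(nrow(hcc$clusters), 2L)
  expect_setequal(hcc$clusters$label, c("IBD", "Non-IBD"))
  protCluster <- hcc$clusters$cluster_id[hcc$clusters$label == "IBD"]
  expect_equal(unname(hcc$composition[[as.character(protCluster)]]["Proteobacteria"]), 1)
})
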