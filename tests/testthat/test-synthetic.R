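# Synthetic cohort generator: determinism, planted structure, reader
# compatibility, backbone exponent recovery, growth series.

test_that("taxonomy generation is deterministic and respects phylum weights", {
  t1 <- generateTaxonomy(nGenomes = 100, seed = 1)
  t2 <- generateTaxonomy(nGenomes = 100, seed = 1)
  expect_identical(t1, t2)
  t3 <- generateTaxonomy(nGenomes = 100, seed = 2)
  expect_false(identical(t1$taxonomy$phylum, t3$taxonomy$phylum))
  # multinomial check: counts near expectation for the default weights
  counts <- table(t1$taxonomy$phylum)
  expected <- c(Actinobacteria = 10, Bacteroidetes = 30, Firmicutes = 40,
                Proteobacteria = 20)
  expect_true(all(abs(counts[names(expected)] - expected) <= 15))
  # genes tile without overlap, inside the genome
  genes <- t1$genes[t1$genes$genome == t1$taxonomy$genome[1], ]
  expect_true(all(genes$start >= 1 & genes$end <= 200000))
  expect_true(all(genes$start[-1] > genes$end[-nrow(genes)]))
  # minimal case
  tiny <- generateTaxonomy(nGenomes = 2, seed = 5)
  expect_equal(nrow(tiny$taxonomy), 2L)
  expect_error(generateTaxonomy(nGenomes = 1),
               class = "hgtnet_parameter_error")
  expect_error(generateTaxonomy(phylumWeights = c(A = 0.7, B = 0.7)),
               class = "hgtnet_parameter_error")
})

test_that("cohort generation is deterministic and its files pass every reader", {
  tax <- generateTaxonomy(nGenomes = 80, seed = 3)
  cfg <- cohortConfig("mother-child", nFamilies = 2L, motherSize = 50L,
                      childSizes = c(20L, 30L),
                      childTimePoints = c("birth", "1mo"),
                      nFusionInGene = 4L, nFusionIntergenic = 4L, seed = 4)
  c1 <- generateCohort(cfg, tax)
  c2 <- generateCohort(cfg, tax)
  expect_identical(c1$events, c2$events)
  expect_identical(c1$depth, c2$depth)
  d <- file.path(tempdir(), "cohort-readers")
  paths <- writeCohort(c1, d, tax)
  ev <- readEvents(paths[["events"]])
  expect_equal(nrow(ev), nrow(c1$events))
  expect_true(all(ev$genome_a < ev$genome_b))
  expect_equal(nrow(readMetadata(paths[["metadata"]])), nrow(c1$metadata))
  expect_silent(readTaxonomy(paths[["taxonomy"]]))
  expect_silent(readDepth(paths[["depth"]]))
  anno <- readGeneAnnotations(paths[["annotations"]])
  expect_equal(length(anno), nrow(tax$genes))
})

test_that("generated edge multiplicities match the recorded truth table", {
  tax <- generateTaxonomy(nGenomes = 80, seed = 3)
  cfg <- cohortConfig("mother-child", nFamilies = 1L, motherSize = 50L,
                      childSizes = c(25L), childTimePoints = c("birth"),
                      seed = 6)
  coh <- generateCohort(cfg, tax)
  for (sid in unique(coh$events$sample_id)) {
    net <- buildNetwork(coh$events[coh$events$sample_id == sid, ])
    g <- networkGraph(net)
    truth <- coh$truth$edges[coh$truth$edges$sample_id == sid, ]
    ids <- igraph::get_edge_ids(g, rbind(truth$genome_a, truth$genome_b))
    expect_equal(igraph::E(g)$weight[ids], truth$weight)
    expect_equal(igraph::ecount(g), nrow(truth))
  }
})

test_that("family sharing rho controls mother-child key overlap", {
  tax <- generateTaxonomy(nGenomes = 150, seed = 3)
  jaccards <- function(rho, seed) {
    cfg <- cohortConfig("mother-child", nFamilies = 3L, motherSize = 80L,
                        childSizes = c(40L), childTimePoints = c("birth"),
                        rho = rho, seed = seed)
    coh <- generateCohort(cfg, tax)
    keysOf <- function(sid)
      unique(eventKey(coh$events[coh$events$sample_id == sid, ], 100))
    fams <- 1:3
    within <- vapply(fams, function(f) presenceJaccard(
      keysOf(sprintf("F%02d_M_birth", f)),
      keysOf(sprintf("F%02d_C_birth", f))), 0)
    cross <- vapply(fams, function(f) presenceJaccard(
      keysOf(sprintf("F%02d_M_birth", f)),
      keysOf(sprintf("F%02d_C_birth", 1 + f %% 3))), 0)
    c(within = mean(within), cross = mean(cross))
  }
  j0 <- jaccards(0, 21)
  jhalf <- jaccards(0.5, 22)
  # with rho = 0 mother and child share essentially nothing
  expect_lt(j0[["within"]], 0.05)
  # with rho = 0.5 the within-family overlap clearly exceeds cross-family
  expect_gt(jhalf[["within"]], jhalf[["cross"]] + 0.05)
})

test_that("backbone degree sequences recover the target exponent", {
  set.seed(71)
  alphas <- vapply(1:10, function(i) {
    net <- sampleScaleFreeNetwork(3000, 2.5)
    fitPowerLaw(igraph::degree(networkGraph(net)))@alpha
  }, 0)
  expect_lt(abs(median(alphas) - 2.5), 0.3)
})

test_that("growth series are strictly nested with larger mother networks", {
  gs <- generateGrowthSeries(sizes = c(50, 100, 200), motherSize = 400,
                             seed = 9)
  for (i in 2:3) {
    prev <- networkGraph(gs$child[[i - 1]]); cur <- networkGraph(gs$child[[i]])
    expect_true(all(igraph::V(prev)$name %in% igraph::V(cur)$name))
    elPrev <- igraph::as_edgelist(prev)
    ids <- igraph::get_edge_ids(cur, t(elPrev), error = FALSE)
    expect_true(all(ids > 0))  # every earlier edge persists
  }
  expect_gt(networkSize(gs$mother), networkSize(gs$child[[3]]))
  expect_error(generateGrowthSeries(sizes = c(50, 50, 100)),
               class = "hgtnet_parameter_error")
  expect_error(generateGrowthSeries(sizes = c(50, 100), motherSize = 80),
               class = "hgtnet_parameter_error")
})

test_that("entropy, size and event rate are non-decreasing along a growth series", {
  gs <- generateGrowthSeries(sizes = c(40, 80, 160, 320), motherSize = 600,
                             seed = 10)
  ent <- vapply(gs$child, vonNeumannEntropy, 0)
  sz <- vapply(gs$child, networkSize, 0L)
  H <- vapply(gs$child, function(n)
    sum(igraph::E(networkGraph(n))$weight), 0)
  rate <- vapply(H, function(h) hgtEventRate(h, 500, 1e6)$rate, 0)
  expect_true(all(diff(ent) >= 0))
  expect_true(all(diff(sz) > 0))
  expect_true(all(diff(rate) >= 0))
})
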