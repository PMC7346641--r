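# Seeded synthetic-cohort generator.
#
# Emulates the structure the analyses assume — families with mother/child
# longitudinal sampling or CD/UC/non-IBD patient groups, scale-free
# per-sample networks with a target degree exponent, family-shared and
# group-specific event pools, planted community motifs, co-occurrence
# blocks and in-gene/intergenic fusion events — and records truth tables
# for every planted structure.  All randomness flows from a single root
# seed through named substreams so components are independently
# reproducible.

subSeed <- function(seed, k) {
  as.integer((as.numeric(seed) * 7919 + k * 104729) %% 2147483647)
}

productVocabulary <- function() {
  c("recombinase family protein",
    "plasmid mobilization relaxosome protein Mob",
    "IS110 family transposase",
    "site-specific integrase",
    "conjugal transfer protein TraG",
    "transposase",
    "multidrug SMR transporter",
    "multidrug transporter AcrB",
    "ABC transporter ATP-binding protein",
    "MFS transporter",
    "DNA polymerase III subunit alpha",
    "50S ribosomal protein L2",
    "glycosyl hydrolase family protein",
    "two-component sensor histidine kinase",
    "hypothetical protein")
}

#' Generate a synthetic taxonomy with tiled gene annotations
#'
#' Genomes are assigned a phylum by weighted draw (three genera per phylum,
#' one species per genome) and carry non-overlapping gene intervals tiled
#' along the genome with fixed intergenic gaps, so planted breakpoints can
#' be placed inside genes or in gaps by construction.
#'
#' @param nGenomes number of genomes (>= 2).
#' @param phylumWeights named positive weights summing to 1.
#' @param genomeLength genome length in bp (all genomes).
#' @param geneLength,intergenicGap tiling parameters in bp.
#' @param seed root seed; the same seed reproduces identical output.
#' @return list with `taxonomy` (data.frame genome/species/genus/phylum),
#'   `genes` (data.frame genome/gene_id/start/end/strand/product) and
#'   `genomeLength` (named vector).
#' @export
generateTaxonomy <- function(nGenomes = 300,
                             phylumWeights = c(Firmicutes = 0.4,
                                               Bacteroidetes = 0.3,
                                               Proteobacteria = 0.2,
                                               Actinobacteria = 0.1),
                             genomeLength = 200000,
                             geneLength = 900, intergenicGap = 300,
                             seed = 1) {
  if (nGenomes < 2) hgtStop("nGenomes must be >= 2", "hgtnet_parameter_error")
  if (is.null(names(phylumWeights)) || any(phylumWeights <= 0) ||
      abs(sum(phylumWeights) - 1) > 1e-8)
    hgtStop("phylumWeights must be named, positive and sum to 1",
            "hgtnet_parameter_error")
  set.seed(subSeed(seed, 1))
  genomes <- sprintf("G%04d", seq_len(nGenomes))
  phylum <- sample(names(phylumWeights), nGenomes, replace = TRUE,
                   prob = phylumWeights)
  genus <- paste0(phylum, "_genus", sample.int(3, nGenomes, replace = TRUE))
  species <- paste0(genus, "_sp", seq_len(nGenomes))
  taxonomy <- data.frame(genome = genomes, species = species,
                         genus = genus, phylum = phylum)
  nGenes <- floor((genomeLength - intergenicGap) /
                  (geneLength + intergenicGap))
  starts <- intergenicGap + 1 + (seq_len(nGenes) - 1) * (geneLength + intergenicGap)
  vocab <- productVocabulary()
  genes <- do.call(rbind, lapply(genomes, function(g) {
    data.frame(genome = g,
               gene_id = sprintf("%s_g%03d", g, seq_len(nGenes)),
               start = starts, end = starts + geneLength - 1,
               strand = sample(c("+", "-"), nGenes, replace = TRUE),
               product = sample(vocab, nGenes, replace = TRUE))
  }))
  list(taxonomy = taxonomy, genes = genes,
       genomeLength = setNames(rep(genomeLength, nGenomes), genomes))
}

#' Write gene annotations as GFF3
#' @param genes data.frame as produced by [generateTaxonomy()].
#' @param path output file.
#' @param genomeLength optional named lengths for `##sequence-region` lines.
#' @return `path`, invisibly.
#' @export
writeGFF3 <- function(genes, path, genomeLength = NULL) {
  lines <- "##gff-version 3"
  if (!is.null(genomeLength))
    lines <- c(lines, sprintf("##sequence-region %s 1 %d",
                              names(genomeLength), as.integer(genomeLength)))
  lines <- c(lines, sprintf(
    "%s\thgtnet_sim\tgene\t%d\t%d\t.\t%s\t.\tID=%s;product=%s",
    genes$genome, as.integer(genes$start), as.integer(genes$end),
    genes$strand, genes$gene_id, genes$product))
  writeLines(lines, path)
  invisible(path)
}

#' Sample a scale-free network with a target degree exponent
#'
#' Draws an exact discrete power-law degree sequence at `alpha` and realizes
#' it with the configuration model (simplified to a simple graph; vertices
#' left isolated by simplification are dropped).  Fitted exponents of these
#' networks recover `alpha` closely for sizes of a few hundred and up.
#'
#' @param n number of nodes before simplification.
#' @param alpha target degree exponent (typically in (2, 3)).
#' @param genomes optional genome names to label nodes with (sampled without
#'   replacement; needs `length(genomes) >= n`).
#' @param sampleId sample id for the returned network.
#' @return an [HGTNetwork-class] with unit edge weights.
#' @export
sampleScaleFreeNetwork <- function(n, alpha = 2.5, genomes = NULL,
                                   sampleId = NA_character_) {
  d <- rPowerLaw(n, alpha)
  d[d > n - 1] <- n - 1
  if (sum(d) %% 2 == 1) d[1] <- d[1] + 1
  g <- igraph::simplify(igraph::sample_degseq(d, method = "configuration"))
  nm <- if (is.null(genomes)) sprintf("N%05d", seq_len(n))
        else sample(genomes, n)
  igraph::V(g)$name <- nm
  deg <- igraph::degree(g)
  if (any(deg == 0)) g <- igraph::delete_vertices(g, which(deg == 0))
  igraph::E(g)$weight <- rep(1L, igraph::ecount(g))
  newHGTNetwork(g, sampleId)
}

#' Sample a preferential-attachment (Barabási–Albert) network
#'
#' @param n number of nodes.
#' @param m edges added per step (default 2).
#' @param sampleId sample id for the returned network.
#' @return an [HGTNetwork-class] with unit edge weights.
#' @export
samplePaNetwork <- function(n, m = 2, sampleId = NA_character_) {
  g <- igraph::sample_pa(n, power = 1, m = m, directed = FALSE)
  igraph::V(g)$name <- sprintf("N%05d", seq_len(n))
  igraph::E(g)$weight <- rep(1L, igraph::ecount(g))
  newHGTNetwork(g, sampleId)
}

# pool of unique candidate events (genome pairs with fixed breakpoint
# positions) from a scale-free backbone over the supplied genome names
poolFromBackbone <- function(n, alpha, genomes, genomeLength) {
  net <- sampleScaleFreeNetwork(n, alpha, genomes = genomes)
  el <- igraph::as_edgelist(networkGraph(net))
  lenOf <- function(g) unname(genomeLength[g])
  df <- data.frame(genome_a = el[, 1],
                   pos_a = sampleIntVec(lenOf(el[, 1])),
                   genome_b = el[, 2],
                   pos_b = sampleIntVec(lenOf(el[, 2])))
  canonicalizeEvents(df)
}

sampleIntVec <- function(maxes) {
  floor(runif(length(maxes), min = 1, max = maxes + 1))
}

expandMultiplicity <- function(pool, sampleIdStr, multiplicityProb) {
  if (nrow(pool) == 0L) return(NULL)
  mult <- 1L + rgeom(nrow(pool), multiplicityProb)
  idx <- rep(seq_len(nrow(pool)), mult)
  data.frame(sample_id = sampleIdStr,
             genome_a = pool$genome_a[idx], pos_a = pool$pos_a[idx],
             genome_b = pool$genome_b[idx], pos_b = pool$pos_b[idx])
}

#' Cohort generator configuration
#'
#' Returns the default study conditions for one of the two emulated cohort
#' designs, with any field overridable through `...`:
#'
#' * `"mother-child"`: families with children sampled at five time points
#'   (network sizes growing from birth to three months) and mothers sampled
#'   at three time points with large, flat network sizes; a fraction `rho`
#'   of each child's events is copied from its mother's pool.
#' * `"ibd"`: CD/UC/non-IBD patients sampled longitudinally, each group
#'   with its own event pool and degree exponent.
#'
#' Planted structure (community motifs, co-occurrence blocks, fusion
#' events) is off by default; tests switch on what they probe.
#'
#' @param design `"mother-child"` or `"ibd"`.
#' @param ... overrides of individual fields.
#' @return list of configuration fields (see source for the full set).
#' @export
cohortConfig <- function(design = c("mother-child", "ibd"), ...) {
  design <- match.arg(design)
  base <- list(
    design = design,
    multiplicityProb = 0.6,
    depthRange = c(3e-4, 1e-3),
    nMotifs = 0L, motifSize = 8L, motifSamples = 6L,
    motifBiasPhyla = c("Proteobacteria", "Actinobacteria"),
    motifBias = 0.6,
    nBlocks = 0L, blockSize = 12L, blockSamples = 6L,
    maxBlockOverlap = 0.2,
    nFusionInGene = 0L, nFusionIntergenic = 0L,
    seed = 1L)
  spec <- if (design == "mother-child") {
    list(nFamilies = 6L,
         childTimePoints = c("birth", "2wk", "1mo", "2mo", "3mo"),
         childSizes = c(40L, 55L, 75L, 100L, 130L),
         motherTimePoints = c("gest", "birth", "3mo_post"),
         motherSize = 220L,
         alphaMother = 2.8, alphaChild = 2.4,
         rho = 0.5, motherSampleFrac = 0.85,
         motifGroup = "Child")
  } else {
    list(nCD = 5L, nUC = 4L, nNonIBD = 3L,
         timePoints = c("t1", "t2", "t3", "t4"),
         sizes = c(CD = 110L, UC = 120L, `Non-IBD` = 100L),
         alphas = c(CD = 2.5, UC = 2.7, `Non-IBD` = 2.3),
         groupPoolFrac = 0.4,
         motifGroup = "CD")
  }
  modifyList(c(base, spec), list(...))
}

#' Generate a synthetic cohort with truth tables
#'
#' Emits an event table, sample metadata, a read-depth summary and a truth
#' list covering every planted structure; the same configuration and seed
#' reproduce identical tables.
#'
#' @param config list from [cohortConfig()].
#' @param taxonomy list from [generateTaxonomy()] (taxonomy + genes +
#'   genome lengths).
#' @return list: `events`, `metadata`, `depth` (data.frames ready for the
#'   corresponding readers) and `truth` with elements `edges` (per-sample
#'   multiplicity table), `familyShared` (mother-pool keys copied into each
#'   child sample), `blocks`/`blockSamples`, `motifs`/`motifGenomes`,
#'   `fusions`.
#' @export
generateCohort <- function(config, taxonomy) {
  genomesAll <- taxonomy$taxonomy$genome
  genomeLength <- taxonomy$genomeLength
  nReserve <- config$nMotifs * config$motifSize
  if (nReserve >= length(genomesAll) - 10)
    hgtStop("not enough genomes for the requested motifs",
            "hgtnet_parameter_error")
  reserved <- if (nReserve) utils::tail(genomesAll, nReserve) else character(0)
  avail <- setdiff(genomesAll, reserved)

  set.seed(subSeed(config$seed, 2))
  events <- list()
  meta <- list()
  familyShared <- list()

  if (config$design == "mother-child") {
    maxSize <- max(config$motherSize, config$childSizes)
    if (maxSize > length(avail))
      hgtStop("network sizes exceed available genomes",
              "hgtnet_parameter_error")
    for (f in seq_len(config$nFamilies)) {
      fid <- sprintf("F%02d", f)
      motherPool <- poolFromBackbone(config$motherSize, config$alphaMother,
                                     avail, genomeLength)
      for (tp in config$motherTimePoints) {
        sid <- sprintf("%s_M_%s", fid, tp)
        keep <- sort(sample.int(nrow(motherPool),
                                round(config$motherSampleFrac * nrow(motherPool))))
        events[[sid]] <- expandMultiplicity(motherPool[keep, , drop = FALSE],
                                            sid, config$multiplicityProb)
        meta[[sid]] <- data.frame(sample_id = sid,
                                  individual = paste0(fid, "_M"),
                                  group = "Mother", time_point = tp)
      }
      for (ti in seq_along(config$childTimePoints)) {
        tp <- config$childTimePoints[ti]
        sid <- sprintf("%s_C_%s", fid, tp)
        own <- poolFromBackbone(config$childSizes[ti], config$alphaChild,
                                avail, genomeLength)
        nShare <- ceiling(config$rho * nrow(own))
        nOwn <- nrow(own) - nShare
        shared <- motherPool[sample.int(nrow(motherPool),
                                        min(nShare, nrow(motherPool))), ,
                             drop = FALSE]
        pool <- rbind(own[seq_len(nOwn), , drop = FALSE], shared)
        events[[sid]] <- expandMultiplicity(pool, sid,
                                            config$multiplicityProb)
        familyShared[[sid]] <- eventKey(shared, 100)
        meta[[sid]] <- data.frame(sample_id = sid,
                                  individual = paste0(fid, "_C"),
                                  group = "Child", time_point = tp)
      }
    }
  } else {
    groups <- c(rep("CD", config$nCD), rep("UC", config$nUC),
                rep("Non-IBD", config$nNonIBD))
    if (max(config$sizes) > length(avail))
      hgtStop("network sizes exceed available genomes",
              "hgtnet_parameter_error")
    groupPools <- lapply(unique(groups), function(g)
      poolFromBackbone(2L * config$sizes[[g]], config$alphas[[g]],
                       avail, genomeLength))
    names(groupPools) <- unique(groups)
    for (p in seq_along(groups)) {
      grp <- groups[p]
      pid <- sprintf("P%02d", p)
      for (tp in config$timePoints) {
        sid <- sprintf("%s_%s", pid, tp)
        own <- poolFromBackbone(config$sizes[[grp]], config$alphas[[grp]],
                                avail, genomeLength)
        nPool <- ceiling(config$groupPoolFrac * nrow(own))
        gp <- groupPools[[grp]]
        fromPool <- gp[sample.int(nrow(gp), min(nPool, nrow(gp))), ,
                       drop = FALSE]
        pool <- rbind(own[seq_len(nrow(own) - nrow(fromPool)), , drop = FALSE],
                      fromPool)
        events[[sid]] <- expandMultiplicity(pool, sid,
                                            config$multiplicityProb)
        meta[[sid]] <- data.frame(sample_id = sid, individual = pid,
                                  group = grp, time_point = tp)
      }
    }
  }

  metadata <- do.call(rbind, meta)
  rownames(metadata) <- NULL

  # planted co-occurrence blocks: identical event sets injected into a
  # designated sample set
  set.seed(subSeed(config$seed, 3))
  blocks <- NULL; blockSamples <- NULL
  if (config$nBlocks > 0) {
    blockRows <- list(); bs <- list()
    chosenSets <- list()
    # sample sets with bounded pairwise overlap so blocks stay separable
    drawBlockSamples <- function() {
      best <- NULL; bestOv <- Inf
      for (try in 1:200) {
        cand <- sample(metadata$sample_id, config$blockSamples)
        ov <- if (length(chosenSets) == 0) 0 else
          max(vapply(chosenSets, function(s)
            length(intersect(s, cand)) / length(union(s, cand)), 0))
        if (ov <= config$maxBlockOverlap) return(cand)
        if (ov < bestOv) { best <- cand; bestOv <- ov }
      }
      best
    }
    for (b in seq_len(config$nBlocks)) {
      ga <- sample(avail, config$blockSize)
      gb <- sample(setdiff(avail, ga), config$blockSize)
      blk <- canonicalizeEvents(data.frame(
        genome_a = ga, pos_a = sampleIntVec(unname(genomeLength[ga])),
        genome_b = gb, pos_b = sampleIntVec(unname(genomeLength[gb]))))
      sids <- drawBlockSamples()
      chosenSets[[b]] <- sids
      for (sid in sids)
        events[[paste0("blk", b, "_", sid)]] <-
          cbind(data.frame(sample_id = sid), blk)
      blockRows[[b]] <- data.frame(key = eventKey(blk, 100), block = b)
      bs[[b]] <- data.frame(block = b, sample_id = sids)
    }
    blocks <- do.call(rbind, blockRows)
    blockSamples <- do.call(rbind, bs)
  }

  # planted community motifs: cliques over reserved genomes, biased toward
  # the configured phyla, injected into samples of the motif group
  set.seed(subSeed(config$seed, 4))
  motifs <- NULL; motifGenomes <- NULL
  if (config$nMotifs > 0) {
    phylumOf <- setNames(taxonomy$taxonomy$phylum, taxonomy$taxonomy$genome)
    resBias <- reserved[phylumOf[reserved] %in% config$motifBiasPhyla]
    resOther <- setdiff(reserved, resBias)
    mg <- list(); mrows <- list()
    pool <- metadata$sample_id[metadata$group == config$motifGroup]
    for (m in seq_len(config$nMotifs)) {
      nBias <- min(round(config$motifBias * config$motifSize), length(resBias))
      gs <- c(sample(resBias, nBias),
              sample(resOther, config$motifSize - nBias))
      resBias <- setdiff(resBias, gs); resOther <- setdiff(resOther, gs)
      pairs <- t(combn(gs, 2))
      motifEvents <- canonicalizeEvents(data.frame(
        genome_a = pairs[, 1],
        pos_a = sampleIntVec(unname(genomeLength[pairs[, 1]])),
        genome_b = pairs[, 2],
        pos_b = sampleIntVec(unname(genomeLength[pairs[, 2]]))))
      sids <- sample(pool, min(config$motifSamples, length(pool)))
      for (sid in sids)
        events[[paste0("motif", m, "_", sid)]] <-
          cbind(data.frame(sample_id = sid), motifEvents)
      mg[[m]] <- gs
      mrows[[m]] <- data.frame(motif = m, sample_id = sids)
    }
    motifs <- do.call(rbind, mrows)
    motifGenomes <- mg
  }

  # planted fusion events: both breakpoints inside genes, or both in
  # intergenic gaps (positions 1..gap precede the first gene by construction)
  set.seed(subSeed(config$seed, 5))
  fusions <- NULL
  nf <- config$nFusionInGene + config$nFusionIntergenic
  if (nf > 0) {
    fusions <- generatePlantedFusions(taxonomy, config$nFusionInGene,
                                      config$nFusionIntergenic,
                                      metadata$sample_id)
    for (i in seq_len(nrow(fusions)))
      events[[paste0("fus", i)]] <- fusions[i, c("sample_id", "genome_a",
                                                 "pos_a", "genome_b", "pos_b")]
  }

  eventTable <- do.call(rbind, events)
  rownames(eventTable) <- NULL
  eventTable <- canonicalizeEvents(eventTable)

  truthEdges <- aggregate(list(weight = rep(1L, nrow(eventTable))),
                          by = list(sample_id = eventTable$sample_id,
                                    genome_a = eventTable$genome_a,
                                    genome_b = eventTable$genome_b),
                          FUN = sum)

  # per-sample depth: r_i ~ Poisson(depth * l_i) over the genomes linked by
  # events in the sample (the set entering the event-rate denominator)
  set.seed(subSeed(config$seed, 6))
  depth <- do.call(rbind, lapply(unique(eventTable$sample_id), function(sid) {
    sub <- eventTable[eventTable$sample_id == sid, ]
    gs <- sort(unique(c(sub$genome_a, sub$genome_b)))
    target <- runif(1, config$depthRange[1], config$depthRange[2])
    reads <- rpois(length(gs), target * genomeLength[gs])
    if (sum(reads) == 0) reads[1] <- 1L
    data.frame(sample_id = sid, genome = gs, reads = reads,
               length = unname(genomeLength[gs]))
  }))
  rownames(depth) <- NULL

  list(events = eventTable, metadata = metadata, depth = depth,
       truth = list(edges = truthEdges,
                    familyShared = familyShared,
                    blocks = blocks, blockSamples = blockSamples,
                    motifs = motifs, motifGenomes = motifGenomes,
                    fusions = fusions),
       config = config)
}

# planted fusion truth events; exported separately so the fusion stage can
# be validated in isolation from the cohort machinery

#' Planted fusion events with in-gene / intergenic truth flags
#'
#' @param taxonomy list from [generateTaxonomy()].
#' @param nInGene events with both breakpoints inside annotated genes.
#' @param nIntergenic events with both breakpoints in intergenic gaps.
#' @param sampleIds sample ids to assign events to (recycled at random).
#' @return data.frame of events plus logical column `in_gene`.
#' @export
generatePlantedFusions <- function(taxonomy, nInGene, nIntergenic,
                                   sampleIds = "sim") {
  genes <- taxonomy$genes
  if (is.null(genes))
    hgtStop("taxonomy carries no gene annotations", "hgtnet_parameter_error")
  gap <- min(genes$start) - 1  # positions 1..gap are intergenic by tiling
  genomes <- unique(genes$genome)
  onePos <- function(inGene, g) {
    if (inGene) {
      rows <- which(genes$genome == g)
      r <- rows[sample.int(length(rows), 1)]
      sample(genes$start[r]:genes$end[r], 1)
    } else sample.int(gap, 1)
  }
  n <- nInGene + nIntergenic
  inGene <- rep(c(TRUE, FALSE), c(nInGene, nIntergenic))
  rows <- lapply(seq_len(n), function(i) {
    gs <- sample(genomes, 2)
    data.frame(sample_id = sample(sampleIds, 1),
               genome_a = gs[1], pos_a = onePos(inGene[i], gs[1]),
               genome_b = gs[2], pos_b = onePos(inGene[i], gs[2]),
               in_gene = inGene[i])
  })
  canonicalizeEvents(do.call(rbind, rows))
}

#' Write a generated cohort to a directory of flat files
#'
#' @param cohort list from [generateCohort()].
#' @param dir output directory (created if needed).
#' @param taxonomy optional list from [generateTaxonomy()]; when given,
#'   `taxonomy.tsv` and `genes.gff3` are written alongside.
#' @return named vector of file paths.
#' @export
writeCohort <- function(cohort, dir, taxonomy = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(events = file.path(dir, "events.tsv"),
             metadata = file.path(dir, "metadata.tsv"),
             depth = file.path(dir, "depth.tsv"))
  write.table(cohort$events, paths["events"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(cohort$metadata, paths["metadata"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(cohort$depth, paths["depth"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  if (!is.null(taxonomy)) {
    paths <- c(paths, taxonomy = file.path(dir, "taxonomy.tsv"),
               annotations = file.path(dir, "genes.gff3"))
    write.table(taxonomy$taxonomy, paths["taxonomy"], sep = "\t",
                quote = FALSE, row.names = FALSE)
    writeGFF3(taxonomy$genes, paths["annotations"], taxonomy$genomeLength)
  }
  paths
}

#' Nested growth series of a child network plus a mother network
#'
#' One preferential-attachment graph is grown to the final size and
#' snapshotted at the requested sizes, so each time point's network is a
#' supergraph of the previous (nodes and edges only added); edge
#' multiplicities are drawn once on the full graph and inherited by the
#' snapshots.  The mother network is larger than all child snapshots.
#'
#' @param sizes strictly increasing child network sizes.
#' @param motherSize mother network size (> max(sizes)).
#' @param m preferential-attachment edges per step.
#' @param multiplicityProb geometric parameter for event multiplicities.
#' @param seed root seed.
#' @return list: `child` (list of nested [HGTNetwork-class]), `mother`,
#'   `sizes`.
#' @export
generateGrowthSeries <- function(sizes = c(50, 100, 200, 400, 800),
                                 motherSize = 1200, m = 2,
                                 multiplicityProb = 0.6, seed = 1) {
  if (any(diff(sizes) <= 0))
    hgtStop("sizes must be strictly increasing", "hgtnet_parameter_error")
  if (motherSize <= max(sizes))
    hgtStop("motherSize must exceed the largest child size",
            "hgtnet_parameter_error")
  set.seed(subSeed(seed, 7))
  g <- igraph::sample_pa(max(sizes), power = 1, m = m, directed = FALSE)
  igraph::V(g)$name <- sprintf("G%05d", seq_len(max(sizes)))
  igraph::E(g)$weight <- 1L + rgeom(igraph::ecount(g), multiplicityProb)
  child <- lapply(seq_along(sizes), function(i) {
    sub <- igraph::induced_subgraph(g, seq_len(sizes[i]))
    newHGTNetwork(sub, sprintf("child_t%d", i))
  })
  gm <- igraph::sample_pa(motherSize, power = 1, m = m, directed = FALSE)
  igraph::V(gm)$name <- sprintf("G%05d", seq_len(motherSize))
  igraph::E(gm)$weight <- 1L + rgeom(igraph::ecount(gm), multiplicityProb)
  list(child = child, mother = newHGTNetwork(gm, "mother"), sizes = sizes)
}
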