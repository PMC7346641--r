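# Community detection (Leiden), cross-sample clustering of communities into
# HCCs, bias-corrected cluster labeling, and taxonomic composition profiles.

#' Detect communities in one HGT network
#'
#' Runs the Leiden algorithm (modularity objective, event-count edge
#' weights) on the network.  The partition is deterministic for a fixed
#' seed, covers every node, and its modularity is no worse than the trivial
#' one-block partition.
#'
#' @param network non-empty [HGTNetwork-class].
#' @param resolution Leiden resolution parameter (default 1).
#' @param seed integer RNG seed controlling the refinement.
#' @param nIterations Leiden iterations (default 5).
#' @return data.frame with columns `sample_id`, `community` (integer id) and
#'   `genome`, one row per node.
#' @export
detectCommunities <- function(network, resolution = 1, seed = 1L,
                              nIterations = 5L) {
  g <- networkGraph(network)
  if (igraph::vcount(g) == 0)
    hgtStop("cannot detect communities in an empty network",
            "hgtnet_validation_error")
  set.seed(seed)
  cl <- igraph::cluster_leiden(g, objective_function = "modularity",
                               resolution = resolution,
                               n_iterations = nIterations,
                               weights = igraph::E(g)$weight)
  memb <- igraph::membership(cl)
  if (igraph::ecount(g) > 0) {
    q <- igraph::modularity(g, memb, weights = igraph::E(g)$weight)
    q1 <- igraph::modularity(g, rep(1L, igraph::vcount(g)),
                             weights = igraph::E(g)$weight)
    if (q < q1 - 1e-12) memb[] <- 1L  # never worse than the trivial partition
  }
  data.frame(sample_id = sampleId(network),
             community = as.integer(memb),
             genome = igraph::V(g)$name, row.names = NULL)
}

#' Detect communities in every network of a cohort
#'
#' @param networks list of [HGTNetwork-class].
#' @inheritParams detectCommunities
#' @return row-bound community table across samples.
#' @export
collectCommunities <- function(networks, resolution = 1, seed = 1L) {
  do.call(rbind, lapply(networks, detectCommunities,
                        resolution = resolution, seed = seed))
}

# canonical ordering of communities: by sorted-member signature then sample,
# so downstream clustering is invariant to input order
communityList <- function(communityTable) {
  key <- paste(communityTable$sample_id, communityTable$community, sep = "\r")
  members <- split(communityTable$genome, key)
  sampleIds <- vapply(strsplit(names(members), "\r", fixed = TRUE), `[[`, "", 1L)
  sig <- vapply(members, function(m) paste(sort(m), collapse = ","), "")
  ord <- order(sig, sampleIds)
  list(members = lapply(members[ord], sort),
       sampleId = sampleIds[ord], signature = sig[ord])
}

jaccardDistanceMatrix <- function(sets) {
  n <- length(sets)
  allItems <- unique(unlist(sets))
  M <- matrix(0L, nrow = length(allItems), ncol = n)
  for (i in seq_len(n)) M[match(sets[[i]], allItems), i] <- 1L
  inter <- crossprod(M)
  sizes <- diag(inter)
  uni <- outer(sizes, sizes, "+") - inter
  D <- 1 - inter / uni
  diag(D) <- 0
  D
}

# static cut at cutHeight on an average-linkage dendrogram, followed by the
# minimum-size gate: classes below minSize go to the unclustered pool (0)
cutSizeGated <- function(D, cutHeight, minSize) {
  hc <- hclust(as.dist(D), method = "average")
  # average linkage is monotone; round away sub-1e-10 floating-point
  # inversions that cutree(h=) would reject
  hc$height <- cummax(round(hc$height, 10))
  cl <- cutree(hc, h = cutHeight)
  sizes <- table(cl)
  small <- as.integer(names(sizes)[sizes < minSize])
  cl[cl %in% small] <- 0L
  # relabel surviving clusters 1..K in order of first appearance
  keep <- cl != 0L
  cl[keep] <- as.integer(factor(cl[keep], levels = unique(cl[keep])))
  cl
}

#' Cluster communities across samples into HGT community clusters (HCCs)
#'
#' The distance between two communities is one minus the Jaccard similarity
#' of their member genome sets.  Average-linkage hierarchical clustering is
#' cut at `maxDistance`; clusters with fewer than `minSize` member
#' communities are moved to the unclustered pool (cluster id 0).  Every
#' community is assigned exactly once, and the assignment is invariant to
#' the order of the input rows (communities are canonically ordered before
#' clustering).
#'
#' @param communityTable data.frame from [collectCommunities()].
#' @param maxDistance dendrogram cut height (default 0.6).
#' @param minSize minimum communities per cluster (default 2; a cluster of
#'   one community is noise).
#' @return data.frame with one row per community: `sample_id`, `community`,
#'   `cluster` (0 = unclustered) and `members` (comma-joined genome set).
#' @export
clusterCommunities <- function(communityTable, maxDistance = 0.6,
                               minSize = 2L) {
  cl <- communityList(communityTable)
  if (length(cl$members) < 2L)
    hgtStop("need >= 2 communities to cluster", "hgtnet_insufficient_data")
  D <- jaccardDistanceMatrix(cl$members)
  assignment <- cutSizeGated(D, maxDistance, minSize)
  commIds <- vapply(strsplit(names(cl$members), "\r", fixed = TRUE),
                    `[[`, "", 2L)
  data.frame(sample_id = cl$sampleId,
             community = as.integer(commIds),
             cluster = assignment,
             members = vapply(cl$members, paste, "", collapse = ","),
             row.names = NULL)
}

#' Bias-corrected cluster label
#'
#' A cluster drawn from groups of unequal size would be dominated by the
#' larger group if labels were assigned by raw majority.  The label is
#' therefore the group maximizing `COUNT(label) / num(label)`, the count of
#' member communities/events carrying the label relative to the number of
#' samples with that label in the dataset.  An exact tie yields
#' `"ambiguous"`.
#'
#' @param counts named numeric: member count per label (>= 0, not all 0).
#' @param num named numeric: samples per label in the dataset (all >= 1);
#'   must cover the names of `counts`.
#' @return single character label, or `"ambiguous"` on a tie.
#' @examples
#' labelCluster(c(`Non-IBD` = 10, IBD = 20), c(`Non-IBD` = 38, IBD = 109))
#' @export
labelCluster <- function(counts, num) {
  if (length(num) < 2L)
    hgtStop("need counts for >= 2 labels", "hgtnet_parameter_error")
  if (any(num <= 0))
    hgtStop("every num(label) must be positive", "hgtnet_parameter_error")
  extra <- setdiff(names(counts), names(num))
  if (length(extra))
    hgtStop(paste0("labels missing from num: ", paste(extra, collapse = ", ")),
            "hgtnet_parameter_error")
  full <- setNames(numeric(length(num)), names(num))
  full[names(counts)] <- counts
  if (all(full == 0))
    hgtStop("all counts are zero", "hgtnet_validation_error")
  scores <- full / num
  top <- which(scores == max(scores))
  if (length(top) > 1L) "ambiguous" else names(scores)[top]
}

#' Taxonomic composition of a genome multiset
#'
#' @param genomes genome accessions *with multiplicity* (e.g. the
#'   concatenated member genome sets of a cluster's communities).
#' @param taxonomy data.frame from [readTaxonomy()]; unresolvable accessions
#'   are an error naming the accession.
#' @param rank `"phylum"` or `"genus"`.
#' @return named numeric vector of fractions, sorted decreasing; sums to 1.
#' @export
clusterComposition <- function(genomes, taxonomy, rank = c("phylum", "genus")) {
  rank <- match.arg(rank)
  if (length(genomes) == 0)
    hgtStop("empty genome set", "hgtnet_validation_error")
  taxa <- taxonomyLookup(taxonomy, genomes, rank)
  tab <- table(taxa)
  fr <- setNames(as.numeric(tab) / length(taxa), names(tab))
  sort(fr, decreasing = TRUE)
}

#' Compare a taxon's per-cluster fractions between two groups of clusters
#'
#' Two-sided pooled-variance Student's t-test on the fractions of `taxon`
#' across the clusters of each side; a profile lacking the taxon contributes
#' a fraction of 0.
#'
#' @param profilesA,profilesB lists of composition profiles (named fraction
#'   vectors as from [clusterComposition()]); >= 2 per side.
#' @param taxon taxon name to compare.
#' @return list: `pValue`, `tStatistic`, `meanA`, `meanB`, `direction`
#'   (`"A>B"`, `"B>A"` or `"equal"`).
#' @export
compareCompositions <- function(profilesA, profilesB, taxon) {
  frac <- function(p) if (taxon %in% names(p)) unname(p[[taxon]]) else 0
  a <- vapply(profilesA, frac, 0)
  b <- vapply(profilesB, frac, 0)
  if (length(a) < 2L || length(b) < 2L)
    hgtStop("need >= 2 clusters per side", "hgtnet_insufficient_data")
  tt <- t.test(a, b, var.equal = TRUE)
  list(pValue = tt$p.value, tStatistic = unname(tt$statistic),
       meanA = mean(a), meanB = mean(b),
       direction = if (mean(a) > mean(b)) "A>B"
                   else if (mean(a) < mean(b)) "B>A" else "equal")
}

#' Full HCC analysis: cluster, label and profile communities
#'
#' Clusters a cross-sample community table, labels every surviving cluster
#' with the bias-corrected rule ([labelCluster()]; a community carries its
#' sample's group label, `num` counts samples per group over the whole
#' metadata), and profiles each cluster's concatenated genome multiset.
#'
#' @param communityTable from [collectCommunities()].
#' @param metadata data.frame with `sample_id` and `group`.
#' @param taxonomy optional taxonomy for composition profiles.
#' @param maxDistance,minSize see [clusterCommunities()].
#' @param rank composition rank (default phylum).
#' @return list: `membership` (per-community assignment), `clusters`
#'   (cluster_id, label, nCommunities), `composition` (named list of
#'   fraction vectors, when taxonomy given).
#' @export
communityClusters <- function(communityTable, metadata, taxonomy = NULL,
                              maxDistance = 0.6, minSize = 2L,
                              rank = c("phylum", "genus")) {
  rank <- match.arg(rank)
  membership <- clusterCommunities(communityTable, maxDistance, minSize)
  groupOf <- setNames(metadata$group, metadata$sample_id)
  if (anyNA(groupOf[membership$sample_id]))
    hgtStop("community sample ids missing from metadata",
            "hgtnet_validation_error")
  num <- table(metadata$group)
  num <- setNames(as.numeric(num), names(num))
  ids <- sort(unique(membership$cluster[membership$cluster > 0]))
  clusters <- do.call(rbind, lapply(ids, function(cid) {
    rows <- membership[membership$cluster == cid, , drop = FALSE]
    counts <- table(groupOf[rows$sample_id])
    lab <- labelCluster(setNames(as.numeric(counts), names(counts)), num)
    data.frame(cluster_id = cid, label = lab, nCommunities = nrow(rows))
  }))
  composition <- NULL
  if (!is.null(taxonomy)) {
    composition <- lapply(ids, function(cid) {
      rows <- membership[membership$cluster == cid, , drop = FALSE]
      genomes <- unlist(strsplit(rows$members, ",", fixed = TRUE))
      clusterComposition(genomes, taxonomy, rank)
    })
    names(composition) <- as.character(ids)
  }
  list(membership = membership, clusters = clusters,
       composition = composition)
}
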