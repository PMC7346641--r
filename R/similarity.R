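# Pairwise network similarity metrics and within/between group testing.

#' Jaccard similarity of node sets
#'
#' @param netA,netB [HGTNetwork-class] objects.
#' @return `|A intersect B| / |A union B|`; comparing two empty networks is
#'   an error rather than 0/0.
#' @export
nodeJaccard <- function(netA, netB) {
  a <- networkNodes(netA); b <- networkNodes(netB)
  if (length(a) == 0 && length(b) == 0)
    hgtStop("similarity undefined: both networks are empty",
            "hgtnet_undefined_similarity")
  length(intersect(a, b)) / length(union(a, b))
}

nodeProperty <- function(net, property) {
  g <- networkGraph(net)
  v <- switch(property,
    degree = igraph::degree(g),
    pagerank = igraph::page_rank(g, damping = 0.85, weights = NA)$vector,
    clustering_coefficient = {
      cc <- igraph::transitivity(g, type = "local", isolates = "zero")
      names(cc) <- igraph::V(g)$name
      # nodes of degree < 2 have no defined triangle fraction; use 0
      cc[is.nan(cc)] <- 0
      cc
    },
    hgtStop(paste0("unknown topology property: ", property),
            "hgtnet_parameter_error"))
  if (is.null(names(v))) names(v) <- igraph::V(g)$name
  v
}

#' Spearman correlation of a topological property over shared nodes
#'
#' For the nodes present in both networks, the property (degree, PageRank
#' with damping 0.85, or local clustering coefficient; all unweighted) is
#' computed per network *before* restriction to the shared set, then the
#' Spearman rank correlation of the two value lists is returned.
#'
#' @param netA,netB [HGTNetwork-class] objects.
#' @param property `"degree"`, `"pagerank"` or `"clustering_coefficient"`.
#' @return correlation in `[-1, 1]`.  Fewer than 3 shared nodes is an
#'   insufficient-overlap error; zero variance in either ranking is an
#'   undefined-correlation error.
#' @export
topologyCorrelation <- function(netA, netB,
                                property = c("degree", "pagerank",
                                             "clustering_coefficient")) {
  property <- match.arg(property)
  shared <- intersect(networkNodes(netA), networkNodes(netB))
  if (length(shared) < 3L)
    hgtStop(sprintf("only %d shared node(s); rank correlation needs >= 3",
                    length(shared)), "hgtnet_insufficient_overlap")
  va <- nodeProperty(netA, property)[shared]
  vb <- nodeProperty(netB, property)[shared]
  if (length(unique(va)) == 1L || length(unique(vb)) == 1L)
    hgtStop("zero variance in a ranking: correlation undefined",
            "hgtnet_undefined_correlation")
  cor(va, vb, method = "spearman")
}

#' Combined network similarity: node Jaccard times degree correlation
#'
#' The product captures both membership overlap and topological consistency.
#' When the degree correlation is undefined (fewer than 3 shared nodes, or a
#' tied ranking), the combined similarity is defined as 0 and flagged via
#' the `"degenerate"` attribute instead of dropping the pair.
#'
#' @param netA,netB [HGTNetwork-class] objects.
#' @return numeric in `[-1, 1]` with attribute `degenerate` (logical).
#' @export
combinedSimilarity <- function(netA, netB) {
  j <- nodeJaccard(netA, netB)
  dc <- tryCatch(topologyCorrelation(netA, netB, "degree"),
                 hgtnet_insufficient_overlap = function(e) NA_real_,
                 hgtnet_undefined_correlation = function(e) NA_real_)
  if (is.na(dc))
    return(structure(0, degenerate = TRUE))
  structure(j * dc, degenerate = FALSE)
}

#' Student's t-test of within-group vs between-group similarity values
#'
#' @param within,between numeric similarity values for pairs in the same
#'   group (family/individual) and in different groups; each needs >= 2
#'   values.
#' @return list with the pooled-variance two-sided `tStatistic` and
#'   `pValue`, a one-sided `pGreater` for within > between, the class means
#'   and sizes.
#' @export
withinBetweenTest <- function(within, between) {
  if (length(within) < 2L || length(between) < 2L)
    hgtStop("need >= 2 similarity values in each class",
            "hgtnet_insufficient_data")
  tt <- t.test(within, between, var.equal = TRUE)
  tg <- t.test(within, between, var.equal = TRUE, alternative = "greater")
  list(tStatistic = unname(tt$statistic), pValue = tt$p.value,
       pGreater = tg$p.value,
       meanWithin = mean(within), meanBetween = mean(between),
       nWithin = length(within), nBetween = length(between))
}

#' All pairwise similarities between a set of networks
#'
#' Convenience sweep used by [runPipeline()]: computes the requested metrics
#' for every unordered pair.  Pairs where a correlation metric is undefined
#' get `NA` (or 0 for `"combined"`, which carries its own degenerate rule).
#'
#' @param networks named list of [HGTNetwork-class] (names = sample ids, or
#'   taken from the networks).
#' @param metrics subset of `c("jaccard", "degree", "pagerank",
#'   "clustcoef", "combined")`.
#' @return long data.frame: `sample_a`, `sample_b`, `metric`, `value`.
#' @export
pairwiseSimilarity <- function(networks,
                               metrics = c("jaccard", "degree", "combined")) {
  ok <- c("jaccard", "degree", "pagerank", "clustcoef", "combined")
  bad <- setdiff(metrics, ok)
  if (length(bad))
    hgtStop(paste0("unknown metric(s): ", paste(bad, collapse = ", ")),
            "hgtnet_parameter_error")
  if (is.null(names(networks)))
    names(networks) <- vapply(networks, sampleId, "")
  if (length(networks) < 2L)
    hgtStop("need >= 2 networks", "hgtnet_insufficient_data")
  prop <- c(degree = "degree", pagerank = "pagerank",
            clustcoef = "clustering_coefficient")
  pairs <- combn(names(networks), 2L)
  rows <- lapply(seq_len(ncol(pairs)), function(i) {
    a <- networks[[pairs[1, i]]]; b <- networks[[pairs[2, i]]]
    vals <- vapply(metrics, function(m) {
      if (m == "jaccard") nodeJaccard(a, b)
      else if (m == "combined") as.numeric(combinedSimilarity(a, b))
      else tryCatch(topologyCorrelation(a, b, prop[[m]]),
                    hgtnet_error = function(e) NA_real_)
    }, 0)
    data.frame(sample_a = pairs[1, i], sample_b = pairs[2, i],
               metric = metrics, value = vals, row.names = NULL)
  })
  do.call(rbind, rows)
}
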