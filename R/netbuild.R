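# Network construction, network size, HGT event rate, group event overlap.

#' Build the HGT network of one sample
#'
#' Genomes linked by at least one HGT event become nodes; the weight of an
#' edge is the number of HGT events linking its two genomes.  The network is
#' undirected (breakpoint callers do not orient donor vs recipient).
#'
#' @param events canonical event data.frame for a single sample (see
#'   [readEvents()]).  An empty table yields an empty network.
#' @param sampleId optional sample id; defaults to the (unique) `sample_id`
#'   of `events`.  Mixed sample ids are a validation error.
#' @return an [HGTNetwork-class].
#' @examples
#' ev <- data.frame(sample_id = "s1",
#'                  genome_a = c("gA", "gA", "gA", "gB"),
#'                  pos_a = c(10, 10, 30, 5),
#'                  genome_b = c("gB", "gB", "gB", "gC"),
#'                  pos_b = c(100, 100, 200, 7))
#' net <- buildNetwork(ev)
#' networkSize(net)  # 3
#' @export
buildNetwork <- function(events, sampleId = NULL) {
  events <- canonicalizeEvents(events)
  ids <- unique(events$sample_id)
  if (length(ids) > 1L)
    hgtStop(paste0("events span multiple samples: ",
                   paste(ids, collapse = ", ")), "hgtnet_validation_error")
  if (is.null(sampleId))
    sampleId <- if (length(ids)) ids else NA_character_
  if (nrow(events) == 0L)
    return(newHGTNetwork(igraph::make_empty_graph(0, directed = FALSE),
                         sampleId))
  if (any(events$genome_a == events$genome_b))
    hgtStop("events must link two different genomes",
            "hgtnet_validation_error")
  tab <- aggregate(list(weight = rep(1L, nrow(events))),
                   by = list(u = events$genome_a, v = events$genome_b), FUN = sum)
  g <- igraph::graph_from_data_frame(tab[, c("u", "v")], directed = FALSE)
  igraph::E(g)$weight <- tab$weight
  newHGTNetwork(g, sampleId)
}

#' Number of nodes in an HGT network
#' @param network an [HGTNetwork-class]
#' @return integer node count
#' @export
networkSize <- function(network) {
  as.integer(igraph::vcount(networkGraph(network)))
}

#' Normalized HGT event rate
#'
#' The raw event count of a sample depends on sequencing effort, so it is
#' normalized by the average read depth over the genomes linked by events:
#' `rate = ln( H / (sum(reads) / sum(lengths)) )`, a dimensionless quantity
#' on the natural-log scale.
#'
#' @param H number of HGT events detected in the sample (>= 1).
#' @param reads per-genome uniquely mapped read counts (>= 0, summing > 0).
#' @param lengths per-genome lengths in bp (>= 1), parallel to `reads`.
#' @return list with elements `H`, `depth` (reads/bp) and `rate`.
#' @examples
#' hgtEventRate(100, 500, 1e6)$rate  # log(2e5)
#' @export
hgtEventRate <- function(H, reads, lengths) {
  if (length(reads) != length(lengths))
    hgtStop("reads and lengths must be parallel vectors",
            "hgtnet_parameter_error")
  if (!is.numeric(H) || length(H) != 1L || H < 1)
    hgtStop("event rate undefined for H < 1", "hgtnet_undefined_rate")
  if (any(lengths < 1))
    hgtStop("genome lengths must be >= 1", "hgtnet_validation_error")
  if (sum(reads) < 1)
    hgtStop("event rate undefined when no reads are mapped",
            "hgtnet_undefined_rate")
  depth <- sum(reads) / sum(lengths)
  list(H = H, depth = depth, rate = log(H / depth))
}

#' Per-sample event rates from an event table and a depth summary
#'
#' @param events event data.frame covering one or more samples.
#' @param depth depth data.frame from [readDepth()].
#' @return data.frame with columns `sample_id`, `H`, `depth`, `rate`.
#' @export
eventRateTable <- function(events, depth) {
  samples <- unique(events$sample_id)
  out <- lapply(samples, function(s) {
    H <- sum(events$sample_id == s)
    d <- depth[depth$sample_id == s, , drop = FALSE]
    if (nrow(d) == 0L)
      hgtStop(paste0("no depth records for sample ", s),
              "hgtnet_validation_error")
    r <- hgtEventRate(H, d$reads, d$length)
    data.frame(sample_id = s, H = H, depth = r$depth, rate = r$rate)
  })
  do.call(rbind, out)
}

#' Venn-cell overlap of HGT events between groups
#'
#' Events are identified across samples by their canonical binned keys
#' ([eventKey()]) and deduplicated within each group, so cell counts are
#' counts of distinct events.  All non-empty subsets of groups are reported
#' (including empty cells).
#'
#' @param events event data.frame spanning all samples.
#' @param groups named character vector mapping `sample_id` to group, or a
#'   metadata data.frame with `sample_id` and `group` columns.
#' @param binSize coordinate bin width for event identity (default 100).
#' @return data.frame with columns `cell` (group names joined by `&`),
#'   `groups` (number of groups in the cell) and `count`.
#' @export
groupEventOverlap <- function(events, groups, binSize = 100) {
  if (is.data.frame(groups))
    groups <- setNames(groups$group, groups$sample_id)
  grp <- groups[events$sample_id]
  if (anyNA(grp))
    hgtStop(paste0("samples missing from group mapping: ",
                   paste(unique(events$sample_id[is.na(grp)]), collapse = ", ")),
            "hgtnet_validation_error")
  gnames <- sort(unique(grp))
  if (length(gnames) < 2L)
    hgtStop("overlap requires at least two groups", "hgtnet_parameter_error")
  keys <- eventKey(events, binSize)
  keySets <- lapply(gnames, function(g) unique(keys[grp == g]))
  names(keySets) <- gnames
  allKeys <- unique(unlist(keySets))
  member <- vapply(keySets, function(s) allKeys %in% s,
                   logical(length(allKeys)))
  if (length(allKeys) == 1L) member <- matrix(member, nrow = 1L,
                                              dimnames = list(NULL, gnames))
  cellOf <- apply(member, 1L, function(row)
    paste(gnames[row], collapse = "&"))
  cells <- unlist(lapply(seq_along(gnames), function(k)
    apply(combn(gnames, k), 2L, paste, collapse = "&")))
  counts <- vapply(cells, function(cl) sum(cellOf == cl), 0L)
  data.frame(cell = cells,
             groups = lengths(strsplit(cells, "&", fixed = TRUE)),
             count = as.integer(counts), row.names = NULL)
}
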