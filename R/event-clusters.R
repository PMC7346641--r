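# HGT event clusters (HECs): events grouped by the samples they occur in.

#' Presence profiles of HGT events across samples
#'
#' Events are identified by their canonical binned keys; an event occurring
#' several times in one sample counts once in its presence set (presence,
#' not abundance).
#'
#' @param events event table spanning all samples.
#' @param binSize key bin width (default 100).
#' @return named list mapping event key to the character vector of samples
#'   containing it.
#' @export
eventPresences <- function(events, binSize = 100) {
  keys <- eventKey(events, binSize)
  pairs <- unique(data.frame(key = keys, sample_id = events$sample_id))
  split(pairs$sample_id, pairs$key)
}

#' Drop events seen in fewer than a minimum number of samples
#'
#' Events that show in less than `minSamples` samples are filtered out;
#' equality is retained.  Typical thresholds: 5 (mother–child cohorts) and
#' 4 (longitudinal IBD cohorts) — see [hecPreset()].
#'
#' @param presences from [eventPresences()].
#' @param minSamples minimum presence count (>= 1).
#' @return filtered presence list.
#' @export
filterEventsByPrevalence <- function(presences, minSamples) {
  if (!is.numeric(minSamples) || minSamples < 1)
    hgtStop("minSamples must be >= 1", "hgtnet_parameter_error")
  presences[lengths(presences) >= minSamples]
}

#' Jaccard similarity of two presence sets
#' @param a,b character vectors of sample ids (non-empty).
#' @return numeric in `[0, 1]`.
#' @export
presenceJaccard <- function(a, b) {
  if (length(a) == 0 || length(b) == 0)
    hgtStop("presence sets must be non-empty", "hgtnet_validation_error")
  length(intersect(a, b)) / length(union(a, b))
}

#' Dataset-profile presets for event clustering
#'
#' `"mother-child"`: minimum presence 5 samples, minimum class size 10.
#' `"ibd"`: minimum presence 4 samples, minimum class size 20.
#' Both use cut distance 0.6.
#'
#' @param name preset name.
#' @return list with `minSamples`, `minClassSize`, `maxDistance`.
#' @export
hecPreset <- function(name = c("mother-child", "ibd")) {
  name <- match.arg(name)
  switch(name,
         "mother-child" = list(minSamples = 5, minClassSize = 10,
                               maxDistance = 0.6),
         "ibd" = list(minSamples = 4, minClassSize = 20, maxDistance = 0.6))
}

#' Cluster HGT events into co-occurrence classes (HECs)
#'
#' Distance between two events is one minus the Jaccard similarity of their
#' presence sets.  An average-linkage dendrogram is cut at `maxDistance`
#' and classes below `minClassSize` are moved to the unclustered pool, so
#' every event is assigned exactly once.  Each surviving cluster is labeled
#' with the bias-corrected rule ([labelCluster()]): an event contributes the
#' group label of every sample it occurs in, and `num` counts samples per
#' group over the metadata.  With a taxonomy, a genus composition profile is
#' computed counting *both* endpoint genomes of every member event.
#'
#' @param presences filtered presence list (>= 2 entries; see
#'   [filterEventsByPrevalence()]).
#' @param metadata data.frame with `sample_id` and `group`.
#' @param taxonomy optional taxonomy data.frame for genus composition.
#' @param maxDistance dendrogram cut height (default 0.6).
#' @param minClassSize minimum events per class (default 10).
#' @return list: `membership` (data.frame `key`, `cluster`; 0 = unclustered),
#'   `clusters` (cluster_id, label, nEvents), `composition` (per-cluster
#'   genus fractions, or NULL).
#' @export
clusterEvents <- function(presences, metadata, taxonomy = NULL,
                          maxDistance = 0.6, minClassSize = 10L) {
  if (length(presences) < 2L)
    hgtStop("need >= 2 event presences to cluster",
            "hgtnet_insufficient_data")
  presences <- presences[order(names(presences))]  # canonical event order
  D <- jaccardDistanceMatrix(presences)
  cl <- cutSizeGated(D, maxDistance, minClassSize)
  membership <- data.frame(key = names(presences), cluster = cl,
                           row.names = NULL)
  groupOf <- setNames(metadata$group, metadata$sample_id)
  num <- table(metadata$group)
  num <- setNames(as.numeric(num), names(num))
  ids <- sort(unique(cl[cl > 0]))
  clusters <- NULL
  composition <- NULL
  if (length(ids)) {
    clusters <- do.call(rbind, lapply(ids, function(cid) {
      keys <- membership$key[membership$cluster == cid]
      samples <- unlist(presences[keys])
      grp <- groupOf[samples]
      if (anyNA(grp))
        hgtStop("presence samples missing from metadata",
                "hgtnet_validation_error")
      counts <- table(grp)
      lab <- labelCluster(setNames(as.numeric(counts), names(counts)), num)
      data.frame(cluster_id = cid, label = lab, nEvents = length(keys))
    }))
    if (!is.null(taxonomy)) {
      composition <- lapply(ids, function(cid) {
        keys <- membership$key[membership$cluster == cid]
        genomes <- as.vector(keyGenomes(keys))  # both endpoints count
        clusterComposition(genomes, taxonomy, "genus")
      })
      names(composition) <- as.character(ids)
    }
  }
  list(membership = membership, clusters = clusters,
       composition = composition)
}
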