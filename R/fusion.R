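# Fusion genes: HGT events whose two breakpoints both fall inside annotated
# genes on their respective genomes.

#' Detect fusion genes at HGT breakpoints
#'
#' An event yields a fusion record for every pair `(gene_a, gene_b)` with
#' `pos_a` inside `gene_a` on `genome_a` and `pos_b` inside `gene_b` on
#' `genome_b`.  Containment is inclusive on both ends (1-based GFF3
#' convention) and ignores strand — a breakpoint is strandless.  Events with
#' either breakpoint intergenic (including genomes absent from the
#' annotation) yield nothing; overlapping genes yield one record per
#' overlapping pair.
#'
#' @param events canonical event data.frame.
#' @param annotations [GenomicRanges::GRanges] from [readGeneAnnotations()]
#'   (metadata columns `gene_id`, `product`).
#' @return data.frame with one row per (event, gene pair): `sample_id`,
#'   `genome_a`, `pos_a`, `gene_a`, `product_a`, `genome_b`, `pos_b`,
#'   `gene_b`, `product_b` and `event_uid` (stable event identifier).
#' @export
detectFusions <- function(events, annotations) {
  events <- canonicalizeEvents(events)
  empty <- data.frame(sample_id = character(), genome_a = character(),
                      pos_a = numeric(), gene_a = character(),
                      product_a = character(), genome_b = character(),
                      pos_b = numeric(), gene_b = character(),
                      product_b = character(), event_uid = character())
  if (nrow(events) == 0L) return(empty)
  uid <- paste(events$sample_id, events$genome_a, events$pos_a,
               events$genome_b, events$pos_b, sep = "|")
  lv <- union(unique(c(events$genome_a, events$genome_b)),
              GenomeInfoDb::seqlevels(annotations))
  anno <- annotations
  GenomeInfoDb::seqlevels(anno) <- lv
  sideHits <- function(genomes, positions) {
    bp <- GenomicRanges::GRanges(genomes,
                                 IRanges::IRanges(positions, positions))
    GenomeInfoDb::seqlevels(bp) <- lv
    GenomicRanges::findOverlaps(bp, anno, ignore.strand = TRUE)
  }
  hitsA <- sideHits(events$genome_a, events$pos_a)
  hitsB <- sideHits(events$genome_b, events$pos_b)
  aBy <- split(S4Vectors::subjectHits(hitsA), S4Vectors::queryHits(hitsA))
  bBy <- split(S4Vectors::subjectHits(hitsB), S4Vectors::queryHits(hitsB))
  both <- intersect(names(aBy), names(bBy))
  if (length(both) == 0L) return(empty)
  gid <- annotations$gene_id
  prod <- annotations$product
  rows <- lapply(both, function(ei) {
    i <- as.integer(ei)
    combos <- expand.grid(ga = aBy[[ei]], gb = bBy[[ei]])
    data.frame(sample_id = events$sample_id[i],
               genome_a = events$genome_a[i], pos_a = events$pos_a[i],
               gene_a = gid[combos$ga], product_a = prod[combos$ga],
               genome_b = events$genome_b[i], pos_b = events$pos_b[i],
               gene_b = gid[combos$gb], product_b = prod[combos$gb],
               event_uid = uid[i], row.names = NULL)
  })
  out <- do.call(rbind, rows)
  out[order(match(out$event_uid, uid), out$gene_a, out$gene_b), ,
      drop = FALSE] -> out
  rownames(out) <- NULL
  out
}

#' Summarize gene functions involved in fusion events
#'
#' For every distinct product description, counts the number of fusion
#' *events* in which a gene with that product appears (an event is counted
#' once per product, even when both genes share it).
#'
#' @param fusions data.frame from [detectFusions()].
#' @return list: `counts` (named integer vector, sorted decreasing) and
#'   `totalFusions` (number of distinct fusion events).
#' @export
summarizeFusionFunctions <- function(fusions) {
  if (nrow(fusions) == 0L)
    return(list(counts = setNames(integer(0), character(0)),
                totalFusions = 0L))
  perEvent <- unique(rbind(
    data.frame(event = fusions$event_uid, product = fusions$product_a),
    data.frame(event = fusions$event_uid, product = fusions$product_b)))
  tab <- table(perEvent$product)
  counts <- sort(setNames(as.integer(tab), names(tab)), decreasing = TRUE)
  list(counts = counts, totalFusions = length(unique(fusions$event_uid)))
}
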