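# Readers/writers for the flat external formats and canonical event identity.
#
# Event TSV:    sample_id  genome_a  pos_a  genome_b  pos_b
# Taxonomy TSV: genome  species  genus  phylum
# Depth TSV:    sample_id  genome  reads  length
# Metadata TSV: sample_id  individual  group  time_point
# Annotations:  GFF3 (gene features); networks: GraphML / weighted edge list.

hgtStop <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "hgtnet_error"), call = call))
}

#' Read an HGT event table
#'
#' Each row records one HGT event: a pair of breakpoints on two different
#' reference genomes in one sample.  Rows are canonicalized so that
#' `genome_a < genome_b` lexicographically (sides swapped where needed);
#' malformed rows are reported with their file line numbers (the header is
#' line 1).
#'
#' @param path path to a tab-separated file with columns `sample_id`,
#'   `genome_a`, `pos_a`, `genome_b`, `pos_b`.
#' @return data.frame of canonicalized events.  Coordinates are 1-based.
#' @examples
#' f <- tempfile()
#' writeLines(c("sample_id\tgenome_a\tpos_a\tgenome_b\tpos_b",
#'              "s1\tgB\t10\tgA\t20"), f)
#' readEvents(f)  # sides swapped so genome_a < genome_b
#' @export
readEvents <- function(path) {
  if (!file.exists(path)) hgtStop(paste0("event file not found: ", path),
                                  "hgtnet_format_error")
  df <- read.delim(path, colClasses = "character", check.names = FALSE)
  need <- c("sample_id", "genome_a", "pos_a", "genome_b", "pos_b")
  missing <- setdiff(need, names(df))
  if (length(missing))
    hgtStop(paste0("event table missing column(s): ",
                   paste(missing, collapse = ", ")), "hgtnet_format_error")
  df <- df[need]
  if (nrow(df) == 0L) {
    df$pos_a <- numeric(0); df$pos_b <- numeric(0)
    return(df)
  }
  lineNo <- seq_len(nrow(df)) + 1L
  for (col in c("pos_a", "pos_b")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- is.na(v) | v < 1 | v != floor(v)
    if (any(bad))
      hgtStop(sprintf("column %s is not a positive integer at line(s) %s",
                      col, paste(lineNo[bad], collapse = ", ")),
              "hgtnet_parse_error")
    df[[col]] <- v
  }
  same <- df$genome_a == df$genome_b
  if (any(same))
    hgtStop(sprintf(
      "events must link two different genomes; offending line(s): %s",
      paste(lineNo[same], collapse = ", ")), "hgtnet_validation_error")
  df <- canonicalizeEvents(df)
  rownames(df) <- NULL
  df
}

# swap sides so genome_a < genome_b; pure and idempotent
canonicalizeEvents <- function(df) {
  swap <- df$genome_a > df$genome_b
  if (any(swap)) {
    ga <- df$genome_a[swap]; pa <- df$pos_a[swap]
    df$genome_a[swap] <- df$genome_b[swap]
    df$pos_a[swap] <- df$pos_b[swap]
    df$genome_b[swap] <- ga
    df$pos_b[swap] <- pa
  }
  df
}

#' Canonical binned event keys
#'
#' Two events from different samples are considered the same HGT event when
#' they link the same genome pair and their breakpoints fall into the same
#' fixed-width coordinate bins.  Position `p` maps to bin
#' `floor((p - 1) / binSize)`, so position 1 is bin 0 and bins are
#' side-swap invariant.
#'
#' @param events event data.frame (as from [readEvents()]); rows need not be
#'   canonicalized beforehand.
#' @param binSize bin width in bp (default 100); must be >= 1.
#' @return character vector of keys, `"genome_a|genome_b|bin_a|bin_b"`.
#' @export
eventKey <- function(events, binSize = 100) {
  if (!is.numeric(binSize) || length(binSize) != 1L || binSize < 1)
    hgtStop("binSize must be a single number >= 1", "hgtnet_parameter_error")
  events <- canonicalizeEvents(events)
  binA <- floor((events$pos_a - 1) / binSize)
  binB <- floor((events$pos_b - 1) / binSize)
  paste(events$genome_a, events$genome_b, binA, binB, sep = "|")
}

# parse the two genome accessions back out of a key
keyGenomes <- function(keys) {
  parts <- strsplit(keys, "|", fixed = TRUE)
  cbind(vapply(parts, `[[`, "", 1L), vapply(parts, `[[`, "", 2L))
}

#' Read a genome taxonomy table
#'
#' @param path TSV with columns `genome`, `species`, `genus`, `phylum`.
#'   Duplicate identical rows are deduplicated; duplicate rows with
#'   conflicting ranks are rejected.  Empty rank strings are replaced with
#'   `"unclassified"` (with a warning).
#' @return data.frame keyed by `genome`.
#' @export
readTaxonomy <- function(path) {
  df <- read.delim(path, colClasses = "character", check.names = FALSE)
  need <- c("genome", "species", "genus", "phylum")
  missing <- setdiff(need, names(df))
  if (length(missing))
    hgtStop(paste0("taxonomy table missing column(s): ",
                   paste(missing, collapse = ", ")), "hgtnet_format_error")
  df <- unique(df[need])
  empty <- df$species == "" | df$genus == "" | df$phylum == "" |
    is.na(df$species) | is.na(df$genus) | is.na(df$phylum)
  if (any(empty)) {
    warning("empty taxonomy ranks replaced with 'unclassified'")
    for (col in c("species", "genus", "phylum")) {
      bad <- df[[col]] == "" | is.na(df[[col]])
      df[[col]][bad] <- "unclassified"
    }
    df <- unique(df)
  }
  dup <- df$genome[duplicated(df$genome)]
  if (length(dup))
    hgtStop(paste0("conflicting taxonomy rows for genome(s): ",
                   paste(unique(dup), collapse = ", ")),
            "hgtnet_validation_error")
  rownames(df) <- NULL
  df
}

#' Look up a taxonomic rank for genome accessions
#'
#' Fails loudly on unknown accessions rather than returning `NA`.
#'
#' @param taxonomy data.frame from [readTaxonomy()].
#' @param genomes character vector of genome accessions.
#' @param rank one of `"species"`, `"genus"`, `"phylum"`.
#' @return character vector of rank labels, parallel to `genomes`.
#' @export
taxonomyLookup <- function(taxonomy, genomes, rank = c("phylum", "genus", "species")) {
  rank <- match.arg(rank)
  idx <- match(genomes, taxonomy$genome)
  if (anyNA(idx))
    hgtStop(paste0("genome(s) absent from taxonomy: ",
                   paste(unique(genomes[is.na(idx)]), collapse = ", ")),
            "hgtnet_taxonomy_error")
  taxonomy[[rank]][idx]
}

#' Read a per-sample read-depth summary
#' @param path TSV with columns `sample_id`, `genome`, `reads`, `length`.
#' @return data.frame with numeric `reads` (>= 0) and `length` (>= 1).
#' @export
readDepth <- function(path) {
  df <- read.delim(path, check.names = FALSE)
  need <- c("sample_id", "genome", "reads", "length")
  missing <- setdiff(need, names(df))
  if (length(missing))
    hgtStop(paste0("depth table missing column(s): ",
                   paste(missing, collapse = ", ")), "hgtnet_format_error")
  if (any(df$reads < 0) || any(df$length < 1))
    hgtStop("depth table requires reads >= 0 and length >= 1",
            "hgtnet_validation_error")
  df[need]
}

#' Read sample metadata
#' @param path TSV with columns `sample_id`, `individual`, `group`,
#'   `time_point`; `sample_id` must be unique.
#' @return data.frame.
#' @export
readMetadata <- function(path) {
  df <- read.delim(path, colClasses = "character", check.names = FALSE)
  need <- c("sample_id", "individual", "group", "time_point")
  missing <- setdiff(need, names(df))
  if (length(missing))
    hgtStop(paste0("metadata missing column(s): ",
                   paste(missing, collapse = ", ")), "hgtnet_format_error")
  if (anyDuplicated(df$sample_id))
    hgtStop("metadata sample_id values must be unique",
            "hgtnet_validation_error")
  df[need]
}

#' Read gene annotations from GFF3
#'
#' Keeps features of type `gene`; coordinates are 1-based inclusive per the
#' GFF3 standard.  The product description is taken from the `product`
#' attribute, with `"NA"` as the explicit fallback marker.
#'
#' @param path GFF3 file.
#' @return [GenomicRanges::GRanges] with metadata columns `gene_id` and
#'   `product`; seqnames are genome accessions.
#' @export
readGeneAnnotations <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[!is.na(gr$type) & as.character(gr$type) == "gene"]
  ids <- if ("ID" %in% names(S4Vectors::mcols(gr))) as.character(gr$ID)
         else rep(NA_character_, length(gr))
  noId <- is.na(ids) | ids == ""
  if (any(noId)) ids[noId] <- sprintf("gene_%06d", which(noId))
  prod <- if ("product" %in% names(S4Vectors::mcols(gr))) as.character(gr$product)
          else rep(NA_character_, length(gr))
  prod[is.na(prod) | prod == ""] <- "NA"
  out <- GenomicRanges::granges(gr)
  S4Vectors::mcols(out)$gene_id <- ids
  S4Vectors::mcols(out)$product <- prod
  out
}

#' Write / read an HGT network
#'
#' `"edgelist"` writes a headerless 3-column tab-separated table
#' `u  v  w`; isolated nodes (never produced by [buildNetwork()]) are not
#' representable in this format.  `"graphml"` round-trips the full graph
#' including the sample id.
#'
#' @param network an [HGTNetwork-class].
#' @param path output file.
#' @param format `"edgelist"` or `"graphml"`.
#' @return `path`, invisibly.
#' @export
writeNetwork <- function(network, path, format = c("edgelist", "graphml")) {
  if (is.character(format) && length(format) == 1L &&
      !format %in% c("edgelist", "graphml"))
    hgtStop(paste0("unknown network format: ", format),
            "hgtnet_parameter_error")
  format <- match.arg(format)
  g <- networkGraph(network)
  if (format == "edgelist") {
    el <- igraph::as_edgelist(g)
    w <- if (igraph::ecount(g)) igraph::E(g)$weight else integer(0)
    df <- data.frame(u = el[, 1], v = el[, 2], w = w)
    write.table(df, path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  } else {
    g2 <- g
    g2 <- igraph::set_graph_attr(g2, "sampleId", as.character(sampleId(network)))
    igraph::write_graph(g2, path, format = "graphml")
  }
  invisible(path)
}

#' @rdname writeNetwork
#' @param sampleId sample id to attach when reading an edge list (the format
#'   itself does not carry one).
#' @export
readNetwork <- function(path, format = c("edgelist", "graphml"),
                        sampleId = NA_character_) {
  if (is.character(format) && length(format) == 1L &&
      !format %in% c("edgelist", "graphml"))
    hgtStop(paste0("unknown network format: ", format),
            "hgtnet_parameter_error")
  format <- match.arg(format)
  if (format == "edgelist") {
    info <- file.info(path)
    if (!is.na(info$size) && info$size == 0) {
      g <- igraph::make_empty_graph(0, directed = FALSE)
      return(newHGTNetwork(g, sampleId))
    }
    df <- read.delim(path, header = FALSE, colClasses = c("character", "character", "numeric"))
    g <- igraph::graph_from_data_frame(df[, 1:2], directed = FALSE)
    igraph::E(g)$weight <- df[[3]]
    newHGTNetwork(g, sampleId)
  } else {
    g <- igraph::read_graph(path, format = "graphml")
    sid <- NULL
    if ("sampleId" %in% igraph::graph_attr_names(g)) {
      sid <- igraph::graph_attr(g, "sampleId")
      g <- igraph::delete_graph_attr(g, "sampleId")
    }
    newHGTNetwork(g, if (is.null(sid)) sampleId else sid)
  }
}
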