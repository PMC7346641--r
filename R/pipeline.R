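# One-command orchestration: build -> fit -> entropy/rate -> similarity ->
# communities (HCC) -> event clusters (HEC) -> fusion, with a
# machine-readable JSON report.  Deterministic given the config seed;
# report files are written via write-then-rename so failures never leave a
# half-written report.

pipelineDefaults <- function() {
  list(bin_size = 100, min_nodes = 100, resolution = 1, seed = 1,
       hcc = list(max_distance = 0.6, min_size = 2),
       hec = list(min_samples = 5, min_class_size = 10, max_distance = 0.6),
       similarity_metrics = c("jaccard", "degree", "combined"),
       stages = c("build", "fit", "entropy", "rate", "similarity",
                  "communities", "events", "fusion"))
}

#' Run the full HGT-network analysis pipeline
#'
#' Executes every enabled stage on a dataset directory and writes stage
#' outputs plus a JSON report to `out_dir`.  The configuration may be a
#' YAML file path or a list with fields `events`, `metadata` and `out_dir`
#' (required), `taxonomy`, `depth`, `annotations` (optional inputs) and the
#' parameters of [pipelineDefaults()].  A `hec` entry may name a `preset`
#' (`"mother-child"` or `"ibd"`).  Configuration problems abort before any
#' computation; stage errors abort with the stage name.
#'
#' @param config YAML path or list.
#' @return the report, invisibly (also serialized to
#'   `out_dir/report.json`).
#' @export
runPipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- modifyList(pipelineDefaults(), config)
  if (!is.null(cfg$hec$preset))
    cfg$hec <- modifyList(cfg$hec, hecPreset(cfg$hec$preset))

  # ---- fail-fast validation, before any compute ----
  for (key in c("events", "metadata", "out_dir"))
    if (is.null(cfg[[key]]))
      hgtStop(paste0("config missing required field: ", key),
              "hgtnet_config_error")
  for (key in c("events", "metadata", "taxonomy", "depth", "annotations"))
    if (!is.null(cfg[[key]]) && !file.exists(cfg[[key]]))
      hgtStop(paste0("config file for '", key, "' not found: ", cfg[[key]]),
              "hgtnet_config_error")
  stages <- cfg$stages
  if (("communities" %in% stages || "events" %in% stages) &&
      is.null(cfg$taxonomy))
    hgtStop("communities/events stages require a taxonomy for composition",
            "hgtnet_config_error")
  if ("rate" %in% stages && is.null(cfg$depth))
    hgtStop("rate stage requires a depth table", "hgtnet_config_error")
  if ("fusion" %in% stages && is.null(cfg$annotations))
    hgtStop("fusion stage requires gene annotations", "hgtnet_config_error")

  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  logStage <- function(stage) message(sprintf("[%s] %s", Sys.time(), stage))
  inStage <- function(stage, expr) {
    tryCatch(expr, error = function(e) stop(sprintf(
      "pipeline stage '%s' failed: %s", stage, conditionMessage(e)),
      call. = FALSE))
  }
  writeTsv <- function(df, file)
    write.table(df, file.path(cfg$out_dir, file), sep = "\t", quote = FALSE,
                row.names = FALSE)

  report <- list(parameters = cfg[setdiff(names(cfg), "stages")],
                 stages = stages)

  logStage("read inputs")
  events <- inStage("read", readEvents(cfg$events))
  metadata <- inStage("read", readMetadata(cfg$metadata))
  taxonomy <- if (!is.null(cfg$taxonomy)) inStage("read", readTaxonomy(cfg$taxonomy))
  depth <- if (!is.null(cfg$depth)) inStage("read", readDepth(cfg$depth))
  anno <- if (!is.null(cfg$annotations))
    inStage("read", readGeneAnnotations(cfg$annotations))

  logStage("build networks")
  networks <- inStage("build", {
    bySample <- split(events, events$sample_id)
    lapply(bySample, buildNetwork)
  })

  perSample <- data.frame(sample_id = names(networks),
                          network_size = vapply(networks, networkSize, 0L),
                          n_events = vapply(split(events, events$sample_id),
                                            nrow, 0L))
  if ("entropy" %in% stages) {
    logStage("entropy")
    perSample$entropy <- inStage("entropy",
      vapply(networks, vonNeumannEntropy, 0))
  }
  if ("rate" %in% stages) {
    logStage("event rate")
    rates <- inStage("rate", eventRateTable(events, depth))
    perSample <- merge(perSample, rates[, c("sample_id", "depth", "rate")],
                       by = "sample_id")
  }

  if ("fit" %in% stages) {
    logStage("degree-distribution fits")
    fits <- inStage("fit", {
      rows <- lapply(names(networks), function(sid) {
        g <- networkGraph(networks[[sid]])
        deg <- igraph::degree(g)
        if (length(deg) < cfg$min_nodes) return(NULL)
        fit <- fitPowerLaw(deg, minNodes = cfg$min_nodes)
        llr <- lapply(c("exponential", "lognormal_positive", "weibull"),
                      function(fam) compareFits(deg, fam, plFit = fit))
        data.frame(sample_id = sid, alpha = fit@alpha, xmin = fit@xmin,
                   ks = fit@ksDistance, n_tail = fit@nTail,
                   llr_exp = llr[[1]]@ratio, p_exp = llr[[1]]@pValue,
                   llr_logn_pos = llr[[2]]@ratio, p_logn_pos = llr[[2]]@pValue,
                   llr_weibull = llr[[3]]@ratio, p_weibull = llr[[3]]@pValue)
      })
      do.call(rbind, rows)
    })
    if (!is.null(fits)) {
      writeTsv(fits, "fits.tsv")
      report$fits <- fits
      groupOf <- setNames(metadata$group, metadata$sample_id)
      byGroup <- split(fits$alpha, groupOf[fits$sample_id])
      byGroup <- byGroup[lengths(byGroup) >= 2]
      if (length(byGroup) >= 2) {
        gs <- inStage("fit", summarizeGroupFits(byGroup))
        report$group_fits <- gs
        report$group_fit_tests <- attr(gs, "pairwise")
      }
    }
    trend <- tryCatch(diameterLnlnTrend(networks),
                      hgtnet_insufficient_data = function(e) NULL,
                      hgtnet_degenerate_regression = function(e) NULL)
    if (!is.null(trend))
      report$diameter_trend <- trend[c("slope", "intercept", "r")]
  }

  if ("similarity" %in% stages && length(networks) >= 2) {
    logStage("pairwise similarity")
    sim <- inStage("similarity",
                   pairwiseSimilarity(networks, cfg$similarity_metrics))
    writeTsv(sim, "similarity.tsv")
    report$similarity_pairs <- nrow(sim)
  }

  if ("communities" %in% stages) {
    logStage("communities and HCCs")
    hcc <- inStage("communities", {
      ct <- collectCommunities(networks, resolution = cfg$resolution,
                               seed = cfg$seed)
      communityClusters(ct, metadata, taxonomy,
                        maxDistance = cfg$hcc$max_distance,
                        minSize = cfg$hcc$min_size)
    })
    if (!is.null(hcc$clusters)) writeTsv(hcc$clusters, "hcc_clusters.tsv")
    writeTsv(hcc$membership, "hcc_membership.tsv")
    report$hcc <- hcc$clusters
  }

  if ("events" %in% stages) {
    logStage("event clusters (HECs)")
    hec <- inStage("events", {
      pres <- filterEventsByPrevalence(
        eventPresences(events, cfg$bin_size), cfg$hec$min_samples)
      if (length(pres) < 2) NULL
      else clusterEvents(pres, metadata, taxonomy,
                         maxDistance = cfg$hec$max_distance,
                         minClassSize = cfg$hec$min_class_size)
    })
    if (!is.null(hec)) {
      writeTsv(hec$membership, "hec_membership.tsv")
      if (!is.null(hec$clusters)) writeTsv(hec$clusters, "hec_clusters.tsv")
      report$hec <- hec$clusters
    }
  }

  if ("fusion" %in% stages) {
    logStage("fusion genes")
    fus <- inStage("fusion", detectFusions(events, anno))
    writeTsv(fus, "fusions.tsv")
    fsum <- summarizeFusionFunctions(fus)
    report$fusion <- list(total = fsum$totalFusions,
                          products = as.list(fsum$counts))
    if (length(fsum$counts))
      writeTsv(data.frame(product = names(fsum$counts),
                          n_events = as.integer(fsum$counts)),
               "fusion_summary.tsv")
  }

  writeTsv(perSample, "per_sample.tsv")
  report$per_sample <- perSample

  tmp <- file.path(cfg$out_dir, ".report.json.tmp")
  jsonlite::write_json(report, tmp, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", force = TRUE)
  file.rename(tmp, file.path(cfg$out_dir, "report.json"))
  invisible(report)
}
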