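# Fixtures and independent oracles shared across test files.
# All fixtures are built in code; nothing is read from disk except files the
# tests themselves write to tempdir().

# events with unit positions from a 2-column pair matrix/list
eventsFromPairs <- function(pairs, sample_id = "s") {
  data.frame(sample_id = sample_id,
             genome_a = pairs[, 1], pos_a = 1,
             genome_b = pairs[, 2], pos_b = 1)
}

# small named network from explicit edges (unit weights unless given)
makeNet <- function(from, to, weight = NULL, sampleId = "s") {
  ev <- data.frame(sample_id = sampleId, genome_a = from, pos_a = 1,
                   genome_b = to, pos_b = 1)
  if (!is.null(weight))
    ev <- ev[rep(seq_len(nrow(ev)), weight), , drop = FALSE]
  buildNetwork(ev)
}

# complete graph (clique) over the given node names
cliqueNet <- function(nodes, sampleId = "s") {
  p <- t(combn(nodes, 2))
  buildNetwork(eventsFromPairs(p, sampleId))
}

# star: one hub connected to each leaf
starNet <- function(hub, leaves, sampleId = "s") {
  makeNet(rep(hub, length(leaves)), leaves, sampleId = sampleId)
}

writeTempTsv <- function(df, ...) {
  f <- tempfile(fileext = ".tsv")
  write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE, ...)
  f
}

tinyTaxonomy <- function() {
  data.frame(
    genome = c("gA", "gB", "gC", "gD"),
    species = paste0("sp", 1:4),
    genus = c("Escherichia", "Bacteroides", "Escherichia", "Clostridium"),
    phylum = c("Proteobacteria", "Bacteroidetes", "Proteobacteria",
               "Firmicutes"))
}

# Spearman correlation from first principles: mid-ranks + the Pearson
# product-moment formula, written independently of stats::cor
bruteSpearman <- function(x, y) {
  midRank <- function(v) {
    r <- numeric(length(v))
    for (i in seq_along(v))
      r[i] <- sum(v < v[i]) + (sum(v == v[i]) + 1) / 2
    r
  }
  rx <- midRank(x); ry <- midRank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# pooled-variance two-sample t statistic and two-sided p, by the formula
bruteT <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  list(t = t, p = 2 * pt(-abs(t), na + nb - 2))
}

# adjusted Rand index between two label vectors (used when mclust is
# unavailable; cross-checked against mclust in tests where it is)
bruteARI <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(n) n * (n - 1) / 2
  sumij <- sum(comb2(tab))
  ai <- sum(comb2(rowSums(tab)))
  bj <- sum(comb2(colSums(tab)))
  n2 <- comb2(sum(tab))
  expected <- ai * bj / n2
  (sumij - expected) / ((ai + bj) / 2 - expected)
}
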