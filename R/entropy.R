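# Simplified von Neumann entropy of an HGT network.

#' Simplified von Neumann entropy
#'
#' Network complexity measure
#' `H_VN = 1 - 1/|V| - (1/|V|^2) * sum over edges (u,v) of 1/(d_u d_v)`,
#' where `d_u` is the unweighted degree of node `u` and each undirected edge
#' is counted once.  It can be read as the thermodynamic entropy of the
#' graph: a single isolated node has entropy 0, and for any non-empty
#' network `H_VN < 1 - 1/|V|`.
#'
#' Edge multiplicities (event counts) are ignored: the entropy is a function
#' of the unweighted edge set.
#'
#' @param network an [HGTNetwork-class] with at least one node.
#' @return entropy in `[0, 1)`.
#' @examples
#' ev <- data.frame(sample_id = "s", genome_a = c("a", "b"), pos_a = c(1, 1),
#'                  genome_b = c("b", "c"), pos_b = c(1, 1))
#' vonNeumannEntropy(buildNetwork(ev))  # path a-b-c: 5/9
#' @export
vonNeumannEntropy <- function(network) {
  g <- networkGraph(network)
  V <- igraph::vcount(g)
  if (V == 0)
    hgtStop("entropy undefined for an empty network",
            "hgtnet_undefined_entropy")
  if (igraph::ecount(g) == 0)
    return(1 - 1 / V)
  deg <- igraph::degree(g)
  ends <- igraph::ends(g, igraph::E(g), names = FALSE)
  1 - 1 / V - sum(1 / (deg[ends[, 1]] * deg[ends[, 2]])) / V^2
}
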