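#' HGTNetwork: a per-sample horizontal gene transfer network
#'
#' An undirected weighted graph whose nodes are reference genome accessions
#' and whose edge weights count the HGT events linking two genomes in one
#' sample.  Self-loops are forbidden (an HGT event links two *different*
#' genomes) and weights are positive integers.
#'
#' @slot sampleId single character, the sample the network belongs to
#'   (may be `NA` for synthetic or anonymous networks).
#' @slot graph an undirected simple [igraph::igraph] with a positive
#'   integer `weight` edge attribute.
#'
#' @seealso [buildNetwork()], [networkSize()], [vonNeumannEntropy()]
#' @exportClass HGTNetwork
setClass("HGTNetwork",
  representation(sampleId = "character", graph = "ANY"),
  prototype(sampleId = NA_character_)
)

setValidity("HGTNetwork", function(object) {
  msgs <- character()
  if (length(object@sampleId) != 1L)
    msgs <- c(msgs, "sampleId must be a single character value")
  g <- object@graph
  if (!inherits(g, "igraph")) {
    msgs <- c(msgs, "graph must be an igraph object")
  } else {
    if (igraph::is_directed(g))
      msgs <- c(msgs, "graph must be undirected")
    if (igraph::any_loop(g))
      msgs <- c(msgs, "graph must not contain self-loops")
    if (igraph::ecount(g) > 0) {
      w <- igraph::E(g)$weight
      if (is.null(w))
        msgs <- c(msgs, "edges must carry a 'weight' attribute")
      else if (any(w < 1) || any(w != round(w)))
        msgs <- c(msgs, "edge weights must be integers >= 1")
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' PowerLawFit: discrete power-law fit to a degree distribution
#'
#' @slot alpha fitted degree exponent (> 1).
#' @slot xmin lower cutoff degree of the fitted tail.
#' @slot ksDistance Kolmogorov–Smirnov distance between the empirical and
#'   fitted tail CDFs.
#' @slot nTail number of degrees >= `xmin`.
#' @slot loglik tail log-likelihood at the fitted parameters.
#' @slot method `"discrete"` (default) or `"continuous"` (closed-form
#'   cross-check estimator).
#' @exportClass PowerLawFit
setClass("PowerLawFit",
  representation(alpha = "numeric", xmin = "numeric", ksDistance = "numeric",
                 nTail = "integer", loglik = "numeric", method = "character")
)

setValidity("PowerLawFit", function(object) {
  msgs <- character()
  if (object@alpha <= 1) msgs <- c(msgs, "alpha must exceed 1")
  if (object@xmin < 1) msgs <- c(msgs, "xmin must be >= 1")
  if (object@ksDistance < 0 || object@ksDistance > 1)
    msgs <- c(msgs, "ksDistance must lie in [0, 1]")
  if (object@nTail < 2L) msgs <- c(msgs, "nTail must be >= 2")
  if (length(msgs)) msgs else TRUE
})

#' AltFit: a heavy-tailed alternative model fitted to the same degree tail
#'
#' Families: `"exponential"` (discrete/geometric, rate lambda),
#' `"lognormal_positive"` (mu >= 0 enforced, never silently clipped: when the
#' unconstrained optimum has mu < 0 the fit is refit at mu = 0 and
#' `constraintBound` is set), `"weibull"` (shape, scale).
#'
#' @slot family model family name.
#' @slot params named numeric parameter vector.
#' @slot loglik tail log-likelihood.
#' @slot nTail tail size.
#' @slot logNorm log normalizing constant of the discretized pmf on the tail
#'   support (internal; used to evaluate per-observation likelihoods).
#' @slot constraintBound `TRUE` when the mu >= 0 constraint is active.
#' @exportClass AltFit
setClass("AltFit",
  representation(family = "character", params = "numeric", loglik = "numeric",
                 nTail = "integer", logNorm = "numeric",
                 constraintBound = "logical"),
  prototype(constraintBound = FALSE)
)

#' LLRResult: Vuong-normalized log-likelihood ratio of power law vs alternative
#'
#' `ratio > 0` means the power law fits the shared tail better than the
#' alternative; the p-value tests whether the sign is distinguishable from
#' chance.  Tails smaller than the minimum-tail guard are reported as
#' `"undecided"`.
#'
#' @slot ratio normalized (Vuong) log-likelihood ratio.
#' @slot rawRatio unnormalized sum of per-observation log-likelihood
#'   differences (power law minus alternative).
#' @slot pValue two-sided significance of the sign of the ratio.
#' @slot winner one of `"power_law"`, `"alternative"`, `"undecided"`.
#' @slot family the alternative family compared against.
#' @slot nTail shared tail size.
#' @exportClass LLRResult
setClass("LLRResult",
  representation(ratio = "numeric", rawRatio = "numeric", pValue = "numeric",
                 winner = "character", family = "character", nTail = "integer")
)

setValidity("LLRResult", function(object) {
  msgs <- character()
  if (object@pValue < 0 || object@pValue > 1)
    msgs <- c(msgs, "pValue must lie in [0, 1]")
  if (!object@winner %in% c("power_law", "alternative", "undecided"))
    msgs <- c(msgs, "winner must be power_law, alternative or undecided")
  if (object@winner == "power_law" && !(object@ratio > 0))
    msgs <- c(msgs, "winner power_law requires ratio > 0")
  if (length(msgs)) msgs else TRUE
})

#' @describeIn HGTNetwork-class compact display
#' @param object an `HGTNetwork`
#' @export
setMethod("show", "HGTNetwork", function(object) {
  g <- object@graph
  cat(sprintf("HGTNetwork '%s': %d genomes, %d edges, %d events\n",
              object@sampleId, igraph::vcount(g), igraph::ecount(g),
              if (igraph::ecount(g)) sum(igraph::E(g)$weight) else 0L))
})

setMethod("show", "PowerLawFit", function(object) {
  cat(sprintf("PowerLawFit (%s): alpha = %.4f, xmin = %g, KS = %.4f, n_tail = %d\n",
              object@method, object@alpha, object@xmin, object@ksDistance,
              object@nTail))
})

setMethod("show", "AltFit", function(object) {
  cat(sprintf("AltFit [%s]: %s; loglik = %.3f, n_tail = %d%s\n",
              object@family,
              paste(sprintf("%s = %.4f", names(object@params), object@params),
                    collapse = ", "),
              object@loglik, object@nTail,
              if (object@constraintBound) " (constraint mu >= 0 active)" else ""))
})

setMethod("show", "LLRResult", function(object) {
  cat(sprintf("LLR power_law vs %s: ratio = %.4f (raw %.2f), p = %.4g -> %s\n",
              object@family, object@ratio, object@rawRatio, object@pValue,
              object@winner))
})

# ---- accessors ----

#' Sample identifier of a network
#' @param x an [HGTNetwork-class]
#' @return single character sample id
#' @export
sampleId <- function(x) {
  stopifnot(is(x, "HGTNetwork"))
  x@sampleId
}

#' Underlying igraph of a network
#' @param x an [HGTNetwork-class]
#' @return the [igraph::igraph] carried by the network
#' @export
networkGraph <- function(x) {
  stopifnot(is(x, "HGTNetwork"))
  x@graph
}

#' Genome accessions present in a network
#' @param x an [HGTNetwork-class]
#' @return character vector of node names
#' @export
networkNodes <- function(x) {
  stopifnot(is(x, "HGTNetwork"))
  igraph::V(x@graph)$name
}

# internal constructor used throughout
newHGTNetwork <- function(graph, sampleId = NA_character_) {
  new("HGTNetwork", sampleId = as.character(sampleId), graph = graph)
}
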