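---
title: "Methods: HGT networks, heavy-tail fits, and cluster labeling"
author: "hgtnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: HGT networks, heavy-tail fits, and cluster labeling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, the tunable parameters, the numerical
choices and the deliberate design decisions behind `hgtnet`, in the spirit
of a methods section: what is computed, under which assumptions, and what
the synthetic validation does and does not demonstrate.

## The network model

An HGT event is a breakpoint pair linking two *different* reference
genomes in one sample; events on a single genome are rejected at ingest.
The per-sample network is undirected — split-read callers do not resolve
donor versus recipient — with genomes as nodes and the number of events
between two genomes as the edge weight. Nodes are genome assemblies (one
accession per taxon), not scaffolds. Networks never contain isolated
nodes: a genome enters only by participating in an event, so every degree
is at least 1.

### Event identity across samples

Callers report breakpoint coordinates with a few base pairs of jitter, so
equality of raw coordinates would under-count recurrences. Events are
therefore identified by `(genome pair, coordinate bin pair)` with a
default bin width of 100 bp, exposed as `binSize` wherever identity
matters (Venn overlaps, presence profiles). Coordinates are 1-based
inclusive throughout (the GFF3 convention) and binning uses
`floor((pos - 1)/binSize)` so position 1 falls in bin 0 and identity is
invariant to swapping the two sides of an event. The 100 bp default is a
package choice — there is no community-standard tolerance — and analyses
sensitive to it should sweep it.

## Heavy-tail degree-distribution machinery

Degrees are counts, so the default likelihoods are discrete:

* power law `P(k) = k^(-alpha) / zeta(alpha, xmin)` with the Hurwitz zeta
  evaluated by Euler–Maclaurin summation (25 explicit terms plus
  correction; accurate to ~1e-13 over the relevant parameter range);
* exponential as the geometric law on `k - xmin` (closed-form MLE);
* positive lognormal and Weibull as their continuous densities evaluated
  at integers and renormalized over the support `[xmin, cap]`, with
  `cap = max(1e5, 10 * max degree)` so the truncated mass is negligible.

The positive-lognormal location is constrained to `mu >= 0` because a
degree set has median at least 1; when the unconstrained optimum violates
the constraint the model is refit at `mu = 0` and flagged
(`constraintBound`), never clipped silently.

`xmin` is chosen by scanning the observed degree values and minimizing the
Kolmogorov–Smirnov distance between the empirical and fitted tail CDFs
(the standard cutoff-selection approach for power-law fits). The scan
only considers cutoffs leaving at least `minTail = 50` tail points:
smaller tails let the KS objective chase noise and produce wild
exponents. The continuous closed form
`alpha = 1 + n / sum(log(x / xmin))` is retained as
`method = "continuous"` purely as an independent cross-check; it is the
oracle the test suite validates the discrete route against.

Model comparison fits both candidates on the *identical* tail and
normalizes the log-likelihood ratio by `sd * sqrt(n)` of the
per-observation differences (the Vuong construction), giving a two-sided
p-value for the sign. Verdicts on tails below 50 points are reported as
`"undecided"` — the sign of the ratio is noise there. Whole networks with
fewer than 100 nodes are excluded from fitting by default (`minNodes`),
matching the filtering a cohort-scale analysis applies; `force = TRUE`
bypasses the guard for exploration.

The diameter trend uses the largest connected component of each network
(sparse HGT networks are frequently disconnected; the giant component
carries the distance structure) and regresses `d` on `ln(ln(N))` for
networks with at least 3 nodes.

## Entropy, event rate, similarity

The simplified von Neumann entropy
`1 - 1/|V| - (1/|V|^2) * sum over edges 1/(d_u d_v)` is evaluated on the
*unweighted* edge set: multiplicities describe evidence strength, not
extra structure, and the entropy's thermodynamic reading assumes simple
degrees. The event rate `ln(H / (sum r_i / sum l_i))` uses exactly the
genomes linked by events in the sample as the depth denominator set.

Similarity metrics: node Jaccard; Spearman correlations of degree,
PageRank (damping 0.85, unweighted) and local clustering coefficient
(unweighted; nodes of degree < 2 contribute 0) computed per network
*before* restriction to the shared node set; and the combined score
`jaccard * degree correlation`. Correlations need at least 3 shared nodes
and non-degenerate rankings; the combined score of such pairs is defined
as 0 with an explicit `degenerate` flag rather than dropping the pair, so
group sweeps keep their denominators. Group comparisons use the classical
pooled-variance two-sided Student's t-test (one-sided variant reported
alongside for directional questions).

## Communities, HCCs, HECs and labels

Communities come from the Leiden algorithm (modularity objective,
event-count weights, resolution 1 by default, 5 iterations, explicit
seed). The contract is partition quality, not a specific implementation:
the result is checked to be a partition at least as good as the trivial
one-block partition.

Communities from all samples are clustered by `1 - Jaccard` of their
member sets with average linkage, cut at 0.6, minimum cluster size 2 —
a "cluster" of one community is noise. Events are clustered the same way
on their sample-presence profiles after a prevalence filter; the presets
carry the two cohort profiles (`mother-child`: minimum presence 5,
minimum class 10; `ibd`: 4 and 20; cut 0.6 in both). The cut is a static
height cut followed by the minimum-size gate (undersized classes move to
an explicit unclustered pool), which keeps the procedure deterministic;
average-linkage heights are rounded at 1e-10 and made non-decreasing to
absorb floating-point inversions. Community clustering orders its input
canonically (by sorted member signature) so results are invariant to row
order.

Cluster labels correct for unequal group sizes: a cluster's label is
`argmax_label COUNT(label) / num(label)`, where `num` counts samples per
group in the dataset at hand. Exact ties return `"ambiguous"` rather than
forcing a side. Composition profiles keep genome multiplicity across a
cluster's member communities; HEC genus profiles count *both* endpoint
genomes of every member event, so fractions are well defined even when an
event's two sides differ in genus.

## Fusion genes

A fusion gene is called when both breakpoints of an event fall inside
annotated genes on their respective genomes. Containment is inclusive on
both ends and ignores strand — a breakpoint is strandless. When several
genes overlap a breakpoint, every gene pair is reported; function
summaries count *events* per product (once per product per event), so
overlapping annotations never inflate totals.

## The synthetic cohort generator

The generator emulates the structure the analyses assume: families with
mothers sampled at three time points and children at five (child network
sizes growing, mother sizes large and flat), or CD/UC/non-IBD patients
sampled longitudinally; a fraction `rho` (default 0.5) of each child's
events copied from its mother's pool; group-specific event pools;
planted community motifs over reserved genomes with a configurable taxon
bias; co-occurrence blocks injected into sample sets whose pairwise
overlap is bounded (default 0.2) so blocks are separable by construction;
and fusion events planted inside genes or in intergenic gaps, which the
tiled gene layout guarantees to exist.

Per-sample network backbones draw an exact discrete power-law degree
sequence at the group's target exponent (defaults 2.8 for mothers, 2.4
for children; 2.5/2.7/2.3 for CD/UC/non-IBD — all inside the
ultra-small-world band (2,3)) and realize it with the configuration
model. A tunable-exponent preferential-attachment scheme was considered
and rejected: nonlinear attachment kernels do not produce power-law tails
with prescribed exponents in (2,3), and in prototype measurements the
static fitness model biased fitted exponents upward at realistic sizes,
while the configuration-model route recovers the target to within a few
hundredths at 200–3000 nodes. Classic Barabási–Albert graphs (m = 2) are
kept (`samplePaNetwork`) for nested growth series, where snapshots of one
growing graph give genuine supergraph chains.

Edge multiplicities are geometric (minimum 1, default mean 1.67) so edge
weights vary; depths draw `r_i ~ Poisson(depth * l_i)` with per-sample
depth uniform in 3e-4–1e-3 reads/bp, putting event rates in the low
double digits on the natural-log scale, as cohort-scale gut metagenomes
show. Randomness flows from one root seed through named substreams
(taxonomy, events, blocks, motifs, fusions, depth), so components are
independently reproducible and the same configuration is byte-identical
across runs.

What passing synthetic tests shows — and what it does not: the generator
produces clean planted structure (exact key copies for shared events,
identical motif cliques on reserved genomes, blocks with bounded
overlap). Real data adds coordinate jitter beyond one bin, chimeric and
missed calls, incomplete reference databases and compositional depth
biases, none of which are modeled. Recovery on the generator therefore
validates the *pipeline logic* (the statistics, clustering and
containment machinery), not robustness to caller noise.

## Problem sizes

The validation suite runs at deliberate desk scale: cohorts of 3–6
families (or 6–12 patients) with networks of 20–250 nodes for structural
checks, 50 networks of 200–3000 nodes for the scale-free verdict, degree
samples of 1e3–1e5 for estimator consistency, and 10-seed repetitions for
stochastic claims (majority thresholds stated per test). These sizes were
chosen so the full suite exercises every stage in a couple of minutes
while keeping every stochastic margin comfortable; all of them are
parameters, and nothing in the package caps larger runs.

## Known limitations

* Breakpoint calling quality is invisible here: garbage in, garbage out.
* Event identity by fixed binning can split one true event across a bin
  boundary (mitigated, not eliminated, by the swap-invariant keying).
* The Vuong comparison assumes independent tail observations; degrees of
  one network are weakly dependent, so borderline ratios near zero should
  not be over-read.
* Leiden with a fixed seed is deterministic but not canonical: different
  seeds may split borderline communities differently; HCC/HEC membership
  for well-separated structure is stable across seeds.
* `num(label)` counts samples per group in the metadata supplied; if a
  dataset is subset after metadata creation, labels must be recomputed.
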