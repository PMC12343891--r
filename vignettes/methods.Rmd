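---
title: "Methods: automated gating by exhaustive projection pursuit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: automated gating by exhaustive projection pursuit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epp)
```

## The model and its assumptions

`epp` treats a compensated (or unmixed), pre-gated cytometry sample as a
draw from a mixture of cell phenotypes, each of which is approximately
unimodal in every marker dimension after a suitable display transform.
Under that assumption, any two phenotypes that are distinguishable at all
are separated by a density valley in at least one two-dimensional marker
projection, so a recursion over the best two-dimensional split at each
stage recovers every statistically supportable population — the same
spatial reasoning a human analyst applies, made exhaustive and
reproducible. Because each step is an ordinary 2-D gate, the output can be
reviewed, edited, or implemented on a sorting instrument with standard
tools; nothing in the procedure prevents follow-up analysis of the
resulting populations with higher-dimensional methods.

Two caveats are inherent. First, distributions exist whose components
cannot be cleanly separated by any sequence of axis-pair gates; in
practice, compensated marker panels rarely produce them, but the method is
blind to such structure by construction. Second, errors accumulate: an
event misassigned at one split is never recovered below it. The scoring
rule — fewest events near the boundary — is a proxy for choosing the
split with the fewest misallocations at each stage.

## Display transforms

Raw fluorescence values are mapped to the unit interval by the logicle
(biexponential) scale: linear around zero, logarithmic at high signal,
with `decades` (default 4.5) setting the dynamic range, `width_w` (in
decades; typically 0.5–1.55) the linearized region, and `top_of_scale`
the instrument value that maps to exactly 1. Mass cytometry uses the
4.3-decade, width-0 variant, which reduces to an arcsinh rescaled so the
configured top of scale maps to 1; small integer counts then land inside
the first decade without special-casing. The scale-to-data direction is
the closed-form biexponential; the data-to-scale direction inverts it by
vectorized bisection (64 halvings, resolution ≈ 1e-19 on the scale axis),
so the round trip is an identity to well below the 1e-9 contract the
tests enforce. Instruments differ in how a conventional top of scale is
chosen, so `top_of_scale` is deliberately a configuration value rather
than something inferred from data. Events with any retained value outside
the closed interval [0, 1], or any non-finite value, are censored
(dropped and counted) before analysis.

## Dimension qualification

At each node the marginal of every phenotyping dimension is compared with
a moment-matched normal reference; in mass mode the non-zero values are
also compared with a moment-matched exponential, because processed mass
data leave negative channels with a spike at zero and a roughly
exponential tail. The divergence estimator discretizes the sample onto
256 equal-probability bins of the fitted reference and accumulates
`sum(p log(p/q))` in nats with a +0.5 pseudo-count per bin. For data truly
from the reference its expectation is ≈ (256−1)/(2n) ≈ 0.006 at
n = 20,000, comfortably below the qualification threshold of 0.04 (0.2
for the exponential test), while a bimodal marginal with modes four
standard deviations apart scores well above it — the calibration the
acceptance tests verify. The binned estimator was chosen over, e.g.,
spacing estimators for stability at large n and because it only needs the
already-sorted data; its exact form is a design decision, so both
thresholds remain configuration values. Populations under 50 events score
0 (they are below any size at which the recursion should still be
splitting); a zero-variance dimension also scores 0 and is left to the
modal-clustering stage. Pairing rules guarantee at least one pair per
node: all pairs of qualified dimensions; one qualified dimension is
paired with the highest-divergence unqualified one; none qualified, the
two highest-divergence dimensions are paired.

## Density estimation

Each examined pair is binned onto a fixed 257 × 257 grid (node (i, j) at
coordinates (i/256, j/256)) with bilinear weights, conserving total event
mass exactly. Smoothing with an isotropic Gaussian kernel of standard
deviation W — initially 0.01 of full scale for fluorescence and 0.025 for
mass, the latter chosen for stability of sparse mass data — is applied in
the cosine-transform domain: the weight array is evenly extended to the
512-point period, multiplied in the Fourier domain by the transform of
the discretely sampled kernel, and truncated back. This is exactly
convolution with reflected (even) boundary conditions, the property the
acceptance suite checks against an explicit reflection-operator oracle at
sup-norm 1e-6. Kernels narrower than one grid step (1/256) are refused.
The density is normalized to unit trapezoidal integral over the unit
square; a second pass with the squared kernel, scaled by the same
constants, gives the pointwise variance of the estimate used by the dip
test. When a stage signals overload the kernel is widened by √2 and the
pair restarted from its weights; a cap of 8 widenings (then treating the
projection as yielding no split) guards against pathological inputs.

## Modal clustering and the cluster graph

Grid points are processed in descending density order (ties broken by
row-major index, making the scan fully deterministic). A point with no
cluster-labelled 4-neighbour founds a new cluster — it is a local
maximum; a point whose labelled 4-neighbours span two clusters becomes a
boundary point; otherwise the point joins its neighbour's cluster. To
limit counting noise, founding is only allowed above a noise floor: a
window whose length is the number of grid cells covering the kernel spot
(side 4W, i.e. `round((4W·256)²)` points) slides along the
density-sorted grid points, and the floor is the density at the top of
the first window holding more than σ² events (σ = 3, hence 9 events).
The "top of the first qualifying window" convention is ours; any point
inside that window differs negligibly. As each point is classified,
seven of its eight surrounding points are marked contiguous, the omitted
diagonal rotating on a counter modulo 4 (cycle NE, SE, SW, NW) for
radial symmetry. Below-floor points are then absorbed iteratively by the
same neighbour rule, restricted so no cluster can be founded below the
floor — a point seeing only boundary neighbours extends the boundary
instead. More than 12 clusters trigger kernel widening.

Boundary points separating exactly two clusters are grouped by that face
pair into 8-connected chains (edges); points seeing three or more
clusters form vertices. Each edge records its saddle (highest-density
point, ties row-major) and its endpoint keys — vertex components or
border terminations. Planarity is verified by an Euler check in which
border terminations become degree-1 vertices joined by arcs in perimeter
order and the exterior face is counted only when the border is touched:
V − E + F must equal 1 plus the number of connected components.
Inconsistent graphs (dangling chain ends away from the border, edges
with more than two endpoint keys, Euler violations, more than 32 edges)
are treated as the rare pathological cases they are and resolved by
widening the kernel — conservative and always available.

Events are assigned to clusters by the label of their nearest grid node,
with boundary nodes resolved deterministically to the lowest-numbered
adjacent cluster.

## The density-dip significance test

Edges are tested in descending saddle order: an edge survives only if
both adjacent mode densities exceed the saddle density by
z<sub>1−α/m</sub> standard errors, with SE² = Var(f̂ at the mode) +
Var(f̂ at the saddle) from the squared-kernel pass, α = 0.05 one-sided
and m the current edge count (Bonferroni; `"none"` available). The
variance uses the leading term (K²∗w)·c²·256⁴/n² and omits the −f̂²/n
correction, which slightly overstates SE and is therefore conservative.
The first insignificant edge is removed, its faces merged — the merged
face is represented by the higher of the two modes, a bookkeeping choice
any consistent rule could replace — edges left meeting at a now-degree-2
vertex with the same face pair are spliced into one, and the scan
restarts; it terminates when all remaining edges are significant (or
none remain, and the projection yields no split). The exact statistic
and calibration of density-based merging are design decisions here: the
z-type difference test matches the verbal definition of the procedure,
and α is exposed as configuration.

## Candidate boundaries via the dual graph

With more than two clusters, the valid separations are the edge subsets
forming one continuous curve that divides the plane into two contiguous
regions. These are enumerated on the dual graph (a node per face, a dual
edge per cluster edge, both as positions in 32-bit masks): repeatedly
remove a dual edge and merge its endpoints, OR-merging any dual edges
that then join the same node pair; every fully simplified dual — a
single composite edge — is dual to a candidate boundary, with the two
merged node sets as the partition. A depth-first stack search over
removal orders is pruned by requiring each removed composite to be
greater than everything removed before it. The comparison key is the
composite's *highest* constituent bit: comparing by the lowest bit
provably loses candidates once merged composites appear, while the
max-bit rule reproduces the brute-force partition enumeration exactly on
every random planar fixture in the acceptance suite (200 partitions with
2–6 faces). Duplicate masks are suppressed defensively, and every
emitted candidate is re-verified geometrically (each shared endpoint on
exactly two cut edges, open ends only at the grid border and then
exactly two, one connected curve) to guard the pathological cases the
planarity check cannot see.

## Scoring, selection and recursion

A candidate's raw score estimates the events within ±W of the boundary:
n × Σ density over boundary points × (2W/256). The scaling is
approximate by construction; only the ordering of scores is meaningful.
In the default best-balance mode the raw score is divided by
4·P·(1−P) — P being the event fraction on the side containing the
lowest-numbered face — so unbalanced splits are penalized; best-separation
mode uses raw scores and tends to pick small outlying populations first.
Degenerate candidates (P of 0 or 1) are discarded. The minimum adjusted
score across all pairs wins, with deterministic ties (pair indices, then
edge-mask value); raw strip scores are compared across pairs without
per-pair renormalization. Children are defined by cluster membership on
each side of the boundary — the reported polygon is a presentation
artifact with its own tolerance, so membership never depends on it. The
recursion is depth-first with the lower-weight child first (affecting
only leaf numbering), and stops on: no surviving candidate, fewer than
two phenotyping dimensions, or optional absolute/relative population
floors (off by default, since stopping on size is an optional behavior).
Everything is single-threaded in this implementation; the stage
decomposition would parallelize naturally, and determinism does not
depend on scheduling.

## Outputs

The gating tree is serialized as JSON: per split, the dimension pair, raw
and balance-adjusted scores, P, the kernel width used, and one gate
polygon per child — the marching-squares outline of the child's grid
region (closed along the border where needed), simplified by
Ramer–Douglas–Peucker at a tolerance of 1% of full scale (every removed
vertex stays within tolerance of the simplified polyline; endpoints are
preserved; degenerate inputs are returned unchanged). A CSV gives each
event's leaf id and its Mahalanobis distance from the leaf center over
the phenotyping dimensions. Both outputs are byte-stable across reruns.
Leaf labels (marker + / − against the parent's medians) are a heuristic
convenience, not a biological assessment. For comparisons with a
reference gating, `match_table()` counts shared events per population
pair, `jaccard()` is |A∩B|/|A∪B|, and `central_similarity()` recomputes
the Jaccard index after restricting A∪B to its central fraction (default
80%) by Mahalanobis distance from the union mean — the union reading
keeps the metric symmetric in A and B where a per-set reading would not
be. Singular covariances are ridge-regularized (1e-6 × trace) with a
warning.

## What the synthetic data do and do not emulate

`generate_mixture()` draws seeded Gaussian mixtures in the unit cube
(resampling out-of-cube draws, since clipping would create boundary
spikes that modal clustering would legitimately detect and null tests
would misread), with optional mass-mode dimensions replaced by
zero-inflated exponentials. This captures the features the algorithm
actually consumes — near-normal unimodal populations, valley-separated
modes, zero-spiked negative mass channels — but not spectral spillover
residuals, acquisition drift, doublets, or heavy-tailed outliers. Passing
the suite therefore demonstrates the algorithm's behavior under its own
model assumptions, not performance on any particular instrument's data.
`generate_planar_partition()` builds cluster-graph fixtures by running
the real clustering on mixtures of equal Gaussian bumps at seeded random
sites, so enumeration tests exercise graphs that satisfy every invariant
by construction.

## Problem sizes and numerical choices

The test and acceptance runs use n = 50,000 events for mixture-recovery
checks (50 seeded replicates of each of the two- and five-component
designs), n = 20,000 for the null control (100 replicates) and
qualification calibration, 200 random planar partitions for the
enumeration oracle, and 20 random weight arrays per kernel width for the
KDE oracle — sizes at which the Monte-Carlo margins in those checks are
comfortable while the full suite runs in minutes on one CPU. Key numeric
tolerances: bisection to 1e-14 for the logicle width equation and 64
halvings for the forward transform; KDE oracle agreement at sup-norm
1e-6; densities renormalized to unit trapezoidal integral; dip-test SEs
from the conservative leading-order variance; RDP tolerance 0.01 of full
scale; all sort-order ties broken by row-major grid index.

## Known limitations

Axis-pair separability is assumed, not checked; phenotypes only
separable along oblique or higher-dimensional directions are not found.
The dip test's calibration constants are this package's own; a different
choice of statistic would shift the significance boundary and hence leaf
counts on marginal populations. The 32-edge mask and 12-cluster cap
bound the graph complexity per projection — overly complex projections
are smoothed, not subdivided. Scores across pairs share a single
approximate scale; pathological cases where strip scores of different
pairs are not comparable would bias selection. Population labels are
heuristic. Compensation, unmixing, and live/single-cell pre-gating are
out of scope and assumed done upstream.
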