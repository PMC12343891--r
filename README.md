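# epp — automated cytometry gating by exhaustive projection pursuit

Phenotyping — delineating the distinct cell populations in a flow or mass
cytometry sample — is still mostly done by manual projection pursuit: an
analyst inspects two-dimensional marker plots, draws a gate around each
visible population, and repeats on every subpopulation until no clear
separation remains. The result is conventional and sortable, but slow,
subjective, and not guaranteed to find either the best separations or all
of them.

`epp` automates this procedure end to end while keeping its output
entirely conventional: a gating tree of ordinary 2-D polygon gates. At
every stage of the recursion the engine

1. **qualifies dimensions** — each marker's marginal is compared with a
   moment-matched normal (and, in mass mode, exponential) reference by
   Kullback–Leibler divergence; dimensions that look like a uniform
   positive or negative stain (KLD < 0.04 nats, exponential threshold 0.2)
   are set aside, and every pair of qualified dimensions is examined
   (with a fallback so at least the most promising pair is always tried);
2. **estimates the density** of each pair on a fixed 257 × 257 grid:
   events are linearly binned and smoothed with a Gaussian kernel
   (initial σ = 1% of full scale for fluorescence, 2.5% for mass) applied
   in the discrete-cosine-transform domain, which implies reflective
   boundaries; a second, squared-kernel pass provides the pointwise
   variance of the estimate;
3. **clusters modally** — grid points are classified in descending density
   order above a counting-noise floor (a sliding window covering the
   kernel spot must hold > σ² = 9 events), producing faces (one per
   density mode), edges (boundary chains between two faces) and vertices
   (where ≥ 3 faces meet) of a planar cluster graph; too many clusters
   (> 12) or edges (> 32) trigger a √2 kernel widening and a restart;
4. **tests every dip** — for each edge, the density at its highest point
   (the saddle) is compared with the two adjacent mode densities; the edge
   survives only if both modes exceed the saddle by z standard errors
   (one-sided α = 0.05, Bonferroni over the current edges), insignificant
   edges being merged away one at a time;
5. **enumerates candidate separations** — the dual graph is simplified by
   systematically removing dual edges (bit-vector representation, removal
   in increasing bit order), and every simple dual — one composite edge —
   is a continuous boundary splitting the sample into two contiguous
   regions;
6. **scores and recurses** — each candidate's score is the estimated event
   count in a strip of half-width W along the boundary; in the default
   *best balance* mode it is divided by the balance factor 4·P·(1−P),
   where P is the fraction of events on one side. The minimum-score split
   divides the population, and both children re-enter step 1. A population
   with no statistically supported split is a leaf — an **algorithmic
   phenotype**.

The pipeline is deterministic: the same input and configuration always
give the same tree, assignments and serialized outputs.

## Worked example

Three overlapping populations on two markers, with ground truth retained
by the generator:

```r
library(epp)

components <- tibble::tibble(
  weight = c(0.4, 0.35, 0.25),
  mean   = list(c(0.25, 0.3), c(0.7, 0.25), c(0.55, 0.75)),
  sd     = 0.05)
ev  <- generate_mixture(components, n_events = 30000, seed = 42)
fit <- epp(ev)
fit
#> <epp_fit> 30000 events, 5 nodes, 3 algorithmic phenotypes

tidy(fit)[, c("node", "parent", "n_events", "is_leaf", "phenotype", "P", "label")]
#>   node parent n_events is_leaf phenotype         P  label
#> 1    1     NA    30000   FALSE        NA 0.7506667   <NA>
#> 2    2      1     7480    TRUE         1        NA M1+M2+
#> 3    3      1    22520   FALSE        NA 0.5375666   <NA>
#> 4    4      3    10414    TRUE         2        NA M1+M2-
#> 5    5      3    12106    TRUE         3        NA M1-M2+

mclust::adjustedRandIndex(fit$assignment, true_labels(ev))
#> [1] 1
```

The root split peels off the upper-right population (P = 0.75 of events on
the other side), the second split separates the two lower populations, and
the three leaves reproduce the generating components exactly (adjusted
Rand index 1). `epp_assignments(fit)` returns per-event leaf ids with
Mahalanobis distances from the leaf centers; `write_epp_outputs(fit, dir)`
serializes the gating tree (JSON, with per-boundary scores and
RDP-simplified gate polygons) and the per-event CSV. `autoplot(fit)` shows
a split's density with its gates; `autoplot(fit, "tree")` draws the tree.

Real acquisitions enter through `read_events()` (FCS 3.0/3.1 or delimited
text) with per-dimension logicle / mass-logicle display transforms
declared in a small JSON or YAML config; out-of-range events are censored.
A thin command line lives at `inst/scripts/epp`
(`epp run`, `epp simulate`, `epp compare`).

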