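---
title: "Colored motif significance analysis: model, null, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Colored motif significance analysis: model, null, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coloredmotifs)
```

## The question the package answers

A wiring diagram alone treats every node alike. In a neuronal network,
however, a sensor neuron feeding an interneuron plays a different
computational role than an interneuron feeding a sensor, even though both
are the same one-arc topology. This package analyzes *colored* motifs:
isomorphism classes of small connected induced subgraphs in which each node
carries a categorical label (a color), so that topology and labeling are
matched simultaneously. The driving application is the *C. elegans*
somatic nervous system — three colors (sensor, inter, motor), directed
chemical synapses, undirected gap junctions — but nothing in the machinery
is specific to it: the color alphabet is configurable and the graph model
is any simple mixed graph.

The statistical question is conditional: **given the observed wiring,
are particular colorations of motifs more common than expected if colors
were interchangeable?** The null model therefore randomizes the color
assignment only, never the edges. This deliberately differs from the
edge-rewiring controls of classical (uncolored) motif analysis, which test
a different hypothesis; no edge-rewiring null is provided.

## Graph model and encodings

A `colored_graph` holds nodes with exactly one color each, a set of
directed arcs, and a set of undirected links stored canonically
(`from < to`). Self-loops are rejected and duplicate edges merge (the
census is unweighted; synapse multiplicities are out of scope). Two derived
views feed the census:

* **Directed encoding** — each link {u, v} becomes the reciprocal arc pair
  (u, v), (v, u), which is exactly what an adjacency matrix representation
  of a gap junction is. A consequence worth stating: an arc and a link
  between the same pair collapse onto the same reciprocal pair, and a
  reciprocal pair of chemical synapses is indistinguishable from a gap
  junction *inside a motif class*. The `colored_graph` retains both edge
  kinds so reports can flag such pairs (`has_reciprocal` in the
  classifier's output); the census itself follows the matrix.
* **Undirected projection** — every edge, whatever its kind or direction,
  becomes a link; this is the substrate of the undirected census mode.

Connectivity is *weak* connectivity in directed mode. This is forced by
the combinatorics: the uncolored directed class counts (13 classes of size
3, 199 of size 4) are the weakly connected digraph counts.

## Census and canonical keys

The census enumerates every connected induced k-subset exactly once with
the ESU algorithm (the FANMOD core) and canonicalizes each instance by
exhaustive permutation: the key is the lexicographic minimum, over all k!
simultaneous row/column and color-sequence permutations, of the pair
(adjacency bit code, color sequence). At k ≤ 4 this means at most 24
permutations per instance, so no partition-refinement canonicalizer is
needed; the enumeration and canonicalization loops are C++.

Keys serialize as `"k|mode|adjacency-code|color-code"` — e.g. the
sensor→inter→motor relay chain is `"3|d|6|201"` — and parse back with
`parse_motif_key()`. Counting is of *induced* subgraphs, overlaps allowed,
matching the actual-vs-possible bookkeeping of the class enumeration:
`enumerate_motif_classes()` brute-forces every edge configuration ×
coloring, filters connected ones, and deduplicates by the same canonical
key. Size 5 is refused by design: with three colors the possible class
count reaches the millions and the multiple-testing machinery below loses
all power at any realistic number of randomizations.

```{r table1}
nrow(enumerate_motif_classes(3, 3, "directed"))   # 273 possible classes
nrow(enumerate_motif_classes(4, 3, "directed"))   # 13,770
```

## The color-permutation null

`shuffle_colors()` implements the null: repeatedly switch the colors of two
randomly chosen nodes. The swap count is not critical — any number of
transpositions beyond coupon-collector scale mixes the chain — and the
default is **10 swaps per node**. The stationary distribution of this chain
is the uniform permutation of the color vector, available directly as
`method = "permute"`; the test suite verifies the two are equidistributed
on a small graph where all arrangements can be tabulated. Both preserve
the topology and the color histogram exactly, which the ensemble tests
assert per replicate.

`build_ensemble()` runs N independent shuffles, censuses each, and aligns
the counts into an N×M matrix over the union of classes seen in the real
graph or any replicate (all-zero classes outside that union cannot affect
any statistic below — their replicate raw P-values are ~1 and never the
minimum). Replicate r's random stream depends only on (seed, r): the
master seed draws N sub-seeds up front, so the matrix is reproducible and
indifferent to evaluation order.

## Per-motif statistics

For each class: observed count, null mean, null SD, z, log2 ratio, raw
permutation P, min-P adjusted P, and a two-tailed one-sample t-test of the
ensemble column against the observed count (the t-test treats the ensemble
as the sample; the observed count is the hypothesized mean).

Numerical conventions, chosen once:

* **σ is the population SD** of the ensemble column (divide by N): the
  ensemble *is* the null distribution, and at N ≥ 1000 the N/(N−1) choice
  is invisible in rank-ordered reporting.
* **Degenerate nulls**: σ = 0 gives z = 0 when the observed count equals
  the null mean and ±Inf otherwise; log2 ratios use ±Inf when exactly one
  of the two counts is zero and NA when both are.
* **Ties count as exceedances** (Heaviside H(0) = 1): raw P is the
  fraction of replicates with a count *at least* the observed count, so
  p = 0 means strictly more abundant than every randomization.
* **One-sidedness**: the permutation P and min-P machinery test
  over-representation only; suppression is reported through negative z and
  log2 ratios and the two-tailed t-test.

### Single-step min-P

The adjusted P-value compares each motif's raw P against the distribution
of the *most extreme* raw P attainable by chance within its size class:
for each randomization r, `p̃_i^(r)` is the raw P of replicate r's count
against the counts of the **other** replicates (divided by N, ties
counting), `m*^(r) = min_i p̃_i^(r)`, and
`P_adj(i) = (1/N) Σ_r H(p_i − m*^(r))`. The adjustment is performed
separately per size class.

Excluding the self-comparison in `p̃` is deliberate and load-bearing. It
mirrors how the observed count is treated (the observed graph is not a
member of its own ensemble), making the procedure symmetric under
exchangeability — this is what gives the family-wise type-I control that
the calibration tests verify. And it permits `m*^(r) = 0` (replicate r
strictly exceeding all others for some motif), which produces the
characteristic *floor*: the smallest attainable adjusted P equals the
fraction of randomizations with a vanishing minimum. With 100,000
randomizations and 5,560 vanishing minima the floor is 0.0556 exactly:

```{r floor}
min_p <- c(rep(0, 5560), runif(100000 - 5560, min = 1e-9))
adjust_from_minp(0, min_p)
```

The floor shrinks as N grows, and — the flip side — it grows with the
number of effective hypotheses M. As a rule of thumb significance at
α = 0.05 needs N to exceed M several-fold. At the package's routine test
scale (N = 200) this means only the 2-node family (15 possible classes
with three colors) can clear the floor; 3-node analyses (273 classes) need
N in the thousands and 4-node analyses (13,770 classes) far more. This is
a property of the method, not of the implementation, and it dictated the
design of the calibration studies below.

## The synthetic generator and what the tests do (and do not) show

`generate_network()` draws a simple graph with exact arc/link counts,
uniformly placed edges, and colors assigned by a uniform permutation of the
color multiset — precisely the exchangeability the shuffle null assumes.
`worm_preset()` fixes the worm-scale summary statistics: 279 nodes, 2,194
arcs, 514 links, 86 sensors, 80 interneurons, and motor neurons as the
remainder — 113, since the published 86/80/114 split over-counts 279 by
one and the 29% interneuron baseline pins the total at 279. An optional
heavy-tailed out-degree model exists for robustness exploration only; the
calibration studies use the uniform model.

`plant_motif()` adds vertex-disjoint copies of a colored motif onto
existing, pairwise-edge-free nodes of matching colors, so node count,
color frequencies — and hence the shuffle null — are untouched and each
instance is induced. Reciprocal pairs in the planted class are written as
links.

Study conditions of the two standing experiments, fixed once:

* **Type-I calibration**: 100 independent 100-node backgrounds
  (34/33/33 colors, 30 arcs), exchangeable colors, N = 200, 2-node
  directed census; the fraction of runs in which *any* motif reaches
  adjusted P ≤ 0.05 must be compatible with 5% (binomial tolerance). The
  2-node family is used because it is the regime where flags are
  attainable at N = 200 — at size 3 the floor exceeds α and the check
  would pass vacuously.
* **Planted recovery**: the same background plus 20 planted sensor→inter
  pairs; across 50 seeded repetitions the planted class must rank first by
  z *and* clear α after min-P correction in at least 95%. A pilot of the
  *null* floor (no planting) guided the background density: the experiment
  is only well-posed where the floor sits below α. A size-3 relay chain
  planted at the same scale is additionally required to rank first by z;
  its adjusted P cannot clear the floor at N = 200 for the reasons above,
  and the suite does not pretend otherwise.

What passing these tests shows: the census is exact (it is checked
instance-for-instance against a brute-force subset oracle on ~100 random
graphs), the null is unbiased, the correction controls the family-wise
error, and planted structure of realistic effect size is recovered. What
they do not show: behavior on real connectomes, whose reciprocity, degree
heterogeneity and modularity the uniform generator deliberately does not
emulate, and whose size-3/4 significance lists require ensembles of 10^5
randomizations.

## Structural classification of significant motifs

Feed-forward-dominated wiring sorts 4-node directed motifs into five
recurring families. The families are usually described by example rather
than by definition — a bi-fan has two high-in-degree outputs, a nested
feed-forward *usually* a single one — so the package fixes one consistent
set of predicates, evaluated in order:

1. **bifan** — exactly two sinks, each with in-degree ≥ 2, and exactly two
   sources;
2. **chain** — acyclic with every in- and out-degree ≤ 1 (acyclicity added
   so the directed 4-cycle, whose degrees also satisfy the bound, falls to
   *other* with the rest of the rings);
3. **ffl_entry_exit** — an induced 3-node feed-forward loop plus a fourth
   node attached by exactly one arc;
4. **nested_feed_forward** — acyclic, a single sink, and at least one node
   pair joined by two distinct directed paths (a feed-forward "shortcut");
5. **integration_bifurcation** — acyclic with no shortcut pair: signals
   only merge and branch;
6. **other** — everything else, notably anything cyclic.

These predicates label all 199 directed 4-node topologies exactly once and
agree with the drawn exemplars of each family; they are one consistent
completion of a prose taxonomy, and are documented as such. Motifs whose
key contains a reciprocal pair are classified on that encoding and flagged,
since an undirected edge can straddle two families.

## Known limitations

* Synapse multiplicities and edge weights are ignored; the census is of
  the simple graph.
* The directed encoding cannot distinguish a gap junction from a
  reciprocal synapse pair inside a motif class (flagged, not resolved).
* Only the single-step form of min-P is implemented; the step-down variant
  tightens nothing at the floor, which is the binding constraint in
  practice.
* Exact enumeration only (no RAND-ESU sampling), sizes 2–4.
* With ensembles of a few hundred randomizations, min-P significance is
  attainable only for motif families whose class count is well below the
  number of randomizations; that is the method's arithmetic, and the
  package reports the attainable floor (`min_attainable_p_adj` in
  `glance()`) so users can see it.
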