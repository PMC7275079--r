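---
title: "Dynamic plex percolation: model, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic plex percolation: model, parameters, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dynplex)
```

## The problem

Functional brain networks inferred from multichannel voltage recordings
are binary graphs that change from second to second, and the edges are
noisy — in particular, true connections are frequently *missed*
(type-II edge noise), because type-I errors are what the inference step
controls.  Tracking how groups of nodes organize and reorganize over
time in such sequences is the dynamic community detection problem.
`dynplex` implements a percolation-style answer: communities are
maximal aggregations of small template subgraphs (*k-plexes*) that can
be "walked" within a time slice and, through an explicitly constructed
bridge, across adjacent slices.

A k-plex of size $m$ is a vertex set $S$, $|S| = m$, in which every
member is adjacent to at least $m - k$ of the others — each vertex may
miss at most $k - 1$ neighbors.  A 1-plex is a clique, so the method
strictly generalizes clique percolation (CPM); the slack $k$ is what
buys robustness to missing edges.  The definition requires $m > k \ge 1$.

## The method

For a sequence $G_1, \dots, G_N$ on a common vertex set of size $p$:

1. **Within slices.** All maximal k-plexes with at least $m$ vertices
   are enumerated in each $G_t$.  Two plexes belong to the same static
   community when they are linked by a chain of pairwise vertex
   overlaps of at least $m - 1$ (one can be walked to the other, one
   vertex exchanged at a time).  The secondary plex-overlap graph is
   never materialized; only its connected components are computed.
   Communities may overlap — an element can carry several labels.
2. **Across slices.** For every adjacent pair $(G_t, G_{t+1})$ an
   enhanced *bislice* graph on $2p$ vertices is built: both slices'
   observed edges, a *self* (maturation) edge $v_t$–$v_{t+1}$ for every
   vertex, and mirrored *railroad* edges $u_t$–$v_{t+1}$,
   $v_t$–$u_{t+1}$ for every edge present in both slices.  Maximal
   k-plexes of this graph are percolated by the same $m - 1$ rule.  A
   plex with vertices on both sides must contain at least one railroad
   edge to count (*admissibility*): self edges alone carry no evidence
   that structure persisted, and without this rule any vertex would
   bridge time whenever $m - k \le 1$.  For $m - k \ge 2$ the degree
   condition already forces railroads into any cross plex, so the rule
   only bites in the degenerate regime.
3. **Label propagation.** The static and bislice community fragments
   are merged to a fixed point: two fragments join when, at some common
   slice, they share an observed labeled edge, or at least $m - 1$
   labeled vertices.  The closure is computed by union-find, so the
   result is idempotent and independent of processing order, and every
   dynamic community ends with one id spanning its full extent forward
   and backward in time.  There is no randomness anywhere in the
   procedure.

The exact published semantics of the propagation step are not spelled
out beyond "iterative forward and backward propagation"; the fixed
point above is this package's reconstruction.  The shared-edge clause
is what lets a persistently present edge hold one community together
across three or more slices even when the per-slice fragments are
small; the vertex clause mirrors the plex-walk threshold.  Note one
consequence of walking in the doubled graph: both copies of a shared
vertex count toward plex overlap, so two static communities sharing
$\lceil (m-1)/2 \rceil$ vertices can merge across time even though they
stay distinct within a slice.  This is intrinsic to the construction,
not an implementation choice.

### Exact versus heuristic mode

Exact mode (the default) runs all three steps.  Heuristic mode runs
only step 1 and then links communities at $t$ and $t+1$ whose vertex
overlap is strictly greater than $m - 1$ (configurable to "at least",
and optionally also requiring an edge present in both slices and
labeled in both communities).  This is dramatically cheaper — no
$2p$-vertex enumeration — and on persistent, well-separated community
structure it provably reaches the same answer; the test suite pins this
on constant disjoint-clique networks.  On overlapping or rapidly
changing structure the two modes genuinely differ (exact mode can merge
via cross-slice plexes the heuristic never sees), so exact mode remains
the normative default, and the package uses heuristic mode only for the
large benchmark studies, where per-slice communities are large and
persistent.

### Parameters that matter

* `m` (minimum plex size) and `k` (plex order): `(4, 2)` and `(5, 3)`
  are the workhorse settings — the motif scale of functional networks.
  `(3, 2)` is legal but degenerate-adjacent ($m - k = 1$); with
  admissibility on it behaves as designed and reproduces the toy
  ladder below.
* CPM baseline: minimum clique size `m` (3–5), an across-time linking
  threshold (default 1 shared vertex, the value the deterministic toy
  outcomes pin down), and a seed for its coin-flip tie-breaks — unlike
  DPPM, CPM's linking is stochastic.
* Enumeration guard: exact enumeration refuses graphs above `cap`
  (default 512 nodes) because the worst case is exponential; the
  enumerator peels vertices of degree < `m - k` and, when
  $m \ge 2k - 1$ (a k-plex that large is necessarily connected), works
  per connected component.  The opt-in clique-first shortcut mirrors
  the published speed-up but can miss maximal plexes that straddle
  cliques, so it is never the default.

## The benchmark generators

`make_scenario()` plants the four stereotyped behaviors — expansion,
contraction, splitting, merging — on 64 nodes, in 20-layer intervals
(100 layers for split/merge, 140 for expand/contract; one layer
represents 1 s).  Active nodes share a single planted label (stored as
label 0, outside the random range so noise can never coincidentally
join the planted block); all other nodes redraw a uniform label in
1..64 independently every layer, so the background is full of tiny
one-layer coincidental blocks.  Contraction is expansion with the time
axis reversed, layer by layer.  Within each same-label block, expected
degrees follow a truncated power law (exponent −2, bounds [3, 20],
capped at block size − 1) and edges are realized by a degree-corrected
Chung–Lu-style sampler with up to 100 rejections of self/duplicate
draws per block; mixing is 0, so edges never cross blocks.  This is a
deliberately simplified re-implementation of the published multilayer
benchmark generator: it honors the five printed parameters, but not
that generator's interlayer dependence beyond the label matrix.  What
passing tests show is therefore recovery of *planted block structure
under label noise*, not performance on real recordings — real
functional networks have transitive correlation structure, volume
conduction, and non-stationary density that no block sampler emulates.

`noise_template_sim()` replicates a fixed connected 9-node, 8-edge
template (a tree, by the counts) for 100 layers, deleting two uniformly
chosen edges per layer — pure type-II noise.  The published template is
available only as a figure; the default here is a synthetic double star
(hubs 3 and 5), consistent with the reported two-hub structure.  On
this template a run's dominant community is robustly tracked, but runs
where the hub–hub bridge edge drops out of consecutive shared-edge sets
while one star's shared edges thin can split the track or shed small
transient fragments: across 100 runs roughly a quarter produce exactly
one community (mean count ≈ 2.7).  A single-hub star template would
make the single-community outcome deterministic (every shared edge
percolates through the hub, and at least $8 - 2 \times 3 = 2$ edges
survive any three consecutive layers); the double star was kept because
it is the faithful reconstruction, and the acceptance script reports
the honest distribution.

`toy_fixture()` provides the deterministic 7-node, two-layer ladder:
two triangles at layer 0, a single connected component at layer 1
sharing 0, 1, or 2 edges with layer 0.  DPPM (3, 2) distinguishes the
three cases (3, 2, and 1 dynamic communities); CPM cannot (always 2),
because its ad hoc overlap linking ignores which edges persist.

## The inference front-end

`infer_functional_networks()` turns a channels × samples voltage array
into one binary graph per window: zero-phase FIR band-pass (order 1000,
4–50 Hz, applied forward and reverse via FFT convolution), 1 s windows
hopped by 0.5 s (trailing partial windows dropped), per-window
per-channel standardization (population variance; flat channels are
flagged and excluded from that window's edges), then for every channel
pair the maximum absolute cross-correlation over lags up to ±0.2 s.
The null model follows the published recipe to the extent it is
printed: the statistic is referred to a zero-mean normal whose variance
is the dataset-wide average, over all pairs and windows, of the
variance of the cross-correlation across lags.  Because the statistic
is a maximum over ~200 correlated lags, the tail probability is
Bonferroni-corrected by the number of lags before Benjamini–Hochberg
FDR at q = 0.05 within each window; without that correction every pair
would look significant under pure noise.  This combination keeps the
false-edge density of independent white noise at (in practice well
below) the FDR level while detecting a duplicated channel in
essentially every window.  The lag range and the per-window
multiple-comparison family are declared defaults, not published values.
No re-referencing is applied.

## Scoring

`sensitivity_specificity()` compares the largest detected community
$c_L(t)$ (greatest total node-layer extent; ties broken by first layer,
then smallest member id) against the planted trajectory $c_T(t)$,
summing $TP = \sum_t |c_T(t) \cap c_L(t)|$ and its three companions
over all layers, with complements inside the fixed vertex set; then
$S^+ = TP/(TP+FN)$, $S^- = TN/(TN+FP)$.  Community lifespans are
first-to-last layer inclusive (interior gaps count — a convention, and
the conservative one for persistence claims) times an explicit
layer-duration; node loyalty is the labeled-layer fraction; recruitment
ranks use mid-ranks for ties and keep never-joining nodes missing
through the median-across-runs reducer.

## Problem sizes used by the shipped studies

The test suite and `scripts/acceptance.R` run the toy ladder exactly;
the noise study at its full 100 layers × 100 seeds; the scenario study
at the printed network sizes (64 nodes, 100/140 layers) with 25 seeds
per scenario in the acceptance script and 6 in the tests — a seed count
chosen so the whole study remains a desk-scale computation on one CPU;
the separation between DPPM and CPM sensitivities (≈ 0.91 vs ≈ 0.12) is
far wider than seed-to-seed variation, so more seeds change nothing
qualitative.  The inference checks run the full 64-channel, 100 s,
500 Hz geometry.  The clinical analyses the method was built for
(seizure-onset community expansion, recruitment maps, outcome
correlations) require recordings that are not redistributable and are
out of scope here; the statistics they would consume (`community_stats`,
`node_loyalty`, `recruitment_order`) are implemented and tested on
synthetic data.

## Known limitations

* Exact enumeration is exponential in the worst case; the `cap` guard
  and the heuristic mode are the intended escape hatches.
* The multilayer modularity baseline (GenLouvain) is not implemented;
  its published comparison grids (γ ∈ {0.01, 0.1, 0.5, 1, 2},
  ω ∈ {0.01, 0.1, 0.5, 1, 2, 5, 10}, Newman–Girvan null, discard of
  communities smaller than 3 nodes or lasting one step) are recorded
  here for completeness only.
* Weighted networks, links across non-adjacent layers, and
  time-varying plex order are out of scope.
* The label-propagation fixed point and the bislice admissibility rule
  are reconstructions of an incompletely specified published procedure;
  both are documented above and pinned by tests on every outcome the
  publication states deterministically.
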