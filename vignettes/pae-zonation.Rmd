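---
title: "Parsimony analysis of endemicity with PAEzone: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Parsimony analysis of endemicity with PAEzone}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(PAEzone)
```

## The method

Parsimony analysis of endemicity (PAE) classifies geographic areas by their
shared species the way cladistics classifies taxa by shared characters.  The
data object is a binary areas-by-species matrix: areas are the "taxa" (rows),
species the "characters" (columns), and a cell is 1 when the species occurs
in the area.  A maximum-parsimony tree over the areas — the area cladogram —
then groups areas that share many species, and a clade backed by species
found in *all* of its areas and *nowhere else* (synapomorphic species) is
interpreted as an area of endemism (AOE).

Because parsimony needs a rooting and a direction of character change, an
artificial area with no species at all (the *hypothetical root*) is appended
to the matrix.  Every recorded species is then a variable character
(present somewhere, absent at the root), and rooting the cladogram on this
all-zero area orients the nesting of areas from species-poor towards
species-rich assemblages.

The scoring engine is Fitch parsimony for unordered binary characters: a
post-order pass assigns each internal node the intersection of its child
state sets when non-empty, otherwise the union at the cost of one step.  The
compiled kernel actually applies Hartigan's majority rule at each node,
which is identical to Fitch on bifurcating nodes for two states and remains
exact on multifurcations — so the same kernel scores consensus trees and the
basal trichotomy of unrooted trees without special cases.  Ambiguous "?"
cells carry the full state set \{0,1\}.

## Search strategy

Tree search follows standard parsimony practice:

* **Starting trees** by stepwise addition: areas are added in a (seeded)
  random order, each attaching to the edge that minimizes the Fitch length.
  Ties go to the first-encountered edge under a fixed, documented edge
  ordering, so a run is exactly reproducible from its seed.  A
  `deterministicAddition` mode uses the lexicographic area order instead.
* **Branch swapping** by tree bisection-reconnection (TBR): the tree is
  bisected on every edge and all reconnections between edge pairs of the two
  reduced halves are tried (bisections on external edges contribute the
  single-tip moves; on 4 taxa the neighborhood already spans all three
  topologies).  SPR and NNI are available as restricted moves.
* **Acceptance** is first-improvement with a full restart of the sweep after
  each accepted move.  Equal-length distinct topologies are pooled (capped
  at `maxTrees`, default 1000, with a truncation warning) but are *not* used
  as further swap bases unless `steepest = TRUE`.  The source analyses of
  this kind name TBR but no acceptance policy; this policy was chosen
  because it is deterministic given the seed and cheap.  Plateau walking
  (`steepest`) matters on noisy matrices, where equal-length networks of
  topologies separate local from global optima: in the oracle-equivalence
  experiments the `steepest` setting is what makes 5 random-addition
  replicates reliably reach the exact optimum on random 5-8-area matrices.
* **Exhaustive search** enumerates all `(2n-5)!!` topologies up to 9 areas
  and is the testing oracle for the heuristic.

Ties and orderings everywhere (addition order, neighbor order, pool
membership) follow canonical rules — areas by label, edges by row order —
so identical configurations reproduce identical outputs byte for byte.

## Fit indices and tree-length distributions

For each species the minimum steps over all trees is `m` (0 for a constant
character, else 1), the observed steps on the designated tree `s`, and the
worst-case steps `g = min(#0s, #1s)`.  The ensemble indices are
CI = Σm/Σs, RI = (Σg−Σs)/(Σg−Σm), RC = CI·RI and HI = 1−CI.  Constant
characters are always excluded; parsimony-uninformative variable characters
(singletons, `m = s = g = 1`) are *included* by default — the common
parsimony-software convention — with `includeUninformative = FALSE` to drop
them.  HI = 1−CI and RC = CI·RI hold to machine precision by construction;
when a result carries several equally parsimonious trees the indices are
computed on the first and verified across all, any divergence being reported
per tree.

The random-tree length distribution draws labeled topologies uniformly by
sequential insertion at uniformly chosen edges (one sampler, shared with the
synthetic generator) and summarizes lengths by mean, SD and the adjusted
Fisher-Pearson sample skewness `g1 = n/((n−1)(n−2)) · Σ((x−x̄)/s)³` — one of
several definitions of sample skewness; this one was fixed and documented.
A strongly negative `g1` indicates hierarchical signal.  Note that a
standardized `g1` is bounded by roughly `±√n`, so values reported in the
hundreds in the applied literature cannot be this statistic and are not a
reproduction target.

## Bootstrap and consensus

The nonparametric bootstrap resamples species columns with replacement to
the original character count, keeping the root area in every replicate, and
reruns the search with reduced effort (one addition replicate by default;
both replicate counts are configurable — the source analyses do not state
theirs, and 100 replicates is the conventional minimum).  When a replicate
returns several equally parsimonious trees, each split receives a fractional
weight so that one replicate contributes exactly one unit, avoiding
over-counting.  Supports are mapped onto the strict consensus of the
full-data MPTs — matching the convention of annotating the final parsimony
tree — with a flag to annotate the bootstrap majority-rule tree instead.

## From tree to zones

The published zoning rule is prose ("areas at the ends of the same branch
are combined and nested into the areas at superior branches").  PAEzone
formalizes one consistent reading, with "superior" read root-to-tip:

1. Root the support-annotated consensus on the hypothetical root area and
   prune the root tip.
2. Traversing from the root, every *maximal* clade with support ≥
   `supportFloor` (default 70, echoing the convention of trusting nodes
   above 70%) and ≥ `minZoneSize` areas (default 2) becomes a zone.
3. A tip hanging beside a qualifying sibling clade nests into the first such
   zone in traversal order; tips absorbed by no qualifying clade become
   singleton zones.
4. Within a zone, cherries (sister tip pairs strictly inside the zone's
   clade) become subzones; remaining tips attach directly.

Zones always partition the non-root areas (asserted on every output).  The
AOE criterion is fixed at ≥ 2 strict synapomorphic species by default
(standard PAE practice; configurable), with a leniency parameter admitting
species that leak into at most `k` outside areas as "near-supporters".
Zone labels are generated (A, B, C, ... in traversal order), not matched to
any published naming, which is presentation.  An exact published zone count
is not guaranteed by this formalization: where a study's internal decisions
(e.g. zone vs subzone status of weakly supported clades) are unstated, the
rule here is deterministic and configurable rather than matched.

## The synthetic generator

`simulateMatrix()` emulates the structure PAE assumes: a rooted binary
"true" area tree is drawn uniformly (or supplied); every non-root clade
receives `endemicsPerClade` species occurring exactly in that clade;
`nWidespread` species occur in all real areas; `nSingleton` species occur in
exactly one; and every real-area cell is flipped independently with
`flipProbability`, injecting homoplasy.  The all-zero root row is appended
afterwards and never touched by noise — the root is an analytic device, not
data.  At flip probability 0 every planted endemic is a strict synapomorphy,
each character costs exactly one step on the true tree, every internal edge
is supported, and the search provably recovers the planted topology with
CI = 1; this is the identifiable end of the dial that the test suite pins
down exactly.  The default fixture (8 areas, 5 endemics per clade, 10
widespread, 5 singletons, flip 0.05, seed 20200812) is small, fast and
non-trivial.

What the generator does *not* emulate: spatially structured dispersal,
richness gradients, correlated absences from uneven sampling effort, or
taxonomic error.  Passing the recovery tests therefore demonstrates
correctness of the machinery under the hierarchical-vicariance model, not
robustness of PAE to real survey data.

## Problem sizes and numerical choices

The validation experiments run at sizes chosen to keep the whole suite
interactive: oracle equivalence on 200 random matrices of 5-8 areas and
10-40 characters (the exhaustive oracle caps at 9 areas = 135,135
topologies); noise-response curves over 30 seeds at flips 0.02 and 0.15 on
the 8-area fixture; bootstrap calibration with 100 replicates.  Real PAE
matrices (tens of areas, hundreds of species) run through the same code
paths; only the exhaustive oracle is size-limited.

Degenerate inputs are handled explicitly: matrices of constant characters
give length 0, undefined indices with a warning, and an undefined (NaN)
skewness; uninformative matrices yield star consensus trees; Σg = Σm makes
RI undefined (warning) rather than silently 0/0.  Ambiguous cells count as
absences in richness, supporter and widespread computations (documented
behaviour, as supporter status should not be granted on unknown evidence),
while in tree scoring they take whichever state is cheaper.

## Known limitations

* The zonation rule is one formalization of a prose procedure; alternative
  readings (tip-to-root nesting, support-gated subzones) are plausible and
  would change zone counts on weakly supported trees.
* Bootstrap replicates default to reduced search effort; on hard landscapes
  this can depress support values slightly compared to full-effort
  replicates (a `replicateConfig` argument restores full effort).
* The exhaustive oracle refuses more than 9 areas, so global optimality on
  study-sized matrices is corroborated only by replicate convergence.
* Split bookkeeping stores label sets; for matrices with hundreds of areas
  a bitset representation would be faster.
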