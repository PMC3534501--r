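---
title: "Assigning protein structural domains by clustering: models, parameters and design choices"
author: "domaincut"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assigning protein structural domains by clustering}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(domaincut)
```

## The model

A structural domain is treated as a compact region whose internal buried
contacts outnumber its contacts to the rest of the structure. Both
algorithms in this package make that operational through hierarchical
agglomerative clustering of geometric objects — buried α-carbon positions
(CA algorithm) or secondary-structure element vectors (SS algorithm) —
followed by a single gap-based cut of the merge dendrogram. Nothing in
either pipeline looks at chain identity until output time, which is why
domains spanning several chains come out naturally.

The underlying assumptions are worth stating because they bound where the
method works:

* domains are spatially compact and separated by a region of lower contact
  density — interdigitated or highly elongated domains violate this;
* the separation shows up as one (or more) clear height gaps in the
  average-linkage dendrogram;
* buriedness computed from Cα density alone (no side chains, no solvent
  model) is a fair proxy for the hydrophobic core.

## The CA algorithm step by step

1. **Burial**: a residue is buried when at least `burialCount = 9` other
   Cαs lie within `burialRadius = 7` Å (the residue itself is not
   counted). Counting runs across all chains.
2. **Distance matrix** over buried residues only: Euclidean Cα–Cα
   distances. With `useSSEConstraint = TRUE` (default) pairs inside one
   helix or strand are clamped to `constraintDistance = 4` Å — roughly the
   backbone Cα spacing — which discourages boundaries mid-element. The
   analogous `useSheetConstraint` clamps same-β-sheet pairs but is off by
   default: it helps some sheet-rich structures and hurts others, so it is
   left to the user.
3. **Average-linkage clustering** to a dendrogram, then the m/s cut
   (below).
4. **Exposed attachment**: every exposed residue joins the cluster of its
   nearest buried Cα (Euclidean; ties go to the lower residue index).
   Attachment happens *before* cleanup, so cleanup sees complete domains.
5. **Cleanup**: domains smaller than `minClusterFraction = 0.10` of the
   largest are deleted (orphans re-attach to the nearest retained
   residue); then, per chain, maximal same-domain segments shorter than
   `minSegmentLen = 20` residues that are enclosed by one same other
   domain, or that touch a chain end, are absorbed. The scan repeats to a
   fixed point — the published description is a single pass, but repeating
   handles cascades (each absorption strictly reduces the number of
   segment boundaries, so termination is guaranteed) and is idempotent on
   anything a single pass would already fix.

If fewer than two residues are buried (short peptides), the pipeline
returns one domain with a warning rather than failing: for such inputs the
notion of a buried core is vacuous.

## The SS algorithm step by step

Elements are maximal runs of helix (DSSP codes H, G, I) or strand (E)
labels, split at chain boundaries and at chain breaks — a consecutive
Cα–Cα distance above 4.5 Å or a gap in author numbering. Runs shorter than
3 residues are demoted to coil: a principal axis needs at least two
distinct points, and two-residue "strands" are annotation noise more often
than geometry. Each element becomes a vector: direction = unit eigenvector
of the 3×3 covariance of its Cα coordinates with the largest eigenvalue,
sign-chosen to point N→C; endpoints = projections of the first/last
residue onto the axis through the center of mass. Helices and strands
curve, but gently enough that a straight vector represents them well at
domain scale.

Element distances are either midpoint distances (default — it performed
best in the original parameterisation) or closest approach of the two
segments. Sequence-consecutive same-chain elements are clamped to 4 Å by
default, which keeps consecutive elements together unless geometry clearly
says otherwise and so reduces fragmented assignments. After clustering and
cutting, clusters with fewer than `minClusterElements = 3` elements
dissolve: each orphan element joins the retained cluster with the smallest
average distance to it. If *no* cluster survives that rule the assignment
falls back to a single domain with a warning. Finally, within each chain a
domain boundary is placed midway along the sequence between consecutive
elements of different clusters (`floor` of the mean of the neighbouring
residue indices); residues outside any element follow the nearest flanking
element, and an element-free chain follows the element nearest its
centroid, so every residue is always assigned.

The algorithm requires at least `minElementsRequired = 3` elements and
otherwise raises an error directing the user to the CA algorithm — with
one or two vectors the cluster structure is meaningless. The threshold is
a documented package choice; "enough secondary structure" has no standard
definition.

## The dendrogram cut

Both pipelines share the cut rule, controlled by the only two real tuning
parameters: `m` (minimum cut height, Å) and `s` (step size, Å). From the
root height D, repeatedly: stop without cutting if D < m; cut at D − s/2
if no merge height lies in [D − s, D); otherwise set D to the largest
merge height in that window and continue. The interval is half-open —
a merge exactly at D counts as already traversed, one exactly at D − s is
inside the window — and since the open gap (D − s, D) contains no merge
when a cut fires, *any* cut level in the gap yields the same partition;
D − s/2 is just the canonical representative. The defaults m = 22, s = 5
are the method's operating point: larger values of either bias towards
single-domain assignments, smaller values oversplit.

Monotonicity note: raising `m` can never increase the number of domains
(the descent path does not depend on m, so a larger m can only convert a
cut into a no-cut). The same is *not* true of `s` in general — a larger
step can close the top gap and make the descent cut deeper, producing more
clusters on trees with several stacked gaps — although on clean two-level
dendrograms (compact well-separated domains) raising s only merges.

## Determinism and numerical choices

* Merge ties break lexicographically by (older cluster id, younger
  cluster id), with leaves numbered in input order and merged clusters in
  creation order; the whole pipeline is bit-for-bit reproducible.
* Near-equal top eigenvalues in an element covariance (no unique principal
  axis, e.g. perfectly symmetric point sets) are resolved deterministically
  towards the largest |x|, then |y| component, with a warning.
* Exposed-residue attachment and orphan re-attachment both break distance
  ties towards the lower residue index.
* Distance matrices are validated to 1e-9 symmetry; degenerate element
  geometry (all points coincident) is an error rather than a NaN.
* The best-permutation overlap search is exhaustive up to 8 domains
  (lexicographically first permutation on ties) and switches to a
  shortest-augmenting-path optimal assignment beyond; published benchmark
  sets stop at 4 domains, so the exhaustive path is the one that matters
  in practice.
* Per-domain-count MCC treats "assigns k domains" as a binary classifier
  per chain and uses the standard confusion formula with the
  zero-denominator → 0 convention. This construction is a documented
  package choice; alternatives (e.g. multiclass MCC) exist.

## The synthetic generator: what it does and does not emulate

`makeGlobuleStructure()` builds one self-avoiding random walk per domain —
3.8 Å bond steps (the canonical consecutive Cα distance), 3.0 Å minimum
non-bonded separation enforced across *all* domains — confined to a sphere
of `packingRadius = 10` Å, with sphere centers on a line
`centerSeparation` apart. Defaults (2 domains × 60 residues, 40 Å apart)
give compact globules with realistic interior density, so burial counts
and the two-level dendrogram structure of real two-domain proteins are
reproduced. At small separations the fixed radius can be geometrically
unpackable (at separation 0 the defaults imply a ~0.40 packing fraction,
beyond random-insertion jamming); the confinement radius therefore swells
by 10% per 20 exhausted walk restarts — deterministic given the seed, and
never triggered at separations ≥ 15 Å — mimicking the volume increase of
fused domains. Generation restores the caller's RNG state afterwards.

What the generator deliberately does **not** emulate: real secondary
structure and its hydrogen-bond geometry (SS-algorithm tests therefore
label ideal helices through the TSV annotation path instead of running
DSSP), side chains, realistic loop topology between domains (walks are
concatenated directly), or interdigitated domain interfaces. Passing the
synthetic recovery suite therefore demonstrates that the pipeline machinery
is correct on structures that satisfy the model's assumptions — it does not
certify accuracy on real, messier structures, where published agreement
with curated references is around 70–80% for methods of this family.

`makeIdealHelix()` provides the canonical α-helical spiral (rise 1.5
Å/residue, radius 2.3 Å, 100°/residue turn) used by the element-geometry
tests; its consecutive-point spacing (~3.8 Å) matches real backbones, so
chain-break detection behaves as it would on genuine helices.

## Problem sizes used in the shipped checks

The test suite and `scripts/acceptance.R` run entirely on generated data:
50 seeds × 120 residues for the two-globule recovery condition, 50 single
globules, a 5-point separation sweep (0–60 Å) over several seeds, 100
random matrices (N ≤ 12) against a naive cubic clustering reference, 100
random segment pairs against a dense-sampling closest-approach oracle, and
200 random label vectors for the overlap invariances. These sizes give
stable pass/fail behaviour at negligible runtime.

## Known limitations

* Very small domains are beyond the m = 22 Å operating point: two genuine
  domains a dozen residues each merge into one (lowering m recovers them
  at the cost of oversplitting elsewhere).
* The CA algorithm is sensitive to small coordinate perturbations for
  structures whose dendrogram gap sits near m; near-identical chains can
  be assigned differently.
* Assignments are most meaningful on the full biological unit; a chain
  analysed in isolation may show "extra" domains that are really pieces of
  an interface with a partner chain.
* β-sheet integrity is not enforced by default; `useSheetConstraint`
  exists for structures where a split sheet is suspected.
* DSSP is consumed as a file (classic format) or as a plain per-residue
  TSV; the package does not compute secondary structure itself.
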