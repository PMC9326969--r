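---
title: "Extended continuous similarity and ECS-MeDiv frame selection: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Extended continuous similarity and ECS-MeDiv frame selection: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecsmediv)
```

## The model

`ecsmediv` scores the similarity of an arbitrary number of molecular
conformations at once and uses that score to pick representative, diverse
frames from a trajectory.  The central object is the frame matrix: each
conformation's Cartesian coordinates (by default the backbone N, Cα, C
atoms) flattened into a row, giving an $N \times m$ matrix with
$m = 3\,n_\mathrm{atoms}$.

Three assumptions matter:

* **Frames are comparable as raw coordinates.**  No superposition is
  applied anywhere in the similarity pipeline; trajectory postprocessing
  normally yields frames in a common reference (and the RMSD evaluator
  has an opt-in `superpose` flag for data that is not).
* **One global scaling.**  Normalization maps the *whole* matrix to
  $[0,1]$ through a single $(\min, \max)$ pair,
  $n(q) = (q - \min q)/(\max q - \min q)$.  Because this is one affine
  map, every L1 distance between frames is multiplied by the same
  positive constant, so no pair of conformations ever swaps order — the
  consistency requirement that makes similarity-driven selection
  commensurate with RMSD-based assessment.  The suite verifies the
  ordering is preserved *exactly* on random frame quadruples.  A
  corollary used throughout: subsets (pairs, leave-one-out sets, growing
  selections) are always evaluated under the full-set scaling, never
  renormalized, otherwise values at different steps would not be
  comparable.
* **Column sums suffice.**  All information the indices use is the
  column-sum vector $s$ of the normalized matrix plus $N$ — one $O(Nm)$
  pass, no pairwise matrix.

### Counters and the index family

Each column $j$ is scored by $\Delta_j = |2 s_j - N|$, the imbalance of
that coordinate across the set.  Columns with $\Delta_j > \gamma$ carry a
similarity signal — 1-similarity ($a$) when $s_j > N/2$, 0-similarity
($d$) when $s_j < N/2$ — and the remainder are dissimilarity columns
($b{+}c$).  Two parallel books are kept:

* raw counts: every column contributes 1, so $a + d + (b{+}c) = p = m$;
* weighted counters: similarity columns contribute
  $f_s(\Delta) = \Delta/N$ and dissimilarity columns
  $f_d(\Delta) = 1 - (\Delta - N \bmod 2)/N$.

The sixteen indices are ratios in which the *numerators always use the
weighted counters* (including the weighted total $w_p$ where the total
appears, as in CT2) while the denominators use the raw counts — the
"nonweighted" family, the default here and the variant used for
trajectory work.  Setting `weighted = TRUE` switches the denominators to
the weighted counters as well.  The weighting is not cosmetic: real-valued
column sums clear a zero threshold almost surely, so with count-only
counters nearly every index would collapse to a constant; the
$\Delta/N$ weights are what make the continuous indices discriminate.
In the two-object binary limit all weights are exactly 1 and each index
reduces to its classical contingency-table coefficient — the property the
test suite pins down against an independent oracle for all sixteen
indices.

### ECS-MeDiv

Selection proceeds in two movements:

1. **Medoid seeding.**  The complementary similarity of frame $i$ is the
   extended similarity of the other $N-1$ frames (computed from the total
   column sums minus row $i$; one pass).  Removing a frame that sits with
   the bulk leaves the stragglers exposed, so central frames score low;
   the argmin is taken as the medoid and anchors the selection at a
   representative conformation rather than an arbitrary outlier.
2. **Greedy diversity.**  Given the selected set $C$, the candidate $c'$
   minimizing the extended similarity of $C \cup \{c'\}$ is appended,
   using a running column-sum vector so each step costs $O(Nm)$.
   Candidates within `tie_tol` of the minimum are tied; ties resolve by
   the lowest mean *pairwise* similarity (the two-object form of the same
   index, under the global scaling) to the selected frames, and any
   residue by the lowest frame index.  Every tie event is recorded in an
   audit table.

For a small fixed number of picks the whole algorithm is linear in $N$;
the suite fits the wall-time exponent on $N \in \{1000, 2000, 4000,
8000\}$ and requires it below 1.3.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `index` | `"RT"` | which of the 16 indices drives scoring; RT (Rogers–Tanimoto) and CT2 (Consonni–Todeschini 2) are the variants that performed best in the trajectory benchmarks this package follows |
| `gamma` | `0` | coincidence threshold on $\Delta$; similarity columns need $\Delta > \gamma$ strictly.  0 reproduces the plain partition, and an exact $\Delta = 0$ is measure-zero for continuous coordinates |
| `weighted` | `FALSE` | denominator family; nonweighted matches the published usage |
| `tie_tol` | `1e-12` | absolute tie window on similarity values; floating-point equality would be meaningless |
| `atom_selection` | `"backbone"` | N/CA/C name filter for structure formats, names matched exactly after whitespace stripping; altLoc blank or `A` only |
| `superpose` | `FALSE` | optional Kabsch fit (via bio3d) before pair RMSD |

Frame indexing is 1-based everywhere, as native to R; report ranks are
1-based as well.

## What the synthetic generator emulates

`make_multibasin()` mimics a trajectory that hops between $k$ metastable
states: centres drawn uniformly in a cube of edge `basin_spread` (20 Å
default) in the full $m$-dimensional coordinate space, frames assigned to
basins in contiguous dwell blocks (a seeded permutation of the basin
order, as trajectories dwell rather than shuffle), plus isotropic
Gaussian noise (`noise_sd`, 1 Å default).  `make_drift()` is the opposite
regime — a Gaussian random walk that explores space sparsely and never
revisits — with the expected squared displacement
$m \, g \, \sigma^2$ over a gap of $g$ frames checked against simulation.
Defaults (1000 frames, 30 atoms) follow the regime of the case studies
this methodology targets, where every trajectory holds 1000 frames and
basin separations sit an order of magnitude above thermal noise.

What the generator does *not* emulate: bonded geometry, anisotropic or
correlated atomic fluctuations, overall rotation/translation drift, and
unequal basin populations.  Passing tests therefore demonstrate the
algebraic and statistical behaviour of the method under clean basin
structure, not force-field realism; on real data the contrast between
basins will be softer than here.

## Numerical choices

* Degenerate constant matrix (global max = min): normalized to all zeros
  rather than erroring, so pathological inputs still flow through (the
  columns become 0-similarity counters).
* 0/0 index forms (e.g. JT with $a = b{+}c = 0$) are defined as 0 — no
  similarity evidence — with a warning in the scalar API; the vectorised
  selection kernels apply the same rule silently, since a warning per
  candidate per step would flood the console.
* Counters are accumulated in double precision with a fixed left-to-right
  column order, so repeated runs are bit-identical; the incremental
  leave-one-out and growing-set values are required to match brute-force
  recomputation within $10^{-12}$.
* Candidate sweeps are processed in row blocks (1024 rows) so the
  classification temporaries stay cache-resident on long trajectories;
  block size affects speed only, never values.
* Selection with exactly two frames degenerates to both frames in index
  order (a medoid needs $N \ge 3$).
* The spread reported with the average pairwise RMSD is the
  population-form root-mean-square of the pair deviations (divide by the
  number of pairs); with a handful of pairs the sample/population
  distinction is immaterial and the simpler form is fixed and documented.

## Design choices that were genuinely open

* **Weighted-variant convention.**  The continuous indices admit several
  weighting schemes; this package uses fraction weights in all
  numerators with raw-count denominators as the default family, because
  it reduces exactly to the classical coefficients in the binary limit
  and is the convention under which the published trajectory results are
  coherent (count-only counters provably degenerate on continuous data).
* **Pairwise tiebreak index.**  The tie-break uses the two-object form of
  the *same* index being minimized, keeping the algorithm
  single-parameter; the audit table records enough to reconstruct every
  tie decision.
* **Candidate pool.**  Already-selected frames are excluded from the
  candidate set (the set notation of the algorithm implies distinct
  conformations).
* **Medoid semantics.**  On cluster-structured data the minimal
  complementary similarity lands on a frame of the densest, most
  repeated conformation — the behaviour the algorithm relies on.  On a
  single featureless Gaussian cloud the same criterion is driven by the
  projection onto the column-consensus direction and is only loosely
  tied to the geometric centre; users wanting a geometric medoid of an
  unstructured ensemble should use an RMSD-based criterion instead.
  This is a documented property of the similarity-based definition, not
  a defect of the implementation.

## Validation scales

The shipped suite runs at desk scale, chosen to finish in minutes on one
CPU: 500 binary pairs ($m = 50$) for the binary-limit oracle, 100 random
matrices ($N \le 50$, $m \le 30$) for the leave-one-out oracle, a
$100 \times 60$ matrix with 10 picks for the selection oracle, 20 seeded
3-basin and 5-basin fixtures ($N = 300$, 30 atoms) for diversity gain and
coverage, $N$ up to 8000 for the scaling fit, and one full 1000-frame,
$16$-index, $k = 5..10$ workflow with 291 atoms.  `scripts/acceptance.R`
recomputes all of these from a single `--seed` and writes the resulting
quantities as JSON.

## Known limitations

* Trajectory formats needing vendor toolkits (dcd/xtc/dtr) are out of
  scope; convert to multi-model PDB, XYZ or the delimited matrix format.
* The indices operate on whatever atoms the frame matrix carries;
  selection quality depends on that choice (backbone by default).
* Heavily skewed basin populations can absorb more than one pick into
  the dominant basin before the first small basin is visited, since the
  greedy criterion is global, not per-basin.
* The binary-limit equivalence holds for the two-object case; extended
  values for $N > 2$ are a genuine generalisation, not an average of
  pairwise values, and should be compared only across sets of the same
  $N$.
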