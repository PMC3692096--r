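---
title: "CircleMap scenes: model, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{CircleMap scenes: model, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(circlemapr)
```

## The visual model

A CircleMap scene couples two structures. The first is a **typed pathway
graph**: nodes are molecular entities (proteins, complexes, families,
small molecules, abstract processes), edges are typed interactions —
activating (drawn with an arrowhead), inhibiting (T-bar), structural
component/member links (dashed), and undirected associations — and every
edge carries the name of the network *track* it came from, so evidence
from independent sources stays distinguishable by color. The second is a
set of **gene × sample matrices**, one per measurement platform, joined
to graph nodes by exact gene-symbol match.

Each displayed gene with data becomes a glyph of nested annular rings,
innermost ring first in the configured matrix order, each ring divided
into angular cells. In *full* mode a cell is one sample; in *aggregated*
mode a cell is one sample group and shows the group mean. Three
invariants make the display readable:

1. **Coordination.** The cell-index-to-sample map is a single shared
   permutation for every ring of every glyph in the scene.
2. **Closure.** Per ring, cell extents sum to one full turn (numerical
   tolerance 1e-9 on the fraction of the turn).
3. **Value-space aggregation.** A group segment's color is
   `colorize(mean(values))`, never an average of colors: averaging in
   color space depends on the color model and is not reproducible, while
   the mean of the measured values is well defined (for 0/1 mutation
   calls it is exactly the group mutation frequency).

## Sorting semantics

`sort_samples()` is a stable lexicographic multi-key sort. Each key ranks
samples either by one gene's values in one named ring or by a categorical
sample annotation; the first key is primary. Two deliberate conventions:

* **Missing values sort after all non-missing values under either
  direction.** Flipping direction reverses every strictly ranked pair but
  never moves the missing block to the front, where it would visually
  dominate a descending sort.
* **Full ties keep the incoming universe order** (the sort is stable).
  The universe order is itself deterministic — first appearance across
  the matrices in configuration order — so output order is fully
  reproducible without any additional tie-break. We considered a final
  identifier tie-break, but it would contradict stability whenever the
  universe is not identifier-sorted, and stability is the property users
  rely on when refining an existing order with a new key.

Sorting returns a permutation; rebuilding glyphs on the sorted universe
permutes every ring of every glyph identically, which is what makes a
single-ring sort informative for all other genes.

## Grouping and aggregation

`partition_samples()` forms one group per annotation category in order of
first appearance along the universe, with unannotated samples collected
into a final `"unannotated"` group; within groups the universe order is
preserved. Group segments get angular extents proportional to group size
by default (a 90%/10% dichotomy should look like one), with an
`equal_width_segments` scene option for the alternative reading; the
proportional default makes the aggregated view an honest area-weighted
summary of the full view.

## Color

Continuous rings default to a diverging blue–white–red scale symmetric
around 0, clipped at the 95th percentile of the matrix's absolute
non-missing values — outlier-robust and conventional for omics heatmaps —
and overridable per ring. Interpolation is channel-wise linear in RGB
with exact endpoints and midpoint. Binary rings use a white-to-dark
two-color ramp whose interior is only reached by aggregated frequencies.
Missing cells use the scene's single missing color, so "no data" looks
identical in every ring.

## Networks

Background filtering (`extract_subnetwork`) is a strict induced
subgraph: no one-hop neighborhood expansion, because pulling unselected
neighbors silently grows the display past the user's gene set. The one
optional extension is complex/family expansion: a complex node is
retained when it has at least one protein neighbor via structural edges
and *all* such neighbors are selected. The at-least-one guard matters —
a memberless complex satisfies the "all members selected" condition
vacuously but would render as a data-less glyph. Expansion defaults off
for the same reason.

Track overlay adds a track's edge only when both endpoints are already
displayed, never new nodes, and keeps parallel edges from different
tracks as distinct records so each renders in its source color;
`edge_support()` counts supporting *tracks* (a track with several edge
records between a pair contributes one), which is the quantity that
expresses independent-evidence confidence.

## Rendering and determinism

Layout is Fruchterman–Reingold (igraph) from a seeded random start, run
for a fixed 500 iterations, followed by a deterministic pairwise
separation pass that guarantees center distances of at least one glyph
diameter plus padding; coincident points are split along an
index-determined direction so the pass has no hidden randomness. Angular
origin is 12 o'clock, proceeding clockwise; the convention is arbitrary
but fixed, and fixing it is what makes byte-identical output possible.
All coordinates are serialized at three decimals through one formatting
path. Arrowheads and T-bars are drawn as explicit per-edge elements
rather than SVG `<marker>` definitions: markers cannot inherit the
per-track stroke color, so the marker route would need one definition
per (shape, color) pair for no visual gain.

The stable CSS classes `node`, `edge`, `spoke`, `segment`, `legend` are
part of the package's contract: scene combinatorics (spokes = glyphs ×
rings × cells, edge groups = edge multiset size) are machine-checkable
on the output document.

## The synthetic generators

The generators define the study conditions the package is tested under;
they are first-class, tested code.

**Two-gene inhibition toy** (`generate_toy`). A Gaussian
structural-equation scheme on standardized variables: a shared latent
factor gives the two genes' promoter methylation a correlation of
`rho_meth` (default 0.8); expression of A loads on methylation of A with
coefficient `rho_meth_expr` (default −0.8); expression of B loads on
expression of A with `rho_inhibit` (default −0.8, the inhibition) and on
its own methylation with `rho_meth_expr`. The coefficients are *path
loadings*, not pairwise correlation targets: with both genes' expression
tied to positively correlated methylation, demanding a pairwise
expression correlation of −0.8 is infeasible (the implied covariance
matrix is not positive semi-definite), while the loading formulation is
feasible and still forces the three qualitative signs the display is
meant to reveal. Residual variances standardize every signal to unit
variance; an infeasible combination (negative residual variance) is
rejected at specification time. Observed values add measurement noise
(`noise_sd`, default 0.3, chosen as a realistic but non-dominant assay
noise level). Default `n_samples = 10` mirrors a small illustrative
cohort; the sign-recovery analyses use n = 500.

**Hypermutated cohort** (`generate_cohort`). Two hundred samples by
default, 15% hypermutated — the ballpark of hypermutation frequency in
colorectal tumor cohorts. The driver gene (BRAF) mutates with
probability 0.60 in hypermutated and 0.05 in non-hypermutated samples;
non-driver genes mutate at elevated background rates in the hypermutated
group (0.20 vs 0.03), since an elevated genome-wide rate is what the
phenotype means. Copy number is standard normal per gene; expression
couples to copy number (0.5) and inferred activity to expression (0.7),
with mutated driver samples getting a unit activity bump — enough
structure for the rings to be visibly non-independent without modeling
real marginal distributions, mutation spectra or cohort sizes, which is
out of scope.

What passing tests on these fixtures shows: the operations (coordination,
sorting, aggregation, filtering, rendering) behave exactly as specified
on data with known generative structure. What it does not show: behavior
under real-data pathologies such as heavy-tailed platforms, batch
effects, systematically missing panels, or symbol mismatches between
annotation vintages — only the missing-value and absent-gene paths among
those are exercised.

## Numerical and degenerate-input choices

* Angular extents are computed as `360 * w / sum(w)`; closure holds to
  1e-9 of a turn and exactly in rational cases.
* A single cell spans the full turn and is drawn as two half-annuli so
  SVG arc flags stay well defined.
* A gene absent from one ring's matrix yields an all-missing ring, not
  an error; a gene set disjoint from the background network is an error
  ("0 genes matched"), since an empty scene is never what was asked for.
* Parsers fail loudly with line numbers on ragged rows, duplicate keys
  and unknown vocabulary; unknown SIF relations are errors rather than
  being coerced to undirected, because edge type selects the glyph.

## Problem sizes

The shipped tests run the sorting and aggregation oracles on 200 random
cases each, the network-algebra oracles on 100 random graphs of up to 50
nodes, sign-recovery on 100 replicates of 500 samples, and end-to-end
renders on cohorts of 60–80 samples; the full suite completes in well
under a minute on one core. These sizes were chosen to exercise every
code path with comfortable statistical margins at desk scale.

## Known limitations

Single-threaded, desk-scale rendering: scenes beyond a few hundred genes
produce large SVG documents and an increasingly hairball layout. The
HTTP service is a read-only, single-connection figure server for trusted
local use, not a hardened web application. Gene matching is exact and
case-sensitive with no alias resolution, so inputs must agree on symbol
vintage. Layout optimizes only non-overlap and spring energy; it does
not reproduce any particular hand-curated pathway arrangement.
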