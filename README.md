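# circlemapr

Pathway-context visualization of multi-platform omics data with
**CircleMaps**: per-gene glyphs of nested rings, one ring per data
platform, one angular cell ("spoke") per sample, drawn on the nodes of a
typed interaction graph and serialized to deterministic SVG.

Heatmaps show the dominant structure of one matrix at a time; a targeted
relationship between two interacting genes — say, gene A's product
inhibiting gene B's expression while both genes co-cluster in DNA
methylation — can sit rows apart in every clustered view. A CircleMap
scene instead wraps each gene's data around its node in the pathway, and
keeps the spoke order **coordinated**: every ring of every gene lays its
samples out at the same angular positions. Sorting the spokes by any one
ring propagates the permutation to the whole scene, so one sort on gene
A's expression makes gene B's anti-correlated expression visible as a
color gradient running the opposite way around its circle.

For whom: computational biologists who have gene × sample matrices
(expression, copy number, methylation, mutation calls, pathway-inference
scores) plus an interaction network, and want publication-quality,
reproducible figures from the shell or from R.

## Core operations

- **Coordination** — all rings of all glyphs share one sample
  permutation; cell *i* is the same sample everywhere.
- **Sorting** — stable lexicographic multi-key sort of the spokes
  (`ring:GENE:PLATFORM[:asc|desc]` or `annot:NAME[:asc|desc]` keys);
  missing values sort last under either direction.
- **Aggregation** — samples grouped by a phenotype annotation are
  averaged per group: segment value = mean of non-missing values, segment
  color = `colorize(mean)`, segment width ∝ group size. A binary mutation
  ring aggregates to a per-group mutation frequency in [0, 1].
- **Network algebra** — induced-subgraph filtering of a large background
  network by a gene set; overlay of any number of network "tracks" drawn
  in source-distinguishing colors (activating edges end in arrowheads,
  inhibitory ones in T-bars); per-pair support counts across tracks.
- **Deterministic rendering** — seeded force-directed layout with a
  glyph-separation pass; identical inputs, seed and config give
  byte-identical SVG. Element classes (`node`, `edge`, `spoke`,
  `segment`, `legend`) are stable and machine-queryable.

## Worked example

Everything below runs offline: the package ships seeded generators that
emulate (i) a two-gene toy in which methylation is positively correlated
between genes A and B while A inhibits B's expression, and (ii) a
colorectal-cancer-flavored cohort with a hypermutated subgroup in which
the BRAF driver is preferentially mutated.

```r
library(circlemapr)

co  <- generate_cohort(cohort_spec(n_samples = 400, seed = 1))
uni <- sample_universe(co$matrices)
prt <- partition_samples(uni, co$annotation)
aggregate_ring(co$matrices$mutation, "BRAF", prt)
#> non-hypermutated     hypermutated
#>       0.04705882       0.56666667
```

The aggregated BRAF mutation ring recovers the generative rates (0.05
non-hypermutated, 0.60 hypermutated): the hypermutated segment renders
dark, the non-hypermutated segment near white — the full→aggregated view
transition in one pair of numbers.

From the shell (the same pipeline, file-based):

```sh
Rscript inst/cli/circlemap.R fixtures cohort --out demo --seed 1
Rscript inst/cli/circlemap.R render \
  --matrix mutation:binary:demo/mutation.tsv \
  --matrix expression:continuous:demo/expression.tsv \
  --network crc:demo/pathway.tsv \
  --genes demo/genes.txt \
  --annotation hypermutated:demo/hypermutated.tsv \
  --sort annot:hypermutated:desc --sort ring:BRAF:mutation:desc \
  --seed 1 --out demo/scene.svg
#> circlemapr: 9 genes matched
#> circlemapr: 7 edges displayed
#> circlemapr: 200 samples in universe
#> circlemapr: wrote demo/scene.svg
```

`--matrix` order is ring order, inner to outer; the first `--network` is
the background graph filtered by the gene set. `circlemap.R serve
--data-dir demo --port 8765` exposes the identical renderer over HTTP
GET (`/render?matrix=...&network=...&genes=...`), returning bytes equal
to the CLI output for the equivalent query.

Input formats: tab-separated gene × sample matrices (first row sample
ids, first column gene symbol; `NA`/`nan`/empty = missing), two-column
sample annotations, one-symbol-per-line gene sets, SIF networks, and a
typed-node pathway dialect (protein/complex/family/smallmolecule/process
nodes; activating, inhibiting, component, member, undirected edges).

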