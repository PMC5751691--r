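# nwsteiner

Node-weighted Steiner trees for identifying candidate elements of
signaling pathways in protein–protein interaction (PPI) networks.

## What problem does this solve?

Signals in a pathway such as PI3K/Akt enter through receptor tyrosine
kinases (*source* proteins) and end at downstream effectors (*terminal*
proteins). Given a confidence-scored PPI network and these pathway
anchors, `nwsteiner` extracts a small, credible subnetwork connecting all
of them, then ranks its proteins and interactions — a data-driven
candidate skeleton of the pathway at the protein level, for systems
biologists who want a shortlist worth experimental follow-up.

The model is the node-weighted Steiner tree problem on
`G = (V, E, w, c)`: find a connected subnetwork `G' = (V', E')`
containing every compulsory terminal that minimizes

```
sum_{e in E'} c(e)  -  sum_{v in V'} w(v)
```

with edge costs `c(i,j) = alpha / con^beta` (high-confidence interactions
are cheap; annotated pathway members get a 50% confidence boost) and node
weights `w(i) = -gamma / degree(i)` for non-terminals (poorly connected
detours are penalised), while terminals are REQUIRED. Instances are
shrunk by two optimum-preserving degree-1 reductions, solved with a
modified unrooted Goemans–Williamson moat-growing heuristic (dynamic edge
splitting at ratio `1:(s-1)`, merge tolerance `mu`) followed by strong
pruning, and the identified tree is scored with *source-to-terminal
betweenness degrees*: the number of source→terminal tree paths through
each protein or interaction. Elements whose degree strictly exceeds
`max(|S|, |T'|)` are reported as important.

## Worked example

The package ships the curated 29-protein PI3K/Akt–MAPK reference
subnetwork in the same input formats the pipeline consumes:

```r
library(nwsteiner)

fx   <- pi3k_mapk_inputs()                      # records + annotation
inst <- build_instance(fx$records, fx$annotation)
inst
#> Node-weighted Steiner instance
#>   29 vertices, 28 edges, 22 compulsory terminals
#>   edge costs: [88.89, 88.89]

tr  <- nwst_solve(inst)                         # reduce, grow, prune
rep <- select_important(
  st_betweenness(tr, fx$annotation$sources, fx$annotation$terminals))
rep
#> Betweenness report: 29 proteins, 28 interactions (8 sources, 14 terminals)
#>   threshold 14: 9 proteins and 8 interactions selected
#>   top proteins: AKT1=112, PIK3R1=112, MDM2=64, p53=64, EP300=56
```

AKT1 and PIK3R1 score 112 = 8 × 14: every source→terminal path runs
through them, marking them as the pathway's central junctions. The auto
threshold is `max(|S|, |T'|) = 14`, so the receptor proteins sitting at
exactly 14 stay unselected, leaving 9 proteins and 8 interactions as the
identified important elements.

The same chain runs from files via `run_pipeline()` (or the thin CLI in
`inst/cli/nwst.R` with subcommands `build`, `preprocess`, `solve`,
`metrics`, `run`, `sweep`, `fixture`), writing the instance (extended
STP text), the solution tree, both betweenness tables, and a JSON
manifest that makes any run reproducible bit-for-bit given its seed.

Validation utilities are first-class: `synth_ppi_instance()` generates
realistic synthetic instances, `brute_force_steiner()` computes exact
optima on tiny instances by exhaustive enumeration, and
`brute_force_betweenness()` re-derives betweenness by explicit path
walks.

## Package layout

- `R/instance.R` — cost/weight transforms, instance construction, objective
- `R/reductions.R` — degree-1 tests, reduction ledger, replay/reassembly
- `R/gw.R` — moat growing, strong pruning, `nwst_solve()`
- `R/metrics.R` — betweenness degrees and threshold selection
- `R/fixtures.R` — reference subnetwork, synthetic generator, oracles
- `R/io.R`, `R/pipeline.R` — file formats, pipeline, parameter sweep
- `vignettes/node-weighted-steiner.Rmd` — model, algorithm, and design notes
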