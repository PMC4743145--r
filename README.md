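# sarlattice

Stereochemistry-aware graphical analysis of analog series.

## The problem

Lead-optimization programs produce large series of structural analogs — tens
to hundreds of compounds sharing a common core and differing in the R-groups
attached at a handful of substitution sites. Classic R-group tables stop
being readable long before a series reaches that size, and they have no
natural place for stereoisomers, which differ in activity but not in
constitution. `sarlattice` organizes such series for medicinal and
computational chemists:

1. **Series extraction.** Compounds read from an SD file are grouped by
   hierarchical molecular scaffold (Bemis–Murcko framework: ring systems
   plus the linkers connecting them; optionally the carbon-skeleton
   generalization).
2. **MCS and R-group decomposition.** For each series the maximum common
   substructure (MCS) over *all* members is computed — connected, atoms
   matched by element, bonds by order (aromatic bonds as their own class),
   ring bonds only onto ring bonds. Every member is mapped onto the MCS with
   a symmetry-consistent canonical embedding, the substitution sites
   R1..Rn are indexed by canonical atom rank, and each compound's R-groups
   are cut out as canonical SMILES fragments with `*` attachment markers.
3. **SAR graphs.** Each compound belongs to exactly one *subset*: the exact
   set of its substituted sites. The **complete graph** is the layered DAG
   over all 2ⁿ site combinations (root `0` = the hypothetical bare core),
   with per-node count, mean potency, and potency range (orders of
   magnitude, since potencies are pKi/pIC50); the **reduced graph** removes
   empty nodes; per-subset **R-group trees** split compounds site by site
   (most conserved site nearest the root) down to one leaf per analog.
   Stereoisomers — identical constitution, different R/S / E/Z descriptors —
   appear as adjacent leaves sharing an incremental stereo-group index
   (1, 2, ...) per tree.
4. **Selectivity views.** For two potency fields the same partition yields
   two reduced graphs of identical topology whose node statistics (and their
   per-node difference) compare target profiles.

Formally, for a series with sites S = {1..n}, each compound c has an
occupancy σ(c) ⊆ S; nodes of the complete graph are the subsets of S with
edges u → v iff u ⊂ v and |v| = |u| + 1, so layer k holds C(n, k) nodes and
the graph has 2ⁿ nodes and n·2ⁿ⁻¹ edges. Node statistics over the compounds
with σ(c) = v are count, mean potency (log units), and range = max − min.

## Worked example

Everything below is generated in code — no downloads. The default demo
fixture emulates a mid-size series: 25 analogs of a benzamide–azepane core
with 5 substitution sites, 12 occupied site combinations and one
three-member stereoisomer set.

```r
library(sarlattice)

path <- tempfile(fileext = ".sdf")
generateSeriesSDF(defaultFixtureSpec(), path)

cs <- readCompounds(path, "pKi")
#> CompoundSet with 25 compounds, 1 potency field(s): pKi

series <- groupIntoSeries(cs)
an <- analyzeSeries(series[[1]], cs)
#> SeriesAnalysis of S1 - 25 members, 5 sites, 12 subsets
seriesCore(an@series)
#> CoreStructure: COc1ccccc1C(=O)NC1CCNCCC1 ( 18 atoms, 19 bonds, 5 sites )

g <- buildCompleteGraph(an@partition, cs)
#> SarGraph ( complete ) for S1 - 32 nodes, 80 edges
reduceGraph(g)
#> SarGraph ( reduced ) for S1 - 12 nodes, 14 edges

tr <- buildRGroupTree(an, "2345")
#> RGroupTree for subset 2345 - 6 leaves, layer order: 3 4 2 5
treeNodes(tr)[treeNodes(tr)$type == "leaf",
              c("compoundId", "potency", "stereoIndex")]
#>  compoundId potency stereoIndex
#>     CPD-021   6.139          NA
#>     CPD-020   7.764          NA
#>     CPD-019   8.212          NA
#>     CPD-022   8.044           1
#>     CPD-023   8.366           1
#>     CPD-024   8.643           1
```

The 32-node complete graph is the full subset lattice over the 5 sites; the
reduced graph keeps the 12 combinations that are actually explored. In the
four-site tree, the three leaves labelled `1` are the stereoisomer set: one
constitution, three distinct R/S signatures, potencies spanning 0.6 log
units. The subset report lists every compound with its per-site R-groups:

```
series_id  subset  compound_id  R1  R2  R3  R4  R5  potency_pKi  stereo_index
S1         0       CPD-001      H   H   H   H   H   6.274
S1         1       CPD-005      *C  H   H   H   H   6.281
...
```

Graphs and trees export to GraphML, DOT and JSON (`exportGraph()`; the JSON
round-trips through `importGraphJSON()`), and `runAnalysis()` — or the
`inst/scripts/sarlattice` command line — drives the whole pipeline in
`multi`, `single`, `selectivity` and `merge` modes:

```sh
Rscript inst/scripts/sarlattice make-fixture --out fixture.sdf
Rscript inst/scripts/sarlattice multi --input fixture.sdf --out results/ \
        --potency-fields pKi --verbose
#> S1: 25 members, 5 sites, 12 subsets, 1 stereo group(s)
#> wrote 17 files to results/
```

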