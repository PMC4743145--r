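---
title: "Methods: organizing analog series around their MCS"
author: "sarlattice"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: organizing analog series around their MCS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sarlattice)
```

## Overview of the procedure

`sarlattice` turns a compound set with potency annotations into a
hierarchical, stereochemistry-aware picture of its structure–activity
relationships. The pipeline has five stages, each exposed as its own
function so intermediate objects can be inspected:

1. `readCompounds()` — SD file in, `CompoundSet` out.
2. `groupIntoSeries()` — partition by hierarchical scaffold.
3. `computeMCS()` / `mapToCore()` / `indexSubstitutionSites()` /
   `decomposeRGroups()` (wrapped by `analyzeSeries()`) — the series core and
   per-compound R-groups.
4. `partitionSeries()` / `buildCompleteGraph()` / `reduceGraph()` /
   `buildRGroupTree()` — the graphical components.
5. `exportGraph()` / `writeSubsetReport()` / `runAnalysis()` — artifacts.

The sections below state the model behind each stage, the tunable
parameters, and the choices made where the design was genuinely open.

## Input model and assumptions

Potency fields are assumed to be on a negative-log scale (pKi, pIC50), so
one unit is one order of magnitude and node "potency range" is simply
max − min. No unit conversion is attempted. Compounds lacking a value in
every configured field are dropped at read time: every graphical attribute
downstream requires a potency, and an uncolored node convention would leak
NA arithmetic through all statistics. Multi-fragment entries (salts) keep
the largest fragment by heavy-atom count, ties broken by canonical SMILES
order. Structurally identical compounds with different identifiers are kept
and logged, not merged — replicate measurements are a data-curation issue,
not a structural one.

Explicit hydrogens are suppressed into per-atom counts using a standard
valence model (B, C, N, O, halogens, Si, P, S with hypervalent P5/S4/S6);
wedge and coordinate information of suppressed hydrogens is retained for
stereo perception. Aromaticity is perceived by OpenBabel and carried as a
separate bond-match class, so two input files with different Kekulé
assignments of the same ring always match.

## Scaffolds

The *framework* level keeps ring atoms, linker atoms on paths between
rings, and atoms double-bonded to either (the Bemis–Murcko convention,
implemented as iterative pruning of terminal non-ring atoms followed by
re-attachment of exocyclic double-bond partners). The *generic skeleton*
additionally maps every atom to carbon and every bond to a single bond.
Grouping defaults to the framework level: each series then shares a
specific chemical core, which is what the downstream MCS expects. Series
whose scaffolds differ only by heteroatoms are *not* merged automatically;
users who want that behavior can group at the skeleton level instead.
Acyclic compounds have no scaffold and are excluded from series formation
rather than pooled into a pseudo-series; `minSeriesSize` defaults to 2
because an MCS and R-group comparison over one compound is meaningless.

## The MCS

The MCS flavor is fixed as: connected; atom match = element identity; bond
match = order identity with aromatic as its own order; ring bonds match
only ring bonds. This keeps R-groups well-defined (a disconnected "MCS"
would leave ambiguous attachment topology) and prevents an aromatic ring
from matching a saturated one.

The search enumerates connected edge subgraphs of the member with the
fewest bonds, testing each against all other members by colored subgraph
monomorphism (igraph's LAD solver on bond-subdivided graphs, with colors
enforced through vertex domains). Two properties make this exact search
affordable:

* embedding failure is monotone under edge addition, so a failing branch is
  cut immediately;
* a greedy near-optimal incumbent — grown from the series scaffold whenever
  it embeds in every member — lets the reachability bound (atoms reachable
  through still-allowed edges) prune almost everything else.

Among maximal solutions the tie-break is: more atoms, more bonds, scaffold
containment preferred, lexicographically smallest canonical SMILES. The
scaffold is thus *preferred but not forced* into the MCS; forcing it could
silently discard a strictly larger common substructure. Degenerate cases:
if no bond is common, the core degrades to a single shared atom; an empty
element intersection yields an empty, flagged core. An MCS smaller than
`minCoverageFrac` (default 2/3) of the mean heavy-atom count flags the
series low-coverage but still processes it. The exact phase runs under a
configurable ceiling (`timeoutSec`, default 60 s per series); on timeout
the scaffold stands in as core and the result is flagged — cost control
has to exist, and the scaffold is the only defensible fallback since every
member contains it by construction.

The suite validates the search against an independent brute-force
enumeration oracle (`oracleMCS()`, a plain backtracking matcher over all
connected edge subsets, deliberately sharing no code with the production
path) on series of molecules with at most 12 heavy atoms — 20 seeded series
in the tests, 8 in the acceptance script, sizes chosen so the oracle's
exhaustive enumeration stays in the seconds range.

## Symmetry-consistent mapping and site indexing

A symmetric core embeds into each member in many automorphic ways; picking
arbitrarily would scatter equivalent substituents over equivalent sites.
The canonical embedding minimizes, in order: (a) the sorted list of
occupied core positions, (b) the per-site substituent SMILES, (c) the
mapped atom index sequence. Core positions are canonical atom ranks,
computed by Morgan-style invariant refinement followed by a canonical
depth-first traversal (ties resolved by exhaustive branch comparison of
traversal signatures) — a DFS ordering is used precisely so that ring
atoms rank consecutively around a ring, giving the familiar 1/2/3/4
ortho/meta/para numbering on a benzene core. Tie-break (c) only
distinguishes embeddings that are fully equivalent under (a) and (b), so
its input-order dependence cannot reach any output.

Substitution sites are the core atoms carrying a non-H substituent in at
least one member, numbered 1..n by canonical rank. R-groups are the
connected fragments outside the mapped core, written as stereo-free
canonical SMILES with a `*` attachment marker; two fragments on one core
atom are joined with `.` after sorting. A fragment bonded to two core atoms
(a ring fused onto the core) is reported at the lower-numbered site with
two attachment markers and flagged — the behavior for such bridges is an
explicit extension, and `reassembleConstitution()` (the decomposition
round-trip check) skips them.

## Stereochemistry

Descriptors are CIP-style: R/S for tetrahedral centers (from wedge bonds
plus 2D coordinates; implicit-H positions are reconstructed opposite the
mean of the explicit neighbors), E/Z for acyclic double bonds (coordinate
side test), `?` for centers present but unannotated. Priorities implement
CIP rule 1a — atomic number over a hierarchical digraph with duplicated
atoms for multiple bonds and implicit hydrogens included — without the
mass or stereo-refinement rules; that resolves ordinary substituent
chemistry, and the test suite pins a panel of descriptors cross-checked
against an independent toolkit. Signatures list descriptors in canonical
atom order, so equal-constitution compounds have positionally comparable
signatures.

Two compounds are stereoisomers iff their constitutions (stereo-free
canonical SMILES) are equal and their signatures differ; centers inside
the core and inside R-groups are deliberately not distinguished. In an
R-group tree, every constitution class with ≥ 2 leaves is a stereo set and
receives indices 1, 2, ... in left-to-right tree order; compounds with
unspecified centers participate through their `?` signatures.

## Graphs and trees

The complete graph materializes all 2ⁿ combinations, so it refuses to build
beyond 12 sites (4096 nodes) — beyond that `buildReducedGraphDirect()`
constructs the reduced graph straight from the occupied combinations.
Subset labels concatenate site digits ("1345"), switching to dot-separated
form ("1.3.10") once a site number needs two digits so the encoding stays
bijective. Reduction is a plain induced subgraph: no transitive edges are
drawn across removed empty nodes (edges are defined only between adjacent
layers), so sparse series legitimately produce disconnected reduced
graphs. A non-empty root (the bare core measured as a compound) survives
reduction like any other non-empty node.

R-group tree layers order the subset's sites by ascending number of
distinct R-groups, ties by site number: the most conserved site sits
nearest the root, so the tree fans out gradually. Sibling order is
lexicographic by R-group SMILES; leaves sort stereo-mates adjacent
(constitution, then compound id).

Visual encodings are exported as numbers, not pictures: count, mean
potency, potency range, an empty flag, and layer/position layout hints.
Suggested display scales (size bins by count tertiles, a linear colormap
over the series potency range, thick borders at range ≥ 1 order of
magnitude) are conventions for the consuming renderer, configurable and
not baked into the data.

Selectivity views drop members lacking either target's potency *before*
partitioning, so both graphs share one partition and one topology; each
node carries the mean-potency difference as an extra attribute.

## The synthetic-series generator

`generateSeriesSDF()` realizes a `FixtureSpec`: a core template SMILES with
`{R1}`..`{Rn}` placeholders, per-site substituent pools with additive
potency effects, an occupancy pattern (one compound per listed site
combination), and a stereo pattern that expands chosen entries into
stereoisomer variants by enumerating sign flips of the chiral marks.
Substituents are drawn by deterministic cycling through the pools, so a
spec realizes the same constitutions on every run; potency = base + Σ
effects + seeded Gaussian noise (default s.d. 0.2 log units — the scale of
typical inter-assay variability, and small against the 0.1–0.9 unit
substituent effects so SAR gradients stay visible). 2D structures come from
the OpenBabel CLI (`--gen2d`); the timestamp OpenBabel stamps into molfile
headers is normalized, making output byte-deterministic in (spec, seed).

The default fixture mirrors a mid-size lead-optimization series: 25
compounds on a 5-site core (asymmetric on purpose, so the designed site
combinations survive canonical renumbering), 12 occupied combinations
including the bare core and a 4-site combination with a 3-member stereo
set. `stereoFixtureSpec()` adds the two-pairs-plus-triple case;
`smallFixtureSpec()` emits ≤ 12-heavy-atom series for the enumeration
oracle. What the generator does **not** emulate: realistic substituent
frequency distributions, activity cliffs, assay censoring, multiple
scaffold families per file, or measurement error structure beyond i.i.d.
noise — so green tests demonstrate algorithmic correctness on
well-formed series, not robustness to curation noise in public databases.

## Determinism and degenerate inputs

All writers are byte-deterministic; the suite checks that permuting both
atom numbering and record order of an input file reproduces identical
subset reports and graph exports. Degenerate inputs have defined behavior:
empty compound sets give empty series lists; a series whose members are all
identical yields the whole molecule as core with zero sites; bond-free
molecules (a single heavy atom) are parsed through a minimal fallback
reader because the primary SDF parser refuses them; unparsable blocks are
skipped with a warning rather than aborting the file.

## Known limitations

* CIP priorities stop at rule 1a; exotic cases (isotopes, stereo-dependent
  priorities, para-stereogenicity) may be mislabeled — though any
  signature difference still separates stereoisomers as long as it is
  consistent.
* Double-bond stereo inside rings is not perceived.
* The MCS is connected-only by design; series related through two
  disconnected common motifs will be flagged low-coverage instead.
* Bridged substituents (two attachment points) are reported and flagged
  but excluded from the reassembly check.
* The exact MCS search is exponential in the worst case; the timeout
  fallback keeps runs bounded at the cost of a flagged, smaller core.
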