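---
title: "gostar: methods, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{gostar: methods, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gostar)
```

## Overview

`gostar` predicts Gene Ontology (GO) terms for target proteins by combining
three orthogonal evidence channels computed on the target's refined
protein–protein interaction (PPI) neighborhood — sequence physico-chemistry,
domain–domain interactions (DDI), and neighborhood annotation enrichment —
and accepting only terms on which at least *n* of the three channels agree
(the *n-star* consensus; `n = 3`, unanimity, by default). This vignette
documents the model, its assumptions, every tunable parameter, the
synthetic benchmark, and the design decisions taken where the design was
genuinely open.

Annotations are treated as **flat labels** throughout: no GO ancestor
closure (true-path propagation) is applied, and the three aspects (BP, MF,
CC) are pooled during prediction and reported separately only at
evaluation. An ontology-aware extension would change both the candidate
sets and the evaluation and is deliberately out of scope.

## Neighborhood refinement

For a target `t`, the *level-2 neighborhood* is the induced subgraph on
`t`, its interactors, and their interactors, with all induced edges (also
level-2-to-level-2). Two refinement stages follow.

**Topological pruning.** Every non-target node is classified on the
original neighborhood, in priority order: *bridge* if it is an articulation
vertex (its removal disconnects the subgraph), else *fjord* if it has
degree ≥ 2 but no triangle through it, else *shore* if it is a leaf.
Labelled nodes are removed simultaneously with their incident edges; the
one-pass rule makes the result independent of any removal order. The
metaphor behind the three labels is that a protein that merely connects
otherwise unrelated parts of the neighborhood (bridge), sits on a
triangle-free corridor (fjord), or dangles off it (shore) contributes
little module-internal evidence; the articulation/triangle-free/leaf
operationalization is the package's own exact rendering of that idea, and
is fully covered by brute-force predicate oracles in the test suite.

**Adaptive double filtering.** With `α` and `σ` the mean and *population*
standard deviation of a value set, the high cutoff is

```
T(values, k) = α + k · σ · (1 − 1 / (1 + σ²)),   k = 3 by default.
```

Pass 1 computes the edge clustering coefficient for every edge,

```
ECC(u, v) = |N(u) ∩ N(v)| / min(deg(u) − 1, deg(v) − 1),
```

(with ECC = 0 when an endpoint has degree 1, so leaves never look
cohesive) and deletes edges with `ECC < T(all ECCs, k)`. Pass 2 applies the
same cutoff to the surviving edge weights. Removal uses strict `<`, so a
zero-variance population (σ = 0, where `T = α`) removes nothing rather
than emptying the graph. ECC is not recomputed after the weight pass, and
the ECC-then-weight order is fixed. Nodes left isolated are dropped —
never the target.

Two consequences are worth knowing. First, the filter is aggressive by
design (`k = 3` is a high cutoff): on sparse neighborhoods the target
itself frequently loses all its incident edges and survives as an isolated
root while the densest parts of its neighborhood persist as separate
components. This is intended: the predictors consume the surviving *node
set* (with its level tags), not paths to the target, and the surviving
nodes are precisely the ones embedded in reliable, module-like structure.
Second, on degenerate uniform graphs (all ECC equal, all weights equal)
the refinement is a no-op, which the test suite asserts.

## The three predictors

### Sequence channel

Seven physico-chemical properties are computed per sequence, all
composition-based (hence invariant under residue permutation, a property
the tests assert):

| property | definition | constants |
|---|---|---|
| extinction coefficient | `5500·nW + 1490·nY + 125·⌊nC/2⌋` (M⁻¹cm⁻¹) | Gill–von Hippel, oxidized cystines |
| absorbance | extinction / MW | — |
| n_neg | #D + #E | ProtParam convention |
| n_pos | #R + #K (His excluded) | ProtParam convention |
| aliphatic index | `X_A + 2.9·X_V + 3.9·(X_I + X_L)`, mole % | Ikai |
| pI / MW | isoelectric point over MW in kDa | classic free-amino-acid pKa table |
| GRAVY | mean Kyte–Doolittle hydropathy | Kyte–Doolittle |

The pI is found by bisection on the net-charge curve (tolerance 1e-4 pH
units; the curve is monotone, so 100 iterations always suffice). The pKa
table is the classic biochemistry one (N-terminus 9.60, C-terminus 2.34;
side chains R 12.48, K 10.53, H 6.00, D 3.65, E 4.25, C 8.18, Y 10.07),
pinned in one constants file; for glycine it gives pI = (2.34 + 9.60)/2 =
5.97 exactly, which anchors the tests. Molecular weights use average
residue masses plus 18.02 for water.

The raw properties span about six orders of magnitude (extinction
coefficient vs GRAVY), so an unstandardized Euclidean distance would be
dominated by a single component. Each component is therefore z-scored
against a **stated reference population — the non-target nodes of the
refined neighborhood** — using the population SD, with zero-variance
components mapped to 0. Distances are computed on the 7-dimensional
z-scored vector; the scalar "property score" (the mean of the seven
standardized components) is kept for reporting but not used for distances,
because averaging collapses information the clustering needs.

Clustering is degree-seeded: the unassigned node of highest degree in the
refined graph (ties by ID) seeds a cluster and admits every unassigned
*direct graph neighbor* within a distance threshold; seed and admitted
nodes leave the pool and the process repeats, so clusters partition the
neighborhood and singletons are allowed. The admission threshold reuses
the package's single thresholding device — the adaptive cutoff over all
pairwise neighbor distances — rather than introducing a second free
parameter. Cluster quality is reported (max intra-member distance vs
minimum inter-centroid distance) as warnings, never failures.

The target (z-scored against the same population) is assigned to the
nearest cluster *that contains at least one annotated protein*, and
inherits the GO terms of the nearest annotated member, scored
`1/(1 + distance)`. Restricting to annotated transfer sources reflects
what the method does on real data, where every candidate carries
annotations: a protein without functions cannot donate functions, so
skipping unannotated members (rather than returning nothing when one
happens to be geometrically nearest) is the faithful generalization of
function transfer to partially annotated inputs. The prediction is empty
only when no cluster member is annotated. The `1/(1+d)` score is an
artifact of this package — the transfer itself carries no natural score,
but threshold-sweeping evaluation (Fmax) needs one, and any strictly
monotone transform of distance serves.

### Domain channel

Neighborhood nodes are mapped to their domains (one-to-many ID mappings
are fully honored — every mapped identity contributes, never just the
first). For every edge of the refined graph, each domain pair with DDI
support (order-insensitive) is *validated*. GO terms of the participating
domains are collected and ranked by frequency, scored
`frequency / max frequency`, and the top `top_n` (default 10) flow to the
target.

The counting unit is one occurrence per distinct **(protein, domain)**
combination participating in at least one validated pair. Counting per
validated pair instead (one occurrence per pair per edge) would square
local edge density: a dense clique that survives filtering with `m` nodes
contributes `O(m²)` occurrences per domain, letting a compact foreign
module outvote the target's own module even when the latter has more
proteins. Per-protein counting keeps the domain channel commensurate with
the annotation-side channels, which count proteins. When the
domain-to-GO table yields no terms at all, the channel falls back to the
annotations of the proteins carrying the validated domains (the target's
own annotations are never consulted).

### Topology channel

Candidate terms are the union of terms annotated to the refined
neighborhood's nodes (the target's own annotations never contribute
evidence — essential for honest held-out evaluation). Each term is tested
for over-representation with the one-sided Fisher exact test: with `N`
annotated background proteins of which `K` carry the term, and `n`
annotated neighbors of which `x` carry it, the p value is the
hypergeometric tail `P(X ≥ x)`, computed exactly in log space. Terms are
ranked by p ascending (ties: larger `x`, then term ID) and scored `1 − p`;
the top `top_n` (default 10) are returned, optionally filtered at a
significance level `alpha` (off by default: the method ranks raw p values,
and no multiple-testing correction is applied to a ranking). The
background defaults to all annotated proteins of the input network and is
configurable. Level-1 and level-2 neighbors are pooled with equal weight.
Because the channel accepts any gene-level edge list, it applies unchanged
to gene–gene association networks.

### Consensus

The n-star consensus accepts terms proposed by at least `n` predictors;
the combined score is the mean of the contributing predictors' scores, and
the star level (number of agreeing predictors) is reported as a
categorical confidence. `result(n+1) ⊆ result(n)` always; 1-star is the
union and 3-star the intersection, which the tests assert on random
inputs. A predictor with no output for a target counts as predicting
nothing, so a 3-star prediction is impossible for that target — the
consensus never invents agreement.

## Evaluation

Targets are evaluated leave-out: their annotations are hidden from every
predictor and serve only as truth. Per target,
`P = |pred ∩ truth|/|pred|` (0 for an empty prediction),
`R = |pred ∩ truth|/|truth|`, `F = 2PR/(P+R)`; macro averages are
unweighted means over targets with non-empty truth. Fmax follows the CAFA
protocol: for each threshold `τ` in `{0, 0.01, …, 1}` terms with score
`≥ τ` are kept; precision is averaged over targets with at least one
surviving prediction, recall over all evaluable targets, and Fmax is the
maximum harmonic mean over the grid. Per-aspect reports restrict both
predictions and truth to terms of one aspect.

## The synthetic benchmark

`generate_world()` builds a fully self-contained world:

* **Network** — planted-partition graph: `n_modules = 4` modules of
  `module_size = 25` proteins; within-module edge probability
  `p_in = 0.3`, between-module `p_out = 0.02`; weights drawn from
  Beta(8, 2) within (mean 0.8) and Beta(2, 8) between (mean 0.2),
  emulating STRING-style confidence separation.
* **Annotations** — each module owns `terms_per_module = 10` private GO
  terms (aspects cycled BP/MF/CC) annotated to all members; a fraction
  `annotation_noise = 0.05` of annotations is rewired to another module's
  terms. Ten terms per protein matches realistic annotation density, and
  the resulting 40-term vocabulary keeps chance-level recovery (with
  top-10 predictors) near F ≈ 0.03, far below any planted signal.
* **Sequences** — length 150, drawn from a module-biased composition:
  `composition_shift = 0.5` of the probability mass moves onto a
  module-specific two-residue signature (W/Y, D/E, K/R, I/V, …), which
  separates modules along several of the seven properties at once (the
  signatures were chosen to hit different property subsets).
* **Domains** — `domains_per_module = 2` private domains per module
  carried by every member, within-module DDIs, and domain→GO links to the
  module's terms.
* **Holdout** — `holdout_fraction = 0.1` of proteins become targets: their
  annotations are removed from the table and their *planted* module terms
  become the truth. Truth is the planted signal, not the noisy
  observations — noise models annotation error in the observed table, and
  every truth term remains carried by non-target module mates, so recovery
  is possible in principle for every target. A 90/10 split also keeps rare
  the structural failure in which a target's best transfer source is
  itself held out.

All randomness flows through one seed; identical parameters and seed give
byte-identical worlds on disk. What the generator does **not** emulate:
scale-free degree distributions, realistic protein sequences, shared
domains across modules, hierarchical GO structure, and annotation
incompleteness beyond the holdout. Passing the planted-recovery tests
therefore demonstrates that the machinery recovers modular signal under
the stated noise — not that real-proteome performance will match it.

With the default world, the unanimous 3-star pipeline recovers the planted
truth with macro F around 0.85–0.9 across seeds; the residual losses come
from proteins that sit on module boundaries (their refined neighborhood is
legitimately dominated by the adjacent module) and from annotation noise
propagated by the single-source sequence transfer. Shuffling all label
sources (protein→term and domain→term) collapses recovery to chance
(F ≤ ~0.05), and relaxing the consensus from 3-star to 1-star can only
gain recall at the cost of precision — all three facts are asserted by the
test suite and recomputed by `scripts/acceptance.R`.

## Numerical and degenerate-input conventions

* Population SD everywhere (thresholds, z-scores); σ = 0 populations are
  legal: thresholds collapse to the mean, z-components to 0.
* Strict `<` for all removals; ties always break deterministically
  (ID/term ascending), making every stage order-independent and the whole
  pipeline reproducible byte for byte.
* Sequence identity (the ≥ 90% ID-mapping fallback) is global
  Needleman–Wunsch with match 1 / mismatch 0 / linear gap −1; identity =
  matches / alignment length (gaps count in the denominator), threshold
  inclusive, all qualifying hits returned (consistent with the
  one-to-many mapping policy). An unmappable ID yields an empty result,
  not an error.
* Hypergeometric tails come from the exact log-space implementation in
  `stats::phyper`; the suite cross-checks it against exhaustive draw
  enumeration (universes up to N = 12) and an independent `lchoose`
  summation, and verifies null calibration on shuffled neighborhoods.
* Target selection (`select_targets`) samples `ceil(fraction × n)`
  candidates without replacement (deduplication after sampling is then a
  no-op, which is logged for transparency); the default fraction is 0.20
  over proteins carrying the top-10 most frequent terms.

## Known limitations

* Flat-label treatment of GO ignores term hierarchy; shallow and deep
  terms weigh equally in both prediction and evaluation.
* The bridge/fjord/shore operationalization is one defensible reading of
  the topological-role metaphor; other renderings (e.g. betweenness-based)
  would prune differently.
* The aggressive `k = 3` filter can leave the target isolated; predictors
  then rely on the surviving node set, which on very sparse neighborhoods
  may be dominated by an adjacent module (the main residual error source
  on the synthetic benchmark).
* The sequence channel transfers annotations from a single best source
  protein; one rewired annotation in that source propagates directly into
  the prediction.

## Problem sizes

The shipped tests and the acceptance script run on the default synthetic
scale — 100-protein worlds, 10 held-out targets, exhaustive graph
enumeration up to 6 nodes, 1,000-case random oracle sweeps, 2,000-draw
null calibrations — sizes chosen so the complete evidence chain (unit
oracles, property checks, end-to-end recovery, determinism) executes in a
few minutes on a laptop while still exercising every code path at
non-trivial scale.
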