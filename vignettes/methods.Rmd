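---
title: "Controllability-based candidate gene prioritization: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Controllability-based candidate gene prioritization: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(topcontrol)
```

## The model

`topcontrol` treats candidate disease-gene prioritization as a network
controllability question. The object of study is a typed directed graph:
transcription factors (TFs), genes and miRNAs connected by TF→gene,
TF→miRNA and miRNA→gene regulations, restricted to the differentially
expressed part of an experiment. The working assumption is that a node
which *controls* this differential network — because many regulations
flow through it — is a better disease candidate than a node that is
merely strongly deregulated, and that agreement between several
independent notions of control is stronger evidence than any single one.

Three notions of control are used:

* **Hubs.** The top decile of nodes by degree, where degree counts
  distinct interaction partners: in-degree plus out-degree over distinct
  (source, target) pairs, so a pair connected by two edge types counts
  once and a self-loop contributes 2. Exactly ⌈fraction·N⌉ nodes are
  returned.
* **Minimum dominating set (MDS).** Domination is *directed*: a node
  covers itself and its out-neighbors, because regulation flows from
  regulator to target; an MDS is the smallest set whose closed
  out-neighborhoods cover every node, i.e. the smallest set of regulators
  that controls the whole network. The equivalent binary program is
  minimize Σ x_v subject to x_v + Σ_{u∈pred(v)} x_u ≥ 1. We deliberately
  reject undirected domination: a target does not control its regulator.
* **Minimum connected dominating set (MCDS).** A dominating set of the
  largest connected component whose members additionally induce a
  connected subgraph of the *underlying undirected* graph — a dominating
  pathway. Connectivity is judged undirected because regulatory cascades
  mix edge directions; for the same reason "largest connected component"
  means largest *weakly* connected component.

A node's **score** is the number of these roles it plays (0–3); nodes
with score ≥ 1 form the candidate (fourth) layer and nodes with score 3
the top (fifth) layer, so the fifth layer is nested in the fourth by
construction. Within a score block the ranking falls back to
deregulation strength, |log2 fold change| descending — the absolute
value, so a strongly down-regulated gene outranks a mildly up-regulated
one. miRNAs carry no fold change in the expression table and are placed
after all fold-change-bearing nodes of their score block, whatever their
degree. Residual ties break by degree descending, then node id
ascending; the last two keys are ours, added purely so that the ranking
is a total, reproducible order.

## Network construction

Layer 2→3 has two statistical steps, both strict at their thresholds:

* **DE filtering** keeps records with adjusted p-value `< de_alpha`
  (default 0.05; the boundary value is excluded).
* **miRNA selection** tests, for each catalog miRNA, whether its partner
  set — the union of its target genes and its TF regulators — is
  over-represented among the DE genes. The test is the inclusive
  upper-tail hypergeometric probability P(X ≥ k) with the catalog's
  gene/TF nodes as universe, followed by Benjamini–Hochberg adjustment
  across the tested miRNAs and a cutoff of 0.001. Testing the union in
  one test is a design choice: targets and regulators could equally be
  tested separately, and `enrich_mirnas(mode = "separate")` does exactly
  that (both tests must pass, jointly BH-adjusted); the union is the
  default because it is the simplest reading and does not silently
  discard miRNAs that have, say, no TF regulator in the catalog. The
  universe is the catalog, not the genome, because the workflow nowhere
  supplies a genome size.

The differential network keeps a catalog edge only when all its gene/TF
endpoints are DE and all its miRNA endpoints are selected; nodes with no
surviving edge are dropped. Enlarging the DE set therefore can only add
edges, never remove them.

Node kinds are derived from the supplied edges alone: sources of TF-type
edges are TFs, miRNA-role endpoints are miRNAs, everything else is a
gene. A node appearing only as a TF→gene target is a gene even if it is
a TF elsewhere in the literature — there is no external kind oracle, and
guessing one would change overlap counts downstream. Contradictory
implications (a node in both TF and miRNA roles) are an error, not a
silent pick. Identifier matching everywhere is exact, case-preserving
and whitespace-trimmed; aliasing symbols would silently alter every
evaluation count.

## Solvers and numerical choices

* **Exact MDS** is a branch-and-bound over set covers: greedy solution
  as upper bound; at each branch node the hardest-to-cover element is
  chosen and each of its possible dominators tried in order of coverage;
  pruning uses the maximum of a coverage bound ⌈undominated/max-cover⌉
  and a disjoint-element packing bound. The greedy fallback is classic
  set-cover greedy with the tie cascade (max new coverage, max degree,
  lexicographic id). `mode = "auto"` (default) switches to greedy above
  `size_limit = 500` nodes — differential networks of a few hundred
  nodes solve exactly in well under a second, and the limit sits safely
  above the network sizes this method is designed for. Nodes that
  nothing else can dominate (in-degree 0, self-loops aside) are forced
  into the set before any search.
* **MCDS heuristic.** The literature describes connected-dominating-set
  heuristics at varying levels of detail; the schedule implemented here
  is this package's normative definition. Seed with the node of maximum
  out-degree (ties: total degree, then id); repeatedly add the node
  adjacent (undirected) to the current set covering the most undominated
  nodes; when no adjacent node helps, walk one step along a shortest
  undirected path towards the nearest undominated node; finally prune
  members, in ascending coverage order, whose removal keeps the set
  dominating and connected, to a fixed point. The output is validated
  post-hoc on every run — dominating and connected or the function
  aborts — and is never smaller than the exact MDS of the same
  component, since connectivity is an extra constraint.
* **Determinism.** Every tie-break in the package ultimately lands on a
  lexicographic id comparison, performed with radix (byte-order)
  sorting, so results are identical across locales and across edge-list
  permutations of the same network. Hub selection cuts boundary ties to
  exactly ⌈fraction·N⌉ nodes rather than expanding them; the ceiling
  reproduces the natural reading of "top 10 %" at the network sizes of
  interest (27.5 → 28, 46.3 → 47).
* **Evaluation.** Confusion counts satisfy tp+fn = K, tp+fp = n,
  tp+fp+fn+tn = N by construction; annotated ids absent from the network
  are excluded from K, because the network is the sampling background.
  Percentages are reported rounded half-up to integer percent (51.5 % →
  52 %); proportions are also kept unrounded in the report object.
  Degenerate cases are flagged, not failed: an empty annotation gives an
  undefined (NA) sensitivity, a candidate set equal to the universe an
  undefined specificity. The hypergeometric tail is computed via
  `stats::phyper` (log-space internally); BH via `stats::p.adjust`.

## The synthetic generator

Real inputs to this workflow are a DE table from an RNA-Seq contrast and
interaction catalogs exported from curated regulatory databases. The
generator emulates their structural properties so the whole stack is
testable offline: TF out-degrees are drawn by preferential attachment
(weight i^−a over TF ranks, default a = 1), giving the right-skewed,
hub-dominated degree distribution regulatory catalogs show; DE nodes
(default fraction 0.30 of genes and TFs) get adjusted p-values uniform
on (0, 0.05) and signed-exponential fold changes (scale 1.5); a planted
subset of miRNAs (40 %) draws its partners entirely from the DE set,
sized so the exact hypergeometric tail is below 1e−5 — comfortably past
the BH-adjusted 0.001 cutoff — while the rest draw uniformly; the
disease annotation samples 25 % of the planted network's layer-4 nodes
plus a 5 % background, emulating an annotation database that is enriched
in, but not confined to, controllable nodes. Default sizes (40 TFs, 800
genes, 10 miRNAs) yield differential networks of roughly 120–220 nodes,
the scale this method is aimed at. One integer seed drives a private RNG
stream; the global random state is saved and restored, and identical
specs yield byte-identical files.

What the generator does *not* emulate: correlated expression noise,
miRNA expression values, database ascertainment bias, multi-evidence
duplicate interactions, or any real gene symbols. Passing tests
therefore demonstrate that the algorithms implement their definitions
and recover planted structure — not that the biological assumptions hold
on any particular dataset.

The fixed 20-node toy network (`generate_toy_paper_network()`) is a
frozen regression fixture: its hubs, exact MDS and MCDS were computed
once with the oracle-validated solvers and are asserted verbatim in the
test suite. It is a synthetic illustration, not transcribed data.

## Problem sizes used by the test suite

Exact solvers are checked against exhaustive brute force where
enumeration is feasible: dominating sets on 8-node random digraphs (50
instances), connected dominating sets on 8-node random connected
digraphs (50 instances), and the hypergeometric tail against full draw
enumeration for all universes up to N = 12. End-to-end behavior
(determinism, layer nesting, planted-signal recovery) is checked across
100 generator seeds at the default spec. These sizes keep the full suite
around a minute while leaving the oracle comparisons exhaustive.

## Known limitations

* MDS and MCDS are generally non-unique; the package returns one
  deterministic optimum (or heuristic set), so *membership* of an
  individual borderline node is solver-dependent even though the MDS
  *size* is provably minimal. Scores of such nodes inherit that caveat.
* The MCDS is heuristic: validity is guaranteed, minimality is not.
* Enrichment selection is only as good as the catalog: a miRNA absent
  from the catalog, or present without DE partners, can never enter the
  network.
* No identifier mapping is attempted; mixed symbol conventions between
  the expression table, catalog and annotation will silently reduce
  overlaps. This is deliberate (aliasing is riskier than the failure it
  masks) but worth checking in inputs.
* The method ranks within one network; scores are not comparable across
  networks of different density, since hub counts and dominating-set
  sizes scale with density.
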