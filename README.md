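# topcontrol

Prior-knowledge-free prioritization of candidate disease genes and miRNAs
from the controllability of a TF–miRNA co-regulatory network.

## The problem

A differential-expression experiment between disease and normal tissue
typically yields thousands of significant genes — far too many to follow
up. Most prioritization tools narrow this list by training on known
disease genes, which biases them towards what is already annotated.
`topcontrol` instead ranks candidates purely from the *structure* of the
regulatory network the DE genes form: genes and miRNAs that topologically
control the network are promoted, and no disease seed list is ever used.

The workflow is a stack of five increasingly selective layers:

1. **All profiled genes** — the expression table (id, log2 fold change,
   adjusted p-value).
2. **DE genes** — adjusted p-value strictly below `de_alpha`
   (default 0.05).
3. **The differential co-regulatory network** — a typed directed graph
   with edges TF→gene, TF→miRNA and miRNA→gene, restricted from a catalog
   of experimentally validated interactions to the DE genes/TFs plus the
   miRNAs whose partner sets (targets ∪ TF regulators) are enriched among
   the DE genes (upper-tail hypergeometric test, Benjamini–Hochberg
   adjusted, cutoff 0.001).
4. **Controllability candidates** — the union of three node sets:
   - **hubs**: the top 10 % of nodes by degree, exactly
     ⌈0.1·N⌉ of them;
   - **MDS**: a minimum dominating set under directed domination (every
     node is a member or directly regulated by one) — the smallest set of
     regulators that controls the whole network, solved exactly by
     branch-and-bound (or greedily beyond a size limit);
   - **MCDS**: a minimum connected dominating set of the largest
     (weakly) connected component — a connected "dominating pathway" —
     from a deterministic growth-and-prune heuristic.
5. **Top candidates** — nodes selected by all three criteria.

Every node gets a **score** equal to the number of roles it plays
(0–3). The final ranking orders by score, then |log2 fold change|
descending (miRNAs, which carry no fold change, trail their score block),
then degree, then id. When a disease annotation (e.g. a DisGeNET/HMDD
export) is supplied, the layer-4 candidates are evaluated against it with
confusion-matrix metrics and the significance of the overlap by the
inclusive upper-tail hypergeometric test

P(X ≥ tp) = Σ_{i=tp}^{min(K,n)} C(K,i)·C(N−K,n−i) / C(N,n)

with the network's N nodes as background, K annotated nodes and n
candidates.

## Worked example

Everything runs on synthetic data with planted ground truth — no
downloads. The generator emulates a hub-skewed regulatory catalog, a DE
table, enriched miRNAs and a disease annotation concentrated in the
high-score nodes:

```r
library(topcontrol)
syn <- generate_synthetic(synthetic_spec(seed = 1))
fit <- topcontrol(syn$expression, syn$catalog, annotation = syn$annotation)
summary(fit, n = 8)
```

```
topcontrol prioritization
Regulatory network: 170 nodes (13 TF, 153 gene, 4 miRNA), 215 typed edges
  hubs 17 | MDS 17 (exact) | MCDS 27 | layer 4: 29 | layer 5: 15
  layer-4 overlap p = 0.00307

Top-ranked candidates:
Priority table: 170 nodes (29 in layer 4, 15 in layer 5)
 node kind degree hub mds mcds score     lfc layer rank
 TF02   TF     65   1   1    1     3 -2.3494     5    1
 TF32   TF      4   1   1    1     3 -1.9645     5    2
 TF28   TF      6   1   1    1     3  1.4991     5    3
 ...

Candidate-set evaluation (universe N = 170, annotated K = 14, candidates n = 29)
  tp=7 fp=22 fn=7 tn=134
  sensitivity 50%, specificity 86%, accuracy 83%
  hypergeometric p = 0.00307
```

Reading this: the 215-edge differential network has 170 nodes; 29 of them
carry at least one controllability role (layer 4) and 15 carry all three
(layer 5). TF02 tops the ranking — it is a hub (degree 65), an MDS member
and on the dominating pathway, with |LFC| = 2.35. Of the 14
disease-annotated network nodes, 7 are recovered by the 29 layer-4
candidates; an overlap that extreme has probability 0.003 under random
draws from the network, so the topological selection is picking up the
planted disease signal.

The same workflow runs from the shell:

```sh
exec/topcontrol synth --out demo/ --seed 1
exec/topcontrol run --de demo/expression.tsv --catalog demo/catalog.tsv \
    --annotation demo/annotation.txt --out demo/out/
```

which writes `network.tsv`, `node_sets.tsv`, the ranked `priority.tsv`,
`mirna_enrichment.tsv`, `evaluation.json`, `summary.json` and a
`run_log.txt` echoing every parameter.

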