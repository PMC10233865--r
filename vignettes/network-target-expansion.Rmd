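---
title: "Layered chemical–target networks: models, evaluation protocol and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Layered chemical-target networks: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`hetlink` treats target identification for herbal chemicals as link
prediction on a single undirected simple graph whose nodes are chemicals
and protein targets and whose edges carry a layer label:

* **CTC** (chemical–target): bioassay-supported activity, taken directly
  from input records;
* **CCC** (chemical–chemical): fingerprint Tanimoto similarity at or above
  a threshold. The premise is the classical similarity principle —
  structurally similar molecules tend to share biological activities — so
  a similarity edge is indirect evidence that two chemicals' target sets
  overlap;
* **PPI** (target–target): protein interaction confidence at or above a
  threshold, the analogous premise being that interacting proteins tend to
  share ligands and pathways.

Scores on CCC/PPI edges are kept as metadata but the graph is treated as
unweighted downstream: none of the five scorers uses edge weights, and
mixing a similarity scale with a confidence scale into one weight would be
arbitrary.

Nodes carry a role (`chemical`/`target`) and a non-empty origin set drawn
from `DS` and `CX` (the two herbs) and `drug`. Origins drive two things:
**group assembly** — a chemical enters a group (e.g. `DS-drug`) iff its
origin set intersects the group's tags, and targets enter through an
incident CTC edge with a selected chemical — and the **expansion filter**,
which keeps predicted edges from herbal chemicals to drug targets. The
group rule is the minimal one consistent with origin tags; no silent
pruning of isolated nodes is done (they are retained in the graph but
start no walks).

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| Tanimoto threshold | 0.6 | minimum `|A∩B|/|A∪B|` for a CCC edge; the conventional "structurally similar" cut for 2D fingerprints |
| PPI threshold | 0.9 | minimum interaction confidence (0–1 scale) for a PPI edge; the high-confidence band of STRING-style scores |
| `p`, `q` | 1, 1 | node2vec return and in–out bias; at 1/1 the walk is an unbiased second-order walk |
| `dims`, walks, length, window | 128, 10, 80, 10 | embedding width and walk-corpus shape, the original node2vec defaults |
| `epochs`, `negative`, `alpha` | 3, 5, 0.025 | skip-gram training passes, negatives per positive, initial SGD rate |
| spectral `k` | 16 | Laplacian eigenvectors kept as node features |
| split | 6:3:1, 10 rounds | train/validation/test fractions and resampling rounds |
| `neg_ratio` | 1 | sampled non-edges per positive, the community default for link-prediction evaluation |
| prediction threshold | 0.5 | minimum classifier probability for a retained new edge |

## Evaluation protocol

"Tenfold cross validation" of a 6:3:1 split is contradictory if read as
classical fold partitioning — ten disjoint folds cannot produce those
fractions — so the protocol is implemented as **ten independent reseeded
6:3:1 resampling rounds**, which preserves both facts. Per round:

* edge positives are partitioned 6:3:1 uniformly at random (exact on
  multiples of ten); the training graph keeps only training edges but all
  nodes, so held-out endpoints remain addressable;
* negatives are sampled uniformly from verified non-edges of the *full*
  graph, 1:1 with positives and disjoint across partitions. The default
  candidate universe is all node pairs, matching graph-level evaluation
  over all edge types; an option restricts it to chemical–target pairs;
* the validation partition is reserved for hyperparameter selection and is
  never used to fit the final classifier;
* test pairs are scored and summarized by AUROC (normalized Mann–Whitney
  U, ties counted ½ — exactly the "random positive outranks random
  negative" expectation) and average precision via the ranked threshold
  sweep `Σ_n (R_n − R_{n−1}) P_n`.

Numerical conventions: AP uses a stable sort on descending score, so tied
blocks are deterministic; labeled pair sets are row-shuffled (seeded) so a
degenerate all-ties scorer cannot inherit signal from input order; Jaccard
of two isolated nodes is 0 by convention; Adamic–Adar uses the natural
logarithm (the base only rescales scores and leaves rankings unchanged —
and a common neighbor necessarily has degree ≥ 2, so `log|N(z)|` never
vanishes).

## The five scorers

AA, Jaccard and PA are neighborhood indices computed on the training
graph; their raw values suffice for rank-based metrics, and when
probabilities are needed (the 0.5 prediction-value filter) they pass
through a one-feature logistic calibration fitted on the training pairs.

node2vec walks the merged graph ignoring layer labels (each dataset is
embedded as one graph), with the second-order rule: from state (t → v) a
neighbor x of v has unnormalized weight `1/p` if `x = t`, `1` if x is
adjacent to t, `1/q` otherwise. Skip-gram training is word2vec-style SGNS:
shrunk context windows, unigram^0.75 negative table, linearly decaying
rate, single-threaded with all draws from R's RNG — so a fixed seed gives
bitwise-identical embeddings. Edge features combine endpoint vectors with
the Hadamard product by default (the best operator in the original
node2vec study; `average`, `l1`, `l2` are available), and a logistic
classifier on labeled training pairs produces edge probabilities.

Spectral embedding takes the k eigenvectors of the symmetric normalized
Laplacian `I − D^{-1/2} A D^{-1/2}` with smallest eigenvalues as node
features. It feeds the *same* logistic head as node2vec — distance- or
KNN-style rules belong to clustering, not edge labeling, and a uniform
head isolates the comparison to the embedding itself. On disconnected
graphs the zero eigenvalue has multiplicity equal to the number of
components; this is reported, not treated as an error. Test pairs with an
endpoint the training embedding never saw are scored through zero-vector
features (with a warning), which collapses to the classifier's intercept
probability — a deliberate "no information" fallback.

## Target expansion

The extraction model is retrained on 100% of the dataset's edges (not
reused from a cross-validation round): extraction is a deployment step,
and discarding 40% of known edges would only degrade it. Candidates are
chemical–target non-edges within the group (only CTC predictions are
analyzed downstream); an `"all"` flag also scores chemical–chemical and
target–target non-edges for total-edge accounting. Retained records
(probability ≥ 0.5) are filtered to herbal-chemical → drug-target pairs
and tabulated as counts and percentages,
`round(100 × expanded / original, 2)` per category. Downstream manual
curation steps (indication review, literature support, structure
availability) are external curation calls and are left to the user.

## The synthetic generator

Real curated pharmacology networks cannot be redistributed, so the
generator plants the latent structure the analysis premises assume: a
shared block assignment for chemicals and targets. Within a block,
chemical–target edges are denser (`ctc_p_in` vs `ctc_p_out`); each block
owns a random signature of fingerprint bits and a chemical's fingerprint
is its block signature with per-bit flip noise, so the Tanimoto cut
concentrates CCC edges within blocks; protein-pair confidences are clipped
normals with a high intra-block mean (0.92) and a low inter-block mean
(0.4), so the 0.9 cut keeps almost exclusively intra-block pairs.
`herb_fraction` of chemicals are tagged herbal (DS, CX, or occasionally
both, mirroring compounds shared by two herbs); targets inherit the union
of their partners' origins.

The default profile matches the scale of the curated study (~400
chemicals, ~1000 targets, CTC edges in the low thousands). The small
profile (`tiny_config`: 40/100, 4 blocks) raises the within-block edge
probability to 0.28 so the CTC layer still lands near 350 edges at a tenth
the node count; it is the profile used by the test suite, the analysis
scripts and the acceptance script, chosen so a full benchmark grid runs in
about a minute. Emitted protein pairs are floored at score 0.6 — pairs
below that can never pass a high-confidence cut and would only bloat the
files.

What the generator does *not* emulate: scale-free degree structure, valid
chemistry (fingerprints are abstract bit sets, not molecules), hub
promiscuity of real targets, and curation biases. Passing tests therefore
demonstrate that the pipeline recovers planted shared-latent-group signal
— the mechanism the method relies on — not that any particular AUROC will
be attained on a real curated network.

One consequence of the block design is worth stating: a held-out planted
edge is statistically exchangeable with every other intra-block non-edge,
so recovery is assessed by rank (held-out edges concentrate in the top
quantile of candidates and pass the 0.5 cut), not by exact top-k
membership.

## Reproducibility

A single master seed fans out to per-stage seeds through a deterministic
hash (`derive_seed`), so stages are independently reproducible; every
output TSV records the seed in a comment header. All stochastic components
— the generator, splits, negative sampling, walks, SGNS — draw from R's
RNG and run single-threaded, so identical seeds give byte-identical
outputs (asserted in the test suite).

## Known limitations

* The logistic head is unregularized; with very small training sets and
  128-dimensional Hadamard features it can separate perfectly (coefficients
  diverge), which is harmless for ranking but makes raw probabilities
  extreme near the decision boundary.
* AP under heavy score ties depends on the tie convention; the stable-sort
  sweep is deterministic but other software may collapse tied blocks and
  report slightly different values.
* The candidate universe for full-graph extraction grows quadratically;
  at a few thousand nodes the dense spectral decomposition and exhaustive
  candidate scoring remain comfortable, but both would need sparse/blocked
  variants well beyond that.
* Preferential attachment carries no block information by construction, so
  on planted-block data it hovers near chance on the layered datasets —
  visible in the benchmark grid, and a useful negative control.
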