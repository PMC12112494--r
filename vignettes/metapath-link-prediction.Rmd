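---
title: "Metapath-guided MDA link prediction: model, assumptions and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Metapath-guided MDA link prediction: model, assumptions and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(hetmda)
```

This vignette is the package's own account of its science: the model and
its assumptions, the tunables that matter, what the synthetic generator
does and does not emulate, the numerical choices, and the places where the
design was genuinely open. It states no empirical number that the test
suite or `scripts/acceptance.R` does not itself compute.

## 1. Problem and leakage protocol

Given a typed biological network over miRNA, disease, mRNA, lncRNA,
circRNA, protein, drug and microbe nodes, we predict missing edges of the
miRNA–disease relation as a balanced binary classification over node
pairs. Two leakage channels dominate this literature and both are closed
here by construction:

* **Split leakage.** Positive edges are split 75:10:15 into
  train/valid/test (floor counts, remainder to train, so the test share
  never exceeds its nominal fraction); negatives are drawn once, uniformly
  without replacement from the non-edge miRNA×disease pairs, 1:1 per
  split and disjoint across splits. `build_training_graph()` then removes
  every held-out positive from the graph: message passing and metapath
  materialization only ever see training edges.
* **Target-edge leakage.** The evidence set served for a candidate pair
  `(u, v)` never contains the step `(u, v)` itself. Instances are
  node-simple (no repeated node), which on this schema already implies the
  exclusion; the guard is nevertheless enforced explicitly and asserted in
  the tests, because it is the property that keeps the decoder from
  reading its own label.

Deliberately absent: GIP-kernel and MISIM-style similarity features, which
import the association matrix into the feature space.

## 2. Model

**Pre-encoding.** Per-type linear maps `W_T` project raw features to a
shared `d`-dimensional space. Types without measured features receive
learnable free embeddings (seeded normal, width `d_in`), the standard
choice when entities have no covariates. One RGCN layer follows, with a
full `d × d` matrix per *directed* relation (34 on this schema) plus a
self weight; the normalizer is `1/|N_r(v)|`, the standard per-node,
per-relation in-degree rule (the source text leaves `c_r` open). A single
layer is the default: it captures first-order heterogeneous neighborhoods
and converges fast; deeper stacks are configurable (`n_layers`) but not
part of the reference pipeline. The `-HMPNN` ablation switch routes the
projected features directly downstream.

**Metapath encoding.** Twelve node-specific classes (six per anchor type)
and thirteen common classes are enumerated from the schema by rule:
length-2 paths `A–X–A` for node-specific; for common classes, miRNA→disease
paths of length 2–3 whose intermediates exclude the anchor types, plus the
alternating `miRNA–disease–miRNA–disease` pattern. Plain exhaustive
enumeration would also emit paths such as miRNA–drug–miRNA–disease; the
intermediate-type rule is the unique simple rule that reproduces the
published 25-class catalogue, and the alternating pattern is the
common-neighbor analogue on the bipartite target graph. Instances are
materialized by depth-first traversal on the training graph, capped at 32
per (anchor, class) by seeded uniform subsampling (the alternating class
grows quadratically in MDA degree; 32 instances of a 3-edge path already
summarize a neighborhood well at fixture scale, and the cap bounds memory
linearly in the pair count).

Each instance encodes as `W_P ·` (mean of all node embeddings on the
path, endpoints included); classes aggregate instances by mean followed by
LeakyReLU (the default — intra-class attention with per-class score
vectors Θ is the `+iattn` variant, which the evidence says is not worth
its cost); and the `M` class vectors of a sample fuse by sample-wise
multiplicative self-attention: `X = tanh(H W1 + b1)`, `Q/K/V` projections,
row-softmax `QKᵀ/√d_k`, class scores `(A V) W2`, and weights `β` by
softmax over classes. Everything is computed within one sample, so the
operator is batch independent and the weights are comparable across
samples — the printed form leaves `β` unnormalized, and a flag
(`beta_normalize = FALSE`) preserves that literal reading, but normalized
weights are the default because per-sample weight distributions are
otherwise incomparable, which is what the exported heatmaps rely on. The
`-attn` ablation replaces this with batch-based additive attention (one
softmax over class scores averaged across the batch), which is *not*
batch independent — the property tests demonstrate the difference.

A class with no surviving instances contributes a degenerate completion —
the anchor node itself, or the bare pair `(u, v)` — so `M` is constant
(6/6/13) and `β` remains comparable across samples. This "complete the
metapath with the nodes themselves" rule also means the encoder degrades
gracefully on isolated nodes.

**Decoder.** `y = f(f1(h_u ⊙ h_v) + β_dec · f2(h_uv))`, MLPs `f1, f2:
d→d` and `f: d→1`, each one hidden layer of width `d` with layer
normalization (ε = 1e-5) and LeakyReLU; `β_dec` initialized to 1 so the
structural term starts active and training scales it. `use_link = FALSE`
(the `-link` ablation) is exactly the `β_dec = 0` restriction, asserted
by test. Scores are logits; probabilities via sigmoid; the classification
threshold for precision/recall/F1 is 0.5.

**Training.** Full-batch binary cross-entropy with logits (the standard
loss for 1:1-sampled link prediction; the source never names its loss),
Adam (β₁ 0.9, β₂ 0.999, ε 1e-8) with weight decay 1e-4 applied to
matrix-valued parameters, learning rate 5e-3, at most 200 epochs, early
stopping on validation AUC with patience 20, best-validation parameters
restored. The protocol trains five seeds that re-partition train/valid
while the test set stays fixed (`test_seed`), and reports mean ± sd per
metric in percent. Forward, backward and Adam are hand-implemented on
dense/sparse matrices; a finite-difference check in the test suite
verifies every parameter group's gradient.

## 3. Metrics as printed

AUC uses the exact pairwise form (ties count ½), computed via midranks —
algebraically identical to the double loop, and the tests assert exact
equality against a brute-force oracle. AP is the *trapezoidal* area under
the precision–recall polyline with one threshold per distinct score,
descending, anchored at (recall 0, precision 1); this deliberately differs
from the step-wise AP of common toolkits, and monotone transforms of the
scores leave it unchanged. Precision is reported as 0 (with a warning)
when no positive predictions exist.

## 4. The synthetic world: what a green test establishes

`synth_generate()` draws a stochastic block model over the full 8-type
schema: every node gets one of `C = 3` latent clusters; each relation
draws edges independently with `p_in = 0.3` within clusters and
`p_out = 0.02` between (defaults); the default node counts
(60/60/80/40/20/60/40/10) train in minutes on one CPU. Cluster structure
is the simplest mechanism that makes common metapaths informative — the
property the decoder exploits — and the ground-truth labels are written
alongside the edges.

**Detectability calculus.** In a pure SBM, every pair statistic is a
function of cluster co-membership, so the Bayes-optimal pair score takes
two values and the optimal AUC has the closed form
`a(1-b) + (ab + (1-a)(1-b))/2` with `a = P(same cluster | edge)` and
`b = P(same cluster | non-edge)`. With uniform 0.3/0.02 densities this
ceiling is ≈ 0.81 — no method could meet a 0.85 recovery bar in that
world. The target-relation densities are therefore fixed once at
`p_in_target = 0.5`, `p_out_target = 0.005`, giving `a ≈ 0.99`,
`b ≈ 0.20` and a ceiling of ≈ 0.89. This is a design rule, not a tuned
number: the fixture is meant to be information-sufficient, and the
recovery test then measures whether the pipeline approaches the ceiling.

**Signal modes.** `mixed` (default) structures every relation;
`mediated` scales the target densities by `mda_scale = 0.25` so the few
retained training MDA edges carry little direct/alternating-path evidence
and signal flows mainly through shared intermediates; `direct` flattens
all non-target relations to a density-matched uniform probability. A
literal "uniform MDA" mediated mode would make the labels independent of
the entire graph (provably AUC 0.5 for any method), so cluster alignment
is retained and sparsity does the weakening.

**What the generator does not emulate:** real degree heavy-tails and hub
structure, isolated nodes, relation-specific densities, correlated
cluster memberships across types, and real-data scale (the real network
is ~50× larger). A green recovery test therefore establishes that the
pipeline extracts planted block structure through heterogeneous
metapaths without leakage — not that it matches published accuracy on
curated databases.

**A known red check, and why.** The directional ablation check — full
model ≥ `-link` on the mediated fixture over 3 seeds — fails honestly at
desk scale and is left red. The mediated world does contain pair-level
structural signal (the raw instance count alone scores ≈ 0.81 AUC), but
in an SBM cluster co-membership is a sufficient statistic which the
node-embedding route expresses fully, so the common-metapath term adds no
*information*; its measured effect is a finite-sample difference an order
of magnitude smaller than the ±5% seed noise at 123 training positives.
Demonstrating the decoder's benefit requires worlds where link evidence
exceeds what node representations can carry (hubs, overlapping
communities, real networks), which the block model deliberately does not
provide.

## 5. Numerical choices and degenerate inputs

* Dimensions: `d = 64`, `d' = d`, `d_k = d/2`; attention softmaxes are
  max-shifted; BCE uses the `log1p(exp(-|z|))` stable form.
* LeakyReLU slope 0.01 everywhere a hidden activation is needed; `tanh`
  inside the self-attention transform as printed.
* Isolated node: RGCN degenerates to `σ(W_0 h_v)`; all metapath classes
  fall back to the degenerate instance; the pipeline stays defined.
* Duplicate edge rows collapse at load time with a warning; reversed
  orientations (`dst_type`/`src_type` swapped) are canonicalized.
* Subsample seeds derive from a 31-bit string hash of (class, key), so
  stores are reproducible regardless of iteration order; R's global RNG
  state is always restored.
* Empty validation split: training runs to the epoch budget and returns
  the final state.

## 6. Open-design decisions

* Pre-encoding is trained jointly end to end (the workflow implies joint
  training; a frozen pre-training phase is not implemented).
* Node embeddings entering the decoder are purely the secondary
  (metapath) encodings — no residual concatenation of the RGCN output.
* One `W_P` per metapath class, shared by all instances of that class.
* Negatives are fixed at split time (per-epoch resampling exists behind
  `resample` flags in the roadmap but is off; the protocol samples once).
* The `+self_super` flag is accepted and documented as a no-op: auxiliary
  node-type/metapath-type classification does not improve this
  architecture, so the default build omits it.
* Config files for the CLI are JSON rather than YAML: the deployment
  environment ships no YAML parser, and `jsonlite` round-trips the same
  structure.

## 7. Limitations

Desk-scale only: dense per-relation weight matrices and full-batch
training are appropriate for hundreds of nodes, not the ~12k-node real
network, which would want sparse minibatching and basis-decomposed
relation weights. The generator's SBM ceiling (section 4) bounds what any
recovery test can show. Metrics are reported at a fixed 0.5 threshold;
no calibration is attempted.
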