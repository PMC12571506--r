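---
title: "Methods: multimodal protein function prediction over protein family networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multimodal protein function prediction over protein family networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(pfnet)
```

This vignette is the package's account of its model, its evaluation
stack, the synthetic benchmark it ships, and the design choices that
were genuinely open. The README shows the corresponding runnable
example.

## The prediction problem

Gene Ontology annotation is hierarchical multilabel classification.
Each protein carries a set of terms from one namespace (BPO, CCO or
MFO); the namespaces are directed acyclic graphs, and the true-path
rule makes every annotation imply all of its ancestors. Training data
are scarce and noisy — only experimentally supported annotations are
trusted — so the pipeline starts with evidence-code filtering
(`filterEvidence()`, presets `EXPERIMENTAL` = EXP, IDA, IMP, IPI, IGI,
IEP, TAS, IC and `EXTENDED`, which adds the high-throughput codes HTP,
HDA, HMP, HGI, HEP), true-path propagation
(`propagateAnnotations()`), and a label filter that keeps only terms
annotated to at least 10 training proteins (`filterLabels()`; roots are
excluded, because predicting the root is uninformative). Models are
trained per namespace, since the three DAGs have very different
branching statistics and label counts.

## The model

Two feature views are encoded in parallel and fused late.

**Graph tower.** The protein family network (PFN, `buildPFN()`) links
two proteins iff they share a qualifying InterPro signature — family,
domain or motif by default; clique expansion per signature. Edges are
unweighted for message passing; the number of distinct shared
signatures is kept only as metadata, since no principled weighting rule
presents itself. Over this graph a two-layer graph attention network
runs with protein language-model embeddings as node features
(mean-pooled encoder states, width 1536 for the usual provider). The
attention is the original additive form: for edge $j \to i$ and head
$h$,

$$e_{ij} = \mathrm{LeakyReLU}\!\left(a_{1h}^\top W_h x_i + a_{2h}^\top W_h x_j;\ 0.2\right),
\qquad \alpha_{ij} = \mathrm{softmax}_{j \in N(i) \cup \{i\}}(e_{ij}),$$

$$o_i^{(h)} = \sum_j \alpha_{ij} W_h x_j .$$

Layer 1 uses 3 heads of width 128, concatenated (384), followed by an
ELU — the customary inter-layer activation for this architecture.
Layer 2 is a single head of width 512 with no activation before
fusion. Self-loops are added transiently so isolated proteins reduce
to a linear map of their own features.

**Signature tower.** Each protein's 0/1 signature profile (vocabulary
frozen on the training split; unseen proteins get all-zero rows) passes
through three affine layers with LeakyReLU after the first two,
reducing gradually — intermediate widths interpolate geometrically
between the vocabulary size and the 512-d output.

**Fusion.** The two 512-d representations are concatenated (1024) and
passed through one hidden layer (1024 wide, LeakyReLU, dropout 0.2)
to per-term sigmoid outputs. The five ablation modes reuse the same
head: `LLM` feeds the raw embedding directly, `BPV` the encoded
signature profile, `BPV_GNN` runs the GAT with binary rows as node
features, `LLM_BPV` concatenates raw embedding and encoded profile
without any graph. We implement concatenation fusion only; no residual
path crosses the towers.

**Training.** Mean per-label binary cross-entropy on sigmoid outputs —
the standard multilabel choice — minimized with Adam (lr 1e-3 by
default) on minibatches of 64 seed proteins. Graph modes use two-hop
neighborhood sampling (`sampleNeighborhood()`): up to `fanouts[1]` (25)
neighbors per seed, then up to `fanouts[2]` (10) per first-hop node;
the second hop must not exceed the first. Sampling is uniform without
replacement and deterministic per seed. After each epoch the
validation loss is monitored: the learning rate halves after 2 epochs
without improvement, training stops after 5 (the early-stopping
patience), and the best-validation checkpoint is returned. Inference
always uses full (un-sampled) neighborhoods and no dropout, so
prediction is deterministic. Multi-seed runs are summarized as
mean ± standard deviation per metric (`summarizeRuns()`).

## Evaluation

`evaluatePredictions()` re-implements the CAFA protocol. Scores are
first max-propagated up the DAG (each term takes the maximum over
itself and its descendants), root terms are dropped from both
predicted and truth sets, and proteins with empty ground truth are
excluded from $n$. At threshold $\tau$ the predicted set is every
label scoring $\ge \tau$ — except that a score of exactly 0 never
counts as a prediction: an unscored term was not submitted, so the
$\tau = 0$ grid point evaluates "all submitted predictions". Precision
averages over only the $m(\tau)$ proteins with non-empty predictions;
recall over all $n$. Fmax is the maximum harmonic mean over the
101-point grid $\{0, 0.01, \ldots, 1\}$.

Information content is estimated on the propagated **training**
annotations only (test annotations must not leak into the evaluation
weights): $IC(x) = -\log\left(n(x) / n(P(x))\right)$ with $n(P(x))$
the number of proteins carrying *all* direct parents of $x$ (the
corpus size for roots). Zero or undefined ratios are clamped to
$1/(\text{corpus}+1)$ so IC stays finite; the natural log is the
default base. Smin is the minimum over the grid of
$\sqrt{ru(\tau)^2 + mi(\tau)^2}$, with $ru$/$mi$ the mean total IC of
missed / spurious terms. AUPRC is micro-averaged over all
(protein, term) pairs with step-wise summation and no interpolation
(macro averaging per label is available via a flag). Per-taxon
breakdowns reuse the same machinery per group
(`evaluateByGroup()`).

All of these are checked in the test suite against a brute-force
evaluator that materializes every predicted set explicitly, to 1e-9.

## The synthetic benchmark

`generateWorld()` builds a closed world in which the ground truth is
known by construction: a single-rooted random DAG; 30 signatures, each
carrying a planted rule pointing at one or two leaf terms; 300
proteins, each drawing 2 signatures; annotations formed as the
propagated union of the rule terms of a protein's signatures, with
each planted term dropped with probability 0.05 and a
Poisson(0.05)-distributed count of spurious terms added; 70/15/15
train/valid/test splits by protein index (mimicking chronological
benchmark construction); taxa assigned round-robin over three model
organisms. Synthetic embeddings (`syntheticEmbeddings()`) are
unit-variance Gaussian vectors keyed by a hash of accession and seed —
so they are identical regardless of request order — plus a
class-specific offset (class = the protein's lexicographically first
signature) so the embedding tower carries signal as well.

Two shape choices matter and were fixed after a small design pilot:

- **DAG growth** mixes recency-biased attachment (probability 0.5,
  window 6) with uniform attachment and a 0.15 chance of a second
  parent. Pure uniform attachment yields a shallow, bushy DAG in which
  propagated annotation sets share a large common core; pure recency
  yields a single chain with the same problem. The mixture produces
  deep *and* branching ontologies, so different proteins' truth sets
  are genuinely distinct — as in real GO — and a label-prevalence
  baseline cannot trivially match a real model.
- **Rules target leaves** (not arbitrary deep terms), again so truth
  sets are long, mostly disjoint ancestor chains.

As noise goes to zero a protein's annotations become an exact function
of its signatures, so the Bayes-optimal predictor approaches Fmax 1;
the tests verify that the trained full model approaches it (median
Fmax at least 0.90 over five seeds at 5% noise) and beats the
prevalence baseline by at least 0.3. What passing these tests shows is
that the architecture, gradients, sampling and evaluation interlock
correctly on a separable world; it does **not** show real-data
performance — real GO corpora have five orders of magnitude more
annotations, far more promiscuous signatures, and embeddings whose
class structure is not planted.

## Numerical choices

- Parameter initialization is variance-scaled (Glorot) uniform, keyed
  by the model seed; all randomness (initialization, shuffling,
  sampling, dropout) derives from explicit seeds, and repeated runs
  with the same seeds are bitwise-identical.
- Gradients are analytic throughout (including through the grouped
  attention softmax) and are verified against central finite
  differences at tolerance 1e-4 in every ablation mode.
- Binary cross-entropy is computed on logits with the stable
  softplus form; attention softmax subtracts the per-neighborhood
  maximum.
- Ties in the Fmax argmax resolve to the smallest threshold; AUPRC
  groups tied scores and evaluates at the last index of each tie.
- The bundled experiments use desk-scale widths (embedding 64, GAT
  3x32 to 64, signature latent 64, fusion hidden 128) so a full
  5-seed run takes well under a minute on one CPU core; the
  `modelConfig()` defaults remain the full-scale widths
  (1536 / 3x128 / 512 / 512 / 1024).

## Limitations

- Real protein language-model inference is out of scope; embeddings
  are consumed from files (`loadEmbeddings()`) or simulated. The
  mean-pooling contract is only verified for mock encoders.
- The PFN treats all qualifying signatures equally; one promiscuous
  signature creates quadratically many edges. `buildPFN()` offers a
  `maxGroupSize` cap, off by default to match the dense graphs the
  method targets (sampling, not sparsification, is the intended
  mitigation).
- InterProScan's standard 13-column TSV carries no entry type, so
  signatures parse as type OTHER unless the optional 14th column is
  present; with real files either widen `qualifyingTypes` or supply
  the extra column.
- Checkpoint portability is guarded only by a vocabulary hash; no
  versioned serialization format.
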