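# pfnet

Multimodal prediction of protein function (Gene Ontology annotation) in
R, for computational biologists who have InterProScan output and protein
language-model embeddings but no GPU stack.

Automatic function prediction is a hierarchical multilabel problem:
each protein carries a set of GO terms from one of three namespaces
(BPO, CCO, MFO), and annotation to a term implies annotation to all of
its ancestors in the GO DAG (the true-path rule). `pfnet` implements a
network-based predictor around three ideas:

1. **Protein family network (PFN).** Proteins that share an InterPro
   family, domain or motif signature are linked by an edge (clique
   expansion per signature). This graph is denser and more broadly
   available than protein–protein interaction networks.
2. **Two-tower encoder.** A two-layer graph attention network (GAT; 3
   heads x 128 then 1 head x 512, additive attention with LeakyReLU
   slope 0.2, softmax over the sampled in-neighborhood including a
   self-loop) runs over the PFN with mean-pooled protein language-model
   embeddings (1536-d by default) as node features. In parallel, the
   0/1 signature profile of each protein is compressed to 512
   dimensions by a three-layer LeakyReLU perceptron.
3. **Late fusion.** The two 512-d representations are concatenated and
   fed to a fusion MLP with per-term sigmoid outputs, trained per
   subontology with mean binary cross-entropy, Adam, a
   reduce-on-plateau learning-rate scheduler, two-hop neighborhood
   sampling and early stopping (patience 5).

Five ablation configurations are expressible through `modelConfig(mode=)`:
`LLM` (embeddings only), `BPV` (signature vectors only), `BPV_GNN`
(GAT over signature vectors), `LLM_BPV` (no graph), and `FULL`.

Evaluation follows the CAFA protocol, implemented from scratch:
protein-centric **Fmax** (precision averaged over the m(τ) proteins
with at least one prediction at threshold τ, recall over all n
evaluated proteins), **Smin** = min over τ of
sqrt(ru(τ)² + mi(τ)²) where ru/mi are the information-content-weighted
remaining uncertainty and misinformation, with
IC(x) = −log Pr(x | parents(x)) estimated from training annotation
counts, and micro-averaged **AUPRC**. Scores are max-propagated up the
DAG before evaluation and root terms are excluded.

A synthetic-world generator (`generateWorld()`) produces a complete
desk-scale benchmark — random GO-like DAG, signature catalog with
planted signature→term rules, propagated annotations with controlled
noise, deterministic embeddings with class signal, chronological-style
splits — so the entire pipeline is testable without downloads.

## Worked example

```r
library(pfnet)

world <- generateWorld(seed = 42)   # 300 proteins, 60 terms, 30 signatures
world
#> SyntheticWorld: 300 proteins, 60 terms, 30 signatures; seed 42
#>  test train valid
#>    45   210    45

data <- worldPipelineData(world)    # PFN, embeddings, labels, IC table
data$pfn
#> ProteinFamilyNetwork: 300 nodes, 5845 edges, mean degree 38.97 , 0 isolated

config <- modelConfig(mode = "FULL", inputDim = 64, gatHeads = 3,
                      gatHidden = 32, gatOut = 64, sigLatent = 64,
                      fusionHidden = 128)
fit <- trainModel(data, config, optSettings(lr = 3e-3, maxEpochs = 40),
                  seed = 1)

testIds <- names(data$splits)[data$splits == "test"]
preds <- predictScores(fit, testIds, data)
report <- evaluatePredictions(
  preds, subsetAnnotations(data$annotations, testIds), data$dag, data$ic)
report
#> EvaluationReport [MFO] n=45  Fmax=0.9478 (tau*=0.35)  Smin=0.9233  AUPRC=0.9776
```

The report says: over the 45 test proteins, the best threshold (0.35)
gives a harmonic-mean precision/recall of 0.948; the residual
IC-weighted annotation error is 0.92 nats; and the pooled
precision-recall area over all (protein, term) pairs is 0.978. A
label-prevalence baseline (`prevalenceBaseline()`) reaches Fmax ≈ 0.55
on the same world — the gap is what the graph and signature towers
contribute.

`cmdSimulate()` writes the world as plain-text fixtures (OBO,
InterProScan TSV, annotation TSV, embedding TSV, split manifest);
`cmdRun()` (or the `inst/scripts/pfnet` command-line wrapper) drives
build → train → predict → evaluate for a YAML config over multiple
seeds and writes per-seed reports plus a mean ± sd summary.

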