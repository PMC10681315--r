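# hgdrug

Multi-branch hypergraph attention models for drug interaction prediction on
drug-substructure networks.

## The problem

Link prediction in drug-related interaction networks — drug–drug (DDI),
drug–target (DTI), drug–disease (DDiI) and drug–side-effect (DSI) — usually
relies on pairwise edges alone and ignores two sources of signal: the
*chemical substructure* of the drugs, and *high-order relations* ("these two
drugs share a functional group", "these two drugs hit the same target")
that involve more than two nodes. `hgdrug` is for computational biologists
and cheminformaticians who want a desk-scale, fully inspectable
implementation of a hypergraph-learning approach that exploits both.

The pipeline:

1. **Fragmentation.** Every drug SMILES is cleaved recursively at BRICS
   (retrosynthetically interesting) bonds down to indivisible
   functional-group fragments, giving directed drug→fragment (DFI) and
   parent→child fragment (FFI) networks. The chemistry primitives use RDKit
   through a small batch helper; the recursion, canonical merging of
   fragments and edge assembly are implemented in R.
2. **Heterogeneous network.** The typed adjacency matrices — `S` (drug–drug),
   `Y` (drug–fragment), `Z` (fragment–fragment), plus optional `W`/`G`/`V`
   task matrices — are assembled into one drug-centric container.
3. **Motif-driven hypergraphs.** Twelve triangle/quadrilateral motifs
   anchored on two drugs are counted in closed form
   (e.g. `A1 = (SS)∘S`, `A2 = (YYᵀ)∘S`, `A5 = YYᵀ`,
   `A3 = Am + Amᵀ` with `Am = (YZYᵀ)∘S`, …), redundancy between
   drug-related and drug-independent motifs is subtracted
   (`A4 ← A4 − A1`, …), and the four group sums
   `I_j = A1+A2+A3`, `I_p = A4+A5+A6`, `I_i = A7+A8+A9`, `I_u = A10+A11+A12`
   define four drug hypergraphs (row *d* = the drug-*d*-centred hyperedge).
4. **Encoder.** Per branch *x*: a self-gate `D0ˣ = D0 ∘ σ(D0 Pgˣ + Bgˣ)`
   followed by `L` hypergraph-attention layers
   `D_{l+1} = Deg⁻¹ relu( softmax(Iˣ D_l D_lᵀ) D_l · Pmˣ + Bmˣ )`,
   layer-averaged; a per-drug softmax attention fuses the branches; a graph
   convolution over the task matrix `R` interleaves drug and entity updates;
   final scores are inner products `ŝ_{d,i} = d_dᵀ m_i`.
5. **Objective.** Bayesian personalized ranking over sampled `(d, i, j)`
   triples plus a DGI-style self-supervised term (node vs sub-hypergraph vs
   whole-graph summaries against shuffled negatives), `L = L_bpr + λ·L_self`,
   trained with an adaptive-moment optimizer. Gradients come from a small
   reverse-mode tape included in the package.
6. **Evaluation.** k-fold cross-validated AUROC/AUPR against per-fold
   sampled negatives, novel-pair ranking, and cosine drug similarity.

## Worked example

```r
library(hgdrug)

# a planted-partition benchmark network: 60 drugs, 40 entities, 2 blocks
net <- make_planted_network(planted_spec(seed = 1))
net
#> Drug-centric heterogeneous network (task: DTI )
#>   drugs: 60  entities: 40
#>   S: 60 x 60, 510 edges
#>   Y: 60 x 12, 420 edges
#>   Z: 12 x 12, 10 edges
#>   W: 60 x 40, 324 edges

folds <- make_folds(net, k = 5, seed = 1)
fit <- hgdrug(net, fold = folds[[1]],
              control = hgdrug_control(dim = 32, epochs = 100), seed = 1)
fit
#> Hypergraph-attention link prediction model (DTI task)
#>   drugs: 60  entities: 40  dim: 32  layers: 2
#>   variant: full  branches: j,p,i,u
#>   trained 100 epochs; loss 185.0194 -> 141.7953

auroc_aupr(predict(fit, folds[[1]]$test), predict(fit, folds[[1]]$test_neg))
#>     auroc      aupr
#> 0.6930178 0.5999551
```

Per-fold AUROC fluctuates around its mean of ~0.74 across seeds and folds
(this fold draws 0.69). That mean is at the information ceiling of the
generator: with `p_in = 0.25`, within-block pairs are exchangeable, so no
scorer can beat block recovery (see the methods vignette).

Fragmentation on real SMILES:

```r
drugs <- data.frame(drug_id = "aspirin", smiles = "CC(=O)Oc1ccccc1C(=O)O")
recursive_decompose(drugs)
#> BRICS fragmentation: 1 drugs, 9 fragments, 6 DFI edges, 14 FFI edges
```

A command-line interface over the same functions ships in
`inst/cli/hgdrug` with subcommands `simulate`, `decompose`,
`build-hypergraphs`, `train`, `evaluate`, `predict`.

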