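# hetdti

Drug–target interaction (DTI) prediction on a heterogeneous biomedical
network, for computational drug-discovery work: given known interactions
plus drug-, protein-, disease- and side-effect-related networks, rank
the unknown drug–protein pairs most likely to interact.

## The model

`hetdti` implements a graph autoencoder over a network with four node
types (drug, protein, disease, side effect) and eight edge types (six
binary association/interaction networks and two real-valued similarity
networks). The encoder runs one round of edge-type-specific neighborhood
aggregation,

```
a_v^r = (1/|N_r(v)|) Σ_{u ∈ N_r(v)} ReLU(W_r h_u⁰ + b_r)
h_v*  = MEAN({h_v⁰} ∪ {a_v^r : N_r(v) ≠ ∅})
```

followed by random-walk-with-restart (personalized PageRank) propagation
on the similarity-free subnetwork,

```
Z⁰ = H*,   Z^{k+1} = (1−α) A Z^k + α Z⁰   →   α (I − (1−α)A)⁻¹ H*
```

which extends the receptive field to multi-hop neighborhoods without
stacking layers (and without over-smoothing). The decoder is DistMult:
`s(u, r, v) = e_uᵀ M_r e_v` with a diagonal `M_r` per edge type,
reconstructing every network from the embeddings. Training minimizes a
masked squared reconstruction loss with L2 regularization by full-batch
Adam with exact analytic gradients; the drug–target network is masked to
the training pairs (known interactions + sampled negatives at 1:10),
with stratified 0.855/0.045/0.1 train/validation/test splits,
early stopping, and AUROC / average-precision ranking evaluation. A
synthetic-network generator with a planted low-rank signal provides
fully reproducible end-to-end experiments.

See `vignettes/hetdti-methods.Rmd` for the model, the design choices and
their rationale, and known limitations.

## Worked example

Generate a synthetic network, hold out 10% of the interactions, train,
and rank the held-out interactions against sampled non-interactions:

```r
library(hetdti)

sim <- generate_network(synth_config(seed = 42))
print(sim$network)
#> Heterogeneous network: 100 drugs, 150 proteins, 80 diseases, 60 side effects
#>   drug_target      drug x protein  [binary]  300 edges
#>   drug_drug        drug x drug  [binary, symmetric]  296 edges
#>   ...

ho <- hold_out_dti(sim$network, sim$truth, fraction = 0.1, seed = 7)
ctrl <- hetdti_control(dim = 32, learning_rate = 0.02, max_epochs = 300,
                       patience = 50, min_epochs = 100)
fit <- hetdti(ho$network, control = ctrl, sampling_seed = 1)
print(fit)
#> Graph-autoencoder DTI model
#>   network: 100 drug, 150 protein, 80 disease, 60 side_effect
#>   embedding dim 32, alpha 0.1, walk length 10
#>   148 epochs (best epoch 97, validation auprc 0.4451), early-stopped

scores <- predict(fit)           # 100 x 150 matrix of raw DTI scores
held <- ho$held_out
negs <- sample_negatives(sim$network$matrices$drug_target, "all", seed = 1)
set.seed(2); negs <- negs[sample(nrow(negs), 10 * nrow(held)), ]
s <- c(scores[held], scores[negs])
lab <- c(rep(1, nrow(held)), rep(0, nrow(negs)))
cat(sprintf("held-out AUROC %.3f, AUPRC %.3f\n", auroc(s, lab), auprc(s, lab)))
#> held-out AUROC 0.717, AUPRC 0.336
```

The printed AUROC is the probability that a held-out true interaction
outranks a random non-interacting pair; AUPRC is average precision over
the held-out positives (prevalence here is 1/11 ≈ 0.09, so 0.336 is well
above chance). This quick demonstration stops after 148 epochs; the
package's full recovery protocol (`synthetic_recovery()`, a fixed
3000-epoch schedule) reaches held-out AUROC around 0.9 on the default
generator.

Cross-validation experiments, the all-unknown-negatives and
homology-filtered scenarios, and the case-study candidate aggregation
are driven by `run_cv_experiment()`, `build_candidate_tables()` and
`hit_count()`; a command-line driver with `simulate / build-net / train /
predict / evaluate / rank` subcommands is installed at
`inst/cli/hetdti.R`.

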