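---
title: "Methods: a graph autoencoder for drug-target interaction prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a graph autoencoder for drug-target interaction prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem and the data model

Predicting which drugs bind which protein targets is a link-prediction
problem on a heterogeneous biomedical network. The package works on the
standard benchmark layout: four node populations (drugs, proteins,
diseases, side effects) joined by eight edge types — six binary
association/interaction networks (drug–target, drug–drug,
protein–protein, drug–disease, drug–side-effect, protein–disease) and
two real-valued similarity networks in $[0,1]$ (drug chemical-structure
similarity, protein sequence similarity). Nodes live on a fixed global
index: contiguous blocks in the order drug, protein, disease,
side-effect; every embedding matrix in the package uses this order, so
indexing is deterministic across modules.

Matrices are dense whitespace-delimited text files declared by a JSON
manifest (`load_network()` / `write_network()`). Binary matrices must be
exactly $\{0,1\}$-valued; values within $10^{-9}$ of 0 or 1 are snapped,
anything else is an error naming the offending cell. Similarity matrices
must be symmetric with unit diagonal. `validate_network()` reports every
violation as data rather than raising.

## The model

The model is a graph autoencoder trained end to end.

**Encoder, stage 1 — edge-type-specific aggregation.** Each node starts
from a learnable embedding $h_v^0 \in \mathbb{R}^d$ (rows of per-type
projection matrices; equivalently a learned projection of one-hot
codes). For each *directed* edge type $r$, a single-layer network
aggregates the neighborhood:

$$a_v^r = \frac{1}{c_{rv}} \sum_{u \in N_r(v)} w_{uv}\,
  \mathrm{ReLU}(W_r\, h_u^0 + b_r),$$

with $w_{uv} = 1$ and $c_{rv} = |N_r(v)|$ for binary edge types, and
$w_{uv}$ the similarity value with $c_{rv} = \sum_u w_{uv}$ for the two
similarity edge types (a configuration switch,
`similarity_weighting = "binary"`, restores the unweighted mean over
positive-similarity neighbors). A node is never its own neighbor: the
unit diagonal of the similarity matrices is excluded, since the self
term enters through $h_v^0$. The updated embedding is the element-wise
mean

$$h_v^\ast = \mathrm{MEAN}\left(\{h_v^0\} \cup \{a_v^r : N_r(v) \neq
\emptyset\}\right),$$

where edge types with an empty neighborhood at $v$ contribute neither a
term nor a count to the denominator. Cross-node-type edge types carry
separate $(W_r, b_r)$ per direction while same-type edge types share
one pair, so the eight standard edge types yield twelve aggregation
weight matrices; together with the four initialization projections and
the eight decoder diagonals these are the three trainable parameter
groups.

**Encoder, stage 2 — propagation by random walk with restart.**
One aggregation round sees only first-order neighborhoods; stacking
layers instead invites over-smoothing. The package therefore propagates
the aggregated embeddings with personalized PageRank,

$$Z^0 = H^\ast, \qquad Z^{k+1} = (1-\alpha)\, A\, Z^k + \alpha Z^0,$$

whose fixed point is $\alpha (I - (1-\alpha) A)^{-1} H^\ast$. $A$ is the
row-stochastic transition matrix of the *similarity-free* subnetwork:
all binary edge types are merged into one symmetric unweighted
adjacency (each co-occurring pair summed over edge types before
normalization), each row divided by its sum. The two similarity edge
types are dense, so they are deleted before the walk; the graph
convolution still sees them. Nodes with no walk-eligible edge get a
unit self-loop, which preserves their own features exactly under
restart semantics. Row normalization (rather than column) makes each
row of $Z^{k+1}$ a convex combination of rows of $Z^k$ and $Z^0$, so
propagation is a smoother: per-coordinate ranges can only shrink. The
walk runs inside the training graph — gradients flow through all $K$
iterations.

Defaults: $\alpha = 0.1$, $K = 10$ iterations, iterative mode (a direct
solve is available below a 2000-node cap). The reference embedding
dimension is $d = 1000$ with learning rate $0.001$; the synthetic
experiments below use smaller, faster settings.

**Decoder.** DistMult: $s(u, r, v) = e_u^\top M_r e_v$ with a diagonal
$M_r$ per edge type, applied blockwise to reconstruct every network,
e.g. the drug–target block $V_{drug}\, M_{DTI}\, V_{protein}^\top$.
Scores are raw (no sigmoid): the loss below compares them to 0/1
targets directly, and the evaluation metrics are rank-based, so no
calibration layer is added. The diagonal bilinear form is symmetric in
its arguments; for same-type edge types the package symmetrizes the
reconstruction exactly, removing floating-point summation-order noise.
One diagonal is kept per edge type; both directions of a cross-type
relation share it.

**Objective.** The masked squared reconstruction loss

$$\mathcal{L} = \sum_r \sum_{ij} \left(P_r \circ
(X_r - \hat X_r)\right)_{ij}^2 + \lambda \sum_w w^2,$$

where $P_r$ is all-ones for the seven auxiliary networks and, for the
drug–target network, marks exactly the training pairs (positives plus
sampled negatives) of the active split. Validation and test pairs are
never reconstructed against; the tests assert bitwise that masked-out
entries influence neither loss nor gradients.

## Training

There is no automatic differentiation engine in the package's
dependency set, and none is needed: the computation graph is fixed, so
the package ships exact hand-derived reverse-mode gradients
(`R/gradient.R`) — backward through the decoder, a replay of the exact
number of walk iterations the forward pass executed, the mean update,
the ReLU channels (subgradient 0 at the kink), and the L2 term. A
finite-difference test enforces agreement to relative error $10^{-4}$
over every parameter.

Optimization is full-batch Adam ($\beta_1 = 0.9$, $\beta_2 = 0.999$).
The dataset is built by sampling ten negatives per known interaction
uniformly from the zero cells (capped with a warning if fewer exist;
`"all"` converts every unknown pair into a negative), then split
0.855/0.045/0.1 into train/validation/test, positives and negatives
stratified separately. Cross-validation assigns the test share per fold
(test sets partition the dataset) and carves validation from the
remainder at $0.045/0.9$, so ten folds realize the same ratios. After
each epoch the validation metric (average precision by default, suited
to the 10:1 class imbalance) is evaluated; the best-validation snapshot
is kept and training stops after `patience` non-improving epochs. Two
refinements matter in practice and are exposed as control options:

* `min_epochs` — the validation trajectory shows an early transient
  peak followed by a dip before the real signal emerges; a burn-in
  period before early stopping is armed prevents stopping on the
  transient.
* `snapshot = "final"` — on small datasets the 4.5% validation split is
  too small to select a model reliably (a dozen positives); fixed-epoch
  schedules that keep the final parameters behave better there.

Aggregation weights are initialized at one tenth of the Glorot range
(projections at the full range, biases at zero, decoder diagonals from
$\mathcal{N}(0, 0.1^2)$). Starting with near-silent message-passing
branches leaves the early optimization in a well-conditioned
embedding-only regime; the branches grow in as training proceeds. This
measurably improves held-out ranking over full-range initialization. A
step learning-rate decay (`lr_decay_epoch`, factor 0.25) is available
for long schedules.

**Evaluation hygiene.** Beyond the mask, `run_cv_experiment()` and
`synthetic_recovery()` rebuild the drug–target matrix per fold from
training positives only, so held-out edges are also invisible to the
aggregation and the walk — without this, test edges leak through
message passing and ranking results are trivially optimistic
(transductive link-prediction practice). One global seed expands
deterministically into per-purpose seeds (`derive_seed()`): sampling,
folds, initialization, shuffles; reruns are byte-identical.

Scenario variants mirror the standard comparison protocols: "A"
(1:10 sampled negatives), "B" (all unknown pairs negative), and "C",
which first removes positives recoverable from similarity — a positive
$(d, t)$ is dropped when another drug with structure similarity
$> 0.6$ binds $t$, or $d$ binds another protein with sequence
similarity $> 0.4$. The exact removal rule is a package choice (any
similar partner with a shared interaction disqualifies the pair).

## Evaluation

AUROC is computed by the Mann–Whitney rank formula (ties count one
half). AUPRC is average precision — the step-wise integral of precision
over recall at each retrieved positive — not trapezoidal PR
interpolation, which can be anti-conservative under heavy imbalance;
ties are ordered by descending score then original index, so results
are deterministic. Both are checked against exhaustive pair-counting /
step-integration oracles and an independent library implementation.

The case-study procedure aggregates, per drug, the top-$m'$ scored
unknown targets from every (round × fold) score table (known positives
excluded; ties broken by higher score then lower index), counts each
candidate's occurrences across tables, orders candidates by occurrence
count with ties broken by mean within-table rank then index — the
tie-break is a package choice — and counts hits of the per-drug top-$m$
predictions against a verification set.

Per-fold metrics are macro-averaged across folds and rounds; per-fold
values are always retained alongside the summary.

## The synthetic generator

`generate_network()` emulates the benchmark's structure with a planted
low-rank relational signal so that every stage, and end-to-end
recovery, is testable without external data. Latent vectors are drawn
from a spherical Gaussian (scaled to unit expected norm), one diagonal
relation vector per edge type; each binary network thresholds the
planted DistMult scores at the quantile matching its target density
(symmetrized for same-type edge types). Quantile thresholding rather
than Bernoulli-per-edge removes density variance from tests.
Similarity networks are cosine similarities of the latents affinely
rescaled into $[0,1]$ with unit diagonal — they are exact, un-binarized
functions of the latents, as in the real benchmark where similarities
are computed rather than observed.

The noise model is a density-preserving corruption swap: each true edge
is deleted with the configured probability and an equal number of
non-edges are inserted. At the default rate of 0.02 about 2% of edges
are spurious, so the planted signal stays dominant at every density —
a per-cell flip rate would instead make roughly half of all positives
pure noise at 2% density, defeating the generator's purpose.

Default scale: 100 drugs, 150 proteins, 80 diseases, 60 side effects,
latent rank 16, drug–target density 0.02, other association densities
0.03–0.04, noise 0.02. These were chosen once so that end-to-end
training finishes in minutes on one CPU while recovery stays
challenging but feasible. What the generator does *not* emulate:
heavy-tailed degree distributions, biological module structure,
correlated measurement error, or the scale of the real benchmark —
passing the recovery experiment demonstrates correct mechanics and
estimation on idealized data, not real-world accuracy.

`hold_out_dti()` removes a seeded fraction of drug–target positives
from the network (nothing else changes) and records them;
`synthetic_recovery()` trains on the remainder and ranks the held-out
positives against ten unseen sampled negatives each, reporting AUROC,
average precision, and a label-shuffled null averaged over 100
permutations. The recovery configuration is a fixed 3000-epoch
schedule at $d = 32$, learning rate 0.02 stepped down 4× after epoch
1500, final-epoch parameters — problem sizes and schedule are the
package's standard small-scale study conditions. For context, an
unconstrained per-node-embedding DistMult factorization of the same
data attains similar held-out AUROC, indicating the defaults operate
near the information limit of the generator's densities.

## Numerical choices and degenerate inputs

* Transition rows of walk-isolated nodes: unit self-loop (not uniform
  teleport) — preserves the node's features exactly.
* Row-sum tolerance for "row-stochastic": $10^{-12}$ in the invariants,
  $10^{-9}$ on input checking.
* Empty neighborhoods: zero aggregate, excluded from the mean
  denominator; a fully isolated node keeps $h^\ast = h^0$.
* ReLU subgradient at 0 is taken as 0; the gradient test verifies the
  evaluation point is bounded away from the kink.
* Negative sampling with more requested than available zero cells:
  capped with a warning; an all-ones matrix yields an empty negative
  set.
* Divergent training (non-finite loss) aborts with a diagnostic rather
  than returning garbage.
* `max_epochs = 0` returns the initialized parameters unchanged.

## Limitations

The model is transductive: new drugs or targets require retraining, and
isolated nodes unconnected to the training graph cannot be scored
meaningfully. Raw DistMult scores are not probabilities. Full-batch
optimization holds all dense reconstructions in memory, which is
comfortable at benchmark scale but not beyond. The synthetic evidence
supports implementation correctness and small-scale recovery only.
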