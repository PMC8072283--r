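# Fixtures built in code: a tiny synthetic network for fast training
# tests, a three-node network small enough to compose the encoder by
# hand, and random row-stochastic matrices for propagation tests.

tiny_synth_config <- function(seed = 1L, noise = 0) {
  synth_config(
    counts = c(drug = 12L, protein = 15L, disease = 8L, side_effect = 6L),
    d_true = 4L,
    densities = c(drug_target = 0.1, drug_drug = 0.1, protein_protein = 0.1,
                  drug_disease = 0.1, drug_se = 0.1, protein_disease = 0.1),
    noise = noise, seed = seed)
}

tiny_network <- function(seed = 1L, noise = 0) generate_network(tiny_synth_config(seed, noise))

# One drug, one protein, one disease, linked drug-target and drug-disease;
# small enough that aggregation, mean update and the walk can be written
# out by hand.
three_node_network <- function(dti = 1, ddis = 1) {
  space <- node_space(c(drug = 1, protein = 1, disease = 1, side_effect = 1))
  edges <- list(
    drug_target = edge_type_spec("drug_target", "drug", "protein"),
    drug_disease = edge_type_spec("drug_disease", "drug", "disease"))
  mats <- list(drug_target = matrix(dti, 1, 1),
               drug_disease = matrix(ddis, 1, 1))
  # side-effect node is isolated: exercises the empty-neighborhood path
  hetero_network(space, edges, mats)
}

# hand-set parameters for the three-node fixture: given embedding rows,
# identity aggregation weights, zero biases
three_node_params <- function(h_drug, h_prot, h_dis, h_se = c(0, 0),
                              dec = list(drug_target = c(1, 1),
                                         drug_disease = c(1, 1))) {
  d <- length(h_drug)
  agg_keys <- c("drug_target..fwd", "drug_target..rev",
                "drug_disease..fwd", "drug_disease..rev")
  agg <- setNames(lapply(agg_keys, function(k)
    list(W = diag(d), b = rep(0, d))), agg_keys)
  p <- structure(list(
    init = list(drug = matrix(h_drug, 1), protein = matrix(h_prot, 1),
                disease = matrix(h_dis, 1), side_effect = matrix(h_se, 1)),
    agg = agg, dec = dec), class = "model_params")
  attr(p, "embedding_dim") <- d
  p
}

rand_row_stochastic <- function(n) {
  m <- matrix(runif(n * n), n)
  m / rowSums(m)
}

# brute-force ranking oracles, independent of the package implementation
auroc_oracle <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  tot / (length(pos) * length(neg))
}

auprc_oracle <- function(scores, labels) {
  ord <- order(-scores, seq_along(scores))
  lab <- labels[ord]
  hits <- 0; total <- 0
  for (k in seq_along(lab)) {
    if (lab[k] == 1) {
      hits <- hits + 1
      total <- total + hits / k
    }
  }
  total / sum(lab)
}
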