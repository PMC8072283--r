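## Synthetic heterogeneous networks with a planted low-rank relational
## signal, so every stage and end-to-end recovery can be exercised without
## external data.

#' Configuration for the synthetic-network generator
#'
#' Defaults are the package's standard small-scale study conditions: four
#' node populations sized so end-to-end training finishes in minutes on
#' one CPU, a rank-16 planted signal, association densities in the
#' 0.01-0.05 range typical of sparse biomedical association networks, and
#' a 2% edge-flip noise rate.
#'
#' @param counts named node-type counts; default drug 100, protein 150,
#'   disease 80, side_effect 60.
#' @param d_true latent dimension of the planted signal (default 16).
#' @param densities named per-edge-type target densities in `(0, 1)` for
#'   the six binary edge types.
#' @param noise edge flip probability in `[0, 0.5)` (default 0.02).
#' @param diag_scale scale of the planted relation diagonals (default 1).
#' @param seed integer seed (default 1).
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(counts = c(drug = 100L, protein = 150L,
                                    disease = 80L, side_effect = 60L),
                         d_true = 16L,
                         densities = c(drug_target = 0.02, drug_drug = 0.03,
                                       protein_protein = 0.03,
                                       drug_disease = 0.04, drug_se = 0.03,
                                       protein_disease = 0.04),
                         noise = 0.02, diag_scale = 1, seed = 1L) {
  if (any(densities <= 0) || any(densities >= 1))
    fail("densities must lie in (0, 1)")
  if (noise < 0 || noise >= 0.5) fail("noise must lie in [0, 0.5)")
  if (!is_count(d_true)) fail("d_true must be a positive integer")
  structure(list(counts = counts, d_true = as.integer(d_true),
                 densities = densities, noise = noise,
                 diag_scale = diag_scale, seed = as.integer(seed)),
            class = "synth_config")
}

## threshold a continuous score matrix at the exact target density
threshold_at_density <- function(scores, density, same_type) {
  if (same_type) {
    vals <- scores[upper.tri(scores)]
  } else {
    vals <- as.vector(scores)
  }
  k <- max(1L, round(density * length(vals)))
  if (length(unique(vals)) < 2L)
    fail("degenerate planted scores: target density unattainable")
  thr <- sort(vals, decreasing = TRUE)[k]
  m <- (scores >= thr) * 1
  if (same_type) {
    m[lower.tri(m)] <- t(m)[lower.tri(m)]
    diag(m) <- 0
  }
  m
}

## Corrupt a binary matrix while preserving its density: each edge is
## flipped off with probability p and an equal number of non-edges are
## flipped on. At p = 0.02 about 2% of edges are spurious, so the planted
## signal stays dominant at any density.
flip_edges <- function(m, p, same_type) {
  if (p <= 0) return(m)
  if (same_type) {
    ut <- which(upper.tri(m))
    v <- m[ut]
    ones <- ut[v == 1]; zeros <- ut[v == 0]
  } else {
    ones <- which(m == 1); zeros <- which(m == 0)
  }
  k <- stats::rbinom(1, length(ones), p)
  k <- min(k, length(zeros))
  if (k > 0) {
    m[sample(ones, k)] <- 0
    m[sample(zeros, k)] <- 1
  }
  if (same_type) {
    m[lower.tri(m)] <- t(m)[lower.tri(m)]
    diag(m) <- 0
  }
  m
}

#' Generate a synthetic heterogeneous network with planted signal
#'
#' Draws unit-scale latent vectors per node from a fixed spherical
#' Gaussian and a diagonal relation vector per edge type. Each binary
#' network is the planted DistMult score matrix thresholded at the
#' quantile matching its target density (symmetrized for same-type edge
#' types), then perturbed by independent edge flips. The two similarity
#' networks are cosine similarities of the latents affinely rescaled into
#' `[0, 1]` with unit diagonal. Fully reproducible under the config seed.
#'
#' @param cfg a `synth_config`.
#' @return A list with `network` (a validated `hetero_network`) and
#'   `truth` (class `planted_truth`: `latents` per node type, `rel_diag`
#'   per edge type, `scores` pre-noise score matrices, `held_out` pair
#'   matrix, initially empty).
#' @export
generate_network <- function(cfg = synth_config()) {
  stopifnot(inherits(cfg, "synth_config"))
  space <- node_space(cfg$counts)
  edges <- default_edge_types()
  with_seed(cfg$seed, {
    latents <- lapply(space$types, function(t) {
      n <- space$counts[[t]]
      matrix(stats::rnorm(n * cfg$d_true), n) / sqrt(cfg$d_true)
    })
    names(latents) <- space$types
    rel_diag <- lapply(edges, function(e)
      stats::rnorm(cfg$d_true, 0, cfg$diag_scale))

    matrices <- list()
    scores <- list()
    for (nm in names(edges)) {
      e <- edges[[nm]]
      U <- latents[[e$src_type]]
      V <- latents[[e$dst_type]]
      if (e$value_kind == "real_unit_interval") {
        nrm <- sqrt(rowSums(U^2))
        C <- (U / nrm) %*% t(V / sqrt(rowSums(V^2)))
        s <- (C + 1) / 2
        diag(s) <- 1
        s <- (s + t(s)) / 2
        scores[[nm]] <- s
        matrices[[nm]] <- s
      } else {
        S <- (U * rep(rel_diag[[nm]], each = nrow(U))) %*% t(V)
        same <- e$src_type == e$dst_type
        if (same) S <- (S + t(S)) / 2
        scores[[nm]] <- S
        m <- threshold_at_density(S, cfg$densities[[nm]], same)
        matrices[[nm]] <- flip_edges(m, cfg$noise, same)
      }
    }
    net <- hetero_network(space, edges, matrices)
    truth <- structure(list(latents = latents, rel_diag = rel_diag,
                            scores = scores,
                            held_out = matrix(integer(), 0, 2,
                                              dimnames = list(NULL, c("drug", "protein")))),
                       class = "planted_truth")
    list(network = net, truth = truth)
  })
}

#' Hold out a fraction of drug-target interactions
#'
#' Removes a seeded random fraction of the DTI positives from the network
#' (nothing else changes) and records them as held-out positives in the
#' returned truth, enabling recovery experiments where the model must
#' re-rank edges it never saw.
#'
#' @param net a `hetero_network`.
#' @param truth the matching `planted_truth`.
#' @param fraction fraction of positives to remove, in `(0, 1)`.
#' @param seed integer seed.
#' @return A list with `network` (training network), `truth` (held-out
#'   pairs recorded), and `held_out` (two-column matrix of removed
#'   drug/protein indices).
#' @export
hold_out_dti <- function(net, truth, fraction, seed = 1L) {
  if (fraction <= 0 || fraction >= 1) fail("fraction must lie in (0, 1)")
  m <- net$matrices$drug_target
  pos <- which(m == 1, arr.ind = TRUE)
  n_rm <- round(fraction * nrow(pos))
  if (n_rm >= nrow(pos)) fail("holding out %d of %d positives leaves none",
                              n_rm, nrow(pos))
  if (n_rm < 1L) fail("fraction %g removes no positives", fraction)
  sel <- with_seed(seed, sample(nrow(pos), n_rm))
  held <- pos[sel, , drop = FALSE]
  colnames(held) <- c("drug", "protein")
  m[held] <- 0
  net$matrices$drug_target <- m
  truth$held_out <- held
  list(network = net, truth = truth, held_out = held)
}
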