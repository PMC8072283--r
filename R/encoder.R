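## Encoder: learnable initialization, one round of edge-type-specific
## neighborhood aggregation (ReLU single-layer networks + element-wise
## mean), then random-walk-with-restart propagation of the embeddings.

#' Random-walk-with-restart configuration
#'
#' Controls the propagation stage `Z^{k+1} = (1-alpha) A Z^k + alpha Z^0`,
#' whose fixed point is `alpha (I - (1-alpha) A)^{-1} Z^0`. `alpha = 1`
#' disables propagation (the embedding stays at the aggregation output).
#'
#' @param alpha restart probability in `(0, 1]`; default 0.1.
#' @param max_iters maximum number of iterations K; default 10.
#' @param tol stop early when the max absolute update falls below `tol`;
#'   `0` always runs `max_iters` steps. Default 1e-6.
#' @param mode `"iterative"` (default) or `"closed_form"` (direct solve,
#'   only permitted up to `closed_form_cap` nodes).
#' @param closed_form_cap node-count cap for the direct solve.
#' @return An object of class `rwr_config`.
#' @export
rwr_config <- function(alpha = 0.1, max_iters = 10L, tol = 1e-6,
                       mode = c("iterative", "closed_form"),
                       closed_form_cap = 2000L) {
  mode <- match.arg(mode)
  if (!is.numeric(alpha) || alpha <= 0 || alpha > 1)
    fail("alpha must lie in (0, 1]")
  if (!is_count(max_iters)) fail("max_iters must be a positive integer")
  if (tol < 0) fail("tol must be >= 0")
  structure(list(alpha = alpha, max_iters = as.integer(max_iters), tol = tol,
                 mode = mode, closed_form_cap = as.integer(closed_form_cap)),
            class = "rwr_config")
}

## Enumerate the directed aggregation channels. Cross-node-type edge types
## contribute two channels (one per direction) with separate parameters;
## same-type edge types contribute one. With the eight standard edge types
## this yields the 12 edge-type-specific weight matrices of the model.
directed_edge_records <- function(edges) {
  recs <- list()
  for (nm in names(edges)) {
    e <- edges[[nm]]
    if (e$src_type == e$dst_type) {
      recs[[nm]] <- list(key = nm, edge = nm, src_type = e$src_type,
                         dst_type = e$dst_type, transpose = FALSE,
                         similarity = e$value_kind == "real_unit_interval")
    } else {
      kf <- paste0(nm, "..fwd"); kr <- paste0(nm, "..rev")
      recs[[kf]] <- list(key = kf, edge = nm, src_type = e$src_type,
                         dst_type = e$dst_type, transpose = TRUE,
                         similarity = FALSE)
      recs[[kr]] <- list(key = kr, edge = nm, src_type = e$dst_type,
                         dst_type = e$src_type, transpose = FALSE,
                         similarity = FALSE)
    }
  }
  recs
}

## Precompute, per directed channel, the fixed row-normalized neighbor
## operator Ntil (n_dst x n_src) with zero rows for empty neighborhoods,
## plus the per-node count of contributing channels for the mean update.
## These depend only on the network, not on parameters.
build_agg_operators <- function(net, similarity_weighting = c("weighted", "binary")) {
  similarity_weighting <- match.arg(similarity_weighting)
  sp <- net$space
  recs <- directed_edge_records(net$edges)
  ops <- list()
  n_contrib <- rep(1, sp$n)  # the node's own h0 always enters the mean
  for (r in recs) {
    m <- net$matrices[[r$edge]]
    N <- if (r$transpose) t(m) else m
    if (r$similarity) {
      diag(N) <- 0  # a node is not its own neighbor; h0 carries the self term
      if (similarity_weighting == "binary") N <- (N > 0) * 1
    }
    rs <- rowSums(N)
    nonempty <- rs > 0
    Ntil <- N * ifelse(nonempty, 1 / rs, 0)
    dst <- block_index(sp, r$dst_type)
    src <- block_index(sp, r$src_type)
    n_contrib[dst] <- n_contrib[dst] + nonempty
    ops[[r$key]] <- list(key = r$key, edge = r$edge, src = src, dst = dst,
                         Ntil = Ntil, nonempty = nonempty)
  }
  list(ops = ops, n_contrib = n_contrib)
}

#' Initialize model parameters
#'
#' The three trainable parameter groups: per-node-type initialization
#' projections (rows are the initial embeddings of one-hot node codes),
#' per-directed-edge-type aggregation weights `W_r` and biases `b_r`
#' (12 pairs under the eight standard edge types), and per-edge-type
#' diagonal decoder vectors. Initialization projections use a symmetric
#' uniform fan-in/fan-out (Glorot) range; aggregation weights use the same
#' scheme scaled by `agg_init_scale` (default 0.1) so optimization starts
#' near the well-conditioned embedding-only regime and the message-passing
#' branches grow in as training proceeds; biases start at zero; decoder
#' diagonals from small-variance Gaussian noise.
#'
#' @param net a `hetero_network`.
#' @param dim embedding dimension `d` (default 1000).
#' @param seed integer seed governing all draws.
#' @param decoder_sd standard deviation of decoder-diagonal noise.
#' @param agg_init_scale multiplier on the Glorot range of the
#'   aggregation weights.
#' @return An object of class `model_params` with elements `init`, `agg`
#'   (each `$W`, `$b`), `dec`, and attribute `dim`.
#' @export
init_params <- function(net, dim = 1000L, seed = 1L, decoder_sd = 0.1,
                        agg_init_scale = 0.1) {
  sp <- net$space
  d <- as.integer(dim)
  recs <- directed_edge_records(net$edges)
  with_seed(seed, {
    init <- lapply(sp$types, function(t) {
      n <- sp$counts[[t]]
      lim <- sqrt(6 / (n + d))
      matrix(stats::runif(n * d, -lim, lim), n, d)
    })
    names(init) <- sp$types
    agg <- lapply(recs, function(r) {
      lim <- agg_init_scale * sqrt(6 / (2 * d))
      list(W = matrix(stats::runif(d * d, -lim, lim), d, d),
           b = rep(0, d))
    })
    dec <- lapply(net$edges, function(e) stats::rnorm(d, 0, decoder_sd))
    params <- structure(list(init = init, agg = agg, dec = dec),
                        class = "model_params")
    attr(params, "embedding_dim") <- d
    params
  })
}

#' Initial embedding matrix H0
#'
#' Vertical concatenation of the per-node-type initialization blocks in
#' global order; equivalent to projecting one-hot node codes through the
#' learnable projections.
#'
#' @param params a `model_params`.
#' @param space a `node_space`.
#' @return A `space$n x d` matrix.
#' @export
init_embeddings <- function(params, space) {
  d <- attr(params, "embedding_dim")
  for (t in space$types) {
    blk <- params$init[[t]]
    if (!is.matrix(blk) || nrow(blk) != space$counts[[t]] || ncol(blk) != d)
      fail("init block '%s' has shape %s, expected %dx%d", t,
           paste(dim(blk), collapse = "x"), space$counts[[t]], d)
  }
  do.call(rbind, params$init[space$types])
}

#' Aggregate neighborhood information for one directed edge type
#'
#' For each destination node `v`, computes the normalized sum
#' `a_v = (1/c_v) sum_u w_uv relu(W h_u + b)` over neighbors `u`, where
#' `w_uv` are the adjacency weights (1 for binary edges, the similarity
#' value for similarity edges) and `c_v` their sum (`|N(v)|` in the binary
#' case). Nodes with empty neighborhoods get the zero vector.
#'
#' @param h embedding matrix of source nodes (`n_src x d`).
#' @param adjacency nonnegative weight matrix, `adjacency[v, u]` = weight
#'   of source node `u` as a neighbor of destination `v` (`n_dst x n_src`).
#' @param W `d x d` weight matrix.
#' @param b length-`d` bias vector.
#' @return `n_dst x d` matrix of aggregated vectors.
#' @export
aggregate_neighbors <- function(h, adjacency, W, b) {
  if (any(adjacency < 0)) fail("adjacency must be nonnegative")
  if (!all(is.finite(W)) || !all(is.finite(b)))
    fail("non-finite aggregation parameters")
  phi <- pmax(h %*% t(W) + rep(b, each = nrow(h)), 0)
  rs <- rowSums(adjacency)
  Ntil <- adjacency * ifelse(rs > 0, 1 / rs, 0)
  Ntil %*% phi
}

#' Mean update of node embeddings
#'
#' `h_v*` is the element-wise mean of the node's own `h_v0` and the
#' aggregated vectors of every directed edge type incident to its node
#' type with a non-empty neighborhood; edge types with no neighbors of
#' `v` are excluded from the denominator.
#'
#' @param h0 global `n x d` initial embedding matrix.
#' @param aggregates list with, per channel, elements `values`
#'   (`n_dst x d`), `dst` (global row indices) and `nonempty`
#'   (logical per destination node).
#' @return `n x d` matrix of updated embeddings.
#' @export
update_embeddings <- function(h0, aggregates) {
  acc <- h0
  cnt <- rep(1, nrow(h0))
  for (a in aggregates) {
    keep <- a$nonempty
    acc[a$dst[keep], ] <- acc[a$dst[keep], , drop = FALSE] +
      a$values[keep, , drop = FALSE]
    cnt[a$dst] <- cnt[a$dst] + keep
  }
  acc / cnt
}

#' Propagate embeddings by random walk with restart
#'
#' Iterative mode runs `Z^{k+1} = (1-alpha) A Z^k + alpha Z^0` from
#' `Z^0 = hstar`, stopping at `max_iters` or when the largest absolute
#' update falls below `tol`. Closed-form mode solves
#' `alpha (I - (1-alpha) A)^{-1} hstar` directly.
#'
#' @param hstar `n x d` embedding matrix after aggregation.
#' @param A row-stochastic transition matrix (dense or `Matrix` sparse).
#' @param cfg an `rwr_config`.
#' @return `n x d` propagated embedding matrix.
#' @export
rwr_propagate <- function(hstar, A, cfg = rwr_config()) {
  stopifnot(inherits(cfg, "rwr_config"))
  check_row_stochastic(A)
  if (cfg$mode == "closed_form") {
    n <- nrow(hstar)
    if (n > cfg$closed_form_cap)
      fail("closed-form propagation requested for %d nodes (cap %d)",
           n, cfg$closed_form_cap)
    M <- diag(n) - (1 - cfg$alpha) * as.matrix(A)
    return(cfg$alpha * solve(M, hstar))
  }
  rwr_iterate(hstar, A, cfg)$Z
}

check_row_stochastic <- function(A, tol = 1e-9) {
  rs <- if (inherits(A, "Matrix")) Matrix::rowSums(A) else rowSums(A)
  if (max(abs(rs - 1)) > tol)
    fail("transition matrix is not row-stochastic (max row-sum error %g)",
         max(abs(rs - 1)))
  invisible(TRUE)
}

## iterative RWR, returning the result and the iteration count actually
## executed (the backward pass replays exactly that many steps)
rwr_iterate <- function(hstar, A, cfg) {
  Z <- hstar
  k <- 0L
  while (k < cfg$max_iters) {
    Znew <- as.matrix((1 - cfg$alpha) * (A %*% Z)) + cfg$alpha * hstar
    k <- k + 1L
    delta <- max(abs(Znew - Z))
    Z <- Znew
    if (cfg$tol > 0 && delta < cfg$tol) break
  }
  list(Z = Z, iters = k)
}

## Full encoder forward pass with optional cache of the intermediates the
## backward pass needs.
encode_forward <- function(net, params, cfg = rwr_config(), operators = NULL,
                           A = NULL, keep = FALSE) {
  if (is.null(operators)) operators <- build_agg_operators(net)
  if (is.null(A) && cfg$alpha < 1) A <- build_transition_matrix(net)
  sp <- net$space
  h0 <- init_embeddings(params, sp)
  phis <- list()
  aggregates <- list()
  for (op in operators$ops) {
    p <- params$agg[[op$key]]
    pre <- h0[op$src, , drop = FALSE] %*% t(p$W) + rep(p$b, each = length(op$src))
    phi <- pmax(pre, 0)
    aggregates[[op$key]] <- list(values = op$Ntil %*% phi, dst = op$dst,
                                 nonempty = op$nonempty)
    if (keep) phis[[op$key]] <- phi
  }
  hstar <- update_embeddings(h0, aggregates)
  it <- if (cfg$alpha == 1) list(Z = hstar, iters = 0L)
        else if (cfg$mode == "closed_form")
          list(Z = rwr_propagate(hstar, A, cfg), iters = NA_integer_)
        else rwr_iterate(hstar, A, cfg)
  out <- list(h0 = h0, hstar = hstar, h1 = it$Z, iters = it$iters,
              operators = operators, A = A)
  if (keep) out$phis <- phis
  out
}

#' Encode a heterogeneous network into node embeddings
#'
#' Composition of the full encoder: initialization projection, one round
#' of per-edge-type ReLU aggregation with element-wise mean update, then
#' random-walk-with-restart propagation. Deterministic given parameters
#' and configuration; `alpha = 1` reduces to the aggregation-only
#' embedding.
#'
#' @param net a `hetero_network`.
#' @param params a `model_params` shaped for `net`.
#' @param cfg an `rwr_config`.
#' @param similarity_weighting `"weighted"` (similarity-weighted mean,
#'   default) or `"binary"` (unweighted mean over positive-similarity
#'   neighbors).
#' @return `n x d` matrix of propagated node embeddings, rows in global
#'   node order.
#' @export
encode <- function(net, params, cfg = rwr_config(),
                   similarity_weighting = "weighted") {
  ops <- build_agg_operators(net, similarity_weighting)
  encode_forward(net, params, cfg, operators = ops)$h1
}
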