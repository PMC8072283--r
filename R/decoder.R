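## Decoder: DistMult bilinear-diagonal scoring and reconstruction of each
## edge-type network from the propagated node embeddings.

#' DistMult score of one node pair under one relation
#'
#' `s(u, r, v) = e_u' M_r e_v` with diagonal relation matrix `M_r`, i.e.
#' `sum_i e_u[i] * diag_r[i] * e_v[i]`. Symmetric in `u` and `v`.
#'
#' @param e_u,e_v embedding vectors.
#' @param diag_r diagonal of the relation matrix, same length.
#' @return A single numeric score.
#' @examples
#' distmult_score(c(1, 2), c(3, -1), c(2, 1))  # 6 - 2 = 4
#' @export
distmult_score <- function(e_u, diag_r, e_v) {
  if (length(e_u) != length(diag_r) || length(e_v) != length(diag_r))
    fail("distmult_score: length mismatch (%d, %d, %d)",
         length(e_u), length(diag_r), length(e_v))
  sum(e_u * diag_r * e_v)
}

#' Reconstruct one edge-type network from embeddings
#'
#' Computes the full score matrix `V_src diag(M_r) V_dst'` from the
#' node-type blocks of the propagated embedding matrix; entry `(i, j)`
#' equals [distmult_score()] of the corresponding embedding rows.
#'
#' @param h1 global `n x d` embedding matrix (rows in global node order).
#' @param params a `model_params` holding the decoder diagonals.
#' @param net the `hetero_network` the embeddings belong to.
#' @param edge_type name of the edge type to reconstruct.
#' @return An object of class `score_table`: list with `edge_type`,
#'   `scores` (`n_src x n_dst` matrix).
#' @export
reconstruct_network <- function(h1, params, net, edge_type) {
  e <- net$edges[[edge_type]]
  if (is.null(e)) fail("unknown edge type '%s'", edge_type)
  diag_r <- params$dec[[edge_type]]
  if (is.null(diag_r)) fail("no decoder diagonal for edge type '%s'", edge_type)
  U <- h1[block_index(net$space, e$src_type), , drop = FALSE]
  V <- h1[block_index(net$space, e$dst_type), , drop = FALSE]
  scores <- (U * rep(diag_r, each = nrow(U))) %*% t(V)
  ## the diagonal bilinear form is symmetric in its arguments; enforce the
  ## identity exactly against floating-point summation-order noise
  if (e$src_type == e$dst_type) scores <- (scores + t(scores)) / 2
  structure(list(edge_type = edge_type, scores = scores),
            class = "score_table")
}

#' @export
print.score_table <- function(x, ...) {
  cat(sprintf("DistMult score table '%s': %d x %d, range [%.4g, %.4g]\n",
              x$edge_type, nrow(x$scores), ncol(x$scores),
              min(x$scores), max(x$scores)))
  invisible(x)
}

#' Predict drug-target interaction scores
#'
#' Runs the full encoder on the network and reconstructs the drug-target
#' edge type, yielding a drugs x targets matrix of raw interaction scores
#' (higher = more likely to interact). Deterministic given inputs.
#'
#' @param net a `hetero_network`.
#' @param params trained or initialized `model_params`.
#' @param cfg an `rwr_config`.
#' @param edge_type edge type to score (default `"drug_target"`).
#' @return A `score_table` for the requested edge type.
#' @export
predict_dti <- function(net, params, cfg = rwr_config(),
                        edge_type = "drug_target") {
  h1 <- encode(net, params, cfg)
  reconstruct_network(h1, params, net, edge_type)
}
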