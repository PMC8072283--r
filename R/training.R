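## Dataset construction for training: negative sampling, stratified
## train/validation/test splits and cross-validation folds, training
## masks, and the homology filter of the hard evaluation scenario.

#' Sample negative drug-target pairs
#'
#' Draws `ratio` negatives per positive uniformly without replacement from
#' the zero entries of the interaction matrix, the standard 1:10 sampling
#' regime by default. `ratio = "all"` turns every zero entry into a
#' negative (the all-unknown-negatives scenario). When fewer zeros exist
#' than requested, all of them are returned with a warning.
#'
#' @param dti_matrix binary drug x target matrix.
#' @param ratio positive integer, or `"all"`.
#' @param seed integer seed.
#' @return Two-column integer matrix (`drug`, `protein`) of sampled
#'   negative pairs.
#' @export
sample_negatives <- function(dti_matrix, ratio = 10L, seed = 1L) {
  zeros <- which(dti_matrix == 0, arr.ind = TRUE)
  colnames(zeros) <- c("drug", "protein")
  if (identical(ratio, "all")) return(zeros)
  if (!is_count(ratio)) fail("ratio must be a positive integer or 'all'")
  n_pos <- sum(dti_matrix == 1)
  want <- ratio * n_pos
  if (want > nrow(zeros)) {
    warning(sprintf("requested %d negatives but only %d zero entries; capping",
                    want, nrow(zeros)))
    want <- nrow(zeros)
  }
  if (want == 0L)
    return(zeros[integer(0), , drop = FALSE])
  sel <- with_seed(seed, sample(nrow(zeros), want))
  zeros[sel, , drop = FALSE]
}

pair_df <- function(pairs, label) {
  data.frame(drug = as.integer(pairs[, 1]), protein = as.integer(pairs[, 2]),
              label = rep(label, nrow(pairs)))
}

## deal indices of one class into train/val/test by ratios (single split)
deal_one_class <- function(n, ratios) {
  idx <- sample(n)
  n_test <- round(ratios[3] * n)
  n_val <- round(ratios[2] * n)
  held <- n_test + n_val
  list(test = idx[seq_len(n_test)],
       val = idx[n_test + seq_len(n_val)],
       train = if (held > 0) idx[-seq_len(held)] else idx)
}

#' Build a single stratified train/validation/test split
#'
#' Positives and negatives are split separately (stratification), so each
#' part keeps the global class ratio up to rounding.
#'
#' @param positives,negatives two-column (drug, protein) index matrices.
#' @param ratios train/validation/test proportions summing to 1; default
#'   `c(0.855, 0.045, 0.1)`.
#' @param seed integer seed.
#' @return A `dti_split`: list with data frames `train`, `val`, `test`
#'   (columns drug, protein, label), plus `fold`, `seed`.
#' @export
make_split <- function(positives, negatives, ratios = c(0.855, 0.045, 0.1),
                       seed = 1L) {
  if (abs(sum(ratios) - 1) > 1e-8) fail("ratios must sum to 1")
  with_seed(seed, {
    p <- deal_one_class(nrow(positives), ratios)
    n <- deal_one_class(nrow(negatives), ratios)
    structure(list(
      fold = 1L,
      train = rbind(pair_df(positives[p$train, , drop = FALSE], 1L),
                    pair_df(negatives[n$train, , drop = FALSE], 0L)),
      val   = rbind(pair_df(positives[p$val, , drop = FALSE], 1L),
                    pair_df(negatives[n$val, , drop = FALSE], 0L)),
      test  = rbind(pair_df(positives[p$test, , drop = FALSE], 1L),
                    pair_df(negatives[n$test, , drop = FALSE], 0L)),
      seed = seed), class = "dti_split")
  })
}

#' Build stratified cross-validation folds
#'
#' The k test sets partition the sampled dataset; within each fold the
#' validation part is carved from the non-test portion at
#' `ratios[2] / (ratios[1] + ratios[2])`, so with the default ratios and
#' k = 10 each fold realizes the 0.855/0.045/0.1 division. Positives and
#' negatives are assigned independently (stratification). Deterministic
#' under `seed`.
#'
#' @inheritParams make_split
#' @param k number of folds (>= 2).
#' @return List of `k` `dti_split` objects.
#' @export
make_folds <- function(positives, negatives, k = 10L,
                       ratios = c(0.855, 0.045, 0.1), seed = 1L) {
  if (!is_count(k) || k < 2) fail("k must be an integer >= 2")
  if (abs(sum(ratios) - 1) > 1e-8) fail("ratios must sum to 1")
  n_pos <- nrow(positives); n_neg <- nrow(negatives)
  if (n_pos < k || n_neg < k)
    fail("too few samples to stratify %d folds (%d positives, %d negatives)",
         k, n_pos, n_neg)
  val_frac <- ratios[2] / (ratios[1] + ratios[2])
  with_seed(seed, {
    fold_pos <- sample(rep(seq_len(k), length.out = n_pos))
    fold_neg <- sample(rep(seq_len(k), length.out = n_neg))
    lapply(seq_len(k), function(f) {
      carve <- function(pairs, fold_of) {
        test_i <- which(fold_of == f)
        rest <- which(fold_of != f)
        rest <- rest[sample(length(rest))]
        n_val <- round(val_frac * length(rest))
        train_i <- if (n_val > 0) rest[-seq_len(n_val)] else rest
        list(test = pairs[test_i, , drop = FALSE],
             val = pairs[rest[seq_len(n_val)], , drop = FALSE],
             train = pairs[train_i, , drop = FALSE])
      }
      p <- carve(positives, fold_pos)
      n <- carve(negatives, fold_neg)
      structure(list(
        fold = f,
        train = rbind(pair_df(p$train, 1L), pair_df(n$train, 0L)),
        val   = rbind(pair_df(p$val, 1L), pair_df(n$val, 0L)),
        test  = rbind(pair_df(p$test, 1L), pair_df(n$test, 0L)),
        seed = seed), class = "dti_split")
    })
  })
}

#' @export
print.dti_split <- function(x, ...) {
  f <- function(d) sprintf("%d (%d+/%d-)", nrow(d), sum(d$label == 1),
                           sum(d$label == 0))
  cat(sprintf("DTI split (fold %d): train %s, val %s, test %s\n",
              x$fold, f(x$train), f(x$val), f(x$test)))
  invisible(x)
}

#' Build per-edge-type training masks
#'
#' The drug-target mask marks exactly the training pairs of the split
#' (positives and sampled negatives); every other edge type is fully
#' observed, represented as `NULL` (all-ones). Validation and test pairs
#' are never reconstructed against.
#'
#' @param net a `hetero_network`.
#' @param split a `dti_split`.
#' @return Named list of masks aligned with `net$edges`.
#' @export
build_masks <- function(net, split) {
  dti <- net$matrices$drug_target
  P <- matrix(0, nrow(dti), ncol(dti))
  P[cbind(split$train$drug, split$train$protein)] <- 1
  masks <- vector("list", length(net$edges))
  names(masks) <- names(net$edges)
  masks$drug_target <- P
  masks
}

#' Remove interactions recoverable from drug or protein similarity
#'
#' The homology-filtered evaluation scenario: a positive pair `(d, t)` is
#' removed when another drug `d'` with structure similarity
#' `> drug_threshold` is already known to bind `t`, or another protein
#' `t'` with sequence similarity `> protein_threshold` is already a known
#' target of `d`.
#'
#' @param net a `hetero_network` with `drug_sim` / `protein_sim` matrices.
#' @param positives two-column (drug, protein) matrix of positive pairs.
#' @param drug_threshold similarity cutoff for drugs (default 0.6).
#' @param protein_threshold similarity cutoff for proteins (default 0.4).
#' @return The filtered two-column positives matrix.
#' @export
filter_homologous <- function(net, positives, drug_threshold = 0.6,
                              protein_threshold = 0.4) {
  M <- net$matrices$drug_target
  Dsim <- net$matrices$drug_sim > drug_threshold
  Psim <- net$matrices$protein_sim > protein_threshold
  diag(Dsim) <- FALSE
  diag(Psim) <- FALSE
  ## similar_drug_has[d, t]: some other drug similar to d interacts with t
  similar_drug_has <- (Dsim %*% M) > 0
  similar_prot_has <- (M %*% Psim) > 0
  flagged <- similar_drug_has[positives] | similar_prot_has[positives]
  positives[!flagged, , drop = FALSE]
}
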