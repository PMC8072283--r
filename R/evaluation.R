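## Ranking evaluation: AUROC (Mann-Whitney), AUPRC (average precision),
## and the case-study procedure of aggregating per-drug top-m' candidate
## lists across cross-validation tables and counting hits against a set
## of newly approved interactions.

#' Area under the ROC curve
#'
#' The probability that a uniformly random positive outscores a uniformly
#' random negative, with ties counted 1/2 (Mann-Whitney convention).
#'
#' @param scores numeric scores.
#' @param labels binary labels (0/1), same length.
#' @return AUROC in `[0, 1]`.
#' @examples
#' auroc(c(0.9, 0.8, 0.7, 0.1), c(1, 0, 1, 0))  # 0.75
#' @export
auroc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  labels <- as.integer(labels)
  n_pos <- sum(labels == 1); n_neg <- sum(labels == 0)
  if (n_pos == 0L || n_neg == 0L)
    fail("auroc requires both classes (got %d positives, %d negatives)",
         n_pos, n_neg)
  r <- rank(scores)
  (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Area under the precision-recall curve (average precision)
#'
#' Step-wise integral of precision over recall: the mean, over positives,
#' of the precision at the rank where each positive is retrieved. Ties are
#' resolved deterministically by descending score then original index.
#'
#' @inheritParams auroc
#' @return Average precision in `(0, 1]`.
#' @examples
#' auprc(c(0.9, 0.8, 0.7, 0.1), c(1, 0, 1, 0))  # 5/6
#' @export
auprc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  labels <- as.integer(labels)
  n_pos <- sum(labels == 1)
  if (n_pos == 0L) fail("auprc requires at least one positive")
  ord <- order(-scores, seq_along(scores))
  lab <- labels[ord]
  cum_pos <- cumsum(lab)
  prec_at_pos <- (cum_pos / seq_along(lab))[lab == 1]
  mean(prec_at_pos)
}

#' Evaluate a score matrix on the test pairs of a split
#'
#' @param scores drug x target score matrix.
#' @param split a `dti_split`.
#' @param part which pair list to evaluate (default `"test"`).
#' @return A one-row data frame with `auroc`, `auprc`, `n_pos`, `n_neg`.
#' @export
evaluate_split <- function(scores, split, part = "test") {
  d <- split[[part]]
  s <- scores[cbind(d$drug, d$protein)]
  data.frame(auroc = auroc(s, d$label), auprc = auprc(s, d$label),
             n_pos = sum(d$label == 1), n_neg = sum(d$label == 0))
}

#' Build per-drug candidate tables from cross-validation score tables
#'
#' For every score table (one per round x fold) and every drug, records
#' the `m_prime` highest-scoring targets that are not already known
#' interactions, with deterministic tie-breaking (higher score, then lower
#' target index), then aggregates occurrence counts and mean within-table
#' ranks of each candidate across all tables.
#'
#' @param score_tables list of drug x target score matrices.
#' @param known_dti binary drug x target matrix of known interactions.
#' @param m_prime list length per drug and table (default 40).
#' @return An object of class `candidate_tables`: `tables` (list of
#'   drug x m_prime target-index matrices), `aggregate` (per drug, a data
#'   frame of candidate target, occurrence count, mean rank, ordered by
#'   the case-study rule), `m_prime`.
#' @export
build_candidate_tables <- function(score_tables, known_dti, m_prime = 40L) {
  if (!is_count(m_prime)) fail("m_prime must be a positive integer")
  n_drug <- nrow(known_dti); n_prot <- ncol(known_dti)
  n_unknown <- rowSums(known_dti == 0)
  if (any(n_unknown < m_prime))
    warning(sprintf("%d drugs have fewer than %d unknown targets; truncating",
                    sum(n_unknown < m_prime), m_prime))
  tables <- lapply(score_tables, function(S) {
    if (!all(dim(S) == dim(known_dti)))
      fail("score table shape %s does not match known DTI matrix",
           paste(dim(S), collapse = "x"))
    t(vapply(seq_len(n_drug), function(i) {
      cand <- which(known_dti[i, ] == 0)
      ord <- cand[order(-S[i, cand], cand)]
      out <- rep(NA_integer_, m_prime)
      out[seq_len(min(m_prime, length(ord)))] <-
        ord[seq_len(min(m_prime, length(ord)))]
      out
    }, integer(m_prime)))
  })
  aggregate <- lapply(seq_len(n_drug), function(i) {
    targ <- unlist(lapply(tables, function(tb) tb[i, ]))
    rnk <- rep(seq_len(m_prime), times = length(tables))
    keep <- !is.na(targ)
    targ <- targ[keep]; rnk <- rnk[keep]
    if (length(targ) == 0L)
      return(data.frame(target = integer(), count = integer(),
                        mean_rank = numeric()))
    counts <- tapply(rnk, targ, length)
    mrank <- tapply(rnk, targ, mean)
    df <- data.frame(target = as.integer(names(counts)),
                     count = as.integer(counts),
                     mean_rank = as.numeric(mrank))
    df[order(-df$count, df$mean_rank, df$target), , drop = FALSE]
  })
  structure(list(tables = tables, aggregate = aggregate, m_prime = m_prime,
                 n_drug = n_drug, n_protein = n_prot),
            class = "candidate_tables")
}

#' Count verified hits among the top-m aggregated predictions
#'
#' For each drug, candidate targets are ordered by occurrence count
#' (descending), ties broken by mean within-table rank then target index;
#' the top `m` form the prediction set. Returns the number of predicted
#' pairs present in the verification set.
#'
#' @param candidates a `candidate_tables` object.
#' @param new_dti_set two-column (drug, target) matrix of newly verified
#'   interactions.
#' @param m predictions retained per drug.
#' @return Integer hit count.
#' @export
hit_count <- function(candidates, new_dti_set, m) {
  stopifnot(inherits(candidates, "candidate_tables"))
  if (!is_count(m)) fail("m must be a positive integer")
  if (NROW(new_dti_set) == 0L) return(0L)
  new_dti_set <- as.matrix(new_dti_set)[, 1:2, drop = FALSE]
  new_key <- paste(new_dti_set[, 1], new_dti_set[, 2])
  hits <- 0L
  for (i in seq_len(candidates$n_drug)) {
    agg <- candidates$aggregate[[i]]
    if (nrow(agg) == 0L) next
    top <- agg$target[seq_len(min(m, nrow(agg)))]
    hits <- hits + sum(paste(i, top) %in% new_key)
  }
  hits
}
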