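## Experiment orchestration: rounds x folds cross-validation and the
## synthetic planted-signal recovery experiment.

dti_positive_pairs <- function(net) {
  p <- which(net$matrices$drug_target == 1, arr.ind = TRUE)
  colnames(p) <- c("drug", "protein")
  p
}

## network whose drug-target matrix contains only the given positive pairs;
## validation/test edges are removed from the adjacency the encoder and the
## walk see, so held-out links cannot leak through message passing
mask_network_dti <- function(net, train_pairs) {
  m <- net$matrices$drug_target
  m[] <- 0
  m[as.matrix(train_pairs)] <- 1
  net$matrices$drug_target <- m
  net
}

#' Run a rounds x folds cross-validation experiment
#'
#' For each round, negatives are sampled once (so folds partition a fixed
#' dataset), stratified folds are built, and per fold the model is trained
#' on a network containing only that fold's training interactions, scored,
#' and evaluated on the test pairs. Scenario `"A"` samples
#' `control$negative_ratio` negatives per positive, `"B"` treats every
#' unknown pair as a negative, and `"C"` additionally removes positives
#' recoverable from drug similarity > 0.6 or protein similarity > 0.4
#' before sampling.
#'
#' @param net a `hetero_network`.
#' @param rounds number of cross-validation rounds (default 3).
#' @param folds folds per round (default 10).
#' @param control a [hetdti_control()].
#' @param scenario `"A"`, `"B"` or `"C"`.
#' @param seed global seed; expanded deterministically into per-purpose
#'   seeds for sampling, folds and initialization.
#' @param out_dir optional directory; when given, writes `metrics.tsv`
#'   (per-fold rows), `summary.tsv` (macro average), `config.json` and
#'   keeps per-fold score tables out of memory.
#' @param keep_scores keep the per-fold test-score tables in the result
#'   (needed for [build_candidate_tables()]).
#' @return A list with `metrics` (data frame: round, fold, auroc, auprc,
#'   n_pos, n_neg, best_epoch), `summary` (macro-averaged metrics), and
#'   optionally `score_tables`.
#' @export
run_cv_experiment <- function(net, rounds = 3L, folds = 10L,
                              control = hetdti_control(), scenario = "A",
                              seed = 1L, out_dir = NULL,
                              keep_scores = FALSE) {
  scenario <- match.arg(scenario, c("A", "B", "C"))
  positives <- dti_positive_pairs(net)
  if (scenario == "C") positives <- filter_homologous(net, positives)
  rows <- list()
  score_tables <- list()
  for (r in seq_len(rounds)) {
    ratio <- if (scenario == "B") "all" else control$negative_ratio
    negatives <- sample_negatives(net$matrices$drug_target, ratio,
                                  derive_seed(seed, "negatives", r))
    fold_list <- make_folds(positives, negatives, k = folds,
                            seed = derive_seed(seed, "folds", r))
    for (f in seq_len(folds)) {
      split <- fold_list[[f]]
      ctrl <- control
      ctrl$init_seed <- derive_seed(seed, "init", r * 1000L + f)
      net_f <- mask_network_dti(net,
                                split$train[split$train$label == 1, 1:2])
      fit <- hetdti(net_f, split, ctrl)
      scores <- predict(fit)
      met <- evaluate_split(scores, split)
      rows[[length(rows) + 1L]] <-
        cbind(data.frame(round = r, fold = f), met,
              data.frame(best_epoch = fit$best_epoch))
      if (keep_scores)
        score_tables[[sprintf("r%d_f%d", r, f)]] <- scores
    }
  }
  metrics <- do.call(rbind, rows)
  summary <- data.frame(
    rounds = rounds, folds = folds, scenario = scenario,
    auroc_mean = mean(metrics$auroc), auroc_sd = stats::sd(metrics$auroc),
    auprc_mean = mean(metrics$auprc), auprc_sd = stats::sd(metrics$auprc))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(metrics, file.path(out_dir, "metrics.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(summary, file.path(out_dir, "summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    cfg <- c(control[setdiff(names(control), "verbose")],
             list(rounds = rounds, folds = folds, scenario = scenario,
                  seed = seed))
    jsonlite::write_json(cfg, file.path(out_dir, "config.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  out <- list(metrics = metrics, summary = summary)
  if (keep_scores) out$score_tables <- score_tables
  out
}

#' Synthetic planted-signal recovery experiment
#'
#' Generates a synthetic heterogeneous network with a planted low-rank
#' relational signal, removes a fraction of the drug-target interactions,
#' trains the model on the remaining network, and measures how well the
#' held-out interactions are re-ranked against sampled unseen negatives
#' (1:`eval_neg_ratio`). A label-shuffled AUROC is reported as a null
#' control.
#'
#' @param seed global seed for generation, hold-out, sampling, shuffling
#'   and initialization.
#' @param synth a [synth_config()]; its seed is overridden from `seed`.
#' @param control a [hetdti_control()]; the default small-scale training
#'   configuration is a fixed 3000-epoch schedule at dim 32, learning rate
#'   0.02 stepped down 4x after epoch 1500, final-epoch parameters, with
#'   the standard restart probability 0.1 and 10 walk iterations (the
#'   validation split is too small here for snapshot selection).
#' @param holdout_fraction fraction of DTI positives held out (default 0.1).
#' @param eval_neg_ratio evaluation negatives per held-out positive
#'   (default 10).
#' @param n_shuffles label permutations averaged for the null control
#'   (default 100).
#' @return A list: `auroc`, `auprc`, `auroc_shuffled` (mean over the
#'   permutations), `n_pos`, `n_neg`, `best_epoch`, `epochs`.
#' @export
synthetic_recovery <- function(seed = 1L, synth = synth_config(),
                               control = hetdti_control(
                                 dim = 32L, learning_rate = 0.02,
                                 max_epochs = 3000L, patience = 3000L,
                                 lr_decay_epoch = 1500L,
                                 snapshot = "final"),
                               holdout_fraction = 0.1,
                               eval_neg_ratio = 10L, n_shuffles = 100L) {
  synth$seed <- derive_seed(seed, "synth")
  sim <- generate_network(synth)
  full_dti <- sim$network$matrices$drug_target
  ho <- hold_out_dti(sim$network, sim$truth, holdout_fraction,
                     derive_seed(seed, "holdout"))
  net <- ho$network

  positives <- dti_positive_pairs(net)
  ## negatives must avoid the held-out positives: sample from cells that
  ## are zero in the pre-hold-out matrix
  negatives <- sample_negatives(full_dti, control$negative_ratio,
                                derive_seed(seed, "negatives"))
  split <- make_split(positives, negatives,
                      seed = derive_seed(seed, "split"))
  ctrl <- control
  ctrl$init_seed <- derive_seed(seed, "init")
  fit <- hetdti(net, split, ctrl)
  scores <- predict(fit)

  ## evaluation set: held-out positives vs unseen sampled negatives
  held <- ho$held_out
  n_eval_neg <- eval_neg_ratio * nrow(held)
  zero_cells <- which(full_dti == 0, arr.ind = TRUE)
  used <- paste(c(split$train$drug, split$val$drug, split$test$drug),
                c(split$train$protein, split$val$protein, split$test$protein))
  avail <- zero_cells[!(paste(zero_cells[, 1], zero_cells[, 2]) %in% used), ,
                      drop = FALSE]
  n_eval_neg <- min(n_eval_neg, nrow(avail))
  neg_eval <- avail[with_seed(derive_seed(seed, "eval_negatives"),
                              sample(nrow(avail), n_eval_neg)), , drop = FALSE]
  s <- c(scores[held], scores[neg_eval])
  lab <- c(rep(1L, nrow(held)), rep(0L, n_eval_neg))
  null_auroc <- with_seed(derive_seed(seed, "shuffle"),
                          mean(vapply(seq_len(n_shuffles),
                                      function(i) auroc(s, sample(lab)),
                                      numeric(1))))
  list(auroc = auroc(s, lab), auprc = auprc(s, lab),
       auroc_shuffled = null_auroc,
       n_pos = nrow(held), n_neg = n_eval_neg,
       best_epoch = fit$best_epoch, epochs = nrow(fit$history))
}
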