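## Model fitting: full-batch Adam on the masked reconstruction objective,
## validation-based early stopping, best-snapshot selection.

#' Training control parameters
#'
#' Defaults follow the reference configuration of the model: embedding
#' dimension 1000, learning rate 0.001, 1:10 negative sampling. The
#' remaining knobs (L2 coefficient, restart probability, walk length,
#' patience) have conventional defaults; all are documented with the
#' package's methods vignette.
#'
#' @param dim embedding dimension `d` (default 1000).
#' @param learning_rate Adam step size (default 0.001).
#' @param lambda L2 regularization coefficient (default 1e-4).
#' @param negative_ratio negatives per positive, or `"all"` (default 10).
#' @param alpha restart probability of the propagation stage (default
#'   0.1); `1` disables propagation (aggregation-only model).
#' @param rwr_iters walk iterations K per forward pass (default 10).
#' @param patience early-stopping patience in epochs (default 20).
#' @param min_epochs epochs to run before early stopping is armed
#'   (default 0); the best-validation snapshot is tracked from epoch 1
#'   regardless.
#' @param lr_decay_epoch epoch after which the learning rate is multiplied
#'   by `lr_decay_factor` (`NULL`, the default, keeps it constant).
#' @param lr_decay_factor step-decay multiplier (default 0.25).
#' @param snapshot which parameters the fitted model keeps: the
#'   best-validation snapshot (`"best"`, default) or the final epoch
#'   (`"final"`, for fixed-schedule runs whose validation set is too small
#'   to select a model reliably).
#' @param max_epochs maximum training epochs (default 200); `0` returns
#'   the initialized parameters unchanged.
#' @param init_seed seed for parameter initialization.
#' @param val_metric early-stopping metric, `"auprc"` (default, suited to
#'   the class imbalance) or `"auroc"`.
#' @param similarity_weighting `"weighted"` or `"binary"` neighbor mean
#'   for the similarity edge types.
#' @param verbose print per-epoch progress.
#' @return An object of class `hetdti_control`.
#' @export
hetdti_control <- function(dim = 1000L, learning_rate = 0.001, lambda = 1e-4,
                           negative_ratio = 10L, alpha = 0.1,
                           rwr_iters = 10L, patience = 20L, min_epochs = 0L,
                           max_epochs = 200L, lr_decay_epoch = NULL,
                           lr_decay_factor = 0.25,
                           snapshot = c("best", "final"),
                           init_seed = 1L, val_metric = c("auprc", "auroc"),
                           similarity_weighting = c("weighted", "binary"),
                           verbose = FALSE) {
  val_metric <- match.arg(val_metric)
  snapshot <- match.arg(snapshot)
  similarity_weighting <- match.arg(similarity_weighting)
  stopifnot(dim >= 1, learning_rate > 0, lambda >= 0, alpha > 0, alpha <= 1,
            rwr_iters >= 1, patience >= 1, min_epochs >= 0, max_epochs >= 0)
  structure(list(dim = as.integer(dim), learning_rate = learning_rate,
                 lambda = lambda, negative_ratio = negative_ratio,
                 alpha = alpha, rwr_iters = as.integer(rwr_iters),
                 patience = as.integer(patience),
                 min_epochs = as.integer(min_epochs),
                 max_epochs = as.integer(max_epochs),
                 lr_decay_epoch = if (!is.null(lr_decay_epoch))
                   as.integer(lr_decay_epoch),
                 lr_decay_factor = lr_decay_factor, snapshot = snapshot,
                 init_seed = as.integer(init_seed), val_metric = val_metric,
                 similarity_weighting = similarity_weighting,
                 verbose = isTRUE(verbose)),
            class = "hetdti_control")
}

#' Fit the graph-autoencoder DTI model
#'
#' Trains the encoder (initialization projections + per-edge-type
#' aggregation weights) and the DistMult decoder diagonals end to end by
#' full-batch Adam on the masked squared reconstruction loss with L2
#' regularization. The drug-target network is reconstructed only at the
#' training pairs of `split`; the seven auxiliary networks are fully
#' observed. After each epoch the early-stopping metric is evaluated on
#' the validation pairs; the best-validation parameter snapshot is kept
#' and training stops once `patience` epochs pass without improvement.
#' Fully reproducible under the seeds in `control` and `split`.
#'
#' @param net a `hetero_network`. For honest evaluation the drug-target
#'   matrix should contain only training positives (see
#'   [run_cv_experiment()], which rebuilds it per fold).
#' @param split a `dti_split`; when `NULL`, one is built by sampling
#'   negatives at `control$negative_ratio` and splitting at
#'   0.855/0.045/0.1 under `sampling_seed`.
#' @param control a [hetdti_control()].
#' @param sampling_seed seed for the automatic split when `split` is NULL.
#' @return An object of class `hetdti`: `params` (best snapshot),
#'   `history` (per-epoch loss and validation metric), `best_epoch`,
#'   `best_val`, `split`, `control`, `network`, `rwr` config.
#' @examples
#' sim <- generate_network(synth_config(counts = c(drug = 20, protein = 25,
#'                                                 disease = 10, side_effect = 10)))
#' fit <- hetdti(sim$network, control = hetdti_control(dim = 8, max_epochs = 3,
#'                                                     learning_rate = 0.01))
#' print(fit)
#' @export
hetdti <- function(net, split = NULL, control = hetdti_control(),
                   sampling_seed = 1L) {
  stopifnot(inherits(net, "hetero_network"),
            inherits(control, "hetdti_control"))
  if (is.null(split)) {
    positives <- which(net$matrices$drug_target == 1, arr.ind = TRUE)
    negatives <- sample_negatives(net$matrices$drug_target,
                                  control$negative_ratio,
                                  derive_seed(sampling_seed, "negatives"))
    split <- make_split(positives, negatives,
                        seed = derive_seed(sampling_seed, "split"))
  }
  masks <- build_masks(net, split)
  cfg <- rwr_config(alpha = control$alpha, max_iters = control$rwr_iters,
                    tol = 0)
  operators <- build_agg_operators(net, control$similarity_weighting)
  A <- if (control$alpha < 1) build_transition_matrix(net) else NULL
  params <- init_params(net, control$dim, control$init_seed)
  metric_fun <- if (control$val_metric == "auprc") auprc else auroc

  object <- structure(list(params = params, history = data.frame(),
                           best_epoch = 0L, best_val = NA_real_,
                           split = split, control = control, network = net,
                           rwr = cfg, converged = FALSE),
                      class = "hetdti")
  if (control$max_epochs == 0L) return(object)

  flat <- flatten_params(params)
  m <- numeric(length(flat)); v <- numeric(length(flat))
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  best_flat <- flat; best_val <- -Inf; best_epoch <- 0L
  hist <- vector("list", control$max_epochs)
  val_idx <- cbind(split$val$drug, split$val$protein)
  ## the validation forward is skipped when neither early stopping nor
  ## snapshot selection can use it
  need_val <- control$snapshot == "best" ||
    control$patience < control$max_epochs || control$verbose

  for (epoch in seq_len(control$max_epochs)) {
    lg <- loss_and_grad(net, params, masks, cfg, control$lambda,
                        operators = operators, A = A)
    if (!is.finite(lg$loss))
      fail("training diverged at epoch %d (loss %g); lower the learning rate",
           epoch, lg$loss)
    gflat <- flatten_params(lg$grad)
    m <- b1 * m + (1 - b1) * gflat
    v <- b2 * v + (1 - b2) * gflat^2
    mhat <- m / (1 - b1^epoch)
    vhat <- v / (1 - b2^epoch)
    rate <- control$learning_rate
    if (!is.null(control$lr_decay_epoch) && epoch > control$lr_decay_epoch)
      rate <- rate * control$lr_decay_factor
    flat <- flat - rate * mhat / (sqrt(vhat) + eps)
    params <- unflatten_params(flat, params)

    ## validation metric for the updated parameters
    val_metric <- NA_real_
    if (need_val && nrow(val_idx) > 0 &&
        length(unique(split$val$label)) == 2L) {
      h1 <- encode_forward(net, params, cfg, operators = operators, A = A)$h1
      st <- reconstruct_network(h1, params, net, "drug_target")
      val_metric <- metric_fun(st$scores[val_idx], split$val$label)
    }

    hist[[epoch]] <- data.frame(epoch = epoch, loss = lg$loss,
                                val = val_metric)
    if (control$verbose)
      message(sprintf("epoch %3d  loss %.4f  val_%s %.4f", epoch, lg$loss,
                      control$val_metric, val_metric))
    if (!is.na(val_metric) && val_metric > best_val) {
      best_val <- val_metric
      best_epoch <- epoch
      best_flat <- flat
    }
    if (epoch > control$min_epochs && best_epoch > 0L &&
        epoch - best_epoch > control$patience) break
  }

  hist <- do.call(rbind, hist[!vapply(hist, is.null, logical(1))])
  names(hist)[names(hist) == "val"] <- paste0("val_", control$val_metric)
  if (best_epoch == 0L) { best_flat <- flat; best_epoch <- nrow(hist) }
  if (control$snapshot == "final") best_flat <- flat
  object$params <- unflatten_params(best_flat, params)
  object$history <- hist
  object$best_epoch <- best_epoch
  object$best_val <- best_val
  object$converged <- nrow(hist) < control$max_epochs
  object
}
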