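## S3 methods for fitted models.

#' @export
print.hetdti <- function(x, ...) {
  ctrl <- x$control
  cat("Graph-autoencoder DTI model\n")
  cat(sprintf("  network: %s\n",
              paste(sprintf("%d %s", x$network$space$counts,
                            x$network$space$types), collapse = ", ")))
  cat(sprintf("  embedding dim %d, alpha %.3g, walk length %d\n",
              ctrl$dim, ctrl$alpha, ctrl$rwr_iters))
  if (nrow(x$history) == 0L) {
    cat("  untrained (initialized parameters)\n")
  } else {
    cat(sprintf("  %d epochs (best epoch %d, validation %s %.4f)%s\n",
                nrow(x$history), x$best_epoch, ctrl$val_metric, x$best_val,
                if (x$converged) ", early-stopped" else ""))
  }
  invisible(x)
}

#' @export
summary.hetdti <- function(object, ...) {
  res <- list(control = object$control, history = object$history,
              best_epoch = object$best_epoch, best_val = object$best_val,
              n_params = length(flatten_params(object$params)),
              split_sizes = vapply(object$split[c("train", "val", "test")],
                                   nrow, integer(1)))
  class(res) <- "summary.hetdti"
  res
}

#' @export
print.summary.hetdti <- function(x, ...) {
  cat(sprintf("Graph-autoencoder DTI model: %d trainable parameters\n",
              x$n_params))
  cat(sprintf("  split sizes: train %d / val %d / test %d\n",
              x$split_sizes[1], x$split_sizes[2], x$split_sizes[3]))
  if (nrow(x$history) > 0L) {
    cat(sprintf("  epochs: %d; final loss %.5g; best val_%s %.4f at epoch %d\n",
                nrow(x$history), x$history$loss[nrow(x$history)],
                x$control$val_metric, x$best_val, x$best_epoch))
  }
  invisible(x)
}

#' @export
coef.hetdti <- function(object, ...) object$params

#' Predict interaction scores from a fitted model
#'
#' @param object a fitted `hetdti` model.
#' @param newdata optionally, a different `hetero_network` to encode
#'   (defaults to the training network).
#' @param edge_type edge type to reconstruct (default `"drug_target"`).
#' @param pairs optional two-column (row, column) index matrix; when
#'   supplied, returns only those scores as a vector.
#' @param ... unused.
#' @return The full score matrix, or a vector of pair scores.
#' @export
predict.hetdti <- function(object, newdata = NULL, edge_type = "drug_target",
                           pairs = NULL, ...) {
  net <- if (is.null(newdata)) object$network else newdata
  h1 <- encode(net, object$params, object$rwr,
               object$control$similarity_weighting)
  st <- reconstruct_network(h1, object$params, net, edge_type)
  if (is.null(pairs)) st$scores else st$scores[as.matrix(pairs[, 1:2])]
}

#' Training-set reconstruction residuals
#'
#' Residuals `observed - predicted` of the drug-target network at the
#' masked (training) entries; all other entries are `NA`.
#'
#' @param object a fitted `hetdti` model.
#' @param ... unused.
#' @return A drugs x targets matrix.
#' @export
residuals.hetdti <- function(object, ...) {
  scores <- predict(object)
  masks <- build_masks(object$network, object$split)
  out <- object$network$matrices$drug_target - scores
  out[masks$drug_target == 0] <- NA_real_
  out
}

#' Plot training history
#'
#' Training loss (log scale) and the validation metric per epoch, with
#' the best-validation epoch marked.
#'
#' @param x a fitted `hetdti` model.
#' @param ... passed to [graphics::plot()].
#' @export
plot.hetdti <- function(x, ...) {
  h <- x$history
  if (nrow(h) == 0L) {
    warning("no training history to plot")
    return(invisible(x))
  }
  vcol <- grep("^val_", names(h), value = TRUE)
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::plot(h$epoch, h$loss, type = "l", log = "y", xlab = "epoch",
                 ylab = "masked loss", main = "training loss", ...)
  graphics::plot(h$epoch, h[[vcol]], type = "l", xlab = "epoch",
                 ylab = sub("val_", "validation ", vcol),
                 main = "validation metric", ...)
  graphics::abline(v = x$best_epoch, lty = 2)
  invisible(x)
}
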