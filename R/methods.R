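# S3 methods for fitted models ------------------------------------------------

#' @export
print.triweight <- function(x, ...) {
  cat("Three-level source-reweighting fit\n")
  cat(sprintf("  source examples: %d   target train/val/test: %d/%d/%d\n",
              x$source$M, length(x$target$train), length(x$target$val),
              length(x$target$test)))
  cat(sprintf("  epochs run: %d (%s)%s\n", x$epochs,
              if (x$converged) "converged" else "epoch cap reached",
              if (x$diverged) " [diverged; last good state]" else ""))
  cat(sprintf("  reweighting: %s\n",
              if (x$reweight) "on" else "off (weights frozen at 1)"))
  if (x$epochs > 0) {
    h <- x$history[nrow(x$history), ]
    cat(sprintf("  final losses: stage I %.4f, stage II %.4f, val %.4f\n",
                h$stage1_loss, h$stage2_loss, h$val_loss))
  }
  cat(sprintf("  importance weights: mean %.3f, range [%.3f, %.3f]\n",
              mean(x$weights), min(x$weights), max(x$weights)))
  invisible(x)
}

#' Summarize a three-level reweighting fit
#'
#' Reports loss trajectories, the ranking diagnostic, test-set metrics and
#' (when the source carries a corruption mask) the clean/corrupted weight
#' separation and weighted class-balance ratio.
#'
#' @param object A fitted [triweight()] model.
#' @param ... Unused.
#' @return A list of class `summary.triweight`.
#' @export
summary.triweight <- function(object, ...) {
  test_metrics <- NULL
  if (length(object$target$test) > 0) {
    pred <- predict(object, object$target$test)
    truth <- vapply(object$target$test, function(e) e$label, integer(1))
    test_metrics <- class_metrics(pred, truth, object$target$class_count)
  }
  sep <- NULL
  balance <- NULL
  msk <- object$source$corruption_mask
  if (!is.null(msk) && any(msk) && !all(msk))
    sep <- weight_separation(object$weights, msk)
  labs <- vapply(object$source$examples, function(e) e$label, integer(1))
  if (any(labs == 0L) && any(labs == 1L) &&
      sum(object$weights[labs == 0L]) > 0 &&
      sum(object$weights[labs == 1L]) > 0)
    balance <- class_balance_ratio(object$weights, labs)
  structure(list(fit = object, test_metrics = test_metrics,
                 weight_separation = sep, class_balance = balance),
            class = "summary.triweight")
}

#' @export
print.summary.triweight <- function(x, ...) {
  print(x$fit)
  if (!is.null(x$weight_separation)) {
    s <- x$weight_separation
    cat(sprintf("  weight separation: clean %.3f vs corrupted %.3f (gap %.3f)\n",
                s$mean_clean, s$mean_corrupted, s$gap))
  }
  if (!is.null(x$class_balance))
    cat(sprintf("  weighted source class-balance ratio: %.3f\n",
                x$class_balance))
  if (!is.null(x$test_metrics)) {
    cat("  test metrics:\n")
    print(x$test_metrics, row.names = FALSE)
  }
  invisible(x)
}

#' Extract the learned importance weights
#'
#' @param object A fitted [triweight()] model.
#' @param ... Unused.
#' @return The length-M weight vector C, each entry in \[0,1\].
#' @export
coef.triweight <- function(object, ...) object$weights

#' Predict target classes or class probabilities
#'
#' @param object A fitted [triweight()] model.
#' @param newdata List of [example()]s (defaults to the target test split).
#' @param type `"class"` for 0-based labels, `"prob"` for a probability
#'   matrix.
#' @param ... Unused.
#' @return Integer labels or an n-by-K probability matrix.
#' @export
predict.triweight <- function(object, newdata = NULL,
                              type = c("class", "prob"), ...) {
  type <- match.arg(type)
  if (is.null(newdata)) newdata <- object$target$test
  em <- examples_matrix(newdata)
  E <- em$agg %*% net_forward(object$networks$enc_t, em$X)
  P <- softmax_probs(net_forward(object$networks$head_t, E))
  if (type == "prob") P else max.col(P) - 1L
}

#' Plot training histories of a fit
#'
#' Draws the three loss trajectories and, on a second panel, the
#' same-class percentage of the global ranking plus (when available) the
#' mean weights of clean and corrupted source examples.
#'
#' @param x A fitted [triweight()] model.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.triweight <- function(x, ...) {
  h <- x$history
  if (nrow(h) == 0) stop("no epochs to plot")
  old <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(old))
  graphics::matplot(h$epoch, cbind(h$stage1_loss, h$stage2_loss, h$val_loss),
                    type = "l", lty = 1, xlab = "epoch", ylab = "loss", ...)
  graphics::legend("topright", c("stage I", "stage II", "validation"),
                   col = 1:3, lty = 1, bty = "n")
  has_w <- all(c("mean_weight_clean", "mean_weight_corrupted") %in% names(h))
  ys <- if (has_w)
    cbind(h$same_class_pct, h$mean_weight_clean, h$mean_weight_corrupted)
  else cbind(h$same_class_pct)
  graphics::matplot(h$epoch, ys, type = "l", lty = 1, ylim = c(0, 1),
                    xlab = "epoch", ylab = "diagnostic")
  graphics::legend("bottomright",
                   c("same-class %", if (has_w) c("mean w (clean)",
                                                  "mean w (corrupted)")),
                   col = seq_len(ncol(ys)), lty = 1, bty = "n")
  invisible(x)
}
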