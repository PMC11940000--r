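#' Training configuration
#'
#' The study setup: Adam, binary cross-entropy over a 2-class softmax, 300
#' epochs, batch size 68, cosine-decayed learning rate from 0.001 with floor
#' factor alpha = 0.01, checkpointing on best validation accuracy.
#'
#' @param epochs Number of epochs (default 300).
#' @param batch_size Minibatch size (default 68).
#' @param lr_init Initial learning rate (default 0.001).
#' @param lr_alpha Cosine-decay floor factor in `(0, 1]` (default 0.01); the
#'   schedule bottoms out at `lr_init * lr_alpha`.
#' @param seed RNG seed controlling weight initialization and batch shuffling.
#' @return An object of class `train_config`.
#' @export
train_config <- function(epochs = 300L, batch_size = 68L, lr_init = 0.001,
                         lr_alpha = 0.01, seed = 1L) {
  if (epochs < 1 || batch_size < 1) stop("epochs and batch_size must be >= 1",
                                         call. = FALSE)
  if (!(lr_alpha > 0 && lr_alpha <= 1)) stop("lr_alpha must be in (0, 1]",
                                             call. = FALSE)
  structure(list(optimizer = "adam", loss = "binary_crossentropy",
                 epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 lr_init = lr_init, lr_alpha = lr_alpha, seed = as.integer(seed),
                 checkpoint_metric = "val_accuracy"),
            class = "train_config")
}

#' Cosine-decayed learning rate at an epoch
#'
#' `lr(e) = lr_init * (alpha + (1 - alpha) * 0.5 * (1 + cos(pi * e / epochs)))`
#' for `0 <= e <= epochs`: `lr(0) = lr_init`, decaying monotonically to the
#' floor `lr_init * alpha` at `e = epochs`.
#'
#' @param epoch Epoch index (0-based; vectorized).
#' @param config A [train_config()].
#' @return Learning rate(s).
#' @export
lr_at <- function(epoch, config = train_config()) {
  if (any(epoch < 0 | epoch > config$epochs)) {
    stop(sprintf("epoch out of range [0, %d]", config$epochs), call. = FALSE)
  }
  a <- config$lr_alpha
  config$lr_init * (a + (1 - a) * 0.5 * (1 + cos(pi * epoch / config$epochs)))
}

# Forward pass in memory-bounded chunks; returns loss and accuracy (and
# optionally predictions).
.eval_pass <- function(params, spec, X, Cx, y, chunk = 256L, want_pred = FALSE) {
  n <- length(y)
  loss_sum <- 0; correct <- 0
  pred <- if (want_pred) integer(n) else NULL
  probs1 <- if (want_pred) numeric(n) else NULL
  for (start in seq(1L, n, by = chunk)) {
    idx <- start:min(start + chunk - 1L, n)
    Xb <- if (!is.null(X)) X[idx, , , drop = FALSE] else NULL
    Cb <- if (!is.null(Cx)) Cx[idx, , drop = FALSE] else NULL
    fw <- .nn_forward(params, spec, Xb, Cb, keep_cache = FALSE)
    loss_sum <- loss_sum + .ce_loss(fw$probs, y[idx]) * length(idx)
    p <- max.col(fw$probs, ties.method = "first") - 1L
    correct <- correct + sum(p == y[idx])
    if (want_pred) {
      pred[idx] <- p
      probs1[idx] <- fw$probs[, 2]
    }
  }
  list(loss = loss_sum / n, accuracy = correct / n, pred = pred, probs1 = probs1)
}

#' Train a model on pre-encoded inputs
#'
#' Minibatch Adam with the cosine-decayed learning rate, shuffling each epoch,
#' recording per-epoch training metrics (running minibatch averages),
#' validation metrics and the learning-rate trace. The returned weights are
#' the checkpoint with the best validation accuracy (ties resolved to the
#' earliest epoch), not the final epoch. Deterministic given `config$seed`.
#'
#' @param spec A [build_model()] result.
#' @param data A list with `train` and `val` elements, each a list
#'   `list(X = <n x frames x 7 array or NULL>, Cx = <n x d matrix or NULL>,
#'   y = <0/1 vector>)` as produced by [prepare_model_inputs()].
#' @param config A [train_config()].
#' @return An object of class `fitted_model`: `spec`, best-checkpoint
#'   `params`, `history` (class `training_history`), `best_epoch`, `config`.
#' @export
train_model <- function(spec, data, config = train_config()) {
  tr <- data$train; va <- data$val
  if (!length(tr$y) || !length(va$y)) stop("empty train or validation split",
                                           call. = FALSE)
  if (!is.null(spec$context) && (is.null(tr$Cx) || ncol(tr$Cx) != spec$context_input_dim)) {
    stop(sprintf("context input dimension mismatch: model expects %d",
                 spec$context_input_dim), call. = FALSE)
  }
  if (!is.null(spec$emg) && is.null(tr$X)) stop("model requires EMG input",
                                                call. = FALSE)
  .with_seed(config$seed, {
    params <- nn_init(spec)
    state <- .adam_init(params)
    n <- length(tr$y)
    hist <- data.frame(epoch = seq_len(config$epochs), lr = NA_real_,
                       train_loss = NA_real_, train_accuracy = NA_real_,
                       val_loss = NA_real_, val_accuracy = NA_real_)
    best <- list(acc = -Inf, epoch = NA_integer_, params = params)
    for (e in seq_len(config$epochs)) {
      lr <- lr_at(e - 1L, config)
      ord <- sample.int(n)
      loss_sum <- 0; correct <- 0
      for (start in seq(1L, n, by = config$batch_size)) {
        idx <- ord[start:min(start + config$batch_size - 1L, n)]
        Xb <- if (!is.null(spec$emg)) tr$X[idx, , , drop = FALSE] else NULL
        Cb <- if (!is.null(spec$context)) tr$Cx[idx, , drop = FALSE] else NULL
        yb <- tr$y[idx]
        fw <- .nn_forward(params, spec, Xb, Cb, keep_cache = TRUE)
        loss_sum <- loss_sum + .ce_loss(fw$probs, yb) * length(yb)
        correct <- correct + sum((max.col(fw$probs, ties.method = "first") - 1L) == yb)
        grads <- .nn_backward(params, spec, fw$cache, .ce_grad_logits(fw$probs, yb))
        upd <- .adam_step(params, grads, state, lr)
        params <- upd$params; state <- upd$state
      }
      ve <- .eval_pass(params, spec,
                       if (!is.null(spec$emg)) va$X else NULL,
                       if (!is.null(spec$context)) va$Cx else NULL, va$y)
      hist$lr[e] <- lr
      hist$train_loss[e] <- loss_sum / n
      hist$train_accuracy[e] <- correct / n
      hist$val_loss[e] <- ve$loss
      hist$val_accuracy[e] <- ve$accuracy
      if (ve$accuracy > best$acc) {
        best <- list(acc = ve$accuracy, epoch = e, params = params)
      }
    }
    structure(list(spec = spec, params = best$params,
                   history = structure(list(table = hist, best_epoch = best$epoch),
                                       class = "training_history"),
                   best_epoch = best$epoch, config = config),
              class = "fitted_model")
  })
}

#' Evaluate a fitted model on one split
#'
#' Argmax class decisions; metrics from the confusion matrix (rows = true,
#' columns = predicted, class order `[0, 1]`, cylindrical = positive class):
#' accuracy `(TP+TN)/n`, precision `TP/(TP+FP)`, recall `TP/(TP+FN)`. A zero
#' denominator yields 0 with `degenerate = TRUE`.
#'
#' @param fitted A [train_model()] result.
#' @param samples A list `list(X, Cx, y)` for the split.
#' @param split_name Label stored on the report.
#' @return An object of class `eval_report`.
#' @export
evaluate <- function(fitted, samples, split_name = "test") {
  if (!length(samples$y)) stop("empty evaluation split", call. = FALSE)
  spec <- fitted$spec
  ev <- .eval_pass(fitted$params, spec,
                   if (!is.null(spec$emg)) samples$X else NULL,
                   if (!is.null(spec$context)) samples$Cx else NULL,
                   samples$y, want_pred = TRUE)
  y <- samples$y; p <- ev$pred
  cm <- matrix(c(sum(y == 0 & p == 0), sum(y == 0 & p == 1),
                 sum(y == 1 & p == 0), sum(y == 1 & p == 1)),
               nrow = 2, byrow = TRUE,
               dimnames = list(true = c("0", "1"), pred = c("0", "1")))
  tp <- cm["1", "1"]; tn <- cm["0", "0"]; fp <- cm["0", "1"]; fn <- cm["1", "0"]
  degenerate <- FALSE
  precision <- if (tp + fp == 0) { degenerate <- TRUE; 0 } else tp / (tp + fp)
  recall <- if (tp + fn == 0) { degenerate <- TRUE; 0 } else tp / (tp + fn)
  structure(list(loss = ev$loss, accuracy = (tp + tn) / length(y),
                 precision = precision, recall = recall, confusion_matrix = cm,
                 split_name = split_name, n_samples = length(y),
                 degenerate = degenerate),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> %s (n=%d): loss %.4f, acc %.4f, prec %.4f, rec %.4f\n",
              x$split_name, x$n_samples, x$loss, x$accuracy, x$precision, x$recall))
  print(x$confusion_matrix)
  invisible(x)
}

#' Export learning curves
#'
#' Writes the per-epoch history to `curves.csv` under `path` and renders the
#' accuracy curves with an 85% reference line to `curves.pdf`.
#'
#' @param history A `training_history` (from a [train_model()] fit).
#' @param path Output directory (created if absent).
#' @param reference_line Accuracy reference line (default 0.85).
#' @return Invisibly, a list with `path`, `csv`, `plot_file`,
#'   `reference_line` and `best_epoch`.
#' @export
export_curves <- function(history, path, reference_line = 0.85) {
  tab <- history$table
  if (!nrow(tab)) stop("empty training history", call. = FALSE)
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  csv <- file.path(path, "curves.csv")
  utils::write.csv(tab, csv, row.names = FALSE)
  long <- rbind(
    data.frame(epoch = tab$epoch, accuracy = tab$train_accuracy, split = "train"),
    data.frame(epoch = tab$epoch, accuracy = tab$val_accuracy, split = "validation")
  )
  p <- ggplot2::ggplot(long, ggplot2::aes(x = epoch, y = accuracy,
                                          colour = split)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = reference_line, linetype = "dashed") +
    ggplot2::labs(x = "epoch", y = "accuracy") +
    ggplot2::theme_minimal()
  plot_file <- file.path(path, "curves.pdf")
  ggplot2::ggsave(plot_file, p, width = 6, height = 4)
  invisible(list(path = path, csv = csv, plot_file = plot_file,
                 reference_line = reference_line, best_epoch = history$best_epoch))
}
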