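#' Fit the GPR-class LSTM sequence classifier
#'
#' Trains a stacked LSTM on encoded, padded VMAT arcs to predict the QA
#' class (`Replan` / `Investigate` / `Ideal`).  Minibatches are reshuffled
#' every epoch; the Adam optimizer minimizes mean cross-entropy on the
#' logits.  With a validation set, early stopping monitors the validation
#' loss: any strict decrease resets the patience counter, and the
#' parameters from the best-validation-loss epoch are restored when
#' training stops.  Without a validation set (or with `epochs` given),
#' training runs for a fixed number of epochs — the protocol used for the
#' final model after cross-validation has chosen the epoch budget.
#'
#' One seed governs weight initialization, batch shuffling and dropout, so
#' a fit is bit-reproducible.
#'
#' @param train an [arc_dataset()] with all classes present.
#' @param val optional validation [arc_dataset()] for early stopping.
#' @param config a [model_config()].
#' @param control a [train_control()].
#' @param epochs if given, train for exactly this many epochs with no early
#'   stopping (overrides `control$max_epochs` and `patience`).
#' @param seed integer seed for the whole fit.
#' @param verbose print a progress line every `verbose` epochs (0 = quiet).
#' @return An object of class `gpr_lstm` with components `weights`,
#'   `config`, `control`, `history` (per-epoch data frame), `stopped_epoch`,
#'   `best_epoch`, `norm` (min-max parameters or `NULL`), `seq_length` and
#'   `levels`.
#' @seealso [predict.gpr_lstm()], [run_cv()], [export_model()]
#' @export
gpr_lstm <- function(train, val = NULL, config = model_config(),
                     control = train_control(), epochs = NULL, seed = 1L,
                     verbose = 0L) {
  stopifnot(inherits(train, "arc_dataset"), inherits(config, "model_config"),
            inherits(control, "train_control"))
  if (dim(train$x)[2] != config$input_size)
    stop("dataset feature width ", dim(train$x)[2],
         " does not match config input_size ", config$input_size,
         call. = FALSE)
  if (any(class_distribution(train$labels) == 0L))
    stop("every class must be present in the training data", call. = FALSE)

  norm <- NULL
  if (isTRUE(config$normalize)) {
    norm <- fit_norm(train)
    train <- apply_norm(train, norm)
    if (!is.null(val)) val <- apply_norm(val, norm)
  }

  y <- as.integer(train$labels) - 1L
  n <- length(train)
  max_epochs <- if (is.null(epochs)) control$max_epochs else as.integer(epochs)
  use_early <- is.null(epochs) && !is.null(val)
  if (!is.null(val)) yv <- as.integer(val$labels) - 1L

  weights <- init_weights(config, seed = seed)
  skeleton <- weights
  par <- par_flatten(weights)
  m <- v <- numeric(length(par))
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8; t_adam <- 0L

  best_loss <- Inf; best_par <- par; best_epoch <- 0L; wait <- 0L
  hist <- vector("list", max_epochs)
  stopped <- max_epochs

  with_seed(seed + 1L, {
    for (epoch in seq_len(max_epochs)) {
      ord <- sample.int(n)
      batches <- split(ord, ceiling(seq_along(ord) / control$batch_size))
      ep_loss <- 0; ep_pred <- integer(n)
      for (bt in batches) {
        xb <- train$x[, , bt, drop = FALSE]
        g <- lstm_grad_cpp(weights, xb, y[bt], train$true_length[bt],
                           identical(config$readout, "length_aware"),
                           config$dropout,
                           sample.int(.Machine$integer.max, 1L))
        gv <- par_flatten(g$grads)
        if (is.finite(control$grad_clip)) {
          gn <- sqrt(sum(gv^2))
          if (gn > control$grad_clip) gv <- gv * (control$grad_clip / gn)
        }
        t_adam <- t_adam + 1L
        m <- b1 * m + (1 - b1) * gv
        v <- b2 * v + (1 - b2) * gv^2
        mhat <- m / (1 - b1^t_adam)
        vhat <- v / (1 - b2^t_adam)
        par <- par - control$learning_rate * mhat / (sqrt(vhat) + eps)
        weights <- par_unflatten(par, skeleton)
        ep_loss <- ep_loss + g$loss * length(bt)
        ep_pred[bt] <- max.col(g$logits, ties.method = "first") - 1L
      }
      row <- data.frame(epoch = epoch, train_loss = ep_loss / n,
                        train_acc = mean(ep_pred == y))
      row <- cbind(row, ova_history_row(y, ep_pred, "train"))
      if (!is.null(val)) {
        lv <- lstm_forward(weights, val$x, val$true_length, config$readout)
        ev <- eval_logits(lv, yv)
        row$val_loss <- ev$loss
        row$val_acc <- ev$acc
        row <- cbind(row, ova_history_row(yv, ev$pred, "val"))
      }
      hist[[epoch]] <- row
      if (verbose > 0L && epoch %% verbose == 0L)
        message(sprintf("epoch %d: train loss %.4f acc %.3f%s", epoch,
                        row$train_loss, row$train_acc,
                        if (!is.null(val))
                          sprintf(", val loss %.4f acc %.3f", row$val_loss,
                                  row$val_acc) else ""))
      if (use_early) {
        if (row$val_loss < best_loss) {
          best_loss <- row$val_loss; best_par <- par
          best_epoch <- epoch; wait <- 0L
        } else {
          wait <- wait + 1L
          if (wait >= control$patience) { stopped <- epoch; break }
        }
      }
    }
  })

  if (use_early && best_epoch > 0L) {
    par <- best_par
    weights <- par_unflatten(par, skeleton)
  } else {
    best_epoch <- stopped
  }

  structure(list(
    weights = weights, config = config, control = control,
    history = do.call(rbind, hist[!vapply(hist, is.null, logical(1))]),
    stopped_epoch = stopped, best_epoch = best_epoch,
    norm = norm, seq_length = dim(train$x)[1], levels = gpr_levels
  ), class = "gpr_lstm")
}

# one-vs-all sensitivity/specificity columns for the training history;
# classes absent from the truth give NA sensitivity
ova_history_row <- function(y_int, pred_int, prefix) {
  out <- list()
  for (k in seq_along(gpr_levels)) {
    cls <- k - 1L
    tp <- sum(y_int == cls & pred_int == cls)
    fn <- sum(y_int == cls & pred_int != cls)
    fp <- sum(y_int != cls & pred_int == cls)
    tn <- sum(y_int != cls & pred_int != cls)
    nm <- tolower(gpr_levels[k])
    out[[paste0(prefix, "_sens_", nm)]] <-
      if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_
    out[[paste0(prefix, "_spec_", nm)]] <-
      if (tn + fp > 0) 100 * tn / (tn + fp) else NA_real_
  }
  as.data.frame(out)
}

#' Predict QA classes for encoded arcs
#'
#' @param object a fitted [gpr_lstm()].
#' @param newdata an [arc_dataset()] or an `L x 127 x n` array (with
#'   `true_length` then taken as `L` for every sample).
#' @param type `"class"` for labels, `"prob"` for the softmax class
#'   probabilities, `"logits"` for raw logits, `"all"` for everything.
#' @param ... unused.
#' @return Depending on `type`: a factor, an `n x 3` matrix, or a list.
#'   Argmax ties are broken toward the lower ordinal (Replan first).
#' @export
predict.gpr_lstm <- function(object, newdata,
                             type = c("class", "prob", "logits", "all"),
                             ...) {
  type <- match.arg(type)
  if (inherits(newdata, "arc_dataset")) {
    x <- newdata$x; lens <- newdata$true_length
  } else {
    x <- newdata
    if (length(dim(x)) != 3L) stop("newdata must be an L x 127 x n array")
    lens <- rep(dim(x)[1], dim(x)[3])
  }
  if (dim(x)[1] != object$seq_length)
    stop("sequence length ", dim(x)[1], " does not match the model's ",
         object$seq_length, "; re-pad with pad_arcs()", call. = FALSE)
  if (!is.null(object$norm)) x <- apply_norm(x, object$norm, lens)
  logits <- lstm_forward(object$weights, x, lens, object$config$readout)
  colnames(logits) <- gpr_levels
  prob <- softmax_rows(logits)
  cls <- factor(gpr_levels[max.col(prob, ties.method = "first")],
                levels = gpr_levels, ordered = TRUE)
  switch(type,
         class = cls,
         prob = prob,
         logits = logits,
         all = list(class = cls, prob = prob, logits = logits))
}

#' @export
print.gpr_lstm <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "<gpr_lstm> %d-layer LSTM, hidden %d, %s readout, %d parameters\n",
    cfg$num_layers, cfg$hidden_size, cfg$readout, n_parameters(x)))
  cat(sprintf("  trained %d epoch(s)%s\n", x$stopped_epoch,
              if (x$best_epoch != x$stopped_epoch)
                sprintf(" (restored best epoch %d)", x$best_epoch) else ""))
  invisible(x)
}

#' @export
summary.gpr_lstm <- function(object, ...) {
  h <- object$history
  last <- h[nrow(h), ]
  cat(sprintf("LSTM GPR classifier: hidden %d x %d layers, dropout %g\n",
              object$config$hidden_size, object$config$num_layers,
              object$config$dropout))
  cat(sprintf("Parameters: %d;  padded sequence length: %d\n",
              n_parameters(object), object$seq_length))
  cat(sprintf("Epochs run: %d (best epoch %d)\n", object$stopped_epoch,
              object$best_epoch))
  cat(sprintf("Final training loss %.4f, accuracy %.1f%%\n",
              last$train_loss, 100 * last$train_acc))
  if ("val_loss" %in% names(h))
    cat(sprintf("Final validation loss %.4f, accuracy %.1f%%\n",
                last$val_loss, 100 * last$val_acc))
  invisible(object)
}

#' Plot training history curves
#'
#' Loss (training, and validation when present) on the left axis and
#' accuracy on the right, against epoch.
#'
#' @param x a fitted [gpr_lstm()].
#' @param ... passed to [graphics::matplot()].
#' @export
plot.gpr_lstm <- function(x, ...) {
  h <- x$history
  has_val <- "val_loss" %in% names(h)
  old <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(old))
  loss <- cbind(h$train_loss, if (has_val) h$val_loss)
  graphics::matplot(h$epoch, loss, type = "l", lty = 1,
                    col = c("black", "red")[seq_len(ncol(loss))],
                    xlab = "epoch", ylab = "cross-entropy loss", ...)
  graphics::legend("topright", bty = "n",
                   legend = c("train", if (has_val) "validation"),
                   col = c("black", "red")[seq_len(ncol(loss))], lty = 1)
  acc <- cbind(h$train_acc, if (has_val) h$val_acc) * 100
  graphics::matplot(h$epoch, acc, type = "l", lty = 1,
                    col = c("black", "red")[seq_len(ncol(acc))],
                    xlab = "epoch", ylab = "accuracy (%)", ...)
  invisible(x)
}

#' Extract model weights
#'
#' @param object a fitted [gpr_lstm()].
#' @param ... unused.
#' @return The nested weight list (see [init_weights()]).
#' @export
coef.gpr_lstm <- function(object, ...) object$weights
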