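#' Model architecture configuration
#'
#' A stacked LSTM over the 127-feature control-point sequence, with a linear
#' head compressing the final hidden state to three class logits.  The
#' reference architecture is hidden size 64, 3 layers, no dropout.
#'
#' @param input_size feature width; must equal the encoding width (127).
#' @param hidden_size LSTM hidden width, default 64.
#' @param num_layers stacked LSTM layers, default 3.
#' @param dropout inter-layer dropout probability in `[0, 1)`, default 0.
#' @param num_classes output classes, default 3.
#' @param readout `"last"` reads the hidden state at the final (padded)
#'   time step — the whole zero-padded sequence is fed through the
#'   recurrence; `"length_aware"` reads the hidden state at each arc's last
#'   real control point instead.
#' @param normalize if `TRUE`, fit per-feature min-max normalization on the
#'   training data and apply it to every input (see [fit_norm()]).
#' @return A `model_config` list.
#' @export
model_config <- function(input_size = 127L, hidden_size = 64L,
                         num_layers = 3L, dropout = 0,
                         num_classes = 3L,
                         readout = c("last", "length_aware"),
                         normalize = FALSE) {
  readout <- match.arg(readout)
  stopifnot(input_size >= 1L, hidden_size >= 1L, num_layers >= 1L,
            dropout >= 0, dropout < 1, num_classes >= 2L)
  structure(list(input_size = as.integer(input_size),
                 hidden_size = as.integer(hidden_size),
                 num_layers = as.integer(num_layers),
                 dropout = dropout,
                 num_classes = as.integer(num_classes),
                 readout = readout, normalize = normalize),
            class = "model_config")
}

#' Training configuration
#'
#' Defaults follow the reference protocol: up to 1000 epochs, minibatches of
#' 64, Adam with starting learning rate 1e-2, cross-entropy loss on the
#' logits, and early stopping on validation loss with a patience of 500
#' epochs (any strict decrease resets the counter; the parameters from the
#' best-validation-loss epoch are restored at stop).
#'
#' @param max_epochs epoch budget.
#' @param batch_size minibatch size (batches reshuffled each epoch; the
#'   last, possibly smaller, batch is kept).
#' @param learning_rate Adam starting learning rate.
#' @param patience early-stopping patience in epochs (ignored without a
#'   validation set).
#' @param grad_clip clip threshold on the global gradient L2 norm,
#'   `Inf` to disable (default).
#' @return A `train_control` list.
#' @export
train_control <- function(max_epochs = 1000L, batch_size = 64L,
                          learning_rate = 1e-2, patience = 500L,
                          grad_clip = Inf) {
  stopifnot(max_epochs >= 1L, batch_size >= 1L, learning_rate > 0,
            patience >= 1L, patience <= max_epochs, grad_clip > 0)
  structure(list(max_epochs = as.integer(max_epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 patience = as.integer(patience),
                 grad_clip = grad_clip),
            class = "train_control")
}

#' Initialize LSTM weights
#'
#' All weights and biases are drawn from `U(-1/sqrt(H), 1/sqrt(H))` under
#' the given seed.  Each layer carries one combined bias vector of length
#' `4H` (gate order: input, forget, cell, output).
#'
#' @param config a [model_config()].
#' @param seed integer seed.
#' @return Weight list: `layers[[l]]$W_i` (`4H x in_l`), `layers[[l]]$W_h`
#'   (`4H x H`), `layers[[l]]$b` (`4H`), plus head `W_out` (`C x H`),
#'   `b_out` (`C`).
#' @export
init_weights <- function(config, seed = 1L) {
  H <- config$hidden_size
  k <- 1 / sqrt(H)
  with_seed(seed, {
    layers <- lapply(seq_len(config$num_layers), function(l) {
      in_l <- if (l == 1L) config$input_size else H
      list(W_i = matrix(stats::runif(4 * H * in_l, -k, k), 4 * H, in_l),
           W_h = matrix(stats::runif(4 * H * H, -k, k), 4 * H, H),
           b = stats::runif(4 * H, -k, k))
    })
    w <- list(layers = layers,
              W_out = matrix(stats::runif(config$num_classes * H, -k, k),
                             config$num_classes, H),
              b_out = stats::runif(config$num_classes, -k, k))
  })
  w
}

#' Count model parameters
#'
#' @param weights a weight list from [init_weights()] or a fitted
#'   `gpr_lstm`.
#' @return Integer total parameter count.
#' @export
n_parameters <- function(weights) {
  if (inherits(weights, "gpr_lstm")) weights <- weights$weights
  length(unlist(weights, use.names = FALSE))
}

# ---- flat parameter vector helpers (for the Adam update) ----

par_flatten <- function(w) unlist(w, use.names = FALSE)

par_unflatten <- function(v, skeleton) {
  pos <- 0L
  walk <- function(s) {
    if (is.list(s)) return(lapply(s, walk))
    n <- length(s)
    out <- v[pos + seq_len(n)]
    pos <<- pos + n
    attributes(out) <- attributes(s)
    out
  }
  walk(skeleton)
}

lstm_forward <- function(weights, x, lengths, readout) {
  lstm_forward_cpp(weights, x, as.integer(lengths),
                   identical(readout, "length_aware"))
}

softmax_rows <- function(logits) {
  z <- logits - apply(logits, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

# mean cross-entropy + accuracy + predictions from logits
eval_logits <- function(logits, y_int) {
  p <- softmax_rows(logits)
  n <- nrow(p)
  loss <- -mean(log(pmax(p[cbind(seq_len(n), y_int + 1L)], 1e-300)))
  pred <- max.col(p, ties.method = "first") - 1L
  list(loss = loss, pred = pred, acc = mean(pred == y_int), prob = p)
}
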