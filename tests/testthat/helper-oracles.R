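# Independent scalar implementations used as oracles.  These deliberately
# avoid the package's C++ kernels: plain R loops over scalars/vectors.

# step-by-step LSTM recurrence for a single sequence (matrix L x F),
# returning the class logits; gate order i, f, g, o with one bias per layer
scalar_lstm_forward <- function(weights, xmat, readout_step = nrow(xmat)) {
  sigm <- function(z) 1 / (1 + exp(-z))
  inp <- xmat
  for (ly in weights$layers) {
    H <- ncol(ly$W_h)
    h <- rep(0, H); cc <- rep(0, H)
    out <- matrix(0, nrow(inp), H)
    for (t in seq_len(nrow(inp))) {
      z <- as.numeric(ly$W_i %*% inp[t, ] + ly$W_h %*% h + ly$b)
      i <- sigm(z[1:H])
      f <- sigm(z[H + 1:H])
      g <- tanh(z[2 * H + 1:H])
      o <- sigm(z[3 * H + 1:H])
      cc <- f * cc + i * g
      h <- o * tanh(cc)
      out[t, ] <- h
    }
    inp <- out
  }
  as.numeric(weights$W_out %*% inp[readout_step, ] + weights$b_out)
}

# brute-force one-vs-all counts from label vectors
brute_ova <- function(y_true, y_pred, cls) {
  tp <- sum(y_true == cls & y_pred == cls)
  fn <- sum(y_true == cls & y_pred != cls)
  fp <- sum(y_true != cls & y_pred == cls)
  tn <- sum(y_true != cls & y_pred != cls)
  list(tp = tp, fn = fn, fp = fp, tn = tn)
}

# AUROC as the normalized Mann-Whitney U statistic (ties count half)
mann_whitney_auc <- function(pos_scores, neg_scores) {
  s <- 0
  for (p in pos_scores)
    for (q in neg_scores)
      s <- s + (p > q) + 0.5 * (p == q)
  s / (length(pos_scores) * length(neg_scores))
}

# small random labeled dataset (random features, not arcs) for
# resampling/fold-plan property tests
random_toy_dataset <- function(counts, L = 4L, seed = 1L) {
  withr::local_seed(seed)
  labels <- rep(arcgate::gpr_levels, times = counts)
  arcs <- lapply(seq_along(labels), function(i) {
    m <- matrix(stats::rnorm(L * 127), L, 127)
    structure(m, true_length = L, label = labels[i],
              class = c("encoded_arc", "matrix", "array"))
  })
  arcgate::arc_dataset(arcs, labels = labels)
}

# a tiny valid arc built by hand
toy_arc <- function(n_cp = 3L, plan_id = "p", arc_id = "a") {
  mw <- seq(0, 1, length.out = n_cp)
  cps <- lapply(seq_len(n_cp), function(t)
    arcgate::control_point(t - 1L, mw[t], c(-50, 50, -40, 40),
                           (t - 1) * 2, seq(-30, 29.5, length.out = 120)))
  arcgate::arc_sequence(plan_id, arc_id, cps)
}
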