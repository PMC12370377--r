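test_that("initialization is seeded and the head maps hidden to 3 classes", {
  cfg <- model_config()
  w1 <- init_weights(cfg, seed = 5)
  w2 <- init_weights(cfg, seed = 5)
  expect_identical(w1, w2)
  w3 <- init_weights(cfg, seed = 6)
  expect_false(identical(w1, w3))
  expect_equal(dim(w1$W_out), c(3L, 64L))
  expect_length(w1$b_out, 3L)
})

test_that("parameter count matches the closed form for a gated stack", {
  # per layer: 4H weights for input and recurrence plus one bias block,
  # 4H*(in + H + 1); head: H*C + C
  for (H in c(2L, 16L, 64L)) {
    cfg <- model_config(hidden_size = H)
    expected <- 4 * H * (127 + H + 1) + 2 * (4 * H * (H + H + 1)) +
      H * 3 + 3
    expect_identical(n_parameters(init_weights(cfg)), as.integer(expected))
  }
})

test_that("batched forward pass matches the scalar recurrence oracle", {
  cfg <- model_config(input_size = 127L, hidden_size = 2L, num_layers = 3L)
  w <- init_weights(cfg, seed = 2)
  set.seed(10)
  L <- 3L; n <- 4L
  x <- array(rnorm(L * 127 * n), dim = c(L, 127, n))
  lens <- c(3L, 2L, 3L, 1L)
  for (readout in c("last", "length_aware")) {
    logits <- arcgate:::lstm_forward(w, x, lens, readout)
    for (i in seq_len(n)) {
      step <- if (readout == "last") L else lens[i]
      expect_equal(as.numeric(logits[i, ]),
                   scalar_lstm_forward(w, x[, , i], step), tolerance = 1e-5)
    }
  }
})

test_that("forward pass is deterministic and duplicates map to equal logits", {
  cfg <- model_config(hidden_size = 4L)
  w <- init_weights(cfg, seed = 1)
  set.seed(2)
  x1 <- array(rnorm(5 * 127), dim = c(5, 127, 1))
  xx <- array(c(x1, x1, rnorm(5 * 127)), dim = c(5, 127, 3))
  lg <- arcgate:::lstm_forward(w, xx, rep(5L, 3), "last")
  expect_identical(lg[1, ], lg[2, ])
  expect_identical(lg, arcgate:::lstm_forward(w, xx, rep(5L, 3), "last"))
  expect_equal(dim(lg), c(3L, 3L))
  # softmax rows sum to one
  p <- arcgate:::softmax_rows(lg)
  expect_equal(rowSums(p), rep(1, 3), tolerance = 1e-6)
  expect_true(all(is.finite(lg)))
  # width mismatch is a shape error
  bad <- array(0, dim = c(5, 126, 1))
  expect_error(arcgate:::lstm_forward(w, bad, 5L, "last"), "width")
})

test_that("batch loss equals the mean of per-sample cross-entropies", {
  cfg <- model_config(hidden_size = 3L)
  w <- init_weights(cfg, seed = 4)
  set.seed(5)
  n <- 6L
  x <- array(rnorm(4 * 127 * n), dim = c(4, 127, n))
  y <- sample(0:2, n, replace = TRUE)
  g <- arcgate:::lstm_grad_cpp(w, x, y, rep(4L, n), FALSE, 0, 1)
  per_sample <- vapply(seq_len(n), function(i) {
    lg <- scalar_lstm_forward(w, x[, , i])
    p <- exp(lg - max(lg)); p <- p / sum(p)
    -log(p[y[i] + 1])
  }, numeric(1))
  expect_equal(g$loss, mean(per_sample), tolerance = 1e-6)
})

test_that("predictions break argmax ties toward Replan and match probabilities", {
  # synthetic logits through the shared decision rule
  p <- arcgate:::softmax_rows(rbind(c(0, 0, 0), c(0, 0, 10)))
  expect_equal(p[1, ], rep(1 / 3, 3), tolerance = 1e-9)
  expect_identical(max.col(p, ties.method = "first")[1], 1L)  # Replan
  expect_identical(max.col(p, ties.method = "first")[2], 3L)  # Ideal
  set.seed(1)
  lg <- matrix(rnorm(3000), ncol = 3)
  expect_identical(max.col(arcgate:::softmax_rows(lg), ties.method = "first"),
                   max.col(lg, ties.method = "first"))
})

test_that("early stopping and fixed-epoch rules behave as specified", {
  ds <- random_toy_dataset(c(6L, 6L, 6L), L = 2L, seed = 3)
  cfg <- model_config(hidden_size = 2L)
  # fixed-epoch training: exactly 5 epochs of history
  fit <- gpr_lstm(ds, config = cfg,
                  control = train_control(max_epochs = 500L, batch_size = 9L),
                  epochs = 5L, seed = 1)
  expect_identical(nrow(fit$history), 5L)
  expect_identical(fit$stopped_epoch, 5L)
  # max_epochs cap with large patience
  fit2 <- gpr_lstm(ds, val = ds, config = cfg,
                   control = train_control(max_epochs = 4L, batch_size = 9L,
                                           patience = 4L), seed = 1)
  expect_identical(fit2$stopped_epoch, 4L)
  # patience 1: stops at the first epoch with no improvement
  fit3 <- gpr_lstm(ds, val = ds, config = cfg,
                   control = train_control(max_epochs = 200L, batch_size = 9L,
                                           patience = 1L, learning_rate = 10),
                   seed = 2)
  expect_lt(fit3$stopped_epoch, 200L)
  expect_identical(fit3$best_epoch,
                   which.min(fit3$history$val_loss))
  expect_error(gpr_lstm(ds[1:6], config = cfg), "every class")
})

test_that("training history tracks loss, accuracy and one-vs-all metrics", {
  ds <- random_toy_dataset(c(8L, 8L, 8L), L = 2L, seed = 6)
  fit <- gpr_lstm(ds, val = ds, config = model_config(hidden_size = 2L),
                  control = train_control(batch_size = 12L), epochs = 3L,
                  seed = 3)
  h <- fit$history
  expect_true(all(c("train_loss", "train_acc", "val_loss", "val_acc",
                    "train_sens_replan", "val_spec_ideal") %in% names(h)))
  expect_true(all(is.finite(h$train_loss)))
  rates <- unlist(h[grep("sens|spec", names(h))])
  expect_true(all(rates >= 0 & rates <= 100, na.rm = TRUE))
})

test_that("a fit is bit-reproducible under one seed", {
  ds <- random_toy_dataset(c(5L, 5L, 5L), L = 2L, seed = 9)
  cfg <- model_config(hidden_size = 2L)
  ctl <- train_control(batch_size = 8L)
  f1 <- gpr_lstm(ds, config = cfg, control = ctl, epochs = 3L, seed = 42)
  f2 <- gpr_lstm(ds, config = cfg, control = ctl, epochs = 3L, seed = 42)
  expect_identical(f1$weights, f2$weights)
  expect_identical(f1$history, f2$history)
})

test_that("dropout training runs and stays seed-deterministic", {
  ds <- random_toy_dataset(c(5L, 5L, 5L), L = 2L, seed = 9)
  cfg <- model_config(hidden_size = 4L, dropout = 0.3)
  f1 <- gpr_lstm(ds, config = cfg, control = train_control(batch_size = 15L),
                 epochs = 2L, seed = 7)
  f2 <- gpr_lstm(ds, config = cfg, control = train_control(batch_size = 15L),
                 epochs = 2L, seed = 7)
  expect_identical(f1$weights, f2$weights)
})

test_that("the model learns a separable three-class sequence toy", {
  # three classes distinguished by the scale of a leaf-motion-like feature
  set.seed(11)
  L <- 8L
  mk <- function(scale, label) {
    m <- matrix(rnorm(L * 127, sd = 0.05), L, 127)
    m[, 8:127] <- m[, 8:127] + scale
    structure(m, true_length = L, label = label,
              class = c("encoded_arc", "matrix", "array"))
  }
  arcs <- c(lapply(1:20, function(i) mk(-1, "Replan")),
            lapply(1:20, function(i) mk(0, "Investigate")),
            lapply(1:20, function(i) mk(1, "Ideal")))
  ds <- arc_dataset(arcs)
  fit <- gpr_lstm(ds, config = model_config(hidden_size = 8L),
                  control = train_control(batch_size = 16L,
                                          learning_rate = 5e-3),
                  epochs = 60L, seed = 2)
  acc <- tail(fit$history$train_acc, 1)
  expect_gte(acc, 0.95)
})
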