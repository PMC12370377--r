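# The published 222-arc test confusion matrix (rows truth Ideal,
# Investigate, Replan) used as an exact oracle for the metric definitions.
published_cm <- function() {
  as_confusion_matrix3(c(58, 12, 4,
                         17, 56, 1,
                         2, 3, 69))
}

test_that("the published confusion matrix reproduces all printed metrics", {
  cm <- published_cm()
  expect_identical(sum(cm), 222L)
  expect_equal(sensitivity_ova(cm, "Ideal"), 78.38)
  expect_equal(sensitivity_ova(cm, "Investigate"), 75.68)
  expect_equal(sensitivity_ova(cm, "Replan"), 93.24)
  expect_equal(specificity_ova(cm, "Ideal"), 87.16)
  expect_equal(specificity_ova(cm, "Investigate"), 89.86)
  expect_equal(specificity_ova(cm, "Replan"), 96.62)
  expect_equal(overall_accuracy(cm), 82.4)
})

test_that("the same matrix regenerates from an explicit 222-pair label list", {
  cm0 <- published_cm()
  y_true <- y_pred <- character(0)
  for (i in rownames(cm0)) for (j in colnames(cm0)) {
    y_true <- c(y_true, rep(i, cm0[i, j]))
    y_pred <- c(y_pred, rep(j, cm0[i, j]))
  }
  expect_identical(confusion_matrix3(y_true, y_pred), cm0)
})

test_that("confusion matrix counts are exhaustive and marginal-consistent", {
  expect_identical(unname(diag(confusion_matrix3(
    rep(gpr_levels, each = 3), rep(gpr_levels, each = 3)))), rep(3L, 3))
  set.seed(4)
  for (rep in 1:20) {
    n <- sample(5:60, 1)
    yt <- sample(gpr_levels, n, TRUE)
    yp <- sample(gpr_levels, n, TRUE)
    cm <- confusion_matrix3(yt, yp)
    expect_identical(sum(cm), n)
    for (cls in gpr_levels) {
      expect_identical(sum(cm[cls, ]), sum(yt == cls))
      expect_identical(sum(cm[, cls]), sum(yp == cls))
    }
  }
  expect_error(confusion_matrix3(c("Ideal"), c("???")), "unknown")
  expect_error(confusion_matrix3(c("Ideal"), c("Ideal", "Replan")),
               "equal length")
})

test_that("one-vs-all metrics agree with brute-force counting", {
  set.seed(9)
  for (rep in 1:30) {
    n <- sample(10:80, 1)
    yt <- sample(gpr_levels, n, TRUE)
    yp <- sample(gpr_levels, n, TRUE)
    cm <- confusion_matrix3(yt, yp)
    for (cls in gpr_levels) {
      o <- brute_ova(yt, yp, cls)
      if (o$tp + o$fn > 0)
        expect_equal(sensitivity_ova(cm, cls, digits = NULL),
                     100 * o$tp / (o$tp + o$fn))
      if (o$tn + o$fp > 0)
        expect_equal(specificity_ova(cm, cls, digits = NULL),
                     100 * o$tn / (o$tn + o$fp))
    }
    expect_equal(overall_accuracy(cm, digits = NULL),
                 100 * mean(yt == yp))
  }
})

test_that("perfect and degenerate matrices hit the boundary values", {
  eye <- as_confusion_matrix3(c(5, 0, 0, 0, 5, 0, 0, 0, 5))
  for (cls in gpr_levels) {
    expect_equal(sensitivity_ova(eye, cls), 100)
    expect_equal(specificity_ova(eye, cls), 100)
  }
  expect_equal(overall_accuracy(eye), 100)
  empty_row <- as_confusion_matrix3(c(0, 0, 0, 1, 1, 0, 0, 0, 2))
  expect_error(sensitivity_ova(empty_row, "Ideal"), "undefined")
})

test_that("accuracy equals the truth-weighted mean of per-class recalls", {
  set.seed(12)
  for (rep in 1:20) {
    cm <- as_confusion_matrix3(sample(0:9, 9, TRUE))
    if (any(rowSums(cm) == 0)) next
    recalls <- vapply(rownames(cm), function(cls)
      sensitivity_ova(cm, cls, digits = NULL), numeric(1))
    expect_equal(overall_accuracy(cm, digits = NULL),
                 sum(recalls * rowSums(cm)) / sum(cm))
  }
})

test_that("ROC endpoints and ties behave as specified", {
  yt <- rep(c("Ideal", "Replan"), each = 4)
  sep <- c(0.9, 0.8, 0.85, 0.95, 0.1, 0.2, 0.3, 0.15)
  expect_equal(roc_ova(yt, sep, "Ideal")$auroc, 1.0)
  expect_equal(roc_ova(yt, rep(0.5, 8), "Ideal")$auroc, 0.5)
  r <- roc_ova(yt, sep, "Ideal")$roc
  expect_equal(r$fpr[1], 0); expect_equal(r$tpr[1], 0)
  expect_equal(r$fpr[nrow(r)], 1); expect_equal(r$tpr[nrow(r)], 1)
  expect_error(roc_ova(rep("Ideal", 4), runif(4), "Ideal"), "undefined")
})

test_that("AUROC equals the normalized Mann-Whitney statistic", {
  set.seed(21)
  for (rep in 1:200) {
    n <- sample(4:20, 1)
    yt <- sample(gpr_levels, n, TRUE)
    if (length(unique(yt)) < 2) next
    scores <- round(runif(n), sample(1:3, 1))  # coarse -> forced ties
    cls <- sample(unique(yt), 1)
    if (all(yt == cls) || !any(yt == cls)) next
    a <- roc_ova(yt, scores, cls)$auroc
    expect_equal(a, mann_whitney_auc(scores[yt == cls], scores[yt != cls]),
                 tolerance = 1e-12)
  }
})

test_that("AUROC is invariant under strictly monotone score transforms", {
  set.seed(3)
  yt <- sample(gpr_levels, 40, TRUE)
  s <- runif(40)
  a0 <- roc_ova(yt, s, "Ideal")$auroc
  expect_equal(roc_ova(yt, exp(3 * s), "Ideal")$auroc, a0)
  expect_equal(roc_ova(yt, rank(s, ties.method = "min"), "Ideal")$auroc, a0)
})

test_that("ROC/AUROC agree with the pROC reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(8)
  for (rep in 1:20) {
    n <- sample(15:60, 1)
    yt <- sample(gpr_levels, n, TRUE)
    if (min(table(factor(yt, levels = gpr_levels))) < 1) next
    s <- round(runif(n), 2)
    for (cls in unique(yt)) {
      if (all(yt == cls)) next
      ours <- roc_ova(yt, s, cls)$auroc
      ref <- suppressMessages(
        as.numeric(pROC::auc(pROC::roc(yt == cls, s, direction = "<",
                                       quiet = TRUE))))
      expect_equal(ours, ref, tolerance = 1e-12)
    }
  }
})

test_that("evaluate_model assembles a coherent report from a model", {
  ds <- random_toy_dataset(c(4L, 4L, 4L), L = 2L, seed = 5)
  fit <- gpr_lstm(ds, config = model_config(hidden_size = 2L),
                  control = train_control(batch_size = 12L), epochs = 2L,
                  seed = 1)
  rep <- evaluate_model(fit, ds)
  expect_s3_class(rep, "evaluation_report")
  expect_identical(sum(rep$confusion), 12L)
  expect_true(all(rep$sensitivity >= 0 & rep$sensitivity <= 100))
  expect_true(all(rep$auroc >= 0 & rep$auroc <= 1))
  dir <- withr::local_tempdir()
  write_evaluation_report(rep, dir)
  expect_true(file.exists(file.path(dir, "report.json")))
  expect_true(file.exists(file.path(dir, "roc_ideal.csv")))
})
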