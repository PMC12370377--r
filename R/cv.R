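#' Plan stratified cross-validation folds
#'
#' Builds a fold plan in which the validation sets partition the dataset
#' and every validation set holds exactly `per_class_val` samples of each
#' class.  On a balanced training set of 296 samples per class with
#' `per_class_val = 2` this yields 148 folds of validation size 6 — the
#' many-fold protocol that maximizes the data available to each fold's
#' training run at the cost of noisier per-fold validation estimates.
#'
#' @param ds an [arc_dataset()].
#' @param per_class_val validation samples per class per fold, default 2.
#' @param seed integer seed for the within-class shuffle.
#' @return A `fold_plan`: list with `folds` (each a list of `train` and
#'   `val` index vectors) and `per_class_val`.
#' @export
make_fold_plan <- function(ds, per_class_val = 2L, seed = 1L) {
  stopifnot(inherits(ds, "arc_dataset"), per_class_val >= 1L)
  counts <- class_distribution(ds$labels)
  rem <- counts %% per_class_val
  if (any(rem != 0L))
    stop("class counts not divisible by per_class_val: ",
         paste(sprintf("%s %d (remainder %d)", names(counts)[rem != 0],
                       counts[rem != 0], rem[rem != 0]), collapse = ", "),
         call. = FALSE)
  n_folds <- unique(counts %/% per_class_val)
  if (length(n_folds) != 1L)
    stop("stratified fold partition requires equal class counts, got ",
         paste(counts, collapse = "/"), call. = FALSE)
  val_sets <- replicate(n_folds, integer(0), simplify = FALSE)
  with_seed(seed, {
    for (cls in gpr_levels) {
      idx <- sample(which(ds$labels == cls))
      fold_of <- rep(seq_len(n_folds), each = per_class_val)
      for (f in seq_len(n_folds))
        val_sets[[f]] <- c(val_sets[[f]], idx[fold_of == f])
    }
  })
  all_idx <- seq_len(length(ds))
  folds <- lapply(val_sets, function(v) {
    v <- sort(v)
    list(train = setdiff(all_idx, v), val = v)
  })
  structure(list(folds = folds, per_class_val = as.integer(per_class_val)),
            class = "fold_plan")
}

#' Run stratified cross-validation with early stopping
#'
#' Each fold trains an independent model from a fresh seeded initialization
#' (per-fold seed = `seed + fold index`) with early stopping on its
#' validation fold, recording per-epoch loss, accuracy and one-vs-all
#' sensitivity/specificity.  Curves are averaged across folds; folds that
#' stopped early are carried at their last recorded value so every epoch
#' averages over all folds.  The final epoch budget is the mean of the
#' per-fold stopping epochs, rounded half up.
#'
#' @param ds training [arc_dataset()].
#' @param config a [model_config()].
#' @param control a [train_control()].
#' @param plan a `fold_plan` from [make_fold_plan()]; built automatically
#'   when `NULL`.
#' @param seed base seed; fold `i` uses `seed + i`.
#' @param verbose print one line per completed fold.
#' @return A `gpr_cv` object: `stopped_epochs`, `final_epochs`, `curves`
#'   (fold-averaged per-epoch data frame), `histories` (per-fold), `plan`.
#' @export
run_cv <- function(ds, config = model_config(), control = train_control(),
                   plan = NULL, seed = 1L, verbose = FALSE) {
  if (is.null(plan)) plan <- make_fold_plan(ds, seed = seed)
  stopifnot(inherits(plan, "fold_plan"))
  histories <- vector("list", length(plan$folds))
  stopped <- integer(length(plan$folds))
  for (f in seq_along(plan$folds)) {
    fold <- plan$folds[[f]]
    fit <- tryCatch(
      gpr_lstm(ds[fold$train], val = ds[fold$val], config = config,
               control = control, seed = seed + f),
      error = function(e) stop("fold ", f, ": ", conditionMessage(e),
                               call. = FALSE))
    histories[[f]] <- fit$history
    stopped[f] <- fit$stopped_epoch
    if (verbose)
      message(sprintf("fold %d/%d stopped at epoch %d", f,
                      length(plan$folds), stopped[f]))
  }
  structure(list(
    stopped_epochs = stopped,
    final_epochs = round_half_up(mean(stopped)),
    curves = average_curves(histories),
    histories = histories,
    plan = plan
  ), class = "gpr_cv")
}

round_half_up <- function(x) as.integer(floor(x + 0.5))

# fold-averaged per-epoch curves; shorter histories are extended by
# carrying their last value forward so each epoch averages all folds
average_curves <- function(histories) {
  max_ep <- max(vapply(histories, nrow, integer(1)))
  cols <- setdiff(names(histories[[1L]]), "epoch")
  out <- data.frame(epoch = seq_len(max_ep))
  for (cn in cols) {
    acc <- matrix(NA_real_, max_ep, length(histories))
    for (f in seq_along(histories)) {
      v <- histories[[f]][[cn]]
      acc[, f] <- c(v, rep(v[length(v)], max_ep - length(v)))
    }
    out[[cn]] <- rowMeans(acc, na.rm = TRUE)
  }
  out
}

#' @export
print.gpr_cv <- function(x, ...) {
  cat(sprintf("<gpr_cv> %d folds; stopping epochs %d-%d (mean %.1f)\n",
              length(x$stopped_epochs), min(x$stopped_epochs),
              max(x$stopped_epochs), mean(x$stopped_epochs)))
  cat(sprintf("  final epoch budget: %d\n", x$final_epochs))
  invisible(x)
}

#' Train the final model on all training data
#'
#' After cross-validation has fixed the epoch budget, the deployed model is
#' trained on the entire training dataset with no hold-out and no early
#' stopping.
#'
#' @param train training [arc_dataset()].
#' @param config a [model_config()].
#' @param control a [train_control()] (batch size, learning rate).
#' @param epochs epoch count, typically `cv$final_epochs`.
#' @param seed integer seed.
#' @return A fitted [gpr_lstm()].
#' @export
train_final <- function(train, config = model_config(),
                        control = train_control(), epochs, seed = 1L) {
  stopifnot(epochs >= 1L)
  gpr_lstm(train, val = NULL, config = config, control = control,
           epochs = epochs, seed = seed)
}

#' Persist a cross-validation result
#'
#' Writes the fold-averaged curves as CSV and a JSON summary with the
#' per-fold stopping epochs and the derived final epoch budget.
#'
#' @param cv a `gpr_cv` from [run_cv()].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_cv_result <- function(cv, dir) {
  stopifnot(inherits(cv, "gpr_cv"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(cv$curves, file.path(dir, "curves.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(stopped_epochs = cv$stopped_epochs,
         final_epochs = cv$final_epochs),
    file.path(dir, "summary.json"), auto_unbox = TRUE)
  invisible(dir)
}
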