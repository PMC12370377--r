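#' Export a trained model to the portable JSON exchange format
#'
#' Writes a self-contained, human-readable JSON file holding the
#' architecture, every weight matrix at full double precision, the input
#' signature (`n x L x 127`), and — when normalization was enabled at
#' training — the fitted min-max parameters, so the model file and its
#' preprocessing always travel together.  The format is versioned and
#' documented in the file itself (`format` / `format_version` fields);
#' any runtime that can read JSON and multiply matrices can execute it.
#'
#' @param model a fitted [gpr_lstm()].
#' @param path output path (conventionally `.json`).
#' @return `path`, invisibly.
#' @seealso [load_exported_model()], [parity_check()]
#' @export
export_model <- function(model, path) {
  stopifnot(inherits(model, "gpr_lstm"))
  cfg <- model$config
  doc <- list(
    format = "arcgate-lstm",
    format_version = 1L,
    input_signature = list(seq_length = model$seq_length,
                           n_features = cfg$input_size),
    output_classes = model$levels,
    config = list(input_size = cfg$input_size,
                  hidden_size = cfg$hidden_size,
                  num_layers = cfg$num_layers,
                  num_classes = cfg$num_classes,
                  readout = cfg$readout),
    normalization = if (is.null(model$norm)) NULL else
      list(min = model$norm$min, range = model$norm$range),
    weights = list(
      layers = lapply(model$weights$layers, function(ly)
        list(W_i = ly$W_i, W_h = ly$W_h, b = ly$b)),
      W_out = model$weights$W_out,
      b_out = model$weights$b_out))
  jsonlite::write_json(doc, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor", null = "null")
  invisible(path)
}

#' Load an exported portable model
#'
#' @param path a file written by [export_model()].
#' @return A `gpr_lstm` object (without training history) usable with
#'   [predict.gpr_lstm()] and [evaluate_model()].
#' @export
load_exported_model <- function(path) {
  if (!file.exists(path)) stop("model file not found: ", path, call. = FALSE)
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!identical(doc$format, "arcgate-lstm"))
    stop("not an arcgate portable model file: ", path, call. = FALSE)
  as_mat <- function(rows)  # row-major nested list -> matrix
    do.call(rbind, lapply(rows, function(r) as.numeric(unlist(r))))
  has_norm <- !is.null(doc$normalization) &&
    length(doc$normalization$min) > 0
  cfg <- model_config(input_size = doc$config$input_size,
                      hidden_size = doc$config$hidden_size,
                      num_layers = doc$config$num_layers,
                      num_classes = doc$config$num_classes,
                      readout = doc$config$readout,
                      normalize = has_norm)
  wl <- lapply(doc$weights$layers, function(ly)
    list(W_i = as_mat(ly$W_i), W_h = as_mat(ly$W_h),
         b = as.numeric(unlist(ly$b))))
  if (length(wl) != cfg$num_layers)
    stop("model file declares ", cfg$num_layers, " layers but carries ",
         length(wl), call. = FALSE)
  norm <- NULL
  if (has_norm)
    norm <- structure(
      list(min = as.numeric(unlist(doc$normalization$min)),
           range = as.numeric(unlist(doc$normalization$range))),
      class = "minmax_norm")
  structure(list(
    weights = list(layers = wl, W_out = as_mat(doc$weights$W_out),
                   b_out = as.numeric(unlist(doc$weights$b_out))),
    config = cfg, control = NULL, history = NULL,
    stopped_epoch = NA_integer_, best_epoch = NA_integer_,
    norm = norm, seq_length = doc$input_signature$seq_length,
    levels = unlist(doc$output_classes)
  ), class = "gpr_lstm")
}

#' Verify native-vs-exported prediction parity
#'
#' Runs the in-memory model and its exported file on the same samples and
#' compares logits and predicted classes.  The check passes when the
#' maximum absolute logit difference is at most `tol` and the classes agree
#' on every sample whose logits are not tied.
#'
#' @param model a fitted [gpr_lstm()].
#' @param exported_path file written by [export_model()].
#' @param ds an [arc_dataset()] (or `L x 127 x n` array) of comparison
#'   samples.
#' @param tol maximum tolerated absolute logit difference, default 1e-4.
#' @return A `parity_report`: `n`, `max_logit_diff`, `class_agreement`,
#'   `pass`.
#' @export
parity_check <- function(model, exported_path, ds, tol = 1e-4) {
  stopifnot(inherits(model, "gpr_lstm"))
  loaded <- load_exported_model(exported_path)
  a <- predict(model, ds, type = "all")
  b <- predict(loaded, ds, type = "all")
  max_diff <- max(abs(a$logits - b$logits))
  # ignore argmax flips on samples with (near-)tied logits
  srt <- t(apply(a$logits, 1L, sort, decreasing = TRUE))
  tied <- (srt[, 1] - srt[, 2]) <= 2 * tol
  agree_all <- mean(a$class == b$class)
  agree <- if (all(tied)) 1 else
    mean(a$class[!tied] == b$class[!tied])
  structure(list(n = length(a$class), max_logit_diff = max_diff,
                 class_agreement = agree,
                 class_agreement_all = agree_all,
                 pass = max_diff <= tol && agree == 1),
            class = "parity_report")
}

#' @export
print.parity_report <- function(x, ...) {
  cat(sprintf(
    "<parity_report> %d samples: max |logit diff| %.2e, class agreement %.3f -> %s\n",
    x$n, x$max_logit_diff, x$class_agreement,
    if (x$pass) "PASS" else "FAIL"))
  invisible(x)
}

#' Predict QA classes for every arc of a plan file
#'
#' End-to-end prediction: parse the plan, encode and pad each arc to the
#' model's sequence length, and report the predicted class with the three
#' class probabilities per arc.  When the plan carries measured GPRs (or a
#' label table is given) the true class is included for comparison.
#'
#' @param model a fitted [gpr_lstm()], an exported model file path, or a
#'   model loaded with [load_exported_model()].
#' @param plan_path plan file readable by [parse_plan()].
#' @param dialect plan dialect, `"json"` or `"dicom-rt"`.
#' @param labels optional label table (data frame or CSV path with columns
#'   `plan_id`, `arc_id`, `gpr_percent`).
#' @return Data frame with one row per arc: `plan_id`, `arc_id`,
#'   `predicted`, `p_replan`, `p_investigate`, `p_ideal`, and `truth`
#'   when known.
#' @export
predict_plan <- function(model, plan_path, dialect = "json",
                         labels = NULL) {
  if (is.character(model)) model <- load_exported_model(model)
  stopifnot(inherits(model, "gpr_lstm"))
  arcs <- parse_plan(plan_path, dialect)
  if (length(arcs) == 0L) stop("plan contains no treatment arcs",
                               call. = FALSE)
  if (is.character(labels)) labels <- read_label_table(labels)
  enc <- pad_arcs(lapply(arcs, encode_arc),
                  target_length = model$seq_length)
  x <- array(0, dim = c(model$seq_length, 127L, length(enc)))
  for (i in seq_along(enc)) x[, , i] <- unclass(enc[[i]])
  lens <- vapply(enc, function(a) attr(a, "true_length"), integer(1))
  if (!is.null(model$norm)) x <- apply_norm(x, model$norm, lens)
  logits <- lstm_forward(model$weights, x, lens, model$config$readout)
  prob <- softmax_rows(logits)
  out <- data.frame(
    plan_id = vapply(arcs, `[[`, character(1), "plan_id"),
    arc_id = vapply(arcs, `[[`, character(1), "arc_id"),
    predicted = gpr_levels[max.col(prob, ties.method = "first")],
    p_replan = prob[, 1], p_investigate = prob[, 2], p_ideal = prob[, 3])
  gpr <- vapply(arcs, function(a) a$gpr %||% NA_real_, numeric(1))
  if (!is.null(labels)) {
    key <- paste(out$plan_id, out$arc_id)
    lk <- paste(labels$plan_id, labels$arc_id)
    gpr <- ifelse(is.na(gpr), labels$gpr_percent[match(key, lk)], gpr)
  }
  if (any(!is.na(gpr))) {
    truth <- rep(NA_character_, length(gpr))
    ok <- !is.na(gpr)
    truth[ok] <- as.character(discretize_gpr(gpr[ok]))
    out$truth <- truth
  }
  out
}
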