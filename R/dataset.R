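#' Build a labeled dataset of padded encoded arcs
#'
#' The dataset container used throughout training and evaluation.  It holds
#' one `L x 127 x n` array (`x[, , i]` is sample `i`'s padded control-point
#' matrix), the class labels, each arc's true (pre-padding) length, a
#' per-sample provenance flag (`"real"` for measured arcs, `"synthetic"`
#' for SMOTE-generated ones), and the plan/arc identifiers.
#'
#' @param arcs list of padded `encoded_arc` objects sharing one row count
#'   (see [pad_arcs()]).
#' @param labels class labels, one per arc (factor or character using the
#'   levels in [gpr_levels]); if `NULL`, taken from each arc's `label`
#'   attribute.
#' @param plan_id,arc_id optional identifier vectors.
#' @param gpr optional numeric GPR percentages.
#' @param provenance per-sample `"real"`/`"synthetic"` flags, default all
#'   `"real"`.
#' @return An object of class `arc_dataset`.
#' @export
arc_dataset <- function(arcs, labels = NULL, plan_id = NULL, arc_id = NULL,
                        gpr = NULL, provenance = NULL) {
  stopifnot(length(arcs) >= 1L)
  L <- nrow(arcs[[1L]])
  if (!all(vapply(arcs, nrow, integer(1)) == L))
    stop("all encoded arcs must share one padded length; run pad_arcs()",
         call. = FALSE)
  n <- length(arcs)
  x <- array(0, dim = c(L, 127L, n))
  for (i in seq_len(n)) x[, , i] <- unclass(arcs[[i]])
  if (is.null(labels))
    labels <- vapply(arcs, function(a) as.character(attr(a, "label")),
                     character(1))
  labels <- as_gpr_factor(labels)
  if (length(labels) != n) stop("one label per arc required", call. = FALSE)
  structure(list(
    x = x,
    labels = labels,
    true_length = vapply(arcs, function(a) attr(a, "true_length"),
                         integer(1)),
    provenance = provenance %||% rep("real", n),
    plan_id = plan_id %||% rep(NA_character_, n),
    arc_id = arc_id %||% as.character(seq_len(n)),
    gpr = gpr %||% rep(NA_real_, n)
  ), class = "arc_dataset")
}

new_dataset_like <- function(ds, x, labels, true_length, provenance,
                             plan_id, arc_id, gpr) {
  structure(list(x = x, labels = labels, true_length = true_length,
                 provenance = provenance, plan_id = plan_id,
                 arc_id = arc_id, gpr = gpr), class = "arc_dataset")
}

#' @export
print.arc_dataset <- function(x, ...) {
  d <- dim(x$x)
  cat(sprintf("<arc_dataset> %d arcs, padded length %d, %d features\n",
              d[3], d[1], d[2]))
  cnt <- class_distribution(x$labels)
  cat("  classes:", paste(sprintf("%s %d", names(cnt), cnt), collapse = ", "),
      "\n")
  nsyn <- sum(x$provenance == "synthetic")
  if (nsyn > 0) cat(sprintf("  %d synthetic (SMOTE) samples\n", nsyn))
  invisible(x)
}

#' @export
length.arc_dataset <- function(x) dim(x$x)[3]

#' Subset an arc dataset by sample index
#'
#' @param x an `arc_dataset`.
#' @param i integer or logical sample index.
#' @param ... unused.
#' @return An `arc_dataset` with the selected samples.
#' @export
`[.arc_dataset` <- function(x, i, ...) {
  i <- seq_len(dim(x$x)[3])[i]
  new_dataset_like(x, x$x[, , i, drop = FALSE], x$labels[i],
                   x$true_length[i], x$provenance[i], x$plan_id[i],
                   x$arc_id[i], x$gpr[i])
}

#' Flatten a dataset to an n x (L*127) matrix
#'
#' Each sample's padded control-point matrix is flattened row-major (time
#' step by time step), so row `i` reconstructs `x[, , i]` exactly.  This is
#' the view on which SMOTE's Euclidean nearest-neighbour search operates.
#'
#' @param ds an [arc_dataset()].
#' @return Numeric matrix, one row per sample.
#' @export
flatten_dataset <- function(ds) {
  stopifnot(inherits(ds, "arc_dataset"))
  d <- dim(ds$x)
  out <- matrix(0, d[3], d[1] * d[2])
  for (i in seq_len(d[3])) out[i, ] <- as.vector(t(ds$x[, , i]))
  out
}

unflatten_rows <- function(m, L) {
  # inverse of flatten_dataset for a matrix of flattened samples
  n <- nrow(m)
  x <- array(0, dim = c(L, ncol(m) / L, n))
  for (i in seq_len(n)) x[, , i] <- matrix(m[i, ], L, byrow = TRUE)
  x
}

#' Combine datasets sample-wise
#'
#' @param ... `arc_dataset` objects with identical padded length.
#' @return The concatenated `arc_dataset`.
#' @export
c.arc_dataset <- function(...) {
  parts <- list(...)
  L <- dim(parts[[1L]]$x)[1]
  stopifnot(all(vapply(parts, function(p) dim(p$x)[1], numeric(1)) == L))
  n <- sum(vapply(parts, length, integer(1)))
  x <- array(0, dim = c(L, 127L, n))
  at <- 0L
  for (p in parts) {
    k <- length(p)
    x[, , at + seq_len(k)] <- p$x
    at <- at + k
  }
  new_dataset_like(parts[[1L]], x,
                   as_gpr_factor(unlist(lapply(parts, function(p)
                     as.character(p$labels)))),
                   unlist(lapply(parts, `[[`, "true_length")),
                   unlist(lapply(parts, `[[`, "provenance")),
                   unlist(lapply(parts, `[[`, "plan_id")),
                   unlist(lapply(parts, `[[`, "arc_id")),
                   unlist(lapply(parts, `[[`, "gpr")))
}

#' Write / read a dataset as an array file plus a CSV manifest
#'
#' The array is stored with [saveRDS()]; the manifest CSV records per-sample
#' metadata (`plan_id`, `arc_id`, `n_cp`, `gpr`, `label`, `provenance`).
#'
#' @param ds an [arc_dataset()].
#' @param dir directory to create/use.
#' @return `write_dataset`: `dir` invisibly; `read_dataset`: the dataset.
#' @export
write_dataset <- function(ds, dir) {
  stopifnot(inherits(ds, "arc_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  saveRDS(ds$x, file.path(dir, "arrays.rds"))
  utils::write.csv(
    data.frame(plan_id = ds$plan_id, arc_id = ds$arc_id,
               n_cp = ds$true_length, gpr = ds$gpr,
               label = as.character(ds$labels), provenance = ds$provenance),
    file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(dir)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(dir) {
  x <- readRDS(file.path(dir, "arrays.rds"))
  man <- utils::read.csv(file.path(dir, "manifest.csv"),
                         stringsAsFactors = FALSE)
  new_dataset_like(NULL, x, as_gpr_factor(man$label), man$n_cp,
                   man$provenance, as.character(man$plan_id),
                   as.character(man$arc_id), man$gpr)
}
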