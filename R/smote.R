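#' Balance class counts with SMOTE
#'
#' Synthetic minority over-sampling: each minority class is filled up to the
#' majority class count with interpolated samples.  A synthetic sample is
#' `x + u * (z - x)` where `x` is a randomly chosen real minority sample,
#' `z` is one of its `k` nearest same-class neighbours (Euclidean distance
#' on the flattened padded sequence, padding zeros included), and
#' `u ~ Uniform(0, 1)`.  Real samples are kept bit-exactly and flagged
#' `"real"`; synthetic samples are flagged `"synthetic"`.
#'
#' Note that interpolating two deliverable control-point sequences does not
#' generally yield a machine-deliverable one; see
#' [synthetic_deliverability_fraction()] for a diagnostic.  Nothing is
#' filtered.
#'
#' @param ds an [arc_dataset()].
#' @param k_neighbors nearest-neighbour count, default 5; effectively
#'   `min(k, class size - 1)`.
#' @param seed integer seed making the oversampling reproducible.
#' @return A balanced [arc_dataset()] with every class at the majority
#'   count.
#' @export
smote_oversample <- function(ds, k_neighbors = 5L, seed = 1L) {
  stopifnot(inherits(ds, "arc_dataset"))
  counts <- class_distribution(ds$labels)
  target <- max(counts)
  need <- target - counts
  if (all(need == 0L)) return(ds)
  small <- names(counts)[counts < target & counts < 2L]
  if (length(small))
    stop("cannot interpolate a class with fewer than 2 samples: ",
         paste(small, collapse = ", "), call. = FALSE)

  flat <- flatten_dataset(ds)
  L <- dim(ds$x)[1]
  parts <- list(ds)
  with_seed(seed, {
    for (cls in gpr_levels) {
      n_new <- need[[cls]]
      if (n_new == 0L) next
      idx <- which(ds$labels == cls)
      xc <- flat[idx, , drop = FALSE]
      k <- min(k_neighbors, length(idx) - 1L)
      d2 <- as.matrix(stats::dist(xc))
      nn <- apply(d2, 1L, function(row) order(row)[2:(k + 1L)])
      nn <- matrix(nn, nrow = k)  # k x n_class
      base <- sample.int(length(idx), n_new, replace = TRUE)
      pick <- sample.int(k, n_new, replace = TRUE)
      u <- stats::runif(n_new)
      syn <- matrix(0, n_new, ncol(flat))
      for (j in seq_len(n_new)) {
        xb <- xc[base[j], ]
        zb <- xc[nn[pick[j], base[j]], ]
        syn[j, ] <- xb + u[j] * (zb - xb)
      }
      parts[[length(parts) + 1L]] <- new_dataset_like(
        ds, unflatten_rows(syn, L),
        as_gpr_factor(rep(cls, n_new)),
        rep(L, n_new),  # synthetic arcs treated as full padded length
        rep("synthetic", n_new),
        rep(NA_character_, n_new),
        sprintf("smote_%s_%d", tolower(cls), seq_len(n_new)),
        rep(NA_real_, n_new))
    }
  })
  do.call(c, parts)
}

#' Stratified train/test split
#'
#' Splits a dataset so that each class contributes the same fraction to the
#' test set.  The per-class test count is `round(count * test_fraction)`
#' with R's round-half-to-even rule; samples are assigned at random under
#' the seed.  The two parts partition the input exactly.
#'
#' @param ds an [arc_dataset()].
#' @param test_fraction fraction held out, in `(0, 1)`; default 0.2.
#' @param seed integer seed.
#' @return List with elements `train` and `test`.
#' @export
stratified_split <- function(ds, test_fraction = 0.2, seed = 1L) {
  stopifnot(inherits(ds, "arc_dataset"))
  if (!(test_fraction > 0 && test_fraction < 1))
    stop("test_fraction must lie strictly between 0 and 1", call. = FALSE)
  counts <- class_distribution(ds$labels)
  if (any(counts == 0L))
    stop("every class must be present to stratify; missing: ",
         paste(names(counts)[counts == 0L], collapse = ", "), call. = FALSE)
  test_idx <- integer(0)
  with_seed(seed, {
    for (cls in gpr_levels) {
      idx <- which(ds$labels == cls)
      n_test <- round(length(idx) * test_fraction)
      test_idx <- c(test_idx, sample(idx, n_test))
    }
  })
  test_idx <- sort(test_idx)
  train_idx <- setdiff(seq_len(length(ds)), test_idx)
  list(train = ds[train_idx], test = ds[test_idx])
}

# evaluate expr under a temporary RNG state seeded with `seed`,
# restoring the caller's RNG state afterwards
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}
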