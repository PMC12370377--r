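#' Flatten one control point into the 127-element feature vector
#'
#' The fixed feature layout is
#' `[index, meterset_weight, X1, X2, Y1, Y2, gantry_angle,
#'   leaf_1 ... leaf_120]`
#' (leaves bank A 1-60 then bank B 1-60), giving a vector of length exactly
#' 127.  Units are left as stored: mm at isocenter for jaws and leaves,
#' degrees for the gantry angle, and the raw 0-based ordinal for the index.
#' Model weights depend on this ordering; it is part of the exported model
#' contract.
#'
#' @param cp a [control_point()].
#' @return Numeric vector of length 127.
#' @export
encode_control_point <- function(cp) {
  if (!inherits(cp, "control_point")) stop("expected a control_point")
  if (length(cp$leaf_positions) != 120L)
    stop("control point has ", length(cp$leaf_positions),
         " leaf positions; 120 required", call. = FALSE)
  c(cp$index, cp$meterset_weight, cp$jaws, cp$gantry_angle,
    cp$leaf_positions)
}

#' Encode an arc as an (n_cp x 127) feature matrix
#'
#' Row `r` is [encode_control_point()] applied to the `r`-th control point.
#' The result carries its true (un-padded) length and, optionally, a class
#' label, so that downstream padding can preserve both.
#'
#' @param arc an [arc_sequence()].
#' @param label optional class label (see [discretize_gpr()]).
#' @return An `encoded_arc`: a numeric matrix with attributes `true_length`
#'   and `label`.
#' @export
encode_arc <- function(arc, label = NULL) {
  if (!inherits(arc, "arc_sequence")) stop("expected an arc_sequence")
  n <- length(arc$control_points)
  if (n < 1L) stop("cannot encode an empty arc", call. = FALSE)
  m <- t(vapply(arc$control_points, encode_control_point, numeric(127L)))
  encoded_arc(m, true_length = n, label = label)
}

encoded_arc <- function(m, true_length, label = NULL) {
  stopifnot(is.matrix(m), ncol(m) == 127L, true_length <= nrow(m))
  structure(m, true_length = as.integer(true_length), label = label,
            class = c("encoded_arc", "matrix", "array"))
}

#' Zero-pad encoded arcs to a common sequence length
#'
#' Arcs of different control-point counts are padded with all-zero rows at
#' the sequence end so that every arc shares one tensor size.  Real rows are
#' preserved bit-exactly and the recorded true length is unchanged; arcs are
#' never truncated.
#'
#' @param arcs list of `encoded_arc` objects (from [encode_arc()]).
#' @param target_length row count after padding, or `"auto"` (the maximum
#'   true length in `arcs`).
#' @return List of `encoded_arc` objects, all with `target_length` rows.
#' @export
pad_arcs <- function(arcs, target_length = "auto") {
  stopifnot(length(arcs) >= 1L)
  lens <- vapply(arcs, function(a) attr(a, "true_length"), integer(1))
  if (identical(target_length, "auto")) target_length <- max(lens)
  target_length <- as.integer(target_length)
  if (any(lens > target_length))
    stop("target_length ", target_length, " is shorter than an arc of ",
         max(lens), " control points; arcs are never truncated",
         call. = FALSE)
  lapply(arcs, function(a) {
    if (nrow(a) == target_length) return(a)
    m <- matrix(0, target_length, 127L)
    m[seq_len(nrow(a)), ] <- unclass(a)
    encoded_arc(m, attr(a, "true_length"), attr(a, "label"))
  })
}

#' Fit per-feature min-max normalization parameters
#'
#' Optional preprocessing: raw features mix scales (control-point index
#' 0-180, meterset weight 0-1, positions of order 100 mm), which can slow or
#' destabilize gradient training.  Parameters are fit on training data only
#' and map each feature to `[0, 1]`; a feature constant on the training data
#' maps to 0.
#' Padding rows are excluded from the fit so the padded zeros stay zero-ish
#' rather than dominating the per-feature range.
#'
#' @param ds an [arc_dataset()].
#' @return A `minmax_norm` object (list of per-feature `min` and `range`).
#' @seealso [apply_norm()]
#' @export
fit_norm <- function(ds) {
  stopifnot(inherits(ds, "arc_dataset"))
  x <- ds$x
  n <- dim(x)[3]
  mins <- rep(Inf, 127L); maxs <- rep(-Inf, 127L)
  for (i in seq_len(n)) {
    rows <- seq_len(ds$true_length[i])
    m <- x[rows, , i, drop = FALSE]
    dim(m) <- c(length(rows), 127L)
    mins <- pmin(mins, apply(m, 2L, min))
    maxs <- pmax(maxs, apply(m, 2L, max))
  }
  rng <- maxs - mins
  rng[rng <= 0] <- 1  # constant feature maps to 0
  structure(list(min = mins, range = rng), class = "minmax_norm")
}

#' Apply fitted min-max normalization to a dataset or plain array
#'
#' Padding rows (beyond each arc's true length) are reset to zero after
#' scaling so the padded tail remains all-zero.
#'
#' @param ds an [arc_dataset()] or an `L x 127 x n` array.
#' @param norm a `minmax_norm` from [fit_norm()].
#' @param true_length required when `ds` is a plain array.
#' @return Object of the same type as `ds`, normalized.
#' @export
apply_norm <- function(ds, norm, true_length = NULL) {
  stopifnot(inherits(norm, "minmax_norm"))
  is_ds <- inherits(ds, "arc_dataset")
  x <- if (is_ds) ds$x else ds
  lens <- if (is_ds) ds$true_length else true_length
  if (is.null(lens)) stop("true_length required for a plain array")
  L <- dim(x)[1]; n <- dim(x)[3]
  for (j in seq_len(127L))
    x[, j, ] <- (x[, j, ] - norm$min[j]) / norm$range[j]
  for (i in seq_len(n))
    if (lens[i] < L) x[(lens[i] + 1L):L, , i] <- 0
  if (is_ds) { ds$x <- x; ds } else x
}
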