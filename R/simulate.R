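#' Machine delivery limits for the synthetic arc generator
#'
#' Geometry and dynamic limits of a Millennium-120-style MLC: 60 opposing
#' leaf pairs (0.5 cm central leaf width at isocenter over the central
#' 20 cm), symmetric jaw travel, a minimum dynamic gap between opposing
#' leaves, a maximum leaf travel per control point, and the gantry span of
#' one arc.  All distances are mm at isocenter.
#'
#' @param n_leaf_pairs opposing pairs, default 60.
#' @param leaf_width central leaf width in mm, default 5.
#' @param jaw_range maximum jaw half-opening in mm, default 200.
#' @param min_gap minimum opposing-leaf gap in mm, default 0.5.
#' @param max_travel maximum leaf travel between consecutive control points
#'   in mm, default 5.
#' @param gantry_span arc gantry span in degrees, default 358.
#' @return A `machine_limits` list.
#' @export
machine_limits <- function(n_leaf_pairs = 60L, leaf_width = 5,
                           jaw_range = 200, min_gap = 0.5, max_travel = 5,
                           gantry_span = 358) {
  stopifnot(n_leaf_pairs >= 1L, leaf_width > 0, jaw_range > 0,
            min_gap > 0, max_travel > 0, gantry_span > 0,
            min_gap < 2 * jaw_range)
  structure(list(n_leaf_pairs = as.integer(n_leaf_pairs),
                 leaf_width = leaf_width, jaw_range = jaw_range,
                 min_gap = min_gap, max_travel = max_travel,
                 gantry_span = gantry_span),
            class = "machine_limits")
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Simulate one deliverability-constrained VMAT arc
#'
#' Generates an arc whose control points satisfy every machine constraint:
#' cumulative meterset weight non-decreasing from 0 to 1, gantry monotone
#' across its span, every leaf inside the jaw-defined aperture, opposing
#' leaves separated by at least the minimum gap, and per-control-point leaf
#' travel within the dynamic limit.  Leaves perform a constrained random
#' walk around an elliptical base aperture; the walk amplitude scales with
#' `complexity`, so complexity 0 gives a near-static aperture and
#' complexity 1 heavy modulation.
#'
#' @param complexity dimensionless modulation level in `[0, 1]`.
#' @param limits a [machine_limits()].
#' @param n_cp number of control points (clinical arcs carry 90-180).
#' @param seed integer seed.
#' @param plan_id,arc_id identifiers for the generated arc.
#' @return An [arc_sequence()].
#' @export
simulate_arc <- function(complexity, limits = machine_limits(), n_cp = 120L,
                         seed = 1L, plan_id = "sim", arc_id = "1") {
  stopifnot(inherits(limits, "machine_limits"),
            complexity >= 0, complexity <= 1, n_cp >= 2L)
  np <- limits$n_leaf_pairs
  with_seed(seed, {
    # jaw aperture: a small stereotactic field
    hw_x <- stats::runif(1, 25, 60)
    hw_y <- stats::runif(1, 20, 50)
    jaws <- c(-hw_x, hw_x, -hw_y, hw_y)

    # meterset: normalized cumulative sum of positive increments
    inc <- stats::runif(n_cp - 1L, 0.5, 1.5)
    mw <- c(0, cumsum(inc)) / sum(inc)

    # gantry: monotone sweep over the span, wrapped into [0, 360)
    g0 <- stats::runif(1, 0, 360)
    dir <- sample(c(-1, 1), 1)
    gantry <- (g0 + dir * limits$gantry_span *
                 (seq_len(n_cp) - 1) / (n_cp - 1)) %% 360

    # leaf pair geometry: pairs whose track crosses the Y field are open
    # with an elliptical base half-opening; the rest park at minimum gap
    centre <- (seq_len(np) - (np + 1) / 2) * limits$leaf_width
    open <- abs(centre) < hw_y
    half <- rep(limits$min_gap / 2, np)
    half[open] <- pmax(limits$min_gap / 2,
                       hw_x * sqrt(1 - (centre[open] / hw_y)^2) *
                         stats::runif(sum(open), 0.7, 1))
    a <- clamp(-half, -hw_x, hw_x - limits$min_gap)             # bank A
    b <- clamp(half, a + limits$min_gap, hw_x)                  # bank B

    sd_step <- complexity * limits$max_travel / 2
    A <- B <- matrix(0, n_cp, np)
    A[1L, ] <- a; B[1L, ] <- b
    for (t in 2:n_cp) {
      step_a <- clamp(stats::rnorm(np, 0, sd_step),
                      -limits$max_travel, limits$max_travel)
      step_b <- clamp(stats::rnorm(np, 0, sd_step),
                      -limits$max_travel, limits$max_travel)
      lo_a <- pmax(-hw_x, a - limits$max_travel)
      hi_a <- pmin(a + limits$max_travel, hw_x - limits$min_gap)
      a <- clamp(a + step_a, lo_a, hi_a)
      lo_b <- pmax(-hw_x + limits$min_gap, a + limits$min_gap,
                   b - limits$max_travel)
      hi_b <- pmin(b + limits$max_travel, hw_x)
      b <- clamp(b + step_b, lo_b, hi_b)
      A[t, ] <- a; B[t, ] <- b
    }

    cps <- lapply(seq_len(n_cp), function(t)
      control_point(t - 1L, mw[t], jaws, gantry[t], c(A[t, ], B[t, ])))
    arc <- arc_sequence(plan_id, arc_id, cps)
  })
  arc
}

#' Check an arc against machine delivery constraints
#'
#' Verifies the five deliverability constraints (meterset monotone from 0
#' to 1, gantry monotone modulo the 0/360 wrap, leaves inside the jaw
#' aperture, opposing-leaf gap, per-control-point travel) and reports every
#' violation.  SMOTE-interpolated sequences typically fail some of these —
#' interpolating two deliverable sequences need not give a deliverable one
#' — which is why this diagnostic exists.
#'
#' @param arc an [arc_sequence()].
#' @param limits a [machine_limits()].
#' @param tol numeric slack applied to every inequality.
#' @return Data frame with columns `constraint`, `control_point` (0-based
#'   index within the sequence) and `leaf` (`NA` where not applicable);
#'   zero rows when the arc is deliverable.
#' @export
deliverability_check <- function(arc, limits = machine_limits(),
                                 tol = 1e-6) {
  stopifnot(inherits(arc, "arc_sequence"))
  np <- limits$n_leaf_pairs
  n <- length(arc$control_points)
  viol <- list()
  add <- function(constraint, cp, leaf = NA_integer_)
    viol[[length(viol) + 1L]] <<- data.frame(
      constraint = constraint, control_point = cp, leaf = leaf)

  mw <- vapply(arc$control_points, `[[`, numeric(1), "meterset_weight")
  for (t in which(diff(mw) < -tol)) add("meterset_monotone", t)
  if (abs(mw[1]) > 1e-6) add("meterset_monotone", 0L)
  if (abs(mw[n] - 1) > 1e-6) add("meterset_monotone", n - 1L)

  g <- vapply(arc$control_points, `[[`, numeric(1), "gantry_angle")
  if (n > 1L) {
    dg <- ((diff(g) + 180) %% 360) - 180
    sgn <- sign(dg[abs(dg) > tol])
    if (length(unique(sgn)) > 1L)
      for (t in which(sign(dg) != sgn[1] & abs(dg) > tol))
        add("gantry_monotone", t)
  }

  for (t in seq_len(n)) {
    cp <- arc$control_points[[t]]
    x1 <- cp$jaws[1]; x2 <- cp$jaws[2]
    a <- cp$leaf_positions[seq_len(np)]
    b <- cp$leaf_positions[np + seq_len(np)]
    for (p in which(a < x1 - tol | a > x2 + tol)) add("leaf_in_jaw", t - 1L, p)
    for (p in which(b < x1 - tol | b > x2 + tol))
      add("leaf_in_jaw", t - 1L, np + p)
    for (p in which(b - a < limits$min_gap - tol)) add("min_gap", t - 1L, p)
    if (t > 1L) {
      prev <- arc$control_points[[t - 1L]]$leaf_positions
      over <- which(abs(cp$leaf_positions - prev) > limits$max_travel + tol)
      for (p in over) add("max_travel", t - 1L, p)
    }
  }
  if (length(viol) == 0L)
    return(data.frame(constraint = character(0),
                      control_point = integer(0), leaf = integer(0)))
  do.call(rbind, viol)
}

#' Arc complexity statistic
#'
#' Mean per-control-point leaf travel normalized by the mean aperture
#' width: a simple modulation index that increases with leaf motion and is
#' computable from the encoded features alone.
#'
#' @param arc an [arc_sequence()] or an `encoded_arc`/matrix in the 127
#'   feature layout.
#' @param true_length rows to use when `arc` is a matrix.
#' @return Non-negative scalar (near 0 for static apertures).
#' @export
arc_complexity <- function(arc, true_length = NULL) {
  if (inherits(arc, "arc_sequence")) {
    m <- t(vapply(arc$control_points, encode_control_point, numeric(127L)))
  } else {
    m <- unclass(arc)
    tl <- true_length %||% attr(arc, "true_length") %||% nrow(m)
    m <- m[seq_len(tl), , drop = FALSE]
  }
  leaves <- m[, 8:127, drop = FALSE]
  np <- 60L
  width <- mean(leaves[, np + seq_len(np)] - leaves[, seq_len(np)])
  if (width <= 0) return(0)
  if (nrow(leaves) < 2L) return(0)
  travel <- mean(abs(diff(leaves)))
  travel / width
}

#' Default GPR label-model parameters
#'
#' The synthetic label model is a stand-in defined by this package (the
#' generator emulates a clinical cohort; no claim is made that real GPRs
#' follow it).  It maps arc complexity to a gamma passing rate with a heavy
#' left tail:
#' `GPR = clip(baseline - slope * C(arc) + eps, 0, 100)` where `C` is
#' [arc_complexity()] and `eps = -(LN - E[LN])` for a log-normal `LN`, so
#' the noise is zero-mean but occasionally produces large downward
#' excursions, as portal-dosimetry failures do.  Defaults are calibrated so
#' a default cohort reproduces the clinical summary statistics (mean GPR
#' about 96, SD about 8, class mix about 79/14/7%).
#'
#' @param baseline GPR in percent for a zero-complexity arc before noise
#'   and clipping (values above 100 make low-complexity arcs saturate at
#'   100, as clinical cohorts do).
#' @param slope GPR percent lost per unit complexity.
#' @param noise_meanlog,noise_sdlog log-normal parameters of the deficit
#'   noise.
#' @return A `label_params` list.
#' @export
label_params <- function(baseline = 118, slope = 800,
                         noise_meanlog = -0.7, noise_sdlog = 1.0) {
  stopifnot(baseline > 0, slope >= 0, noise_sdlog >= 0)
  structure(list(baseline = baseline, slope = slope,
                 noise_meanlog = noise_meanlog, noise_sdlog = noise_sdlog),
            class = "label_params")
}

#' Assign a synthetic GPR to an arc
#'
#' @param arc an [arc_sequence()].
#' @param params a [label_params()].
#' @param seed integer seed (noise is deterministic under it).
#' @return GPR in percent, clipped to `[0, 100]`.
#' @export
assign_gpr <- function(arc, params = label_params(), seed = 1L) {
  C <- arc_complexity(arc)
  eps <- 0
  if (params$noise_sdlog > 0) {
    with_seed(seed, {
      ln <- stats::rlnorm(1, params$noise_meanlog, params$noise_sdlog)
    })
    eps <- -(ln - exp(params$noise_meanlog + params$noise_sdlog^2 / 2))
  }
  clamp(params$baseline - params$slope * C + eps, 0, 100)
}

#' Specification of a synthetic arc cohort
#'
#' Defaults emulate the clinical cohort the classifier was designed for:
#' 117 plans of 3-5 arcs each (about 468 arcs), 90-180 control points per
#' arc, complexity drawn from a right-skewed Beta distribution, and GPR
#' labels from [label_params()].
#'
#' @param n_plans number of plans.
#' @param arcs_per_plan integer vector of possible arc counts per plan.
#' @param arcs_per_plan_prob sampling probabilities for `arcs_per_plan`.
#' @param n_cp_range inclusive control-point count range, within
#'   `[90, 180]` by convention.
#' @param complexity_shape1,complexity_shape2 Beta parameters of the
#'   per-arc complexity draw.
#' @param limits a [machine_limits()].
#' @param labels a [label_params()].
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_plans = 117L, arcs_per_plan = c(3L, 4L, 5L),
                        arcs_per_plan_prob = c(0.3, 0.4, 0.3),
                        n_cp_range = c(90L, 180L),
                        complexity_shape1 = 0.6, complexity_shape2 = 4,
                        limits = machine_limits(),
                        labels = label_params()) {
  stopifnot(n_plans >= 1L, length(arcs_per_plan) == length(arcs_per_plan_prob),
            all(arcs_per_plan >= 1L), all(arcs_per_plan_prob >= 0),
            length(n_cp_range) == 2L, n_cp_range[1] <= n_cp_range[2],
            complexity_shape1 > 0, complexity_shape2 > 0)
  structure(list(n_plans = as.integer(n_plans),
                 arcs_per_plan = as.integer(arcs_per_plan),
                 arcs_per_plan_prob = arcs_per_plan_prob,
                 n_cp_range = as.integer(n_cp_range),
                 complexity_shape1 = complexity_shape1,
                 complexity_shape2 = complexity_shape2,
                 limits = limits, labels = labels),
            class = "cohort_spec")
}

#' Simulate a labeled synthetic cohort
#'
#' Draws per-plan arc counts, per-arc control-point counts and complexity
#' levels, simulates every arc with [simulate_arc()] and labels it with
#' [assign_gpr()].  The result is bit-reproducible under the seed.
#'
#' @param spec a [cohort_spec()].
#' @param seed integer seed for the whole cohort.
#' @return A `cohort` list: `arcs` (list of [arc_sequence()] with `gpr`
#'   set) and `labels` (data frame `plan_id`, `arc_id`, `gpr_percent`).
#' @export
simulate_cohort <- function(spec = cohort_spec(), seed = 1L) {
  stopifnot(inherits(spec, "cohort_spec"))
  arcs <- list()
  with_seed(seed, {
    meta <- list()
    for (p in seq_len(spec$n_plans)) {
      k <- spec$arcs_per_plan[sample.int(length(spec$arcs_per_plan), 1L,
                                         prob = spec$arcs_per_plan_prob)]
      ncps <- seq(spec$n_cp_range[1], spec$n_cp_range[2])
      for (a in seq_len(k))
        meta[[length(meta) + 1L]] <- list(
          plan = sprintf("plan%03d", p), arc = sprintf("arc%d", a),
          n_cp = ncps[sample.int(length(ncps), 1L)],
          complexity = stats::rbeta(1, spec$complexity_shape1,
                                    spec$complexity_shape2),
          arc_seed = sample.int(2^30, 1L),
          gpr_seed = sample.int(2^30, 1L))
    }
  })
  for (m in meta) {
    arc <- simulate_arc(m$complexity, spec$limits, m$n_cp, seed = m$arc_seed,
                        plan_id = m$plan, arc_id = m$arc)
    arc$gpr <- assign_gpr(arc, spec$labels, seed = m$gpr_seed)
    arcs[[length(arcs) + 1L]] <- arc
  }
  labels <- data.frame(
    plan_id = vapply(arcs, `[[`, character(1), "plan_id"),
    arc_id = vapply(arcs, `[[`, character(1), "arc_id"),
    gpr_percent = vapply(arcs, `[[`, numeric(1), "gpr"))
  structure(list(arcs = arcs, labels = labels), class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  g <- x$labels$gpr_percent
  cnt <- class_distribution(discretize_gpr(g))
  cat(sprintf("<cohort> %d arcs from %d plans\n", length(x$arcs),
              length(unique(x$labels$plan_id))))
  cat(sprintf("  GPR mean %.1f%%, SD %.1f%%, range %.1f-%.1f%%\n",
              mean(g), stats::sd(g), min(g), max(g)))
  cat("  classes:", paste(sprintf("%s %d", names(cnt), cnt),
                          collapse = ", "), "\n")
  invisible(x)
}

#' Encode a cohort into a labeled dataset
#'
#' Encodes every arc, pads to a common length, and attaches the
#' discretized class labels.
#'
#' @param cohort a `cohort` from [simulate_cohort()], or a list of
#'   [arc_sequence()] objects each carrying `gpr`.
#' @param target_length padding length or `"auto"`.
#' @param thresholds class thresholds for [discretize_gpr()].
#' @return An [arc_dataset()].
#' @export
encode_cohort <- function(cohort, target_length = "auto",
                          thresholds = c(85, 95)) {
  arcs <- if (inherits(cohort, "cohort")) cohort$arcs else cohort
  gpr <- vapply(arcs, function(a) a$gpr %||% NA_real_, numeric(1))
  if (any(is.na(gpr)))
    stop("every arc must carry a GPR to be labeled", call. = FALSE)
  enc <- pad_arcs(lapply(arcs, encode_arc), target_length)
  arc_dataset(enc, labels = discretize_gpr(gpr, thresholds),
              plan_id = vapply(arcs, `[[`, character(1), "plan_id"),
              arc_id = vapply(arcs, `[[`, character(1), "arc_id"),
              gpr = gpr)
}

#' Write a cohort as JSON plan files plus a label CSV
#'
#' One JSON plan file per `plan_id` (the [parse_plan()] dialect) and a
#' `labels.csv` with columns `plan_id`, `arc_id`, `gpr_percent`.
#'
#' @param cohort a `cohort` from [simulate_cohort()].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  plans <- split(cohort$arcs,
                 vapply(cohort$arcs, `[[`, character(1), "plan_id"))
  for (pid in names(plans))
    write_plan(plans[[pid]], file.path(dir, paste0(pid, ".json")))
  utils::write.csv(cohort$labels, file.path(dir, "labels.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' Fraction of SMOTE-synthetic samples violating deliverability
#'
#' Decodes every synthetic sample in a dataset back into a control-point
#' sequence and runs [deliverability_check()].  Nothing is filtered; the
#' number quantifies how often interpolation leaves the machine-deliverable
#' manifold.
#'
#' @param ds an [arc_dataset()] containing SMOTE output.
#' @param limits a [machine_limits()].
#' @return Fraction in `[0, 1]` (`NaN` when no synthetic samples exist).
#' @export
synthetic_deliverability_fraction <- function(ds,
                                              limits = machine_limits()) {
  stopifnot(inherits(ds, "arc_dataset"))
  idx <- which(ds$provenance == "synthetic")
  if (length(idx) == 0L) return(NaN)
  bad <- vapply(idx, function(i) {
    arc <- decode_encoded_matrix(ds$x[, , i], ds$true_length[i])
    nrow(deliverability_check(arc, limits)) > 0L
  }, logical(1))
  mean(bad)
}

# rebuild an (unvalidated) arc_sequence from a 127-feature matrix
decode_encoded_matrix <- function(m, true_length = nrow(m),
                                  plan_id = "decoded", arc_id = "1") {
  rows <- seq_len(true_length)
  cps <- lapply(rows, function(r)
    structure(list(index = as.integer(round(m[r, 1])),
                   meterset_weight = m[r, 2],
                   jaws = m[r, 3:6],
                   gantry_angle = m[r, 7],
                   leaf_positions = m[r, 8:127]),
              class = "control_point"))
  arc_sequence(plan_id, arc_id, cps, validate = FALSE)
}
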