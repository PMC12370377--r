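#' Construct a VMAT control-point record
#'
#' One control point is a snapshot of machine state along a VMAT arc:
#' cumulative meterset weight, the four collimator jaw positions, the gantry
#' angle, and the positions of the 120 Millennium MLC leaves (bank A leaves
#' 1-60 followed by bank B leaves 1-60).  All positions are millimetres
#' projected to isocenter under the IEC 61217 signed convention (X1 at or
#' below X2, Y1 at or below Y2, X1 typically negative); the gantry angle is
#' in degrees in `[0, 360)`; the control-point index is the 0-based ordinal
#' within the arc.
#'
#' @param index 0-based integer ordinal within the arc.
#' @param meterset_weight cumulative fraction of monitor units in `[0, 1]`.
#' @param jaws numeric vector of four jaw positions `c(X1, X2, Y1, Y2)` in mm.
#' @param gantry_angle gantry angle in degrees, `[0, 360)`.
#' @param leaf_positions numeric vector of exactly 120 leaf positions in mm.
#' @return An object of class `control_point`.
#' @export
#' @examples
#' cp <- control_point(0, 0, c(-50, 50, -50, 50), 180, rep(0, 120))
control_point <- function(index, meterset_weight, jaws, gantry_angle,
                          leaf_positions) {
  cp <- structure(
    list(index = as.integer(index),
         meterset_weight = as.numeric(meterset_weight),
         jaws = as.numeric(jaws),
         gantry_angle = as.numeric(gantry_angle),
         leaf_positions = as.numeric(leaf_positions)),
    class = "control_point")
  validate_control_point(cp)
  cp
}

validate_control_point <- function(cp) {
  if (length(cp$leaf_positions) != 120L)
    stop("control point must have exactly 120 leaf positions, got ",
         length(cp$leaf_positions), call. = FALSE)
  if (length(cp$jaws) != 4L)
    stop("control point must have exactly 4 jaw positions", call. = FALSE)
  if (is.na(cp$meterset_weight) || cp$meterset_weight < -1e-9 ||
      cp$meterset_weight > 1 + 1e-9)
    stop("meterset weight must lie in [0, 1]", call. = FALSE)
  if (cp$jaws[1] > cp$jaws[2] || cp$jaws[3] > cp$jaws[4])
    stop("jaw positions must satisfy X1 <= X2 and Y1 <= Y2", call. = FALSE)
  invisible(cp)
}

#' Construct a VMAT arc as an ordered control-point sequence
#'
#' An arc is an ordered sequence of control points with strictly increasing
#' indices and a cumulative meterset weight that is non-decreasing, starting
#' at 0 and ending at 1.  Clinical arcs typically carry 90-180 control
#' points, but any positive length is accepted.
#'
#' @param plan_id,arc_id identifiers (coerced to character).
#' @param control_points list of [control_point()] records in delivery order.
#' @param gpr optional measured gamma passing rate in percent, `[0, 100]`.
#' @param validate if `FALSE`, skip the sequence invariants (for tests and
#'   diagnostic tooling that must represent invalid arcs).
#' @return An object of class `arc_sequence`.
#' @export
arc_sequence <- function(plan_id, arc_id, control_points, gpr = NULL,
                         validate = TRUE) {
  arc <- structure(
    list(plan_id = as.character(plan_id), arc_id = as.character(arc_id),
         control_points = control_points, gpr = gpr),
    class = "arc_sequence")
  if (validate) validate_arc_sequence(arc)
  arc
}

validate_arc_sequence <- function(arc) {
  n <- length(arc$control_points)
  if (n < 1L) stop("arc must contain at least one control point",
                   call. = FALSE)
  mw <- vapply(arc$control_points, `[[`, numeric(1), "meterset_weight")
  idx <- vapply(arc$control_points, `[[`, integer(1), "index")
  if (any(diff(mw) < -1e-9))
    stop("meterset weight must be non-decreasing along the arc (arc ",
         arc$arc_id, ")", call. = FALSE)
  if (abs(mw[1]) > 1e-6)
    stop("first meterset weight must be 0 (arc ", arc$arc_id, ")",
         call. = FALSE)
  if (abs(mw[n] - 1) > 1e-6)
    stop("last meterset weight must be 1 (arc ", arc$arc_id, ")",
         call. = FALSE)
  if (n > 1L && any(diff(idx) <= 0L))
    stop("control point indices must be strictly increasing (arc ",
         arc$arc_id, ")", call. = FALSE)
  if (!is.null(arc$gpr) && (arc$gpr < 0 || arc$gpr > 100))
    stop("GPR must be a percentage in [0, 100]", call. = FALSE)
  invisible(arc)
}

#' @export
print.arc_sequence <- function(x, ...) {
  cat(sprintf("<arc_sequence> plan %s arc %s: %d control points%s\n",
              x$plan_id, x$arc_id, length(x$control_points),
              if (is.null(x$gpr)) "" else sprintf(", GPR %.1f%%", x$gpr)))
  invisible(x)
}

#' @export
length.arc_sequence <- function(x) length(x$control_points)
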