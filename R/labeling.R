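#' Class labels for gamma passing rates
#'
#' The three QA classes, ordered by severity: `Replan` (the arc should be
#' re-planned), `Investigate` (the physicist should look closer), `Ideal`
#' (expected to pass cleanly).  The ordinal encoding is Replan = 0,
#' Investigate = 1, Ideal = 2, increasing with GPR.
#'
#' @format Character vector of the three class names in ordinal order.
#' @export
gpr_levels <- c("Replan", "Investigate", "Ideal")

#' Discretize gamma passing rates into QA classes
#'
#' Maps a GPR percentage to one of three action classes using clinically
#' established thresholds: `Replan` for GPR < 85, `Investigate` for
#' 85 <= GPR < 95, `Ideal` for GPR >= 95.  Boundary inclusivity is exactly
#' as written: 85 is `Investigate`, 95 is `Ideal`.  Thresholds are
#' configurable because other clinics may retune them, but GPR is always a
#' percentage in `[0, 100]`, never a fraction.
#'
#' @param gpr numeric vector of gamma passing rates in percent.
#' @param thresholds numeric `c(replan, ideal)` cut points, default
#'   `c(85, 95)`.
#' @return Ordered factor with levels `Replan < Investigate < Ideal`.
#' @export
#' @examples
#' discretize_gpr(c(96.1, 85, 95, 84.999, 26.7))
discretize_gpr <- function(gpr, thresholds = c(85, 95)) {
  stopifnot(length(thresholds) == 2L, thresholds[1] < thresholds[2])
  if (any(is.na(gpr)) || any(gpr < 0) || any(gpr > 100))
    stop("GPR values must be percentages in [0, 100]", call. = FALSE)
  cls <- ifelse(gpr < thresholds[1], "Replan",
                ifelse(gpr < thresholds[2], "Investigate", "Ideal"))
  factor(cls, levels = gpr_levels, ordered = TRUE)
}

#' Count samples per QA class
#'
#' @param labels factor or character vector of class labels.
#' @return Named integer vector over `Replan`, `Investigate`, `Ideal`
#'   (zero for absent classes); the counts sum to `length(labels)`.
#' @export
class_distribution <- function(labels) {
  labels <- as_gpr_factor(labels)
  table(labels) |> as.integer() |> stats::setNames(gpr_levels)
}

as_gpr_factor <- function(labels) {
  if (is.factor(labels)) labels <- as.character(labels)
  bad <- setdiff(unique(labels), gpr_levels)
  if (length(bad))
    stop("unknown class label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  factor(labels, levels = gpr_levels, ordered = TRUE)
}

#' Read a per-arc GPR label table
#'
#' @param path CSV file with columns `plan_id`, `arc_id`, `gpr_percent`.
#' @return Data frame with those three columns.
#' @export
read_label_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("plan_id", "arc_id", "gpr_percent")
  if (!all(need %in% names(df)))
    stop("label table must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  df$plan_id <- as.character(df$plan_id)
  df$arc_id <- as.character(df$arc_id)
  df[need]
}
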