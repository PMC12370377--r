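#' Read treatment-plan arcs from a plan file
#'
#' Reads a treatment plan and returns its VMAT arcs as a list of
#' [arc_sequence()] objects, control points in delivery order.  Two dialects
#' are supported:
#'
#' * `"json"` — this package's plan fixture dialect (see Details), the
#'   format written by [write_plan()] and by the synthetic cohort generator.
#' * `"dicom-rt"` — a DICOM-RT Plan file (modality RTPLAN).  Parsing is
#'   delegated to the bundled `rtplan_to_json.py` helper, which requires a
#'   `python` interpreter with the `pydicom` package on the `PATH`.
#'
#' Setup and imaging fields (beams without MLC data in the JSON dialect;
#' non-treatment or static beams in DICOM) are skipped.
#'
#' @details The JSON dialect is an object
#' `{"plan_id": ..., "arcs": [ ... ]}` where each arc is
#' `{"arc_id": ..., "gpr": <percent or null>, "control_points": [ ... ]}`
#' and each control point is an object with fields `index`,
#' `meterset_weight`, `jaws` (4 numbers, X1 X2 Y1 Y2, mm), `gantry_angle`
#' (degrees) and `leaf_positions` (120 numbers, mm, bank A then bank B).
#'
#' @param path path to the plan file.
#' @param dialect `"json"` or `"dicom-rt"`.
#' @return List of [arc_sequence()] objects.
#' @seealso [write_plan()], [encode_arc()]
#' @export
parse_plan <- function(path, dialect = c("json", "dicom-rt")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("plan file not found: ", path, call. = FALSE)
  if (dialect == "dicom-rt") {
    path <- rtplan_to_json(path)
    on.exit(unlink(path), add = TRUE)
  }
  doc <- tryCatch(
    jsonlite::fromJSON(path, simplifyVector = FALSE),
    error = function(e) stop("could not parse plan file '", basename(path),
                             "': ", conditionMessage(e), call. = FALSE))
  if (is.null(doc$arcs))
    stop("plan file '", basename(path), "' has no 'arcs' element",
         call. = FALSE)
  plan_id <- doc$plan_id %||% tools::file_path_sans_ext(basename(path))
  arcs <- list()
  for (a in doc$arcs) {
    arc_id <- a$arc_id %||% as.character(length(arcs) + 1L)
    cps <- a$control_points
    if (is.null(cps) || length(cps) == 0L) next  # setup/imaging field
    records <- vector("list", length(cps))
    for (i in seq_along(cps)) {
      cp <- cps[[i]]
      if (is.null(cp$leaf_positions))
        stop("beam '", arc_id, "' control point ", i,
             " is missing MLC leaf data", call. = FALSE)
      records[[i]] <- control_point(
        index = cp$index %||% (i - 1L),
        meterset_weight = cp$meterset_weight,
        jaws = unlist(cp$jaws),
        gantry_angle = cp$gantry_angle %||% 0,
        leaf_positions = unlist(cp$leaf_positions))
    }
    gpr <- if (is.null(a$gpr)) NULL else as.numeric(a$gpr)
    arcs[[length(arcs) + 1L]] <-
      arc_sequence(plan_id, arc_id, records, gpr = gpr)
  }
  arcs
}

rtplan_to_json <- function(path) {
  helper <- system.file("python", "rtplan_to_json.py", package = "arcgate")
  if (helper == "")
    stop("bundled DICOM helper script not found", call. = FALSE)
  if (Sys.which("python") == "")
    stop("reading DICOM-RT plans requires a 'python' interpreter with ",
         "pydicom on the PATH", call. = FALSE)
  out <- tempfile(fileext = ".json")
  res <- suppressWarnings(
    system2("python", c(helper, shQuote(path), shQuote(out)),
            stdout = TRUE, stderr = TRUE))
  status <- attr(res, "status") %||% 0L
  if (status != 0L || !file.exists(out))
    stop("DICOM-RT conversion failed: ", paste(res, collapse = "\n"),
         call. = FALSE)
  out
}

#' Write arcs to a JSON plan file
#'
#' Serializes a list of [arc_sequence()] objects to the package's JSON plan
#' dialect (see [parse_plan()]).  Numeric values are written at full double
#' precision so that a parse round-trip reproduces every field.
#'
#' @param arcs list of [arc_sequence()] objects sharing one `plan_id`, or a
#'   single `arc_sequence`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_plan <- function(arcs, path) {
  if (inherits(arcs, "arc_sequence")) arcs <- list(arcs)
  stopifnot(length(arcs) >= 1L)
  doc <- list(
    plan_id = arcs[[1L]]$plan_id,
    arcs = lapply(arcs, function(a) {
      list(arc_id = a$arc_id, gpr = a$gpr,
           control_points = lapply(a$control_points, function(cp) {
             list(index = cp$index,
                  meterset_weight = cp$meterset_weight,
                  jaws = cp$jaws,
                  gantry_angle = cp$gantry_angle,
                  leaf_positions = cp$leaf_positions)
           }))
    }))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
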