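test_that("a control point flattens to the documented 127-element layout", {
  cp <- control_point(3L, 0.25, c(-51, 52, -43, 44), 181.5,
                      seq(1, 120) / 10)
  v <- encode_control_point(cp)
  expect_length(v, 127L)
  expect_identical(v[1:7], c(3, 0.25, -51, 52, -43, 44, 181.5))
  expect_identical(v[8:127], seq(1, 120) / 10)

  zero <- control_point(0L, 0, c(0, 0, 0, 0), 0, rep(0, 120))
  expect_identical(encode_control_point(zero), rep(0, 127))
})

test_that("leaf 60 of bank A lands at vector position 67 (1-based)", {
  base <- rep(0, 120)
  tweak <- base; tweak[60] <- 7.5
  cp1 <- control_point(0L, 0, c(-10, 10, -10, 10), 0, base)
  cp2 <- control_point(0L, 0, c(-10, 10, -10, 10), 0, tweak)
  d <- which(encode_control_point(cp1) != encode_control_point(cp2))
  expect_identical(d, 67L)  # 7 scalar features + leaf 60
})

test_that("control point validation rejects malformed records", {
  expect_error(control_point(0L, 0, c(-10, 10, -10, 10), 0, rep(0, 119)),
               "120 leaf")
  expect_error(control_point(0L, 1.5, c(-10, 10, -10, 10), 0, rep(0, 120)),
               "\\[0, 1\\]")
  expect_error(control_point(0L, 0, c(10, -10, -10, 10), 0, rep(0, 120)),
               "X1 <= X2")
})

test_that("encode_arc stacks encoded control points row by row", {
  arc <- toy_arc(5L)
  enc <- encode_arc(arc)
  expect_equal(dim(enc), c(5L, 127L))
  expect_identical(attr(enc, "true_length"), 5L)
  # row-major flattening equals concatenated per-control-point encodings
  expect_identical(as.vector(t(unclass(enc))),
                   unlist(lapply(arc$control_points, encode_control_point)))
})

test_that("encoding is injective on distinct control points", {
  set.seed(7)
  cps <- lapply(1:50, function(i) {
    jx <- sort(runif(2, -60, 60)); jy <- sort(runif(2, -60, 60))
    control_point(i, runif(1), c(jx, jy), runif(1, 0, 359),
                  runif(120, -60, 60))
  })
  vecs <- t(vapply(cps, encode_control_point, numeric(127)))
  expect_identical(nrow(unique(vecs)), 50L)
})

test_that("padding appends zero rows, preserves real rows, never truncates", {
  a90 <- encode_arc(toy_arc(90L))
  a180 <- encode_arc(toy_arc(180L))
  padded <- pad_arcs(list(a90, a180), "auto")
  expect_true(all(vapply(padded, nrow, integer(1)) == 180L))
  expect_identical(unclass(padded[[1]])[1:90, ], unclass(a90)[1:90, ])
  expect_true(all(unclass(padded[[1]])[91:180, ] == 0))
  expect_identical(attr(padded[[1]], "true_length"), 90L)
  # idempotent at fixed target length
  again <- pad_arcs(padded, 180L)
  expect_identical(again, padded)
  # identity when target equals own length
  expect_identical(pad_arcs(list(a90), 90L)[[1]], a90)
  expect_error(pad_arcs(list(a180), 90L), "never truncated")
})

test_that("JSON plan round-trip preserves all control-point fields", {
  arcs <- list(simulate_arc(0.4, n_cp = 90L, seed = 1, arc_id = "1"),
               simulate_arc(0.7, n_cp = 180L, seed = 2, arc_id = "2"))
  arcs[[1]]$gpr <- 97.3
  path <- withr::local_tempfile(fileext = ".json")
  write_plan(arcs, path)
  back <- parse_plan(path, "json")
  expect_length(back, 2L)
  expect_identical(vapply(back, length, integer(1)), c(90L, 180L))
  expect_equal(back[[1]]$gpr, 97.3)
  for (k in 1:2)
    for (t in seq_along(arcs[[k]]$control_points)) {
      expect_equal(encode_control_point(back[[k]]$control_points[[t]]),
                   encode_control_point(arcs[[k]]$control_points[[t]]),
                   tolerance = 1e-6)
    }
})

test_that("plan parsing validates arc invariants and file structure", {
  bad <- withr::local_tempfile(fileext = ".json")
  # single control point with meterset 0: last weight != 1
  writeLines(jsonlite::toJSON(list(plan_id = "p", arcs = list(list(
    arc_id = "a", control_points = list(list(
      index = 0, meterset_weight = 0, jaws = c(-10, 10, -10, 10),
      gantry_angle = 0, leaf_positions = rep(0, 120)))))),
    auto_unbox = TRUE), bad)
  expect_error(parse_plan(bad, "json"), "last meterset")

  nomlc <- withr::local_tempfile(fileext = ".json")
  writeLines(jsonlite::toJSON(list(plan_id = "p", arcs = list(list(
    arc_id = "b", control_points = list(list(
      index = 0, meterset_weight = 0, jaws = c(-10, 10, -10, 10),
      gantry_angle = 0))))), auto_unbox = TRUE), nomlc)
  expect_error(parse_plan(nomlc, "json"), "MLC")

  garbage <- withr::local_tempfile(fileext = ".json")
  writeLines("not json {", garbage)
  expect_error(parse_plan(garbage, "json"), "could not parse")
  expect_error(parse_plan("no/such/file.json"), "not found")
})

test_that("a DICOM-RT plan written by pydicom parses into the same arcs", {
  arc <- simulate_arc(0.5, n_cp = 12L, seed = 5)
  json_path <- withr::local_tempfile(fileext = ".json")
  dcm_path <- withr::local_tempfile(fileext = ".dcm")
  write_plan(arc, json_path)
  script <- system.file("python", "json_to_rtplan.py", package = "arcgate")
  expect_true(nzchar(script))
  res <- system2("python", c(script, shQuote(json_path), shQuote(dcm_path)),
                 stdout = TRUE, stderr = TRUE)
  expect_true(file.exists(dcm_path),
              info = paste(res, collapse = "\n"))
  back <- parse_plan(dcm_path, "dicom-rt")
  expect_length(back, 1L)
  expect_equal(length(back[[1]]), 12L)
  for (t in seq_len(12L))
    expect_equal(encode_control_point(back[[1]]$control_points[[t]])[-1],
                 encode_control_point(arc$control_points[[t]])[-1],
                 tolerance = 1e-4)
})

test_that("min-max normalization maps training features into [0,1] and keeps padding at zero", {
  arcs <- pad_arcs(lapply(1:6, function(i)
    encode_arc(simulate_arc(0.5, n_cp = 10L + i, seed = i),
               label = sample(gpr_levels, 1))), 20L)
  ds <- arc_dataset(arcs)
  nm <- fit_norm(ds)
  nd <- apply_norm(ds, nm)
  for (i in seq_len(length(nd))) {
    real <- nd$x[seq_len(nd$true_length[i]), , i]
    expect_true(all(real >= -1e-9 & real <= 1 + 1e-9))
    if (nd$true_length[i] < 20L)
      expect_true(all(nd$x[(nd$true_length[i] + 1L):20L, , i] == 0))
  }
})
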