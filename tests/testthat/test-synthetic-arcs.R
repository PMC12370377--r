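test_that("simulated arcs satisfy every deliverability constraint", {
  set.seed(6)
  for (i in 1:40) {
    arc <- simulate_arc(runif(1), n_cp = sample(90:180, 1), seed = i)
    v <- deliverability_check(arc)
    expect_identical(nrow(v), 0L)
  }
  # the exact requested lengths at the range ends
  expect_length(simulate_arc(0.5, n_cp = 90L, seed = 1), 90L)
  expect_length(simulate_arc(0.5, n_cp = 180L, seed = 1), 180L)
})

test_that("zero complexity gives a near-static aperture", {
  lim <- machine_limits()
  travel <- function(arc) {
    m <- t(vapply(arc$control_points, encode_control_point, numeric(127)))
    sum(abs(diff(m[, 8:127])))
  }
  t0 <- mean(sapply(1:5, function(i)
    travel(simulate_arc(0, n_cp = 100L, seed = i))))
  t1 <- mean(sapply(1:5, function(i)
    travel(simulate_arc(1, n_cp = 100L, seed = i))))
  expect_lt(t0, 0.05 * t1)
})

test_that("the deliverability checker localizes injected violations", {
  arc <- simulate_arc(0.3, n_cp = 20L, seed = 2)
  bad <- arc
  bad$control_points[[10]]$meterset_weight <-
    bad$control_points[[9]]$meterset_weight - 0.05
  v <- deliverability_check(bad)
  expect_identical(unique(v$constraint), "meterset_monotone")
  expect_identical(nrow(v), 1L)

  bad2 <- arc
  bad2$control_points[[5]]$leaf_positions[3] <- 500  # outside any jaw
  v2 <- deliverability_check(bad2)
  expect_true("leaf_in_jaw" %in% v2$constraint)
  expect_true("max_travel" %in% v2$constraint)
  expect_true(all(v2$control_point %in% c(4L, 5L)))
})

test_that("complexity statistic increases with the modulation parameter", {
  C <- sapply(c(0, 0.3, 0.7, 1), function(cx)
    mean(sapply(1:8, function(i)
      arc_complexity(simulate_arc(cx, n_cp = 100L, seed = i)))))
  expect_true(all(diff(C) > 0))
})

test_that("the GPR label model is deterministic and responds to its knobs", {
  arc <- simulate_arc(0.6, n_cp = 100L, seed = 3)
  # slope 0, no noise -> exactly the baseline
  expect_equal(assign_gpr(arc, label_params(baseline = 97, slope = 0,
                                            noise_sdlog = 0)), 97)
  g1 <- assign_gpr(arc, seed = 5)
  expect_identical(g1, assign_gpr(arc, seed = 5))
  expect_true(g1 >= 0 && g1 <= 100)
})

test_that("steeper complexity slopes never raise mean cohort GPR", {
  set.seed(4)
  arcs <- lapply(1:40, function(i)
    simulate_arc(rbeta(1, 0.6, 4), n_cp = sample(90:120, 1), seed = 40 + i))
  means <- sapply(c(200, 800, 1600), function(sl)
    mean(sapply(seq_along(arcs), function(i)
      assign_gpr(arcs[[i]], label_params(slope = sl), seed = i))))
  expect_true(all(diff(means) <= 0))
})

test_that("cohorts are reproducible and carry all three classes", {
  spec <- cohort_spec(n_plans = 2L, arcs_per_plan = 2L,
                      arcs_per_plan_prob = 1, n_cp_range = c(90L, 95L))
  coh <- simulate_cohort(spec, seed = 3)
  expect_length(coh$arcs, 4L)
  expect_identical(coh$labels,
                   simulate_cohort(spec, seed = 3)$labels)
  expect_true(all(coh$labels$gpr_percent >= 0 &
                    coh$labels$gpr_percent <= 100))

  spec2 <- cohort_spec(n_plans = 40L, n_cp_range = c(90L, 100L))
  coh2 <- simulate_cohort(spec2, seed = 9)
  cnt <- class_distribution(discretize_gpr(coh2$labels$gpr_percent))
  expect_true(all(cnt > 0))
  expect_identical(names(which.max(cnt)), "Ideal")
})

test_that("a cohort encodes into a dataset satisfying the encoding invariants", {
  spec <- cohort_spec(n_plans = 3L, arcs_per_plan = 2L,
                      arcs_per_plan_prob = 1, n_cp_range = c(90L, 110L))
  coh <- simulate_cohort(spec, seed = 7)
  ds <- encode_cohort(coh)
  expect_s3_class(ds, "arc_dataset")
  expect_identical(dim(ds$x)[1], max(ds$true_length))
  for (i in seq_len(length(ds))) {
    tl <- ds$true_length[i]
    if (tl < dim(ds$x)[1])
      expect_true(all(ds$x[(tl + 1):dim(ds$x)[1], , i] == 0))
    # prefix rows reproduce the direct encoding bit-exactly
    expect_identical(ds$x[seq_len(tl), , i],
                     unclass(encode_arc(coh$arcs[[i]]))[seq_len(tl), ])
  }
})

test_that("cohorts round-trip through plan files and the label CSV", {
  spec <- cohort_spec(n_plans = 2L, arcs_per_plan = 2L,
                      arcs_per_plan_prob = 1, n_cp_range = c(90L, 92L))
  coh <- simulate_cohort(spec, seed = 2)
  dir <- withr::local_tempdir()
  write_cohort(coh, dir)
  labs <- read_label_table(file.path(dir, "labels.csv"))
  expect_identical(nrow(labs), 4L)
  plans <- list.files(dir, pattern = "^plan.*json$", full.names = TRUE)
  expect_length(plans, 2L)
  back <- unlist(lapply(plans, parse_plan), recursive = FALSE)
  expect_length(back, 4L)
  lens <- sort(vapply(back, length, integer(1)))
  expect_identical(lens,
                   sort(vapply(coh$arcs, length, integer(1))))
})

test_that("SMOTE-synthetic arcs report a deliverability-violation fraction", {
  spec <- cohort_spec(n_plans = 12L, n_cp_range = c(90L, 100L))
  coh <- simulate_cohort(spec, seed = 13)
  ds <- encode_cohort(coh)
  # this seed draws an imbalanced cohort with >= 2 samples per class
  cnt <- class_distribution(ds$labels)
  expect_gte(min(cnt), 2L)
  expect_gt(max(cnt), min(cnt))
  bal <- smote_oversample(ds, seed = 14)
  frac <- synthetic_deliverability_fraction(bal)
  expect_true(frac >= 0 && frac <= 1)
  expect_true(is.nan(synthetic_deliverability_fraction(ds)))
})
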