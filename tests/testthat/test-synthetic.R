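test_that("the default synthetic plan matches the modelled geometry", {
  plan <- default_plan()
  expect_equal(mask_volume_cm3(plan$ctv), 43.3, tolerance = 0.03)
  rx <- plan$spec$prescription
  cdvh <- compute_dvh(plan$dose, plan$ctv)
  pdvh <- compute_dvh(plan$dose, plan$ptv)
  expect_gte(dose_at_volume(cdvh, 95), 0.99 * rx)
  expect_equal(volume_at_dose(pdvh, 0.95 * rx), 100)
  # PTV margin: CTV strictly inside PTV with ~6 mm of headroom by volume
  expect_true(all(plan$ptv$values[plan$ctv$values]))
  expect_gt(mask_volume_cm3(plan$ptv), 2 * mask_volume_cm3(plan$ctv))
})

test_that("zero penumbra gives the prescription indicator on the PTV", {
  spec <- synthetic_plan_spec(ctv_semi_axes = rep(7, 3), penumbra_sigma = 0,
                              border = 10)
  plan <- make_synthetic_plan(spec)
  expect_setequal(unique(as.vector(plan$dose$values)), c(0, 60))
  expect_true(all(plan$dose$values[plan$ptv$values] == 60))
  expect_true(all(plan$dose$values[!plan$ptv$values] == 0))
})

test_that("the dose region keeps its zero border", {
  plan <- small_plan()
  d <- plan$dose$values
  n <- dim(d)
  border <- plan$spec$border
  shell <- d
  inner <- lapply(1:3, function(i) (border + 1):(n[i] - border))
  shell[inner[[1]], inner[[2]], inner[[3]]] <- 0
  expect_lt(max(shell), 1e-3 * plan$spec$prescription)
})

test_that("synthetic drift plateaus at the configured amplitude", {
  spec <- synthetic_motion_spec(drift_amplitude = c(0, -6, -2),
                                drift_timescale = 45, noise_sd = 0,
                                duration = 180)
  tr <- make_motion_trace(spec)
  final <- tr$displacement[nrow(tr$displacement), ]
  # 1 - exp(-4) = 0.9817 of the plateau amplitude
  expect_equal(final, c(0, -5.9, -2.0), tolerance = 0.02,
               ignore_attr = TRUE)
  expect_equal(tr$displacement[1, ], c(0, 0, 0), ignore_attr = TRUE)
})

test_that("zero-amplitude specs give identically zero traces", {
  tr <- make_motion_trace(synthetic_motion_spec(noise_sd = 0))
  expect_true(all(tr$displacement == 0))
})

test_that("traces are reproducible from the seed", {
  spec <- synthetic_motion_spec(drift_amplitude = c(0, -3, -1), seed = 42)
  t1 <- make_motion_trace(spec)
  t2 <- make_motion_trace(spec)
  expect_identical(t1, t2)
  spec2 <- synthetic_motion_spec(drift_amplitude = c(0, -3, -1), seed = 43)
  t3 <- make_motion_trace(spec2)
  expect_false(identical(t1$displacement, t3$displacement))
})

test_that("pauses insert beam-off samples without advancing the couch clock", {
  spec <- synthetic_motion_spec(drift_amplitude = c(0, -6, 0),
                                pause = c(60, 20), duration = 187.3)
  tr <- make_motion_trace(spec)
  expect_true(any(!tr$beam_on))
  expect_equal(max(tr$time), 207.3)
  expect_equal(beam_on_duration(tr), 187.3)
})

test_that("the example course seeds recoverable drift into known fractions", {
  specs <- example_course_specs(seed = 7)
  traces <- lapply(seq_along(specs), function(i)
    make_motion_trace(specs[[i]], fraction_id = i))
  ranked <- rank_fractions_by_motion(traces)
  expect_equal(sort(ranked[1:5]), c(2L, 4L, 12L, 13L, 17L))
  expect_equal(ranked[1], 2L)  # fraction 2 carries the worst drift
  flags <- vapply(traces, function(tr)
    characterize_drift(tr)$sustained_drift, logical(1))
  expect_equal(which(flags), c(2L, 4L, 12L, 13L, 17L))
  # the pause lives in fraction 8
  expect_true(any(!traces[[8]]$beam_on))
})

test_that("treatment courses bundle plan, traces and ground truth", {
  p <- delivery_parameters(n_fractions = 4)
  specs <- example_course_specs(n_fractions = 4, drift_fractions = 2,
                                drift_scales = 1, pause_fraction = NULL,
                                seed = 3)
  course <- make_treatment_course(
    synthetic_plan_spec(ctv_semi_axes = rep(8, 3), penumbra_sigma = 2,
                        border = 12),
    specs, p)
  expect_length(course$traces, 4)
  expect_equal(course$ground_truth$fraction_id, 1:4)
  expect_equal(course$ground_truth$drift_magnitude[2],
               sqrt(sum(c(0, -6, -2)^2)))
  expect_equal(rank_fractions_by_motion(course$traces)[1], 2L)
  expect_error(make_treatment_course(synthetic_plan_spec(), specs,
                                     delivery_parameters()),
               "one motion spec per fraction")
})
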