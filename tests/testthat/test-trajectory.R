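test_that("motion CSV writer and reader round-trip all fields", {
  tr1 <- motion_trace(1, c(0, 60, 120),
                      rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)))
  t2 <- seq(0, 180, by = 20)
  set.seed(42)
  d2 <- rbind(0, matrix(rnorm(3 * (length(t2) - 1)), ncol = 3))
  b2 <- rep(TRUE, length(t2)); b2[5:6] <- FALSE
  tr2 <- motion_trace(2, t2, d2, b2)
  path <- withr::local_tempfile(fileext = ".csv")
  write_motion_csv(list(tr2, tr1), path)

  traces <- read_motion_csv(path)
  expect_length(traces, 2)
  expect_equal(traces[["1"]]$fraction_id, 1L)
  expect_length(traces[["1"]]$time, 3)
  expect_equal(traces[["1"]]$displacement[, 1], c(0, 1, 2),
               ignore_attr = TRUE)
  expect_equal(traces[["2"]]$displacement, tr2$displacement,
               tolerance = 1e-12)
  expect_equal(traces[["2"]]$beam_on, b2)
})

test_that("motion CSV validation rejects malformed input", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines("fraction,time_s,dx_mm,dy_mm,dz_mm,beam_on", path)
  expect_error(read_motion_csv(path), "no data rows")

  writeLines(c("fraction,time_s,dx_mm,dy_mm,dz_mm,beam_on",
               "1,0,0,0,0,true",
               "1,60,oops,0,0,true",
               "1,120,2,0,0,true"), path)
  expect_error(read_motion_csv(path), "line 3")

  writeLines(c("fraction,time_s,dx_mm,dy_mm,dz_mm,beam_on",
               "1,0,0,0,0,true",
               "1,120,1,0,0,true",
               "1,60,2,0,0,true"), path)
  expect_error(read_motion_csv(path), "non-monotone")

  writeLines(c("time_s,dx_mm", "0,1"), path)
  expect_error(read_motion_csv(path), "header")
})

test_that("trace invariants are enforced and non-zero starts are rebased", {
  expect_error(motion_trace(1, 0, matrix(0, 1, 3)), "at least 2")
  expect_error(motion_trace(1, c(0, 0), matrix(0, 2, 3)),
               "strictly increasing")
  expect_error(motion_trace(0, c(0, 1), matrix(0, 2, 3)), "positive")
  expect_warning(
    tr <- motion_trace(1, c(0, 10), rbind(c(1, 1, 1), c(2, 1, 1))),
    "rebasing")
  expect_equal(tr$displacement[1, ], c(0, 0, 0), ignore_attr = TRUE)
  expect_equal(tr$displacement[2, ], c(1, 0, 0), ignore_attr = TRUE)
})

test_that("beam-on duration excludes paused gaps", {
  # no pause: full delivery span
  tr <- zero_trace(duration = 187.3, n = 20)
  expect_equal(beam_on_duration(tr), 187.3)
  # 0..200 s sampled every 10 s with a 20 s pause starting at t = 80
  tt <- seq(0, 200, by = 10)
  bo <- !(tt %in% c(80, 90))
  tr2 <- motion_trace(1, tt, matrix(0, length(tt), 3), bo)
  expect_equal(beam_on_duration(tr2), 180)
  # single interval
  tr3 <- motion_trace(1, c(0, 10), matrix(0, 2, 3))
  expect_equal(beam_on_duration(tr3), 10)
})

test_that("motion interpolation over travel fraction is piecewise linear", {
  tr <- motion_trace(1, c(0, 10), rbind(c(0, 0, 0), c(0, -2, 0)))
  expect_equal(motion_at_travel_fraction(tr, 0), c(0, 0, 0),
               ignore_attr = TRUE)
  expect_equal(motion_at_travel_fraction(tr, 0.5), c(0, -1, 0),
               ignore_attr = TRUE)
  tr2 <- linear_drift_trace(c(0, -6, -2), n = 12)
  expect_equal(motion_at_travel_fraction(tr2, 1), c(0, -6, -2),
               ignore_attr = TRUE)
  expect_error(motion_at_travel_fraction(tr, 1.2), "\\[0, 1\\]")
  expect_error(motion_at_travel_fraction(tr, -0.1), "\\[0, 1\\]")

  # exact on every sample point of a random trace
  set.seed(7)
  n <- 25
  tt <- sort(runif(n, 0, 180)); tt[1] <- 0
  disp <- rbind(0, matrix(rnorm(3 * (n - 1), sd = 2), ncol = 3))
  tr3 <- motion_trace(3, tt, disp)
  total <- beam_on_duration(tr3)
  for (i in seq_len(n)) {
    f <- (tt[i] - tt[1]) / total
    expect_equal(motion_at_travel_fraction(tr3, f), disp[i, ],
                 ignore_attr = TRUE, tolerance = 1e-9)
  }
})

test_that("interpolation uses the beam-on clock when a pause is present", {
  # beam off over the 50-60 s gap; displacement keeps growing on the wall
  # clock. Gaps are attributed by their leading sample, so 40-50 counts as
  # beam-on and 50-60 does not: 70 beam-on seconds in an 80 s fraction.
  tt <- c(0, 20, 40, 50, 60, 80)
  bo <- c(TRUE, TRUE, TRUE, FALSE, TRUE, TRUE)
  disp <- cbind(0, -c(0, 1, 2, 2.5, 3, 4), 0)
  tr <- motion_trace(1, tt, disp, bo)
  expect_equal(beam_on_duration(tr), 70)
  # 5/7 of 70 beam-on seconds = beam-on second 50 = the sample at wall 60 s
  expect_equal(motion_at_travel_fraction(tr, 5 / 7), c(0, -3, 0),
               ignore_attr = TRUE)
})

test_that("drift characterization flags sustained monotone drift only", {
  drift <- make_motion_trace(synthetic_motion_spec(
    drift_amplitude = c(0, -6, 0), noise_sd = 0, duration = 180))
  ds <- characterize_drift(drift)
  expect_true(ds$sustained_drift)
  expect_lt(ds$net_displacement[2], -3)
  expect_equal(ds$net_magnitude, sqrt(sum(ds$net_displacement^2)))

  sine <- make_motion_trace(synthetic_motion_spec(
    periodic_amplitude = 2, periodic_period = 45, periodic_axis = "y",
    noise_sd = 0, duration = 180))  # 4 full periods
  expect_false(characterize_drift(sine)$sustained_drift)

  zero <- zero_trace(n = 20)
  dz <- characterize_drift(zero)
  expect_equal(dz$net_magnitude, 0)
  expect_false(dz$sustained_drift)

  expect_error(characterize_drift(zero_trace(n = 5)), "at least 10")
})

test_that("time-reversed traces give exactly negated net drift", {
  set.seed(11)
  n <- 40
  tt <- seq(0, 180, length.out = n)
  disp <- rbind(0, matrix(rnorm(3 * (n - 1), sd = 2), ncol = 3))
  tr <- motion_trace(1, tt, disp)
  rev_disp <- disp[n:1, ]
  rev_disp <- sweep(rev_disp, 2, rev_disp[1, ])
  suppressWarnings(tr_rev <- motion_trace(1, tt, rev_disp))
  d1 <- characterize_drift(tr)
  d2 <- characterize_drift(tr_rev)
  expect_equal(d1$net_displacement, -d2$net_displacement, tolerance = 1e-12)
})

test_that("fractions rank by descending net drift with id tie-break", {
  mk <- function(id, A) linear_drift_trace(A, n = 20, fraction_id = id)
  traces <- list(mk(1, c(0, -6, 0)), mk(2, c(0, -2, 0)), mk(3, c(0, -4, 0)))
  expect_equal(rank_fractions_by_motion(traces), c(1L, 3L, 2L))
  same <- list(mk(3, c(0, -2, 0)), mk(1, c(0, -2, 0)), mk(2, c(0, -2, 0)))
  expect_equal(rank_fractions_by_motion(same), c(1L, 2L, 3L))
  expect_equal(rank_fractions_by_motion(list(mk(7, c(1, 0, 0)))), 7L)
  expect_error(rank_fractions_by_motion(list()), "non-empty")
})
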