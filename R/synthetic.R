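#' Specification for a synthetic treatment plan
#'
#' Describes an ellipsoidal CTV, its PTV expansion, and a conformal dose
#' distribution with a Gaussian penumbra on a regular grid. Defaults mirror
#' the modelled treatment: a 43.3 cm^3 CTV (sphere-equivalent radius
#' 21.78 mm), a 6 mm CTV-to-PTV margin, 60 Gy in 20 fractions, 1 mm voxels,
#' a 3 mm penumbra sigma and a >= 15 mm zero-dose border so deformations up
#' to ~10 mm stay clear of the grid edge.
#'
#' @param ctv_semi_axes length-3 numeric, ellipsoid semi-axes in mm
#'   (X, Y, Z); default a sphere of volume 43.3 cm^3.
#' @param ptv_margin CTV-to-PTV expansion margin, mm.
#' @param prescription total prescription, Gy.
#' @param n_fractions fraction count.
#' @param penumbra_sigma Gaussian penumbra width, mm (0 gives a hard-edged
#'   prescription indicator on the PTV).
#' @param spacing voxel spacing, mm.
#' @param border minimum zero-dose border, mm.
#' @return An object of class `synthetic_plan_spec`.
#' @export
synthetic_plan_spec <- function(ctv_semi_axes = rep((3 * 43300 / (4 * pi))^(1 / 3), 3),
                                ptv_margin = 6, prescription = 60,
                                n_fractions = 20, penumbra_sigma = 3,
                                spacing = c(1, 1, 1), border = 15) {
  ctv_semi_axes <- as.numeric(ctv_semi_axes)
  stopifnot(length(ctv_semi_axes) == 3, all(ctv_semi_axes > 0),
            ptv_margin >= 0, prescription > 0, n_fractions >= 1,
            penumbra_sigma >= 0, all(spacing > 0), border >= 0)
  structure(list(ctv_semi_axes = ctv_semi_axes, ptv_margin = ptv_margin,
                 prescription = prescription,
                 n_fractions = as.integer(n_fractions),
                 penumbra_sigma = penumbra_sigma,
                 spacing = as.numeric(spacing), border = border),
            class = "synthetic_plan_spec")
}

#' Generate a synthetic plan (dose grid + CTV/PTV masks)
#'
#' The CTV is a digital ellipsoid, the PTV its [expand_mask()] expansion, and
#' the dose is the prescription times a Gaussian-smoothed indicator of the
#' PTV expanded by a conformity buffer. The buffer is the smallest multiple
#' of 0.25 mm for which every PTV voxel receives at least 95% of the
#' prescription -- the tightest conformal coverage, as an optimized clinical
#' plan would deliver, which makes the construction guarantee
#' `PTV V95% = 100%` and `CTV D95% >= 0.99 x prescription` hold by the
#' smallest margin consistent with the penumbra.
#'
#' @param spec a [synthetic_plan_spec()].
#' @return list of class `synthetic_plan` with elements `dose`
#'   ([dose_grid()]), `ctv`, `ptv` ([structure_mask()]) and `spec`.
#' @export
make_synthetic_plan <- function(spec = synthetic_plan_spec()) {
  stopifnot(inherits(spec, "synthetic_plan_spec"))
  sig <- spec$penumbra_sigma
  buffer_max <- if (sig > 0) 2.5 * sig else 0
  half <- spec$ctv_semi_axes + spec$ptv_margin + buffer_max + 3.5 * sig +
    spec$border
  n <- 2 * ceiling(half / spec$spacing) + 1
  origin <- -(n - 1) / 2 * spec$spacing
  ax <- list(x = origin[1] + (seq_len(n[1]) - 1) * spec$spacing[1],
             y = origin[2] + (seq_len(n[2]) - 1) * spec$spacing[2],
             z = origin[3] + (seq_len(n[3]) - 1) * spec$spacing[3])
  e2 <- outer(outer((ax$x / spec$ctv_semi_axes[1])^2,
                    (ax$y / spec$ctv_semi_axes[2])^2, "+"),
              (ax$z / spec$ctv_semi_axes[3])^2, "+")
  ctv <- structure_mask(e2 <= 1, spacing = spec$spacing, origin = origin,
                        name = "CTV")
  ptv <- expand_mask(ctv, spec$ptv_margin, name = "PTV")
  rx <- spec$prescription
  if (sig == 0) {
    dose <- dose_grid(array(rx * as.numeric(ptv$values), dim = n),
                      spacing = spec$spacing, origin = origin)
  } else {
    gk <- gaussian_kernel(sig, spec$spacing)
    buffer <- 0.25 * ceiling(stats::qnorm(0.95) * sig / 0.25)
    repeat {
      if (buffer > buffer_max)
        stop("conformity buffer did not converge; increase the grid border")
      shell <- expand_mask(ptv, buffer)
      vals <- conv3d_same(array(as.numeric(shell$values), dim = n), gk)
      # snap FFT round-off: the smoothed indicator lies in [0, 1]; values
      # within convolution noise of the plateau (or of zero) are exact
      vals[vals > 1 - 1e-9] <- 1
      vals[vals < 1e-9] <- 0
      vals <- pmin(pmax(vals, 0), 1) * rx
      if (min(vals[ptv$values]) >= 0.95 * rx) break
      buffer <- buffer + 0.25
    }
    dose <- dose_grid(array(vals, dim = n), spacing = spec$spacing,
                      origin = origin)
  }
  # construction guarantees, checked on the voxel doses directly
  if (mean(dose$values[ctv$values] >= 0.99 * rx) < 0.95)
    stop("synthetic plan failed its CTV D95 guarantee")
  if (any(dose$values[ptv$values] < 0.95 * rx))
    stop("synthetic plan failed its PTV V95 guarantee")
  if (border_violated(dose, spec$border, 1e-3 * rx))
    stop("dose region violates the required zero-dose border")
  structure(list(dose = dose, ctv = ctv, ptv = ptv, spec = spec),
            class = "synthetic_plan")
}

border_violated <- function(dose, border, threshold) {
  d <- dim(dose$values)
  nb <- ceiling(border / dose$spacing)
  inner <- lapply(1:3, function(i) (nb[i] + 1):(d[i] - nb[i]))
  shellless <- dose$values
  shellless[inner[[1]], inner[[2]], inner[[3]]] <- 0
  any(shellless > threshold)
}

#' Specification for a synthetic motion trace
#'
#' The drift model is an exponential plateau,
#' `m(t) = A (1 - exp(-t / tau))`, matching the observed behaviour of
#' prostate drift trajectories that level off at or before ~6 mm well within
#' a fraction, plus an optional sinusoidal component and Gaussian sampling
#' noise. A mid-fraction pause inserts `beam_on = FALSE` samples whose time
#' advances while the couch (beam-on) clock does not; anatomy keeps moving on
#' the wall clock.
#'
#' @param drift_amplitude length-3 numeric, plateau drift amplitude `A` in
#'   mm (IEC X, Y, Z; e.g. `c(0, -6, -2)` for an inferior+posterior drift).
#' @param drift_timescale plateau time constant tau, s; default
#'   `duration / 4`.
#' @param periodic_amplitude sinusoid amplitude, mm.
#' @param periodic_period sinusoid period, s.
#' @param periodic_axis axis carrying the sinusoid: `"x"`, `"y"` or `"z"`.
#' @param noise_sd per-sample Gaussian noise SD, mm (default 0.2, typical of
#'   sub-millimetre fiducial-tracking residuals).
#' @param duration beam-on duration, s.
#' @param sample_interval sample spacing, s (~3 s matches six images per
#'   ~19 s rotation).
#' @param pause optional `c(start_s, length_s)` mid-fraction pause.
#' @param seed integer fixing the noise realization.
#' @return An object of class `synthetic_motion_spec`.
#' @export
synthetic_motion_spec <- function(drift_amplitude = c(0, 0, 0),
                                  drift_timescale = NULL,
                                  periodic_amplitude = 0,
                                  periodic_period = 30,
                                  periodic_axis = c("z", "x", "y"),
                                  noise_sd = 0.2, duration = 187.3,
                                  sample_interval = 3, pause = NULL,
                                  seed = 1L) {
  drift_amplitude <- as.numeric(drift_amplitude)
  periodic_axis <- match.arg(periodic_axis)
  stopifnot(length(drift_amplitude) == 3, all(is.finite(drift_amplitude)),
            periodic_amplitude >= 0, periodic_period > 0, noise_sd >= 0,
            duration > 0, sample_interval > 0, sample_interval < duration)
  if (is.null(drift_timescale)) drift_timescale <- duration / 4
  stopifnot(drift_timescale > 0)
  if (!is.null(pause)) {
    stopifnot(length(pause) == 2, pause[1] > 0, pause[2] > 0,
              pause[1] < duration)
  }
  structure(list(drift_amplitude = drift_amplitude,
                 drift_timescale = drift_timescale,
                 periodic_amplitude = periodic_amplitude,
                 periodic_period = periodic_period,
                 periodic_axis = periodic_axis,
                 noise_sd = noise_sd, duration = duration,
                 sample_interval = sample_interval, pause = pause,
                 seed = as.integer(seed)),
            class = "synthetic_motion_spec")
}

# Evaluate code under a temporary RNG state seeded with `seed`.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Generate a synthetic motion trace
#'
#' See [synthetic_motion_spec()] for the motion model. The first sample is
#' exactly zero (displacements are relative to the initial position) and the
#' realization is bit-reproducible from `(spec, seed)`.
#'
#' @param spec a [synthetic_motion_spec()].
#' @param fraction_id fraction number for the resulting trace.
#' @return a [motion_trace()].
#' @export
make_motion_trace <- function(spec = synthetic_motion_spec(),
                              fraction_id = 1L) {
  stopifnot(inherits(spec, "synthetic_motion_spec"))
  t_on <- seq(0, spec$duration, by = spec$sample_interval)
  if (t_on[length(t_on)] < spec$duration) t_on <- c(t_on, spec$duration)
  if (!is.null(spec$pause)) {
    ps <- spec$pause[1]; pl <- spec$pause[2]
    # samples at or after the pause start are delayed by the pause length;
    # the pause itself is sampled with beam_on = FALSE
    wall <- t_on + ifelse(t_on >= ps, pl, 0)
    pause_t <- seq(ps, ps + pl, by = spec$sample_interval)
    pause_t <- setdiff(pause_t, wall)
    time <- c(wall, pause_t)
    beam_on <- c(rep(TRUE, length(wall)), rep(FALSE, length(pause_t)))
    ord <- order(time)
    time <- time[ord]; beam_on <- beam_on[ord]
  } else {
    time <- t_on
    beam_on <- rep(TRUE, length(time))
  }
  n <- length(time)
  plateau <- 1 - exp(-time / spec$drift_timescale)
  disp <- outer(plateau, spec$drift_amplitude)
  if (spec$periodic_amplitude > 0) {
    k <- match(spec$periodic_axis, c("x", "y", "z"))
    disp[, k] <- disp[, k] +
      spec$periodic_amplitude * sin(2 * pi * time / spec$periodic_period)
  }
  if (spec$noise_sd > 0) {
    noise <- with_seed(spec$seed,
                       matrix(stats::rnorm(3 * n, sd = spec$noise_sd), n, 3))
    disp <- disp + noise
  }
  disp[1, ] <- 0
  motion_trace(fraction_id, time, disp, beam_on)
}

#' Motion specs emulating the studied treatment course
#'
#' Twenty fractions in which five (by default fractions 2, 4, 12, 13 and 17,
#' as in the studied patient) exhibit sustained inferior+posterior drift --
#' fraction 2 worst at the plateau amplitude `worst_drift` -- and the rest
#' show only sub-millimetre wander. Per-fraction noise seeds are derived from
#' `seed`.
#'
#' @param n_fractions number of fractions.
#' @param drift_fractions fraction ids exhibiting sustained drift, worst
#'   first.
#' @param worst_drift plateau amplitude (mm, 3-vector) of the worst fraction;
#'   the remaining drifting fractions scale it by `drift_scales`.
#' @param drift_scales scale factors for the drifting fractions.
#' @param quiet_drift plateau amplitude of the non-drifting fractions.
#' @param noise_sd per-sample noise SD, mm.
#' @param pause_fraction fraction id receiving a mid-fraction pause (the
#'   studied course paused in fraction 8); `NULL` for none.
#' @param seed base seed.
#' @param ... further arguments passed to [synthetic_motion_spec()].
#' @return list of [synthetic_motion_spec()], one per fraction.
#' @export
example_course_specs <- function(n_fractions = 20,
                                 drift_fractions = c(2, 4, 12, 13, 17),
                                 worst_drift = c(0, -6, -2),
                                 drift_scales = c(1, 0.9, 0.8, 0.75, 0.7),
                                 quiet_drift = c(0, -0.5, -0.2),
                                 noise_sd = 0.2,
                                 pause_fraction = 8,
                                 seed = 1L, ...) {
  stopifnot(length(drift_scales) == length(drift_fractions),
            all(drift_fractions >= 1 & drift_fractions <= n_fractions))
  lapply(seq_len(n_fractions), function(i) {
    j <- match(i, drift_fractions)
    amp <- if (!is.na(j)) drift_scales[j] * worst_drift else quiet_drift
    pause <- if (!is.null(pause_fraction) && i == pause_fraction)
      c(60, 20) else NULL
    synthetic_motion_spec(drift_amplitude = amp, noise_sd = noise_sd,
                          pause = pause, seed = seed + 1000L * i, ...)
  })
}

#' Generate a full synthetic treatment course
#'
#' Bundles a synthetic plan, one motion trace per fraction and a ground-truth
#' table of each fraction's true plateau drift, for end-to-end scenario runs
#' and parameter-recovery tests.
#'
#' @param plan_spec a [synthetic_plan_spec()].
#' @param motion_specs list of [synthetic_motion_spec()], one per fraction.
#' @param p a [delivery_parameters()]; `n_fractions` must match.
#' @return list of class `treatment_course` with `plan`, `traces`,
#'   `ground_truth` (data frame: `fraction_id`, true drift amplitudes and
#'   magnitude) and `p`.
#' @export
make_treatment_course <- function(plan_spec = synthetic_plan_spec(),
                                  motion_specs,
                                  p = delivery_parameters()) {
  if (length(motion_specs) != p$n_fractions)
    stop(sprintf("need one motion spec per fraction (%d), got %d",
                 p$n_fractions, length(motion_specs)))
  plan <- make_synthetic_plan(plan_spec)
  traces <- lapply(seq_along(motion_specs), function(i)
    make_motion_trace(motion_specs[[i]], fraction_id = i))
  gt <- do.call(rbind, lapply(seq_along(motion_specs), function(i) {
    A <- motion_specs[[i]]$drift_amplitude
    data.frame(fraction_id = i, drift_x = A[1], drift_y = A[2],
               drift_z = A[3], drift_magnitude = sqrt(sum(A^2)))
  }))
  structure(list(plan = plan, traces = traces, ground_truth = gt, p = p),
            class = "treatment_course")
}
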