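# Shared fixtures and independent oracles. Everything is generated in code;
# expensive fixtures are built once per test run and cached in this
# environment.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, builder(), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# Full-size default synthetic plan (the study geometry: 43.3 cm^3 spherical
# CTV, 6 mm margin, 60 Gy / 20 fx, 3 mm penumbra).
default_plan <- function() {
  cached("default_plan", function() make_synthetic_plan())
}

# Small plan for fast identity/scenario tests (~65^3 grid).
small_plan <- function() {
  cached("small_plan", function()
    make_synthetic_plan(synthetic_plan_spec(ctv_semi_axes = rep(8, 3),
                                            penumbra_sigma = 2,
                                            border = 12)))
}

delivery_for <- function(plan) {
  delivery_parameters(couch_start_y = default_couch_start(plan$dose))
}

# A smooth synthetic dose blob (Gaussian) for resampling tests.
gaussian_blob_grid <- function(n = 32, spacing = c(1, 1, 1), sigma = 5,
                               centre = c(0, 0, 0), amplitude = 10) {
  origin <- -(rep(n, 3) - 1) / 2 * spacing
  ax <- lapply(1:3, function(i) origin[i] + (seq_len(n) - 1) * spacing[i])
  d2 <- outer(outer((ax[[1]] - centre[1])^2, (ax[[2]] - centre[2])^2, "+"),
              (ax[[3]] - centre[3])^2, "+")
  dose_grid(amplitude * exp(-d2 / (2 * sigma^2)), spacing = spacing,
            origin = origin)
}

# Uniform deformation field on the geometry of `g`.
uniform_field <- function(g, d) {
  dims <- dim(g$values)
  v <- array(0, c(dims, 3))
  for (k in 1:3) v[, , , k] <- d[k]
  deformation_field(v, spacing = g$spacing, origin = g$origin)
}

# Smooth random slice-varying field with |d| <= max_mm.
random_smooth_field <- function(g, max_mm = 4) {
  dims <- dim(g$values)
  v <- array(0, c(dims, 3))
  ys <- seq(0, 2 * pi, length.out = dims[2])
  for (k in 1:3) {
    a <- stats::runif(1, -max_mm, max_mm)
    ph <- stats::runif(1, 0, 2 * pi)
    slice_vals <- a * sin(ys + ph) / 2 + stats::runif(1, -max_mm, max_mm) / 2
    v[, , , k] <- array(rep(slice_vals, each = dims[1]), dim = dims)
  }
  deformation_field(v, spacing = g$spacing, origin = g$origin)
}

# Independent brute-force trilinear pull-back resampler: scalar loops and
# explicit corner products, no shared code with apply_dvf().
oracle_resample <- function(dose, field) {
  v <- dose$values
  d <- dim(v)
  out <- array(0, d)
  for (k in seq_len(d[3])) {
    for (j in seq_len(d[2])) {
      for (i in seq_len(d[1])) {
        ti <- i - field$vectors[i, j, k, 1] / dose$spacing[1]
        tj <- j - field$vectors[i, j, k, 2] / dose$spacing[2]
        tk <- k - field$vectors[i, j, k, 3] / dose$spacing[3]
        if (ti < 1 || ti > d[1] || tj < 1 || tj > d[2] ||
            tk < 1 || tk > d[3]) next
        i0 <- min(max(floor(ti), 1), d[1] - 1)
        j0 <- min(max(floor(tj), 1), d[2] - 1)
        k0 <- min(max(floor(tk), 1), d[3] - 1)
        wi <- ti - i0; wj <- tj - j0; wk <- tk - k0
        out[i, j, k] <-
          v[i0, j0, k0] * (1 - wi) * (1 - wj) * (1 - wk) +
          v[i0 + 1, j0, k0] * wi * (1 - wj) * (1 - wk) +
          v[i0, j0 + 1, k0] * (1 - wi) * wj * (1 - wk) +
          v[i0 + 1, j0 + 1, k0] * wi * wj * (1 - wk) +
          v[i0, j0, k0 + 1] * (1 - wi) * (1 - wj) * wk +
          v[i0 + 1, j0, k0 + 1] * wi * (1 - wj) * wk +
          v[i0, j0 + 1, k0 + 1] * (1 - wi) * wj * wk +
          v[i0 + 1, j0 + 1, k0 + 1] * wi * wj * wk
      }
    }
  }
  out
}

# Quick linear-drift trace reaching `A` mm at `duration` seconds.
linear_drift_trace <- function(A, duration = 187.3, n = 40, fraction_id = 1) {
  tt <- seq(0, duration, length.out = n)
  motion_trace(fraction_id, tt, outer(tt / duration, A))
}

zero_trace <- function(duration = 187.3, n = 20, fraction_id = 1) {
  motion_trace(fraction_id, seq(0, duration, length.out = n),
               matrix(0, n, 3))
}
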