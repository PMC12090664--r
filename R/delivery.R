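#' Helical tomotherapy delivery parameters
#'
#' Geometry and timing of a helical delivery. Defaults are the printed
#' parameters of the treatment this package models: 2.5 cm field width,
#' pitch 0.303, 18.8 s gantry rotation, 187.3 s delivery, 6 planar images per
#' rotation, 60 Gy in 20 fractions, 6.25 mm leaves at isocentre.
#'
#' `couch_start_y` is the IEC-Y coordinate (mm) of the beam plane at beam-on,
#' i.e. the most superior treated position; the couch then moves superiorly so
#' the beam plane sweeps inferiorly through the patient. It is a free
#' geometric parameter: leave it `NA` and [default_couch_start()] (the most
#' superior slice with dose above 1% of maximum) is used when a dose grid is
#' available.
#'
#' @param field_width jaw-defined longitudinal field width, mm.
#' @param pitch couch travel per rotation divided by field width (unitless).
#' @param rotation_time gantry rotation period, s.
#' @param delivery_time beam-on delivery time, s; must be >= `rotation_time`.
#' @param images_per_rotation planned radiographic images per rotation.
#' @param couch_start_y IEC-Y of the beam plane at beam-on, mm (may be `NA`).
#' @param n_fractions number of fractions.
#' @param prescription_total total prescription dose, Gy.
#' @param leaf_width MLC leaf width at isocentre, mm.
#' @return An object of class `delivery_parameters`.
#' @export
delivery_parameters <- function(field_width = 25, pitch = 0.303,
                                rotation_time = 18.8, delivery_time = 187.3,
                                images_per_rotation = 6, couch_start_y = NA,
                                n_fractions = 20, prescription_total = 60,
                                leaf_width = 6.25) {
  pos <- c(field_width = field_width, pitch = pitch,
           rotation_time = rotation_time, delivery_time = delivery_time,
           images_per_rotation = images_per_rotation,
           n_fractions = n_fractions, prescription_total = prescription_total,
           leaf_width = leaf_width)
  if (any(!is.finite(pos)) || any(pos <= 0))
    stop("all delivery parameters except couch_start_y must be positive: ",
         paste(names(pos)[!is.finite(pos) | pos <= 0], collapse = ", "))
  if (delivery_time < rotation_time)
    stop("delivery_time must be at least one rotation_time")
  structure(list(field_width = field_width, pitch = pitch,
                 rotation_time = rotation_time, delivery_time = delivery_time,
                 images_per_rotation = as.integer(images_per_rotation),
                 couch_start_y = as.numeric(couch_start_y),
                 n_fractions = as.integer(n_fractions),
                 prescription_total = prescription_total,
                 leaf_width = leaf_width),
            class = "delivery_parameters")
}

#' @export
print.delivery_parameters <- function(x, ...) {
  cat(sprintf(
    "<delivery_parameters> field %g mm, pitch %g, rotation %g s, delivery %g s\n",
    x$field_width, x$pitch, x$rotation_time, x$delivery_time))
  cat(sprintf("  %d fx of %g Gy total; couch speed %.4f mm/s, travel %.1f mm\n",
              x$n_fractions, x$prescription_total, couch_speed(x),
              couch_travel_length(x)))
  invisible(x)
}

#' Couch speed of a helical delivery
#'
#' `pitch * field_width / rotation_time` -- the standard helical relation
#' (pitch is couch travel per rotation over field width).
#'
#' @param p a [delivery_parameters()].
#' @return couch speed in mm/s.
#' @export
couch_speed <- function(p) {
  stopifnot(inherits(p, "delivery_parameters"))
  p$pitch * p$field_width / p$rotation_time
}

#' Total couch travel over the delivery
#'
#' @param p a [delivery_parameters()].
#' @return couch travel in mm (`couch_speed * delivery_time`).
#' @export
couch_travel_length <- function(p) {
  couch_speed(p) * p$delivery_time
}

#' Planned number of radiographic images per fraction
#'
#' Ceiling of `delivery_time / rotation_time * images_per_rotation`; ceiling
#' is the only rounding consistent with 60 images at 187.3 s / 18.8 s x 6
#' (= 59.8).
#'
#' @param p a [delivery_parameters()].
#' @return integer image count.
#' @export
planned_image_count <- function(p) {
  stopifnot(inherits(p, "delivery_parameters"))
  as.integer(ceiling(p$delivery_time / p$rotation_time * p$images_per_rotation))
}

#' Fraction of couch travel at which the beam plane crossed a slice
#'
#' `f = (couch_start_y - y) / couch_travel_length`, clamped to `[0, 1]`:
#' slices superior to the starting couch position get `f = 0` (no target
#' motion has yet occurred, so no deformation), slices inferior to the final
#' couch position get `f = 1` (the end-of-treatment motion vector applies).
#'
#' @param y IEC-Y slice coordinate(s), mm; vectorized.
#' @param p a [delivery_parameters()] with finite `couch_start_y`.
#' @return travel fraction(s) in `[0, 1]`.
#' @export
slice_travel_fraction <- function(y, p) {
  stopifnot(inherits(p, "delivery_parameters"))
  if (!is.finite(p$couch_start_y))
    stop("couch_start_y is not set; supply it or use default_couch_start()")
  f <- (p$couch_start_y - y) / couch_travel_length(p)
  pmin(pmax(f, 0), 1)
}

#' Worst-case residual targeting error under leaf-quantized adaptation
#'
#' Real-time adaptation steers the jaws and MLC; left-right and
#' anterior-posterior corrections are quantized to the leaf grid, leaving a
#' worst-case residual of half a leaf width (3.125 mm for 6.25 mm leaves).
#'
#' @param p a [delivery_parameters()].
#' @return residual bound in mm.
#' @export
adaptation_residual_bound <- function(p) {
  stopifnot(inherits(p, "delivery_parameters"))
  if (!is.finite(p$leaf_width) || p$leaf_width <= 0)
    stop("leaf_width must be positive")
  p$leaf_width / 2
}

#' Default couch start position for a dose grid
#'
#' The most superior (largest IEC-Y) slice whose maximum dose exceeds
#' `threshold` times the global maximum: the treated length must cover the
#' dose region, and absolute couch coordinates are otherwise free.
#'
#' @param dose a [dose_grid()].
#' @param threshold fraction of maximum dose defining the dose region.
#' @return IEC-Y coordinate in mm.
#' @export
default_couch_start <- function(dose, threshold = 0.01) {
  stopifnot(inherits(dose, "dose_grid"))
  mx <- max(dose$values)
  if (mx <= 0)
    stop("dose grid is empty; cannot place the couch start")
  slice_max <- apply(dose$values, 2, max)
  ys <- grid_axes(dose)$y
  max(ys[slice_max > threshold * mx])
}

# Fill couch_start_y from the dose grid when unset.
resolve_couch_start <- function(p, dose) {
  if (!is.finite(p$couch_start_y))
    p$couch_start_y <- default_couch_start(dose)
  p
}
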