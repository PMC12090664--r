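#' Per-voxel deformation field
#'
#' Displacement vectors (mm) on the same grid geometry as a target
#' [dose_grid()]. Fields built by [build_dvf()] are constant within each
#' transverse (IEC-Y) slice.
#'
#' @param vectors 4D numeric array `nx x ny x nz x 3` of displacements, mm.
#' @param spacing,origin grid geometry; see [dose_grid()].
#' @return An object of class `deformation_field`.
#' @export
deformation_field <- function(vectors, spacing = c(1, 1, 1), origin = NULL) {
  if (!is.array(vectors) || length(dim(vectors)) != 4L ||
      dim(vectors)[4] != 3L)
    stop("`vectors` must be an nx x ny x nz x 3 array")
  if (!all(is.finite(vectors)))
    stop("deformation vectors must be finite")
  spacing <- as.numeric(spacing)
  if (is.null(origin))
    origin <- -(dim(vectors)[1:3] - 1) / 2 * spacing
  structure(list(vectors = vectors, spacing = spacing,
                 origin = as.numeric(origin)),
            class = "deformation_field")
}

#' @export
print.deformation_field <- function(x, ...) {
  d <- dim(x$vectors)
  mg <- sqrt(x$vectors[, , , 1]^2 + x$vectors[, , , 2]^2 +
               x$vectors[, , , 3]^2)
  cat(sprintf("<deformation_field> %d x %d x %d voxels, |d| up to %.2f mm\n",
              d[1], d[2], d[3], max(mg)))
  invisible(x)
}

#' Build the couch-interplay deformation vector field from a motion trace
#'
#' For every transverse slice at IEC-Y coordinate `y`, the voxel dose
#' translation vector is the *reverse* of the target motion vector at the
#' time the beam plane crossed that slice: `d(y) = -m(f(y))`, where
#' `f(y)` is [slice_travel_fraction()] and `m` is
#' [motion_at_travel_fraction()] interpolated over the trace's beam-on time.
#' Slices superior to the couch start carry the zero vector (no motion has
#' occurred yet); slices inferior to the end of couch travel carry the
#' reversed end-of-treatment motion.
#'
#' When the trace contains pauses, its beam-on duration (not the planned
#' delivery time) maps travel fraction to treatment time, because the couch
#' halts with the beam.
#'
#' @param trace a [motion_trace()].
#' @param p a [delivery_parameters()]; if `couch_start_y` is `NA` it is
#'   placed with [default_couch_start()] on `geometry` when that is a dose
#'   grid.
#' @param geometry a [dose_grid()] (or [structure_mask()]) supplying the
#'   output grid geometry.
#' @return A [deformation_field()] on the same geometry.
#' @export
build_dvf <- function(trace, p, geometry) {
  stopifnot(inherits(trace, "motion_trace"),
            inherits(p, "delivery_parameters"))
  if (!is.finite(p$couch_start_y)) {
    if (!inherits(geometry, "dose_grid"))
      stop("couch_start_y is unset and `geometry` is not a dose grid")
    p <- resolve_couch_start(p, geometry)
  }
  d <- grid_dim(geometry)
  ys <- grid_axes(geometry)$y
  f <- slice_travel_fraction(ys, p)
  m <- motion_at_travel_fraction(trace, f)
  m <- matrix(m, ncol = 3)
  vectors <- array(0, dim = c(d, 3L))
  for (k in 1:3) {
    # slice value varies along array dim 2 (IEC-Y), constant along 1 and 3
    vectors[, , , k] <- array(rep(-m[, k], each = d[1]), dim = d)
  }
  deformation_field(vectors, spacing = geometry$spacing,
                    origin = geometry$origin)
}

#' Apply a deformation field to a dose grid
#'
#' Pull-back resampling with trilinear interpolation: the output value at
#' voxel centre `x` is the input dose interpolated at `x - d(x)`. For a
#' spatially uniform field `d` this is exactly the input rigidly translated
#' by `+d`; with fields from [build_dvf()] (where `d = -m`) an
#' inferior+posterior target drift therefore shifts the dose superiorly and
#' anteriorly. Sample points outside the voxel-centre hull take dose 0.
#'
#' @param dose a [dose_grid()].
#' @param field a [deformation_field()] sharing its geometry.
#' @return the deformed [dose_grid()].
#' @export
apply_dvf <- function(dose, field) {
  stopifnot(inherits(dose, "dose_grid"), inherits(field, "deformation_field"))
  stop_if_geometry_differs(dose, field)
  d <- dim(dose$values)
  nx <- d[1]; ny <- d[2]; nz <- d[3]
  n <- prod(d)
  # continuous 1-based sample indices t = i - d/spacing along each axis
  ix <- rep.int(seq_len(nx), ny * nz)
  iy <- rep.int(rep(seq_len(ny), each = nx), nz)
  iz <- rep(seq_len(nz), each = nx * ny)
  tx <- ix - as.vector(field$vectors[, , , 1]) / dose$spacing[1]
  ty <- iy - as.vector(field$vectors[, , , 2]) / dose$spacing[2]
  tz <- iz - as.vector(field$vectors[, , , 3]) / dose$spacing[3]
  inside <- tx >= 1 & tx <= nx & ty >= 1 & ty <= ny & tz >= 1 & tz <= nz
  fx <- pmin(pmax(floor(tx), 1), nx - 1)
  fy <- pmin(pmax(floor(ty), 1), ny - 1)
  fz <- pmin(pmax(floor(tz), 1), nz - 1)
  wx <- tx - fx; wy <- ty - fy; wz <- tz - fz
  v <- dose$values
  base <- fx + (fy - 1) * nx + (fz - 1) * (nx * ny)
  sx <- 1L; sy <- nx; sz <- nx * ny
  out <- (1 - wx) * (1 - wy) * (1 - wz) * v[base] +
    wx * (1 - wy) * (1 - wz) * v[base + sx] +
    (1 - wx) * wy * (1 - wz) * v[base + sy] +
    wx * wy * (1 - wz) * v[base + sx + sy] +
    (1 - wx) * (1 - wy) * wz * v[base + sz] +
    wx * (1 - wy) * wz * v[base + sx + sz] +
    (1 - wx) * wy * wz * v[base + sy + sz] +
    wx * wy * wz * v[base + sx + sy + sz]
  out[!inside] <- 0
  dose_grid(array(out, dim = d), spacing = dose$spacing, origin = dose$origin)
}

#' Dose-weighted centroid
#'
#' Dose-weighted mean position of voxel centres, optionally restricted to a
#' structure mask. Used to quantify the direction a deformation moved the
#' dose (e.g. superior+anterior under inferior+posterior target drift).
#'
#' @param dose a [dose_grid()].
#' @param mask optional [structure_mask()] restricting the region.
#' @return length-3 numeric, mm (IEC X, Y, Z).
#' @export
dose_centroid <- function(dose, mask = NULL) {
  stopifnot(inherits(dose, "dose_grid"))
  w <- dose$values
  if (!is.null(mask)) {
    stop_if_geometry_differs(dose, mask)
    w <- w * mask$values
  }
  tot <- sum(w)
  if (tot <= 0)
    stop("total dose in the region is zero; centroid undefined")
  d <- dim(dose$values)
  ax <- grid_axes(dose)
  cx <- sum(rowSums(w, dims = 1) * ax$x) / tot
  wy <- apply(w, 2, sum)
  cy <- sum(wy * ax$y) / tot
  wz <- apply(w, 3, sum)
  cz <- sum(wz * ax$z) / tot
  c(x = cx, y = cy, z = cz)
}
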