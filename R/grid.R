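#' Regular 3D dose grid
#'
#' A scalar dose volume on a regular grid in IEC patient axes. Array axes map
#' to (X, Y, Z) = (left-right, superior-inferior, anterior-posterior) with
#' +X patient-left, +Y superior, +Z anterior. `origin` is the physical
#' position (mm) of the centre of voxel `[1, 1, 1]`.
#'
#' @param values 3D numeric array of dose in Gy; finite and non-negative.
#' @param spacing length-3 numeric, voxel spacing in mm (> 0). The second
#'   component is the longitudinal (IEC-Y) slice spacing, 1 mm by default.
#' @param origin length-3 numeric, mm. Defaults to centring the grid on the
#'   physical origin.
#' @return An object of class `dose_grid` with fields `values`, `spacing`,
#'   `origin`.
#' @export
dose_grid <- function(values, spacing = c(1, 1, 1), origin = NULL) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("`values` must be a 3D array")
  if (!all(is.finite(values)))
    stop("dose values must all be finite")
  if (any(values < 0))
    stop("dose values must be non-negative")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 positive numbers (mm)")
  if (is.null(origin))
    origin <- -(dim(values) - 1) / 2 * spacing
  origin <- as.numeric(origin)
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("`origin` must be 3 finite numbers (mm)")
  structure(list(values = values, spacing = spacing, origin = origin),
            class = "dose_grid")
}

#' Binary structure mask aligned to a dose grid
#'
#' @param values 3D logical (or 0/1) array with the same dimensions as the
#'   dose grid it annotates.
#' @param spacing,origin grid geometry in mm; see [dose_grid()]. A `dose_grid`
#'   (or another mask) may be passed as `geometry` instead.
#' @param name structure label, e.g. `"CTV"`, `"PTV"`, `"mockCTV"`.
#' @param geometry optional `dose_grid` or `structure_mask` whose geometry is
#'   copied; overrides `spacing`/`origin`.
#' @return An object of class `structure_mask`.
#' @export
structure_mask <- function(values, spacing = c(1, 1, 1), origin = NULL,
                           name = "structure", geometry = NULL) {
  if (!is.null(geometry)) {
    spacing <- geometry$spacing
    origin <- geometry$origin
  }
  if (is.numeric(values)) {
    storage.mode(values) <- "logical"
  }
  if (!is.array(values) || length(dim(values)) != 3L || !is.logical(values))
    stop("mask `values` must be a 3D logical array")
  if (anyNA(values))
    stop("mask values must not contain NA")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("`spacing` must be 3 positive numbers (mm)")
  if (is.null(origin))
    origin <- -(dim(values) - 1) / 2 * spacing
  structure(list(values = values, spacing = spacing,
                 origin = as.numeric(origin), name = as.character(name)),
            class = "structure_mask")
}

#' Voxel-centre coordinate axes of a grid object
#'
#' @param g a `dose_grid`, `structure_mask` or `deformation_field`.
#' @return list with components `x`, `y`, `z`: physical voxel-centre
#'   coordinates (mm) along each array axis.
#' @export
grid_axes <- function(g) {
  d <- grid_dim(g)
  list(x = g$origin[1] + (seq_len(d[1]) - 1) * g$spacing[1],
       y = g$origin[2] + (seq_len(d[2]) - 1) * g$spacing[2],
       z = g$origin[3] + (seq_len(d[3]) - 1) * g$spacing[3])
}

grid_dim <- function(g) {
  d <- dim(if (is.null(g$vectors)) g$values else g$vectors)
  d[1:3]
}

#' Test whether two grid objects share geometry
#'
#' Dimensions must match exactly; spacing and origin to within 1e-6 mm.
#' @param a,b grid objects (`dose_grid`, `structure_mask`,
#'   `deformation_field`).
#' @return logical scalar.
#' @export
same_geometry <- function(a, b) {
  identical(grid_dim(a), grid_dim(b)) &&
    all(abs(a$spacing - b$spacing) < 1e-6) &&
    all(abs(a$origin - b$origin) < 1e-6)
}

stop_if_geometry_differs <- function(a, b) {
  if (!same_geometry(a, b))
    stop("grid geometries differ (dimensions, spacing or origin)")
  invisible(TRUE)
}

#' @export
print.dose_grid <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<dose_grid> %d x %d x %d voxels, spacing (%g, %g, %g) mm\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  dose range [%.3f, %.3f] Gy, origin (%g, %g, %g) mm\n",
              min(x$values), max(x$values),
              x$origin[1], x$origin[2], x$origin[3]))
  invisible(x)
}

#' @export
print.structure_mask <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<structure_mask> '%s': %d of %d voxels (%s cm^3)\n",
              x$name, sum(x$values), prod(d),
              format(mask_volume_cm3(x), digits = 4)))
  invisible(x)
}

#' Physical volume of a structure mask
#'
#' Voxel-counting volume: number of mask voxels times the voxel volume.
#' @param mask a `structure_mask`.
#' @return volume in cm^3.
#' @export
mask_volume_cm3 <- function(mask) {
  sum(mask$values) * prod(mask$spacing) / 1000
}
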