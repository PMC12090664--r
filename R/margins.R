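# 3D "same"-size convolution via FFT. `k` must have odd dimensions with its
# centre voxel at (dim+1)/2. Real output; used for binary morphology (integer
# counts, so the 0.5 threshold is far above FFT round-off) and for Gaussian
# penumbra smoothing.
conv3d_same <- function(a, k) {
  da <- dim(a); dk <- dim(k)
  ds <- vapply(da + dk - 1L, function(n) stats::nextn(n, c(2, 3, 5)),
               numeric(1))
  pa <- array(0, ds); pa[seq_len(da[1]), seq_len(da[2]), seq_len(da[3])] <- a
  pk <- array(0, ds); pk[seq_len(dk[1]), seq_len(dk[2]), seq_len(dk[3])] <- k
  full <- Re(stats::fft(stats::fft(pa) * stats::fft(pk), inverse = TRUE)) /
    prod(ds)
  off <- (dk - 1L) %/% 2L
  full[off[1] + seq_len(da[1]), off[2] + seq_len(da[2]),
       off[3] + seq_len(da[3])]
}

# Ellipsoidal (Euclidean, physical-mm) structuring element: voxel offsets
# whose centre-to-centre distance is <= margin.
ball_kernel <- function(margin, spacing) {
  r <- floor(margin / spacing + 1e-9)
  ox <- (-r[1]:r[1]) * spacing[1]
  oy <- (-r[2]:r[2]) * spacing[2]
  oz <- (-r[3]:r[3]) * spacing[3]
  d2 <- outer(outer(ox^2, oy^2, "+"), oz^2, "+")
  array(as.numeric(d2 <= margin^2 + 1e-9), dim = dim(d2))
}

#' Expand a structure mask by an isotropic Euclidean margin
#'
#' The expanded region contains every voxel whose centre lies within `margin`
#' mm (Euclidean, isotropic in physical units) of some voxel centre of the
#' input region -- the distance-transform definition of a clinical margin,
#' e.g. the 6 mm CTV-to-PTV expansion. Implemented as binary dilation with an
#' ellipsoidal structuring element (exactly the thresholded Euclidean
#' distance transform evaluated at voxel centres).
#'
#' @param mask a [structure_mask()].
#' @param margin margin in mm, `>= 0` (use [contract_mask()] to shrink).
#' @param name label for the result; defaults to the input name.
#' @return the expanded [structure_mask()].
#' @export
expand_mask <- function(mask, margin, name = mask$name) {
  stopifnot(inherits(mask, "structure_mask"))
  if (!is.finite(margin) || margin < 0)
    stop("`margin` must be non-negative; use contract_mask() to shrink")
  out <- mask
  out$name <- name
  if (margin == 0 || !any(mask$values)) return(out)
  k <- ball_kernel(margin, mask$spacing)
  out$values <- conv3d_same(array(as.numeric(mask$values), dim(mask$values)),
                            k) > 0.5
  out
}

#' Contract a structure mask by an isotropic Euclidean margin
#'
#' The contracted region keeps every voxel whose centre lies more than
#' `margin` mm from the region's complement (voxels outside the grid count as
#' complement), e.g. the 3 mm PTV subtraction that creates a mock CTV for an
#' ultra-hypofractionated scenario. Dual of [expand_mask()].
#'
#' @param mask a [structure_mask()].
#' @param margin margin in mm, `>= 0`.
#' @param name label for the result; defaults to the input name.
#' @return the contracted [structure_mask()]; warns if it is empty.
#' @export
contract_mask <- function(mask, margin, name = mask$name) {
  stopifnot(inherits(mask, "structure_mask"))
  if (!is.finite(margin) || margin < 0)
    stop("`margin` must be non-negative")
  out <- mask
  out$name <- name
  if (margin > 0) {
    k <- ball_kernel(margin, mask$spacing)
    r <- (dim(k) - 1L) %/% 2L
    d <- dim(mask$values)
    # complement, padded with TRUE so the world outside the grid erodes too
    comp <- array(1, d + 2L * r)
    comp[r[1] + seq_len(d[1]), r[2] + seq_len(d[2]), r[3] + seq_len(d[3])] <-
      as.numeric(!mask$values)
    hit <- conv3d_same(comp, k) > 0.5
    out$values <- !hit[r[1] + seq_len(d[1]), r[2] + seq_len(d[2]),
                       r[3] + seq_len(d[3])]
  }
  if (!any(out$values))
    warning(sprintf("structure '%s' vanished after %g mm contraction",
                    out$name, margin))
  out
}

# Normalized 3D Gaussian kernel truncated at 4 sigma (physical mm).
gaussian_kernel <- function(sigma, spacing) {
  r <- pmax(ceiling(4 * sigma / spacing), 1)
  gx <- stats::dnorm((-r[1]:r[1]) * spacing[1], sd = sigma)
  gy <- stats::dnorm((-r[2]:r[2]) * spacing[2], sd = sigma)
  gz <- stats::dnorm((-r[3]:r[3]) * spacing[3], sd = sigma)
  k <- outer(outer(gx, gy), gz)
  k / sum(k)
}
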