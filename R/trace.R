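#' Per-fraction target motion trace
#'
#' A time series of 3D target displacement (mm, IEC patient axes: X
#' left-right, Y superior-inferior, Z anterior-posterior; signs +X
#' patient-left, +Y superior, +Z anterior) relative to the initial treatment
#' position. Samples recorded while the beam is paused carry
#' `beam_on = FALSE`; the couch halts with the beam, so paused samples are
#' excluded from the beam-on time axis used to map couch travel to motion.
#'
#' If the first beam-on sample has a non-zero displacement the whole trace is
#' rebased to it (with a warning), so that displacements are always relative
#' to the initial treatment position.
#'
#' @param fraction_id positive integer fraction number.
#' @param time numeric vector, seconds since beam-on; strictly increasing,
#'   non-negative.
#' @param displacement numeric matrix `length(time)` x 3, mm.
#' @param beam_on logical vector (recycled); `FALSE` during a delivery pause.
#' @return An object of class `motion_trace`.
#' @export
motion_trace <- function(fraction_id, time, displacement, beam_on = TRUE) {
  fraction_id <- as.integer(fraction_id)
  if (length(fraction_id) != 1L || is.na(fraction_id) || fraction_id < 1L)
    stop("`fraction_id` must be a single positive integer")
  time <- as.numeric(time)
  displacement <- as.matrix(displacement)
  if (ncol(displacement) != 3L)
    stop("`displacement` must have 3 columns (X, Y, Z in mm)")
  n <- length(time)
  if (n < 2L)
    stop("a motion trace needs at least 2 samples")
  if (nrow(displacement) != n)
    stop("`time` and `displacement` lengths differ")
  if (any(!is.finite(time)) || any(time < 0))
    stop("sample times must be finite and non-negative")
  if (any(diff(time) <= 0))
    stop("sample times must be strictly increasing within a fraction")
  if (any(!is.finite(displacement)))
    stop("displacement components must be finite")
  beam_on <- rep_len(as.logical(beam_on), n)
  if (anyNA(beam_on))
    stop("`beam_on` must be TRUE/FALSE")
  if (!any(beam_on))
    stop("a motion trace needs at least one beam-on sample")
  first_on <- which(beam_on)[1]
  if (any(displacement[first_on, ] != 0)) {
    warning(sprintf(
      "fraction %d: first beam-on sample is non-zero; rebasing displacements",
      fraction_id))
    displacement <- sweep(displacement, 2, displacement[first_on, ])
  }
  dimnames(displacement) <- list(NULL, c("dx", "dy", "dz"))
  structure(list(fraction_id = fraction_id, time = time,
                 displacement = displacement, beam_on = beam_on),
            class = "motion_trace")
}

#' @export
print.motion_trace <- function(x, ...) {
  net <- x$displacement[nrow(x$displacement), ]
  cat(sprintf(
    "<motion_trace> fraction %d: %d samples over %.1f s (beam-on %.1f s)\n",
    x$fraction_id, length(x$time), max(x$time) - min(x$time),
    beam_on_duration(x)))
  cat(sprintf("  final displacement (%.2f, %.2f, %.2f) mm\n",
              net[1], net[2], net[3]))
  invisible(x)
}

#' Total beam-on time of a trace
#'
#' Sums inter-sample gaps whose leading sample is beam-on, so gaps spanning a
#' delivery pause (flagged `beam_on = FALSE`) contribute nothing: the couch
#' and beam halt together.
#'
#' @param trace a [motion_trace()].
#' @return beam-on duration in seconds.
#' @export
beam_on_duration <- function(trace) {
  stopifnot(inherits(trace, "motion_trace"))
  n <- length(trace$time)
  sum(diff(trace$time) * trace$beam_on[-n])
}

# Beam-on time axis: cumulative beam-on seconds at each beam-on sample,
# with the matching displacements. Paused samples are dropped.
beam_on_axis <- function(trace) {
  n <- length(trace$time)
  ct <- c(0, cumsum(diff(trace$time) * trace$beam_on[-n]))
  keep <- trace$beam_on
  t_on <- ct[keep]
  list(time = t_on - t_on[1], disp = trace$displacement[keep, , drop = FALSE])
}

#' Target displacement at a fraction of couch travel
#'
#' Linearly interpolates the observed displacement over the beam-on time axis
#' at `t = f * total_beam_on`. `f = 0` returns the initial displacement (the
#' zero vector by construction) and `f = 1` the final beam-on displacement.
#'
#' @param trace a [motion_trace()].
#' @param f couch-travel fraction(s) in `[0, 1]`; may be a vector.
#' @param total_beam_on beam-on duration (s) used to convert travel fraction
#'   to treatment time; defaults to [beam_on_duration()] of the trace.
#' @return a length-3 vector (mm) for scalar `f`, else a `length(f)` x 3
#'   matrix.
#' @export
motion_at_travel_fraction <- function(trace, f,
                                      total_beam_on = beam_on_duration(trace)) {
  stopifnot(inherits(trace, "motion_trace"))
  if (any(!is.finite(f)) || any(f < 0) || any(f > 1))
    stop("travel fraction `f` must lie in [0, 1]")
  ax <- beam_on_axis(trace)
  tq <- f * total_beam_on
  out <- vapply(1:3, function(k) {
    stats::approx(ax$time, ax$disp[, k], xout = tq, rule = 2)$y
  }, numeric(length(tq)))
  out <- matrix(out, nrow = length(tq), ncol = 3,
                dimnames = list(NULL, c("dx", "dy", "dz")))
  if (length(f) == 1L) drop(out) else out
}

#' Characterize net intrafraction drift
#'
#' The net displacement is the mean of the final 10% of beam-on samples minus
#' the mean of the first 10%. The drift is flagged as sustained when its
#' magnitude exceeds `threshold_mm` *and* the per-sample increments along the
#' dominant axis agree in sign with the net vector for at least
#' `consistency_min` of the beam-on samples -- a deterministic reading of
#' "sustained continuous drift".
#'
#' @param trace a [motion_trace()] with at least 10 beam-on samples.
#' @param threshold_mm drift-magnitude threshold in mm (default 3, the
#'   patient-selection criterion).
#' @param consistency_min minimum sign-consistency fraction in `[0, 1]`.
#' @return An object of class `drift_summary`: list with `net_displacement`
#'   (mm, 3-vector), `net_magnitude` (mm), `monotone_consistency` and
#'   `sustained_drift`.
#' @export
characterize_drift <- function(trace, threshold_mm = 3,
                               consistency_min = 0.5) {
  stopifnot(inherits(trace, "motion_trace"))
  D <- trace$displacement[trace$beam_on, , drop = FALSE]
  n <- nrow(D)
  if (n < 10L)
    stop("drift characterization needs at least 10 beam-on samples")
  k <- ceiling(0.1 * n)
  net <- colMeans(D[(n - k + 1):n, , drop = FALSE]) -
    colMeans(D[1:k, , drop = FALSE])
  mag <- sqrt(sum(net^2))
  dominant <- which.max(abs(net))
  inc <- diff(D[, dominant])
  consistency <- if (length(inc)) mean(sign(inc) == sign(net[dominant])) else 0
  structure(list(net_displacement = unname(net),
                 net_magnitude = mag,
                 monotone_consistency = consistency,
                 sustained_drift = (mag > threshold_mm) &&
                   (consistency >= consistency_min)),
            class = "drift_summary")
}

#' @export
print.drift_summary <- function(x, ...) {
  cat(sprintf(
    "<drift_summary> net (%.2f, %.2f, %.2f) mm, |net| %.2f mm, consistency %.2f, sustained: %s\n",
    x$net_displacement[1], x$net_displacement[2], x$net_displacement[3],
    x$net_magnitude, x$monotone_consistency, x$sustained_drift))
  invisible(x)
}

#' Rank fractions by net drift magnitude
#'
#' @param traces list of [motion_trace()] objects.
#' @param ... passed to [characterize_drift()].
#' @return integer vector of `fraction_id`s sorted by descending net drift
#'   magnitude, ties broken by ascending `fraction_id`.
#' @export
rank_fractions_by_motion <- function(traces, ...) {
  if (!length(traces))
    stop("`traces` must be a non-empty list of motion traces")
  ids <- vapply(traces, function(tr) tr$fraction_id, integer(1))
  mags <- vapply(traces, function(tr)
    characterize_drift(tr, ...)$net_magnitude, numeric(1))
  ids[order(-mags, ids)]
}

#' Read motion traces from the documented CSV dialect
#'
#' One file holds all fractions, header
#' `fraction,time_s,dx_mm,dy_mm,dz_mm,beam_on`, UTF-8, decimal point, rows
#' sorted by (fraction, time). Pause rows (`beam_on = false`) are preserved
#' and flagged.
#'
#' @param path CSV file path.
#' @return named list of [motion_trace()], one per fraction, in ascending
#'   fraction order.
#' @export
read_motion_csv <- function(path) {
  if (!file.exists(path))
    stop("motion CSV not found: ", path)
  df <- utils::read.csv(path, colClasses = "character",
                        strip.white = TRUE)
  expected <- c("fraction", "time_s", "dx_mm", "dy_mm", "dz_mm", "beam_on")
  if (!identical(names(df), expected))
    stop("motion CSV header must be: ", paste(expected, collapse = ","))
  if (nrow(df) == 0L)
    stop("motion CSV contains no data rows: ", path)
  num <- function(col, what) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(!is.finite(v))
    if (length(bad))
      stop(sprintf("motion CSV parse error at line %d: bad %s value '%s'",
                   bad[1] + 1L, what, df[[col]][bad[1]]))
    v
  }
  fraction <- num("fraction", "fraction")
  if (any(fraction != round(fraction) | fraction < 1))
    stop("fraction ids must be positive integers")
  time_s <- num("time_s", "time")
  dx <- num("dx_mm", "dx"); dy <- num("dy_mm", "dy"); dz <- num("dz_mm", "dz")
  bo_raw <- tolower(df$beam_on)
  bo <- bo_raw %in% c("true", "t", "1")
  bad_bo <- which(!(bo_raw %in% c("true", "t", "1", "false", "f", "0")))
  if (length(bad_bo))
    stop(sprintf("motion CSV parse error at line %d: bad beam_on value '%s'",
                 bad_bo[1] + 1L, df$beam_on[bad_bo[1]]))
  ids <- sort(unique(as.integer(fraction)))
  traces <- lapply(ids, function(id) {
    sel <- which(fraction == id)
    tt <- time_s[sel]
    if (any(diff(tt) <= 0))
      stop(sprintf("non-monotone time within fraction %d (line %d)",
                   id, sel[which(diff(tt) <= 0)[1] + 1L] + 1L))
    motion_trace(id, tt, cbind(dx[sel], dy[sel], dz[sel]), bo[sel])
  })
  names(traces) <- as.character(ids)
  traces
}

#' Write motion traces in the same CSV dialect [read_motion_csv()] accepts
#'
#' @param traces list of [motion_trace()] objects (or a single trace).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_motion_csv <- function(traces, path) {
  if (inherits(traces, "motion_trace")) traces <- list(traces)
  if (!length(traces)) stop("no traces to write")
  ids <- vapply(traces, function(tr) tr$fraction_id, integer(1))
  rows <- lapply(traces[order(ids)], function(tr) {
    data.frame(fraction = tr$fraction_id,
               time_s = tr$time,
               dx_mm = tr$displacement[, 1],
               dy_mm = tr$displacement[, 2],
               dz_mm = tr$displacement[, 3],
               beam_on = tolower(as.character(tr$beam_on)))
  })
  df <- do.call(rbind, rows)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
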