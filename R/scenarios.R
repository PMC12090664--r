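#' Uniformly scaled fractional dose
#'
#' @param total a [dose_grid()] of the total planned dose.
#' @param n_fractions number of fractions (`>= 1`).
#' @return the per-fraction [dose_grid()] (`total / n_fractions`).
#' @export
fractional_dose <- function(total, n_fractions) {
  stopifnot(inherits(total, "dose_grid"))
  if (!is.finite(n_fractions) || n_fractions < 1)
    stop("`n_fractions` must be >= 1")
  out <- total
  out$values <- total$values / n_fractions
  out
}

#' Renormalize a dose distribution to a new prescription
#'
#' Voxelwise scaling by `new_rx / old_rx`, used to mimic an
#' ultra-hypofractionated regimen (e.g. 60 Gy rescaled to 40 Gy total,
#' 3 Gy fractions to 8 Gy) from an existing plan.
#'
#' @param dose a [dose_grid()].
#' @param old_rx current prescription, Gy (> 0).
#' @param new_rx target prescription, Gy.
#' @return the rescaled [dose_grid()].
#' @export
renormalize_dose <- function(dose, old_rx, new_rx) {
  stopifnot(inherits(dose, "dose_grid"))
  if (!is.finite(old_rx) || old_rx <= 0)
    stop("`old_rx` must be positive")
  out <- dose
  out$values <- dose$values * (new_rx / old_rx)
  out
}

# DVH metrics (D95, V95, Dmedian) for one structure on planned vs scenario
# total dose. V95 is the % of structure volume receiving >= 95% of the
# prescription.
structure_metrics <- function(planned, scenario_total, mask, prescription,
                              bin_width) {
  cp <- compute_dvh(planned, mask, bin_width)
  cs <- compute_dvh(scenario_total, mask, bin_width)
  v95_dose <- 0.95 * prescription
  pl <- c(D95 = dose_at_volume(cp, 95),
          V95 = volume_at_dose(cp, v95_dose),
          Dmedian = dose_at_volume(cp, 50))
  sc <- c(D95 = dose_at_volume(cs, 95),
          V95 = volume_at_dose(cs, v95_dose),
          Dmedian = dose_at_volume(cs, 50))
  data.frame(structure = mask$name,
             metric = names(pl),
             unit = c("Gy", "%", "Gy"),
             planned = unname(pl),
             scenario = unname(sc),
             delta = unname(sc - pl),
             row.names = NULL)
}

new_scenario_result <- function(kind, total_planned, total_scenario,
                                structures, prescription, bin_width,
                                fraction_ids = NULL) {
  if (is.null(names(structures)))
    names(structures) <- vapply(structures, function(m) m$name, character(1))
  metrics <- do.call(rbind, lapply(structures, function(m)
    structure_metrics(total_planned, total_scenario, m, prescription,
                      bin_width)))
  row.names(metrics) <- NULL
  structure(list(kind = kind, total_dose = total_scenario,
                 metrics = metrics, prescription = prescription,
                 fraction_ids = fraction_ids),
            class = "scenario_result")
}

#' @export
print.scenario_result <- function(x, ...) {
  cat(sprintf("<scenario_result> kind '%s', prescription %g Gy\n",
              x$kind, x$prescription))
  if (!is.null(x$fraction_ids))
    cat("  driven by fraction(s):", paste(x$fraction_ids, collapse = ", "),
        "\n")
  print(x$metrics, digits = 4)
  invisible(x)
}

#' Fraction-wise unmanaged-motion scenario
#'
#' The planned fractional dose (`total / n_fractions`, the same plan
#' delivered daily) is deformed with the field generated from each
#' fraction's own motion trace and the deformed fractional doses are summed.
#'
#' @param total planned total [dose_grid()].
#' @param traces list of [motion_trace()], exactly one per fraction
#'   (`p$n_fractions` of them).
#' @param p a [delivery_parameters()]; an unset `couch_start_y` is placed
#'   with [default_couch_start()] on `total`.
#' @param structures list of [structure_mask()] objects to report on.
#' @param bin_width DVH bin width, Gy.
#' @return a `scenario_result`: list with `kind`, `total_dose`, `metrics`
#'   (data frame of D95/V95/Dmedian, planned vs scenario and deltas),
#'   `prescription`, `fraction_ids`.
#' @export
run_fraction_wise <- function(total, traces, p, structures,
                              bin_width = 0.05) {
  stopifnot(inherits(total, "dose_grid"))
  p <- resolve_couch_start(p, total)
  if (length(traces) != p$n_fractions)
    stop(sprintf("fraction-wise scenario needs %d traces, got %d",
                 p$n_fractions, length(traces)))
  # Each fraction delivers the same planned fractional dose (total / N), so
  # summing apply_dvf(total / N, field_i) equals total + sum(deviations) / N.
  # Accumulating the deviations keeps motionless fractions exactly neutral.
  acc <- 0
  for (tr in traces) {
    def <- apply_dvf(total, build_dvf(tr, p, total))
    acc <- acc + (def$values - total$values)
  }
  out <- total
  out$values <- total$values + acc / p$n_fractions
  new_scenario_result("fraction_wise", total, out, structures,
                      p$prescription_total, bin_width,
                      fraction_ids = vapply(traces, `[[`, integer(1),
                                            "fraction_id"))
}

#' Worst-case unmanaged-motion scenario
#'
#' The total dose is deformed with the field generated from a single
#' (largest-motion) trace -- algebraically identical to deforming the
#' fractional dose and multiplying by the number of fractions, since the
#' field does not depend on dose and resampling commutes with uniform
#' scaling.
#'
#' @param total planned total [dose_grid()].
#' @param trace the driving [motion_trace()].
#' @inheritParams run_fraction_wise
#' @return a `scenario_result` (see [run_fraction_wise()]).
#' @export
run_worst_case <- function(total, trace, p, structures, bin_width = 0.05) {
  stopifnot(inherits(total, "dose_grid"))
  p <- resolve_couch_start(p, total)
  # the field is dose-independent, so deforming the total dose directly is
  # algebraically identical to N x apply_dvf(total / N) and avoids the
  # scale/rescale round trip
  out <- apply_dvf(total, build_dvf(trace, p, total))
  new_scenario_result("worst_case", total, out, structures,
                      p$prescription_total, bin_width,
                      fraction_ids = trace$fraction_id)
}

#' Planned (no-motion) scenario
#'
#' Reports the planned metrics themselves; all deltas are zero by
#' construction. Useful as the reference row set in pipeline reports.
#'
#' @inheritParams run_fraction_wise
#' @return a `scenario_result`.
#' @export
run_planned <- function(total, p, structures, bin_width = 0.05) {
  stopifnot(inherits(total, "dose_grid"))
  new_scenario_result("planned", total, total, structures,
                      p$prescription_total, bin_width)
}
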