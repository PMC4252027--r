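# Fraction-resolved analysis: spike/AUC normalisation, NP/PL split,
# ribosome-density metrics and mechanistic scenario classification.

#' Normalise a 12-fraction abundance profile
#'
#' Divides each fraction's abundance by the sample's spike-in signal and by
#' the polysomal A254 trace area of the same gradient, making profiles
#' comparable across samples with different RNA content and gradient
#' loading.
#'
#' @param abundances Nonnegative numeric vector (one value per fraction).
#' @param spike_signal Positive spike-in signal of the sample.
#' @param trace_area Positive A254 area of the corresponding gradient.
#' @return Normalised abundances, same length.
#' @export
normalize_profile <- function(abundances, spike_signal, trace_area) {
  stop_if(any(!is.finite(abundances)) || any(abundances < 0),
          "abundances must be finite and nonnegative")
  assert_scalar_number(spike_signal, "spike_signal", lower = 1e-300)
  assert_scalar_number(trace_area, "trace_area", lower = 1e-300)
  abundances / spike_signal / trace_area
}

#' Split a profile into non-polysomal and polysomal percentages
#'
#' The summed signal across all fractions is set to 100%; `np_pct` is the
#' share in the non-polysomal pool (fractions before
#' `polysome_start_fraction`) and `pl_pct = 100 - np_pct` the polysomal
#' share.
#'
#' @param abundances Numeric vector of length `scheme$n_fractions`.
#' @param scheme A [fraction_scheme()].
#' @return List with `np_pct` and `pl_pct`; both `NA` (flagged `undefined`)
#'   for an all-zero profile.
#' @export
np_pl_split <- function(abundances, scheme = fraction_scheme()) {
  stop_if(length(abundances) != scheme$n_fractions,
          "profile length must equal scheme$n_fractions")
  total <- sum(abundances)
  if (total <= 0) {
    return(structure(list(np_pct = NA_real_, pl_pct = NA_real_),
                     undefined = TRUE))
  }
  np <- sum(abundances[seq_len(scheme$polysome_start_fraction - 1L)])
  np_pct <- 100 * np / total
  list(np_pct = np_pct, pl_pct = 100 - np_pct)
}

#' Ribosome-density metrics of a fraction profile
#'
#' Summarises where a transcript sediments within the polysomal region:
#' `weighted_index` is the abundance-weighted mean fraction index over the
#' polysomal fractions (the package's ribosome-density proxy — deeper
#' fractions mean more ribosomes per engaged copy), and `peak_fraction` is
#' the polysomal fraction with the largest signal (ties resolved to the
#' lowest index).
#'
#' @inheritParams np_pl_split
#' @return List of class `density_metrics` with `np_pct`, `pl_pct`,
#'   `weighted_index`, `peak_fraction`. All metrics `NA` (flagged
#'   `undefined`) when there is no polysomal signal.
#' @export
density_metrics <- function(abundances, scheme = fraction_scheme()) {
  split <- np_pl_split(abundances, scheme)
  poly_idx <- seq(scheme$polysome_start_fraction, scheme$n_fractions)
  a <- abundances[poly_idx]
  if (isTRUE(attr(split, "undefined")) || sum(a) <= 0) {
    return(structure(list(np_pct = split$np_pct, pl_pct = split$pl_pct,
                          weighted_index = NA_real_,
                          peak_fraction = NA_integer_),
                     undefined = TRUE, class = "density_metrics"))
  }
  structure(list(np_pct = split$np_pct, pl_pct = split$pl_pct,
                 weighted_index = sum(poly_idx * a) / sum(a),
                 peak_fraction = poly_idx[which.max(a)]),
            class = "density_metrics")
}

#' Classify an occupancy/density change into a mechanistic scenario
#'
#' Compares the polysomal occupancy (`pl_pct`) and the density index
#' (`weighted_index`) of a treated profile against its control:
#' both up means increased initiation; occupancy up with density down is the
#' pattern produced by sequestration release, elongation stall or ribosome
#' runoff (more transcript copies engaged, each carrying fewer ribosomes);
#' both down is repression. Changes within tolerance are "no_change".
#'
#' @param control,treated [density_metrics()] of the two arms.
#' @param tol_pct Occupancy tolerance in percentage points (default 1).
#' @param tol_index Density-index tolerance in fraction-index units
#'   (default 0.25).
#' @return One of `"no_change"`, `"initiation_up"` (both up),
#'   `"occupancy_up_density_down"`, `"repression"` (both down, or occupancy
#'   down alone), `"occupancy_up"` / `"density_up"` / `"density_down"`
#'   (single-axis shifts, mechanism ambiguous),
#'   `"occupancy_down_density_up"`.
#' @export
scenario_classify <- function(control, treated, tol_pct = 1, tol_index = 0.25) {
  stop_if(isTRUE(attr(control, "undefined")) || isTRUE(attr(treated, "undefined")),
          "cannot classify undefined density metrics")
  d_occ <- treated$pl_pct - control$pl_pct
  d_den <- treated$weighted_index - control$weighted_index
  occ <- if (abs(d_occ) <= tol_pct) 0L else sign(d_occ)
  den <- if (abs(d_den) <= tol_index) 0L else sign(d_den)
  if (occ == 0 && den == 0) return("no_change")
  if (occ > 0 && den > 0) return("initiation_up")
  if (occ > 0 && den < 0) return("occupancy_up_density_down")
  if (occ > 0) return("occupancy_up")
  if (occ < 0 && den > 0) return("occupancy_down_density_up")
  if (occ < 0) return("repression")
  if (den > 0) "density_up" else "density_down"
}

#' Fraction-resolved analysis of paired profiles
#'
#' Convenience wrapper: normalises control and treated raw profiles, computes
#' density metrics for both and classifies the scenario.
#'
#' @param control_raw,treated_raw Raw fraction abundances.
#' @param control_spike,treated_spike Spike-in signals.
#' @param control_area,treated_area Polysomal trace areas.
#' @param scheme A [fraction_scheme()].
#' @param ... Passed to [scenario_classify()].
#' @return List with `control`, `treated` ([density_metrics()]) and `scenario`.
#' @export
compare_profiles <- function(control_raw, treated_raw,
                             control_spike = 1, treated_spike = 1,
                             control_area = 1, treated_area = 1,
                             scheme = fraction_scheme(), ...) {
  mc <- density_metrics(normalize_profile(control_raw, control_spike, control_area), scheme)
  mt <- density_metrics(normalize_profile(treated_raw, treated_spike, treated_area), scheme)
  list(control = mc, treated = mt, scenario = scenario_classify(mc, mt, ...))
}
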