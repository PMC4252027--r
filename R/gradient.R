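# Gradient-trace processing: A254 profiles from sucrose density gradients.

#' Construct a gradient trace
#'
#' An A254 absorbance profile along a sucrose gradient: paired vectors of
#' strictly increasing positions (gradient depth, arbitrary units) and
#' absorbance readings (AU).
#'
#' @param positions Numeric vector, strictly increasing, length >= 2.
#' @param absorbance Numeric vector of the same length.
#' @return An object of class `gradient_trace`.
#' @export
gradient_trace <- function(positions, absorbance) {
  stop_if(length(positions) < 2L, "a trace needs at least 2 points")
  stop_if(length(positions) != length(absorbance),
          "positions and absorbance must have equal length")
  stop_if(any(!is.finite(positions)) || any(!is.finite(absorbance)),
          "trace values must be finite")
  stop_if(any(diff(positions) <= 0), "positions must be strictly increasing")
  structure(list(positions = as.numeric(positions),
                 absorbance = as.numeric(absorbance)),
            class = "gradient_trace")
}

#' @export
print.gradient_trace <- function(x, ...) {
  cat(sprintf("<gradient_trace: %d points, domain [%g, %g], max A254 %.4g>\n",
              length(x$positions), min(x$positions), max(x$positions),
              max(x$absorbance)))
  invisible(x)
}

#' Define a fraction scheme for a 12-fraction gradient
#'
#' Partitions the trace domain into `n_fractions` contiguous fractions and
#' pools them into non-polysomal (NP), small-polysome (SP) and large-polysome
#' (LP) pools. Also carries the mapping from per-mRNA ribosome counts to
#' fraction indices used when rendering simulated material: free mRNPs
#' (0 ribosomes) sediment in fraction 1, monosomes in `monosome_fraction`,
#' and each additional ribosome moves a copy one fraction deeper, saturating
#' at the bottom fraction.
#'
#' Defaults follow the usual reading of a 12-fraction gradient: NP = fractions
#' 1-4 (free mRNPs, ribosomal subunits, monosomes), SP = 5-8, LP = 9-12, with
#' polysomes starting at fraction 5. These pool boundaries are configurable
#' because published gradient figures mark fractions without printing pool
#' indices.
#'
#' @param domain Numeric length-2: trace domain covered by the fractions.
#' @param n_fractions Number of fractions (default 12).
#' @param polysome_start_fraction First polysomal fraction (default 5).
#' @param monosome_fraction Fraction receiving 1-ribosome copies (default 4).
#' @param boundaries Optional strictly increasing numeric vector of
#'   `n_fractions + 1` cut points; defaults to equal-width slices of `domain`.
#' @return An object of class `fraction_scheme` with fields `n_fractions`,
#'   `boundaries`, `labels`, `pools` (NP/SP/LP index vectors),
#'   `polysome_start_fraction`, `monosome_fraction`.
#' @export
fraction_scheme <- function(domain = c(0, 12), n_fractions = 12L,
                            polysome_start_fraction = 5L,
                            monosome_fraction = 4L,
                            boundaries = NULL) {
  assert_scalar_number(n_fractions, "n_fractions", lower = 2, integer = TRUE)
  assert_scalar_number(polysome_start_fraction, "polysome_start_fraction",
                       lower = 2, upper = n_fractions, integer = TRUE)
  assert_scalar_number(monosome_fraction, "monosome_fraction",
                       lower = 1, upper = polysome_start_fraction - 1,
                       integer = TRUE)
  if (is.null(boundaries)) {
    boundaries <- seq(domain[1], domain[2], length.out = n_fractions + 1L)
  }
  stop_if(length(boundaries) != n_fractions + 1L,
          "boundaries must have n_fractions + 1 cut points")
  stop_if(any(diff(boundaries) <= 0), "boundaries must be strictly increasing")
  np <- seq_len(polysome_start_fraction - 1L)
  mid <- floor((polysome_start_fraction + n_fractions) / 2)
  pools <- list(NP = np,
                SP = seq(polysome_start_fraction, mid),
                LP = seq(mid + 1L, n_fractions))
  structure(list(n_fractions = as.integer(n_fractions),
                 boundaries = as.numeric(boundaries),
                 labels = paste0("fraction_", seq_len(n_fractions)),
                 pools = pools,
                 polysome_start_fraction = as.integer(polysome_start_fraction),
                 monosome_fraction = as.integer(monosome_fraction)),
            class = "fraction_scheme")
}

#' Map ribosome counts to fraction indices
#'
#' @param n Integer vector of ribosome counts per mRNA copy.
#' @param scheme A [fraction_scheme()].
#' @return Integer fraction indices in `1..n_fractions`.
#' @export
count_to_fraction <- function(n, scheme = fraction_scheme()) {
  stop_if(any(n < 0) || any(n != round(n)), "ribosome counts must be nonnegative integers")
  idx <- integer(length(n))
  idx[n == 0] <- 1L
  idx[n == 1] <- scheme$monosome_fraction
  poly <- n >= 2
  idx[poly] <- pmin(scheme$polysome_start_fraction + (n[poly] - 2L),
                    scheme$n_fractions)
  idx
}

interp_trace <- function(trace, at) {
  stats::approx(trace$positions, trace$absorbance, xout = at, rule = 1)$y
}

#' Subtract a blank-gradient baseline
#'
#' Subtracts the absorbance of a blank gradient (measured without sample)
#' from a trace, interpolating the blank linearly onto the trace positions
#' when the two are sampled on different grids. Negative residuals are
#' clipped to zero: A254 is nonnegative and clipping keeps downstream area
#' percentages inside \[0, 100\].
#'
#' @param trace,blank [gradient_trace()] objects; the blank's domain must
#'   cover the trace's.
#' @return A baseline-subtracted `gradient_trace` on the trace's positions.
#' @export
subtract_baseline <- function(trace, blank) {
  stopifnot(inherits(trace, "gradient_trace"), inherits(blank, "gradient_trace"))
  stop_if(min(blank$positions) > min(trace$positions) ||
            max(blank$positions) < max(trace$positions),
          "blank domain does not cover the trace domain")
  b <- interp_trace(blank, trace$positions)
  gradient_trace(trace$positions, pmax(trace$absorbance - b, 0))
}

#' Area under a trace segment
#'
#' Trapezoidal integral of the absorbance over `[lo, hi]`. Endpoints interior
#' to a sampling step are handled by linear interpolation, so the rule is
#' exact for piecewise-linear traces.
#'
#' @param trace A [gradient_trace()].
#' @param lo,hi Integration limits inside the trace domain (defaults: whole
#'   domain).
#' @return Nonnegative area (AU x position units).
#' @export
trace_area <- function(trace, lo = min(trace$positions),
                       hi = max(trace$positions)) {
  stopifnot(inherits(trace, "gradient_trace"))
  stop_if(lo >= hi, "lo must be < hi")
  stop_if(lo < min(trace$positions) - 1e-12 ||
            hi > max(trace$positions) + 1e-12,
          "[lo, hi] outside the trace domain")
  lo <- max(lo, min(trace$positions))
  hi <- min(hi, max(trace$positions))
  inside <- trace$positions > lo & trace$positions < hi
  x <- c(lo, trace$positions[inside], hi)
  y <- c(interp_trace(trace, lo), trace$absorbance[inside],
         interp_trace(trace, hi))
  sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
}

#' Per-fraction areas under a trace
#'
#' @param trace A [gradient_trace()] (baseline-subtracted).
#' @param scheme A [fraction_scheme()] whose boundaries lie inside the trace
#'   domain.
#' @return Named numeric vector of areas, one per fraction.
#' @export
fraction_areas <- function(trace, scheme = fraction_scheme(range(trace$positions))) {
  b <- scheme$boundaries
  areas <- vapply(seq_len(scheme$n_fractions), function(i) {
    trace_area(trace, b[i], b[i + 1])
  }, numeric(1))
  names(areas) <- scheme$labels
  areas
}

#' Polysomal-area percentage of a gradient trace
#'
#' The share of the total area under a baseline-subtracted A254 curve that
#' falls in the polysomal region (fractions at and beyond
#' `polysome_start_fraction`), expressed as a percentage. Normalising to the
#' total area compensates for uneven gradient loading between samples.
#'
#' @inheritParams fraction_areas
#' @return Percentage in \[0, 100\], or `NA` with attribute
#'   `undefined = TRUE` when the total area is not positive.
#' @export
polysomal_area_pct <- function(trace, scheme = fraction_scheme(range(trace$positions))) {
  total <- trace_area(trace, scheme$boundaries[1],
                      scheme$boundaries[scheme$n_fractions + 1])
  if (total <= 0) {
    return(structure(NA_real_, undefined = TRUE))
  }
  poly <- trace_area(trace, scheme$boundaries[scheme$polysome_start_fraction],
                     scheme$boundaries[scheme$n_fractions + 1])
  100 * poly / total
}

#' Replicate-wise difference of polysomal-area percentages
#'
#' Difference of arm means (treated minus control) with a propagated standard
#' deviation and a two-sided Welch t-test p-value. The reported `sd` is
#' `sqrt(sd_treated^2 + sd_control^2)`, the standard deviation of a
#' single-replicate difference; the standard error of the mean difference
#' (`se`) is returned alongside.
#'
#' @param treated,control Numeric vectors of percentages, >= 2 replicates each.
#' @return A list with `difference`, `sd`, `se`, `p_value`, `n_treated`,
#'   `n_control`.
#' @export
pct_difference <- function(treated, control) {
  stop_if(length(treated) < 2L || length(control) < 2L,
          "need at least 2 replicates per arm")
  d <- mean(treated) - mean(control)
  vt <- stats::var(treated); vc <- stats::var(control)
  p <- if (vt + vc == 0) {
    if (d == 0) 1 else 0
  } else {
    stats::t.test(treated, control)$p.value
  }
  list(difference = d,
       sd = sqrt(vt + vc),
       se = sqrt(vt / length(treated) + vc / length(control)),
       p_value = p,
       n_treated = length(treated), n_control = length(control))
}

#' Read / write two-column trace CSV
#'
#' Traces are exchanged as plain CSV with columns `position,a254`.
#'
#' @param path File path.
#' @return `read_trace_csv` returns a [gradient_trace()].
#' @export
read_trace_csv <- function(path) {
  d <- utils::read.csv(path)
  stop_if(!all(c("position", "a254") %in% names(d)),
          "trace CSV needs columns 'position' and 'a254'")
  gradient_trace(d$position, d$a254)
}

#' @rdname read_trace_csv
#' @param trace A [gradient_trace()].
#' @export
write_trace_csv <- function(trace, path) {
  utils::write.csv(data.frame(position = trace$positions,
                              a254 = trace$absorbance),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
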