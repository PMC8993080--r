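#' Percentage of ribosomes in polysomes from a UV trace
#'
#' Integrates the baseline-subtracted 254 nm absorbance over the annotated
#' monosome and polysome regions by the trapezoidal rule and reports
#' `100 * polysome / (monosome + polysome)`.
#'
#' @param trace data frame with columns position (strictly increasing) and
#'   absorbance.
#' @param regions named list with `monosome` and `polysome` `(lo, hi)`
#'   boundaries.
#' @param baseline constant absorbance baseline to subtract; if `NULL`,
#'   estimated as the minimum absorbance inside `baseline_window`.
#' @param baseline_window `(lo, hi)` inter-peak window used only when
#'   `baseline` is `NULL`.
#' @return polysome percentage in `[0, 100]`.
#' @examples
#' uv <- simulate_uv_trace(30, 70)
#' polysome_percentage(uv$trace, uv$regions)  # ~70
#' @export
polysome_percentage <- function(trace, regions, baseline = 0,
                                baseline_window = NULL) {
  stopifnot(all(c("position", "absorbance") %in% names(trace)))
  if (is.unsorted(trace$position, strictly = TRUE))
    stop("trace positions must be strictly increasing")
  if (is.null(baseline)) {
    if (is.null(baseline_window))
      stop("supply either a baseline or a baseline_window")
    inside <- trace$position >= baseline_window[1] &
      trace$position <= baseline_window[2]
    baseline <- min(trace$absorbance[inside])
  }
  area <- function(bounds) {
    sel <- trace$position >= bounds[1] & trace$position <= bounds[2]
    x <- trace$position[sel]
    y <- trace$absorbance[sel] - baseline
    sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
  }
  mono <- area(regions$monosome)
  poly <- area(regions$polysome)
  total <- mono + poly
  if (total <= 0) stop("total ribosome area is not positive")
  100 * poly / total
}

#' Spike-in normalized relative quantity from qPCR Ct values
#'
#' Efficiency-corrected abundance relative to the spike-in control:
#' `AF_target^(-Ct_target) / AF_spike^(-Ct_spike)`. Because a fixed amount
#' of spike-in RNA is added to every fraction before extraction, this ratio
#' cancels recovery and reverse-transcription differences between
#' fractions. An infinite Ct (no amplification) quantifies to 0.
#'
#' @param ct target Ct value(s), cycles.
#' @param spike_ct spike-in Ct value(s).
#' @param af per-cycle amplification factor of the target assay, in (1, 2]
#'   (2 = perfect doubling).
#' @param spike_af amplification factor of the spike-in assay.
#' @return relative quantity (dimensionless), vectorized.
#' @examples
#' spike_normalized_quantity(20, 20)          # 1
#' spike_normalized_quantity(19, 20)          # 2: one cycle earlier
#' @export
spike_normalized_quantity <- function(ct, spike_ct, af = 2, spike_af = af) {
  if (any(af <= 1 | af > 2) || any(spike_af <= 1 | spike_af > 2))
    stop("amplification factors must be in (1, 2]")
  q <- af^(-ct) / spike_af^(-spike_ct)
  q[is.infinite(ct) & ct > 0] <- 0
  q
}

#' Per-fraction percentages and cumulative distribution of an mRNA
#'
#' Converts raw (spike-normalized) per-fraction quantities to percentages
#' of the total and the running cumulative distribution across the
#' gradient, light fractions first.
#'
#' @param quantities non-negative per-fraction quantities, at least one
#'   positive.
#' @return object of class `fraction_series`: data frame with fraction,
#'   quantity, percentage, cumulative.
#' @export
fraction_distribution <- function(quantities) {
  stopifnot(length(quantities) >= 1, all(quantities >= 0))
  if (all(quantities == 0)) stop("all-zero quantity vector")
  pct <- 100 * quantities / sum(quantities)
  cum <- cumsum(pct)
  cum[length(cum)] <- 100  # exact by construction
  structure(
    data.frame(fraction = seq_along(quantities), quantity = quantities,
               percentage = pct, cumulative = cum),
    class = c("fraction_series", "data.frame")
  )
}

#' Area above the cumulative fraction distribution
#'
#' Summary score of how far into heavy (polysomal) fractions an mRNA sits:
#' the area above the cumulative curve, normalized by the number of
#' fractions so the score lies in `[0, (K-1)/K]` regardless of K. An mRNA
#' entirely in fraction 1 scores 0; entirely in the last fraction,
#' `(K-1)/K`; any rightward shift of mass strictly increases the score.
#'
#' @param series a `fraction_series` (or data frame with a `cumulative`
#'   column in percent).
#' @param method `"step"` (right-Riemann sum over fraction indices,
#'   default) or `"trapezoid"` (linearly interpolated cumulative curve).
#' @return list with `score` (normalized, in `[0, 1]`) and `raw_area`
#'   (fraction-index units).
#' @export
area_above_cumulative <- function(series, method = c("step", "trapezoid")) {
  method <- match.arg(method)
  C <- series$cumulative / 100
  K <- length(C)
  raw <- if (method == "step") {
    sum(1 - C)
  } else {
    # trapezoid between successive cumulative values, from C_0 = 0
    sum(1 - (c(0, head(C, -1)) + C) / 2)
  }
  list(score = raw / K, raw_area = raw)
}

#' Mean and SD of association scores per condition
#'
#' @param scores data frame with columns condition and score (one row per
#'   replicate); conditions are reported in order of first appearance.
#' @return data frame: condition, n, mean, sd (`NA` for single
#'   replicates).
#' @export
compare_conditions <- function(scores) {
  stopifnot(all(c("condition", "score") %in% names(scores)))
  conds <- unique(scores$condition)
  out <- do.call(rbind, lapply(conds, function(cc) {
    s <- scores$score[scores$condition == cc]
    data.frame(condition = cc, n = length(s), mean = mean(s),
               sd = if (length(s) > 1) stats::sd(s) else NA_real_)
  }))
  rownames(out) <- NULL
  out
}

#' Quantify a Ct table into a fraction distribution
#'
#' Convenience wrapper: applies [spike_normalized_quantity()] per fraction
#' and [fraction_distribution()] to the result.
#'
#' @param ct_table data frame with columns fraction, ct, spike_ct and
#'   optionally af, spike_af (default 2).
#' @return a `fraction_series`.
#' @export
quantify_ct_table <- function(ct_table) {
  af <- if ("af" %in% names(ct_table)) ct_table$af else 2
  spike_af <- if ("spike_af" %in% names(ct_table)) ct_table$spike_af else af
  ord <- order(ct_table$fraction)
  q <- spike_normalized_quantity(ct_table$ct[ord], ct_table$spike_ct[ord],
                                 af = if (length(af) > 1) af[ord] else af,
                                 spike_af = if (length(spike_af) > 1)
                                   spike_af[ord] else spike_af)
  fraction_distribution(q)
}
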