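#' Kinetic parameters of ribosome loading on a transcript population
#'
#' Bundles the parameters of the loading-kinetics model used throughout the
#' synthetic-data generator. The model: transcription proceeds at
#' `synth_rate_before` until time 0, then steps to `synth_rate_after`;
#' transcripts decay with first-order rate `decay_rate`; a transcript of age
#' `a` carries a ribosome load of `steady_density * min(a / fill_time, 1)`,
#' i.e. loading ramps up linearly over `fill_time` and then saturates.
#' Measurement happens `sample_time` after the step.
#'
#' `fill_time` is an *effective* timescale: it lumps together nuclear
#' processing, export and progressive ribosome recruitment, which is why it
#' can be of the order of hours even though a single ribosome transits an ORF
#' in minutes.
#'
#' @param synth_rate_before,synth_rate_after transcription rates
#'   (transcripts per unit time) before and after the step; both `> 0`.
#' @param decay_rate first-order mRNA decay rate (1/time); `> 0`.
#' @param fill_time time for a newly made transcript to reach its full
#'   ribosome load; `>= 0` (0 is the instantaneous-loading limit).
#' @param steady_density ribosomes per fully loaded transcript; `> 0`.
#' @param sample_time time after the step at which the population is
#'   measured; `>= 0`.
#' @return an object of class `kinetic_params`.
#' @seealso [passive_rd_ratio()]
#' @export
kinetic_params <- function(synth_rate_before = 1,
                           synth_rate_after = 1,
                           decay_rate = 0.25,
                           fill_time = 6,
                           steady_density = 5,
                           sample_time = 4) {
  stopifnot(
    is.finite(synth_rate_before), synth_rate_before > 0,
    is.finite(synth_rate_after), synth_rate_after > 0,
    is.finite(decay_rate), decay_rate > 0,
    is.finite(fill_time), fill_time >= 0,
    is.finite(steady_density), steady_density > 0,
    is.finite(sample_time), sample_time >= 0
  )
  structure(
    list(
      synth_rate_before = synth_rate_before,
      synth_rate_after = synth_rate_after,
      decay_rate = decay_rate,
      fill_time = fill_time,
      steady_density = steady_density,
      sample_time = sample_time
    ),
    class = "kinetic_params"
  )
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat("Kinetic parameters (step induction at t = 0):\n")
  cat(sprintf("  synthesis rate: %g -> %g (fold change %.3g)\n",
              x$synth_rate_before, x$synth_rate_after,
              x$synth_rate_after / x$synth_rate_before))
  cat(sprintf("  decay rate: %g /time   fill time: %g   steady density: %g\n",
              x$decay_rate, x$fill_time, x$steady_density))
  cat(sprintf("  sampled %g after the step\n", x$sample_time))
  invisible(x)
}

# \int_0^x min(a/T, 1) exp(-d a) da, vectorized over x (T, d scalars or
# vectors of the same length). T == 0 means instantaneous loading.
.load_integral <- function(x, d, T) {
  ramp <- function(u) (1 - (1 + d * u) * exp(-d * u)) / (d^2 * pmax(T, .Machine$double.xmin))
  full <- ifelse(T > 0,
                 ramp(pmin(x, T)) + (exp(-d * pmin(x, T)) - exp(-d * x)) / d,
                 (-expm1(-d * x)) / d)
  full
}

#' Passive ribosome-density ratio after a step change in transcription
#'
#' Mean ribosome density of the transcript population at `sample_time` after
#' a step change in synthesis rate, divided by the pre-step steady-state mean
#' density. Ratios below 1 are the kinetic (passive) depression of RD on
#' induced genes: after induction the population is enriched for young, not
#' yet fully loaded transcripts. Repressed genes (`F < 1`) show the mirror
#' effect, a ratio above 1.
#'
#' Under the linear-ramp loading model the population age density at time
#' `t` is `n(a, t) = k(t - a) exp(-decay_rate * a)` with `k` the step
#' synthesis rate, and the mean RD is the load-weighted average over ages;
#' both the numerator and the pre-step steady state have closed forms, which
#' this function evaluates.
#'
#' @param p a [kinetic_params()] object, or a fold change `F` when the other
#'   rates are given via `...` convenience arguments (see
#'   [passive_rd_ratio_vec()] for the vectorized core).
#' @return the dimensionless ratio; exactly 1 when `F = 1` or
#'   `fill_time = 0`, in `(0, 1]` for induction, `>= 1` for repression, and
#'   tending to 1 as `sample_time` grows.
#' @examples
#' passive_rd_ratio(kinetic_params(synth_rate_after = 4))
#' passive_rd_ratio(kinetic_params(synth_rate_after = 1)) # == 1
#' @export
passive_rd_ratio <- function(p) {
  stopifnot(inherits(p, "kinetic_params"))
  passive_rd_ratio_vec(
    fold_change = p$synth_rate_after / p$synth_rate_before,
    decay_rate = p$decay_rate,
    fill_time = p$fill_time,
    sample_time = p$sample_time
  )
}

#' Vectorized passive RD ratio
#'
#' Closed-form evaluation of the passive ribosome-density ratio for vectors
#' of per-gene parameters; the workhorse behind [passive_rd_ratio()] and the
#' count simulator.
#'
#' @param fold_change synthesis-rate fold change `F > 0` (after / before).
#' @param decay_rate first-order decay rate, `> 0`.
#' @param fill_time loading timescale, `>= 0`.
#' @param sample_time time after the step, `>= 0`.
#' @return numeric vector of ratios.
#' @export
passive_rd_ratio_vec <- function(fold_change, decay_rate, fill_time = 6,
                                 sample_time = 4) {
  n <- max(length(fold_change), length(decay_rate), length(fill_time),
           length(sample_time))
  F <- rep_len(as.numeric(fold_change), n)
  d <- rep_len(as.numeric(decay_rate), n)
  T <- rep_len(as.numeric(fill_time), n)
  t <- rep_len(as.numeric(sample_time), n)
  if (any(!is.finite(F) | F <= 0)) stop("fold_change must be finite and > 0")
  if (any(!is.finite(d) | d <= 0)) stop("decay_rate must be finite and > 0")
  if (any(!is.finite(T) | T < 0)) stop("fill_time must be finite and >= 0")
  if (any(!is.finite(t) | t < 0)) stop("sample_time must be finite and >= 0")

  # I_full = \int_0^Inf load(a) e^{-da} da; A_t = same integral up to age t.
  i_full <- ifelse(T > 0, (-expm1(-d * T)) / (d^2 * T), 1 / d)
  a_t <- ifelse(T > 0, .load_integral(t, d, T), (-expm1(-d * t)) / d)
  num <- F * a_t + (i_full - a_t)                 # load-weighted transcripts
  den <- (F * (-expm1(-d * t)) + exp(-d * t)) / d # total transcripts
  ratio <- num / (den * d * i_full)
  # exact limits, so the identities hold to the bit
  ratio[F == 1 | T == 0 | t == 0] <- 1
  ratio[t == 0] <- 1
  ratio
}
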