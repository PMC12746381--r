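# Population threshold model and IEC 60601-2-33 cardiac limit mathematics.
#
# Cardiac stimulation thresholds (in units of E-field rheobase) are taken as
# log-normally distributed across the population, calibrated by a median of
# 12 V/m and 6 V/m at the 1st percentile. Convolving that distribution with
# a distribution of dB/dt-over-E-field conversion ratios (multiplication of
# independent positive variables, i.e. convolution in the log domain) gives
# the population distribution of dB/dt thresholds, whose lower tail sets the
# adverse-event probability of a given dB/dt limit.

#' Calibrate the log-normal threshold distribution
#'
#' `sigma_log = ln(median / anchor_value) / z`, with `z` the standard-normal
#' quantile at `(100 - anchor_percentile) / 100`, so that the CDF at the
#' anchor equals `anchor_percentile / 100` exactly.
#'
#' @param median population median E-field threshold in V/m (default 12).
#' @param anchor_percentile percentile in (0, 50) anchored below the median.
#' @param anchor_value threshold at the anchor percentile in V/m (default 6).
#' @return object of class `threshold_distribution` with fields `median`,
#'   `meanlog`, `sigma_log`, `anchor_percentile`, `anchor_value`.
#' @examples
#' calibrate_lognormal()  # sigma_log = ln(2) / qnorm(0.99) ~= 0.298
#' @export
calibrate_lognormal <- function(median = 12, anchor_percentile = 1,
                                anchor_value = 6) {
  if (!(anchor_percentile > 0 && anchor_percentile < 50))
    stop("anchor percentile must lie in (0, 50)")
  if (!(anchor_value > 0 && anchor_value < median))
    stop("anchor value must be positive and below the median")
  z <- qnorm(1 - anchor_percentile / 100)
  structure(list(median = median, meanlog = log(median),
                 sigma_log = log(median / anchor_value) / z,
                 anchor_percentile = anchor_percentile,
                 anchor_value = anchor_value),
            class = "threshold_distribution")
}

#' Probability that an individual's threshold is below e
#'
#' Log-normal CDF of the calibrated threshold distribution.
#'
#' @param dist a [calibrate_lognormal()] result.
#' @param e E-field value in V/m (> 0); vectorized.
#' @return probability (or vector).
#' @examples
#' prob_E_below(calibrate_lognormal(), 2) * 1e9  # well under 10 ppb
#' @export
prob_E_below <- function(dist, e) {
  stopifnot(inherits(dist, "threshold_distribution"))
  if (any(e <= 0)) stop("e must be positive")
  stats::plnorm(e, meanlog = dist$meanlog, sdlog = dist$sigma_log)
}

#' Threshold quantile
#'
#' @param dist a [calibrate_lognormal()] result.
#' @param p probability in (0, 1); vectorized.
#' @return E-field quantile in V/m.
#' @export
threshold_quantile <- function(dist, p) {
  stats::qlnorm(p, meanlog = dist$meanlog, sdlog = dist$sigma_log)
}

#' Ratio distribution container
#'
#' @param samples positive dB/dt-over-E ratio samples in (T/s)(V/m)^-1; a
#'   single value gives a degenerate (constant) distribution.
#' @param source provenance text.
#' @return object of class `ratio_distribution`.
#' @export
ratio_distribution <- function(samples, source = "unspecified") {
  samples <- as.numeric(samples)
  if (length(samples) == 0) stop("empty ratio sample set")
  if (any(!is.finite(samples)) || any(samples <= 0))
    stop("ratio samples must be positive and finite")
  structure(list(samples = samples, source = source),
            class = "ratio_distribution")
}

#' Distribution of dB/dt thresholds
#'
#' Convolves the E-field threshold distribution with the ratio distribution:
#' each dB/dt threshold is the product R * E of independent draws. Two paths
#' are kept: a seeded Monte-Carlo sample, and the exact stratified closed
#' form (each ratio sample contributes a log-normal shifted by `ln R`),
#' which avoids empirical-CDF truncation at extreme probabilities. A
#' degenerate ratio reduces both to a single shifted log-normal.
#'
#' @param E_dist a [calibrate_lognormal()] result.
#' @param R_dist a [ratio_distribution()] (or numeric samples).
#' @param n_mc Monte-Carlo sample count (>= 1e4).
#' @param seed integer seed for the Monte-Carlo path.
#' @return object of class `dbdt_threshold_dist` with fields `E_dist`,
#'   `ratios`, `samples` (T/s), `degenerate`.
#' @export
dBdt_threshold_distribution <- function(E_dist, R_dist, n_mc = 1e5,
                                        seed = 1) {
  if (!inherits(R_dist, "ratio_distribution"))
    R_dist <- ratio_distribution(R_dist)
  stopifnot(inherits(E_dist, "threshold_distribution"))
  if (n_mc < 1e4) stop("n_mc must be at least 1e4 for the Monte-Carlo path")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  R <- R_dist$samples[sample.int(length(R_dist$samples), n_mc,
                                 replace = TRUE)]
  E <- stats::rlnorm(n_mc, meanlog = E_dist$meanlog,
                     sdlog = E_dist$sigma_log)
  structure(list(E_dist = E_dist, ratios = R_dist$samples,
                 samples = R * E,
                 degenerate = length(unique(R_dist$samples)) == 1),
            class = "dbdt_threshold_dist")
}

#' Probability of a cardiac adverse event
#'
#' CDF of the dB/dt threshold distribution at the given dB/dt: the fraction
#' of the population whose threshold lies below it. The closed-form path is
#' the exact mixture `mean_i Phi((ln(dBdt / R_i) - mu_E) / sigma)` and is
#' reliable in the extreme tail; the Monte-Carlo path is the empirical CDF
#' of the sampled thresholds.
#'
#' @param threshold_dist a [dBdt_threshold_distribution()] result.
#' @param dBdt evaluation point in T/s (> 0); vectorized.
#' @param method `"closed_form"` (default) or `"mc"`.
#' @return probability (or vector).
#' @export
prob_adverse_event <- function(threshold_dist, dBdt,
                               method = c("closed_form", "mc")) {
  method <- match.arg(method)
  stopifnot(inherits(threshold_dist, "dbdt_threshold_dist"))
  if (any(dBdt <= 0)) stop("dBdt must be positive")
  if (method == "mc")
    return(sapply(dBdt,
                  function(t) mean(threshold_dist$samples <= t)))
  ed <- threshold_dist$E_dist
  sapply(dBdt, function(t)
    mean(stats::plnorm(t, meanlog = ed$meanlog + log(threshold_dist$ratios),
                       sdlog = ed$sigma_log)))
}

#' IEC limit parameters
#'
#' Rheobase and chronaxie of the IEC 60601-2-33 cardiac strength-duration
#' limit; the dB/dt rheobase is the E-field rheobase times the governing
#' conversion ratio (20 T/s = 10 x 2 V/m by default).
#'
#' @param rheobase_E E-field rheobase in V/m.
#' @param chronaxie_ms chronaxie in ms.
#' @param conversion_ratio governing dB/dt-over-E ratio.
#' @return object of class `iec_limit_params`.
#' @export
iec_limit_params <- function(rheobase_E = 2, chronaxie_ms = 3,
                             conversion_ratio = 10) {
  stopifnot(rheobase_E > 0, chronaxie_ms > 0, conversion_ratio > 0)
  structure(list(rheobase_E = rheobase_E, chronaxie_ms = chronaxie_ms,
                 conversion_ratio = conversion_ratio,
                 rheobase_dBdt = conversion_ratio * rheobase_E),
            class = "iec_limit_params")
}

#' Effective dB/dt limit for a conversion ratio
#'
#' @param conversion_ratio dB/dt-over-E ratio in (T/s)(V/m)^-1.
#' @param params an [iec_limit_params()].
#' @return dB/dt limit in T/s (`ratio x rheobase_E`; 10 gives 20 T/s).
#' @examples
#' effective_dBdt_limit(10)  # 20 T/s
#' @export
effective_dBdt_limit <- function(conversion_ratio,
                                 params = iec_limit_params()) {
  if (any(conversion_ratio <= 0)) stop("conversion ratio must be positive")
  conversion_ratio * params$rheobase_E
}

strength_duration <- function(rheobase, tau_ms, chronaxie_ms) {
  if (any(tau_ms <= 0)) stop("effective stimulus duration must be positive")
  rheobase / (1 - exp(-tau_ms / chronaxie_ms))
}

#' IEC cardiac E-field limit
#'
#' `E < rheobase_E / (1 - exp(-tau / chronaxie))` for a waveform with
#' effective stimulus duration `tau`.
#'
#' @param tau_s_eff_ms effective stimulus duration in ms (> 0); vectorized.
#' @param params an [iec_limit_params()].
#' @return limit in V/m.
#' @export
iec_E_limit <- function(tau_s_eff_ms, params = iec_limit_params()) {
  strength_duration(params$rheobase_E, tau_s_eff_ms, params$chronaxie_ms)
}

#' IEC cardiac dB/dt limit
#'
#' `dB/dt < rheobase_dBdt / (1 - exp(-tau / chronaxie))`; with defaults the
#' long-duration asymptote is 20 T/s.
#'
#' @inheritParams iec_E_limit
#' @return limit in T/s.
#' @export
iec_dBdt_limit <- function(tau_s_eff_ms, params = iec_limit_params()) {
  strength_duration(params$rheobase_dBdt, tau_s_eff_ms,
                    params$chronaxie_ms)
}

#' Adverse-event probability versus chosen conversion ratio
#'
#' Evaluates the adverse-event probability at the effective dB/dt limit
#' implied by each candidate conversion ratio, against a fixed dB/dt
#' threshold distribution.
#'
#' @param threshold_dist a [dBdt_threshold_distribution()] result.
#' @param ratios candidate conversion ratios.
#' @param params an [iec_limit_params()].
#' @return data.frame with ratio, dBdt_limit and probability.
#' @export
adverse_event_curve <- function(threshold_dist, ratios,
                                params = iec_limit_params()) {
  lim <- effective_dBdt_limit(ratios, params)
  data.frame(ratio = ratios, dBdt_limit = lim,
             probability = prob_adverse_event(threshold_dist, lim))
}

#' Waveform specification
#'
#' @param times strictly increasing sample times in s (>= 3 samples).
#' @param values gradient field samples (T at the evaluation point, or
#'   normalized).
#' @return object of class `waveform_spec`.
#' @export
waveform_spec <- function(times, values) {
  stopifnot(length(times) == length(values), length(times) >= 3)
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  structure(list(times = as.numeric(times), values = as.numeric(values)),
            class = "waveform_spec")
}

#' Effective stimulus duration of a waveform
#'
#' Ratio of the peak-to-peak field variation to the maximum field derivative
#' over one waveform period (first-order finite differences on the samples;
#' at least ~20 samples per ramp are recommended). For a bipolar trapezoid
#' this equals twice the gradient rise time; for a sinusoid of period T it
#' equals T / pi.
#'
#' @param w a [waveform_spec()] (or list with `times` and `values`).
#' @return effective stimulus duration in s.
#' @examples
#' w <- waveform_bipolar_trapezoid(rise = 0.5e-3, flat = 1e-3)
#' effective_stimulus_duration(w)  # 1 ms
#' @export
effective_stimulus_duration <- function(w) {
  if (!inherits(w, "waveform_spec")) w <- waveform_spec(w$times, w$values)
  pp <- max(w$values) - min(w$values)
  if (pp == 0) stop("constant waveform has no stimulus duration")
  slope <- max(abs(diff(w$values) / diff(w$times)))
  pp / slope
}

#' Sampled bipolar trapezoid waveform
#'
#' One period of a bipolar trapezoidal gradient waveform: ramp up over
#' `rise`, hold `+amplitude` for `flat`, ramp down through zero to
#' `-amplitude` (over `2 * rise`), hold, and return.
#'
#' @param rise ramp time in s.
#' @param flat flat-top time in s.
#' @param amplitude plateau value.
#' @param samples_per_ramp samples on each linear ramp (>= 20 recommended).
#' @return a [waveform_spec()].
#' @export
waveform_bipolar_trapezoid <- function(rise, flat, amplitude = 1,
                                       samples_per_ramp = 25) {
  stopifnot(rise > 0, flat >= 0, samples_per_ramp >= 2)
  seg <- function(t0, t1, v0, v1, n)
    list(t = seq(t0, t1, length.out = n), v = seq(v0, v1, length.out = n))
  a <- amplitude
  s1 <- seg(0, rise, 0, a, samples_per_ramp)
  s2 <- seg(rise, rise + flat, a, a, max(2, samples_per_ramp %/% 2))
  s3 <- seg(rise + flat, 3 * rise + flat, a, -a, 2 * samples_per_ramp)
  s4 <- seg(3 * rise + flat, 3 * rise + 2 * flat, -a, -a,
            max(2, samples_per_ramp %/% 2))
  s5 <- seg(3 * rise + 2 * flat, 4 * rise + 2 * flat, -a, 0,
            samples_per_ramp)
  t <- c(s1$t, s2$t, s3$t, s4$t, s5$t)
  v <- c(s1$v, s2$v, s3$v, s4$v, s5$v)
  keep <- !duplicated(t)
  waveform_spec(t[keep], v[keep])
}

#' Sampled sinusoid waveform
#'
#' @param frequency in Hz.
#' @param amplitude peak value.
#' @param n samples over one period.
#' @return a [waveform_spec()].
#' @export
waveform_sinusoid <- function(frequency, amplitude = 1, n = 2000) {
  t <- seq(0, 1 / frequency, length.out = n)
  waveform_spec(t, amplitude * sin(2 * pi * frequency * t))
}
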