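# Synthetic raw signals used to exercise the preprocessing chain. These
# are simple parametric kinematics (a logistic grip-force rise; a pursuit
# ramp followed by a pre-bounce fixation), not biomechanical simulations.

#' Synthetic grip-force trace
#'
#' A smooth logistic force rise whose asymptote (and hence peak force
#' rate) increases monotonically with the lifter's heaviness belief, plus
#' optional additive Gaussian noise, sampled at 500 samples/s. With zero
#' noise the peak force rate is available in closed form:
#' `f_max / (4 * tau)` with `f_max = f_base + f_gain * belief`.
#'
#' @param belief heaviness belief in \[0, 1\].
#' @param noise_sd additive noise standard deviation in newtons (>= 0).
#' @param seed integer seed (traces are reproducible).
#' @param fs sampling rate, samples/s.
#' @param duration trace duration in seconds (>= 1).
#' @param f_base,f_gain force asymptote (N) at belief 0 and its increase
#'   to belief 1.
#' @param tau logistic rise time constant in seconds.
#' @param t_rise time of the steepest force increase, seconds.
#' @param object optional metadata (e.g. a row of a design's trial table)
#'   stored on the trace.
#' @return A `force_trace`: list with `t`, `force`, `fs`, `peak_rate_true`
#'   (the analytic noiseless peak rate) and `meta`.
#' @export
synth_force_trace <- function(belief, noise_sd = 0, seed = 1L, fs = 500,
                              duration = 1.2, f_base = 4, f_gain = 6,
                              tau = 0.05, t_rise = 0.4, object = NULL) {
  stopifnot(belief >= 0, belief <= 1, noise_sd >= 0, fs > 0, duration >= 1)
  t <- seq(0, duration, by = 1 / fs)
  fmax <- f_base + f_gain * belief
  force <- fmax * plogis((t - t_rise) / tau)
  if (noise_sd > 0)
    force <- force + with_seed(seed, stats::rnorm(length(t), 0, noise_sd))
  structure(list(t = t, force = force, fs = fs,
                 peak_rate_true = fmax / (4 * tau),
                 meta = object), class = "force_trace")
}

#' Synthetic gaze pitch-angle trace
#'
#' A downward pursuit ramp followed by a stationary pre-bounce fixation
#' whose pitch angle equals the belief-driven target (plus optional
#' fixation noise), sampled at 120 samples/s. The fixation lasts at least
#' 100 ms so a dispersion-based detector can find it, and spans the bounce
#' moment. Missing samples (tracking loss) are inserted at the requested
#' rate as `NA`.
#'
#' @param pitch_target fixation pitch angle in degrees (head-centred,
#'   positive = up); shifts in the expected bounce height move this target
#'   additively.
#' @param noise_sd fixation noise SD in degrees.
#' @param missing_frac fraction of samples masked as missing, in \[0, 1).
#' @param seed integer seed.
#' @param fs sampling rate, samples/s.
#' @param duration trace duration, seconds.
#' @param bounce_time time of the ball bounce, seconds.
#' @param fixation_onset start of the pre-bounce fixation, seconds.
#' @param pitch_start pursuit starting pitch, degrees.
#' @return A `gaze_trace`: list with `t`, `pitch`, `fs`, `bounce_index`,
#'   `missing` (logical mask) and `missing_frac`.
#' @export
synth_gaze_trace <- function(pitch_target, noise_sd = 0, missing_frac = 0,
                             seed = 1L, fs = 120, duration = 1.5,
                             bounce_time = 1.2, fixation_onset = 0.8,
                             pitch_start = 20) {
  stopifnot(missing_frac >= 0, missing_frac < 1, fs > 0,
            bounce_time < duration, fixation_onset < bounce_time,
            bounce_time - fixation_onset >= 0.1)
  t <- seq(0, duration, by = 1 / fs)
  n <- length(t)
  pitch <- numeric(n)
  ramp <- t < fixation_onset
  pitch[ramp] <- pitch_start +
    (pitch_target - pitch_start) * t[ramp] / fixation_onset
  pitch[!ramp] <- pitch_target
  out <- with_seed(seed, {
    p <- pitch
    if (noise_sd > 0) p[!ramp] <- p[!ramp] +
        stats::rnorm(sum(!ramp), 0, noise_sd)
    miss <- rep(FALSE, n)
    if (missing_frac > 0)
      miss[sample.int(n, round(missing_frac * n))] <- TRUE
    list(p = p, miss = miss)
  })
  pitch <- out$p
  pitch[out$miss] <- NA_real_
  structure(list(t = t, pitch = pitch, fs = fs,
                 bounce_index = which.min(abs(t - bounce_time)),
                 missing = out$miss, missing_frac = mean(out$miss)),
            class = "gaze_trace")
}
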