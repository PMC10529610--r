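# Preprocessing: raw force/gaze signals and stimulus metadata to the
# binary input (u) and response (y) series the learning models consume.

#' Five-point central-difference derivative
#'
#' First derivative on a uniform grid using the five-point stencil
#' `(f[i-2] - 8 f[i-1] + 8 f[i+1] - f[i+2]) / (12 h)`, which is exact for
#' polynomials up to degree 4 at interior points. The two samples at each
#' edge are returned as `NA`.
#'
#' @param x numeric vector sampled at constant spacing.
#' @param h sample spacing (e.g. `1 / fs`).
#' @return Numeric vector of the same length; edges are `NA`.
#' @export
central_diff5 <- function(x, h = 1) {
  n <- length(x)
  if (n < 5) stop("need at least 5 samples for the 5-point stencil")
  d <- rep(NA_real_, n)
  i <- 3:(n - 2)
  d[i] <- (x[i - 2] - 8 * x[i - 1] + 8 * x[i + 1] - x[i + 2]) / (12 * h)
  d
}

# zero-phase low-pass: 2nd-order Butterworth, forward-backward
butter_lowpass <- function(x, fs, cutoff, order = 2) {
  bf <- signal::butter(order, cutoff / (fs / 2), type = "low")
  as.numeric(signal::filtfilt(bf, x))
}

#' Peak grip-force rate
#'
#' Smooths a grip-force trace with a zero-phase (forward-backward)
#' second-order 14 Hz Butterworth filter, differentiates it with the
#' five-point central-difference stencil, and returns the maximum force
#' rate over the pre-contact window.
#'
#' @param trace a `force_trace`, or a numeric force vector (then supply
#'   `fs`).
#' @param fs sampling rate in samples/s (taken from the trace if given).
#' @param cutoff low-pass cutoff in Hz.
#' @param smooth set `FALSE` to skip filtering (e.g. for analytically
#'   constructed segments).
#' @param contact_index optional sample index of object contact; the peak
#'   is searched before it. Defaults to the whole trace, appropriate for
#'   synthetic lifts that end before contact.
#' @return Peak grip-force rate in N/s.
#' @export
extract_pgfr <- function(trace, fs = NULL, cutoff = 14, smooth = TRUE,
                         contact_index = NULL) {
  if (inherits(trace, "force_trace")) {
    f <- trace$force
    fs <- trace$fs
  } else {
    f <- as.numeric(trace)
    if (is.null(fs)) stop("supply `fs` for a bare numeric trace")
  }
  if (length(f) < 13)
    stop("force trace too short for filtering and differentiation")
  if (smooth) f <- butter_lowpass(f, fs, cutoff)
  d <- central_diff5(f, h = 1 / fs)
  if (!is.null(contact_index))
    d <- d[seq_len(min(contact_index, length(d)))]
  max(d, na.rm = TRUE)
}

#' Baseline-correct a peak grip-force rate
#'
#' Subtracts the pGFR of the final baseline lift, so positive values index
#' an expectation of heaviness relative to the reference object.
#'
#' @param pgfr trial pGFR (N/s), vectorised.
#' @param baseline_pgfr pGFR of the final baseline lift.
#' @return `pgfr - baseline_pgfr`.
#' @export
baseline_correct <- function(pgfr, baseline_pgfr) {
  stopifnot(all(is.finite(pgfr)), is.finite(baseline_pgfr))
  pgfr - baseline_pgfr
}

#' Z-score heaviness ratings within subject
#'
#' Places every subject's heaviness ratings on a common scale by
#' subject-wise standardisation (mean 0, SD 1). Affine-invariant: ratings
#' `a + b * r` (b > 0) yield the same z-scores as `r`.
#'
#' @param ratings numeric ratings.
#' @param subject optional subject id per rating; if omitted all ratings
#'   belong to one subject.
#' @return Z-scored ratings (NA preserved).
#' @export
zscore_ratings <- function(ratings, subject = NULL) {
  if (is.null(subject)) subject <- rep(1L, length(ratings))
  stopifnot(length(subject) == length(ratings))
  out <- rep(NA_real_, length(ratings))
  for (s in unique(subject)) {
    i <- subject == s
    r <- ratings[i]
    sdr <- stats::sd(r, na.rm = TRUE)
    if (!is.finite(sdr) || sdr == 0)
      stop("zero rating variance for subject ", s)
    out[i] <- (r - mean(r, na.rm = TRUE)) / sdr
  }
  out
}

#' Code SWI inputs as a binary series
#'
#' Codes each test trial's input `u` as whether size predicted weight:
#' `u = 1` iff the object was (large and heavy) or (small and light).
#' Veridical coding uses the true masses; felt coding replaces the true
#' heaviness with the subject's felt heaviness, classified as heavy when
#' the z-scored rating exceeds that subject's median rating. Missing
#' ratings yield masked (`NA`) trials in felt mode.
#'
#' @param design a `swi_design`.
#' @param mode `"veridical"` or `"felt"`.
#' @param ratings numeric heaviness ratings over the design's test trials
#'   (required for felt mode).
#' @return Integer 0/1 vector (with possible `NA`) over the test trials.
#' @export
code_swi_inputs <- function(design, mode = c("veridical", "felt"),
                            ratings = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(design, "swi_design"))
  tt <- design$trials[design$trials$phase == "test", ]
  if (mode == "veridical") {
    heavy <- tt$mass_class == "heavy"
  } else {
    if (is.null(ratings)) stop("felt coding requires heaviness ratings")
    stopifnot(length(ratings) == nrow(tt))
    z <- zscore_ratings(ratings)
    heavy <- z > stats::median(z, na.rm = TRUE)
    heavy[is.na(ratings)] <- NA
  }
  as.integer((tt$size_class == "large") == heavy)
}

#' Median-split grip responses into a binary series
#'
#' Per-subject median split of baseline-corrected peak grip-force rates
#' over all test trials: `y = 1` (size taken to predict weight) iff the
#' force was above the median for a large object or at/below the median
#' for a small object. Values exactly at the median fall in the low
#' class.
#'
#' @param pgfr baseline-corrected pGFR per test trial.
#' @param size_class `"small"`/`"large"` per test trial.
#' @return Integer 0/1 vector.
#' @export
discretize_grip_responses <- function(pgfr, size_class) {
  stopifnot(length(pgfr) >= 2, length(pgfr) == length(size_class),
            all(size_class %in% c("small", "large")))
  med <- stats::median(pgfr, na.rm = TRUE)
  high <- pgfr > med
  as.integer(ifelse(size_class == "large", high, !high))
}

#' Detect gaze fixations by spatial dispersion
#'
#' Applies a three-frame median filter and a zero-phase second-order 15 Hz
#' Butterworth filter to the pitch-angle signal, then grows windows whose
#' spatial dispersion (max - min pitch) stays within 3 degrees of visual
#' angle and emits those lasting at least 100 ms. Missing samples are
#' linearly interpolated for detection and tracked as quality flags: a
#' trial with more than 20% missing data or a tracking loss longer than
#' 100 ms is flagged invalid.
#'
#' @param trace a `gaze_trace`, or a numeric pitch vector (then supply
#'   `fs` and optionally `bounce_index`).
#' @param fs sampling rate, samples/s.
#' @param bounce_index sample index of the ball bounce.
#' @param max_disp dispersion threshold, degrees.
#' @param min_dur minimum fixation duration, seconds.
#' @param smooth set `FALSE` to skip the filtering stage.
#' @return A `fixation_set`: `fixations` (data.frame: onset, offset,
#'   duration in seconds, centroid pitch), `bounce_pitch` (the filtered
#'   pitch at the bounce moment when a fixation spans it, `NA`
#'   otherwise), `missing_frac`, `max_gap_ms` and `valid`.
#' @export
detect_fixations <- function(trace, fs = NULL, bounce_index = NULL,
                             max_disp = 3, min_dur = 0.1, smooth = TRUE) {
  if (inherits(trace, "gaze_trace")) {
    pitch <- trace$pitch
    fs <- trace$fs
    if (is.null(bounce_index)) bounce_index <- trace$bounce_index
  } else {
    pitch <- as.numeric(trace)
    if (is.null(fs)) stop("supply `fs` for a bare numeric trace")
  }
  n <- length(pitch)
  if (n / fs < min_dur) stop("gaze trace shorter than the minimum fixation")
  miss <- !is.finite(pitch)
  missing_frac <- mean(miss)
  max_gap <- if (any(miss)) {
    r <- rle(miss)
    max(r$lengths[r$values]) / fs * 1000
  } else 0
  # interpolate missing samples for detection
  if (any(miss)) {
    if (all(miss)) stop("gaze trace entirely missing")
    pitch <- stats::approx(which(!miss), pitch[!miss], xout = seq_len(n),
                           rule = 2)$y
  }
  if (smooth) {
    pitch <- stats::runmed(pitch, 3)
    pitch <- butter_lowpass(pitch, fs, 15)
  }
  minlen <- ceiling(min_dur * fs)
  fix <- list()
  i <- 1L
  while (i + minlen - 1L <= n) {
    j <- i + minlen - 1L
    w <- pitch[i:j]
    if (max(w) - min(w) <= max_disp) {
      hi <- max(w); lo <- min(w)
      while (j < n) {
        nh <- max(hi, pitch[j + 1L]); nl <- min(lo, pitch[j + 1L])
        if (nh - nl > max_disp) break
        hi <- nh; lo <- nl; j <- j + 1L
      }
      fix[[length(fix) + 1L]] <-
        c(i, j, mean(pitch[i:j]))
      i <- j + 1L
    } else i <- i + 1L
  }
  fixations <- if (length(fix)) {
    m <- do.call(rbind, fix)
    data.frame(onset = (m[, 1] - 1) / fs, offset = (m[, 2] - 1) / fs,
               duration = (m[, 2] - m[, 1] + 1) / fs, pitch = m[, 3],
               start_index = as.integer(m[, 1]),
               end_index = as.integer(m[, 2]))
  } else data.frame(onset = numeric(0), offset = numeric(0),
                    duration = numeric(0), pitch = numeric(0),
                    start_index = integer(0), end_index = integer(0))
  # pitch at the moment of bounce, provided a fixation spans it
  bounce_pitch <- NA_real_
  if (!is.null(bounce_index) && nrow(fixations)) {
    hit <- fixations$start_index <= bounce_index &
      fixations$end_index >= bounce_index
    if (any(hit)) bounce_pitch <- pitch[bounce_index]
  }
  structure(list(fixations = fixations, bounce_pitch = bounce_pitch,
                 missing_frac = missing_frac, max_gap_ms = max_gap,
                 valid = missing_frac <= 0.2 && max_gap <= 100),
            class = "fixation_set")
}

#' @export
print.fixation_set <- function(x, ...) {
  cat(sprintf("%d fixation(s); bounce pitch %.2f deg; %.1f%% missing%s\n",
              nrow(x$fixations), x$bounce_pitch, 100 * x$missing_frac,
              if (x$valid) "" else " [INVALID]"))
  if (nrow(x$fixations))
    print(x$fixations[c("onset", "offset", "duration", "pitch")],
          row.names = FALSE)
  invisible(x)
}

#' Screen pitch angles for outliers and excluded subjects
#'
#' Flags values more than 3.29 SD from the mean (two-sided p < .001 under
#' normality) as outliers, and marks subjects whose flagged-plus-missing
#' trials exceed 15% as excluded. The mean and SD are computed once from
#' all finite values, so the screen is idempotent.
#'
#' @param values numeric vector of bounce-fixation pitch angles; `NA`
#'   counts as missing.
#' @param subject subject id per value.
#' @param sd_cut outlier cut in SD units.
#' @param max_bad maximum tolerated fraction of flagged + missing trials
#'   per subject.
#' @return A list: `outlier` (logical per value), `valid` (logical per
#'   value: finite and not an outlier), `bad_frac` (per subject),
#'   `excluded` (subject ids over the threshold).
#' @export
screen_outliers <- function(values, subject = rep(1L, length(values)),
                            sd_cut = 3.29, max_bad = 0.15) {
  stopifnot(length(values) >= 3, length(subject) == length(values))
  fin <- is.finite(values)
  m <- mean(values[fin])
  s <- stats::sd(values[fin])
  outlier <- fin & s > 0 & abs(values - m) > sd_cut * s
  bad <- outlier | !fin
  bad_frac <- tapply(bad, subject, mean)
  excluded <- names(bad_frac)[bad_frac > max_bad]
  list(outlier = outlier, valid = fin & !outlier,
       bad_frac = bad_frac, excluded = excluded)
}

#' Discretise gaze pitch angles into a binary response series
#'
#' Converts per-trial bounce-fixation pitch angles into binary belief
#' shifts: a trial-to-trial upward change greater than one SD of the
#' within-condition changes codes `y = 1` (a shift towards higher
#' p(expected)), a downward change below minus one SD codes `y = 0`, and
#' smaller changes carry the previous response forward. The first trial
#' is initialised to 1, the modal expectation.
#'
#' @param pitch per-trial pitch angles (degrees) within one condition;
#'   `NA` allowed (change skipped, previous y carried).
#' @return Integer 0/1 vector the same length as `pitch`.
#' @export
discretize_gaze_responses <- function(pitch) {
  if (sum(is.finite(pitch)) < 2)
    stop("need at least 2 valid trials to discretise gaze responses")
  d <- c(NA, diff(pitch))
  s <- stats::sd(d, na.rm = TRUE)
  if (!is.finite(s) || s == 0) s <- Inf  # no shifts resolvable
  y <- integer(length(pitch))
  y[1] <- 1L
  for (k in seq_along(pitch)[-1]) {
    y[k] <- if (is.finite(d[k]) && d[k] > s) 1L
    else if (is.finite(d[k]) && d[k] < -s) 0L
    else y[k - 1L]
  }
  y
}
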