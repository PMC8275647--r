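#' Raw physiological signal
#'
#' A uniformly sampled pulse or respiration trace. The container is a thin
#' S3 wrapper carrying the sampling rate and start time so all downstream
#' operations can place samples on the scanner clock.
#'
#' @param samples Numeric vector of signal amplitude (arbitrary units).
#' @param sampling_rate Sampling frequency in Hz (> 0).
#' @param start_time Time of the first sample in seconds (default 0).
#' @param channel Either `"pulse"` or `"respiration"`.
#' @return An object of class `raw_signal`.
#' @export
raw_signal <- function(samples, sampling_rate, start_time = 0,
                       channel = c("pulse", "respiration")) {
  channel <- match.arg(channel)
  samples <- as.numeric(samples)
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1L ||
      sampling_rate <= 0) {
    stop("sampling_rate must be a single positive number")
  }
  if (length(samples) < 2L) stop("need at least 2 samples")
  structure(
    list(samples = samples, sampling_rate = sampling_rate,
         start_time = start_time, channel = channel),
    class = "raw_signal"
  )
}

#' @export
print.raw_signal <- function(x, ...) {
  cat(sprintf("<raw_signal> %s, %d samples @ %g Hz (%.1f s from t=%g s)\n",
              x$channel, length(x$samples), x$sampling_rate,
              length(x$samples) / x$sampling_rate, x$start_time))
  invisible(x)
}

signal_times <- function(x) {
  x$start_time + (seq_along(x$samples) - 1L) / x$sampling_rate
}

#' Inter-beat interval series
#'
#' Beat occurrence times with the derived inter-beat intervals (IBIs) in
#' milliseconds. `flags` records, per interval, whether it is considered
#' valid and whether it was corrected by [clean_ibi()]. Corrected intervals
#' no longer equal the raw beat-time differences; the raw timing is kept so
#' windowed analyses stay on the acquisition clock.
#'
#' @param beat_times Strictly increasing beat times in seconds.
#' @param intervals Optional intervals in ms; defaults to
#'   `diff(beat_times) * 1000`.
#' @param valid Logical per-interval validity flags.
#' @param corrected Logical per-interval correction flags.
#' @return An object of class `ibi_series`.
#' @export
ibi_series <- function(beat_times, intervals = NULL, valid = NULL,
                       corrected = NULL) {
  beat_times <- as.numeric(beat_times)
  if (length(beat_times) < 2L) stop("need at least 2 beats")
  if (any(diff(beat_times) <= 0)) stop("beat_times must be strictly increasing")
  if (is.null(intervals)) intervals <- diff(beat_times) * 1000
  if (length(intervals) != length(beat_times) - 1L) {
    stop("intervals must have length(beat_times) - 1")
  }
  if (any(intervals <= 0)) stop("all intervals must be positive")
  n <- length(intervals)
  if (is.null(valid)) valid <- rep(TRUE, n)
  if (is.null(corrected)) corrected <- rep(FALSE, n)
  structure(
    list(beat_times = beat_times, intervals = as.numeric(intervals),
         flags = data.frame(valid = valid, corrected = corrected)),
    class = "ibi_series"
  )
}

#' @export
print.ibi_series <- function(x, ...) {
  cat(sprintf("<ibi_series> %d beats over %.1f s; mean IBI %.0f ms, %d corrected\n",
              length(x$beat_times), diff(range(x$beat_times)),
              mean(x$intervals), sum(x$flags$corrected)))
  invisible(x)
}

# local maxima of a vector (strict on the left, >= on the right so plateaus
# yield their first sample)
local_maxima <- function(x) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
}

#' Detect heartbeats from a finger-pulse waveform
#'
#' Beats are located on the first derivative of the pulse signal: the rapid
#' amplitude increase on pulse-wave arrival makes the derivative maximum of
#' each upstroke a sharp, drift-insensitive fiducial. A candidate upstroke
#' must exceed an adaptive threshold, `deriv_threshold_frac` times the
#' rolling 10-s maximum of the derivative, and detections closer than
#' `min_ibi` to the previous accepted beat are suppressed (refractory rule).
#'
#' @param signal A `raw_signal` with channel `"pulse"`.
#' @param min_ibi Minimum plausible inter-beat interval in ms (default 300).
#' @param deriv_threshold_frac Fraction of the local derivative maximum a
#'   candidate upstroke must reach (default 0.4).
#' @return An [ibi_series()].
#' @export
detect_pulse_peaks <- function(signal, min_ibi = 300,
                               deriv_threshold_frac = 0.4) {
  if (!inherits(signal, "raw_signal")) stop("signal must be a raw_signal")
  if (signal$channel != "pulse") stop("detect_pulse_peaks needs a pulse channel")
  fs <- signal$sampling_rate
  x <- signal$samples
  # zero-phase low-pass before differentiation: the upstroke lives below
  # ~10 Hz while differentiation amplifies broadband sensor noise
  lp_cut <- min(10, 0.4 * fs / 2)
  bf <- signal::butter(2, lp_cut / (fs / 2), type = "low")
  x <- signal::filtfilt(bf, x)
  d <- diff(x) * fs
  # rolling maximum over a 10 s window, evaluated blockwise for speed
  win <- max(3L, round(10 * fs))
  n <- length(d)
  nblock <- ceiling(n / win)
  block_max <- vapply(seq_len(nblock), function(b) {
    i0 <- (b - 1L) * win + 1L
    max(d[i0:min(n, i0 + win - 1L)])
  }, numeric(1))
  # threshold at sample i uses the max of its block and the neighbours
  roll_max <- vapply(seq_len(nblock), function(b) {
    max(block_max[max(1L, b - 1L):min(nblock, b + 1L)])
  }, numeric(1))
  thr <- deriv_threshold_frac * roll_max[pmin(nblock, (seq_len(n) - 1L) %/% win + 1L)]
  cand <- local_maxima(d)
  cand <- cand[d[cand] > pmax(thr[cand], 0)]
  if (length(cand) < 2L) stop("no beats detected")
  # refractory: among candidates closer than min_ibi, keep the one with
  # the steeper upstroke
  min_gap <- min_ibi / 1000 * fs
  keep <- cand[1L]
  for (i in cand[-1L]) {
    last <- keep[length(keep)]
    if (i - last >= min_gap) {
      keep <- c(keep, i)
    } else if (d[i] > d[last]) {
      keep[length(keep)] <- i
    }
  }
  if (length(keep) < 2L) stop("no beats detected")
  beat_times <- signal$start_time + (keep - 1L) / fs
  ibi_series(beat_times)
}

running_median <- function(x, k = 11L) {
  n <- length(x)
  h <- k %/% 2L
  vapply(seq_len(n), function(i) {
    stats::median(x[max(1L, i - h):min(n, i + h)])
  }, numeric(1))
}

#' Flag and correct inter-beat-interval artifacts
#'
#' An automated stand-in for visual inspection of beat detections.
#' Intervals outside `abs_bounds` or deviating by more than `rel_tol`
#' (fractionally) from an 11-beat running median are flagged invalid and
#' replaced by linear interpolation between the nearest valid neighbours.
#' All replacements are flagged `corrected` so they can be audited. If more
#' than `max_invalid_frac` of intervals are invalid the recording is
#' rejected as unusable.
#'
#' @param ibi An [ibi_series()].
#' @param abs_bounds Plausible IBI range in ms (default `c(300, 2000)`).
#' @param rel_tol Maximum fractional deviation from the running median
#'   (default 0.3).
#' @param max_invalid_frac Rejection threshold on the invalid fraction
#'   (default 0.2).
#' @return An [ibi_series()] with corrected intervals and updated flags.
#' @export
clean_ibi <- function(ibi, abs_bounds = c(300, 2000), rel_tol = 0.3,
                      max_invalid_frac = 0.2) {
  if (!inherits(ibi, "ibi_series")) stop("ibi must be an ibi_series")
  x <- ibi$intervals
  n <- length(x)
  med <- running_median(x, 11L)
  bad <- x < abs_bounds[1] | x > abs_bounds[2] | abs(x - med) / med > rel_tol
  # the usable-recording judgement needs a minimally informative series;
  # very short segments are always corrected rather than rejected
  if (n >= 10L && mean(bad) > max_invalid_frac) {
    stop(sprintf("unusable recording: %.0f%% of intervals invalid",
                 100 * mean(bad)))
  }
  if (any(bad)) {
    good <- which(!bad)
    if (length(good) < 2L) stop("unusable recording: too few valid intervals")
    x[bad] <- stats::approx(good, x[good], xout = which(bad), rule = 2)$y
  }
  out <- ibi_series(ibi$beat_times, intervals = x,
                    valid = !bad, corrected = bad | ibi$flags$corrected)
  attr(out, "n_corrected") <- sum(bad)
  out
}

#' Time-domain heart rate variability metrics
#'
#' Computes mean heart rate and the two standard time-domain HRV measures:
#' SDNN, the sample standard deviation (n-1 denominator) of all intervals,
#' and RMSSD, the root mean square of successive interval differences.
#' Heart rate is defined as `60000 / mean(IBI)` beats per minute.
#'
#' @param ibi An [ibi_series()], or a numeric vector of intervals in ms.
#' @return A list of class `hrv_metrics` with `hr` (bpm), `sdnn` (ms),
#'   `rmssd` (ms) and `n_beats`.
#' @export
hrv_metrics <- function(ibi) {
  x <- if (inherits(ibi, "ibi_series")) ibi$intervals else as.numeric(ibi)
  if (length(x) < 3L) stop("insufficient beats: need at least 3 intervals")
  structure(
    list(hr = 60000 / mean(x),
         sdnn = stats::sd(x),
         rmssd = sqrt(mean(diff(x)^2)),
         n_beats = length(x) + 1L),
    class = "hrv_metrics"
  )
}

#' @export
print.hrv_metrics <- function(x, ...) {
  cat(sprintf("<hrv_metrics> HR %.2f bpm, SDNN %.2f ms, RMSSD %.2f ms (%d beats)\n",
              x$hr, x$sdnn, x$rmssd, x$n_beats))
  invisible(x)
}

#' Detect respiratory peaks and troughs
#'
#' Finds local maxima of the respiration trace with a minimum prominence of
#' 10% of the signal range (guarding against small superimposed wiggles)
#' and a minimum separation of `min_period` seconds; a trough is then
#' placed at the signal minimum between each pair of successive maxima, so
#' peaks and troughs alternate by construction.
#'
#' @param signal A `raw_signal` with channel `"respiration"`.
#' @param min_period Minimum breath period in seconds (default 1.5).
#' @param min_prominence_frac Prominence floor as a fraction of signal
#'   range (default 0.1).
#' @return A list of class `resp_extrema` with `peak_times`, `trough_times`,
#'   `peak_amps`, `trough_amps`.
#' @export
detect_resp_extrema <- function(signal, min_period = 1.5,
                                min_prominence_frac = 0.1) {
  if (!inherits(signal, "raw_signal")) stop("signal must be a raw_signal")
  if (signal$channel != "respiration") {
    stop("detect_resp_extrema needs a respiration channel")
  }
  x <- signal$samples
  fs <- signal$sampling_rate
  rng <- diff(range(x))
  if (rng == 0) stop("no breaths detected: flat signal")
  cand <- local_maxima(x)
  # prominence: height above the higher of the two flanking minima within
  # one min_period on each side
  h <- max(1L, round(min_period * fs))
  prom <- vapply(cand, function(i) {
    lo_l <- min(x[max(1L, i - h):i])
    lo_r <- min(x[i:min(length(x), i + h)])
    x[i] - max(lo_l, lo_r)
  }, numeric(1))
  cand <- cand[prom >= min_prominence_frac * rng]
  # enforce minimum separation, keeping the taller of close pairs
  if (length(cand) > 1L) {
    ord <- cand[order(-x[cand])]
    kept <- integer(0)
    for (i in ord) {
      if (!length(kept) || all(abs(i - kept) >= h)) kept <- c(kept, i)
    }
    cand <- sort(kept)
  }
  if (length(cand) < 2L) stop("no breaths detected")
  tt <- signal_times(signal)
  troughs <- vapply(seq_len(length(cand) - 1L), function(k) {
    seg <- cand[k]:cand[k + 1L]
    seg[which.min(x[seg])]
  }, integer(1))
  structure(
    list(peak_times = tt[cand], trough_times = tt[troughs],
         peak_amps = x[cand], trough_amps = x[troughs]),
    class = "resp_extrema"
  )
}

#' @export
print.resp_extrema <- function(x, ...) {
  cat(sprintf("<resp_extrema> %d maxima, %d minima; mean period %.2f s\n",
              length(x$peak_times), length(x$trough_times),
              mean(diff(x$peak_times))))
  invisible(x)
}

#' Breathing rate from respiratory maxima
#'
#' The inverse of the average interval between successive respiratory
#' maxima, in breaths per minute.
#'
#' @param extrema A [detect_resp_extrema()] result.
#' @return Breathing rate in breaths/min.
#' @export
breathing_rate <- function(extrema) {
  if (!inherits(extrema, "resp_extrema")) stop("extrema must be resp_extrema")
  if (length(extrema$peak_times) < 2L) stop("insufficient breaths")
  60 / mean(diff(extrema$peak_times))
}
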