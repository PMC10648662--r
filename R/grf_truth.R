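# Gold-standard vertical GRF feature extraction from force-plate signals.
#
# Stance is bounded by a 10 N threshold. The impact ("first") peak is
# localized on a high-frequency (HiF) reconstruction of the stance signal:
# the Fourier components below 10 Hz are zeroed and the signal is inverse
# transformed; the earliest local maximum of the HiF signal after 5% of
# stance marks the first-peak time, and the magnitude is read off the
# original force there. The loading rate is the secant slope over 20-80% of
# the onset-to-first-peak interval. The active ("second") peak is the
# largest local maximum after the first peak (global maximum when no first
# peak exists). The average is the arithmetic mean over stance.

#' Detect stance bounds by force threshold
#'
#' Finds the longest run of samples at or above `threshold` and returns its
#' half-open index range. A series that never drops below the threshold is
#' treated as a full-window stance (trimmed recordings may begin mid-stance).
#'
#' @param force numeric vector, vertical force in N.
#' @param threshold stance threshold in N (default 10).
#' @param fs sampling rate in Hz.
#' @return object of class `stance_bounds`: list with `start`, `end`
#'   (1-based, half-open: samples `start:(end - 1)` are stance) and `fs`.
#' @export
detect_stance_bounds <- function(force, threshold = 10, fs = 1000) {
  if (!is.numeric(force) || length(force) == 0) {
    stop("`force` must be a non-empty numeric vector")
  }
  above <- force >= threshold
  if (!any(above)) {
    stop("force never reaches the ", threshold, " N stance threshold")
  }
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  runs <- which(r$values)
  best <- runs[which.max(r$lengths[runs])]
  structure(list(start = starts[best], end = ends[best] + 1L, fs = fs),
            class = "stance_bounds")
}

#' Impact (first) peak via high-frequency spectral reconstruction
#'
#' @param force_stance numeric vector: stance-segmented vertical force (N).
#' @param fs sampling rate in Hz.
#' @param cutoff_hz spectral split frequency; components with |f| below this
#'   are zeroed before the inverse transform (default 10 Hz, DC included).
#' @param gate fraction of stance before which peaks are ignored
#'   (default 0.05).
#' @param min_rel_amplitude minimum HiF value at a qualifying peak,
#'   relative to the peak of the original force. Even an impact-free
#'   stance leaks a few percent of its amplitude into the >= 10 Hz bins
#'   (the windowed half-sine has kinks at its endpoints), so without a
#'   floor the earliest ripple maximum would always be reported; the
#'   default 0.05 separates genuine impact transients from spectral
#'   leakage and filtered noise. Set to 0 for the unthresholded detector.
#' @return list with `magnitude` (N, from the original signal), `time` (s
#'   from stance onset) and `index`, or `NULL` when the HiF signal has no
#'   qualifying local maximum.
#' @export
hif_first_peak <- function(force_stance, fs = 1000, cutoff_hz = 10,
                           gate = 0.05, min_rel_amplitude = 0.05) {
  n <- length(force_stance)
  if (n < 10) stop("stance too short (<10 samples) for spectral analysis")
  X <- stats::fft(force_stance)
  freq <- (seq_len(n) - 1) * fs / n
  freq <- pmin(freq, fs - freq)          # two-sided bin frequencies
  X[freq < cutoff_hz] <- 0 + 0i
  hif <- Re(stats::fft(X, inverse = TRUE)) / n
  peaks <- local_maxima(hif)
  gate_idx <- gate * (n - 1) + 1         # time > 5% of stance duration
  peaks <- peaks[peaks > gate_idx & peaks < n]
  peaks <- peaks[hif[peaks] >= min_rel_amplitude * max(force_stance)]
  if (length(peaks) == 0) return(NULL)
  idx <- peaks[1]
  list(magnitude = force_stance[idx], time = (idx - 1) / fs, index = idx)
}

#' Loading rate over 20-80% of onset to first peak
#'
#' Secant slope of the original force between 20% and 80% of the interval
#' from stance onset (first stance sample) to the first-peak time, with
#' linear interpolation at the fractional sample times.
#'
#' @param force_stance stance-segmented vertical force (N).
#' @param first_peak_time first-peak time in seconds from stance onset, or
#'   `NULL` when no first peak exists.
#' @param fs sampling rate in Hz.
#' @return slope in N/s, or `NA_real_` when the first peak is absent or the
#'   20-80% window spans fewer than 2 samples.
#' @export
loading_rate <- function(force_stance, first_peak_time, fs = 1000) {
  if (is.null(first_peak_time) || is.na(first_peak_time)) return(NA_real_)
  t20 <- 0.2 * first_peak_time
  t80 <- 0.8 * first_peak_time
  if ((t80 - t20) * fs < 2) return(NA_real_)
  tt <- (seq_along(force_stance) - 1) / fs
  f20 <- stats::approx(tt, force_stance, xout = t20)$y
  f80 <- stats::approx(tt, force_stance, xout = t80)$y
  (f80 - f20) / (t80 - t20)
}

#' Active (second) peak magnitude
#'
#' The maximum of the vertical GRF, or, when an impact peak precedes it, the
#' largest local maximum after the first-peak time (falling back to the
#' global maximum when none exists).
#'
#' @param force_stance stance-segmented vertical force (N).
#' @param first_peak_index sample index of the first peak, or `NULL`.
#' @return force in N.
#' @export
second_peak <- function(force_stance, first_peak_index = NULL) {
  if (is.null(first_peak_index) || is.na(first_peak_index)) {
    return(max(force_stance))
  }
  peaks <- local_maxima(force_stance)
  peaks <- peaks[peaks > first_peak_index]
  if (length(peaks) == 0) return(max(force_stance))
  max(force_stance[peaks])
}

#' Average force across stance
#'
#' @param force_stance stance-segmented vertical force (N).
#' @return arithmetic mean in N.
#' @export
average_force <- function(force_stance) {
  if (length(force_stance) == 0) stop("empty stance")
  mean(force_stance)
}

#' Classify foot strike from foot strike angle
#'
#' Foot strike angle (FSA) is the sagittal foot angle at initial contact
#' relative to quiet standing, positive when dorsiflexed. Angles above
#' 0.14 rad are rear-foot strikes (RFS), angles in [-0.03, 0.14] rad
#' mid-foot strikes (MFS), and angles below -0.03 rad forefoot strikes (FFS).
#'
#' @param fsa numeric vector of foot strike angles (radians).
#' @return character vector of labels in {"RFS", "MFS", "FFS"}.
#' @export
classify_foot_strike <- function(fsa) {
  if (any(!is.finite(fsa))) stop("foot strike angle must be finite")
  ifelse(fsa > 0.14, "RFS", ifelse(fsa >= -0.03, "MFS", "FFS"))
}

#' Extract all gold-standard vGRF features from a force recording
#'
#' Applies a zero-phase 4th-order low-pass Butterworth filter (default
#' 50 Hz), detects stance by threshold, then computes the impact peak,
#' loading rate, active peak, and stance average.
#'
#' @param force raw vertical force series in N (may include pre/post-stance
#'   samples).
#' @param fs sampling rate in Hz.
#' @param threshold stance threshold in N.
#' @param cutoff low-pass cutoff in Hz, or `NULL` to skip filtering.
#' @return object of class `grf_features`: list with `first_peak`,
#'   `first_peak_time`, `loading_rate`, `second_peak`, `average`,
#'   `time_series` (stance-segmented filtered force), `bounds`, `fs`.
#' @export
extract_features <- function(force, fs = 1000, threshold = 10, cutoff = 50) {
  filtered <- if (is.null(cutoff)) force else lowpass_filter(force, fs, cutoff)
  bounds <- detect_stance_bounds(filtered, threshold, fs)
  stance <- filtered[bounds$start:(bounds$end - 1)]
  fp <- hif_first_peak(stance, fs)
  grf_features(
    first_peak = if (is.null(fp)) NA_real_ else fp$magnitude,
    first_peak_time = if (is.null(fp)) NA_real_ else fp$time,
    loading_rate = loading_rate(stance,
                                if (is.null(fp)) NULL else fp$time, fs),
    second_peak = second_peak(stance, if (is.null(fp)) NULL else fp$index),
    average = average_force(stance),
    time_series = stance, bounds = bounds, fs = fs)
}

#' Construct a GRF feature set
#'
#' Container for the five vGRF targets of one stance: first (impact) peak,
#' loading rate, second (active) peak, stance average, and the stance time
#' series. Absent features (e.g. no impact transient) are `NA`.
#'
#' @param first_peak,first_peak_time,loading_rate,second_peak,average
#'   scalar features (N, s, N/s, N, N).
#' @param time_series stance force series (N) or `NULL`.
#' @param bounds optional `stance_bounds`.
#' @param fs sampling rate in Hz.
#' @return object of class `grf_features`.
#' @export
grf_features <- function(first_peak = NA_real_, first_peak_time = NA_real_,
                         loading_rate = NA_real_, second_peak = NA_real_,
                         average = NA_real_, time_series = NULL,
                         bounds = NULL, fs = 1000) {
  structure(list(first_peak = first_peak, first_peak_time = first_peak_time,
                 loading_rate = loading_rate, second_peak = second_peak,
                 average = average, time_series = time_series,
                 bounds = bounds, fs = fs),
            class = "grf_features")
}

#' @export
print.grf_features <- function(x, ...) {
  cat("vGRF features:\n")
  cat(sprintf("  first peak   : %s\n",
              if (is.na(x$first_peak)) "absent"
              else sprintf("%.1f N at %.3f s", x$first_peak,
                           x$first_peak_time)))
  cat(sprintf("  loading rate : %s\n",
              if (is.na(x$loading_rate)) "absent"
              else sprintf("%.0f N/s", x$loading_rate)))
  cat(sprintf("  second peak  : %.1f N\n", x$second_peak))
  cat(sprintf("  average      : %.1f N\n", x$average))
  if (!is.null(x$time_series)) {
    cat(sprintf("  time series  : %d samples at %g Hz\n",
                length(x$time_series), x$fs))
  }
  invisible(x)
}

# names of the five estimable features, in reporting order
grf_feature_names <- function() {
  c("first_peak", "loading_rate", "second_peak", "average", "time_series")
}
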