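# Round half-up to an integer sample index.
round_half_up <- function(x) floor(x + 0.5)

# Odd Savitzky-Golay window closest to 50 ms at rate fs (51 at 1000 Hz).
sg_window_for <- function(fs) max(2L * floor(0.05 * fs / 2) + 1L, 5L)

#' Savitzky-Golay smoothing of one channel
#'
#' Second-order Savitzky-Golay filter with a 50 ms window (odd sample count
#' nearest 50 ms at the given rate; 51 samples at 1000 Hz). Length preserving;
#' exactly reproduces quadratics in the window interior.
#'
#' @param x numeric vector.
#' @param fs sample rate in Hz.
#' @return smoothed numeric vector of the same length.
#' @export
smooth_channel <- function(x, fs = 1000) {
  w <- sg_window_for(fs)
  if (w >= length(x)) stop("signal shorter than the smoothing window")
  signal::sgolayfilt(x, p = 2, n = w)
}

#' Isoelectric baseline before the QRS onset
#'
#' Median amplitude of the 30 ms window ending at (and excluding) the QRS
#' onset. A window truncated by the record start is used as long as at least
#' 10 ms of samples remain; otherwise `NA` is returned and the beat is
#' excluded on that channel.
#'
#' @param x channel samples (microvolts).
#' @param qrs_onset onset sample index.
#' @param fs sample rate in Hz.
#' @return baseline level in microvolts, or `NA`.
#' @export
compute_baseline <- function(x, qrs_onset, fs = 1000) {
  lo <- qrs_onset - round(0.030 * fs)
  hi <- qrs_onset - 1L
  lo <- max(lo, 1L)
  if (hi < 1L || hi - lo + 1L < round(0.010 * fs)) return(NA_real_)
  stats::median(x[lo:hi])
}

#' Local T peak within the beat's search window
#'
#' The extremum (maximum or minimum) with the largest absolute amplitude
#' relative to the baseline, searched between R + 50 ms and R + 70% of the
#' preceding RR interval.
#'
#' @param x smoothed channel samples.
#' @param r_peak R-peak sample index.
#' @param rr_prev preceding RR interval in ms.
#' @param baseline baseline level in microvolts.
#' @param fs sample rate in Hz.
#' @return list with `t_peak` (index) and `t_amp` (signed microvolts relative
#'   to baseline), or `NULL` when the window leaves the record.
#' @export
find_local_t_peak <- function(x, r_peak, rr_prev, baseline, fs = 1000) {
  lo <- r_peak + round(0.050 * fs)
  hi <- r_peak + round(0.7 * rr_prev / 1000 * fs)
  if (lo >= hi || hi > length(x)) return(NULL)
  dev <- x[lo:hi] - baseline
  i <- which.max(abs(dev))
  list(t_peak = lo + i - 1L, t_amp = dev[i])
}

#' T-wave end by the tangent method
#'
#' Within `[t_peak, t_peak + 0.3 RR]`, finds the point of maximal deflection
#' directed from the T extremum toward the baseline, using the +/-5 ms
#' central-difference derivative `(V(t+5) - V(t-5)) / 10`. The tangent line
#' through that point intersected with the baseline level gives the T end
#' (continuous-time crossing, rounded half-up to a sample).
#'
#' @param x smoothed channel samples.
#' @param t_peak local T-peak sample index.
#' @param t_amp signed T amplitude relative to baseline (microvolts).
#' @param rr_prev preceding RR in ms.
#' @param baseline baseline level (microvolts).
#' @param fs sample rate in Hz.
#' @return list with `t_end`, `slope_point` (indices) and `reason` (`""` on
#'   success; `"window"`, `"flat"` or `"no-crossing"` on exclusion).
#' @export
tangent_t_end <- function(x, t_peak, t_amp, rr_prev, baseline, fs = 1000) {
  fail <- function(reason) list(t_end = NA_integer_,
                                slope_point = NA_integer_, reason = reason)
  n <- length(x)
  hi <- t_peak + round(0.3 * rr_prev / 1000 * fs)
  h <- round(0.005 * fs)
  if (hi > n) return(fail("window"))
  lo <- max(t_peak, h + 1L)
  hi_d <- min(hi, n - h)
  if (lo > hi_d) return(fail("window"))
  idx <- lo:hi_d
  ms_per_sample <- 1000 / fs
  slope <- (x[idx + h] - x[idx - h]) / (2 * h * ms_per_sample)  # uV per ms
  if (t_amp >= 0) {
    j <- which.min(slope)
    if (slope[j] >= 0) return(fail("no-crossing"))
  } else {
    j <- which.max(slope)
    if (slope[j] <= 0) return(fail("no-crossing"))
  }
  if (abs(slope[j]) < 0.1) return(fail("flat"))  # < 1 uV per 10 ms
  sp <- idx[j]
  cross <- sp + (baseline - x[sp]) / (slope[j] * ms_per_sample)
  if (cross < sp) return(fail("no-crossing"))
  limit <- t_peak + 0.5 * rr_prev / 1000 * fs
  if (cross > limit || cross > n) return(fail("no-crossing"))
  t_end <- round_half_up(cross)
  if (t_end <= t_peak) return(fail("no-crossing"))
  list(t_end = as.integer(t_end), slope_point = sp, reason = "")
}

#' Apply the 50 uV T-amplitude exclusion rule
#'
#' Landmarks from the 12 standard leads with `|t_amp| < 50` uV are excluded
#' (reason `"low-amplitude"`; strict inequality). The scalar channels
#' (`RMS`, `SD`, `VCGMAG`) are never excluded by this rule.
#'
#' @param landmarks data frame of channel landmarks with columns `channel`,
#'   `t_amp`, `included`, `reason`.
#' @return the data frame with the rule applied.
#' @export
apply_amplitude_rule <- function(landmarks) {
  hit <- landmarks$channel %in% STANDARD_LEADS &
    landmarks$included & abs(landmarks$t_amp) < 50
  landmarks$included[hit] <- FALSE
  landmarks$reason[hit] <- "low-amplitude"
  landmarks
}

#' Delineate T-wave landmarks on every channel of every beat
#'
#' For each channel (12 standard leads plus scalar channels, whichever are
#' present) and each beat with a defined preceding RR and QRS onset:
#' smooths the channel, measures the baseline, locates the local T peak and
#' the tangent T end, and applies the 50 uV amplitude rule.
#'
#' @param record a conditioned [ecg_record] (canonical rate) with scalar
#'   channels appended.
#' @param fiducials data frame from [beat_fiducials].
#' @param channels channel labels to delineate; default: all standard leads
#'   and scalar channels present in the record.
#' @return data frame, one row per beat x channel: `beat`, `channel`,
#'   `t_peak`, `t_end`, `t_amp`, `baseline`, `slope_point`, `included`,
#'   `reason`.
#' @export
delineate_channels <- function(record, fiducials, channels = NULL) {
  fs <- record$fs
  if (is.null(channels))
    channels <- intersect(c(STANDARD_LEADS, SCALAR_LEADS),
                          colnames(record$samples))
  beats <- fiducials[!is.na(fiducials$rr_prev) & !is.na(fiducials$qrs_onset), ]
  empty <- data.frame(beat = integer(0), channel = character(0),
                      t_peak = integer(0), t_end = integer(0),
                      t_amp = numeric(0), baseline = numeric(0),
                      slope_point = integer(0), included = logical(0),
                      reason = character(0), stringsAsFactors = FALSE)
  if (nrow(beats) == 0L || !length(channels)) return(empty)
  rows <- vector("list", length(channels))
  for (ci in seq_along(channels)) {
    ch <- channels[ci]
    xs <- smooth_channel(record$samples[, ch], fs)
    out <- data.frame(beat = beats$beat, channel = ch,
                      t_peak = NA_integer_, t_end = NA_integer_,
                      t_amp = NA_real_, baseline = NA_real_,
                      slope_point = NA_integer_,
                      included = FALSE, reason = "",
                      stringsAsFactors = FALSE)
    for (k in seq_len(nrow(beats))) {
      b <- beats[k, ]
      base <- compute_baseline(xs, b$qrs_onset, fs)
      if (is.na(base)) { out$reason[k] <- "baseline"; next }
      pk <- find_local_t_peak(xs, b$r_peak, b$rr_prev, base, fs)
      if (is.null(pk)) { out$reason[k] <- "window"; next }
      te <- tangent_t_end(xs, pk$t_peak, pk$t_amp, b$rr_prev, base, fs)
      out$t_peak[k] <- pk$t_peak
      out$t_amp[k] <- pk$t_amp
      out$baseline[k] <- base
      if (nzchar(te$reason)) { out$reason[k] <- te$reason; next }
      out$t_end[k] <- te$t_end
      out$slope_point[k] <- te$slope_point
      out$included[k] <- TRUE
    }
    rows[[ci]] <- out
  }
  apply_amplitude_rule(do.call(rbind, rows))
}
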