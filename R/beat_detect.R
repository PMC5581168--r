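#' Detect R peaks on the RMS channel (Pan-Tompkins)
#'
#' Pan-Tompkins detector applied to the nonnegative cross-lead RMS channel:
#' 5-15 Hz band-pass, derivative, squaring, 150 ms moving-window integration,
#' adaptive dual thresholds with a 200 ms refractory period and search-back.
#' Each detection is refined to the RMS argmax within +/-30 ms.
#'
#' @param rms numeric vector, the RMS scalar channel in microvolts.
#' @param fs sample rate in Hz (canonical rate, 1000 Hz, expected).
#' @return integer vector of R-peak sample indices (possibly empty).
#' @export
detect_r_peaks <- function(rms, fs = 1000) {
  n <- length(rms)
  if (n < 2 * fs) return(integer(0L))
  if (max(rms) - min(rms) < 1e-9) return(integer(0L))

  bp <- signal::butter(2, c(5, 15) / (fs / 2), type = "pass")
  xf <- apply_padded(rms, round(fs), function(z) signal::filtfilt(bp, z))
  der <- c(0, diff(xf))
  sq <- der^2
  w <- max(1L, round(0.150 * fs))
  mwi <- as.numeric(stats::filter(sq, rep(1 / w, w), sides = 1))
  mwi[is.na(mwi)] <- 0

  refr <- round(0.2 * fs)
  cand <- local_maxima(mwi, min_dist = refr)
  if (!length(cand)) return(integer(0L))

  # adaptive thresholds, textbook update rules
  init <- mwi[seq_len(min(n, 2 * fs))]
  spki <- max(init) * 0.6
  npki <- mean(init) * 0.5
  qrs_mwi <- integer(0L)
  rr_hist <- numeric(0L)
  last <- -Inf
  for (i in cand) {
    thr <- npki + 0.25 * (spki - npki)
    if (mwi[i] > thr && i - last >= refr) {
      spki <- 0.125 * mwi[i] + 0.875 * spki
      qrs_mwi <- c(qrs_mwi, i)
      if (length(qrs_mwi) > 1L)
        rr_hist <- utils::tail(c(rr_hist, i - last), 8L)
      last <- i
    } else {
      npki <- 0.125 * mwi[i] + 0.875 * npki
      # search-back: if a long gap elapsed, accept the best candidate above
      # half threshold
      rr_avg <- if (length(rr_hist)) mean(rr_hist) else NA_real_
      if (!is.na(rr_avg) && i - last > 1.66 * rr_avg && mwi[i] > thr / 2 &&
          i - last >= refr) {
        spki <- 0.25 * mwi[i] + 0.75 * spki
        qrs_mwi <- c(qrs_mwi, i)
        rr_hist <- utils::tail(c(rr_hist, i - last), 8L)
        last <- i
      }
    }
  }
  if (!length(qrs_mwi)) return(integer(0L))

  # the MWI peak lags the R wave: locate the RMS maximum in the 150 ms
  # window before each MWI peak, then refine within +/-30 ms
  r <- vapply(qrs_mwi, function(i) {
    lo <- max(1L, i - w)
    lo - 1L + which.max(rms[lo:i])
  }, numeric(1L))
  half <- round(0.03 * fs)
  r <- vapply(r, function(i) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    lo - 1L + which.max(rms[lo:hi])
  }, numeric(1L))
  r <- as.integer(r)
  r <- sort(unique(r))
  # enforce refractory on the refined peaks (keep the larger of close pairs)
  keep <- logical(length(r))
  last <- -Inf; lastk <- 0L
  for (j in seq_along(r)) {
    if (r[j] - last >= refr) {
      keep[j] <- TRUE; last <- r[j]; lastk <- j
    } else if (rms[r[j]] > rms[r[lastk]]) {
      keep[lastk] <- FALSE; keep[j] <- TRUE; last <- r[j]; lastk <- j
    }
  }
  r[keep]
}

# Indices of local maxima separated by at least min_dist samples (greedy,
# by descending height).
local_maxima <- function(x, min_dist) {
  n <- length(x)
  if (n < 3L) return(integer(0L))
  i <- which(x[2:(n - 1L)] >= x[1:(n - 2L)] & x[2:(n - 1L)] > x[3:n]) + 1L
  i[order(i)]
}

#' Locate the QRS onset from the second derivative of the RMS channel
#'
#' The QRS onset is the sample with the largest (signed) second derivative of
#' the RMS channel within the window 100 to 20 ms before the R peak; the
#' upstroke of the nonnegative RMS complex makes positive curvature the
#' onset signature. Ties break toward the later sample (closer to R).
#'
#' @param rms numeric vector, RMS channel.
#' @param r_peak R-peak sample index.
#' @param fs sample rate in Hz.
#' @return onset sample index, or `NA_integer_` when the window would extend
#'   before the record start (beat flagged and skipped upstream).
#' @export
detect_qrs_onset <- function(rms, r_peak, fs = 1000) {
  lo <- r_peak - round(0.100 * fs)
  hi <- r_peak - round(0.020 * fs)
  if (lo < 2L) return(NA_integer_)
  d2 <- rms[(lo - 1L):(hi + 1L)]
  d2 <- d2[3:length(d2)] - 2 * d2[2:(length(d2) - 1L)] +
    d2[1:(length(d2) - 2L)]
  idx <- which(d2 == max(d2))
  as.integer(lo + idx[length(idx)] - 1L)
}

#' Per-beat fiducials: R peaks, QRS onsets, preceding RR
#'
#' @param rms RMS channel at the canonical rate.
#' @param fs sample rate in Hz.
#' @return data frame with columns `beat`, `r_peak`, `qrs_onset` (sample
#'   indices; `qrs_onset` is `NA` for beats whose onset window leaves the
#'   record) and `rr_prev` (ms; `NA` for the first beat).
#' @export
beat_fiducials <- function(rms, fs = 1000) {
  r <- detect_r_peaks(rms, fs)
  onset <- vapply(r, function(i) detect_qrs_onset(rms, i, fs), integer(1L))
  rr <- if (length(r)) c(NA_real_, diff(r)) * 1000 / fs else numeric(0)
  data.frame(beat = seq_along(r), r_peak = r, qrs_onset = onset,
             rr_prev = rr)
}
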