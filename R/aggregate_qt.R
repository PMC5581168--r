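# Median with even counts resolved as the mean of the two middle values,
# rounded half-up to a sample index.
median_sample <- function(x) round_half_up(stats::median(x))

#' Fuse local landmarks into a global landmark (median with 2-SD rejection)
#'
#' Given the included local landmark positions across channels: values whose
#' absolute deviation from the median exceeds twice the standard deviation
#' (population SD of the included values) are excluded in a single pass, and
#' the global landmark is the median of the survivors (even counts: mean of
#' the two middle values, rounded half-up to a sample). If the SD is zero,
#' nothing is excluded.
#'
#' @param values numeric vector of included local landmark sample indices.
#' @return list with `global` (sample index), `n_used` (survivor count) and
#'   `kept` (logical vector aligned with `values`).
#' @export
fuse_landmarks <- function(values) {
  if (!length(values)) stop("no included landmarks to fuse")
  med <- stats::median(values)
  sd_pop <- sqrt(mean((values - mean(values))^2))
  kept <- if (sd_pop == 0) rep(TRUE, length(values))
          else abs(values - med) <= 2 * sd_pop
  list(global = median_sample(values[kept]),
       n_used = sum(kept), kept = kept)
}

#' Bazett heart-rate correction of the QT interval
#'
#' `QTc = QT / sqrt(RR / 1000)` with QT and RR in ms.
#'
#' @param qt QT interval in ms.
#' @param rr_prev preceding RR interval in ms.
#' @return QTc in ms (`NaN` when `rr_prev` is missing).
#' @export
qtc_bazett <- function(qt, rr_prev) {
  ifelse(is.na(rr_prev), NaN, qt / sqrt(rr_prev / 1000))
}

#' Local QT intervals per channel
#'
#' For every included channel landmark: local T end minus the global QRS
#' onset, in ms. Excluded channels are absent from the result. These local
#' intervals feed QT-dispersion measures.
#'
#' @param landmarks data frame of one beat's channel landmarks (columns
#'   `channel`, `t_end`, `included`).
#' @param qrs_onset global QRS-onset sample index for the beat.
#' @param fs sample rate in Hz.
#' @return named numeric vector, channel -> local QT in ms.
#' @export
local_qt_intervals <- function(landmarks, qrs_onset, fs = 1000) {
  inc <- landmarks[landmarks$included, ]
  stats::setNames((inc$t_end - qrs_onset) * 1000 / fs, inc$channel)
}

#' Aggregate channel landmarks into per-beat measurements
#'
#' Applies the median/2-SD fusion independently to the local T peaks and
#' T ends of each beat, computes QT (global T end minus QRS onset), Bazett
#' QTc and the per-channel local QT intervals, and emits one measurement row
#' per beat. Per-beat flags: `no-T` (no included landmark; beat not emitted
#' unless `keep_empty`), `low-n` (fewer than 4 surviving channels), `edge`
#' (no QRS onset or no preceding RR).
#'
#' @param landmarks data frame from [delineate_channels].
#' @param fiducials data frame from [beat_fiducials].
#' @param fs sample rate in Hz.
#' @return a measurement table (see [measurement_table]) plus a `local_qt`
#'   attribute: a list (one element per emitted beat) of named local-QT
#'   vectors.
#' @export
measure_beats <- function(landmarks, fiducials, fs = 1000) {
  ms <- function(idx) (idx - 1L) * 1000 / fs
  rows <- list(); locals <- list()
  for (k in seq_len(nrow(fiducials))) {
    f <- fiducials[k, ]
    if (is.na(f$qrs_onset) || is.na(f$rr_prev)) next  # "edge": not measurable
    lm <- landmarks[landmarks$beat == f$beat, ]
    inc <- lm[lm$included, ]
    if (nrow(inc) == 0L) next                         # "no-T": not emitted
    fp <- fuse_landmarks(inc$t_peak)
    fe <- fuse_landmarks(inc$t_end)
    qt <- (fe$global - f$qrs_onset) * 1000 / fs
    flags <- character(0L)
    if (fe$n_used < 4L) flags <- c(flags, "low-n")
    rows[[length(rows) + 1L]] <- data.frame(
      beat = f$beat,
      r_ms = ms(f$r_peak),
      qrs_onset_ms = ms(f$qrs_onset),
      rr_prev_ms = f$rr_prev,
      t_peak_ms = ms(fp$global),
      t_end_ms = ms(fe$global),
      qt_ms = qt,
      qtc_ms = qtc_bazett(qt, f$rr_prev),
      n_used = fe$n_used,
      flags = paste(flags, collapse = ";"),
      stringsAsFactors = FALSE)
    locals[[length(locals) + 1L]] <- local_qt_intervals(lm, f$qrs_onset, fs)
  }
  tab <- if (length(rows)) do.call(rbind, rows)
         else stats::setNames(
           data.frame(integer(0), numeric(0), numeric(0), numeric(0),
                      numeric(0), numeric(0), numeric(0), numeric(0),
                      integer(0), character(0), stringsAsFactors = FALSE),
           MEASUREMENT_COLUMNS)
  tab <- measurement_table(tab)
  attr(tab, "local_qt") <- locals
  tab
}
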