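#' End-to-end beat-to-beat QT measurement
#'
#' Runs the full chain on a raw multi-lead record: pre-processing (band-pass,
#' notch, baseline removal, resampling to the canonical rate), scalar-channel
#' construction, Pan-Tompkins R detection and QRS-onset location on the RMS
#' channel, per-channel tangent T-end delineation, and median/2-SD fusion
#' into per-beat global landmarks.
#'
#' @param record a raw [ecg_record] containing at least leads I, II and
#'   V1-V6.
#' @param spec a [filter_spec]; its `target_fs` is the analysis rate.
#' @param channels optional channel subset for delineation (default: all
#'   standard leads and scalar channels).
#' @param qc if `TRUE`, the per-channel landmark table is returned for
#'   quality control.
#' @return list with `measurements` (a measurement table, see
#'   [measurement_table]), `fiducials`, `clean` (the conditioned record with
#'   scalar channels), and `landmarks` (when `qc = TRUE`).
#' @export
qt_pipeline <- function(record, spec = filter_spec(), channels = NULL,
                        qc = FALSE) {
  clean <- preprocess_ecg(record, spec)
  clean <- add_scalar_channels(clean)
  fs <- clean$fs
  fid <- beat_fiducials(ecg_channel(clean, "RMS"), fs)
  landmarks <- delineate_channels(clean, fid, channels)
  meas <- measure_beats(landmarks, fid, fs)
  out <- list(measurements = meas, fiducials = fid, clean = clean)
  if (qc) out$landmarks <- landmarks
  out
}
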