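#' Multi-lead ECG record
#'
#' Container for a multi-lead ECG: a samples-by-leads numeric matrix in
#' microvolts, the sample rate in Hz and a start-time offset in seconds.
#' Sample index `i` (1-based) corresponds to time `t0 + (i - 1) / fs` seconds;
#' millisecond values appear only at the API surface.
#'
#' @param samples numeric matrix, one column per lead, one row per sample,
#'   amplitudes in microvolts.
#' @param lead_names character vector of channel labels; defaults to
#'   `colnames(samples)`. The 12 standard labels (I, II, III, aVR, aVL, aVF,
#'   V1-V6) are recognized case-insensitively and normalized to their
#'   canonical spelling.
#' @param fs sample rate in Hz (> 0).
#' @param t0 start time offset in seconds (default 0).
#'
#' @return An object of class `ecg_record` with elements `samples`, `fs`, `t0`.
#' @export
ecg_record <- function(samples, lead_names = colnames(samples), fs, t0 = 0) {
  if (is.data.frame(samples)) samples <- as.matrix(samples)
  if (!is.matrix(samples) || !is.numeric(samples))
    stop("'samples' must be a numeric matrix (samples x leads)")
  if (nrow(samples) < 1L) stop("record must contain at least one sample")
  if (anyNA(samples)) stop("'samples' contains missing values")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("'fs' must be a single positive number")
  if (is.null(lead_names)) stop("lead names are required")
  lead_names <- normalize_lead_names(as.character(lead_names))
  if (length(lead_names) != ncol(samples))
    stop("length of 'lead_names' does not match number of channels")
  if (anyDuplicated(lead_names))
    stop("lead names must be unique")
  colnames(samples) <- lead_names
  structure(list(samples = samples, fs = fs, t0 = t0),
            class = "ecg_record")
}

#' @export
print.ecg_record <- function(x, ...) {
  cat(sprintf("<ecg_record> %d leads x %d samples @ %g Hz (%.1f s)\n",
              ncol(x$samples), nrow(x$samples), x$fs,
              nrow(x$samples) / x$fs))
  cat("  leads:", paste(colnames(x$samples), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.ecg_record <- function(x) dim(x$samples)

# Canonical names of the 12 standard leads, in the canonical order.
STANDARD_LEADS <- c("I", "II", "III", "aVR", "aVL", "aVF",
                    "V1", "V2", "V3", "V4", "V5", "V6")

# Names reserved for the derived scalar channels.
SCALAR_LEADS <- c("RMS", "SD", "VCGMAG")

#' Normalize ECG lead names
#'
#' Maps the 12 standard lead labels (and the reserved scalar-channel labels)
#' to their canonical spelling, case-insensitively. Unrecognized labels are
#' returned unchanged. The mapping is idempotent.
#'
#' @param x character vector of channel labels.
#' @return character vector of the same length.
#' @export
normalize_lead_names <- function(x) {
  canon <- c(STANDARD_LEADS, SCALAR_LEADS)
  idx <- match(toupper(trimws(x)), toupper(canon))
  out <- trimws(x)
  out[!is.na(idx)] <- canon[idx[!is.na(idx)]]
  out
}

#' Extract one channel of an ECG record
#'
#' @param record an `ecg_record`.
#' @param lead channel label (normalized before lookup).
#' @return numeric vector of samples in microvolts.
#' @export
ecg_channel <- function(record, lead) {
  lead <- normalize_lead_names(lead)
  if (!lead %in% colnames(record$samples))
    stop(sprintf("lead '%s' not present in record", lead))
  record$samples[, lead]
}

# Reorder channels to the canonical 12-lead order when all 12 are present;
# scalar channels (if any) follow. Otherwise the original order is kept.
order_leads_canonical <- function(record) {
  nm <- colnames(record$samples)
  if (all(STANDARD_LEADS %in% nm)) {
    rest <- setdiff(nm, STANDARD_LEADS)
    record$samples <- record$samples[, c(STANDARD_LEADS, rest), drop = FALSE]
  }
  record
}
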