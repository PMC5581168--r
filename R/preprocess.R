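#' Filter specification for the pre-processing chain
#'
#' Collects the parameters of the conditioning chain applied before
#' delineation: a 2nd-order bidirectional Butterworth band-pass, a 2nd-order
#' IIR power-line notch, per-lead running-median baseline correction and
#' resampling to the canonical 1000 Hz analysis rate.
#'
#' @param bp_low,bp_high band-pass corner frequencies in Hz (defaults 0.5 and
#'   100; design corners of the single pass, at -3 dB).
#' @param bp_order Butterworth prototype order (default 2).
#' @param notch_freq power-line notch center in Hz (default 50).
#' @param notch_bw3db -3 dB bandwidth of the notch in Hz (default 0.33).
#' @param baseline_window running-median window in samples at the native rate;
#'   `NULL` (default) selects the odd sample count closest to 835 ms at the
#'   record's rate (501 samples at 600 Hz).
#' @param target_fs canonical analysis rate in Hz (default 1000).
#'
#' @return an object of class `filter_spec`.
#' @export
filter_spec <- function(bp_low = 0.5, bp_high = 100, bp_order = 2,
                        notch_freq = 50, notch_bw3db = 0.33,
                        baseline_window = NULL, target_fs = 1000) {
  if (!(bp_low > 0 && bp_low < bp_high))
    stop("require 0 < bp_low < bp_high")
  if (notch_bw3db <= 0) stop("notch_bw3db must be positive")
  if (!is.null(baseline_window)) {
    if (baseline_window < 3 || baseline_window %% 2 == 0)
      stop("baseline_window must be odd and >= 3")
  }
  structure(list(bp_low = bp_low, bp_high = bp_high, bp_order = bp_order,
                 notch_freq = notch_freq, notch_bw3db = notch_bw3db,
                 baseline_window = baseline_window, target_fs = target_fs),
            class = "filter_spec")
}

#' Read a filter specification from a key=value config file
#'
#' Unknown keys error; missing keys keep their defaults. Values are parsed
#' as numbers.
#'
#' @param path config file path; lines of the form `key = value`, `#` comments
#'   allowed.
#' @return a [filter_spec].
#' @export
filter_spec_from_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  kv <- strsplit(lines, "\\s*=\\s*")
  bad <- lengths(kv) != 2L
  if (any(bad)) stop("malformed config line: ", lines[bad][1L])
  keys <- vapply(kv, `[[`, "", 1L)
  vals <- suppressWarnings(as.numeric(vapply(kv, `[[`, "", 2L)))
  allowed <- names(formals(filter_spec))
  unknown <- setdiff(keys, allowed)
  if (length(unknown)) stop("unknown config key(s): ",
                            paste(unknown, collapse = ", "))
  if (anyNA(vals)) stop("non-numeric config value for key: ",
                        keys[which(is.na(vals))[1L]])
  do.call(filter_spec, as.list(stats::setNames(vals, keys)))
}

# Odd running-median window (samples) closest to 835 ms at rate fs;
# gives the specified 501 samples at 600 Hz.
baseline_window_for <- function(spec, fs) {
  if (!is.null(spec$baseline_window)) return(spec$baseline_window)
  w <- round(0.835 * fs)
  if (w %% 2 == 0) w <- w + 1
  max(w, 3)
}

# Anti-symmetric reflect padding keeps level and slope continuous at the
# edges, which tames IIR start-up transients for both filter directions.
pad_reflect <- function(x, np) {
  n <- length(x)
  np <- min(np, n - 1L)
  if (np < 1L) return(list(x = x, np = 0L))
  head <- 2 * x[1L] - x[(np + 1L):2L]
  tail <- 2 * x[n] - x[(n - 1L):(n - np)]
  list(x = c(head, x, tail), np = np)
}

apply_padded <- function(x, np, filter_fun) {
  p <- pad_reflect(x, np)
  y <- filter_fun(p$x)
  y[(p$np + 1L):(p$np + length(x))]
}

# Butterworth band-pass design for a given sample rate (single pass).
design_bandpass <- function(spec, fs) {
  if (spec$bp_high >= fs / 2)
    stop(sprintf("band-pass corner %g Hz infeasible at fs = %g Hz",
                 spec$bp_high, fs))
  signal::butter(spec$bp_order, c(spec$bp_low, spec$bp_high) / (fs / 2),
                 type = "pass")
}

# Second-order IIR notch biquad with an exact digital -3 dB bandwidth
# (constrained-zero design with beta = tan(pi * bw / fs), which avoids the
# bandwidth shrinkage of the analog-prototype parameterization).
design_notch <- function(notch_freq, notch_bw3db, fs) {
  if (notch_freq >= fs / 2)
    stop(sprintf("notch frequency %g Hz at or above Nyquist (fs = %g Hz)",
                 notch_freq, fs))
  w0 <- 2 * pi * notch_freq / fs
  beta <- tan(pi * notch_bw3db / fs)
  b <- c(1, -2 * cos(w0), 1) / (1 + beta)
  a <- c(1, -2 * cos(w0) / (1 + beta), (1 - beta) / (1 + beta))
  signal::Arma(b = b, a = a)
}

# Minimum record length for the band-pass: three warm-up lengths, where the
# warm-up is taken as one period of the low corner.
check_bp_length <- function(n, spec, fs) {
  warmup <- round(fs / spec$bp_low)
  if (n <= 3 * warmup)
    stop(sprintf(paste0("record too short for band-pass filtering: ",
                        "%d samples <= 3 x %d warm-up samples"), n, warmup))
}

#' Zero-phase Butterworth band-pass
#'
#' Applies the band-pass of `spec` to every lead, forward and backward
#' (bidirectional, zero phase). The design corners are the -3 dB points of
#' the single pass; they are not pre-warped to compensate for the doubled
#' attenuation of the two passes.
#'
#' @param record an [ecg_record].
#' @param spec a [filter_spec].
#' @return the filtered [ecg_record].
#' @export
bandpass_bidirectional <- function(record, spec = filter_spec()) {
  fs <- record$fs
  check_bp_length(nrow(record$samples), spec, fs)
  flt <- design_bandpass(spec, fs)
  np <- round(5 * fs)
  record$samples <- apply(record$samples, 2L, function(x)
    apply_padded(x, np, function(z) signal::filtfilt(flt, z)))
  record
}

#' Power-line notch filter
#'
#' Applies a second-order IIR notch at `spec$notch_freq` with a -3 dB
#' bandwidth of `spec$notch_bw3db` to every lead (single pass, so the
#' implemented magnitude response has the specified bandwidth).
#'
#' @inheritParams bandpass_bidirectional
#' @return the filtered [ecg_record].
#' @export
notch_powerline <- function(record, spec = filter_spec()) {
  flt <- design_notch(spec$notch_freq, spec$notch_bw3db, record$fs)
  np <- round(5 * record$fs)
  record$samples <- apply(record$samples, 2L, function(x)
    apply_padded(x, np, function(z)
      as.numeric(signal::filter(flt, z))))
  record
}

#' Running-median baseline correction
#'
#' Per lead, estimates the slow baseline trend as a running median over
#' `baseline_window` samples (window truncated at the record edges) and
#' subtracts it.
#'
#' @inheritParams bandpass_bidirectional
#' @return the baseline-corrected [ecg_record].
#' @export
remove_baseline <- function(record, spec = filter_spec()) {
  w <- baseline_window_for(spec, record$fs)
  if (nrow(record$samples) <= w)
    stop("record shorter than the baseline window")
  record$samples <- apply(record$samples, 2L, function(x)
    x - stats::runmed(x, w, endrule = "median"))
  record
}

#' Resample to the canonical analysis rate
#'
#' Band-limited polyphase resampling of every lead to `spec$target_fs`
#' (default 1000 Hz). Edges are handled by reflect padding. Downsampling is
#' supported; the polyphase filter provides the anti-alias guard.
#'
#' @inheritParams bandpass_bidirectional
#' @return the [ecg_record] at the target rate.
#' @export
resample_canonical <- function(record, spec = filter_spec()) {
  fs <- record$fs
  target <- spec$target_fs
  if (isTRUE(all.equal(fs, target))) return(record)
  pq <- rational_ratio(target, fs)
  p <- pq[1L]; q <- pq[2L]
  n <- nrow(record$samples)
  nout <- round(n * target / fs)
  # pad with a whole number of q-sample blocks so the pad maps to an integer
  # number of output samples
  np <- q * max(1L, ceiling(min(n - 1, fs) / q))
  off <- np * p / q
  record$samples <- apply(record$samples, 2L, function(x) {
    pr <- pad_reflect(x, np)
    y <- signal::resample(pr$x, p, q)
    start <- pr$np * p / q
    out <- y[(start + 1L):min(length(y), start + nout)]
    if (length(out) < nout) out <- c(out, rep(out[length(out)],
                                              nout - length(out)))
    out
  })
  record$fs <- target
  record
}

# Small-integer rational approximation of a/b.
rational_ratio <- function(a, b) {
  ai <- round(a * 1000); bi <- round(b * 1000)
  g <- gcd_int(ai, bi)
  c(ai %/% g, bi %/% g)
}

gcd_int <- function(a, b) {
  a <- abs(a); b <- abs(b)
  while (b > 0) { t <- a %% b; a <- b; b <- t }
  a
}

#' Full pre-processing chain
#'
#' Applies, in fixed order: band-pass, power-line notch, baseline removal,
#' resampling to the canonical rate. Delineation windows downstream are
#' always computed at the canonical rate.
#'
#' @inheritParams bandpass_bidirectional
#' @return the conditioned [ecg_record] at `spec$target_fs`.
#' @export
preprocess_ecg <- function(record, spec = filter_spec()) {
  record <- bandpass_bidirectional(record, spec)
  record <- notch_powerline(record, spec)
  record <- remove_baseline(record, spec)
  resample_canonical(record, spec)
}
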