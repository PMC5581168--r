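#' Read a multi-lead ECG recording
#'
#' Reads either a delimited-text file (one column per lead, header row naming
#' the leads) or a waveform-database (WFDB) record (header `.hea` plus a
#' format-16 signal file). Amplitudes are converted to microvolts and, when
#' all 12 standard leads are present, channels are reordered to the canonical
#' I, II, III, aVR, aVL, aVF, V1-V6 order.
#'
#' For delimited text the sample rate must be supplied via `fs`, unless a
#' column named `time` (seconds) is present, in which case it is inferred and
#' the column dropped. The amplitude unit must be supplied via `unit` for
#' delimited text; WFDB headers carry their own units and gain.
#'
#' @param path path to a delimited-text file, or to a WFDB record (with or
#'   without the `.hea` extension).
#' @param unit amplitude unit of the stored values: one of `"uV"`, `"mV"`,
#'   `"V"`. Required for delimited text.
#' @param fs sample rate in Hz. Required for delimited text without a time
#'   column.
#' @param format `"auto"` (default; WFDB if a matching `.hea` exists),
#'   `"csv"` or `"wfdb"`.
#' @param sep,dec field and decimal separator for delimited text. Use
#'   `sep = ";"`, `dec = ","` for the European dialect.
#'
#' @return An [ecg_record].
#' @export
read_ecg <- function(path, unit = NULL, fs = NULL,
                     format = c("auto", "csv", "wfdb"),
                     sep = ",", dec = ".") {
  format <- match.arg(format)
  hea <- if (grepl("\\.hea$", path)) path else paste0(path, ".hea")
  if (format == "auto")
    format <- if (file.exists(hea)) "wfdb" else "csv"
  if (format == "wfdb")
    return(read_ecg_wfdb(hea))
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  df <- utils::read.table(path, header = TRUE, sep = sep, dec = dec,
                          check.names = FALSE, fill = FALSE,
                          stringsAsFactors = FALSE)
  nm <- names(df)
  ti <- which(tolower(nm) %in% c("time", "t", "time_s"))
  if (length(ti) == 1L) {
    tt <- df[[ti]]
    if (length(tt) < 2L) stop("time column too short to infer sample rate")
    fs <- 1 / stats::median(diff(tt))
    df <- df[, -ti, drop = FALSE]
  }
  if (is.null(fs)) stop("sample rate unknown: supply 'fs' or a time column")
  if (ncol(df) < 2L) stop("fewer than 2 channels in file")
  if (!all(vapply(df, is.numeric, logical(1L))))
    stop("non-numeric lead column(s) in file")
  scale <- unit_to_uv(unit)
  rec <- ecg_record(as.matrix(df) * scale, lead_names = names(df), fs = fs)
  order_leads_canonical(rec)
}

# Conversion factor from a declared amplitude unit to microvolts.
unit_to_uv <- function(unit) {
  if (is.null(unit)) stop("amplitude unit unknown and no hint given")
  u <- tolower(trimws(unit))
  u <- sub("^micro(volts?)?$", "uv", u)
  u <- sub("^milli(volts?)?$", "mv", u)
  switch(u,
         "uv" = 1, "µv" = 1,
         "mv" = 1e3,
         "v"  = 1e6, "volt" = 1e6, "volts" = 1e6,
         stop(sprintf("unknown amplitude unit '%s'", unit)))
}

# Minimal WFDB reader: header + format-16 (16-bit little-endian two's
# complement, channel-interleaved) signal file. Other storage formats error.
read_ecg_wfdb <- function(hea_path) {
  if (!file.exists(hea_path)) stop(sprintf("file not found: %s", hea_path))
  lines <- readLines(hea_path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  rl <- strsplit(trimws(lines[1L]), "\\s+")[[1L]]
  if (length(rl) < 3L) stop("malformed WFDB header record line")
  nsig <- as.integer(rl[2L])
  fs <- as.numeric(sub("/.*$", "", rl[3L]))   # strip counter frequency
  nsamp <- if (length(rl) >= 4L) as.integer(rl[4L]) else NA_integer_
  if (nsig < 2L) stop("fewer than 2 channels in record")
  sig <- lines[2L:(1L + nsig)]
  fields <- strsplit(trimws(sig), "\\s+")
  fname <- unique(vapply(fields, `[[`, "", 1L))
  if (length(fname) != 1L)
    stop("multi-file WFDB records are not supported")
  fmt <- vapply(fields, `[[`, "", 2L)
  if (!all(sub("x.*$", "", fmt) == "16"))
    stop("only WFDB signal format 16 is supported")
  gainspec <- vapply(fields, function(f)
    if (length(f) >= 3L) f[3L] else "200", "")
  gain <- as.numeric(sub("^([-0-9.eE+]+).*$", "\\1", gainspec))
  gain[is.na(gain) | gain == 0] <- 200
  baseline <- rep(0, nsig)
  hasb <- grepl("\\(", gainspec)
  baseline[hasb] <- as.numeric(sub("^.*\\(([-0-9]+)\\).*$", "\\1",
                                   gainspec[hasb]))
  units <- rep("mV", nsig)
  hasu <- grepl("/", gainspec)
  units[hasu] <- sub("^.*/", "", gainspec[hasu])
  desc <- vapply(fields, function(f)
    if (length(f) >= 9L) paste(f[9:length(f)], collapse = " ") else "", "")
  lead_names <- ifelse(nzchar(desc), desc, paste0("ch", seq_len(nsig)))
  dat <- file.path(dirname(hea_path), fname)
  if (!file.exists(dat)) stop(sprintf("signal file not found: %s", dat))
  nval <- file.size(dat) / 2L
  raw <- readBin(dat, "integer", n = nval, size = 2L, endian = "little",
                 signed = TRUE)
  n <- length(raw) %/% nsig
  if (!is.na(nsamp) && nsamp > 0L) n <- min(n, nsamp)
  adu <- matrix(raw[seq_len(n * nsig)], ncol = nsig, byrow = TRUE)
  phys <- sweep(sweep(adu, 2L, baseline, "-"), 2L, gain, "/")
  scale <- vapply(units, unit_to_uv, numeric(1L))
  phys <- sweep(phys, 2L, scale, "*")
  rec <- ecg_record(phys, lead_names = lead_names, fs = fs)
  order_leads_canonical(rec)
}

# Fixed column set of the per-beat measurement table.
MEASUREMENT_COLUMNS <- c("beat", "r_ms", "qrs_onset_ms", "rr_prev_ms",
                         "t_peak_ms", "t_end_ms", "qt_ms", "qtc_ms",
                         "n_used", "flags")

#' Construct and validate a per-beat measurement table
#'
#' One row per beat: beat index, R-peak time, QRS-onset time, preceding RR,
#' global T-peak and T-end times, QT and Bazett-corrected QTc (all in ms,
#' relative to record start), the number of channels used for the global
#' T end, and a `;`-separated flags string. Rows whose landmarks are all
#' present must satisfy `qrs_onset < t_peak < t_end` and
#' `qt = t_end - qrs_onset`.
#'
#' @param df data frame with the columns named above (column order free).
#' @return validated data frame with class `c("qt_measurements", "data.frame")`.
#' @export
measurement_table <- function(df) {
  missing_cols <- setdiff(MEASUREMENT_COLUMNS, names(df))
  if (length(missing_cols))
    stop("missing measurement columns: ", paste(missing_cols, collapse = ", "))
  df <- as.data.frame(df)[, MEASUREMENT_COLUMNS]
  df$beat <- as.integer(df$beat)
  df$n_used <- as.integer(df$n_used)
  df$flags <- as.character(df$flags)
  ok <- stats::complete.cases(df[, c("qrs_onset_ms", "t_peak_ms", "t_end_ms")])
  if (any(ok)) {
    v <- df[ok, ]
    if (any(v$qrs_onset_ms >= v$t_peak_ms) || any(v$t_peak_ms >= v$t_end_ms))
      stop("invalid row: require qrs_onset < t_peak < t_end")
    if (any(abs(v$qt_ms - (v$t_end_ms - v$qrs_onset_ms)) > 1e-6))
      stop("invalid row: qt must equal t_end - qrs_onset")
  }
  class(df) <- c("qt_measurements", "data.frame")
  df
}

#' Write a measurement table as delimited text
#'
#' Writes the fixed header and one row per beat. Numeric values are written
#' with six decimals (ms scale), so a write/read round trip reproduces the
#' table to 1e-6 ms.
#'
#' @param table a measurement table (see [measurement_table]).
#' @param path output file path.
#' @param sep,dec field and decimal separator (`";"` + `","` for the European
#'   dialect).
#' @return the path, invisibly.
#' @export
write_measurements <- function(table, path, sep = ",", dec = ".") {
  table <- measurement_table(table)
  out <- table
  num <- vapply(out, is.double, logical(1L))
  for (j in which(num)) {
    s <- sprintf("%.6f", out[[j]])
    s[is.na(out[[j]])] <- "NA"
    if (dec != ".") s <- gsub(".", dec, s, fixed = TRUE)
    out[[j]] <- s
  }
  con <- tryCatch(file(path, "w"), error = function(e)
    stop(sprintf("cannot write to '%s'", path)))
  on.exit(close(con))
  utils::write.table(out, con, sep = sep, row.names = FALSE,
                     col.names = TRUE, quote = FALSE, na = "NA")
  invisible(path)
}

#' Read a measurement table written by [write_measurements]
#'
#' @inheritParams write_measurements
#' @return a measurement table.
#' @export
read_measurements <- function(path, sep = ",", dec = ".") {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  df <- utils::read.table(path, header = TRUE, sep = sep, dec = dec,
                          stringsAsFactors = FALSE,
                          colClasses = c(flags = "character"))
  if (nrow(df) == 0L)
    df$flags <- character(0L)
  measurement_table(df)
}
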