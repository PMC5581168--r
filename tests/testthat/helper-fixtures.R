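# Shared fixtures: small records and toy signals built in code.

# A short clean synthetic record (no noise/mains/wander), at the given rate.
clean_sim <- function(duration = 30, fs = 1000, seed = 42, ...) {
  synth_ecg(synth_config(duration = duration, fs = fs, seed = seed,
                         noise_uv = 0, mains_uv = 0, wander_uv = 0,
                         rr_jitter = 0, ...))
}

# Match emitted measurement rows to truth beats by nearest R time.
match_truth <- function(measurements, truth) {
  idx <- vapply(measurements$r_ms,
                function(r) which.min(abs(truth$r_ms - r)), integer(1L))
  truth[idx, ]
}

# Constant-column multi-lead record.
const_record <- function(value, n = 6000, fs = 600, k = 2) {
  ecg_record(matrix(value, n, k), lead_names = paste0("ch", seq_len(k)),
             fs = fs)
}

# Sinusoid record (single frequency on every lead).
sine_record <- function(freq, n = 6000, fs = 600, amp = 1, k = 2) {
  t <- (0:(n - 1)) / fs
  ecg_record(matrix(rep(amp * sin(2 * pi * freq * t), k), ncol = k),
             lead_names = paste0("ch", seq_len(k)), fs = fs)
}

# Magnitude response of an Arma/butter filter at given frequencies (Hz),
# evaluated directly on the transfer function.
mag_at <- function(flt, f, fs) {
  w <- 2 * pi * f / fs
  ew <- function(coef) as.vector(
    exp(-1i * outer(w, seq_along(coef) - 1)) %*% coef)
  abs(ew(flt$b) / ew(flt$a))
}

# Brute-force reference for the median/2-SD fusion rule, written as an
# explicit loop so it shares no code path with fuse_landmarks().
brute_fuse <- function(v) {
  med <- sort(v)[ceiling(length(v) / 2)]
  if (length(v) %% 2 == 0) {
    s <- sort(v)
    med <- (s[length(v) / 2] + s[length(v) / 2 + 1]) / 2
  }
  mu <- sum(v) / length(v)
  sdp <- sqrt(sum((v - mu)^2) / length(v))
  keep <- rep(TRUE, length(v))
  if (sdp > 0) for (i in seq_along(v)) if (abs(v[i] - med) > 2 * sdp)
    keep[i] <- FALSE
  sv <- sort(v[keep])
  m <- if (length(sv) %% 2 == 1) sv[(length(sv) + 1) / 2]
       else (sv[length(sv) / 2] + sv[length(sv) / 2 + 1]) / 2
  list(global = floor(m + 0.5), n_used = sum(keep))
}
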