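test_that("band-pass rejects DC and passes mid-band within tolerance", {
  spec <- filter_spec()
  # constant (DC) input: below the 0.5 Hz high-pass corner
  rec <- const_record(100, n = 6000, fs = 600)
  out <- bandpass_bidirectional(rec, spec)
  expect_lt(max(abs(out$samples)), 1)     # < 1% of the 100 uV input

  # 10 Hz unit sinusoid: amplitude within 2% of unity after edge discard
  rec <- sine_record(10, n = 12000, fs = 600)
  out <- bandpass_bidirectional(rec, spec)
  i <- 2000:10000
  expect_lt(abs(max(abs(out$samples[i, 1])) - 1), 0.02)

  # and the two-pass amplitude matches the design response squared
  h10 <- mag_at(design_bandpass(spec, 600), 10, 600)
  expect_equal(max(abs(out$samples[i, 1])), h10^2, tolerance = 5e-3)
})

test_that("band-pass design corners sit at -3 dB", {
  spec <- filter_spec()
  flt <- design_bandpass(spec, 600)
  expect_equal(mag_at(flt, 0.5, 600), 1 / sqrt(2), tolerance = 1e-3)
  expect_equal(mag_at(flt, 100, 600), 1 / sqrt(2), tolerance = 1e-3)
  expect_error(bandpass_bidirectional(const_record(1, fs = 150),
                                      filter_spec()), "infeasible")
})

test_that("notch suppresses 50 Hz, spares 10 Hz, and has the design bandwidth", {
  spec <- filter_spec()
  rec <- sine_record(50, n = 12000, fs = 600)
  out <- notch_powerline(rec, spec)
  i <- 4000:10000
  expect_lt(max(abs(out$samples[i, 1])), 0.05)

  rec <- sine_record(10, n = 12000, fs = 600)
  out <- notch_powerline(rec, spec)
  expect_lt(abs(max(abs(out$samples[i, 1])) - 1), 0.01)

  # sweep the implemented response: half-power crossings 0.33 Hz apart
  flt <- design_notch(50, 0.33, 600)
  f <- seq(49, 51, by = 1e-4)
  mag <- mag_at(flt, f, 600)
  below <- which(mag < 1 / sqrt(2))
  bw <- f[max(below)] - f[min(below)]
  expect_lt(abs(bw - 0.33), 0.05 * 0.33)

  expect_error(notch_powerline(const_record(1, fs = 90), filter_spec()),
               "Nyquist")
})

test_that("running-median baseline removal matches a brute-force oracle", {
  spec <- filter_spec(baseline_window = 101)
  # constant offset: interior exactly zero
  rec <- const_record(7, n = 2000, fs = 600)
  out <- remove_baseline(rec, spec)
  expect_equal(max(abs(out$samples[200:1800, ])), 0)
  # zero in, zero out
  rec <- const_record(0, n = 2000, fs = 600)
  expect_equal(remove_baseline(rec, spec)$samples, rec$samples)

  # impulse train on a linear ramp: ramp removed, impulses preserved
  n <- 3000
  ramp <- seq(0, 50, length.out = n)
  x <- ramp
  spikes <- seq(300, 2700, by = 300)
  x[spikes] <- x[spikes] + 200
  rec <- ecg_record(cbind(a = x, b = x), fs = 600)
  out <- remove_baseline(rec, spec)$samples[, 1]
  # brute-force truncated-window running median on the toy input
  w2 <- 50
  brute <- vapply(seq_len(n), function(i)
    median(x[max(1, i - w2):min(n, i + w2)]), numeric(1))
  interior <- 200:2800
  expect_lt(max(abs(out[interior] - (x - brute)[interior])), 1e-9)
  expect_true(all(abs(out[spikes] - 200) < 0.05 * 200))
  # away from any window that contains a spike, the ramp is removed exactly
  clear <- setdiff(interior, as.vector(outer(spikes, -51:51, "+")))
  expect_lt(max(abs(out[clear])), 1e-9)
})

test_that("resampling preserves band-limited content and lengths", {
  spec <- filter_spec()
  # constant signal: constant out, round(N * 1000/600) samples
  rec <- const_record(3, n = 6000, fs = 600)
  out <- resample_canonical(rec, spec)
  expect_equal(out$fs, 1000)
  expect_identical(nrow(out$samples), 10000L)
  expect_lt(max(abs(out$samples - 3)), 0.01)  # polyphase FIR ripple

  # 5 Hz sinusoid 600 -> 1000 Hz: pointwise error < 1% after edge discard
  rec <- sine_record(5, n = 6000, fs = 600)
  out <- resample_canonical(rec, spec)
  t2 <- (0:(nrow(out$samples) - 1)) / 1000
  ref <- sin(2 * pi * 5 * t2)
  i <- 500:(length(ref) - 500)
  expect_lt(max(abs(out$samples[i, 1] - ref[i])), 0.01)

  # already at the canonical rate: identity
  rec <- sine_record(5, n = 4000, fs = 1000)
  out <- resample_canonical(rec, spec)
  expect_identical(out$samples, rec$samples)
})

test_that("the full chain is linear in the input amplitude", {
  sim <- clean_sim(duration = 10, fs = 600, seed = 9)
  rec <- sim$record
  reca <- rec
  reca$samples <- 3.7 * reca$samples
  c1 <- preprocess_ecg(rec)
  c2 <- preprocess_ecg(reca)
  expect_equal(c2$samples, 3.7 * c1$samples, tolerance = 1e-9)
})

test_that("filter specs validate and load from key=value config", {
  expect_error(filter_spec(bp_low = 0), "bp_low")
  expect_error(filter_spec(baseline_window = 100), "odd")
  expect_error(filter_spec(notch_bw3db = 0), "positive")
  tmp <- withr::local_tempfile()
  writeLines(c("# comment", "bp_high = 80", "notch_freq=60"), tmp)
  sp <- filter_spec_from_config(tmp)
  expect_equal(sp$bp_high, 80)
  expect_equal(sp$notch_freq, 60)
  expect_equal(sp$bp_low, 0.5)
  writeLines("nonsense = 1", tmp)
  expect_error(filter_spec_from_config(tmp), "unknown config key")
})
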