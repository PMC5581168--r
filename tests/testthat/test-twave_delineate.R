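test_that("Savitzky-Golay smoothing is exact on quadratics and constants", {
  t <- seq_len(1200)
  q <- 3 + 0.5 * t - 2e-4 * t^2
  out <- smooth_channel(q, 1000)
  i <- 100:1100
  expect_equal(out[i], q[i], tolerance = 1e-9)
  expect_equal(smooth_channel(rep(4, 500), 1000)[50:450], rep(4, 401),
               tolerance = 1e-9)
})

test_that("white-noise attenuation matches the filter-coefficient norm", {
  set.seed(10)
  x <- rnorm(200000, sd = 5)
  out <- smooth_channel(x, 1000)
  g <- signal::sgolay(p = 2, n = 51)
  gain <- sqrt(sum(g[26, ]^2))
  expect_equal(sd(out[1000:199000]), 5 * gain, tolerance = 0.1 * 5 * gain)
})

test_that("the local T peak is the largest-|deviation| extremum", {
  fs <- 1000
  t <- (0:2999) / fs
  bump <- function(mu, s, a) a * exp(-((t - mu) / s)^2 / 2)
  x <- bump(1.2, 0.06, 300)
  pk <- find_local_t_peak(x, r_peak = 900L, rr_prev = 1000, baseline = 0,
                          fs = fs)
  expect_equal(pk$t_peak, 1201L)
  expect_equal(pk$t_amp, 300, tolerance = 1e-6)

  # sign symmetry: inverted T gives the same index, negated amplitude
  pkn <- find_local_t_peak(-x, 900L, 1000, 0, fs)
  expect_identical(pkn$t_peak, pk$t_peak)
  expect_equal(pkn$t_amp, -pk$t_amp)

  # biphasic with the larger negative phase: negative extremum chosen
  xb <- bump(1.15, 0.05, 150) - bump(1.35, 0.05, 260)
  pkb <- find_local_t_peak(xb, 900L, 1000, 0, fs)
  expect_equal(pkb$t_peak, 1351L, tolerance = 3)
  expect_lt(pkb$t_amp, 0)

  # window leaving the record excludes the channel
  expect_null(find_local_t_peak(x[1:1300], 900L, 1000, 0, fs))
})

test_that("tangent T end matches the analytic Gaussian intercept", {
  fs <- 1000
  t <- (0:2999) / fs
  for (A in c(100, 300, 800)) {
    for (s in c(0.060, 0.100, 0.160)) {
      x <- A * exp(-((t - 1.0) / s)^2 / 2)
      xs <- smooth_channel(x, fs)
      pk <- find_local_t_peak(xs, 700L, 1200, 0, fs)
      te <- tangent_t_end(xs, pk$t_peak, pk$t_amp, 1200, 0, fs)
      expect_identical(te$reason, "")
      # analytic: inflection mu + s, tangent crosses baseline at mu + 2s
      expect_lt(abs((te$t_end - 1) - (1000 + 2 * s * 1000)), 6)
      expect_lt(abs((te$slope_point - 1) - (1000 + s * 1000)), 6)
      # sign symmetry
      ten <- tangent_t_end(-xs, pk$t_peak, -pk$t_amp, 1200, 0, fs)
      expect_identical(ten$t_end, te$t_end)
      # translation invariance: signal and baseline shifted together
      teb <- tangent_t_end(xs + 40, pk$t_peak, pk$t_amp, 1200, 40, fs)
      expect_identical(teb$t_end, te$t_end)
    }
  }
})

test_that("flat and non-crossing slopes are excluded with reasons", {
  fs <- 1000
  x <- rep(0, 2000)
  te <- tangent_t_end(x, 1000L, 0, 1000, 0, fs)
  expect_identical(te$reason, "no-crossing")
  # shallow descending ramp: slope below 1 uV per 10 ms
  x2 <- 100 - 0.05 * seq_len(2000)   # 0.05 uV/ms
  te2 <- tangent_t_end(x2, 1000L, 50, 1000, 0, fs)
  expect_identical(te2$reason, "flat")
  # interval leaving the record
  te3 <- tangent_t_end(x2[1:1100], 1000L, 50, 1000, 0, fs)
  expect_identical(te3$reason, "window")
})

test_that("positive rescaling leaves the landmark indices unchanged", {
  fs <- 1000
  t <- (0:2499) / fs
  x <- 250 * exp(-((t - 1.1) / 0.08)^2 / 2) + 20
  xs <- smooth_channel(x, fs)
  run <- function(z, base) {
    pk <- find_local_t_peak(z, 800L, 1100, base, fs)
    te <- tangent_t_end(z, pk$t_peak, pk$t_amp, 1100, base, fs)
    c(pk$t_peak, te$t_end)
  }
  expect_identical(run(xs, 20), run(5 * xs, 100))
})

test_that("the pre-QRS baseline is a robust median", {
  x <- rep(12, 500)
  expect_equal(compute_baseline(x, 400L, 1000), 12)
  x2 <- x; x2[380] <- 900
  expect_equal(compute_baseline(x2, 400L, 1000), 12)
  # linear ramp: median equals the window midpoint value
  x3 <- 2 + 0.5 * seq_len(500)
  expect_equal(compute_baseline(x3, 400L, 1000),
               median(x3[370:399]))
  expect_equal(compute_baseline(x3, 400L, 1000), 2 + 0.5 * 384.5)
  # truncated window: >= 10 ms is used, less excludes
  expect_false(is.na(compute_baseline(x3, 15L, 1000)))
  expect_true(is.na(compute_baseline(x3, 8L, 1000)))
})

test_that("the 50 uV rule spares scalar channels and uses strict inequality", {
  lm <- data.frame(channel = c("V5", "V5", "RMS", "aVL"),
                   t_amp = c(40, 50, 10, -49.9),
                   included = TRUE, reason = "",
                   stringsAsFactors = FALSE)
  out <- apply_amplitude_rule(lm)
  expect_identical(out$included, c(FALSE, TRUE, TRUE, FALSE))
  expect_identical(out$reason, c("low-amplitude", "", "", "low-amplitude"))
})

test_that("per-channel delineation keeps onset < t_peak < t_end", {
  sim <- clean_sim(duration = 15, fs = 1000, seed = 12)
  rec <- add_scalar_channels(sim$record)
  fid <- beat_fiducials(ecg_channel(rec, "RMS"), 1000)
  lm <- delineate_channels(rec, fid)
  inc <- lm[lm$included, ]
  expect_gt(nrow(inc), 0)
  on <- fid$qrs_onset[match(inc$beat, fid$beat)]
  expect_true(all(on < inc$t_peak))
  expect_true(all(inc$t_peak < inc$t_end))
})
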