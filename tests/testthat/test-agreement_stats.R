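test_that("validation-beat strata follow the percentile conventions", {
  rr <- seq(500, 1490, by = 10)   # 100 equally spaced RR values
  # brute-force oracle with type-7 (linear interpolation) percentiles
  p <- unname(quantile(rr, c(0.10, 0.25, 0.75, 0.90), type = 7))
  n_low <- sum(rr < p[1]); n_iqr <- sum(rr >= p[2] & rr <= p[3])
  n_high <- sum(rr > p[4])
  expect_identical(c(n_low, n_iqr, n_high), c(10L, 50L, 10L))

  sel <- select_validation_beats(rr, seed = 99)
  expect_identical(names(sel), c("low", "iqr", "high"))
  expect_lt(rr[sel["low"]], p[1])
  expect_gt(rr[sel["high"]], p[4])
  expect_true(rr[sel["iqr"]] >= p[2] && rr[sel["iqr"]] <= p[3])
  # determinism
  expect_identical(select_validation_beats(rr, seed = 99), sel)
  expect_false(identical(select_validation_beats(rr, seed = 100), sel))
})

test_that("degenerate RR series are rejected", {
  expect_error(select_validation_beats(rep(800, 5), 1), "at least 10")
  expect_error(select_validation_beats(rep(800, 20), 1), "stratum")
})

test_that("Bland-Altman reproduces direct arithmetic", {
  x <- c(400, 410, 420, 430)
  ba <- bland_altman(x, x)
  expect_equal(ba$bias, 0)
  expect_equal(ba$loa_low, 0)
  expect_equal(ba$loa_high, 0)

  ba2 <- bland_altman(x, x + 5)
  expect_equal(ba2$bias, -5)
  expect_equal(ba2$loa_high - ba2$loa_low, 0)

  ba3 <- bland_altman(c(390, 400, 410), c(400, 400, 400))
  expect_equal(ba3$bias, 0)
  expect_equal(ba3$sd_diff, 10)
  expect_equal(ba3$loa_low, -19.6)
  expect_equal(ba3$loa_high, 19.6)

  expect_error(bland_altman(1, 2), "at least 2")
  expect_error(bland_altman(1:3, 1:4), "equal length")
})

test_that("Pearson r and Fisher CI match the direct formulas", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(pearson_ci(x, 2 * x + 1)$r, 1)
  expect_equal(pearson_ci(x, -x)$r, -1)

  set.seed(30)
  a <- rnorm(10); b <- 0.6 * a + rnorm(10)
  p <- pearson_ci(a, b)
  r_oracle <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(p$r, r_oracle, tolerance = 1e-12)
  z <- 0.5 * log((1 + r_oracle) / (1 - r_oracle))
  expect_equal(p$ci_low, tanh(z - qnorm(0.975) / sqrt(7)), tolerance = 1e-12)
  expect_equal(p$ci_high, tanh(z + qnorm(0.975) / sqrt(7)), tolerance = 1e-12)

  expect_error(pearson_ci(1:2, 2:3), "at least 3")
  expect_error(pearson_ci(rep(1, 5), 1:5), "variance")
})

test_that("absolute-agreement ICC matches an ANOVA mean-squares oracle", {
  m <- matrix(c(9, 2, 5, 8,
                6, 1, 3, 2,
                8, 4, 6, 8,
                7, 1, 2, 6,
                10, 5, 6, 9,
                6, 2, 4, 7), nrow = 6, byrow = TRUE)
  icc <- icc_agreement(m)
  # independent oracle: mean squares from aov pushed through the standard
  # absolute-agreement closed forms
  d <- data.frame(y = as.vector(m),
                  subj = factor(rep(seq_len(nrow(m)), ncol(m))),
                  rater = factor(rep(seq_len(ncol(m)), each = nrow(m))))
  ms <- anova(stats::aov(y ~ subj + rater, data = d))[["Mean Sq"]]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  n <- nrow(m); k <- ncol(m)
  single <- (msr - mse) / (msr + (k - 1) * mse + k / n * (msc - mse))
  average <- (msr - mse) / (msr + (msc - mse) / n)
  expect_equal(icc$icc_single, single, tolerance = 1e-9)
  expect_equal(icc$icc_average, average, tolerance = 1e-9)
  expect_true(icc$single_ci[1] <= icc$icc_single &&
                icc$icc_single <= icc$single_ci[2])
})

test_that("absolute agreement is sensitive to a constant rater shift", {
  set.seed(31)
  a <- rnorm(10, 100, 1)
  m <- cbind(a, a + 10)   # shift 10x the subject SD
  icc <- icc_agreement(m)
  expect_lt(icc$icc_single, 0.5)
  # identical raters: perfect agreement
  icc2 <- icc_agreement(cbind(a, a, a))
  expect_equal(icc2$icc_single, 1)
  expect_equal(icc2$icc_average, 1)
  expect_error(icc_agreement(cbind(a, ifelse(seq_along(a) == 1, NA, a))),
               "missing")
  expect_error(icc_agreement(matrix(1:3, ncol = 1)), "at least 2")
})

test_that("icc_average dominates icc_single and stats are order-invariant", {
  set.seed(32)
  for (rep in 1:20) {
    m <- matrix(rnorm(8 * 3, sd = 5), 8, 3) + rnorm(8, sd = 10)
    icc <- icc_agreement(m)
    expect_gte(icc$icc_average, icc$icc_single - 1e-12)
    perm <- sample(nrow(m))
    icc_p <- icc_agreement(m[perm, ])
    expect_equal(icc_p$icc_single, icc$icc_single, tolerance = 1e-12)
    x <- rnorm(12); y <- x + rnorm(12)
    ba <- bland_altman(x, y); bap <- bland_altman(x[perm[1:8]], y[perm[1:8]])
    expect_equal(bland_altman(rev(x), rev(y))$bias, ba$bias)
    expect_equal(pearson_ci(rev(x), rev(y))$r, pearson_ci(x, y)$r)
  }
})

test_that("the agreement report bundles the three statistics", {
  set.seed(33)
  x <- rnorm(30, 400, 30); y <- x + rnorm(30, 2, 5)
  rep <- agreement_report(x, y)
  expect_s3_class(rep, "agreement_report")
  expect_equal(rep$bland_altman$bias, mean(x - y))
  expect_equal(rep$pearson$r, cor(x, y))
  expect_output(print(rep), "Pearson")
})
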