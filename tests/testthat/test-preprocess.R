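test_that("median despiking replaces spikes and respects preconditions", {
  const <- scr_recording(rep(1, 50), 100)
  expect_equal(median_despike(const)$values, rep(1, 50))

  x <- c(1, 1, 1, 1, 1, 9, 1, 1, 1, 1, 1)
  # brute-force oracle: median over the centred 11-point window
  oracle <- vapply(seq_along(x), function(i)
    median(x[max(1, i - 5):min(length(x), i + 5)]), numeric(1))
  got <- median_despike(scr_recording(x, 100), 10)$values
  expect_equal(got, oracle)
  expect_equal(got[6], 1)

  expect_error(median_despike(scr_recording(x, 100), 3), "even")
  expect_error(median_despike(scr_recording(c(1, 2), 100), 10), "shorter")
})

test_that("a bi-directional high-pass removes DC exactly", {
  rec <- scr_recording(rep(3.7, 2000), 10)
  out <- butter_filter(rec, filter_spec("highpass", 0.0159,
                                        direction = "bi"))
  expect_lt(max(abs(out$values[100:1900])), 1e-6)
})

test_that("the doubled first-order high-pass halves a sinusoid at cutoff", {
  # |H|^2 at the cutoff is (1/sqrt(2))^2 = 1/2 for two passes of a
  # first-order Butterworth, for either direction
  fc <- 0.05; rate <- 10
  tt <- seq(0, 2000, by = 1 / rate)
  x <- sin(2 * pi * fc * tt)
  for (dir in c("bi", "uni")) {
    out <- butter_filter(scr_recording(x, rate),
                         filter_spec("highpass", fc, direction = dir))
    # steady state: fit amplitude on the central stretch via sin/cos basis
    mid <- seq(round(length(tt) * 0.3), round(length(tt) * 0.7))
    fit <- lm(out$values[mid] ~ sin(2 * pi * fc * tt[mid]) +
                cos(2 * pi * fc * tt[mid]))
    amp <- sqrt(sum(coef(fit)[2:3]^2))
    expect_equal(amp, 0.5, tolerance = 0.01)
  }
})

test_that("bi-directional filtering is zero-phase, uni-directional shifts", {
  # symmetric bump: bi keeps the peak sample exactly; two forward passes
  # displace it (the first-order high-pass has a non-zero phase response)
  rate <- 10
  tt <- seq(0, 200, by = 1 / rate)
  bump <- exp(-(tt - 100)^2 / (2 * 2^2))
  rec <- scr_recording(bump, rate)
  pk_in <- which.max(bump)
  hp_bi <- butter_filter(rec, filter_spec("highpass", 0.0159,
                                          direction = "bi"))
  hp_uni <- butter_filter(rec, filter_spec("highpass", 0.0159,
                                           direction = "uni"))
  expect_equal(which.max(hp_bi$values), pk_in)
  expect_gte(abs(which.max(hp_uni$values) - pk_in), 1)
  # the zero-phase property against a time-reversal oracle: filtering the
  # reversed bump forwards twice, reversed back, lands the peak where the
  # uni-directional pass of the original does, mirrored
  rev_uni <- butter_filter(scr_recording(rev(bump), rate),
                           filter_spec("highpass", 0.0159,
                                       direction = "uni"))
  expect_equal(length(bump) + 1 - which.max(rev_uni$values),
               2 * pk_in - which.max(hp_uni$values), tolerance = 1)
})

test_that("filters reject cutoffs at or beyond Nyquist", {
  rec <- scr_recording(rnorm(100), 10)
  expect_error(butter_filter(rec, filter_spec("highpass", 5)), "Nyquist")
  expect_error(filter_spec("highpass", -1), "positive")
})

test_that("resampling decimates by integer factors and refuses upsampling", {
  rec <- scr_recording(rep(2, 1000), 100)
  out <- resample_to(rec, 10)
  expect_equal(out$rate, 10)
  expect_equal(out$values, rep(2, 100))

  ramp <- scr_recording(seq(0, 9.99, by = 0.01), 100)
  dec <- resample_to(ramp, 10)
  expect_equal(dec$values, ramp$values[seq(1, 1000, by = 10)])

  long <- scr_recording(rnorm(60000), 1000)  # a 60 s record
  expect_equal(length(resample_to(long, 10)$values), 600)

  expect_error(resample_to(rec, 200), "upsampling")
})

test_that("normalisation has minimum 0 and unit sample SD", {
  expect_equal(normalise(scr_recording(c(2, 4, 6), 1))$values, c(0, 1, 2))
  set.seed(4)
  out <- normalise(scr_recording(rnorm(500, 5, 3), 10))
  expect_equal(min(out$values), 0, tolerance = 1e-12)
  expect_equal(sd(out$values), 1, tolerance = 1e-12)
  expect_error(normalise(scr_recording(rep(1, 10), 10)), "degenerate")
  # idempotence
  expect_equal(normalise(out)$values, out$values, tolerance = 1e-12)
})

test_that("the preprocessing pipeline composes and is deterministic", {
  set.seed(5)
  raw <- scr_recording(cumsum(rnorm(20000)) / 100 + 8, 100)
  out1 <- preprocess_pipeline(raw)
  out2 <- preprocess_pipeline(raw)
  expect_equal(out1$rate, 10)
  expect_equal(min(out1$values), 0, tolerance = 1e-12)
  expect_equal(sd(out1$values), 1, tolerance = 1e-12)
  expect_identical(out1$values, out2$values)
  expect_true(any(grepl("normalise", out1$provenance)))
  expect_error(preprocess_pipeline(raw, hp = filter_spec("lowpass", 1)),
               "highpass")
})

test_that("the six cutoff presets are exposed with the standard default", {
  expect_equal(hp_cutoff_presets,
               c(0.005, 0.01, 0.0159, 0.035, 0.05, 0.06))
  expect_true(0.0159 %in% hp_cutoff_presets)
})
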