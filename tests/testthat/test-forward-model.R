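test_that("the sudomotor input is a sum of Gaussian bursts", {
  des <- make_design(4)
  zero <- trial_params(des, 0, des$trials$cs_onset + 1, 0.3)
  expect_true(all(sudomotor_input(zero, des)$values == 0))

  one <- trial_params(des, c(2, 0, 0, 0), des$trials$cs_onset + 2, 0.5)
  u <- sudomotor_input(one, des, rate = 10)
  at <- round((des$trials$cs_onset[1] + 2) * 10) + 1
  expect_equal(u$values[at], 2, tolerance = 1e-9)

  # burst integral against a quadrature oracle: amplitude * disp * sqrt(2*pi)
  integral <- sum(u$values) / 10
  expect_equal(integral, 2 * 0.5 * sqrt(2 * pi), tolerance = 1e-3)
})

test_that("bursts outside their windows are rejected", {
  des <- make_design(3)
  expect_error(trial_params(des, 1, des$trials$cs_onset + 5, 0.3),
               "within")
  expect_error(trial_params(des, -1, des$trials$cs_onset + 1, 0.3),
               "non-negative")
  sf_bad <- data.frame(onset = des$trials$cs_onset[1] + 1,  # inside CS
                       amplitude = 1, dispersion = 0.3)
  expect_error(trial_params(des, 1, des$trials$cs_onset + 1, 0.3,
                            sf = sf_bad), "inter-trial")
})

test_that("predicted traces are linear in the burst amplitudes", {
  des <- make_design(4)
  tp <- make_params(des)
  base <- predict_scr(tp, des, canonical_rf(), include_scl = FALSE)
  expect_true(all(predict_scr(
    trial_params(des, 0, des$trials$cs_onset, 0.3),
    des, canonical_rf(), include_scl = FALSE)$values == 0))

  tp3 <- trial_params(des, 3 * tp$trials$amp_ant, tp$trials$onset_ant,
                      tp$trials$disp_ant, 3 * tp$trials$amp_evoked)
  expect_equal(predict_scr(tp3, des, canonical_rf(),
                           include_scl = FALSE)$values,
               3 * base$values, tolerance = 1e-9)
})

test_that("ODE integration matches the kernel-convolution oracle", {
  des <- make_design(4)
  tp <- make_params(des)
  pred <- predict_scr(tp, des, canonical_rf(), rate = 10,
                      include_scl = FALSE,
                      duration = max(des$trials$cs_onset) + 40)
  tt <- rec_times(pred)
  b <- scrdcm:::all_bursts(tp, des)
  u <- scrdcm:::gauss_input(tt, b$onset, b$amplitude, b$dispersion)
  kern <- impulse_response(canonical_rf(), 60, 10)$values
  conv <- scrdcm:::conv_causal(u, kern, 0.1)
  expect_lt(max(abs(pred$values - conv)) / max(abs(pred$values)), 1e-4)
})

test_that("superposition holds to near machine precision", {
  des <- make_design(3)
  on <- des$trials$cs_onset
  a <- trial_params(des, c(1, 0.4, 0.7), on + 1.2, 0.3, c(0.5, 0.2, 0.9))
  b <- trial_params(des, c(0.3, 1.1, 0.2), on + 1.2, 0.3, c(0.1, 0.8, 0.4))
  ab <- trial_params(des, a$trials$amp_ant + b$trials$amp_ant, on + 1.2,
                     0.3, a$trials$amp_evoked + b$trials$amp_evoked)
  pa <- predict_scr(a, des, canonical_rf(), include_scl = FALSE)
  pb <- predict_scr(b, des, canonical_rf(), include_scl = FALSE)
  pab <- predict_scr(ab, des, canonical_rf(), include_scl = FALSE)
  expect_equal(pab$values, pa$values + pb$values, tolerance = 1e-9)
})

test_that("the prediction is causal", {
  des <- make_design(3)
  tp <- trial_params(des, 1, des$trials$cs_onset + 2, 0.2, 1)
  pred <- predict_scr(tp, des, canonical_rf(), include_scl = FALSE,
                      baseline = 0.5)
  first_burst <- min(des$trials$cs_onset + 2) - 3 * 0.2
  before <- rec_times(pred) < first_burst
  expect_lt(max(abs(pred$values[before] - 0.5)), 1e-6)
})

test_that("time-shifted onsets shift the output by the same lag", {
  des <- make_design(3)
  on <- des$trials$cs_onset
  shift <- 2
  des2 <- session_design(on + shift, des$trials$cs_type,
                         des$trials$reinforced)
  tp1 <- trial_params(des, c(1, .5, .8), on + 1.5, 0.3, c(.4, .6, .2))
  tp2 <- trial_params(des2, c(1, .5, .8), on + shift + 1.5, 0.3,
                      c(.4, .6, .2))
  dur <- max(on) + 42
  p1 <- predict_scr(tp1, des, canonical_rf(), include_scl = FALSE,
                    duration = dur)
  p2 <- predict_scr(tp2, des2, canonical_rf(), include_scl = FALSE,
                    duration = dur)
  lag <- shift * 10
  n <- length(p1$values)
  expect_equal(p2$values[(lag + 1):n], p1$values[1:(n - lag)],
               tolerance = 1e-7)
})

test_that("tonic drift is slow and reaches the per-trial increments", {
  tt <- seq(0, 300, by = 0.1)
  d <- scrdcm:::scl_drift(tt, c(10, 100), c(0.5, -0.2))
  expect_equal(d[tt < 10], rep(0, sum(tt < 10)))
  expect_equal(d[length(d)], 0.3, tolerance = 0.01)  # asymptote 0.5 - 0.2
})
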