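test_that("a flat recording yields amplitudes shrunk toward zero", {
  des <- make_design(3)
  rec <- scr_recording(rep(0, (max(des$trials$cs_onset) + 40) * 10), 10)
  ch <- suppressWarnings(invert_chunk(rec, des, 1, canonical_rf(),
                                      inversion_options()))
  expect_lt(max(ch$params$amp_ant), 0.05)
  expect_lt(max(ch$params$amp_evoked), 0.05)
})

test_that("noiseless chunks recover known parameters", {
  des <- make_design(4, seed = 7)
  tp <- make_params(des, seed = 8)
  rec <- make_clean_recording(des, tp)
  ch <- suppressWarnings(invert_chunk(rec, des, 1, canonical_rf(),
                                      inversion_options()))
  expect_equal(ch$params$amp_ant[1], tp$trials$amp_ant[1],
               tolerance = 0.05)
  expect_lt(abs(ch$params$onset_ant[1] - tp$trials$onset_ant[1]), 0.25)
})

test_that("inversion is deterministic", {
  des <- make_design(4, seed = 9)
  tp <- make_params(des, seed = 10)
  set.seed(123)
  rec <- scr_recording(make_clean_recording(des, tp)$values +
                         rnorm(length(make_clean_recording(des, tp)$values),
                               0, 0.05), 10)
  e1 <- suppressWarnings(invert_session(rec, des))
  e2 <- suppressWarnings(invert_session(rec, des))
  expect_identical(e1$amp_ant, e2$amp_ant)
  expect_identical(e1$onset_ant, e2$onset_ant)
})

test_that("depth 1 on well-separated trials equals per-trial inversion", {
  on <- c(10, 60, 110)
  des <- session_design(on, c("CS+", "CS-", "CS+"), rep(FALSE, 3))
  tp <- trial_params(des, c(1, 0.4, 0.8), on + 1.5, 0.3, c(0.5, 0.3, 0.7))
  rec <- predict_scr(tp, des, canonical_rf(), include_scl = FALSE,
                     duration = 160)
  opts <- inversion_options(trial_depth = 1)
  ses <- suppressWarnings(invert_session(rec, des, canonical_rf(), opts))
  for (j in 1:3) {
    ch <- suppressWarnings(invert_chunk(rec, des, j, canonical_rf(), opts))
    expect_equal(ses$amp_ant[j], ch$params$amp_ant[1], tolerance = 0.02)
  }
})

test_that("trial depths 2 and 3 both recover noiseless amplitudes", {
  des <- make_design(6, seed = 13)
  tp <- make_params(des, seed = 14)
  rec <- make_clean_recording(des, tp)
  for (depth in 2:3) {
    est <- suppressWarnings(invert_session(
      rec, des, canonical_rf(), inversion_options(trial_depth = depth)))
    expect_equal(est$amp_ant, tp$trials$amp_ant, tolerance = 0.05)
  }
})

test_that("single-trial sessions clamp the depth with a warning", {
  des <- session_design(10, "CS+", FALSE)
  tp <- trial_params(des, 1, 11.5, 0.3, 0.5)
  rec <- predict_scr(tp, des, canonical_rf(), include_scl = FALSE,
                     duration = 60)
  expect_warning(est <- invert_session(rec, des), "clamped")
  expect_equal(nrow(est), 1)
  expect_equal(est$amp_ant[1], 1, tolerance = 0.05)
})

test_that("recordings shorter than the design span are refused", {
  des <- make_design(4)
  rec <- scr_recording(rnorm(100), 10)
  expect_error(invert_session(rec, des), "shorter")
})

test_that("onsets never leave the CS-US window", {
  des <- make_design(5, seed = 15)
  set.seed(16)
  rec <- scr_recording(
    abs(cumsum(rnorm((max(des$trials$cs_onset) + 40) * 10)) / 20), 10)
  est <- suppressWarnings(invert_session(rec, des))
  expect_true(all(est$onset_ant >= des$trials$cs_onset))
  expect_true(all(est$onset_ant <= des$trials$cs_onset + des$soa))
  expect_true(all(est$amp_ant >= 0))
})

test_that("the chunk objective does not decrease over optimisation", {
  des <- make_design(4, seed = 17)
  tp <- make_params(des, seed = 18)
  rec <- make_clean_recording(des, tp)
  ch <- suppressWarnings(invert_chunk(rec, des, 1, canonical_rf(),
                                      inversion_options()))
  expect_gte(ch$objective, ch$objective_start)
})

test_that("estimates are invariant to constant shifts when SCL is modelled", {
  des <- make_design(4, seed = 19)
  tp <- make_params(des, seed = 20)
  rec <- make_clean_recording(des, tp)
  shifted <- scr_recording(rec$values + 2.5, 10)
  e1 <- suppressWarnings(invert_session(rec, des))
  e2 <- suppressWarnings(invert_session(shifted, des))
  expect_equal(e1$amp_ant, e2$amp_ant, tolerance = 1e-3)
  expect_equal(e1$onset_ant, e2$onset_ant, tolerance = 1e-3)
})

test_that("amplitude recovery survives measurement noise", {
  spec <- cohort_spec(n_participants = 3, trials_per_type = 6, seed = 23,
                      sf_rate = 0, scl_drift_sd = 0, gain_sd = 0,
                      lability_sd = 0)
  cors <- vapply(1:3, function(p) {
    ses <- generate_session(spec, p)
    est <- suppressWarnings(invert_session(ses$recording, ses$design))
    cor(est$amp_ant, ses$truth$trials$amp_ant)
  }, numeric(1))
  expect_gt(mean(cors), 0.7)
})
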