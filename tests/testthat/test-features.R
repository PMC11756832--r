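sine_recording <- function(freq = 1000, duration = 1, sr = 16000,
                           amplitude = 0.5) {
  recording(amplitude * sin(2 * pi * freq * (0:(duration * sr - 1)) / sr),
            sr, "tone")
}

chirp_recording <- function(duration = 1, sr = 16000) {
  t <- (0:(duration * sr - 1)) / sr
  # linear chirp 300 -> 3000 Hz plus mild noise so no column is constant
  withr::with_seed(11, {
    x <- 0.5 * sin(2 * pi * (300 * t + (2700 / (2 * duration)) * t^2)) +
      0.01 * rnorm(length(t))
  })
  recording(x / max(abs(x)), sr, "chirp")
}

test_that("feature matrices have 3 x n_coeff columns with the MFCC layout", {
  ap <- test_audio_params(duration = 1)
  rec <- synthesize_speech(list(kfrail_score = 2L, sex = "male"),
                           ap$baseline, ap$severe, seed = 2)
  f <- extract_mfcc_features(rec)
  expect_equal(ncol(f), 60)
  expect_equal(unname(attr(f, "layout")), c(20, 20, 20))
  expect_true(all(is.finite(f)))
  expect_gte(nrow(f), 1)
  expect_length(attr(f, "frame_times"), nrow(f))
  # non-default coefficient count scales the column contract
  f12 <- extract_mfcc_features(rec, feature_config(n_coeff = 12))
  expect_equal(ncol(f12), 36)
})

test_that("stationary input gives vanishing delta blocks", {
  f <- extract_mfcc_features(sine_recording())
  expect_lt(max(abs(f[, 21:60])), 1e-6)
})

test_that("delta blocks equal the windowed-regression oracle", {
  f <- extract_mfcc_features(chirp_recording())
  mfcc <- unclass(f)[, 1:20]
  expect_lt(max(abs(unclass(f)[, 21:40] - oracle_delta(mfcc, 9))), 1e-6)
  expect_lt(max(abs(unclass(f)[, 41:60] -
                      oracle_delta(oracle_delta(mfcc, 9), 9))), 1e-6)
})

test_that("compute_deltas has the closed-form regression properties", {
  # constant rows -> zero slope
  expect_equal(compute_deltas(matrix(3, 10, 4), 1, 5), matrix(0, 10, 4))
  # linear ramp c_t = a * t -> interior frames equal a
  a <- c(0.5, -2)
  ramp <- outer(1:20, a)
  d <- compute_deltas(ramp, 1, 7)
  interior <- 4:17
  expect_equal(d[interior, ], matrix(rep(a, each = length(interior)),
                                     ncol = 2), tolerance = 1e-12)
  # second-order delta of a quadratic is constant in the interior
  quad <- matrix((1:30)^2, ncol = 1)
  d2 <- compute_deltas(quad, 2, 5)
  expect_lt(max(abs(diff(d2[5:26, 1]))), 1e-9)
  expect_error(compute_deltas(ramp, 1, 4), "odd")
})

test_that("the delta operator is linear", {
  withr::with_seed(3, {
    A <- matrix(rnorm(60), 15, 4)
    B <- matrix(rnorm(60), 15, 4)
  })
  expect_lt(max(abs(compute_deltas(A + B, 1, 9) -
                      compute_deltas(A, 1, 9) - compute_deltas(B, 1, 9))),
            1e-9)
})

test_that("amplitude scaling shifts only the energy-like coefficient", {
  rec1 <- chirp_recording()
  rec2 <- recording(rec1$samples * 0.25, rec1$sample_rate, "quiet")
  f1 <- extract_mfcc_features(rec1)
  f2 <- extract_mfcc_features(rec2)
  # shape coefficients 1..19 unchanged
  expect_lt(max(abs(f1[, 2:20] - f2[, 2:20])), 1e-8)
  # coefficient 0 shifted by a frame-independent constant
  shift <- f1[, 1] - f2[, 1]
  expect_lt(max(shift) - min(shift), 1e-8)
  expect_gt(mean(shift), 0)
})

test_that("feature extraction is deterministic and rejects too-short clips", {
  rec <- sine_recording(duration = 0.2)
  expect_identical(extract_mfcc_features(rec), extract_mfcc_features(rec))
  tiny <- recording(numeric(100), 16000, "tiny")
  expect_error(extract_mfcc_features(tiny), "shorter than one")
})

test_that("functional vectors are duration-invariant in length", {
  ap <- test_audio_params()
  a <- extract_functionals(synthesize_speech(list(kfrail_score = 1L,
                                                  sex = "male"),
                                             ap$baseline, ap$severe, seed = 1))
  bp <- test_audio_params(duration = 3)
  b <- extract_functionals(synthesize_speech(list(kfrail_score = 1L,
                                                  sex = "male"),
                                             bp$baseline, bp$severe, seed = 1))
  expect_length(a, 126)
  expect_length(b, 126)
  expect_identical(names(a), names(b))
})

test_that("a pure 200 Hz periodic source is tracked near 200 Hz", {
  sr <- 16000
  t <- 0:(sr - 1)
  saw <- 2 * ((t * 200 / sr) %% 1) - 1          # 200 Hz sawtooth, no pauses
  fun <- extract_functionals(recording(0.8 * saw, sr, "saw"))
  expect_lt(abs(fun[["f0_mean"]] - 200), 5)
  expect_gt(fun[["voiced_fraction"]], 0.9)
  expect_lt(fun[["pause_fraction"]], 0.1)
})

test_that("digital silence is flagged with pause fraction one", {
  fun <- extract_functionals(recording(numeric(8000), 16000, "silence"))
  expect_equal(fun[["pause_fraction"]], 1)
  expect_equal(fun[["voiced_fraction"]], 0)
  expect_equal(fun[["f0_mean"]], 0)
  expect_equal(fun[["rms_mean"]], 0)
  expect_true(attr(fun, "silent"))
})

test_that("resampling preserves the analysis contract at 48 kHz input", {
  sr <- 48000
  x <- 0.5 * sin(2 * pi * 500 * (0:(sr / 2 - 1)) / sr)
  f <- extract_mfcc_features(recording(x, sr, "hi-rate"))
  expect_equal(ncol(f), 60)
  # 0.5 s at the 16 kHz analysis rate, 25 ms window, 10 ms hop
  expect_equal(nrow(f), 1 + floor((8000 - 400) / 160))
})
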