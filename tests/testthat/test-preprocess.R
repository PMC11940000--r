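# Frequency-response oracle: magnitude of the designed filter's transfer
# function evaluated at frequency f, squared because the default application
# is forward-backward.
.freq_gain <- function(filt, f, fs, zero_phase = TRUE) {
  w <- 2 * pi * f / fs
  num <- sum(as.numeric(filt$b) * exp(-1i * w * (seq_along(filt$b) - 1)))
  den <- sum(as.numeric(filt$a) * exp(-1i * w * (seq_along(filt$a) - 1)))
  g <- Mod(num / den)
  if (zero_phase) g^2 else g
}

rms <- function(x) sqrt(mean(x^2))

test_that("band-pass rejects DC and matches its frequency-response oracle in pass and stop bands", {
  fs <- 2000
  cfg <- preprocess_config()
  warm <- 500:3500
  const <- matrix(5, 7, 4000)
  out <- bandpass(const, fs, cfg)
  expect_lt(max(abs(out[, warm])), 0.01 * 5)

  filt <- signal::butter(4, c(25, 500) / (fs / 2), type = "pass")
  t <- (1:4000) / fs
  for (f in c(100, 5)) {
    x <- matrix(rep(sin(2 * pi * f * t), each = 7), nrow = 7)
    y <- bandpass(x, fs, cfg)
    ratio <- rms(y[1, warm]) / rms(x[1, warm])
    oracle <- .freq_gain(filt, f, fs)
    expect_equal(ratio, oracle, tolerance = 0.05)
  }
  # spec-level absolute bounds: pass-band within 5%, stop-band below 10%
  x100 <- matrix(rep(sin(2 * pi * 100 * t), each = 7), nrow = 7)
  expect_equal(rms(bandpass(x100, fs, cfg)[1, warm]) / rms(x100[1, warm]), 1,
               tolerance = 0.05)
  x5 <- matrix(rep(sin(2 * pi * 5 * t), each = 7), nrow = 7)
  expect_lt(rms(bandpass(x5, fs, cfg)[1, warm]) / rms(x5[1, warm]), 0.10)
})

test_that("band-pass errors when fs is too low and caps the design edge at Nyquist with a warning", {
  expect_error(bandpass(matrix(0, 7, 100), fs = 40), "too low")
  expect_warning(bandpass(toy_emg(2000), fs = 1000), "Nyquist")
  out <- suppressWarnings(bandpass(toy_emg(2000), fs = 1000))
  expect_true(all(is.finite(out)))
})

test_that("rectification is absolute value and idempotent", {
  x <- matrix(c(-1, 2, -3), 1, 3)
  expect_equal(rectify(x), matrix(c(1, 2, 3), 1, 3))
  expect_equal(rectify(matrix(0, 7, 10)), matrix(0, 7, 10))
  y <- toy_emg(50)
  expect_identical(rectify(rectify(y)), rectify(y))
})

test_that("low-pass has unit DC gain and matches its frequency-response oracle", {
  fs <- 1000
  cfg <- preprocess_config()
  warm <- 1000:2000
  const <- matrix(3, 7, 3000)
  out <- lowpass(const, fs, cfg)
  expect_equal(out[, warm], const[, warm], tolerance = 0.01)

  filt <- signal::butter(4, 8 / (fs / 2), type = "low")
  t <- (1:3000) / fs
  for (f in c(2, 50)) {
    x <- matrix(rep(sin(2 * pi * f * t), each = 7), nrow = 7)
    y <- lowpass(x, fs, cfg)
    ratio <- rms(y[1, warm]) / rms(x[1, warm])
    expect_equal(ratio, .freq_gain(filt, f, fs), tolerance = 0.05)
  }
  x2 <- matrix(rep(sin(2 * pi * 2 * t), each = 7), nrow = 7)
  expect_equal(rms(lowpass(x2, fs, cfg)[1, warm]) / rms(x2[1, warm]), 1,
               tolerance = 0.05)
  x50 <- matrix(rep(sin(2 * pi * 50 * t), each = 7), nrow = 7)
  expect_lt(rms(lowpass(x50, fs, cfg)[1, warm]) / rms(x50[1, warm]), 0.05)
  expect_error(lowpass(matrix(0, 7, 10), fs = 10), "too low")
})

test_that("gaussian smoothing uses a unit-sum kernel and reduces variance", {
  fs <- 1000
  const <- matrix(2.5, 7, 500)
  expect_equal(gaussian_smooth(const, fs, 0.05), const, tolerance = 1e-12)
  imp <- matrix(0, 1, 2001); imp[1, 1001] <- 1
  sm <- gaussian_smooth(imp, fs, 0.05)
  expect_equal(sum(sm), 1, tolerance = 1e-6)
  expect_equal(which.max(sm[1, ]), 1001)
  set.seed(4)
  noise <- matrix(rnorm(7 * 3000), 7)
  expect_lt(stats::var(as.numeric(gaussian_smooth(noise, fs, 0.05))),
            stats::var(as.numeric(noise)))
  # non-negative input stays non-negative
  expect_true(all(gaussian_smooth(abs(noise), fs, 0.05) >= 0))
  expect_error(gaussian_smooth(noise, fs, 0), "sigma")
})

test_that("MVC profiles take channel-wise maxima over recordings and MVC movements", {
  fs <- 2000
  cfg <- preprocess_config()
  rec <- toy_recording(emg = toy_emg(1500, seed = 9), fs = fs)
  prof <- compute_mvc_profile(list(rec), config = cfg)
  # oracle: independent straight-line composition of the four exported stages
  env <- gaussian_smooth(lowpass(rectify(bandpass(rec$emg, fs, cfg)), fs, cfg),
                         fs, cfg$gaussian_sigma_s)
  expect_equal(prof$channel_max, apply(env, 1, max))
  # dominant MVC movements set the profile
  prof2 <- compute_mvc_profile(list(rec), mvc_movements = list(rec$emg * 3),
                               config = cfg)
  expect_equal(prof2$channel_max, 3 * prof$channel_max, tolerance = 1e-10)
  # an everywhere-zero channel is an error
  z <- rec
  z$emg[4, ] <- 0
  expect_error(compute_mvc_profile(list(z), config = cfg), "4")
  expect_error(compute_mvc_profile(list()), "at least one")
})

test_that("MVC normalization divides per channel and bounds in-sample data by 1", {
  x <- matrix(2, 7, 10)
  prof <- mvc_profile(1, rep(4, 7))
  expect_equal(max(normalize_by_mvc(x, prof)), 0.5)
  fs <- 2000
  cfg <- preprocess_config()
  recs <- lapply(1:3, function(i) toy_recording(id = paste0("R", i),
                                                emg = toy_emg(1200, seed = i),
                                                fs = fs))
  prof2 <- compute_mvc_profile(recs, config = cfg)
  normed <- lapply(recs, function(r) preprocess(r, prof2, cfg)$emg)
  expect_true(all(vapply(normed, max, numeric(1)) <= 1 + 1e-12))
  # the profile-defining frames reach exactly 1
  expect_equal(max(vapply(normed, max, numeric(1))), 1, tolerance = 1e-12)
  bad <- prof2; bad$channel_max[2] <- 0
  expect_error(normalize_by_mvc(x, bad), "non-positive")
})

test_that("the chain preserves shape, equals its stage-by-stage composition, and zero maps to zero", {
  fs <- 2000
  cfg <- preprocess_config()
  rec <- toy_recording(emg = toy_emg(900, seed = 2), fs = fs)
  prof <- compute_mvc_profile(list(rec), config = cfg)
  out <- preprocess(rec, prof, cfg)
  expect_equal(dim(out$emg), dim(rec$emg))
  manual <- normalize_by_mvc(
    gaussian_smooth(lowpass(rectify(bandpass(rec$emg, fs, cfg)), fs, cfg),
                    fs, cfg$gaussian_sigma_s), prof)
  expect_equal(out$emg, manual)
  expect_true(all(out$emg >= 0))
  zrec <- rec; zrec$emg[] <- 0
  expect_equal(preprocess(zrec, prof, cfg)$emg, zrec$emg)
})

test_that("zero-phase filtering leaves a symmetric burst's envelope peak in place", {
  fs <- 1000
  cfg <- preprocess_config()
  L <- 2000; centre <- 1200
  t <- 1:L
  burst <- exp(-((t - centre)^2) / (2 * 60^2)) * sin(2 * pi * 80 * t / fs)
  x <- matrix(rep(burst, each = 7), nrow = 7)
  env <- suppressWarnings(
    gaussian_smooth(lowpass(rectify(bandpass(x, fs, cfg)), fs, cfg),
                    fs, cfg$gaussian_sigma_s))
  expect_lte(abs(which.max(env[1, ]) - centre), 2)
})
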