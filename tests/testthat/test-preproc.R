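test_that("band-pass plus notch attenuates line noise and passes alpha", {
  r50 <- sine_recording(50)
  out50 <- bandpass_notch(r50)
  expect_lte(rms(out50$data), 0.1 * rms(r50$data))
  r10 <- sine_recording(10)
  out10 <- bandpass_notch(r10)
  expect_gte(rms(out10$data), 0.7 * rms(r10$data))
  z <- eeg_recording(matrix(0, 3, 100), 250)
  expect_equal(bandpass_notch(z)$data, z$data)
  expect_error(bandpass_notch(sine_recording(10), low_hz = 1, high_hz = 200),
               "Nyquist")
  expect_error(bandpass_notch(sine_recording(10), notch_hz = 130), "Nyquist")
})

test_that("common average reference zeroes channel means and is idempotent", {
  const <- eeg_recording(matrix(5, 4, 10), 250)
  expect_equal(average_reference(const)$data, matrix(0, 4, 10))
  set.seed(1)
  r <- eeg_recording(matrix(rnorm(200), 8, 25), 250)
  a1 <- average_reference(r)
  expect_equal(max(abs(colMeans(a1$data))), 0, tolerance = 1e-10)
  expect_equal(average_reference(a1)$data, a1$data, tolerance = 1e-12)
})

test_that("downsampling preserves duration and passband content", {
  set.seed(2)
  r <- eeg_recording(matrix(rnorm(2 * 300000), 2, 300000), 1000)  # 300 s
  d <- downsample(r, 250)
  expect_equal(d$sfreq, 250)
  expect_true(abs(ncol(d$data) - 75000) <= 1)
  s5 <- sine_recording(5, sfreq = 500, duration_s = 8)
  d5 <- downsample(s5, 250)
  expect_equal(rms(d5$data), rms(s5$data), tolerance = 0.02)
  expect_error(downsample(s5, 500), "below")
})

test_that("GFP matches its closed form and scales homogeneously", {
  r <- eeg_recording(matrix(c(1, -1), 2, 2), 250)
  expect_equal(gfp(r)$values, c(1, 1))
  z <- eeg_recording(matrix(0, 3, 5), 250)
  expect_equal(gfp(z)$values, rep(0, 5))
  set.seed(3)
  r2 <- eeg_recording(matrix(rnorm(40), 4, 10), 250)
  r3 <- r2; r3$data <- 3 * r2$data
  expect_equal(gfp(r3)$values, 3 * gfp(r2)$values)
  # invariance to channel-common offsets
  r4 <- r2; r4$data <- r2$data + matrix(7, 4, 10)
  expect_equal(gfp(r4)$values, gfp(r2)$values)
})

test_that("GFP peak detection is strict, leftmost on plateaus, and endpoint-free", {
  expect_equal(gfp_peaks(c(0, 1, 0, 2, 0)), c(2L, 4L))
  expect_equal(gfp_peaks(seq(0, 1, length.out = 10)), integer(0))
  expect_equal(gfp_peaks(c(0, 1, 1, 0)), 2L)                # plateau -> leftmost
  expect_equal(gfp_peaks(c(2, 1, 3)), integer(0))           # endpoints excluded
  # rectified 10 Hz envelope at 250 Hz for 10 s: two humps per cycle
  t <- seq(0, 10 - 1 / 250, by = 1 / 250)
  v <- abs(sin(2 * pi * 10 * t)) + 0.2
  np <- length(gfp_peaks(v))
  expect_true(abs(np - 200) <= 5)
  # min separation keeps the highest peaks
  expect_equal(gfp_peaks(c(0, 1, 0, 2, 0), min_separation_samples = 3), 4L)
})

test_that("the preprocessing chain keeps the data average-referenced", {
  set.seed(4)
  r <- eeg_recording(matrix(rnorm(8 * 5000), 8, 5000), 1000)
  out <- downsample(average_reference(bandpass_notch(r)), 250)
  expect_equal(max(abs(colMeans(out$data))), 0, tolerance = 1e-8)
  # full determinism of the chain
  out2 <- downsample(average_reference(bandpass_notch(r)), 250)
  expect_identical(out$data, out2$data)
})
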