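test_that("label assignment is polarity-invariant, thresholded, and validates input", {
  M <- orthogonal_maps(3, 8)
  tm <- template_maps(M)
  # a sample equal to minus map B gets label B with |r| = 1
  rec <- eeg_recording(t(rbind(-5 * M[2, ], 2 * M[1, ])), 250)
  seg <- assign_labels(rec, tm, threshold = 0.5)
  expect_equal(seg$labels, c(2L, 1L))
  expect_equal(seg$abs_corr, c(1, 1), tolerance = 1e-12)
  # a sample orthogonal to all maps stays unassigned at threshold 0.5
  ortho <- orthogonal_maps(4, 8)[4, ]
  rec2 <- eeg_recording(t(rbind(ortho, M[1, ])), 250)
  seg2 <- assign_labels(rec2, tm, threshold = 0.5)
  expect_equal(seg2$labels[1], 0L)
  wrong <- eeg_recording(matrix(rnorm(10), 5, 2), 250)
  expect_error(assign_labels(wrong, tm), "channel count")
})

test_that("smoothing with zero window and strength is the identity", {
  s <- small_setup(n_channels = 12)
  sq <- simulate_state_sequence(s$truth, 4, 250, seed = 1)
  rec <- simulate_recording(s$truth, sq, s$montage, seed = 2)
  seg <- assign_labels(average_reference(rec), s$templates, threshold = 0.5)
  sm <- smooth_labels(seg, half_window = 0, strength = 0)
  expect_identical(sm$labels, seg$labels)
})

test_that("smoothing removes an isolated one-sample label flip", {
  M <- orthogonal_maps(2, 10)
  tm <- template_maps(M)
  labels <- rep(1L, 120)
  labels[60] <- 2L
  sq <- structure(list(labels = labels, sfreq = 250), class = "state_sequence")
  truth <- simulation_truth(tm, snr = Inf)
  rec <- simulate_recording(truth, sq, make_montage(10), snr = Inf, seed = 3)
  seg <- assign_labels(average_reference(rec), tm, threshold = 0)
  expect_identical(seg$labels, labels)          # the flip is really there
  sm <- smooth_labels(seg)                      # defaults: window 3, strength 10
  expect_identical(sm$labels, rep(1L, 120))
})

test_that("no one-sample runs survive smoothing of an alternating sequence", {
  M <- orthogonal_maps(2, 10)
  tm <- template_maps(M)
  labels <- rep(c(1L, 2L), 60)
  sq <- structure(list(labels = labels, sfreq = 250), class = "state_sequence")
  truth <- simulation_truth(tm, snr = Inf)
  rec <- simulate_recording(truth, sq, make_montage(10), snr = Inf, seed = 4)
  seg <- assign_labels(average_reference(rec), tm, threshold = 0)
  sm <- smooth_labels(seg)
  expect_true(min(rle(sm$labels)$lengths) >= 2)
  # and the result is a fixed point of the smoothing operator
  sm2 <- smooth_labels(sm)
  expect_identical(sm2$labels, sm$labels)
})

test_that("unassigned samples break runs and are never relabeled", {
  seg <- make_seg(c(1, 1, 0, 2, 2), k = 2)
  sm <- smooth_labels(seg)
  expect_equal(sm$labels[3], 0L)
  expect_equal(transition_counts(seg), matrix(0L, 2, 2))
})

test_that("metrics match closed forms on hand-built segmentations", {
  # constant map A: coverage 100%, occurrence 0.25/s, mean duration 4000 ms
  m1 <- compute_metrics(make_seg(rep(1, 1000), sfreq = 250, k = 1))
  expect_equal(m1$coverage, 100)
  expect_equal(m1$occurrence, 0.25)
  expect_equal(m1$mean_duration, 4000)
  # two maps alternating every 25 samples at 250 Hz
  m2 <- compute_metrics(make_seg(rep(rep(1:2, each = 25), 20), sfreq = 250))
  expect_equal(m2$coverage, c(50, 50))
  expect_equal(m2$mean_duration, c(100, 100))
  expect_equal(m2$occurrence, c(5, 5))
  # GEV sums to 100 only when everything is assigned with correlation 1
  expect_equal(sum(m2$gev), 100, tolerance = 1e-9)
})

test_that("back-fit metrics of a noiseless recording equal the planted truth", {
  s <- small_setup(n_channels = 12)
  sq <- simulate_state_sequence(s$truth, 20, 250, seed = 6)
  rec <- simulate_recording(s$truth, sq, s$montage, snr = Inf, seed = 7)
  seg <- assign_labels(average_reference(rec), s$templates, threshold = 0)
  got <- compute_metrics(seg)
  want <- sequence_metrics(sq)
  expect_equal(got$coverage, want$coverage, tolerance = 1e-9)
  expect_equal(got$occurrence, want$occurrence, tolerance = 1e-9)
  expect_equal(got$mean_duration, want$mean_duration, tolerance = 1e-9)
  expect_equal(sum(got$gev), 100, tolerance = 1e-6)
})

test_that("metrics are invariant to amplitude scaling of the recording", {
  s <- small_setup(n_channels = 12)
  sq <- simulate_state_sequence(s$truth, 8, 250, seed = 8)
  rec <- simulate_recording(s$truth, sq, s$montage, seed = 9)
  rec5 <- rec; rec5$data <- 5 * rec$data
  m1 <- compute_metrics(assign_labels(average_reference(rec), s$templates))
  m5 <- compute_metrics(assign_labels(average_reference(rec5), s$templates))
  expect_equal(m1, m5, tolerance = 1e-9)
})

test_that("GEV contributions never exceed 100 percent in total", {
  s <- small_setup(n_channels = 12)
  sq <- simulate_state_sequence(s$truth, 8, 250, seed = 10)
  rec <- simulate_recording(s$truth, sq, s$montage, seed = 11)
  m <- compute_metrics(assign_labels(average_reference(rec), s$templates))
  expect_lte(sum(m$gev), 100)
})
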