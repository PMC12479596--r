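test_that("montage is deterministic, distinct, and confined to the upper hemisphere", {
  m204 <- make_montage(204)
  expect_equal(nrow(m204), 204)
  expect_equal(nrow(unique(m204[, c("x", "y", "z")])), 204)
  m8 <- make_montage(8)
  expect_equal(nrow(unique(m8[, c("x", "y", "z")])), 8)
  expect_true(all(make_montage(32)$z >= 0))
  expect_identical(make_montage(64), make_montage(64))
  expect_error(make_montage(7), "n_channels")
})

test_that("template maps are average-referenced, unit-norm, separated, seed-dependent", {
  mont <- make_montage(32)
  tm <- make_template_maps(4, mont, seed = 7)
  expect_equal(unname(rowSums(tm$maps)), rep(0, 4), tolerance = 1e-12)
  expect_equal(unname(rowSums(tm$maps^2)), rep(1, 4), tolerance = 1e-12)
  cc <- abs(tcrossprod(tm$maps))
  expect_true(all(cc[upper.tri(cc)] < 0.8))
  tm2 <- make_template_maps(2, mont, seed = 7)
  expect_equal(max(abs(rowMeans(tm2$maps))), 0, tolerance = 1e-12)
  expect_false(isTRUE(all.equal(make_template_maps(4, mont, seed = 1)$maps,
                                make_template_maps(4, mont, seed = 2)$maps)))
  expect_identical(make_template_maps(4, mont, seed = 3),
                   make_template_maps(4, mont, seed = 3))
})

test_that("semi-Markov sequences reproduce the planted dwell and transition structure", {
  s <- small_setup()
  sq <- simulate_state_sequence(s$truth, 240, 250, seed = 11)
  r <- rle(sq$labels)
  expect_true(all(r$lengths >= 1))
  expect_true(all(sq$labels %in% 1:4))
  # empirical mean dwell close to the planted 80 ms
  expect_equal(mean(r$lengths) * 1000 / 250, 80, tolerance = 5 / 80)
  # per-map dwell means too
  per_map <- tapply(r$lengths, r$values, mean) * 4
  expect_true(all(abs(per_map - 80) < 5))
  # k = 1 degenerates to a single run
  k1 <- list(dwell_mean_ms = 80, transition_matrix = matrix(0, 1, 1))
  sq1 <- simulate_state_sequence(k1, 2, 250)
  expect_identical(unique(sq1$labels), 1L)
  expect_length(sq1$labels, 500)
})

test_that("uniform transition rows give uniform successor frequencies (multinomial check)", {
  s <- small_setup()
  sq <- simulate_state_sequence(s$truth, 600, 250, seed = 13)
  counts <- transition_counts(sq)
  for (i in 1:4) {
    row <- counts[i, -i]
    nt <- sum(row)
    p0 <- 1 / 3
    se <- sqrt(p0 * (1 - p0) / nt)
    expect_true(all(abs(row / nt - p0) < 3 * se),
                info = paste("row", i))
  }
})

test_that("coverage equals occurrence times mean duration on planted sequences", {
  s <- small_setup()
  for (sd in 1:5) {
    sq <- simulate_state_sequence(s$truth, 30, 250, seed = sd)
    sm <- sequence_metrics(sq)
    ok <- is.finite(sm$mean_duration)
    expect_equal(sm$coverage[ok],
                 sm$occurrence[ok] * sm$mean_duration[ok] / 10,
                 tolerance = 1e-12)
  }
})

test_that("recordings hit the requested signal-to-noise ratio", {
  s <- small_setup()
  sq <- simulate_state_sequence(s$truth, 20, 250, seed = 3)
  clean <- simulate_recording(s$truth, sq, s$montage, snr = Inf, seed = 9)
  noisy <- simulate_recording(s$truth, sq, s$montage, snr = 4, seed = 9)
  # same seed means identical signal; the difference is the noise alone
  noise <- noisy$data - clean$data
  expect_equal(rms(clean$data) / rms(noise), 4, tolerance = 0.05)
})

test_that("noiseless recordings back-fit exactly to the planted sequence", {
  s <- small_setup()
  sq <- simulate_state_sequence(s$truth, 10, 250, seed = 21)
  rec <- simulate_recording(s$truth, sq, s$montage, snr = Inf, seed = 22)
  seg <- assign_labels(average_reference(rec), s$templates, threshold = 0)
  expect_identical(seg$labels, sq$labels)
  expect_equal(max(abs(seg$abs_corr - 1)), 0, tolerance = 1e-9)
})

test_that("generated spectra are alpha-dominant with a peak inside 8-14 Hz", {
  s <- small_setup()
  sq <- simulate_state_sequence(s$truth, 40, 250, seed = 31)
  rec <- simulate_recording(s$truth, sq, s$montage, seed = 32)
  sp <- power_spectrum(rec)
  cm <- colMeans(sp$power)
  sel <- sp$freqs >= 3 & sp$freqs <= 45
  expect_gt(sp$freqs[sel][which.max(cm[sel])], 8)
  expect_lt(sp$freqs[sel][which.max(cm[sel])], 14)
  bp <- band_power(sp)
  expect_gt(bp$power[bp$band == "alpha"], bp$power[bp$band == "theta"])
  expect_gt(bp$power[bp$band == "alpha"], bp$power[bp$band == "low_beta"])
})

test_that("cohorts have the study layout and reproduce bitwise under a fixed seed", {
  s <- small_setup(n_channels = 12)
  coh <- simulate_cohort(3, s$truth, duration_s = 5, montage = s$montage,
                         seed = 5)
  expect_length(coh$recordings, 6)
  groups <- vapply(coh$recordings, function(r) r$group, character(1))
  expect_equal(unname(table(groups)[c("A", "B")]), c(3L, 3L),
               ignore_attr = TRUE)
  coh2 <- simulate_cohort(3, s$truth, duration_s = 5, montage = s$montage,
                          seed = 5)
  expect_identical(coh$recordings, coh2$recordings)
  expect_error(simulate_cohort(1, s$truth), "n_per_group")
})

test_that("quadrupling the duration halves the dwell-mean standard error", {
  s <- small_setup()
  est <- function(dur, sd) {
    sq <- simulate_state_sequence(s$truth, dur, 250, seed = sd)
    r <- rle(sq$labels)
    mean(r$lengths[r$values == 1]) * 4
  }
  short <- vapply(1:30, function(sd) est(30, sd), numeric(1))
  long <- vapply(1:30, function(sd) est(120, sd + 1000), numeric(1))
  ratio <- sd(short) / sd(long)
  expect_gt(ratio, 1.4)
  expect_lt(ratio, 2.9)
})
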