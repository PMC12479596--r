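# End-to-end S3 model interface on a small synthetic cohort.

fit_fixture <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    s <- small_setup(n_channels = 16)
    coh <- simulate_cohort(4, s$truth, duration_s = 30, montage = s$montage,
                           seed = 20)
    fit <- microstate_fit(coh$recordings, k = 4, subject_k = 4,
                          restarts = 12, seed = 21)
    cache <<- list(s = s, coh = coh, fit = fit)
    cache
  }
})

test_that("the fitted model exposes maps, metrics and transitions coherently", {
  fx <- fit_fixture()
  fit <- fx$fit
  expect_s3_class(fit, "microstate_fit")
  expect_equal(fit$k, 4)
  expect_equal(dim(coef(fit)), c(4, 16))
  expect_true(fit$gev_total > 0.5 && fit$gev_total <= 1)
  # every subject contributes one row per map
  expect_equal(nrow(fit$metrics), 8 * 4)
  expect_equal(nrow(fit$transitions), 8 * 12)
  # fitted maps recover the generative templates
  cc <- abs(tcrossprod(coef(fit), fx$s$templates$maps))
  expect_true(all(apply(cc, 2, max) >= 0.95))
  expect_output(print(fit), "Microstate model")
})

test_that("summary reports group comparisons with an adjusted alpha", {
  fx <- fit_fixture()
  sm <- summary(fx$fit)
  expect_s3_class(sm, "summary.microstate_fit")
  expect_true(all(c("U", "p", "cliffs_delta") %in% names(sm$parameter_tests)))
  expect_true(all(sm$parameter_tests$p >= 0 & sm$parameter_tests$p <= 1))
  expect_lte(sm$alpha_parameters, 0.05)
  expect_true(all(c("t", "p", "cohens_d") %in% names(sm$transition_tests)))
  expect_output(print(sm), "Sidak-adjusted alpha")
})

test_that("predict back-fits new recordings with the fitted templates", {
  fx <- fit_fixture()
  sq <- simulate_state_sequence(fx$s$truth, 10, 250, seed = 30)
  new_rec <- simulate_recording(fx$s$truth, sq, fx$s$montage, seed = 31)
  seg <- predict(fx$fit, new_rec)
  expect_s3_class(seg, "ms_segmentation")
  expect_length(seg$labels, length(sq$labels))
  # the fitted maps are relabellings of the truth; agreement is up to the
  # map permutation, so compare run structure via coverage totals
  expect_gt(mean(seg$labels > 0), 0.8)
  two <- predict(fx$fit, list(new_rec, new_rec))
  expect_length(two, 2)
  expect_identical(two[[1]]$labels, two[[2]]$labels)
})

test_that("simulate round-trips the fitted model into new recordings", {
  fx <- fit_fixture()
  sims <- simulate(fx$fit, nsim = 2, seed = 40, duration_s = 5,
                   montage = fx$s$montage)
  expect_length(sims, 2)
  expect_s3_class(sims[[1]], "eeg_recording")
  expect_equal(nrow(sims[[1]]$data), 16)
  # simulated data carry the fitted topographies
  seg <- predict(fx$fit, sims[[1]])
  expect_gt(mean(seg$labels > 0), 0.8)
  sims_again <- simulate(fx$fit, nsim = 2, seed = 40, duration_s = 5,
                         montage = fx$s$montage)
  expect_identical(sims, sims_again)
})

test_that("plotting the fitted maps draws without error", {
  fx <- fit_fixture()
  tf <- tempfile(fileext = ".png")
  grDevices::png(tf, width = 600, height = 200)
  expect_no_error(plot(fx$fit, montage = fx$s$montage, grid_n = 25))
  grDevices::dev.off()
  unlink(tf)
})
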