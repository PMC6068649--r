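test_that("peaks on a noiseless pulse train land within 2 samples of ground truth", {
  g <- generate_recording(beat_template(rise_time = 0.2), 15)
  lm <- detect_peaks_valleys(g$recording)
  pk <- lm$time[lm$type == "peak"]
  expect_gte(length(pk), 15)
  err_samples <- abs(pk[1:15] - g$truth$t_pn) * g$recording$rate
  expect_lt(max(err_samples), 2 + 1e-9)
  # strict alternation, peak maximal between flanking valleys
  expect_true(all(lm$type == rep(c("valley", "peak"),
                                 length.out = nrow(lm))))
  vp <- which(lm$type == "peak")
  expect_true(all(lm$value[vp] > lm$value[vp - 1] &
                  lm$value[vp] > lm$value[vp + 1]))
})

test_that("monotone ramps have no peaks; a triangle pulse has exactly one", {
  ramp <- ppg_recording(seq(0, 1, length.out = 500))
  expect_warning(lm0 <- detect_peaks_valleys(ramp), "no peaks")
  expect_equal(nrow(lm0), 0)

  tri <- triangle_recording()
  lm1 <- detect_peaks_valleys(tri)
  expect_equal(sum(lm1$type == "peak"), 1)
  expect_equal(lm1$index, c(1L, 101L, 201L))  # endpoints and apex
})

test_that("beat selection keeps the first k complete beats and names the shortfall", {
  g <- generate_recording(beat_template(rise_time = 0.2), 15)
  lm <- detect_peaks_valleys(g$recording)
  b12 <- select_beats(lm, k = 12)
  expect_equal(nrow(b12), 12)
  expect_equal(b12$beat_index, 1:12)
  expect_true(all(diff(b12$t_pn) > 0))

  g11 <- generate_recording(beat_template(rise_time = 0.2), 11)
  lm11 <- detect_peaks_valleys(g11$recording)
  expect_error(select_beats(lm11, k = 12), "11 < 12")
})

test_that("rising slope follows its defining ratio and offset invariance", {
  expect_equal(rising_slope(1, 0, 0.1, 0), 10)
  expect_equal(rising_slope(3 + 0.4, 3, 0.25, 0.05),
               rising_slope(0.4, 0, 0.25, 0.05))
  expect_error(rising_slope(1, 0, 0.2, 0.2), "strictly greater")
})

test_that("falling slope reports a magnitude, signed value on request", {
  expect_equal(falling_slope(0, 1, 0.2, 0), 5)
  expect_equal(falling_slope(0, 1, 0.2, 0, signed = TRUE), -5)
  expect_error(falling_slope(0, 1, 0.1, 0.1), "strictly greater")

  tri <- extract_beat_features(triangle_recording(), k = 1,
                               min_distance = 0.01)
  expect_equal(tri$rs, tri$fs, tolerance = 1e-9)   # symmetric pulse
  expect_lt(tri$fs_signed, 0)
})

test_that("min-max rescaling is affine, idempotent and matches its elementwise form", {
  expect_equal(rescale01(c(2, 4, 6)), c(0, 0.5, 1))
  set.seed(7)
  x <- stats::rnorm(50)
  r1 <- rescale01(x)
  expect_lt(max(abs(r1 - (x - min(x)) / (max(x) - min(x)))), 1e-12)
  expect_equal(rescale01(r1), r1, tolerance = 1e-12)
  expect_error(rescale01(rep(1, 3)), "degenerate")
})

test_that("summaries use the n-1 variance and reproduce cohort demographics", {
  ages <- hd_patient_table()$age
  s <- summarize_feature(ages, "before", "rs")
  expect_equal(s$mean, 77)
  expect_equal(round(sqrt(s$variance), 1), 10.8)
  expect_equal(s$n, 11)

  expect_equal(summarize_feature(rep(4, 5), "after", "fs")$variance, 0)
  expect_equal(summarize_feature(c(2, 8), "before", "rs")$variance,
               (2 - 8)^2 / 2)
  expect_error(summarize_feature(1, "before", "rs"), "at least 2")
})

test_that("slope features are invariant to a whole-period time shift", {
  g <- generate_recording(beat_template(rise_time = 0.2), 15,
                          noise = noise_spec(noise_sd = 0.01, seed = 13))
  rec <- g$recording
  shifted <- ppg_recording(rec$samples[-(1:800)], rate = rec$rate)
  f0 <- extract_beat_features(rec, k = 13)
  f1 <- extract_beat_features(shifted, k = 12)
  # interior beats (all landmarks away from the record edges) are identical
  expect_equal(f1$rs[2:12], f0$rs[3:13], tolerance = 1e-9)
  expect_equal(f1$fs[2:12], f0$fs[3:13], tolerance = 1e-9)
})

test_that("selected beats always carry positive slopes on a noiseless cohort", {
  coh <- generate_cohort(cohort_spec(n_per_class = c(1, 1, 1),
                                     segments_per_subject = 1), seed = 2)
  for (r in coh$recordings[1:4]) {
    b <- extract_beat_features(detrend_ppg(r$recording), k = 12)
    expect_true(all(b$rs > 0) && all(b$fs > 0))
  }
})

test_that("end-to-end slope recovery on a noiseless cohort is within 2%", {
  spec <- cohort_spec(n_per_class = c(2, 1, 1), segments_per_subject = 1,
                      jitter_base = 0, jitter_coupling = 0,
                      noise = noise_spec())
  coh <- generate_cohort(spec, seed = 17)
  meas <- cohort_slope_summaries(coh, smooth = FALSE)
  truth <- cohort_slope_summaries(coh, use_truth = TRUE)
  expect_lt(max(abs(meas$rs_mean / truth$rs_mean - 1)), 0.02)
  expect_lt(max(abs(meas$fs_mean / truth$fs_mean - 1)), 0.02)
})
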