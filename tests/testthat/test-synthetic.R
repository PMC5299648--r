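test_that("beat template renders the Gaussian sum on the sample grid", {
  wp <- default_wave_params()
  # zero-amplitude waves give an all-zero vector
  wp0 <- wp; wp0$amp_mv <- rep(0, 5)
  expect_equal(make_beat_template(wp0, 0.8, 256)$samples, rep(0, 205))
  # a single symmetric R bump peaks at its center sample
  wp1 <- wp; wp1$amp_mv <- c(0, 0, 1, 0, 0); wp1$width_s[3] <- 0.010
  t1 <- make_beat_template(wp1, 0.8, 256)
  expect_identical(which.max(t1$samples), t1$r_offset + 1L)
  # default PQRST at fs 256, 0.8 s: length 205, max equals R amplitude
  tmpl <- make_beat_template(wp, 0.8, 256)
  expect_length(tmpl$samples, 205)
  expect_equal(max(tmpl$samples), wp$amp_mv[3], tolerance = 1e-6)
  expect_identical(which.max(tmpl$samples), tmpl$r_offset + 1L)
  expect_error(make_beat_template(wp, -1, 256), "positive")
  wp_bad <- wp; wp_bad$width_s[2] <- 0
  expect_error(make_beat_template(wp_bad, 0.8, 256), "width")
})

test_that("noise-free synthesis is exactly periodic with known R indices", {
  tmpl <- make_beat_template(fs = 256)
  rec <- clean_recording(duration = 10, mean_hr = 60)
  expect_length(rec$true_r_indices, 10)
  expect_true(all(diff(rec$true_r_indices) == 256))
  # each laid beat is the template verbatim
  start <- rec$true_r_indices[3] - tmpl$r_offset
  expect_equal(rec$signal$samples[start:(start + 204)], tmpl$samples)
  expect_error(synthesize_recording(tmpl, duration = 1), "duration")
})

test_that("synthesis is bit-reproducible given a seed", {
  tmpl <- make_beat_template(fs = 256)
  a <- synthesize_recording(tmpl, duration = 10, seed = 7,
                            artifact_rate = 0.1)
  b <- synthesize_recording(tmpl, duration = 10, seed = 7,
                            artifact_rate = 0.1)
  expect_identical(a, b)
})

test_that("beat count at 70 bpm tracks the nominal rate under jitter", {
  tmpl <- make_beat_template(fs = 256)
  rec <- synthesize_recording(tmpl, duration = 300, mean_hr = 70,
                              rr_jitter_sd = 0.02, noise_sd = 0,
                              baseline_wander_amp = 0, seed = 7)
  expect_lte(abs(length(rec$true_r_indices) - round(300 * 70 / 60)), 2)
})

test_that("artifact beats are exact x3 scalings and are recorded", {
  tmpl <- make_beat_template(fs = 256)
  rec <- synthesize_recording(tmpl, duration = 30, mean_hr = 60,
                              rr_jitter_sd = 0, noise_sd = 0,
                              baseline_wander_amp = 0, artifact_rate = 0.2,
                              seed = 3)
  expect_gt(length(rec$artifact_beat_indices), 0)
  peaks <- vapply(seq_along(rec$true_r_indices), function(k) {
    s <- rec$true_r_indices[k] - tmpl$r_offset
    max(abs(rec$signal$samples[s:(s + 204)]))
  }, numeric(1))
  clean_max <- max(abs(tmpl$samples))
  expect_equal(peaks[rec$artifact_beat_indices],
               rep(3 * clean_max, length(rec$artifact_beat_indices)))
  expect_equal(peaks[-rec$artifact_beat_indices],
               rep(clean_max, length(peaks) - length(rec$artifact_beat_indices)))
})

test_that("apply_intervention simulates the ground-truth morphology change", {
  tmpl <- make_beat_template(fs = 256)
  delayed <- apply_intervention(tmpl, dtf(1, c(1, 0)))
  expect_equal(delayed$samples, c(0, tmpl$samples[-205]))
  half <- apply_intervention(tmpl$samples, dtf(0.5, c(1, 0)))
  expect_equal(half, 0.5 * c(0, tmpl$samples[-205]))
  imp <- apply_intervention(c(1, rep(0, 5)), dtf(1, c(1, -0.5)))
  expect_equal(imp, c(0, 1, 0.5, 0.25, 0.125, 0.0625))
})

test_that("noise-free homogeneous trials carry an exact estimation target", {
  cfg <- trial_config(n_subjects = 1, period_duration = 10, fs = 256,
                      mean_hr = 60, rr_jitter_sd = 0, noise_sd = 0,
                      baseline_wander_amp = 0, artifact_rate = 0,
                      subject_variation_sd = 0, seed = 5)
  trial <- generate_trial(cfg)
  sub <- trial$subjects[[1]]
  expected <- simulate_tf(cfg$ground_truth_tf_by_pair$bda,
                          sub$template$samples)
  rec <- sub$recordings$during
  start <- rec$true_r_indices[2] - rec$true_template$r_offset
  expect_equal(rec$signal$samples[start:(start + 204)], expected)
  # with zero variation the stored per-subject TFs equal the ground truth
  expect_identical(sub$tf_bda, cfg$ground_truth_tf_by_pair$bda)
})

test_that("trials are reproducible and earlier subjects never reshuffle", {
  cfg2 <- trial_config(n_subjects = 2, period_duration = 8, fs = 256,
                       mean_hr = 70, seed = 9)
  cfg3 <- trial_config(n_subjects = 3, period_duration = 8, fs = 256,
                       mean_hr = 70, seed = 9)
  t2a <- generate_trial(cfg2)
  t2b <- generate_trial(cfg2)
  t3 <- generate_trial(cfg3)
  expect_identical(t2a, t2b)
  expect_identical(t2a$subjects[[1]], t3$subjects[[1]])
  expect_identical(t2a$subjects[[2]], t3$subjects[[2]])
  expect_length(t3$subjects, 3)
  expect_length(t3$subjects[[1]]$recordings, 3)
})

test_that("trial_config rejects invalid study parameters", {
  expect_error(trial_config(n_subjects = 0), "n_subjects")
  expect_error(trial_config(artifact_rate = 1), "artifact_rate")
  expect_error(trial_config(noise_sd = -1), "non-negative")
  expect_error(trial_config(ground_truth_tf_by_pair = list()), "bda")
})
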