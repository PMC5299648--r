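test_that("band-pass filter has the specified pass- and stop-band behaviour", {
  fs <- 256
  t <- (0:(60 * fs - 1)) / fs
  # 10 Hz lies mid-band: RMS preserved within 5%
  in10 <- sampled_signal(sin(2 * pi * 10 * t), fs)
  out10 <- bandpass_filter(in10)
  expect_equal(sqrt(mean(out10$samples^2)), sqrt(mean(in10$samples^2)),
               tolerance = 0.05)
  # 0.05 Hz sits well below the 0.5 Hz edge: attenuated below 10%
  in005 <- sampled_signal(sin(2 * pi * 0.05 * t), fs)
  out005 <- bandpass_filter(in005)
  expect_lt(sqrt(mean(out005$samples^2)), 0.1 * sqrt(mean(in005$samples^2)))
  # constant input is removed entirely
  dc <- bandpass_filter(sampled_signal(rep(1, 2 * fs), fs))
  expect_lt(mean(abs(dc$samples)), 1e-3)
  expect_identical(length(out10$samples), length(in10$samples))
  expect_error(bandpass_filter(in10, high_hz = 200), "fs/2")
})

test_that("R-peak detection is exact on clean recordings and quiet on silence", {
  fs <- 256
  expect_identical(detect_r_peaks(sampled_signal(rep(0, 3 * fs), fs)),
                   integer(0))
  # a single beat in an otherwise flat window
  tmpl <- make_beat_template(fs = fs)
  one <- rep(0, round(2.5 * fs))
  one[300:504] <- tmpl$samples
  det <- detect_r_peaks(sampled_signal(one, fs))
  expect_identical(det, 299L + tmpl$r_offset + 1L)
  # clean 30-s recording: every true R matched within 10 ms, no extras
  rec <- clean_recording(duration = 30, mean_hr = 60)
  det <- detect_r_peaks(bandpass_filter(rec$signal))
  expect_identical(length(det), length(rec$true_r_indices))
  expect_true(all(abs(det - rec$true_r_indices) <= round(0.01 * fs)))
})

test_that("detector keeps sensitivity and precision above 99% under noise", {
  fs <- 256
  tmpl <- make_beat_template(fs = fs)
  hits <- misses <- extras <- 0
  for (s in 1:3) {
    rec <- synthesize_recording(tmpl, duration = 60, mean_hr = 70,
                                rr_jitter_sd = 0.02, noise_sd = 0.1,
                                baseline_wander_amp = 0.05,
                                artifact_rate = 0, seed = 40 + s)
    det <- detect_r_peaks(bandpass_filter(rec$signal))
    tol <- round(0.025 * fs)
    matched <- vapply(rec$true_r_indices,
                      function(r) any(abs(det - r) <= tol), logical(1))
    hits <- hits + sum(matched)
    misses <- misses + sum(!matched)
    extras <- extras + sum(vapply(det, function(d)
      !any(abs(rec$true_r_indices - d) <= tol), logical(1)))
  }
  expect_gte(hits / (hits + misses), 0.99)   # sensitivity
  expect_gte(hits / (hits + extras), 0.99)   # precision
})

test_that("segmentation derives the window from the average heart rate", {
  fs <- 256
  sig <- sampled_signal(rnorm(3000), fs)
  r <- seq(300L, by = 256L, length.out = 10L)
  seg <- segment_beats(sig, r)
  expect_identical(ncol(seg$beats), 256L)
  expect_identical(seg$r_offset, 89L)       # floor(0.35 * 256)
  expect_identical(nrow(seg$beats), 10L)
  # a window underflowing the recording start is dropped
  seg2 <- segment_beats(sig, c(10L, r))
  expect_identical(nrow(seg2$beats), 10L)
  expect_false(10L %in% seg2$r_indices)
  # jittered RRs: window length recomputed from the realized peaks
  set.seed(2)
  rr <- round(0.8 * fs + rnorm(20, 0, 10))
  rj <- cumsum(c(400L, rr))
  sigj <- sampled_signal(rnorm(max(rj) + 400), fs)
  segj <- segment_beats(sigj, rj)
  expect_identical(ncol(segj$beats), as.integer(round(mean(diff(rj)))))
  expect_error(segment_beats(sig, 500L), "2 R peaks")
})

test_that("the x2 amplitude rule rejects by hand-computable thresholds", {
  base <- c(0, 0.5, 1, 0.5, 0)
  mk_set <- function(scales) {
    structure(list(beats = t(vapply(scales, function(s) s * base,
                                    numeric(5))),
                   r_offset = 2L, fs = 256,
                   r_indices = seq_along(scales) * 10L),
              class = "beat_set")
  }
  # homogeneous beats: nothing rejected
  out <- reject_abnormal_beats(mk_set(rep(1, 8)))
  expect_identical(out$n_rejected, 0L)
  # 9 unit beats + one x3: mean-beat max 1.2, threshold 2.4, only the
  # x3 beat (max 3) exceeds it
  out <- reject_abnormal_beats(mk_set(c(rep(1, 9), 3)))
  expect_identical(out$n_rejected, 1L)
  expect_identical(out$rejected, 10L)
  # 9 unit beats + one x1.5: mean max 1.05, threshold 2.1, all kept
  out <- reject_abnormal_beats(mk_set(c(rep(1, 9), 1.5)))
  expect_identical(out$n_rejected, 0L)
  # scale equivariance: scaling the whole recording rejects the same set
  out_scaled <- reject_abnormal_beats(mk_set(7.3 * c(rep(1, 9), 3)))
  expect_identical(out_scaled$rejected, 10L)
  expect_error(reject_abnormal_beats(mk_set(c(1, 100))), NA)
})

test_that("SAECG of a clean periodic recording reproduces the beat", {
  fs <- 256
  tmpl <- make_beat_template(fs = fs)
  rec <- clean_recording(duration = 30, mean_hr = 60)
  sa <- build_saecg(rec$signal)
  expect_s3_class(sa, "saecg")
  expect_identical(sa$n_rejected, 0L)
  # oracle: band-pass the isolated template (zero-padded far from edges)
  pad <- rep(0, 4 * fs)
  iso <- bandpass_filter(sampled_signal(c(pad, tmpl$samples, pad), fs))
  start <- length(pad) + tmpl$r_offset - sa$r_offset + 1L
  oracle <- iso$samples[start:(start + length(sa$samples) - 1L)]
  oracle <- oracle - mean(oracle[1:max(2, round(0.05 * length(oracle)))])
  # the periodic context adds a smooth high-pass sag the isolated-beat
  # oracle does not have (~1.5% of the R amplitude at mid-window)
  expect_lt(sqrt(mean((sa$samples - oracle)^2)), 2e-2)
  expect_identical(which.max(sa$samples), sa$r_offset + 1L)
})

test_that("averaging suppresses noise at the 1/sqrt(n) rate", {
  fs <- 256
  tmpl <- make_beat_template(fs = fs)
  noise_sd <- 0.05
  rec <- synthesize_recording(tmpl, duration = 300, mean_hr = 60,
                              rr_jitter_sd = 0, noise_sd = noise_sd,
                              baseline_wander_amp = 0, artifact_rate = 0,
                              seed = 12)
  sa <- build_saecg(rec$signal)
  expect_gte(sa$n_used, 290L)
  # reference: the same beat layout without measurement noise, so the
  # residual isolates how much noise survives ~300-beat averaging
  clean <- build_saecg(clean_recording(duration = 300, mean_hr = 60)$signal)
  expect_identical(length(clean$samples), length(sa$samples))
  expect_lt(sqrt(mean((sa$samples - clean$samples)^2)),
            noise_sd / sqrt(200))
})

test_that("injected artifact beats are counted by the rejection stage", {
  tmpl <- make_beat_template(fs = 256)
  rec <- synthesize_recording(tmpl, duration = 120, mean_hr = 70,
                              rr_jitter_sd = 0.01, noise_sd = 0.02,
                              baseline_wander_amp = 0.05,
                              artifact_rate = 0.05, seed = 8)
  sa <- build_saecg(rec$signal)
  expect_identical(sa$n_rejected, length(rec$artifact_beat_indices))
})

test_that("SAECG is invariant to prepended flat baseline", {
  rec <- clean_recording(duration = 20, mean_hr = 60)
  sa <- build_saecg(rec$signal)
  padded <- sampled_signal(c(rep(0, 600), rec$signal$samples),
                           rec$signal$fs)
  sa2 <- build_saecg(padded)
  expect_identical(sa2$r_offset, sa$r_offset)
  # filter start-up transients shift the earliest beats slightly; the
  # interior morphology agrees to ~0.1% of the R amplitude
  expect_lt(max(abs(sa2$samples - sa$samples)), 2e-3)
})
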