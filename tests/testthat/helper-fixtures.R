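# Shared fixtures, built in code at test time.

# A small noise-free beat-based subject whose during/after SAECGs are exact
# transfer-function responses of the before SAECG (bypasses recording
# synthesis and preprocessing; used to test estimation stages in isolation).
make_exact_subject <- function(id = 1, tfs = default_ground_truth_tfs(),
                               fs = 256) {
  template <- make_beat_template(fs = fs)
  x <- template$samples
  mk <- function(v) saecg(v, r_offset = template$r_offset, fs = fs,
                          n_used = 10L)
  subject_saecgs(id,
                 before = mk(x),
                 during = mk(simulate_tf(tfs$bda, x)),
                 after  = mk(simulate_tf(tfs$baa, x)))
}

# Brute-force oracle for simulate_tf: truncated impulse response by direct
# difference-equation recursion, then explicit convolution.
sim_by_convolution <- function(tf, x) {
  n <- length(tf$num) - 1L
  m <- length(tf$den) - 1L
  N <- length(x)
  imp <- numeric(N)
  xi <- c(1, rep(0, N - 1))
  for (t in seq_len(N)) {
    acc <- 0
    for (k in seq_len(m)) if (t - k >= 1) acc <- acc - tf$den[k + 1] * imp[t - k]
    for (j in 0:n) {
      d <- m - j
      if (t - d >= 1) acc <- acc + tf$num[n + 1 - j] * xi[t - d]
    }
    imp[t] <- acc
  }
  y <- numeric(N)
  for (t in seq_len(N)) y[t] <- sum(imp[1:t] * x[t:1])
  y
}

# A quiet, fully deterministic recording configuration.
clean_recording <- function(duration = 10, mean_hr = 60, fs = 256,
                            template = make_beat_template(fs = fs), ...) {
  synthesize_recording(template, duration = duration, mean_hr = mean_hr,
                       rr_jitter_sd = 0, noise_sd = 0,
                       baseline_wander_amp = 0, artifact_rate = 0, ...)
}
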