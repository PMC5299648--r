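#' Default PQRST wave parameters
#'
#' Each row describes one Gaussian bump of the beat template: amplitude
#' (mV), center (seconds relative to the R peak) and width (seconds, the
#' Gaussian standard deviation). The defaults give a lead-II-like beat:
#' a small P wave ~200 ms before R, narrow Q and S deflections flanking a
#' dominant 1 mV R wave, and a broad T wave ~220 ms after R.
#'
#' @return A data frame with columns `wave`, `amp_mv`, `center_s`,
#'   `width_s`.
#' @export
default_wave_params <- function() {
  data.frame(
    wave     = c("P", "Q", "R", "S", "T"),
    amp_mv   = c(0.12, -0.10, 1.00, -0.15, 0.30),
    center_s = c(-0.20, -0.04, 0.00, 0.04, 0.22),
    width_s  = c(0.020, 0.008, 0.012, 0.008, 0.035),
    stringsAsFactors = FALSE
  )
}

#' Render a beat template as a sampled waveform
#'
#' The beat is the sum of five Gaussian bumps (P, Q, R, S, T) evaluated on
#' a uniform sample grid of length `round(duration * fs)`. The R peak is
#' anchored at 35% of the window (the same anchor the beat segmentation
#' uses), so the template's sample of maximum value is the R bump's center
#' sample whenever R is the dominant positive wave.
#'
#' @param wave_params data frame as in [default_wave_params()] (five rows:
#'   amplitude mV, center seconds relative to R, width seconds).
#' @param duration beat window length in seconds.
#' @param fs sampling frequency in Hz.
#' @return A `"beat_template"` object: `samples` (mV), `r_offset` (samples
#'   before the R peak), `fs`, `duration`, and the `wave_params` used.
#' @export
make_beat_template <- function(wave_params = default_wave_params(),
                               duration = 0.8, fs = 256) {
  if (duration <= 0 || fs <= 0)
    stop("duration and fs must be positive", call. = FALSE)
  if (any(wave_params$width_s <= 0))
    stop("all wave widths must be positive", call. = FALSE)
  L <- round(duration * fs)
  if (L < 2) stop("duration * fs must be at least 2", call. = FALSE)
  r_offset <- as.integer(floor(0.35 * L))  # samples before the R peak
  t <- (seq_len(L) - 1) / fs             # time of each sample
  t_r <- r_offset / fs                   # R peak lands exactly on a sample
  samples <- rep(0, L)
  for (i in seq_len(nrow(wave_params))) {
    a <- wave_params$amp_mv[i]
    mu <- t_r + wave_params$center_s[i]
    w <- wave_params$width_s[i]
    samples <- samples + a * exp(-(t - mu)^2 / (2 * w^2))
  }
  structure(list(samples = samples, r_offset = r_offset, fs = fs,
                 duration = duration, wave_params = wave_params),
            class = "beat_template")
}

#' Apply a ground-truth transfer function to a beat template
#'
#' Simulates the template through `tf` with zero initial conditions. Used
#' to construct the "during" and "after" period morphologies from the
#' "before" template, so the downstream estimation target is known
#' exactly: the noise-free during-period beat equals
#' `simulate_tf(tf, before_beat)` sample for sample.
#'
#' @param template a `"beat_template"` or a numeric sample vector.
#' @param tf a [dtf()] object (monic denominator, no feedthrough).
#' @return The same type as `template`, with transformed samples.
#' @export
apply_intervention <- function(template, tf) {
  if (inherits(template, "beat_template")) {
    template$samples <- simulate_tf(tf, template$samples)
    template
  } else {
    simulate_tf(tf, as.numeric(template))
  }
}

#' Synthesize one ECG recording from a beat template
#'
#' Lays beats down at RR intervals `60/mean_hr + N(0, rr_jitter_sd)`
#' seconds (overlap-added, so nothing is truncated when beats abut), then
#' adds white measurement noise `N(0, noise_sd)` and a 0.2 Hz sinusoidal
#' baseline wander of amplitude `baseline_wander_amp`. Each beat is,
#' independently with probability `artifact_rate`, scaled by 3 and
#' recorded as an artifact — guaranteed to trip the x2 amplitude
#' rejection rule downstream. Bit-reproducible given `seed`.
#'
#' @param template a `"beat_template"`.
#' @param duration recording length in seconds (long enough for >= 2 beats).
#' @param mean_hr mean heart rate in beats/min.
#' @param rr_jitter_sd beat-to-beat RR jitter SD in seconds.
#' @param noise_sd additive white-noise SD in mV.
#' @param baseline_wander_amp amplitude of the 0.2 Hz wander in mV.
#' @param artifact_rate per-beat probability of a x3 artifact beat.
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @return A `"synthetic_recording"`: `signal` (a [sampled_signal()]),
#'   `true_r_indices` (1-based sample indices), `true_template`,
#'   `artifact_beat_indices` (beat ordinals).
#' @export
synthesize_recording <- function(template, duration = 60, mean_hr = 70,
                                 rr_jitter_sd = 0.02, noise_sd = 0.02,
                                 baseline_wander_amp = 0.05,
                                 artifact_rate = 0, seed = NULL) {
  stopifnot(inherits(template, "beat_template"))
  if (artifact_rate < 0 || artifact_rate >= 1)
    stop("artifact_rate must be in [0, 1)", call. = FALSE)
  fs <- template$fs
  if (duration < 2.5 * 60 / mean_hr)
    stop("duration too short for at least two beats at this heart rate",
         call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  N <- round(duration * fs)
  L <- length(template$samples)
  x <- rep(0, N)
  r_indices <- integer(0)
  artifact_idx <- integer(0)
  beat_start <- 1L
  k <- 0L
  while (beat_start + L - 1L <= N) {
    k <- k + 1L
    scale <- 1
    if (artifact_rate > 0 && stats::runif(1) < artifact_rate) {
      scale <- 3
      artifact_idx <- c(artifact_idx, k)
    }
    idx <- beat_start:(beat_start + L - 1L)
    x[idx] <- x[idx] + scale * template$samples
    r_indices <- c(r_indices, beat_start + template$r_offset)
    rr <- 60 / mean_hr +
      if (rr_jitter_sd > 0) stats::rnorm(1, 0, rr_jitter_sd) else 0
    beat_start <- beat_start + max(2L, round(rr * fs))
  }
  if (noise_sd > 0) x <- x + stats::rnorm(N, 0, noise_sd)
  if (baseline_wander_amp > 0) {
    t <- (seq_len(N) - 1) / fs
    x <- x + baseline_wander_amp * sin(2 * pi * 0.2 * t)
  }
  structure(list(signal = sampled_signal(x, fs),
                 true_r_indices = r_indices,
                 true_template = template,
                 artifact_beat_indices = artifact_idx),
            class = "synthetic_recording")
}

#' Configuration of a synthetic multi-subject trial
#'
#' The defaults mirror the study design the generator emulates: 14
#' subjects, three 5-minute single-lead recordings per subject sampled at
#' 1024 Hz (before / during / after an intervention), with mild RR jitter,
#' measurement noise, baseline wander and occasional artifact beats.
#' `ground_truth_tf_by_pair` carries the period-linking transfer
#' functions: the during-period morphology is the bda-TF response to the
#' before-period beat, the after-period morphology the baa-TF response.
#'
#' @param n_subjects number of subjects (>= 1).
#' @param period_duration seconds per recording period.
#' @param fs sampling frequency, Hz.
#' @param mean_hr mean heart rate, beats/min.
#' @param rr_jitter_sd RR jitter SD, seconds.
#' @param noise_sd white-noise SD, mV.
#' @param baseline_wander_amp 0.2 Hz wander amplitude, mV.
#' @param artifact_rate per-beat artifact probability in `[0, 1)`.
#' @param ground_truth_tf_by_pair named list with elements `bda` and `baa`
#'   ([dtf()] objects) linking before->during and before->after.
#' @param subject_variation_sd relative SD of the per-subject multiplicative
#'   perturbation of the ground-truth TF coefficients.
#' @param seed master seed; per-subject, per-period streams are derived
#'   from it by fixed offsets so adding subjects never reshuffles earlier
#'   ones.
#' @return A `"trial_config"` list.
#' @export
trial_config <- function(n_subjects = 14, period_duration = 300, fs = 1024,
                         mean_hr = 70, rr_jitter_sd = 0.02, noise_sd = 0.02,
                         baseline_wander_amp = 0.05, artifact_rate = 0.02,
                         ground_truth_tf_by_pair = default_ground_truth_tfs(),
                         subject_variation_sd = 0.01, seed = 1L) {
  if (n_subjects < 1) stop("n_subjects must be at least 1", call. = FALSE)
  if (fs <= 0) stop("fs must be positive", call. = FALSE)
  if (artifact_rate < 0 || artifact_rate >= 1)
    stop("artifact_rate must be in [0, 1)", call. = FALSE)
  if (rr_jitter_sd < 0 || noise_sd < 0 || baseline_wander_amp < 0 ||
      subject_variation_sd < 0)
    stop("all standard deviations must be non-negative", call. = FALSE)
  if (!all(c("bda", "baa") %in% names(ground_truth_tf_by_pair)))
    stop("ground_truth_tf_by_pair needs elements 'bda' and 'baa'",
         call. = FALSE)
  structure(list(n_subjects = as.integer(n_subjects),
                 period_duration = period_duration, fs = fs,
                 mean_hr = mean_hr, rr_jitter_sd = rr_jitter_sd,
                 noise_sd = noise_sd,
                 baseline_wander_amp = baseline_wander_amp,
                 artifact_rate = artifact_rate,
                 ground_truth_tf_by_pair = ground_truth_tf_by_pair,
                 subject_variation_sd = subject_variation_sd,
                 seed = as.integer(seed)),
            class = "trial_config")
}

#' Default ground-truth period-linking transfer functions
#'
#' Two fixed, stable third-order systems (numerator order 2, denominator
#' order 3) with unit DC gain: a clear but physiological morphology
#' change for before->during (`bda`) and a different one for
#' before->after (`baa`). Both are chosen so their response to the
#' default beat template peaks at the same sample as the template itself:
#' the intervention reshapes the waveform without moving the R peak,
#' matching how the downstream analysis anchors beats on detected R
#' peaks. Fixed numerically (not drawn at run time) so trials generated
#' with different seeds share the same underlying system.
#'
#' @return Named list of [dtf()] objects (`bda`, `baa`).
#' @export
default_ground_truth_tfs <- function() {
  mk <- function(poles, zeros, dc = 1) {
    den <- poly_from_roots(poles)
    num <- poly_from_roots(zeros)
    num <- num * dc * .polyval(den, 1) / .polyval(num, 1)
    dtf(num, den)
  }
  list(
    bda = mk(poles = c(0.02, 0.04, 0.33), zeros = c(-0.72, 0.82)),
    baa = mk(poles = c(0.38, 0.10, -0.16), zeros = c(-0.65, 0.82))
  )
}

## Multiplicative Gaussian perturbation of TF coefficients; retried until
## the perturbed model simulates the template finitely.
.perturb_tf <- function(tf, rel_sd, template_samples, max_tries = 10L) {
  if (rel_sd == 0) return(tf)
  for (i in seq_len(max_tries)) {
    num <- tf$num * (1 + stats::rnorm(length(tf$num), 0, rel_sd))
    den <- tf$den
    den[-1L] <- den[-1L] * (1 + stats::rnorm(length(den) - 1L, 0, rel_sd))
    cand <- dtf(num, den)
    y <- .sim_dtf(cand$num, cand$den, template_samples)
    if (all(is.finite(y))) return(cand)
  }
  stop("could not draw a finitely simulating perturbed transfer function",
       call. = FALSE)
}

#' Generate a synthetic multi-subject trial
#'
#' For each subject: draws a subject-specific beat template (mild random
#' perturbation of the default PQRST amplitudes and widths), perturbs each
#' pair's ground-truth transfer function by multiplicative coefficient
#' noise of relative SD `subject_variation_sd`, builds the before-period
#' recording from the template and the during/after recordings from the
#' TF-transformed templates, and synthesizes each period with its own
#' derived seed. Deterministic given `config$seed`; the ground truth
#' (templates, per-subject TFs, R indices, artifact ordinals) is returned
#' alongside the signals.
#'
#' @param config a [trial_config()].
#' @return A `"synthetic_trial"`: `config` plus `subjects`, a list with
#'   per-subject `template`, `tf_bda`, `tf_baa`, and `recordings` (named
#'   `before`, `during`, `after`).
#' @export
generate_trial <- function(config = trial_config()) {
  stopifnot(inherits(config, "trial_config"))
  periods <- c("before", "during", "after")
  subjects <- vector("list", config$n_subjects)
  for (s in seq_len(config$n_subjects)) {
    set.seed(config$seed + 1000L * s)
    wp <- default_wave_params()
    wp$amp_mv <- wp$amp_mv * (1 + stats::rnorm(5, 0, 0.10))
    wp$width_s <- wp$width_s * (1 + stats::rnorm(5, 0, 0.05))
    wp$amp_mv[3] <- max(abs(wp$amp_mv))            # R stays dominant
    template <- make_beat_template(wp, duration = 0.8, fs = config$fs)
    tf_bda <- .perturb_tf(config$ground_truth_tf_by_pair$bda,
                          config$subject_variation_sd, template$samples)
    tf_baa <- .perturb_tf(config$ground_truth_tf_by_pair$baa,
                          config$subject_variation_sd, template$samples)
    templates <- list(before = template,
                      during = apply_intervention(template, tf_bda),
                      after  = apply_intervention(template, tf_baa))
    recordings <- list()
    for (p in seq_along(periods)) {
      recordings[[periods[p]]] <- synthesize_recording(
        templates[[periods[p]]],
        duration = config$period_duration, mean_hr = config$mean_hr,
        rr_jitter_sd = config$rr_jitter_sd, noise_sd = config$noise_sd,
        baseline_wander_amp = config$baseline_wander_amp,
        artifact_rate = config$artifact_rate,
        seed = config$seed + 1000L * s + 100L * p)
    }
    subjects[[s]] <- list(subject_id = s, template = template,
                          tf_bda = tf_bda, tf_baa = tf_baa,
                          recordings = recordings)
  }
  structure(list(config = config, subjects = subjects),
            class = "synthetic_trial")
}

#' Write a synthetic trial to disk as CSV + JSON
#'
#' Each recording becomes a two-column CSV (`time_s`, `voltage_mV`) with a
#' JSON sidecar `{fs, subject_id, period, seed}`; the ground truth (R
#' indices, artifact ordinals, per-subject TF coefficients) goes to
#' `ground_truth.json`.
#'
#' @param trial a `"synthetic_trial"`.
#' @param dir output directory (created if needed).
#' @return Invisibly, the [trial_manifest()] describing the written files.
#' @export
write_trial <- function(trial, dir) {
  stopifnot(inherits(trial, "synthetic_trial"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest_rows <- list()
  truth <- list()
  for (sub in trial$subjects) {
    paths <- character(3)
    periods <- c("before", "during", "after")
    for (i in seq_along(periods)) {
      p <- periods[i]
      rec <- sub$recordings[[p]]
      base <- sprintf("subject%02d_%s", sub$subject_id, p)
      csv <- file.path(dir, paste0(base, ".csv"))
      write_signal_csv(rec$signal, csv)
      jsonlite::write_json(
        list(fs = rec$signal$fs, subject_id = sub$subject_id, period = p,
             seed = trial$config$seed),
        file.path(dir, paste0(base, ".json")),
        digits = NA, auto_unbox = TRUE)
      paths[i] <- csv
      truth[[base]] <- list(true_r_indices = rec$true_r_indices,
                            artifact_beat_indices = rec$artifact_beat_indices)
    }
    truth[[sprintf("subject%02d_tf", sub$subject_id)]] <-
      list(bda = list(num = sub$tf_bda$num, den = sub$tf_bda$den),
           baa = list(num = sub$tf_baa$num, den = sub$tf_baa$den))
    manifest_rows[[length(manifest_rows) + 1L]] <-
      list(subject_id = sub$subject_id, path_before = paths[1],
           path_during = paths[2], path_after = paths[3])
  }
  jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                       digits = NA, auto_unbox = TRUE)
  invisible(trial_manifest(dir, manifest_rows, fs = trial$config$fs))
}
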