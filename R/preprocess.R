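#' Uniformly sampled voltage trace
#'
#' @param samples numeric vector of voltages (mV), all finite, length >= 2.
#' @param fs sampling frequency in Hz.
#' @return A `"sampled_signal"` object with elements `samples` and `fs`.
#'   The time of sample `i` is `(i - 1) / fs` seconds.
#' @export
sampled_signal <- function(samples, fs) {
  samples <- as.numeric(samples)
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("fs must be a single positive number", call. = FALSE)
  if (length(samples) < 2L)
    stop("signal must have at least 2 samples", call. = FALSE)
  if (!all(is.finite(samples)))
    stop("all samples must be finite", call. = FALSE)
  structure(list(samples = samples, fs = fs), class = "sampled_signal")
}

#' @export
print.sampled_signal <- function(x, ...) {
  cat(sprintf("Sampled signal: %d samples at %g Hz (%.1f s)\n",
              length(x$samples), x$fs, length(x$samples) / x$fs))
  invisible(x)
}

#' Zero-phase Butterworth band-pass filter
#'
#' A 4th-order Butterworth band-pass applied forward and backward
#' (`signal::filtfilt`), giving zero phase distortion — R-peak positions
#' are not shifted by the filtering. The default 0.5-45 Hz band removes
#' baseline wander and high-frequency noise while keeping the QRS complex
#' intact.
#'
#' @param sig a [sampled_signal()].
#' @param low_hz,high_hz band edges in Hz; `0 < low_hz < high_hz < fs/2`.
#' @return A filtered [sampled_signal()] of the same length.
#' @export
bandpass_filter <- function(sig, low_hz = 0.5, high_hz = 45) {
  stopifnot(inherits(sig, "sampled_signal"))
  nyq <- sig$fs / 2
  if (!(low_hz > 0 && low_hz < high_hz && high_hz < nyq))
    stop("band edges must satisfy 0 < low_hz < high_hz < fs/2",
         call. = FALSE)
  bf <- signal::butter(4, c(low_hz, high_hz) / nyq, type = "pass")
  ## demean (the stopband removes DC in steady state; subtracting it up
  ## front avoids exciting the slow high-pass step transient) and pad by
  ## odd reflection so start-up transients fall outside the signal
  x <- sig$samples - mean(sig$samples)
  N <- length(x)
  P <- min(N - 1L, round(3 * sig$fs / low_hz))
  head_pad <- 2 * x[1L] - rev(x[2L:(P + 1L)])
  tail_pad <- 2 * x[N] - rev(x[(N - P):(N - 1L)])
  filtered <- signal::filtfilt(bf, c(head_pad, x, tail_pad))
  sampled_signal(filtered[(P + 1L):(P + N)], sig$fs)
}

#' Detect R peaks
#'
#' A Pan-Tompkins-style detector: band-limiting to the 5-15 Hz QRS band,
#' derivative, squaring, moving-window
#' integration (150 ms), then a threshold over the integrated signal's
#' local maxima with a 250 ms refractory period. The threshold adapts to
#' the recording: it is a quarter of the median one-second-window maximum
#' of the integration waveform, which tracks the typical QRS energy while
#' staying robust to occasional high-amplitude artifact beats. Each
#' detection is refined to the local maximum of the input signal within
#' +/- 50 ms. Returns an empty vector (not an error) when no peak crosses
#' the threshold.
#'
#' @param sig a [sampled_signal()], at least 2 s long (band-pass filtered
#'   input recommended).
#' @return Integer vector of strictly increasing 1-based R-peak sample
#'   indices.
#' @export
detect_r_peaks <- function(sig) {
  stopifnot(inherits(sig, "sampled_signal"))
  fs <- sig$fs
  x <- sig$samples
  N <- length(x)
  if (N < 2 * fs) stop("signal must be at least 2 s long", call. = FALSE)

  ## QRS energy lives around 5-15 Hz; narrowing to that band before the
  ## derivative keeps wide-band measurement noise out of the energy trace
  qrs_bf <- signal::butter(2, c(5, min(15, 0.45 * fs)) / (fs / 2),
                           type = "pass")
  xq <- signal::filtfilt(qrs_bf, x)
  d <- c(diff(xq), 0)
  sq <- d^2
  w <- max(2L, round(0.15 * fs))
  mwi <- as.numeric(stats::filter(sq, rep(1 / w, w), sides = 2L))
  mwi[!is.finite(mwi)] <- 0

  ## local maxima of the integration waveform
  is_max <- c(FALSE, mwi[2:(N - 1)] >= mwi[1:(N - 2)] &
                     mwi[2:(N - 1)] > mwi[3:N], FALSE)
  cand <- which(is_max & mwi > 0)
  if (length(cand) == 0L) return(integer(0))

  ## threshold adapted to the recording's QRS energy: the median of
  ## one-second window maxima estimates a typical beat's integration
  ## peak and is robust to occasional high-amplitude artifact beats
  win <- round(fs)
  n_win <- ceiling(N / win)
  wmax <- vapply(seq_len(n_win), function(k) {
    lo <- (k - 1L) * win + 1L
    max(mwi[lo:min(N, k * win)])
  }, numeric(1))
  thr <- 0.25 * stats::median(wmax)
  if (thr <= 0) return(integer(0))

  refractory <- round(0.25 * fs)
  above <- cand[mwi[cand] > thr]
  if (length(above) == 0L) return(integer(0))
  ## candidates chained closer than the refractory period belong to one
  ## beat: keep the largest of each chain
  accepted <- integer(0)
  i <- 1L
  while (i <= length(above)) {
    j <- i
    best <- above[i]
    while (j + 1L <= length(above) && above[j + 1L] - above[j] < refractory) {
      j <- j + 1L
      if (mwi[above[j]] > mwi[best]) best <- above[j]
    }
    accepted <- c(accepted, best)
    i <- j + 1L
  }

  ## refine to the local maximum of the signal itself
  half <- round(0.05 * fs)
  refined <- vapply(accepted, function(i) {
    lo <- max(1L, i - half); hi <- min(N, i + half)
    as.integer(lo + which.max(x[lo:hi]) - 1L)
  }, integer(1))
  refined <- sort(unique(refined))
  ## a second refractory pass in case refinement merged neighbours
  keep <- c(TRUE, diff(refined) >= refractory)
  as.integer(refined[keep])
}

#' Segment a recording into beats around its R peaks
#'
#' The beat window length is set by the average heart rate of the
#' recording: `L = round(fs * mean RR)`. Each beat spans the window
#' starting `floor(0.35 * L)` samples before its R peak, so 35% of the
#' window precedes R (capturing the P wave) and 65% follows it (capturing
#' the full T wave). Beats whose window would leave the recording are
#' dropped; all returned beats share the window length and R offset.
#'
#' @param sig a [sampled_signal()].
#' @param r_peaks integer R-peak indices (>= 2 of them).
#' @param pre_r_fraction fraction of the beat window placed before the R
#'   peak (default 0.35).
#' @return A `"beat_set"`: `beats` (matrix, one row per beat), `r_offset`
#'   (samples before R), `fs`, and `r_indices` (the R peak of each kept
#'   beat).
#' @export
segment_beats <- function(sig, r_peaks, pre_r_fraction = 0.35) {
  if (pre_r_fraction <= 0 || pre_r_fraction >= 1)
    stop("pre_r_fraction must lie strictly between 0 and 1", call. = FALSE)
  stopifnot(inherits(sig, "sampled_signal"))
  r_peaks <- as.integer(r_peaks)
  if (length(r_peaks) < 2L)
    stop("need at least 2 R peaks to segment beats", call. = FALSE)
  fs <- sig$fs
  N <- length(sig$samples)
  L <- as.integer(round(mean(diff(r_peaks))))   # fs * mean RR, in samples
  r_offset <- as.integer(floor(pre_r_fraction * L))
  starts <- r_peaks - r_offset
  ok <- starts >= 1L & (starts + L - 1L) <= N
  if (!any(ok))
    stop("no beat window fits inside the recording", call. = FALSE)
  starts <- starts[ok]
  beats <- t(vapply(starts, function(s) sig$samples[s:(s + L - 1L)],
                    numeric(L)))
  structure(list(beats = beats, r_offset = r_offset, fs = fs,
                 r_indices = r_peaks[ok]),
            class = "beat_set")
}

#' Reject abnormal beats by the x2 amplitude rule
#'
#' A single pass: compute the mean beat over all beats; a beat is abnormal
#' when its peak absolute amplitude exceeds twice the peak absolute
#' amplitude of the mean beat. The rule is scale-equivariant: scaling the
#' whole recording rejects the same beats.
#'
#' @param beat_set a `"beat_set"` from [segment_beats()].
#' @param multiplier rejection multiplier (> 1; default 2).
#' @return A list: `kept` (a `"beat_set"` of retained beats),
#'   `n_rejected`, and `rejected` (row indices of removed beats).
#' @export
reject_abnormal_beats <- function(beat_set, multiplier = 2) {
  stopifnot(inherits(beat_set, "beat_set"))
  if (multiplier <= 1)
    stop("rejection multiplier must exceed 1", call. = FALSE)
  beats <- beat_set$beats
  if (nrow(beats) < 1L) stop("need at least one beat", call. = FALSE)
  mean_beat <- colMeans(beats)
  thr <- multiplier * max(abs(mean_beat))
  peak <- apply(abs(beats), 1L, max)
  bad <- which(peak > thr)
  if (length(bad) == nrow(beats))
    stop("all beats rejected as abnormal: degenerate recording",
         call. = FALSE)
  kept <- beat_set
  if (length(bad) > 0L) {
    kept$beats <- beats[-bad, , drop = FALSE]
    kept$r_indices <- beat_set$r_indices[-bad]
  }
  list(kept = kept, n_rejected = length(bad), rejected = bad)
}

## Template-matching refinement of the beat alignment: measurement noise
## can flip the integer sample at which each beat's R maximum is detected,
## and that trigger jitter smears the average around the QRS. Each beat
## window is re-cut at the small integer shift (up to ~10 ms) that
## maximizes its correlation with the current mean beat; two passes are
## enough for the alignment to settle. Windows shifted out of the
## recording are dropped.
.align_beats <- function(sig, beat_set, max_shift = NULL, passes = 2L) {
  fs <- beat_set$fs
  if (is.null(max_shift)) max_shift <- max(1L, round(0.01 * fs))
  L <- ncol(beat_set$beats)
  N <- length(sig$samples)
  starts <- beat_set$r_indices - beat_set$r_offset
  for (pass in seq_len(passes)) {
    template <- colMeans(beat_set$beats)
    new_starts <- integer(0)
    rows <- list()
    for (i in seq_along(starts)) {
      shifts <- (-max_shift):max_shift
      best <- 0L; best_score <- -Inf
      for (s in shifts) {
        a <- starts[i] + s
        if (a < 1L || a + L - 1L > N) next
        score <- sum(sig$samples[a:(a + L - 1L)] * template)
        if (score > best_score) { best_score <- score; best <- s }
      }
      a <- starts[i] + best
      if (a < 1L || a + L - 1L > N) next
      new_starts <- c(new_starts, a)
      rows[[length(rows) + 1L]] <- sig$samples[a:(a + L - 1L)]
    }
    if (length(rows) == 0L)
      stop("beat alignment lost all beats", call. = FALSE)
    beat_set$beats <- do.call(rbind, rows)
    beat_set$r_indices <- new_starts + beat_set$r_offset
    starts <- new_starts
  }
  beat_set
}

#' Build a signal-averaged ECG from one recording
#'
#' The full preprocessing chain: zero-phase 0.5-45 Hz band-pass, R-peak
#' detection, segmentation into average-heart-rate beat windows, a
#' template-matching refinement of the R alignment (correlation with the
#' mean beat, correcting the trigger jitter that measurement noise
#' induces in sample-level peak detection), x2 amplitude artifact
#' rejection, then the element-wise mean of the kept beats.
#'
#' @param sig a raw [sampled_signal()].
#' @param low_hz,high_hz band-pass edges, Hz.
#' @param multiplier artifact-rejection amplitude multiplier.
#' @param pre_r_fraction fraction of the beat window before the R peak.
#' @param baseline_correct subtract the isoelectric level (mean of the
#'   first 5% of the window, which precedes the P wave) from the averaged
#'   beat, so it starts at zero. Band-pass filtering only removes DC over
#'   the whole recording, which leaves the inter-beat baseline of a
#'   periodic signal at a small negative offset; referencing the averaged
#'   beat to its own isoelectric head removes that offset, which matters
#'   for transfer-function fitting with zero initial conditions.
#' @return An `"saecg"` object: `samples` (mV), `r_offset` (samples before
#'   the R peak), `fs`, `n_used` (beats averaged), `n_rejected`.
#' @export
build_saecg <- function(sig, low_hz = 0.5, high_hz = 45, multiplier = 2,
                        pre_r_fraction = 0.35, baseline_correct = TRUE) {
  filtered <- bandpass_filter(sig, low_hz, high_hz)
  r_peaks <- detect_r_peaks(filtered)
  if (length(r_peaks) < 2L)
    stop("fewer than 2 R peaks detected: cannot average beats",
         call. = FALSE)
  segmented <- segment_beats(filtered, r_peaks, pre_r_fraction)
  segmented <- .align_beats(filtered, segmented)
  cleaned <- reject_abnormal_beats(segmented, multiplier)
  kept <- cleaned$kept
  avg <- colMeans(kept$beats)
  if (baseline_correct) {
    head_n <- max(2L, round(0.05 * length(avg)))
    avg <- avg - mean(avg[seq_len(head_n)])
  }
  saecg(avg, r_offset = kept$r_offset, fs = kept$fs,
        n_used = nrow(kept$beats), n_rejected = cleaned$n_rejected)
}

#' Signal-averaged ECG
#'
#' @param samples averaged beat (mV).
#' @param r_offset samples before the R peak within the beat window.
#' @param fs sampling frequency, Hz.
#' @param n_used number of beats averaged.
#' @param n_rejected number of beats removed as abnormal.
#' @return An `"saecg"` object.
#' @export
saecg <- function(samples, r_offset, fs, n_used = 1L, n_rejected = 0L) {
  samples <- as.numeric(samples)
  if (n_used < 1L) stop("n_used must be at least 1", call. = FALSE)
  if (r_offset < 0L || r_offset >= length(samples))
    stop("r_offset must lie within the beat window", call. = FALSE)
  structure(list(samples = samples, r_offset = as.integer(r_offset),
                 fs = fs, n_used = as.integer(n_used),
                 n_rejected = as.integer(n_rejected)),
            class = "saecg")
}

#' @export
print.saecg <- function(x, ...) {
  cat(sprintf(
    "SAECG: %d samples at %g Hz, R at offset %d (%d beats used, %d rejected)\n",
    length(x$samples), x$fs, x$r_offset, x$n_used, x$n_rejected))
  invisible(x)
}
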