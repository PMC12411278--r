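## Companion extracellular procedures: LFP conditioning, sharp-wave-ripple
## detection, waveform-based unit classification, odor responses.

#' Condition a raw LFP trace
#'
#' Anti-aliased downsampling to 2.5 kHz followed by zero-phase
#' second-order Butterworth bandstops removing 60 Hz line noise and its
#' 120/180 Hz harmonics.
#'
#' @param lfp Numeric vector.
#' @param fs_in Input sampling rate (Hz, >= 2500; must be an integer
#'   multiple of 2500).
#' @param notch_halfwidth Half-width of each bandstop (Hz).
#' @return List with \code{trace} and \code{fs} (2500).
#' @export
preprocess_lfp <- function(lfp, fs_in, notch_halfwidth = 2) {
  fs_out <- 2500
  if (fs_in < fs_out) stop("sampling rate below 2.5 kHz")
  x <- lfp
  if (fs_in > fs_out) {
    dec <- fs_in / fs_out
    if (dec != round(dec)) stop("fs_in must be an integer multiple of 2500")
    aa <- butter_filter(4, 0.4 * fs_out, fs_in, "low")
    x <- filtfilt2(aa, x)[seq(1, length(x), by = dec)]
  }
  for (f0 in c(60, 120, 180)) {
    bs <- butter_filter(2, c(f0 - notch_halfwidth, f0 + notch_halfwidth),
                        fs_out, "stop")
    x <- filtfilt2(bs, x)
  }
  list(trace = x, fs = fs_out)
}

#' Detect sharp-wave ripples
#'
#' The conditioned LFP is bandpassed to 120-200 Hz; its binned RMS
#' amplitude is thresholded at 10 s.d. above the mean, and event
#' boundaries are extended to the 2 s.d. crossings.  Events separated by
#' less than 50 ms are concatenated and events shorter than 40 ms are
#' discarded.
#'
#' @param lfp List with \code{trace} and \code{fs} (from
#'   [preprocess_lfp()]) or a numeric vector at 2.5 kHz.
#' @param fs Sampling rate when \code{lfp} is a bare vector.
#' @param rms_bin_ms RMS bin width (ms).
#' @param enter_sd,exit_sd Detection and boundary thresholds (s.d. of the
#'   binned RMS).
#' @return A data.frame of \code{ripple_events}: \code{start_ms},
#'   \code{end_ms}, \code{peak_sd}.
#' @export
detect_ripples <- function(lfp, fs = 2500, rms_bin_ms = 10,
                           enter_sd = 10, exit_sd = 2) {
  if (is.list(lfp)) { fs <- lfp$fs; lfp <- lfp$trace }
  if (stats::sd(lfp) == 0) stop("zero-variance signal")
  bp <- butter_filter(3, c(120, 200), fs, "pass")
  band <- filtfilt2(bp, lfp)
  bl <- round(rms_bin_ms / 1000 * fs)
  nb <- floor(length(band) / bl)
  rms <- sqrt(colMeans(matrix(band[seq_len(nb * bl)]^2, nrow = bl)))
  z <- (rms - mean(rms)) / stats::sd(rms)
  above_exit <- z > exit_sd
  runs <- logical_runs(above_exit)
  if (nrow(runs)) {
    keep <- apply(runs, 1, function(r) any(z[(r[1] + 1):r[2]] > enter_sd))
    runs <- runs[keep, , drop = FALSE]
  }
  runs_ms <- runs * rms_bin_ms # bins -> ms
  runs_ms <- merge_intervals(runs_ms, gap = 50, min_len = 40)
  if (!nrow(runs_ms))
    return(data.frame(start_ms = numeric(0), end_ms = numeric(0),
                      peak_sd = numeric(0)))
  peak <- apply(runs_ms, 1, function(r)
    max(z[(r[1] / rms_bin_ms + 1):(r[2] / rms_bin_ms)]))
  ## refine boundaries to sub-bin precision by linear interpolation of the
  ## binned RMS across the exit-threshold crossing (bin b covers
  ## [(b-1), b) x rms_bin_ms and is represented at its centre)
  refine <- function(r) {
    b1 <- r[1] / rms_bin_ms + 1; b2 <- r[2] / rms_bin_ms
    s <- r[1]; e <- r[2]
    if (b1 > 1 && z[b1] > z[b1 - 1]) {
      fr <- (exit_sd - z[b1 - 1]) / (z[b1] - z[b1 - 1])
      s <- (b1 - 1.5 + min(max(fr, 0), 1)) * rms_bin_ms
    }
    if (b2 < length(z) && z[b2] > z[b2 + 1]) {
      fr <- (z[b2] - exit_sd) / (z[b2] - z[b2 + 1])
      e <- (b2 - 0.5 + min(max(fr, 0), 1)) * rms_bin_ms
    }
    c(s, e)
  }
  ref <- t(apply(runs_ms, 1, refine))
  data.frame(start_ms = ref[, 1], end_ms = ref[, 2], peak_sd = peak)
}

#' Classify units into broad and narrow spiking
#'
#' Units below the 0.5 Hz mean-rate floor are dropped; the peak-trough
#' time distance, peak-trough amplitude ratio and mean rate are z-scored,
#' projected onto principal components, and split by k-means (k = 2,
#' squared Euclidean distance, 100 restarts).  The cluster with shorter
#' peak-trough distances and higher rates is labelled
#' \code{"narrow"} (putative interneurons), the other \code{"broad"}
#' (putative pyramidal cells).
#'
#' @param features data.frame with \code{peak_trough_ms},
#'   \code{peak_trough_ratio}, \code{mean_rate_hz}.
#' @param seed RNG seed for the k-means restarts.
#' @param rate_floor_hz Minimum mean rate (0.5).
#' @return data.frame \code{features} (retained units) with an added
#'   \code{class} column.
#' @export
classify_units <- function(features, seed = 1L, rate_floor_hz = 0.5) {
  stopifnot(all(c("peak_trough_ms", "peak_trough_ratio", "mean_rate_hz") %in%
                  names(features)))
  keep <- features$mean_rate_hz >= rate_floor_hz
  features <- features[keep, , drop = FALSE]
  if (nrow(features) < 2) stop("need >= 2 units above the rate floor")
  X <- scale(as.matrix(features[, c("peak_trough_ms", "peak_trough_ratio",
                                    "mean_rate_hz")]))
  if (any(!is.finite(X))) stop("degenerate clustering: constant feature(s)")
  scores <- stats::prcomp(X, center = FALSE, scale. = FALSE)$x
  set.seed(seed)
  km <- stats::kmeans(scores, centers = 2, nstart = 100, iter.max = 50)
  ## narrow cluster: shorter peak-trough, higher rate (on the z scale)
  sep <- vapply(1:2, function(k)
    mean(X[km$cluster == k, 1]) - mean(X[km$cluster == k, 3]), 0)
  narrow_k <- which.min(sep)
  features$class <- ifelse(km$cluster == narrow_k, "narrow", "broad")
  features
}

#' Odor response of an extracellular unit
#'
#' Firing rates in 10-ms bins are smoothed with a 50-ms Gaussian-weighted
#' average, averaged across trials, normalised by the baseline mean rate
#' (the 1 s before the first odor), and averaged across the first odor
#' cue.  Normalising the trial average rather than each trial keeps the
#' estimate defined for sparsely firing units whose single-trial baseline
#' counts are often zero.  Units are
#' classified odor-excited iff the mean normalised response strictly
#' exceeds 1 (the no-change level), and early/late by the response peak
#' latency (200 ms threshold).
#'
#' @param spikes_by_trial List of per-trial spike-time vectors (ms).
#' @param trial_len_ms,odor_onset,odor_offset Trial layout (ms).
#' @param bin_ms,smooth_window_ms Rate binning and Gaussian window.
#' @return An \code{odor_response} list: \code{response} (baseline-
#'   normalised mean over the odor), \code{sign_class}, \code{peak_latency_ms},
#'   \code{latency_class}, \code{n_trials_used}; \code{NULL} with a
#'   warning when every trial has a zero baseline.
#' @export
odor_response <- function(spikes_by_trial, trial_len_ms = 11000,
                          odor_onset = 1000, odor_offset = 2000,
                          bin_ms = 10, smooth_window_ms = 50) {
  nb <- floor(trial_len_ms / bin_ms)
  base_bins <- ((odor_onset - 1000) / bin_ms + 1):(odor_onset / bin_ms)
  odor_bins <- (odor_onset / bin_ms + 1):(odor_offset / bin_ms)
  w <- max(3, round(smooth_window_ms / bin_ms))
  rates <- lapply(spikes_by_trial, function(st) {
    cnt <- tabulate(floor(st[st < nb * bin_ms] / bin_ms) + 1, nbins = nb)
    gaussian_smooth(cnt / (bin_ms / 1000), w)
  })
  mean_rate <- Reduce(`+`, rates) / length(rates)
  base <- mean(mean_rate[base_bins])
  if (base == 0) {
    warning("unit excluded: zero baseline rate")
    return(NULL)
  }
  avg <- mean_rate / base
  resp <- mean(avg[odor_bins])
  peak_bin <- odor_bins[which.max(avg[odor_bins])]
  peak_lat <- (peak_bin - 1) * bin_ms - odor_onset
  structure(list(response = resp,
                 sign_class = if (resp > 1) "odor-excited" else "odor-inhibited",
                 peak_latency_ms = peak_lat,
                 latency_class = if (peak_lat < 200) "early" else "late",
                 n_trials_used = length(rates)),
            class = "odor_response")
}
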