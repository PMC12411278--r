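## Odor-onset hyperpolarization: detection, per-session summaries, and
## across-trial theta phase-reset quantification.

#' Detect an odor-onset hyperpolarization in one trial
#'
#' The raw (non-de-spiked) dF/F is smoothed (first-order Savitzky-Golay)
#' and z-scored to the mean and s.d. of the 0.5 s preceding the first odor
#' in that trial, giving S.  Segments with S < -1 intersecting the first
#' odor delivery are found; sub-segments closer than 20 ms are merged and
#' the earliest merged segment is the candidate T_h.  T_h is a significant
#' hyperpolarization iff it lasts > 50 ms and contains S < -3 samples
#' totalling > 10 ms.
#'
#' @param trial A \code{trial_record} (needs >= 500 ms pre-odor baseline).
#' @param sg_window Smoothing window (ms).
#' @param invert_dff Set TRUE for positively tuned indicators whose
#'   fluorescence falls with depolarization.
#' @return A \code{hyperpol_event} (onset_ms, trough_ms, duration_ms
#'   relative to odor onset; amplitude_sd; significant) or \code{NULL} if
#'   no candidate segment exists.
#' @export
detect_hyperpolarization <- function(trial, sg_window = 21,
                                     invert_dff = FALSE) {
  on <- trial$odor1_onset
  if (on < 500) stop("need >= 500 ms pre-odor baseline")
  x <- trial$dff
  if (invert_dff) x <- -x
  sm <- moving_average(x, sg_window)
  base <- sm[ms_index(on - 500):(ms_index(on) - 1)]
  sdb <- stats::sd(base)
  if (sdb == 0) stop("degenerate trace: zero baseline s.d.")
  S <- (sm - mean(base)) / sdb
  ## sub-threshold runs during the first odor (allowing a start within the
  ## 20-ms merge tolerance before onset), merged across < 20 ms gaps; the
  ## candidate is the earliest merged run
  lo <- on - 20
  region <- ms_index(lo):(ms_index(trial$odor1_offset) - 1)
  runs <- logical_runs(S[region] < -1)
  if (nrow(runs) == 0) return(NULL)
  runs <- runs + lo
  runs <- merge_intervals(runs, gap = 20)
  hit <- runs[, 2] > on
  if (!any(hit)) return(NULL)
  th <- runs[which(hit)[1], ]
  idx <- (th[1] + 1):th[2]
  deep <- sum(S[idx] < -3)
  significant <- (th[2] - th[1]) > 50 && deep > 10
  imin <- idx[which.min(S[idx])]
  structure(list(onset_ms = th[1] - on,
                 trough_ms = imin - 1 - on,
                 duration_ms = th[2] - th[1],
                 amplitude_sd = min(S[idx]),
                 significant = significant,
                 S = S),
            class = "hyperpol_event")
}

#' Summarize hyperpolarization events over a session
#'
#' @param session A \code{cell_session}.
#' @param ... Passed to [detect_hyperpolarization()].
#' @return A \code{hyperpol_summary}: \code{occurrence_rate} (fraction of
#'   trials with a significant event), moments of onset/trough/duration/
#'   amplitude over significant events, \code{window_amplitude} (per-trial
#'   minimum S in the first 200 ms after odor onset, for low-n
#'   comparisons), \code{post_depolarization} (max S during the odor after
#'   the event), and the per-trial \code{events} list.
#' @export
summarize_hyperpol <- function(session, ...) {
  stopifnot(length(session$trials) >= 1)
  events <- lapply(session$trials, detect_hyperpolarization, ...)
  sig <- vapply(events, function(e) !is.null(e) && e$significant, FALSE)
  win_amp <- post_dep <- rep(NA_real_, length(events))
  for (i in seq_along(events)) {
    tr <- session$trials[[i]]
    e <- events[[i]]
    S <- if (!is.null(e)) e$S else {
      sm <- moving_average(tr$dff, 21)
      base <- sm[ms_index(tr$odor1_onset - 500):(ms_index(tr$odor1_onset) - 1)]
      if (stats::sd(base) == 0) next
      (sm - mean(base)) / stats::sd(base)
    }
    win_amp[i] <- min(S[ms_index(tr$odor1_onset):
                          (ms_index(tr$odor1_onset + 200) - 1)])
    if (!is.null(e) && e$significant) {
      from <- ms_index(tr$odor1_onset + e$onset_ms + e$duration_ms)
      to <- ms_index(tr$odor1_offset) - 1
      if (from < to) post_dep[i] <- max(S[from:to])
    }
  }
  stat <- function(f, field) if (any(sig))
    f(vapply(events[sig], `[[`, 0, field)) else NA_real_
  structure(list(occurrence_rate = mean(sig),
                 n_significant = sum(sig),
                 mean_amplitude = stat(mean, "amplitude_sd"),
                 mean_onset = stat(mean, "onset_ms"),
                 mean_trough = stat(mean, "trough_ms"),
                 mean_duration = stat(mean, "duration_ms"),
                 window_amplitude = win_amp,
                 post_depolarization = post_dep,
                 events = events),
            class = "hyperpol_summary")
}

#' Across-trial circular variance of theta phase
#'
#' At every sample, the circular variance (1 - mean resultant length) of
#' the instantaneous theta phase across trials.  A phase reset appears as
#' a transient variance dip after odor onset.
#'
#' @param session A \code{cell_session} (>= 3 trials).
#' @param despike_first If TRUE, spike waveforms are removed before theta
#'   extraction.
#' @return List: \code{variance} per ms, \code{time_ms} relative to odor
#'   onset, plus \code{pre_mean} (mean variance over the 500 ms before
#'   odor onset) and \code{post_mean} (mean over [0, 150) ms after).
#' @export
phase_reset_variance <- function(session, despike_first = TRUE) {
  ntr <- length(session$trials)
  if (ntr < 3) stop("need >= 3 trials")
  n <- length(session$trials[[1]]$dff)
  ph <- matrix(0, nrow = ntr, ncol = n)
  for (i in seq_len(ntr)) {
    tr <- session$trials[[i]]
    x <- if (despike_first) despike(tr$dff, tr$spike_times) else tr$dff
    ph[i, ] <- theta_extract(x)$phase
  }
  R <- Mod(colMeans(exp(1i * ph)))
  v <- 1 - R
  on <- session$trials[[1]]$odor1_onset
  list(variance = v,
       time_ms = seq_len(n) - 1 - on,
       pre_mean = mean(v[ms_index(on - 500):(ms_index(on) - 1)]),
       post_mean = mean(v[ms_index(on):(ms_index(on + 150) - 1)]))
}
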