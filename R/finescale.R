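## Fine-timescale (5-ms) analysis of odor-onset and rebound spiking.

#' Fine-timescale rate matrix
#'
#' Per-trial 5-ms binned firing rates around the first odor, smoothed with
#' a centred three-point moving average.
#'
#' @param session A \code{cell_session}.
#' @param axis 5-ms axis; default spans 500 ms pre-odor to 1.5 s
#'   post-onset.
#' @return A \code{rate_matrix} (Hz).
#' @export
finescale_rates <- function(session, axis = odor_delay_axis(500, 2500, 5)) {
  bin_rates(session, axis, smooth_points = 3)
}

#' Onset and rebound spiking metrics
#'
#' Mean rates over the 30-50 ms (onset) and 200-500 ms (rebound) windows
#' after odor onset, and their relative change versus the 0.5-s pre-odor
#' baseline.  Windows are half-open with membership by bin start time;
#' means are computed from raw spike counts, so they recompute exactly
#' from the spike trains.
#'
#' @param session A \code{cell_session}.
#' @return A \code{finescale_metrics} list: \code{onset_rate},
#'   \code{rebound_rate}, \code{baseline_rate} (Hz) and
#'   \code{onset_increase}, \code{rebound_increase} (relative change;
#'   \code{NA} with a zero baseline, flagged by warning).
#' @export
onset_rebound_metrics <- function(session) {
  stopifnot(length(session$trials) >= 1)
  win_rate <- function(a, b) { # ms relative to odor onset, half-open
    tot <- 0
    for (tr in session$trials) {
      lo <- tr$odor1_onset + a; hi <- tr$odor1_onset + b
      tot <- tot + sum(tr$spike_times >= lo & tr$spike_times < hi)
    }
    tot / ((b - a) / 1000) / length(session$trials)
  }
  onset <- win_rate(30, 50)
  rebound <- win_rate(200, 500)
  baseline <- win_rate(-500, 0)
  if (baseline == 0) warning("zero baseline rate: increases undefined")
  rel <- function(x) if (baseline > 0) (x - baseline) / baseline else NA_real_
  structure(list(onset_rate = onset, rebound_rate = rebound,
                 baseline_rate = baseline,
                 onset_increase = rel(onset),
                 rebound_increase = rel(rebound)),
            class = "finescale_metrics")
}
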