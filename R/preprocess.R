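## Per-trial signal conditioning: motion segmentation, firing-rate
## matrices, burst index, speed/odor scores, de-spiking, spectral
## estimates, theta phase/amplitude and spike-phase statistics.

#' Segment locomotion into motion and immobility
#'
#' The raw 1 kHz locomotion signal is mode-subtracted, rectified and
#' smoothed (first-order Savitzky-Golay, 21 ms).  Motion is entered when
#' the smoothed signal exceeds 0.02 a.u. and left when it drops below
#' 0.01 (hysteresis).  Motion segments closer than 20 ms are concatenated
#' and segments shorter than 10 ms discarded.
#'
#' @param locomotion Numeric vector (1 sample per ms).
#' @param enter,exit Hysteresis thresholds (a.u.).
#' @param sg_window Smoothing window (ms).
#' @return A \code{motion_segments} object: \code{segments} and
#'   \code{immobility}, both two-column matrices of half-open
#'   \code{[start, end)} times in ms.
#' @export
segment_motion <- function(locomotion, enter = 0.02, exit = 0.01,
                           sg_window = 21) {
  if (!length(locomotion)) stop("empty locomotion signal")
  x <- locomotion - mode_value(locomotion)
  x <- moving_average(abs(x), sg_window)
  above_exit <- x >= exit
  runs <- logical_runs(above_exit)
  keep <- apply(runs, 1, function(r) any(x[(r[1] + 1):r[2]] > enter))
  segs <- runs[keep, , drop = FALSE]
  segs <- merge_intervals(segs, gap = 20, min_len = 10)
  imm <- complement_intervals(segs, length(locomotion))
  structure(list(segments = segs, immobility = imm), class = "motion_segments")
}

mode_value <- function(x) {
  r <- round(x, 4)
  ux <- unique(r)
  ux[which.max(tabulate(match(r, ux)))]
}

complement_intervals <- function(segs, n) {
  if (nrow(segs) == 0) return(matrix(c(0, n), ncol = 2))
  starts <- c(0, segs[, 2])
  ends <- c(segs[, 1], n)
  keep <- ends > starts
  cbind(starts[keep], ends[keep])
}

#' Bin spike times into a trials x bins rate matrix
#'
#' @param session A \code{cell_session}.
#' @param axis An [odor_delay_axis()] (any interval/bin width within the
#'   trial).
#' @param smooth_points Span of the centred moving average applied per
#'   trial (0 or 1 = none; the pipeline default elsewhere is 5 points at
#'   100-ms bins and 3 points at 5-ms bins).
#' @param zscore If TRUE, z-score each trial's rate vector over the axis.
#' @return A \code{rate_matrix}: \code{rates} (Hz), \code{axis},
#'   \code{smoothing} descriptor, \code{odor1} per-trial odor identity.
#' @export
bin_rates <- function(session, axis = odor_delay_axis(), smooth_points = 0,
                      zscore = FALSE) {
  stopifnot(inherits(axis, "odor_delay_axis"))
  ntr <- length(session$trials)
  rates <- matrix(0, nrow = ntr, ncol = axis$n_bins)
  for (i in seq_len(ntr)) {
    st <- session$trials[[i]]$spike_times
    if (axis$end_ms > length(session$trials[[i]]$dff))
      stop("axis extends past trial bounds")
    st <- st[st >= axis$start_ms & st < axis$end_ms]
    cnt <- tabulate(floor((st - axis$start_ms) / axis$bin_ms) + 1,
                    nbins = axis$n_bins)
    r <- cnt / (axis$bin_ms / 1000)
    if (smooth_points > 1) r <- moving_average(r, smooth_points)
    if (zscore) {
      s <- stats::sd(r)
      r <- if (s > 0) (r - mean(r)) / s else r - mean(r)
    }
    rates[i, ] <- r
  }
  structure(list(rates = rates, axis = axis,
                 smoothing = sprintf("ma%d%s", smooth_points,
                                     if (zscore) "+z" else ""),
                 odor1 = vapply(session$trials, `[[`, "", "odor1_id")),
            class = "rate_matrix")
}

#' Burst index
#'
#' Fraction of a cell's spikes participating in inter-spike intervals
#' shorter than 10 ms (counting intervals over total spikes).
#'
#' @param spike_times Spike times (ms); pooled or per trial.
#' @param isi_ms Burst threshold (ms).
#' @return Fraction in [0, 1); \code{NA} with fewer than 2 spikes.
#' @export
burst_index <- function(spike_times, isi_ms = 10) {
  n <- length(spike_times)
  if (n < 2) return(NA_real_)
  sum(diff(spike_times) < isi_ms) / n
}

score_against <- function(session, target_fun, smooth_points = 5,
                          bin_ms = 100, n_surrogates = 0) {
  ntr <- length(session$trials)
  if (ntr < 2) stop("need >= 2 trials")
  cors <- rep(NA_real_, ntr)
  null_cors <- if (n_surrogates > 0) matrix(NA_real_, ntr, n_surrogates) else NULL
  dropped <- 0
  for (i in seq_len(ntr)) {
    tr <- session$trials[[i]]
    nb <- floor(length(tr$dff) / bin_ms)
    ax <- odor_delay_axis(0, nb * bin_ms, bin_ms)
    st <- tr$spike_times[tr$spike_times < ax$end_ms]
    cnt <- tabulate(floor(st / bin_ms) + 1, nbins = nb)
    r <- moving_average(cnt / (bin_ms / 1000), smooth_points)
    tgt <- target_fun(tr, nb, bin_ms)
    if (stats::sd(r) == 0 || stats::sd(tgt) == 0) {
      dropped <- dropped + 1
      next
    }
    cors[i] <- stats::cor(r, tgt)
    if (n_surrogates > 0) {
      shifts <- sample.int(nb - 1, n_surrogates, replace = TRUE)
      for (k in seq_len(n_surrogates)) {
        rs <- c(r[(shifts[k] + 1):nb], r[1:shifts[k]])
        null_cors[i, k] <- stats::cor(rs, tgt)
      }
    }
  }
  if (dropped > 0)
    warning(dropped, " trial(s) with constant rate or target excluded")
  if (all(is.na(cors))) return(list(score = NA_real_, chance = c(NA, NA)))
  res <- list(score = mean(cors, na.rm = TRUE), per_trial = cors)
  if (n_surrogates > 0) {
    null_means <- colMeans(null_cors, na.rm = TRUE)
    res$chance <- stats::quantile(null_means, c(0.025, 0.975), names = FALSE)
  }
  res
}

#' Speed and odor scores
#'
#' Trial-averaged Pearson correlation between the cell's smoothed 100-ms
#' firing rates and (speed score) the bin-averaged locomotion signal, or
#' (odor score) a boxcar that is 1 during odor delivery bins and 0
#' elsewhere.  An optional chance band is estimated from per-trial
#' circular-shift surrogates (2.5/97.5 percentiles of surrogate means).
#'
#' @param session A \code{cell_session}.
#' @param n_surrogates Number of circular-shift surrogates (0 = no band).
#' @return List with \code{score}, \code{per_trial} and (if requested)
#'   \code{chance}.
#' @export
speed_score <- function(session, n_surrogates = 0) {
  score_against(session, function(tr, nb, bin_ms) {
    colMeans(matrix(tr$locomotion[seq_len(nb * bin_ms)], nrow = bin_ms))
  }, n_surrogates = n_surrogates)
}

#' @rdname speed_score
#' @export
odor_score <- function(session, n_surrogates = 0) {
  score_against(session, function(tr, nb, bin_ms) {
    edges <- (seq_len(nb) - 1) * bin_ms
    as.numeric((edges >= tr$odor1_onset & edges < tr$odor1_offset) |
                 (edges >= tr$odor2_onset & edges < tr$odor2_offset))
  }, n_surrogates = n_surrogates)
}

#' Remove spike waveforms from a dF/F trace
#'
#' A 25-ms window around each spike (5 ms before to 19 ms after the peak)
#' is replaced by a boundary-matched linear segment plus noise whose
#' spectrum matches the local subthreshold residual (AR(2) fit on the
#' flanking 50 ms).  Overlapping windows are merged and replaced once.
#' The replacement noise stream is seeded deterministically, so the
#' operation is idempotent for a fixed spike list; samples outside the
#' windows are untouched.
#'
#' @param dff Trace (1 sample per ms).
#' @param spike_times Spike peak times (ms).
#' @param pre_ms,post_ms Window extent around each peak.
#' @return De-spiked trace, same length.
#' @export
despike <- function(dff, spike_times, pre_ms = 5, post_ms = 19) {
  if (!length(spike_times)) return(dff)
  n <- length(dff)
  if (any(spike_times < 0 | spike_times >= n)) stop("spike times outside trace")
  win <- cbind(round(spike_times) - pre_ms, round(spike_times) + post_ms + 1)
  win <- merge_intervals(win, gap = 1)
  win[, 1] <- pmax(win[, 1], 0)
  win[, 2] <- pmin(win[, 2], n)
  seed_state <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(seed_state))
    assign(".Random.seed", seed_state, envir = globalenv()))
  set.seed(length(spike_times) * 131 + round(spike_times[1]))
  ## pass 1: replace every window by its boundary-matched line, so the
  ## flanking samples used by the noise model are spike-free
  lines <- despike_line <- dff
  for (i in seq_len(nrow(win))) {
    a <- win[i, 1]; b <- win[i, 2] # 0-based half-open [a, b)
    left <- if (a > 0) lines[a] else lines[min(b + 1, n)]
    right <- if (b < n) lines[b + 1] else left
    lines[(a + 1):b] <- seq(left, right, length.out = b - a + 2)[2:(b - a + 1)]
  }
  out <- lines
  ## pass 2: add AR(2) noise matched to the detrended flanking residual
  detrend <- function(v)
    stats::lm.fit(cbind(1, seq_along(v)), v)$residuals
  for (i in seq_len(nrow(win))) {
    a <- win[i, 1]; b <- win[i, 2]
    len <- b - a
    fl_l <- if (a >= 20) lines[max(1, a - 50):a] else numeric(0)
    fl_r <- if (n - b >= 20) lines[(b + 1):min(n, b + 50)] else numeric(0)
    res <- c(if (length(fl_l)) detrend(fl_l) else numeric(0),
             if (length(fl_r)) detrend(fl_r) else numeric(0))
    if (length(res) < 20 || stats::sd(res) == 0) next
    fit <- tryCatch(stats::ar.yw(res, order.max = 2, aic = FALSE),
                    error = function(e) NULL)
    noise <- if (!is.null(fit) && length(fit$ar)) {
      innov <- stats::rnorm(len + 20, 0, sqrt(max(fit$var.pred, 0)))
      sim <- as.numeric(stats::filter(innov, fit$ar, method = "recursive"))
      sim[21:(20 + len)]
    } else stats::rnorm(len, 0, stats::sd(res))
    out[(a + 1):b] <- out[(a + 1):b] + noise
  }
  out
}

#' Power spectrum of concatenated trace segments
#'
#' Modified periodogram with a Kaiser taper and a fixed frequency
#' resolution via zero padding.
#'
#' @param segments Numeric vector, or list of vectors that are
#'   concatenated (e.g. motion or immobility segments across trials).
#' @param fs Sampling rate (Hz).
#' @param resolution Frequency resolution (Hz).
#' @param beta Kaiser shape parameter.
#' @param min_len Segments shorter than this (samples) are excluded with a
#'   warning.
#' @return List with \code{freq} and one-sided \code{power}.
#' @export
power_spectrum <- function(segments, fs = 1000, resolution = 0.5, beta = 8,
                           min_len = 256) {
  if (is.list(segments)) {
    short <- vapply(segments, length, 0) < min_len
    if (any(short)) {
      warning(sum(short), " segment(s) shorter than ", min_len, " samples excluded")
      segments <- segments[!short]
    }
    if (!length(segments)) stop("no segments long enough")
    x <- unlist(segments)
  } else x <- segments
  n <- length(x)
  w <- kaiser_window(n, beta)
  xw <- (x - mean(x)) * w
  nfft <- max(n, ceiling(fs / resolution))
  X <- stats::fft(c(xw, rep(0, nfft - n)))
  pw <- Mod(X)^2 / (fs * sum(w^2))
  half <- floor(nfft / 2) + 1
  p1 <- pw[1:half]
  p1[2:(half - 1)] <- 2 * p1[2:(half - 1)]
  list(freq = (0:(half - 1)) * fs / nfft, power = p1)
}

#' Flattened spectrogram
#'
#' Short-time Fourier transform over 512-ms windows with 256-ms overlap,
#' 2-D Gaussian smoothing, and removal of a power-law (1/f^a) trend fitted
#' to the time-averaged spectrum in log-log space.  (2-D interpolation to
#' a finer grid, a display-only refinement in the original pipeline, is
#' not applied.)
#'
#' @param trace Numeric vector (1 kHz).
#' @param fs Sampling rate.
#' @param window,overlap STFT window and overlap (samples).
#' @param sigma 2-D Gaussian smoothing sd (pixels).
#' @param fit_range Frequency band (Hz) for the power-law fit.
#' @param f_max Highest frequency kept (Hz).
#' @return List with \code{freq}, \code{time_s} and \code{power} (freq x
#'   time, trend removed).
#' @export
spectrogram_flattened <- function(trace, fs = 1000, window = 512,
                                  overlap = 256, sigma = 5,
                                  fit_range = c(1, 100), f_max = 100) {
  if (length(trace) < window) stop("trace shorter than one window")
  step <- window - overlap
  starts <- seq(1, length(trace) - window + 1, by = step)
  w <- kaiser_window(window, 6)
  half <- window / 2 + 1
  S <- matrix(0, nrow = half, ncol = length(starts))
  for (j in seq_along(starts)) {
    seg <- trace[starts[j]:(starts[j] + window - 1)]
    X <- stats::fft((seg - mean(seg)) * w)
    S[, j] <- Mod(X[1:half])^2 / (fs * sum(w^2))
  }
  freq <- (0:(half - 1)) * fs / window
  keep <- freq <= f_max
  S <- S[keep, , drop = FALSE]
  freq <- freq[keep]
  S <- gauss_blur2d(S, sigma)
  ## remove power-law trend of the mean spectrum
  ms <- rowMeans(S)
  sel <- freq >= fit_range[1] & freq <= fit_range[2] & ms > 0
  fit <- stats::lm(log(ms[sel]) ~ log(freq[sel]))
  trend <- rep(mean(ms), length(freq))
  pos <- freq > 0
  trend[pos] <- exp(stats::coef(fit)[1] + stats::coef(fit)[2] * log(freq[pos]))
  list(freq = freq, time_s = (starts - 1 + window / 2) / fs,
       power = S / trend)
}

gauss_blur2d <- function(m, sigma) {
  if (sigma <= 0) return(m)
  half <- ceiling(3 * sigma)
  k <- exp(-((-half):half)^2 / (2 * sigma^2))
  k <- k / sum(k)
  blur1 <- function(v) {
    n <- length(v)
    num <- stats::convolve(v, rev(k), type = "open")
    den <- stats::convolve(rep(1, n), rev(k), type = "open")
    idx <- (half + 1):(half + n)
    num[idx] / den[idx]
  }
  m <- apply(m, 2, blur1)
  t(apply(m, 1, blur1))
}

#' Extract intracellular theta phase and amplitude
#'
#' Zero-phase 3rd-order Butterworth bandpass (4-10 Hz) of the de-spiked
#' dF/F, followed by the analytic-signal phase and amplitude; the
#' amplitude trace is smoothed with a first-order Savitzky-Golay filter.
#'
#' @param dff De-spiked dF/F trace (1 kHz).
#' @param fs Sampling rate.
#' @param band Passband (Hz).
#' @param sg_window Amplitude smoothing window (ms).
#' @return A \code{theta_signal}: \code{phase} (rad, per ms),
#'   \code{amplitude} (dF/F units), \code{band}, \code{filtered}.
#' @export
theta_extract <- function(dff, fs = 1000, band = c(4, 10), sg_window = 21) {
  bf <- butter_filter(3, band, fs, "pass")
  filt <- filtfilt2(bf, dff)
  an <- analytic_signal(filt)
  structure(list(phase = Arg(an),
                 amplitude = moving_average(Mod(an), sg_window),
                 band = band, filtered = filt),
            class = "theta_signal")
}

#' Spike theta-phase statistics
#'
#' The phase of each spike is the analytic-signal angle at the spike peak;
#' modulation strength is the mean resultant vector length and the
#' preferred phase its direction.
#'
#' @param theta A \code{theta_signal}.
#' @param spike_times Spike times (ms).
#' @return A \code{spike_phase_stats} list: \code{preferred_phase},
#'   \code{vector_length}, \code{n_spikes}, \code{phases}.
#' @export
spike_phase_stats <- function(theta, spike_times) {
  if (length(spike_times) < 1)
    return(structure(list(preferred_phase = NA_real_,
                          vector_length = NA_real_, n_spikes = 0L,
                          phases = numeric(0)),
                     class = "spike_phase_stats"))
  ph <- theta$phase[ms_index(spike_times)]
  structure(list(preferred_phase = circ_mean(ph),
                 vector_length = circ_r(ph),
                 n_spikes = length(ph), phases = ph),
            class = "spike_phase_stats")
}
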