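## Synthetic DNMS sessions with full ground truth.
##
## The generator states a world: a theta-modulated interneuron (or
## pyramidal cell) with an optional temporal firing field, odor-onset
## hyperpolarization events that reset the theta oscillator, brief
## onset-burst and rebound spiking envelopes, photobleaching drift and
## locomotion bouts.  Every injected event and the per-ms rate function are
## recorded so detectors can be scored against truth.

#' Synthetic-session configuration
#'
#' Defaults encode the task layout (1 s pre-odor, 1 s odors, 5 s delay,
#' 3 s response window; 1 kHz sampling) and population-level event
#' statistics: hyperpolarization onset ~20 ms after odor onset, duration
#' ~190 ms, amplitude ~-4.5 baseline s.d.; onset-burst window 20-50 ms;
#' rebound window 200-500 ms.
#'
#' @param seed Integer seed; same seed, same output.
#' @param n_trials Trials per session.
#' @param baseline_rate_hz Baseline firing rate.
#' @param theta_freq_hz,theta_amp,phase_lock_kappa,theta_pref_phase Theta
#'   oscillation frequency, subthreshold amplitude (dF/F units), spike
#'   phase-locking concentration (von Mises kappa) and preferred phase.
#' @param field One of \code{"none"}, \code{"odorA"}, \code{"odorB"},
#'   \code{"both"}, \code{"delay"}.
#' @param field_center_ms,field_width_ms,field_gain Gaussian rate bump:
#'   centre (ms from trial start), width (2 sd, ms) and peak bump
#'   amplitude in units of the baseline rate (peak rate =
#'   baseline x (1 + gain)).
#' @param hyperpol_prob Per-trial probability of an odor-onset
#'   hyperpolarization event.
#' @param hyperpol_onset_ms,hyperpol_duration_ms,hyperpol_amplitude_sd Mean
#'   onset latency after odor onset, mean duration, mean depth in baseline
#'   s.d. units (negative).
#' @param hyperpol_onset_jitter_ms,hyperpol_duration_jitter_ms,hyperpol_amp_jitter_sd
#'   Across-trial s.d. of the event parameters.
#' @param reset_phase_rad Theta phase snapped at the hyperpolarization
#'   trough (\code{NA} disables phase resetting).
#' @param onset_burst_prob,onset_burst_gain PV-like onset burst: per-trial
#'   probability and rate gain inside the 20-50 ms window.
#' @param rebound_gain Rate gain inside the 200-500 ms rebound window
#'   (theta pacing applies on top).
#' @param spike_amp,spike_halfwidth_ms,spike_ahp Spike waveform peak
#'   amplitude (dF/F), halfwidth and after-hyperpolarization depth.
#' @param noise_sd White measurement noise s.d. (dF/F units).
#' @param pink_sd 1/f subthreshold noise s.d.
#' @param bleach_tau_s,bleach_amp Photobleaching time constant and
#'   asymptotic additive drift.
#' @param bout_rate_hz,bout_dur_ms,odor_bout_prob Locomotion bout rate,
#'   mean duration and probability of an odor-evoked bout.
#' @param retention_prob,field_gain_prob Multiday field dynamics: a field
#'   cell keeps its field on the next session with probability
#'   \code{retention_prob}; a no-field cell gains one with probability
#'   \code{field_gain_prob}.  The session-0 field probability is the
#'   stationary prevalence of that chain, so turnover statistics are
#'   stationary from the first tracked pair.
#' @param n_sessions,train_switch_session Number of sessions and the
#'   session index at which \code{training_state} switches to trained.
#' @param refractory_ms Absolute refractory period for spike thinning.
#' @param trial_len_ms Trial length (11 s by convention).
#' @return A validated \code{synth_config} list.
#' @export
synth_config <- function(seed = 1L, n_trials = 20,
                         baseline_rate_hz = 8,
                         theta_freq_hz = 7, theta_amp = 1.0,
                         phase_lock_kappa = 1.0, theta_pref_phase = 0,
                         field = c("none", "odorA", "odorB", "both", "delay"),
                         field_center_ms = 1500, field_width_ms = 500,
                         field_gain = 3,
                         hyperpol_prob = 0.25,
                         hyperpol_onset_ms = 20, hyperpol_duration_ms = 190,
                         hyperpol_amplitude_sd = -4.5,
                         hyperpol_onset_jitter_ms = 10,
                         hyperpol_duration_jitter_ms = 30,
                         hyperpol_amp_jitter_sd = 0.5,
                         reset_phase_rad = pi / 2,
                         onset_burst_prob = 0.5, onset_burst_gain = 8,
                         rebound_gain = 2,
                         spike_amp = 1.5, spike_halfwidth_ms = 3,
                         spike_ahp = 0.3,
                         noise_sd = 1.0, pink_sd = 0.5,
                         bleach_tau_s = 50, bleach_amp = 0.5,
                         bout_rate_hz = 0.08, bout_dur_ms = 1000,
                         odor_bout_prob = 0.3,
                         retention_prob = 0.5, field_gain_prob = NULL,
                         n_sessions = 2, train_switch_session = 1,
                         refractory_ms = 2, trial_len_ms = 11000) {
  field <- match.arg(field)
  if (is.null(field_gain_prob)) field_gain_prob <- 1 - retention_prob
  cfg <- as.list(environment())
  probs <- c(hyperpol_prob, onset_burst_prob, retention_prob,
             field_gain_prob, odor_bout_prob)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (field_width_ms <= 0 || hyperpol_duration_ms <= 0 || bout_dur_ms <= 0)
    stop("widths and durations must be positive")
  if (phase_lock_kappa < 0) stop("kappa must be >= 0")
  if (n_trials < 1 || trial_len_ms < 8000) stop("invalid trial layout")
  structure(cfg, class = "synth_config")
}

## spike waveform kernel covering [-5, +19] ms around the peak (matching
## the de-spiking window); difference of exponentials + optional AHP lobe
spike_kernel <- function(amp, halfwidth_ms, ahp) {
  t <- 0:24
  tp <- 5
  td <- max(halfwidth_ms / 1.2, 0.8)
  w <- ifelse(t >= tp - 2,
              exp(-(t - tp + 2) / td) - exp(-(t - tp + 2) / 0.6), 0)
  w <- w / max(w) * amp
  w <- w - ahp * amp * exp(-((t - tp - 7)^2) / (2 * 3^2))
  w
}

## raised-cosine-edged box of unit depth
dip_shape <- function(duration_ms, edge = 6) {
  d <- max(round(duration_ms), 2 * edge + 1)
  s <- rep(1, d)
  ramp <- (1 - cos(pi * seq_len(edge) / edge)) / 2
  s[seq_len(edge)] <- ramp
  s[d + 1 - seq_len(edge)] <- ramp
  s
}

field_multiplier <- function(cfg, odor1_id, n) {
  mult <- rep(1, n)
  applies <- switch(cfg$field,
                    none = FALSE,
                    odorA = odor1_id == "A",
                    odorB = odor1_id == "B",
                    both = TRUE,
                    delay = TRUE)
  if (applies) {
    t <- seq_len(n) - 1
    sdv <- cfg$field_width_ms / 2
    mult <- 1 + cfg$field_gain *
      exp(-(t - cfg$field_center_ms)^2 / (2 * sdv^2))
  }
  mult
}

generate_trial <- function(cfg, spikes_only = FALSE) {
  n <- cfg$trial_len_ms
  odor1 <- sample(c("A", "B"), 1)
  odor2 <- sample(c("A", "B"), 1)
  odor_on <- 1000

  ## theta oscillator with optional phase reset at the hyperpolarization trough
  phi0 <- stats::runif(1, -pi, pi)
  t <- seq_len(n) - 1
  phase <- 2 * pi * cfg$theta_freq_hz * t / 1000 + phi0

  hyp <- NULL
  if (stats::runif(1) < cfg$hyperpol_prob) {
    onset <- odor_on + max(0, stats::rnorm(1, cfg$hyperpol_onset_ms,
                                           cfg$hyperpol_onset_jitter_ms))
    dur <- max(60, stats::rnorm(1, cfg$hyperpol_duration_ms,
                                cfg$hyperpol_duration_jitter_ms))
    amp <- min(-3.2, stats::rnorm(1, cfg$hyperpol_amplitude_sd,
                                  cfg$hyperpol_amp_jitter_sd))
    onset <- round(onset); dur <- round(dur)
    trough <- onset + floor(dur / 2)
    hyp <- list(onset_ms = onset, duration_ms = dur, amplitude_sd = amp,
                trough_ms = trough)
    if (!is.na(cfg$reset_phase_rad)) {
      after <- t >= trough
      phase[after] <- cfg$reset_phase_rad +
        2 * pi * cfg$theta_freq_hz * (t[after] - trough) / 1000
    }
  }
  phase <- wrap_angle(phase)

  ## per-ms rate function
  kappa <- cfg$phase_lock_kappa
  theta_mult <- if (kappa > 0)
    exp(kappa * cos(phase - cfg$theta_pref_phase)) / besselI(kappa, 0)
  else rep(1, n)
  rate <- cfg$baseline_rate_hz * field_multiplier(cfg, odor1, n) * theta_mult
  burst <- stats::runif(1) < cfg$onset_burst_prob
  if (burst && cfg$onset_burst_gain != 1) {
    w <- ms_index(odor_on + 20):(ms_index(odor_on + 50) - 1)
    rate[w] <- rate[w] * cfg$onset_burst_gain
  }
  if (cfg$rebound_gain != 1) {
    w <- ms_index(odor_on + 200):(ms_index(odor_on + 500) - 1)
    rate[w] <- rate[w] * cfg$rebound_gain
  }
  if (!is.null(hyp)) {
    w <- ms_index(hyp$onset_ms):min(ms_index(hyp$onset_ms + hyp$duration_ms) - 1, n)
    rate[w] <- rate[w] * 0.1
  }

  spikes <- thin_spikes(pmin(rate / 1000, 1), stats::runif(n), cfg$refractory_ms)

  dff <- NULL; sub <- NULL; loco <- NULL
  if (!spikes_only) {
    theta_jit <- stats::filter(stats::rnorm(n, 0, 0.3 * sqrt(1 - exp(-2 / 500))),
                               exp(-1 / 500), method = "recursive")
    theta_tr <- cfg$theta_amp * (1 + as.numeric(theta_jit)) * sin(phase)
    pink <- cfg$pink_sd * pink_noise(n, fs = 1000)
    white <- stats::rnorm(n, 0, cfg$noise_sd)
    base <- theta_tr + pink + white
    dip <- numeric(n)
    if (!is.null(hyp)) {
      ## depth scaled to the s.d. the detector will z-score by: smoothed
      ## pre-odor baseline of the composite trace
      sm <- moving_average(base, 21)
      sd_b <- stats::sd(sm[ms_index(500):(ms_index(1000) - 1)])
      shp <- dip_shape(hyp$duration_ms)
      idx <- ms_index(hyp$onset_ms):(ms_index(hyp$onset_ms) + length(shp) - 1)
      keep <- idx <= n
      dip[idx[keep]] <- hyp$amplitude_sd * sd_b * shp[keep]
      ## ground truth records the event's observable extent: the S < -1
      ## run of the noise-free smoothed dip (the quantity the detector
      ## estimates), alongside the nominal draw
      S0 <- moving_average(dip, 21) / sd_b
      runs <- logical_runs(S0 < -1)
      hyp$nominal <- hyp[c("onset_ms", "duration_ms", "amplitude_sd",
                           "trough_ms")]
      if (nrow(runs)) {
        hyp$onset_ms <- runs[1, 1]
        hyp$duration_ms <- runs[nrow(runs), 2] - runs[1, 1]
        hyp$amplitude_sd <- min(S0)
        hyp$trough_ms <- which.min(S0) - 1
      }
    }
    bleach <- -cfg$bleach_amp * (1 - exp(-t / (cfg$bleach_tau_s * 1000)))
    sub <- theta_tr + pink + dip + bleach
    dff <- sub + white
    kern <- spike_kernel(cfg$spike_amp, cfg$spike_halfwidth_ms, cfg$spike_ahp)
    for (s in spikes) {
      idx <- (s + 1 - 5):(s + 1 + 19)
      keep <- idx >= 1 & idx <= n
      dff[idx[keep]] <- dff[idx[keep]] + kern[keep]
    }
    ## locomotion: sparse bouts + sensor noise
    loco <- numeric(n)
    nb <- stats::rpois(1, cfg$bout_rate_hz * n / 1000)
    if (nb > 0) {
      starts <- sort(stats::runif(nb, 0, n - 1))
      durs <- pmax(100, stats::rexp(nb, 1 / cfg$bout_dur_ms))
      for (b in seq_len(nb)) {
        idx <- ms_index(starts[b]):min(ms_index(starts[b] + durs[b]), n)
        loco[idx] <- 0.05
      }
    }
    if (stats::runif(1) < cfg$odor_bout_prob) {
      idx <- ms_index(odor_on + 200):ms_index(odor_on + 1200)
      loco[idx] <- 0.05
    }
    loco <- moving_average(loco, 101) + abs(stats::rnorm(n, 0, 0.002))
  } else {
    dff <- numeric(n)
    loco <- numeric(n)
  }

  tr <- trial_record(dff = dff, spike_times = as.numeric(spikes),
                     locomotion = loco, odor1_id = odor1, odor2_id = odor2,
                     response_window_end = n)
  list(trial = tr,
       truth = list(rate_hz = rate, hyperpol = hyp, onset_burst = burst,
                    subthreshold = sub, theta_phase = phase,
                    odor1_id = odor1))
}

#' Generate one synthetic cell-session with ground truth
#'
#' @param cfg A [synth_config()].
#' @param spikes_only If TRUE, skip trace synthesis (dF/F and locomotion
#'   are zero vectors); much faster for spike-train-level analyses.
#' @param cell_id,session_index,training_state Metadata passed through.
#' @return A list with \code{session} (a \code{cell_session}) and
#'   \code{truth} (per-trial rate functions, injected events,
#'   subthreshold-only traces, and the field specification).
#' @export
generate_cell_session <- function(cfg, spikes_only = FALSE,
                                  cell_id = "synth", session_index = 0L,
                                  training_state = "trained") {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(cfg$seed)
  out <- lapply(seq_len(cfg$n_trials), function(i)
    generate_trial(cfg, spikes_only = spikes_only))
  session <- cell_session(lapply(out, `[[`, "trial"), cell_id = cell_id,
                          cell_class = "PV", training_state = training_state,
                          session_index = session_index,
                          sample_rate = 1000)
  truth <- list(trials = lapply(out, `[[`, "truth"),
                field = list(kind = cfg$field,
                             center_ms = cfg$field_center_ms,
                             width_ms = cfg$field_width_ms,
                             gain = cfg$field_gain),
                cfg = cfg)
  list(session = session, truth = truth)
}

## one step of the field birth-death chain; returns updated spec + flags
step_field <- function(spec, cfg) {
  if (spec$has_field) {
    if (stats::runif(1) < cfg$retention_prob)
      return(c(spec, list(kept = TRUE)))
    spec <- draw_field_spec(cfg, force_none = TRUE)
    spec$kept <- FALSE
    return(spec)
  }
  if (stats::runif(1) < cfg$field_gain_prob) {
    spec <- draw_field_spec(cfg, force_field = TRUE)
  } else {
    spec <- draw_field_spec(cfg, force_none = TRUE)
  }
  spec$kept <- FALSE
  spec
}

draw_field_spec <- function(cfg, force_field = FALSE, force_none = FALSE) {
  if (force_none)
    return(list(has_field = FALSE, kind = "none",
                center_ms = NA_real_))
  has <- force_field
  kind <- sample(c("odorA", "odorB"), 1)
  center <- 1000 + stats::runif(1, 100, 900) # within the first odor cue
  list(has_field = has, kind = kind, center_ms = round(center))
}

#' Generate a multiday ensemble for one tracked cell
#'
#' Field status follows a stationary birth-death chain: field cells retain
#' their field with probability \code{retention_prob}, no-field cells gain
#' one with probability \code{field_gain_prob}; session 0 is drawn from the
#' chain's stationary prevalence.  Under stationarity the turnover
#' "stable" percentage equals \code{retention_prob} in expectation.
#'
#' @param cfg A [synth_config()] with \code{n_sessions >= 2}.
#' @param spikes_only Passed to [generate_cell_session()].
#' @param status_only If TRUE, skip session synthesis entirely and return
#'   only the per-session field ground truth (fast path for cohort-level
#'   turnover simulations).
#' @return List with \code{sessions} (list of \code{cell_session}, or NULL
#'   if \code{status_only}) and \code{truth} (per-session field specs and
#'   retention flags).
#' @export
generate_multiday_ensemble <- function(cfg, spikes_only = TRUE,
                                       status_only = FALSE) {
  stopifnot(inherits(cfg, "synth_config"))
  if (cfg$n_sessions < 2) stop("n_sessions must be >= 2")
  set.seed(cfg$seed)
  p_star <- cfg$field_gain_prob /
    (1 - cfg$retention_prob + cfg$field_gain_prob)
  if (!is.finite(p_star)) p_star <- 1 # retention 1 with gain 0
  spec <- if (stats::runif(1) < p_star)
    draw_field_spec(cfg, force_field = TRUE) else draw_field_spec(cfg, force_none = TRUE)
  spec$kept <- NA
  specs <- vector("list", cfg$n_sessions)
  specs[[1]] <- spec
  for (d in 2:cfg$n_sessions) specs[[d]] <- step_field(specs[[d - 1]], cfg)
  seeds <- sample.int(2^31 - 2, cfg$n_sessions)
  sessions <- NULL
  if (!status_only) {
    sessions <- vector("list", cfg$n_sessions)
    for (d in seq_len(cfg$n_sessions)) {
      sp <- specs[[d]]
      scfg <- cfg
      scfg$seed <- seeds[d]
      scfg$field <- if (sp$has_field) sp$kind else "none"
      if (sp$has_field) scfg$field_center_ms <- sp$center_ms
      scfg <- do.call(synth_config, scfg[names(formals(synth_config))])
      g <- generate_cell_session(scfg, spikes_only = spikes_only,
                                 session_index = d - 1L,
                                 training_state = if (d - 1 >=
                                   cfg$train_switch_session) "trained" else "naive")
      sessions[[d]] <- g$session
    }
  }
  list(sessions = sessions,
       truth = list(field_by_session = specs, stationary_prevalence = p_star))
}

#' Generate a synthetic extracellular session
#'
#' Two unit classes with separable waveform/rate features, trial-structured
#' spike trains with assigned odor responses, and an LFP with injected
#' sharp-wave-ripple bursts at known times.
#'
#' @param cfg A [synth_config()] (seed and trial layout are used).
#' @param n_units Number of units.
#' @param narrow_frac Fraction of narrow-spiking (interneuron) units.
#' @param class_separation Multiplier on the distance between class feature
#'   means (1 = defaults, 0 = single population).
#' @param inhibited_frac Fraction of broad units assigned odor-inhibited
#'   responses (the rest are odor-excited).
#' @param n_trials Trials of spiking to draw per unit.
#' @param lfp_duration_s LFP length in seconds (2.5 kHz).
#' @param n_ripples Number of injected ripples.
#' @param ripple_sd Target ripple amplitude in s.d. of the binned RMS of
#'   the 120-200 Hz background.
#' @return List with \code{units} (feature data.frame), \code{spikes}
#'   (per-unit lists of per-trial spike times), \code{odor1_ids},
#'   \code{lfp} (\code{trace}, \code{fs}), and \code{truth} (class labels,
#'   odor-response signs, ripple intervals in ms).
#' @export
generate_ephys_session <- function(cfg, n_units = 60, narrow_frac = 0.16,
                                   class_separation = 1,
                                   inhibited_frac = 0.7, n_trials = 40,
                                   lfp_duration_s = 600, n_ripples = 25,
                                   ripple_sd = 12) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(cfg$seed)
  n_narrow <- round(n_units * narrow_frac)
  cls <- c(rep("narrow", n_narrow), rep("broad", n_units - n_narrow))
  ## class feature means, pulled together as class_separation -> 0
  mid_pt <- 0.525; mid_ratio <- 0.375; mid_lrate <- (log(15) + log(1.5)) / 2
  s <- class_separation
  mu_pt <- ifelse(cls == "narrow", mid_pt - s * 0.275, mid_pt + s * 0.275)
  mu_ratio <- ifelse(cls == "narrow", mid_ratio - s * 0.125,
                     mid_ratio + s * 0.125)
  mu_lrate <- ifelse(cls == "narrow", mid_lrate + s * log(10) / 2,
                     mid_lrate - s * log(10) / 2)
  units <- data.frame(
    unit_id = sprintf("u%03d", seq_len(n_units)),
    peak_trough_ms = pmax(stats::rnorm(n_units, mu_pt, 0.07), 0.05),
    peak_trough_ratio = pmax(stats::rnorm(n_units, mu_ratio, 0.05), 0.02),
    mean_rate_hz = pmax(exp(stats::rnorm(n_units, mu_lrate, 0.3)), 0.6),
    stringsAsFactors = FALSE)
  sign <- rep("interneuron", n_units)
  broad_idx <- which(cls == "broad")
  n_inh <- round(length(broad_idx) * inhibited_frac)
  sign[broad_idx] <- c(rep("odor-inhibited", n_inh),
                       rep("odor-excited", length(broad_idx) - n_inh))
  n <- cfg$trial_len_ms
  odor_idx <- ms_index(1000):(ms_index(2000) - 1)
  odor1_ids <- sample(c("A", "B"), n_trials, replace = TRUE)
  spikes <- vector("list", n_units)
  for (u in seq_len(n_units)) {
    base <- units$mean_rate_hz[u]
    gain <- switch(sign[u], `odor-inhibited` = 0.25, `odor-excited` = 2.5, 1.5)
    spikes[[u]] <- lapply(seq_len(n_trials), function(k) {
      rate <- rep(base, n)
      rate[odor_idx] <- base * gain
      as.numeric(thin_spikes(pmin(rate / 1000, 1), stats::runif(n), 1L))
    })
  }
  ## LFP at 2.5 kHz: 1/f background + ripple bursts whose amplitude is
  ## calibrated against the POST-injection binned-RMS distribution, so
  ## "ripple_sd" means what the detector will measure.  Events occupy a
  ## small fraction of the recording (one per equal slot), as the
  ## s.d.-relative threshold presupposes.
  fs <- 2500
  nl <- round(lfp_duration_s * fs)
  lfp <- pink_noise(nl, fs = fs, f_lo = 0.5, f_hi = 400)
  ripples <- matrix(numeric(0), ncol = 2)
  if (n_ripples > 0) {
    bp <- butter_filter(3, c(120, 200), fs, "pass")
    bg_band <- filtfilt2(bp, lfp)
    bl <- 25 # 10-ms RMS bins
    nbins <- floor(nl / bl)
    rms_bg2 <- colMeans(matrix(bg_band[seq_len(nbins * bl)]^2, nrow = bl))
    dur_ms <- 80
    dur <- round(dur_ms / 1000 * fs)
    slot <- floor((nl - 4 * dur) / n_ripples)
    centers <- 2 * dur + (seq_len(n_ripples) - 1) * slot +
      round(stats::runif(n_ripples, 0.2, 0.8) * slot)
    tt <- seq_len(dur) - dur / 2
    env <- exp(-tt^2 / (2 * (dur / 5)^2))
    f0 <- stats::runif(n_ripples, 130, 180)
    ph0 <- stats::runif(n_ripples, 0, 2 * pi)
    ## mean burst-RMS^2 per covered bin for unit amplitude
    unit_rms2 <- colMeans(matrix((env * sin(2 * pi * 150 * tt / fs))[
      seq_len(floor(dur / bl) * bl)]^2, nrow = bl))
    peak_u2 <- max(unit_rms2)
    ## global solve: peak bin at ripple_sd s.d. of the post-injection
    ## binned-RMS distribution
    post_stats <- function(A) {
      r2 <- rms_bg2
      cov_bins <- unlist(lapply(centers %/% bl, function(cb)
        cb + seq_along(unit_rms2)))
      r2[cov_bins] <- r2[cov_bins] + A^2 * rep(unit_rms2, n_ripples)
      r <- sqrt(r2)
      c(mean(r), stats::sd(r))
    }
    target <- function(A) {
      st <- post_stats(A)
      (sqrt(stats::median(rms_bg2) + A^2 * peak_u2) - st[1]) / st[2] -
        ripple_sd
    }
    A0 <- stats::uniroot(target, c(1e-6, 100 * sqrt(mean(rms_bg2))))$root
    st <- post_stats(A0)
    peak_level <- st[1] + ripple_sd * st[2] # target peak RMS per event
    bound_level <- st[1] + 2 * st[2]        # the 2-s.d. boundary level
    ripples <- matrix(0, nrow = n_ripples, ncol = 2)
    env_sd <- dur / 5
    for (i in seq_len(n_ripples)) {
      ## per-event amplitude: pass the unit burst through the detector's
      ## own zero-phase bandpass (accounting for gain and transient
      ## smearing of the short burst), then set the realised peak bin
      ## (local background + exact bin-grid alignment) to the target level
      u <- env * sin(2 * pi * f0[i] * tt / fs + ph0[i])
      pad <- 2 * dur
      fu <- filtfilt2(bp, c(numeric(pad), u, numeric(pad)))
      fu_idx <- centers[i] + seq_len(length(fu)) - pad - round(dur / 2)
      keep <- fu_idx >= 1 & fu_idx <= nl
      fu <- fu[keep]; fu_idx <- fu_idx[keep]
      bin_of <- (fu_idx - 1) %/% bl + 1
      u2 <- tapply(fu^2, bin_of, sum) / bl
      cb <- tapply(bg_band[fu_idx] * fu, bin_of, sum) / bl
      bins <- as.integer(names(u2))
      sel <- u2 > 0.05 * max(u2) & bins <= length(rms_bg2)
      ## realised bin RMS^2 = bg2 + 2 Ai c + Ai^2 u2 (exact, by linearity
      ## of the filter); solve the quadratic so the peak bin hits the
      ## target level
      ai_bin <- (-cb[sel] + sqrt(pmax(cb[sel]^2 + u2[sel] *
        (peak_level^2 - rms_bg2[bins[sel]]), 0))) / u2[sel]
      Ai <- max(0, min(ai_bin))
      idx0 <- centers[i] + seq_len(dur) - round(dur / 2)
      lfp[idx0] <- lfp[idx0] + Ai * u
      ## ground truth extent: where the band-filtered burst RMS envelope
      ## crosses the 2-s.d. boundary level
      envf <- Ai * Mod(analytic_signal(fu)) / sqrt(2)
      over <- which(envf >= bound_level)
      if (length(over)) {
        ripples[i, ] <- c(fu_idx[min(over)] - 1, fu_idx[max(over)]) / fs * 1000
      } else {
        ripples[i, ] <- (centers[i] + c(-env_sd, env_sd)) / fs * 1000
      }
    }
  }
  list(units = units, spikes = spikes, odor1_ids = odor1_ids,
       lfp = list(trace = lfp, fs = fs),
       truth = list(unit_class = cls, odor_sign = sign,
                    ripples_ms = ripples))
}
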