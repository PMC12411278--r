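## Property-based acceptance battery.  Every function generates its own
## synthetic inputs from a seed, runs the package's detectors, and returns
## the measured quantities; the acceptance test asserts the thresholds and
## the acceptance script reports the numbers.  Cohort sizes follow the
## stated protocol (200 null cells, 100 field cells, 500 trials, ...).

acc_seed <- function(seed, k) (as.integer(seed) * 101L + k * 7919L) %% 2000000000L

#' Acceptance battery: field-detection calibration
#'
#' 200 homogeneous-Poisson cells (no tuning), 20 trials each; the per-odor
#' field detection rate must sit at the nominal 5% of the 95th-percentile
#' circular-shift construction.
#'
#' @param seed Integer seed.
#' @param n_cells,n_trials Cohort size.
#' @return List with \code{detection_rate} (pooled over odors) and
#'   \code{n}.
#' @export
acc_field_calibration <- function(seed, n_cells = 200, n_trials = 20) {
  hits <- matrix(NA, n_cells, 2)
  for (i in seq_len(n_cells)) {
    cfg <- synth_config(seed = acc_seed(seed, i), n_trials = n_trials,
                        baseline_rate_hz = 8, phase_lock_kappa = 0,
                        hyperpol_prob = 0, onset_burst_prob = 0,
                        rebound_gain = 1, field = "none")
    g <- generate_cell_session(cfg, spikes_only = TRUE)
    fr <- detect_fields(g$session, seed = acc_seed(seed, i + 50000))
    hits[i, ] <- c(fr$per_odor$A$significant, fr$per_odor$B$significant)
  }
  list(detection_rate = mean(hits), n = n_cells)
}

#' Acceptance battery: field-detection power and localization
#'
#' 100 cells with an injected odor-A field (bump amplitude 3 x baseline,
#' width 500 ms).  Reports the detection rate, the fraction of detected
#' cells whose field bin lands within one bin of the injected centre, and
#' the fraction classified odorA-specific with |SI| >= 0.42 among cells
#' without a spurious odor-B field (the per-odor null calibration fixes
#' ~5% spurious B fields by construction, so they are tallied separately
#' as \code{b_false_rate}).
#'
#' @param seed Integer seed.
#' @param n_cells Cohort size.
#' @return List of rates.
#' @export
acc_field_power <- function(seed, n_cells = 100) {
  det <- bin_ok <- cat_ok <- b_fp <- logical(n_cells)
  for (i in seq_len(n_cells)) {
    ## 30 trials: mid-range of per-cell trial counts in DNMS recordings
    ## (sets of 20 trials, most cells recorded over 2-3 sets)
    cfg <- synth_config(seed = acc_seed(seed, 1000 + i), n_trials = 30,
                        baseline_rate_hz = 8, phase_lock_kappa = 0,
                        hyperpol_prob = 0, onset_burst_prob = 0,
                        rebound_gain = 1, field = "odorA",
                        ## centre aligned with a bin centre (bin 6 covers
                        ## 1500-1600 ms) so "the truth bin" is unambiguous
                        field_center_ms = 1550, field_width_ms = 500,
                        field_gain = 3)
    g <- generate_cell_session(cfg, spikes_only = TRUE)
    fr <- detect_fields(g$session, seed = acc_seed(seed, 60000 + i))
    det[i] <- fr$per_odor$A$significant
    bin_ok[i] <- det[i] && abs(fr$per_odor$A$field_bin - 6) <= 1
    b_fp[i] <- fr$per_odor$B$significant
    cat_ok[i] <- fr$category == "odorA-specific" && !is.na(fr$SI) &&
      abs(fr$SI) >= 0.42
  }
  list(detection_rate = mean(det),
       bin_within_1 = mean(bin_ok[det]),
       odorA_specific_rate = mean(cat_ok[!b_fp]),
       b_false_rate = mean(b_fp), n = n_cells)
}

#' Acceptance battery: hyperpolarization recovery and false positives
#'
#' Trials with injected dips (-4 s.d., 150 ms, onset 20 ms, realistic
#' noise) score sensitivity and onset/duration error medians against the
#' generator's ground truth; dip-free trials with matched noise score the
#' false-positive rate.
#'
#' @param seed Integer seed.
#' @param n_trials Trials per condition (500).
#' @return List with \code{sensitivity}, \code{median_onset_err_ms},
#'   \code{median_duration_err_ms}, \code{fp_rate}.
#' @export
acc_hyperpol <- function(seed, n_trials = 500) {
  per_batch <- 50
  res <- NULL
  for (b in seq_len(ceiling(n_trials / per_batch))) {
    cfg <- synth_config(seed = acc_seed(seed, 2000 + b),
                        n_trials = per_batch, hyperpol_prob = 1,
                        hyperpol_onset_ms = 20, hyperpol_duration_ms = 150,
                        hyperpol_amplitude_sd = -4,
                        hyperpol_onset_jitter_ms = 0,
                        hyperpol_duration_jitter_ms = 0,
                        hyperpol_amp_jitter_sd = 0)
    g <- generate_cell_session(cfg)
    res <- rbind(res, t(vapply(seq_len(per_batch), function(i) {
      e <- detect_hyperpolarization(g$session$trials[[i]])
      h <- g$truth$trials[[i]]$hyperpol
      c(sig = !is.null(e) && e$significant,
        onset = if (!is.null(e)) abs(e$onset_ms - (h$onset_ms - 1000)) else NA,
        dur = if (!is.null(e)) abs(e$duration_ms - h$duration_ms) else NA)
    }, c(0, 0, 0))))
  }
  fp <- logical(0)
  for (b in seq_len(ceiling(n_trials / per_batch))) {
    cfg0 <- synth_config(seed = acc_seed(seed, 3000 + b),
                         n_trials = per_batch, hyperpol_prob = 0)
    g0 <- generate_cell_session(cfg0)
    fp <- c(fp, vapply(g0$session$trials, function(tr) {
      e <- detect_hyperpolarization(tr)
      !is.null(e) && e$significant
    }, TRUE))
  }
  list(sensitivity = mean(res[, 1]),
       median_onset_err_ms = stats::median(res[, 2], na.rm = TRUE),
       median_duration_err_ms = stats::median(res[, 3], na.rm = TRUE),
       fp_rate = mean(fp), n = n_trials)
}

#' Acceptance battery: theta phase-reset detectability
#'
#' Sessions with phase resetting enabled (every trial carries a
#' hyperpolarization that snaps the theta oscillator); counts the fraction
#' of sessions whose across-trial circular phase variance in [0, 150) ms
#' after odor onset falls below the pre-odor level.
#'
#' @param seed Integer seed.
#' @param n_sessions Number of simulated sessions (100).
#' @return List with \code{frac_reduced} and \code{n}.
#' @export
acc_phase_reset <- function(seed, n_sessions = 100) {
  ok <- logical(n_sessions)
  for (i in seq_len(n_sessions)) {
    cfg <- synth_config(seed = acc_seed(seed, 4000 + i), n_trials = 20,
                        hyperpol_prob = 1)
    g <- generate_cell_session(cfg)
    pv <- phase_reset_variance(g$session)
    ok[i] <- pv$post_mean < pv$pre_mean
  }
  list(frac_reduced = mean(ok), n = n_sessions)
}

#' Acceptance battery: decoder brute-force oracle equivalence
#'
#' Enumerates toy problems (up to 12 extended bins, counts up to 3,
#' several continuity scales) and compares [decode_trial()] with
#' exhaustive posterior maximisation.
#'
#' @param seed Integer seed.
#' @return List with \code{n_problems} and \code{n_mismatches}.
#' @export
acc_decoder_oracle <- function(seed) {
  set.seed(acc_seed(seed, 5000))
  brute <- function(model, counts) {
    pos <- model$ext_bin
    sig <- model$sigma_s / model$tau_s
    out <- integer(length(counts)); prev <- NA
    for (j in seq_along(counts)) {
      post <- vapply(seq_along(pos), function(t) {
        p <- model$K[t] * stats::dpois(counts[j], model$tau_s * model$R_m[t])
        if (!is.na(prev)) p <- p * exp(-(pos[t] - prev)^2 / (2 * sig^2))
        p
      }, 0)
      prev <- pos[which.max(post)]
      out[j] <- prev
    }
    out
  }
  n_prob <- 0L; n_mis <- 0L
  ## exhaustive count patterns on a 2-bin axis, sampled templates
  grid2 <- as.matrix(expand.grid(0:3, 0:3))
  for (rep in 1:25) {
    m <- structure(list(R_m = stats::runif(4, 0, 25), K = rep(0.25, 4),
                        tau_s = 0.1, sigma_s = sample(c(0.1, 3, 100), 1),
                        ext_bin = 1:4, axis = list(n_bins = 2)),
                   class = "decoder_model")
    for (i in seq_len(nrow(grid2))) {
      n_prob <- n_prob + 1L
      if (!identical(decode_trial(m, grid2[i, ]), brute(m, grid2[i, ])))
        n_mis <- n_mis + 1L
    }
  }
  ## random problems up to 12 extended bins
  for (rep in 1:300) {
    nb <- sample(2:6, 1)
    m <- structure(list(R_m = stats::runif(2 * nb, 0, 30),
                        K = rep(1 / (2 * nb), 2 * nb), tau_s = 0.1,
                        sigma_s = sample(c(0.1, 0.5, 3, 50), 1),
                        ext_bin = seq_len(2 * nb),
                        axis = list(n_bins = nb)),
                   class = "decoder_model")
    counts <- sample(0:3, nb, replace = TRUE)
    n_prob <- n_prob + 1L
    if (!identical(decode_trial(m, counts), brute(m, counts)))
      n_mis <- n_mis + 1L
  }
  list(n_problems = n_prob, n_mismatches = n_mis)
}

#' Acceptance battery: decoder recovery and chance calibration
#'
#' A strongly time-tuned cell (broad high-gain field spanning the odor and
#' early delay) must beat half of its own circular-shift chance error; an
#' untuned cell's error must sit inside the central 95% of its chance
#' distribution.
#'
#' @param seed Integer seed.
#' @param n_surrogates Circular-shift repetitions (500).
#' @return List with \code{tuned_error_s}, \code{tuned_chance_s},
#'   \code{tuned_ratio}, \code{untuned_error_s},
#'   \code{untuned_chance_lo}, \code{untuned_chance_hi},
#'   \code{untuned_inside}.
#' @export
acc_decoder_recovery <- function(seed, n_surrogates = 500) {
  cfg <- synth_config(seed = acc_seed(seed, 6000), n_trials = 45,
                      baseline_rate_hz = 15, phase_lock_kappa = 0,
                      hyperpol_prob = 0, onset_burst_prob = 0,
                      rebound_gain = 1, field = "both",
                      field_center_ms = 2500, field_width_ms = 2000,
                      field_gain = 15)
  g <- generate_cell_session(cfg, spikes_only = TRUE)
  m <- fit_decoder(g$session)
  dr <- evaluate_decoding(m, seed = acc_seed(seed, 6001),
                          n_surrogates = n_surrogates)
  cfg0 <- synth_config(seed = acc_seed(seed, 6002), n_trials = 45,
                       baseline_rate_hz = 15, phase_lock_kappa = 0,
                       hyperpol_prob = 0, onset_burst_prob = 0,
                       rebound_gain = 1, field = "none")
  g0 <- generate_cell_session(cfg0, spikes_only = TRUE)
  m0 <- fit_decoder(g0$session)
  d0 <- evaluate_decoding(m0, seed = acc_seed(seed, 6003),
                          n_surrogates = n_surrogates)
  band <- stats::quantile(d0$chance$time_error_s, c(0.025, 0.975),
                          names = FALSE)
  list(tuned_error_s = dr$time_error_s,
       tuned_chance_s = mean(dr$chance$time_error_s),
       tuned_ratio = dr$time_error_s / mean(dr$chance$time_error_s),
       untuned_error_s = d0$time_error_s,
       untuned_chance_lo = band[1], untuned_chance_hi = band[2],
       untuned_inside = d0$time_error_s >= band[1] &&
         d0$time_error_s <= band[2])
}

#' Acceptance battery: spike-phase closed form
#'
#' n = 10,000 von Mises phases at kappa = 2; the resultant vector length
#' must match I1(2)/I0(2).
#'
#' @param seed Integer seed.
#' @return List with \code{vector_length}, \code{expected}, \code{n}.
#' @export
acc_spike_phase <- function(seed) {
  set.seed(acc_seed(seed, 7000))
  n <- 10000
  ph <- rvonmises(n, mu = 0.7, kappa = 2)
  th <- structure(list(phase = ph, amplitude = rep(1, n)),
                  class = "theta_signal")
  st <- spike_phase_stats(th, seq_len(n) - 1)
  list(vector_length = st$vector_length,
       expected = besselI(2, 1) / besselI(2, 0), n = n)
}

#' Acceptance battery: de-spiking fidelity
#'
#' At 10 Hz firing, the 4-10 Hz band power of the de-spiked trace must
#' match the ground-truth subthreshold trace within 10% (session mean).
#'
#' @param seed Integer seed.
#' @param n_trials Trials averaged (10).
#' @return List with \code{band_power_ratio}.
#' @export
acc_despike <- function(seed, n_trials = 10) {
  cfg <- synth_config(seed = acc_seed(seed, 8000), n_trials = n_trials,
                      baseline_rate_hz = 10, field = "none",
                      hyperpol_prob = 0, onset_burst_prob = 0,
                      rebound_gain = 1)
  g <- generate_cell_session(cfg)
  bandpow <- function(x) {
    p <- power_spectrum(x)
    sum(p$power[p$freq >= 4 & p$freq <= 10])
  }
  ratios <- vapply(seq_len(n_trials), function(i) {
    tr <- g$session$trials[[i]]
    bandpow(despike(tr$dff, tr$spike_times)) /
      bandpow(g$truth$trials[[i]]$subthreshold)
  }, 0)
  list(band_power_ratio = mean(ratios), n = n_trials)
}

#' Acceptance battery: multiday turnover recovery
#'
#' 500 tracked cells over 4 sessions with retention probability 0.6; the
#' pooled turnover "stable" percentage must recover 60%.
#'
#' @param seed Integer seed.
#' @param n_cells,n_sessions Cohort shape.
#' @return List with \code{stable_pct}.
#' @export
acc_turnover <- function(seed, n_cells = 500, n_sessions = 4) {
  rows <- vector("list", n_cells * n_sessions)
  k <- 0
  for (i in seq_len(n_cells)) {
    cfg <- synth_config(seed = acc_seed(seed, 9000 + i),
                        retention_prob = 0.6, n_sessions = n_sessions)
    e <- generate_multiday_ensemble(cfg, status_only = TRUE)
    for (d in seq_len(n_sessions)) {
      k <- k + 1
      rows[[k]] <- data.frame(cell_id = paste0("c", i),
                              session_index = d - 1,
                              has_odor_field =
                                e$truth$field_by_session[[d]]$has_field)
    }
  }
  tv <- turnover_rates(do.call(rbind, rows))
  list(stable_pct = 100 * sum(tv$stable_pct / 100 * tv$n_field_curr) /
         sum(tv$n_field_curr), n = n_cells)
}

#' Acceptance battery: ripple detection
#'
#' 25 ripples injected at 12 s.d.; recall and precision with boundary
#' agreement within +-15 ms.
#'
#' @param seed Integer seed.
#' @return List with \code{recall}, \code{precision}, \code{n_detected}.
#' @export
acc_ripples <- function(seed) {
  cfg <- synth_config(seed = acc_seed(seed, 10000))
  e <- generate_ephys_session(cfg, n_units = 2, n_trials = 2, n_ripples = 25)
  rip <- detect_ripples(e$lfp)
  tr <- e$truth$ripples_ms
  hit_t <- apply(tr, 1, function(a)
    nrow(rip) > 0 && any(abs(rip$start_ms - a[1]) <= 15 &
                           abs(rip$end_ms - a[2]) <= 15))
  hit_d <- if (nrow(rip)) apply(rip, 1, function(a)
    any(abs(tr[, 1] - a[1]) <= 15 & abs(tr[, 2] - a[2]) <= 15)) else logical(0)
  list(recall = mean(hit_t),
       precision = if (length(hit_d)) mean(hit_d) else 0,
       n_detected = nrow(rip), n = 25)
}

#' Acceptance battery: unit classification
#'
#' 200 units from two feature populations at Mahalanobis separation >= 6;
#' k-means labelling accuracy against ground truth.
#'
#' @param seed Integer seed.
#' @return List with \code{accuracy} and \code{n}.
#' @export
acc_units <- function(seed) {
  cfg <- synth_config(seed = acc_seed(seed, 11000))
  e <- generate_ephys_session(cfg, n_units = 200, n_trials = 2,
                              n_ripples = 0, lfp_duration_s = 10)
  u <- classify_units(e$units, seed = acc_seed(seed, 11001))
  truth <- e$truth$unit_class[match(u$unit_id, e$units$unit_id)]
  list(accuracy = mean(u$class == truth), n = nrow(u))
}

#' Acceptance battery: pipeline determinism
#'
#' Runs simulate -> hyperpol -> fields -> finescale twice with the same
#' seed and checks every CSV output is byte-identical.
#'
#' @param seed Integer seed.
#' @return List with \code{identical} (logical).
#' @export
acc_determinism <- function(seed) {
  base <- tempfile("acc_det")
  cfgf <- paste0(base, "_cfg.json")
  writeLines(paste0('{"n_cells":2,"n_trials":8,"field":"odorA",',
                    '"field_gain":4,"n_shuffles":200,"n_surrogates":50}'),
             cfgf)
  run <- function(tag) {
    sim <- paste0(base, "_sim", tag)
    out <- paste0(base, "_out", tag)
    voltfield_cli(c("simulate", "--config", cfgf, "--seed", as.character(seed),
                    "--out", sim, "--log-level", "quiet"))
    for (stage in c("hyperpol", "fields", "finescale"))
      voltfield_cli(c(stage, "--config", cfgf, "--seed", as.character(seed),
                      "--in", sim, "--out", out, "--log-level", "quiet"))
    out
  }
  o1 <- run("a"); o2 <- run("b")
  files <- list.files(o1, pattern = "\\.csv$")
  same <- vapply(files, function(f)
    identical(readBin(file.path(o1, f), "raw", 1e8),
              readBin(file.path(o2, f), "raw", 1e8)), TRUE)
  unlink(c(paste0(base, c("_sima", "_simb", "_outa", "_outb")), cfgf),
         recursive = TRUE)
  list(identical = all(same), n_files = length(files))
}
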