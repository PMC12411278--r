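test_that("config validation rejects invalid parameters before sampling", {
  expect_error(synth_config(hyperpol_prob = 1.5), "probabilities")
  expect_error(synth_config(field_width_ms = -1), "positive")
  expect_error(synth_config(phase_lock_kappa = -2), "kappa")
  expect_error(synth_config(n_trials = 0), "trial layout")
})

test_that("silent configuration produces a flat trace and zero spikes", {
  cfg <- synth_config(seed = 1, n_trials = 3, baseline_rate_hz = 0,
                      theta_amp = 0, noise_sd = 0, pink_sd = 0,
                      hyperpol_prob = 0, bleach_amp = 0, bout_rate_hz = 0,
                      odor_bout_prob = 0)
  g <- generate_cell_session(cfg)
  for (tr in g$session$trials) {
    expect_length(tr$spike_times, 0)
    expect_equal(diff(range(tr$dff)), 0)
  }
})

test_that("total spike count matches the Poisson oracle", {
  # baseline 10 Hz x 11 s x 20 trials = 2200 expected; the 2-ms refractory
  # trims ~2%, well inside the 4-sd band
  cfg <- synth_config(seed = 2, n_trials = 20, baseline_rate_hz = 10,
                      phase_lock_kappa = 0, field = "none",
                      hyperpol_prob = 0, onset_burst_prob = 0,
                      rebound_gain = 1)
  g <- generate_cell_session(cfg, spikes_only = TRUE)
  total <- sum(vapply(g$session$trials, function(t) length(t$spike_times), 0))
  expect_lt(abs(total - 2200), 4 * sqrt(2200))
})

test_that("empirical counts track the ground-truth rate integral", {
  cfg <- synth_config(seed = 3, n_trials = 20, baseline_rate_hz = 8,
                      field = "odorA", field_gain = 4,
                      phase_lock_kappa = 1, hyperpol_prob = 0.3)
  g <- generate_cell_session(cfg, spikes_only = TRUE)
  expected <- sum(vapply(g$truth$trials, function(t) sum(t$rate_hz) / 1000, 0))
  total <- sum(vapply(g$session$trials, function(t) length(t$spike_times), 0))
  expect_lt(abs(total - expected), 4 * sqrt(expected) + 0.03 * expected)
})

test_that("same seed reproduces the identical session", {
  cfg <- synth_config(seed = 11, n_trials = 3)
  expect_identical(generate_cell_session(cfg), generate_cell_session(cfg))
})

test_that("spike theta phases concentrate per the configured kappa", {
  cfg <- synth_config(seed = 5, n_trials = 40, baseline_rate_hz = 12,
                      phase_lock_kappa = 2, theta_pref_phase = 0.5,
                      field = "none", hyperpol_prob = 0,
                      onset_burst_prob = 0, rebound_gain = 1)
  g <- generate_cell_session(cfg, spikes_only = TRUE)
  ph <- unlist(lapply(seq_along(g$session$trials), function(i) {
    st <- g$session$trials[[i]]$spike_times
    g$truth$trials[[i]]$theta_phase[st + 1]
  }))
  expect_gt(length(ph), 3000)
  expect_equal(circ_r(ph), besselI(2, 1) / besselI(2, 0), tolerance = 0.05)
  expect_equal(circ_mean(ph), 0.5, tolerance = 0.1)
})

test_that("injected hyperpolarization amplitude is recoverable pre-noise", {
  cfg <- synth_config(seed = 6, n_trials = 10, hyperpol_prob = 1,
                      hyperpol_amplitude_sd = -5, hyperpol_amp_jitter_sd = 0)
  g <- generate_cell_session(cfg)
  for (i in seq_along(g$session$trials)) {
    h <- g$truth$trials[[i]]$hyperpol
    sub <- g$truth$trials[[i]]$subthreshold
    sm <- moving_average(sub, 21)
    base <- sm[501:1000]
    S <- (sm - mean(base)) / sd(base)
    expect_equal(min(S[1001:2000]), -5, tolerance = 1.2)
  }
})

test_that("multiday retention extremes behave as specified", {
  cfg1 <- synth_config(seed = 7, n_sessions = 4, retention_prob = 1,
                       field_gain_prob = 0)
  e1 <- generate_multiday_ensemble(cfg1, status_only = TRUE)
  specs <- e1$truth$field_by_session
  expect_true(all(vapply(specs, `[[`, TRUE, "has_field")))
  expect_length(unique(vapply(specs, `[[`, 0, "center_ms")), 1L)

  cfg0 <- synth_config(seed = 8, n_sessions = 6, retention_prob = 0,
                       field_gain_prob = 0.5)
  e0 <- generate_multiday_ensemble(cfg0, status_only = TRUE)
  st <- vapply(e0$truth$field_by_session, `[[`, TRUE, "has_field")
  expect_false(any(st[-1] & st[-length(st)])) # a field never survives
  expect_error(generate_multiday_ensemble(synth_config(n_sessions = 1)),
               "n_sessions")
})

test_that("multiday sessions carry the per-session field spec", {
  cfg <- synth_config(seed = 9, n_sessions = 3, n_trials = 4,
                      retention_prob = 0.5)
  e <- generate_multiday_ensemble(cfg, spikes_only = TRUE)
  expect_length(e$sessions, 3)
  expect_identical(vapply(e$sessions, `[[`, 0L, "session_index"), 0:2)
  expect_identical(e$sessions[[1]]$training_state, "naive")
  expect_identical(e$sessions[[3]]$training_state, "trained")
})

test_that("ephys generator honours ripple counts and class separation", {
  cfg <- synth_config(seed = 10)
  e0 <- generate_ephys_session(cfg, n_units = 10, n_trials = 2,
                               n_ripples = 0, lfp_duration_s = 10)
  expect_equal(nrow(e0$truth$ripples_ms), 0)
  e <- generate_ephys_session(cfg, n_units = 10, n_trials = 2,
                              n_ripples = 25, lfp_duration_s = 600)
  expect_equal(nrow(e$truth$ripples_ms), 25)
  expect_true(all(diff(e$truth$ripples_ms[, 1]) > 0))
  ## zero separation collapses the class feature distributions
  ez <- generate_ephys_session(cfg, n_units = 400, n_trials = 2,
                               class_separation = 0, n_ripples = 0,
                               lfp_duration_s = 10)
  d <- split(ez$units$peak_trough_ms, ez$truth$unit_class)
  expect_lt(abs(mean(d$narrow) - mean(d$broad)), 0.05)
})
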