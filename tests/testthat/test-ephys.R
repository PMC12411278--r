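test_that("LFP conditioning notches line noise and spares the ripple band", {
  fs <- 2500
  t <- seq(0, 3.9996, by = 1 / fs)
  x60 <- sin(2 * pi * 60 * t)
  y <- preprocess_lfp(x60, fs)$trace
  mid <- 2000:8000
  expect_lt(20 * log10(sd(y[mid]) / sd(x60[mid])), -20)
  ## DC unchanged, 150-Hz tone preserved within 5%
  expect_equal(preprocess_lfp(rep(3, 5000), fs)$trace, rep(3, 5000),
               tolerance = 1e-6)
  x150 <- sin(2 * pi * 150 * t)
  y150 <- preprocess_lfp(x150, fs)$trace
  expect_equal(sd(y150[mid]) / sd(x150[mid]), 1, tolerance = 0.05)
  expect_error(preprocess_lfp(x60, 1000), "below")
  ## downsampling from 10 kHz keeps a low-frequency tone
  t10 <- seq(0, 0.9999, by = 1e-4)
  z <- preprocess_lfp(sin(2 * pi * 20 * t10), 10000)
  expect_equal(z$fs, 2500)
  expect_length(z$trace, 2500)
  expect_equal(sd(z$trace[500:2000]) * sqrt(2), 1, tolerance = 0.05)
})

test_that("ripple detector is quiet on plain 1/f noise", {
  set.seed(61)
  lfp <- pink_noise(600 * 2500, fs = 2500, f_hi = 400)
  expect_lte(nrow(detect_ripples(lfp)), 1)
  expect_error(detect_ripples(numeric(1000)), "zero-variance")
})

test_that("injected ripples are recovered with accurate boundaries", {
  cfg <- synth_config(seed = 62)
  e <- generate_ephys_session(cfg, n_units = 2, n_trials = 2, n_ripples = 25)
  rip <- detect_ripples(e$lfp)
  tr <- e$truth$ripples_ms
  hit <- apply(tr, 1, function(a)
    any(abs(rip$start_ms - a[1]) <= 15 & abs(rip$end_ms - a[2]) <= 15))
  expect_gte(mean(hit), 0.88)
  expect_true(all(rip$end_ms - rip$start_ms >= 40))
  if (nrow(rip) > 1)
    expect_true(all(rip$start_ms[-1] - rip$end_ms[-nrow(rip)] >= 50))
  expect_true(all(rip$peak_sd > 10))
})

test_that("two bursts 30 ms apart are concatenated into one event", {
  set.seed(63)
  fs <- 2500
  lfp <- pink_noise(120 * fs, fs = fs, f_hi = 400)
  tt <- seq_len(150) # 60-ms bursts
  burst <- 40 * exp(-(tt - 75)^2 / (2 * 30^2)) * sin(2 * pi * 150 * tt / fs)
  lfp[50000 + tt] <- lfp[50000 + tt] + burst
  lfp[50000 + 150 + 75 + tt] <- lfp[50000 + 150 + 75 + tt] + burst
  rip <- detect_ripples(lfp)
  near <- rip[abs(rip$start_ms - 20000) < 400, ]
  expect_equal(nrow(near), 1)
})

test_that("unit classification separates synthetic populations", {
  cfg <- synth_config(seed = 64)
  e <- generate_ephys_session(cfg, n_units = 200, n_trials = 2,
                              n_ripples = 0, lfp_duration_s = 10)
  u <- classify_units(e$units, seed = 1)
  truth <- e$truth$unit_class[match(u$unit_id, e$units$unit_id)]
  expect_gte(mean(u$class == truth), 0.95)
  ## rate floor applied
  lowrate <- e$units
  lowrate$mean_rate_hz[1:5] <- 0.1
  u2 <- classify_units(lowrate, seed = 1)
  expect_equal(nrow(u2), 195)
  ## invariance to per-feature affine scaling
  scaled <- e$units
  scaled$peak_trough_ms <- scaled$peak_trough_ms * 1000 + 5
  u3 <- classify_units(scaled, seed = 1)
  expect_identical(u3$class, u$class)
  ## permuting unit order leaves labels attached to the same units
  perm <- sample(nrow(e$units))
  u4 <- classify_units(e$units[perm, ], seed = 1)
  expect_identical(u4$class[match(u$unit_id, u4$unit_id)], u$class)
  dup <- e$units[rep(1, 10), ]
  expect_error(classify_units(dup, seed = 1), "degenerate")
})

test_that("odor responses classify direction and latency", {
  mk <- function(gain, peak_ms = NULL) {
    lapply(1:30, function(i) {
      r <- rep(20 / 1000, 11000)
      r[1001:2000] <- r[1001:2000] * gain
      if (!is.null(peak_ms)) {
        w <- 1000 + peak_ms + (-25:25)
        r[w] <- r[w] + 0.15
      }
      which(runif(11000) < r) - 1
    })
  }
  set.seed(65)
  r_inh <- odor_response(mk(0.5))
  expect_identical(r_inh$sign_class, "odor-inhibited")
  expect_lt(r_inh$response, 1)
  r_exc <- odor_response(mk(2))
  expect_identical(r_exc$sign_class, "odor-excited")
  r_early <- odor_response(mk(1, peak_ms = 80))
  expect_identical(r_early$latency_class, "early")
  r_late <- odor_response(mk(1, peak_ms = 400))
  expect_identical(r_late$latency_class, "late")
  expect_warning(r0 <- odor_response(lapply(1:3, function(i) numeric(0))),
                 "zero baseline")
  expect_null(r0)
})

test_that("cohort odor-sign proportions are recovered", {
  cfg <- synth_config(seed = 66)
  e <- generate_ephys_session(cfg, n_units = 120, narrow_frac = 0,
                              inhibited_frac = 0.7, n_trials = 30,
                              n_ripples = 0, lfp_duration_s = 10)
  signs <- vapply(seq_len(120), function(i) {
    r <- odor_response(e$spikes[[i]])
    if (is.null(r)) NA_character_ else r$sign_class
  }, "")
  expect_lt(abs(mean(signs == "odor-inhibited", na.rm = TRUE) - 0.7), 0.05)
})
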