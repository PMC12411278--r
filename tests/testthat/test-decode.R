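## brute-force posterior maximisation over all candidate bins, computed
## with dpois and explicit normalisation-free products -- the oracle for
## decode_trial

brute_decode <- function(model, counts) {
  pos <- model$ext_bin
  sig <- model$sigma_s / model$tau_s
  out <- integer(length(counts))
  prev <- NA
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

toy_model <- function(R_m, n_bins, K = NULL, sigma_s = 3, ext_bin = NULL) {
  nb2 <- length(R_m)
  structure(list(R_m = R_m,
                 K = if (is.null(K)) rep(1 / nb2, nb2) else K,
                 tau_s = 0.1, sigma_s = sigma_s,
                 ext_bin = if (is.null(ext_bin)) seq_len(nb2) else ext_bin,
                 axis = list(n_bins = n_bins)),
            class = "decoder_model")
}

test_that("decode_trial equals exhaustive posterior maximisation", {
  set.seed(41)
  for (rep in 1:100) {
    nb <- sample(2:6, 1)
    m <- toy_model(runif(2 * nb, 0, 30), nb,
                   sigma_s = sample(c(0.1, 0.5, 3, 50), 1))
    counts <- sample(0:3, nb, replace = TRUE)
    expect_identical(decode_trial(m, counts), brute_decode(m, counts))
  }
  ## exhaustive over every count pattern on a small axis
  m <- toy_model(c(2, 9, 0.5, 14, 3, 1), 3)
  grid <- expand.grid(0:3, 0:3, 0:3)
  for (i in seq_len(nrow(grid))) {
    counts <- as.integer(grid[i, ])
    expect_identical(decode_trial(m, counts), brute_decode(m, counts))
  }
})

test_that("continuity limits: sigma -> 0 pins, sigma -> Inf frees", {
  m0 <- toy_model(c(1, 2, 3, 30, 2, 1, 1, 1), 4, sigma_s = 1e-6)
  d0 <- decode_trial(m0, c(0, 3, 3, 0))
  expect_true(all(d0 == d0[1])) # frozen after the first step
  mi <- toy_model(c(1, 2, 3, 30, 2, 1, 1, 1), 4, sigma_s = 1e6)
  expect_equal(decode_trial(mi, c(0, 3, 3, 0))[2], 4) # peak wins freely
})

test_that("zero spikes with uniform template decode to the earliest bin", {
  m <- toy_model(rep(2, 8), 4)
  d <- decode_trial(m, rep(0, 4))
  expect_equal(d[1], 1)
  expect_true(all(d == 1)) # continuity then pins
})

test_that("eligibility rules are enforced", {
  s9 <- pattern_session(9, function(i) poisson_spikes(10))
  expect_error(fit_decoder(s9), "ineligible")
  sAA <- pattern_session(12, function(i) poisson_spikes(10),
                         odor_seq = c(rep("A", 7), "B", rep("B", 4)))
  expect_error(fit_decoder(sAA), "ineligible")
})

test_that("the fitted model drops silent bins and balances the prior", {
  ## spikes only in the first 3 s; later bins are silent in training
  s <- pattern_session(12, function(i) sort(sample(1000:4000, 60)))
  m <- fit_decoder(s)
  expect_lt(length(m$R_m), 120)
  expect_gt(m$n_dropped, 0)
  expect_equal(sum(m$K), 1)
  ## equal odor counts -> uniform K across halves
  kA <- sum(m$K[m$half == "A"]); kB <- sum(m$K[m$half == "B"])
  expect_equal(kA, kB, tolerance = 1e-12)
  expect_error(decode_trial(m, rep(0, 10)), "axis")
})

test_that("mirrored decoding costs odor accuracy but not time error", {
  ## template peaked at bin 3 of each half, identical halves; a trial with
  ## spikes at step 3 decodes to the same within-trial time whichever half
  ## wins, so time error is 0 there while odor accuracy is ambiguous
  R <- rep(1, 12); R[3] <- 25; R[9] <- 25
  m <- toy_model(R, 6, sigma_s = 50)
  m$orig_bin <- ((m$ext_bin - 1) %% 6) + 1
  m$half <- ifelse(m$ext_bin <= 6, "A", "B")
  m$test_counts <- matrix(c(0, 0, 4, 0, 0, 0), nrow = 1)
  m$test_odor <- "B"
  r <- evaluate_decoding(m, seed = 1, n_surrogates = 10)
  orig <- ((r$decoded[[1]] - 1) %% 6) + 1
  expect_equal(orig[3], 3) # correct time ...
  expect_equal(r$decoded[[1]][3], 3) # ... in the wrong (earliest) half
})

test_that("relabelling odors permutes the decoded halves", {
  set.seed(42)
  cfg <- synth_config(seed = 43, n_trials = 15, baseline_rate_hz = 10,
                      phase_lock_kappa = 0, hyperpol_prob = 0,
                      onset_burst_prob = 0, rebound_gain = 1,
                      field = "odorA", field_center_ms = 2000,
                      field_gain = 8)
  g <- generate_cell_session(cfg, spikes_only = TRUE)
  m <- fit_decoder(g$session)
  sw <- g$session
  for (i in seq_along(sw$trials)) {
    o <- sw$trials[[i]]$odor1_id
    sw$trials[[i]]$odor1_id <- if (o == "A") "B" else "A"
  }
  m2 <- fit_decoder(sw)
  nb <- 60
  ra <- m$R_m[m$half == "A"]; rb2 <- m2$R_m[m2$half == "B"]
  expect_equal(ra, rb2)
})
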