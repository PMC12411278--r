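field_table <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r)
    data.frame(cell_id = r[[1]], session_index = r[[2]],
               has_odor_field = r[[3]])))
}

test_that("turnover extremes and denominators are exact", {
  ft <- field_table(list("a", 0, TRUE), list("a", 1, TRUE),
                    list("b", 0, TRUE), list("b", 1, TRUE))
  tv <- turnover_rates(ft)
  expect_equal(tv$stable_pct, 100)
  expect_equal(tv$inflow_pct, 0)
  expect_equal(tv$outflow_pct, 0)
  ## mixed case recomputes from raw counts
  ft2 <- field_table(list("a", 0, TRUE), list("a", 1, TRUE),
                     list("b", 0, TRUE), list("b", 1, FALSE),
                     list("c", 0, FALSE), list("c", 1, TRUE),
                     list("d", 0, FALSE), list("d", 1, FALSE))
  tv2 <- turnover_rates(ft2)
  expect_equal(tv2$stable_pct, 50)        # 1 of 2 current field cells
  expect_equal(tv2$inflow_pct, 50)
  expect_equal(tv2$stable_pct + tv2$inflow_pct, 100)
  expect_equal(tv2$outflow_pct, 50)       # 1 of 2 previous field cells
  ## no fields anywhere -> NA percentages, flagged not crashing
  ft3 <- field_table(list("a", 0, FALSE), list("a", 1, FALSE))
  tv3 <- turnover_rates(ft3)
  expect_true(is.na(tv3$stable_pct))
  ft4 <- field_table(list("a", 0, TRUE), list("b", 1, TRUE),
                     list("b", 2, TRUE))
  expect_warning(tv4 <- turnover_rates(ft4), "no tracked cells")
  expect_equal(nrow(tv4), 1) # only the 1-2 pair has tracked cells
})

test_that("turnover recovers the retention probability (Bernoulli oracle)", {
  rows <- list()
  for (i in 1:300) {
    cfg <- synth_config(seed = 5000 + i, retention_prob = 0.6, n_sessions = 3)
    e <- generate_multiday_ensemble(cfg, status_only = TRUE)
    for (d in 1:3) rows[[length(rows) + 1]] <- data.frame(
      cell_id = paste0("c", i), session_index = d - 1,
      has_odor_field = e$truth$field_by_session[[d]]$has_field)
  }
  tv <- turnover_rates(do.call(rbind, rows))
  pooled <- 100 * sum(tv$stable_pct / 100 * tv$n_field_curr) /
    sum(tv$n_field_curr)
  expect_lt(abs(pooled - 60), 7)
})

test_that("cross-session correlation spans the template/noise spectrum", {
  ## identical deterministic rates both days -> r = 1
  mk <- function(seed, jitter = 0, session_index = 0L) {
    set.seed(seed)
    trials <- lapply(1:6, function(i) {
      base <- rep(seq(5, 60, length.out = 6), each = 1000)
      st <- sort(unique(round(cumsum(rexp(500, mean(base) / 1000 / 10)))))
      st <- st[st < 11000]
      ## deterministic template: one spike at fixed offsets scaled by bin
      det <- unlist(lapply(0:59, function(b)
        1000 + b * 100 + seq(0, 99, length.out = 2 + b %% 5)))
      toy_trial(spikes = sort(unique(round(det + jitter * runif(length(det))))))
    })
    s <- toy_session(trials)
    s$session_index <- session_index
    s
  }
  a <- mk(1); b <- mk(1, session_index = 3L)
  cc <- cross_session_correlation(a, b)
  expect_equal(cc$mean_r, 1, tolerance = 1e-12)
  expect_equal(cc$session_distance, 3)
  ## independent Poisson rates -> r ~ 0
  pois <- function(seed, idx) {
    set.seed(seed)
    s <- pattern_session(20, function(i) poisson_spikes(20))
    s$session_index <- idx; s
  }
  cc0 <- cross_session_correlation(pois(2, 0L), pois(3, 1L))
  expect_lt(abs(cc0$mean_r), 0.05)
  expect_error(cross_session_correlation(a, { b2 <- b; b2$cell_id <- "x"; b2 }),
               "different cells")
})

test_that("self-correlation equals within-session mean pairwise r", {
  set.seed(4)
  s <- pattern_session(8, function(i)
    sort(unique(c(poisson_spikes(10), 2000 + sort(sample(0:999, 40))))))
  cc <- cross_session_correlation(s, s)
  z <- bin_rates(s, smooth_points = 5, zscore = TRUE)$rates
  manual <- mean(stats::cor(t(z)))
  expect_equal(cc$mean_r, manual, tolerance = 1e-12)
})

test_that("shared template with known noise follows the attenuation oracle", {
  ## rate = template + independent noise per trial; expected pair r equals
  ## var(template)/(var(template)+var(noise)) after z-scoring
  set.seed(5)
  template <- 10 + 40 * exp(-((1:60) - 30)^2 / 50)
  mk <- function(idx) {
    trials <- lapply(1:12, function(i) {
      lam <- pmax(template + rnorm(60, 0, 10), 0)
      st <- unlist(lapply(1:60, function(b)
        1000 + (b - 1) * 100 + sort(sample(0:99, rpois(1, lam[b] / 10)))))
      toy_trial(spikes = sort(unique(st)))
    })
    s <- toy_session(trials); s$session_index <- idx; s
  }
  cc <- cross_session_correlation(mk(0L), mk(1L), smooth_points = 0)
  v_t <- var(template)
  ## per-bin sampling noise: Poisson with mean lam/10 scaled by 10 Hz
  v_n <- 10^2 + mean(template) * 10
  rho <- v_t / (v_t + v_n)
  expect_lt(abs(cc$mean_r - rho), 0.12)
})
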