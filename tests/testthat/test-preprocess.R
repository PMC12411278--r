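test_that("segment_motion thresholds, merges and discards as specified", {
  expect_equal(nrow(segment_motion(numeric(5000))$segments), 0)
  expect_error(segment_motion(numeric(0)), "empty")

  ## rectangular 100-ms bout at 0.05 a.u.
  x <- numeric(5000); x[2001:2100] <- 0.05
  seg <- segment_motion(x)$segments
  expect_equal(nrow(seg), 1)
  expect_lt(abs(seg[1, 1] - 2000), 15) # filter-edge tolerance
  expect_lt(abs(seg[1, 2] - 2100), 15)

  ## two 30-ms bouts 15 ms apart merge into one segment
  y <- numeric(5000); y[1001:1030] <- 0.05; y[1046:1075] <- 0.05
  expect_equal(nrow(segment_motion(y)$segments), 1)
})

test_that("segment_motion output satisfies the MotionSegments invariants", {
  set.seed(3)
  for (rep in 1:5) {
    x <- abs(stats::filter(rnorm(8000, 0, 0.06), rep(1 / 30, 30),
                           sides = 2))
    x[is.na(x)] <- 0
    ms <- segment_motion(as.numeric(x))
    s <- ms$segments
    expect_true(nrow(s) >= 0)
    if (nrow(s) == 0) next
    expect_true(all(s[, 2] - s[, 1] >= 10))
    if (nrow(s) > 1) expect_true(all(s[-1, 1] - s[-nrow(s), 2] >= 20))
    expect_true(all(diff(as.vector(t(s))) >= 0))
  }
})

test_that("bin_rates counts, smooths and conserves spikes", {
  s <- pattern_session(2, function(i) if (i == 1) c(1510, 1520, 1530) else numeric(0))
  rm <- bin_rates(s, odor_delay_axis())
  expect_equal(rm$rates[1, 6], 30) # 3 spikes in one 100-ms bin
  expect_equal(sum(rm$rates[2, ]), 0)
  ## impulse spread 1/5 by the 5-point moving average
  rm5 <- bin_rates(s, odor_delay_axis(), smooth_points = 5)
  expect_equal(rm5$rates[1, 4:8], rep(6, 5))
  ## conservation: row sums x bin width = spike counts inside the axis
  set.seed(2)
  s2 <- pattern_session(5, function(i) poisson_spikes(20))
  rm2 <- bin_rates(s2, odor_delay_axis())
  counts <- vapply(s2$trials, function(tr)
    sum(tr$spike_times >= 1000 & tr$spike_times < 7000), 0)
  expect_equal(rowSums(rm2$rates) * 0.1, counts)
  expect_error(bin_rates(s2, odor_delay_axis(0, 20000, 100)), "bounds")
})

test_that("burst_index follows the interval-counting convention", {
  expect_equal(burst_index(c(0, 5, 200, 400)), 0.25)
  expect_equal(burst_index(c(0, 50, 100)), 0)
  n <- 20
  expect_equal(burst_index(seq(0, by = 5, length.out = n)), (n - 1) / n)
  expect_true(is.na(burst_index(c(3))))
})

test_that("speed and odor scores recover perfect and null correlations", {
  ## build locomotion whose bin means equal the smoothed rate exactly
  set.seed(4)
  spikes <- lapply(1:4, function(i) poisson_spikes(15))
  n <- 11000
  trials <- lapply(1:4, function(i) {
    cnt <- tabulate(floor(spikes[[i]] / 100) + 1, nbins = 110)
    r <- moving_average(cnt / 0.1, 5)
    toy_trial(spikes = spikes[[i]], n = n, loco = rep(r, each = 100))
  })
  s <- toy_session(trials)
  expect_equal(speed_score(s)$score, 1, tolerance = 1e-12)

  ## rate equal to the odor boxcar gives an odor score near 1 (smoothing
  ## only rounds the box edges)
  box <- function(i) c(seq(1000, 1975, by = 25), seq(7000, 7975, by = 25))
  sb <- pattern_session(4, box)
  expect_gt(odor_score(sb)$score, 0.95)
  ## flat rate is excluded -> undefined with warning
  sf <- pattern_session(4, function(i) seq(0, 10975, by = 25))
  expect_warning(sc <- odor_score(sf), "excluded")
  expect_true(is.na(sc$score))
})

test_that("despike replaces only merged windows and is idempotent", {
  set.seed(5)
  x <- rnorm(3000)
  expect_identical(despike(x, numeric(0)), x)
  d1 <- despike(x, c(1000, 1010, 2000))
  d2 <- despike(d1, c(1000, 1010, 2000))
  expect_identical(d1, d2) # idempotent for a fixed spike list
  ## overlapping spikes merge into one window: 995..1029 replaced
  untouched <- setdiff(seq_len(3000), 996:1030)
  untouched <- setdiff(untouched, 1996:2020)
  expect_identical(d1[untouched], x[untouched])
  expect_false(all(d1[996:1030] == x[996:1030]))
  expect_error(despike(x, 5000), "outside")
})

test_that("despike restores theta-band power of a contaminated sinusoid", {
  t <- seq(0, 10.999, by = 1e-3)
  clean <- sin(2 * pi * 7 * t)
  kern <- 5 * c(seq(0, 3, length.out = 6), seq(3, -0.5, length.out = 10),
                seq(-0.5, 0, length.out = 9))
  x <- clean
  spk <- seq(500, 10500, by = 100)
  for (s in spk) x[s + (-5:19) + 1] <- x[s + (-5:19) + 1] + kern
  bp <- function(v) {
    p <- power_spectrum(v)
    sum(p$power[p$freq >= 4 & p$freq <= 10])
  }
  expect_gt(abs(bp(x) / bp(clean) - 1), 0.15) # contamination is material
  expect_lt(abs(bp(despike(x, spk)) / bp(clean) - 1), 0.10)
})

test_that("power_spectrum finds tones and returns zero for silence", {
  t <- seq(0, 5.999, by = 1e-3)
  p <- power_spectrum(sin(2 * pi * 7 * t))
  expect_lt(abs(p$freq[which.max(p$power)] - 7), 0.5)
  p0 <- power_spectrum(numeric(4000))
  expect_equal(max(p0$power), 0)
  expect_warning(power_spectrum(list(numeric(100), sin(2 * pi * 7 * t))),
                 "excluded")
})

test_that("flattened spectrogram of white noise is trend-free", {
  set.seed(6)
  reps <- replicate(5, {
    sg <- spectrogram_flattened(rnorm(8000))
    ms <- rowMeans(sg$power)
    lo <- mean(ms[sg$freq >= 2 & sg$freq <= 20])
    hi <- mean(ms[sg$freq >= 60 & sg$freq <= 95])
    lo / hi
  })
  expect_equal(mean(reps), 1, tolerance = 0.2)
  expect_error(spectrogram_flattened(rnorm(100)), "shorter")
})

test_that("theta extraction and spike-phase statistics are coherent", {
  t <- seq(0, 10.999, by = 1e-3)
  th <- theta_extract(sin(2 * pi * 7 * t))
  expect_true(all(th$phase > -pi & th$phase <= pi))
  expect_true(all(th$amplitude >= 0))
  ## spikes exactly at oscillation peaks -> R = 1 at the peak phase
  peaks <- which(diff(sign(diff(th$filtered))) == -2) + 1
  peaks <- peaks[peaks > 1000 & peaks < 10000]
  st <- spike_phase_stats(th, peaks - 1)
  expect_gt(st$vector_length, 0.99)
  expect_lt(abs(st$preferred_phase), 0.1)
  ## uniform phases -> R near 0
  set.seed(7)
  stu <- spike_phase_stats(th, sort(sample(1000:10000, 2000)) - 1)
  expect_lt(stu$vector_length, 0.1)
  expect_equal(spike_phase_stats(th, numeric(0))$n_spikes, 0L)
})

test_that("spike_phase_stats equals the brute-force phasor oracle", {
  set.seed(8)
  for (rep in 1:5) {
    ph <- runif(200, -pi, pi)
    th <- structure(list(phase = ph, amplitude = rep(1, 200)),
                    class = "theta_signal")
    st <- spike_phase_stats(th, 0:199)
    v <- colSums(cbind(cos(ph), sin(ph))) / 200
    expect_equal(st$vector_length, sqrt(sum(v^2)), tolerance = 1e-12)
    expect_equal(st$preferred_phase, atan2(v[2], v[1]), tolerance = 1e-12)
  }
})
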