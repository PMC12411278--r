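# shared builders for hand-made trials and sessions

toy_trial <- function(spikes = numeric(0), n = 11000, dff = NULL,
                      loco = NULL, odor1 = "A", odor2 = "B") {
  trial_record(dff = if (is.null(dff)) numeric(n) else dff,
               spike_times = spikes,
               locomotion = if (is.null(loco)) numeric(n) else loco,
               odor1_id = odor1, odor2_id = odor2,
               response_window_end = n)
}

toy_session <- function(trials, ...) {
  cell_session(trials, cell_id = "toy", ...)
}

## deterministic session with a given per-trial spike pattern generator
pattern_session <- function(n_trials, spike_fun, odor_seq = NULL, n = 11000) {
  trials <- lapply(seq_len(n_trials), function(i) {
    o <- if (is.null(odor_seq)) c("A", "B")[(i %% 2) + 1] else odor_seq[i]
    toy_trial(spikes = spike_fun(i), n = n, odor1 = o)
  })
  toy_session(trials)
}

## homogeneous Poisson spike times on [0, n) at rate_hz (test-local oracle
## generator, independent of synthgen)
poisson_spikes <- function(rate_hz, n = 11000) {
  k <- stats::rpois(1, rate_hz * n / 1000)
  sort(sample.int(n, min(k, n)) - 1)
}
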