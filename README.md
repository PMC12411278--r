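# voltfield

Analysis of trial-structured voltage-imaging and extracellular
recordings of hippocampal neurons during an odor-cued delayed
non-match-to-sample (DNMS) task: two 1-s odor cues, a 5-s delay, traces
sampled at 1 kHz from 1 s before the first odor (11 s per trial).

The package is aimed at labs analysing optical voltage (dF/F) or
extracellular recordings with this trial structure. It implements:

* **Hyperpolarization detection** — per trial, the smoothed dF/F is
  z-scored to its 0.5-s pre-odor baseline (S); the earliest merged run
  of S < −1 in the first-odor window is a significant event iff it lasts
  > 50 ms and holds S < −3 for > 10 ms, and theta phase resetting is
  quantified as the across-trial circular phase variance.
* **Temporal firing fields** — 100-ms binned, five-point-smoothed,
  per-trial z-scored rates over the 6-s odor-delay interval; the max
  trial-mean rate per odor is tested against a null that circularly
  shifts each trial independently (1000 shuffles, 95th percentile), and
  odor specificity requires |SI| ≥ 0.42 with
  SI = (R_A − R_B)/(R_A + R_B) at the field bin.
* **Bayesian decoding of odor-specific time** — over a doubled axis
  (odor-A template then odor-B template), the decoded bin maximises
  K(t) · (τR_m(t))^s e^(−τR_m(t))/s! · exp(−|t−T̂_prev|²/2σ²) with
  τ = 100 ms and σ = 3 s, with circular-shift chance baselines.
* **Multiday turnover** (stable/inflow/outflow of odor fields) and
  cross-day trial-pair rate correlations.
* **Fine-timescale onset/rebound spiking** (5-ms bins; 30–50 ms and
  200–500 ms windows).
* **Extracellular procedures** — LFP conditioning, sharp-wave-ripple
  detection (120–200 Hz, 10/2 s.d. thresholds), waveform-based unit
  classification (PCA + k-means), odor responses.
* **A ground-truth synthetic generator** for all of the above, used by
  the calibration and acceptance tests.

## Worked example

```r
library(voltfield)

cfg <- synth_config(seed = 42, n_trials = 30, baseline_rate_hz = 8,
                    field = "odorA", field_center_ms = 1550,
                    field_width_ms = 500, field_gain = 3,
                    hyperpol_prob = 0.4)
g <- generate_cell_session(cfg)       # session + ground truth

detect_fields(g$session, seed = 1)
#> <field_result> odorA-specific; bin 5 (odor); SI = 0.539

hs <- summarize_hyperpol(g$session)
#> occurrence 0.43, amplitude -5.9 sd, onset 11 ms, duration 188 ms

dr <- evaluate_decoding(fit_decoder(g$session), seed = 2,
                        n_surrogates = 100)
dr
#> <decode_result> time error 2.05 s (chance 2.29), odor accuracy 0.51

onset_rebound_metrics(g$session)
#> onset 35.0 Hz, rebound 31.1 Hz, rebound increase 2.43
```

Reading the output: the injected odor-A field (bump centred 550 ms into
the cue, peak 4× baseline) is detected as an odor-A-specific field in
the bin covering 1400–1500 ms with selectivity 0.54 (≥ 0.42, so the
odor-specific label stands). Hyperpolarization events were injected in
~40% of trials and recovered at that rate with the expected ~−5 s.d.
amplitude and ~190-ms duration. A single narrow-field interneuron
carries little time information across the whole 6-s interval, so its
decoded-time error (2.05 s) sits only modestly below its own
circular-shift chance (2.29 s) and odor accuracy is near 0.5 — the
expected outcome for this cell type. The rebound-window rate (200–500 ms
after odor onset) is 2.4× above the pre-odor baseline, reflecting the
injected rebound gain and theta pacing.

## Command line

```sh
voltfield simulate  --config cfg.json --seed 1 --out sims/
voltfield fields    --config cfg.json --seed 1 --in sims/ --out results/
voltfield hyperpol  --in sims/ --out results/
voltfield decode    --in sims/ --out results/
voltfield report    --in results/ --out results/
```

(`exec/voltfield`; stages: simulate, preprocess, hyperpol, fields,
decode, multiday, finescale, ephys, report. Config files are JSON, or
YAML when the yaml package is installed.) Every stage is deterministic
given `--seed`: reruns produce byte-identical CSVs.

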