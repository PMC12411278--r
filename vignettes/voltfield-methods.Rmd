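---
title: "voltfield: models, detectors and the synthetic world behind them"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{voltfield: models, detectors and the synthetic world behind them}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(voltfield)
```

## The problem

voltfield analyses trial-structured recordings of hippocampal neurons
during an odor-cued delayed non-match-to-sample (DNMS) task: two 1-s odor
cues separated by a 5-s delay, with recording starting 1 s before the
first odor (11 s per trial at 1 kHz).  The primary signal is a
voltage-imaging fluorescence ratio (dF/F) that tracks membrane potential
and carries optical action potentials; companion tools handle
extracellular units and LFP.  The package implements the full chain of
bespoke analyses such data demand — odor-onset hyperpolarization
detection, permutation-based firing-field detection, odor selectivity,
Bayesian time/odor decoding, multiday turnover, fine-timescale
onset/rebound spiking, ripple detection and waveform-based unit
classification — together with a ground-truth synthetic generator that
every detector is calibrated against.

## Data model

A `trial_record` stores the per-trial dF/F, spike times (frame-aligned
integer ms), locomotion, odor identities and event times; a
`cell_session` is one cell on one day.  All times are milliseconds from
trial start, windows half-open `[a, b)`, odor 1 onset fixed at 1000 ms.
Sessions round-trip losslessly through a structured JSON layout
(`save_session()` / `load_session()`); no HDF5 library is required.
Back-to-back recording sets of one cell are merged with
`concatenate_recordings()` and treated as one continuous recording.

## Signal conditioning

* **Motion segmentation** — the locomotion signal is mode-subtracted,
  rectified and smoothed, then thresholded with hysteresis (enter 0.02,
  exit 0.01 a.u.); motion segments closer than 20 ms merge and segments
  under 10 ms are dropped.
* **De-spiking** — subthreshold analyses need the spike waveforms
  removed.  A 25-ms window around each spike (5 ms before to 19 ms after
  the peak, merged when overlapping) is replaced by a boundary-matched
  line plus AR(2) noise fitted to the detrended flanking 50 ms.  The
  original Bayesian spike-removal method is not reproduced; this
  stand-in is validated by a band-power criterion: at 10 Hz firing the
  4-10 Hz power of the de-spiked trace stays within 10% of the true
  subthreshold trace.  The noise stream is seeded from the spike list,
  so de-spiking is deterministic and idempotent.
* **Theta** — zero-phase 3rd-order Butterworth 4-10 Hz bandpass of the
  de-spiked dF/F, analytic-signal phase/amplitude, amplitude smoothed by
  a first-order Savitzky-Golay (moving-average) filter.  Spike phase
  locking is summarised by the mean resultant vector length and its
  direction.  Filter design (analog prototype + bilinear transform) is
  implemented in the package and verified against independently computed
  reference coefficients.
* **Spectra** — Kaiser-tapered periodograms at 0.5 Hz resolution on
  concatenated motion/immobility segments; spectrograms from 512-ms STFT
  windows with 256-ms overlap, 2-D Gaussian smoothing (sigma = 5 pixels)
  and removal of a log-log power-law fit over 1-100 Hz.

Unstated constants were fixed once and exposed as arguments: 21-sample
first-order Savitzky-Golay windows (a first-order SG smoother evaluated
at the window centre equals the window mean), Kaiser beta = 8, and the
1-100 Hz power-law fit band.

## Hyperpolarization detection

Per trial, the raw dF/F is smoothed and z-scored against the 0.5-s
pre-odor baseline (each trial separately), giving S.  Runs of S < -1
inside the first odor window (tolerating starts up to 20 ms before
onset, the merge tolerance) are merged across gaps under 20 ms; the
earliest merged run is the candidate event, significant iff it lasts
more than 50 ms and holds S < -3 for more than 10 ms in total.  Onset,
duration, trough and minimum S are reported; a fixed-window amplitude
(min S in the first 200 ms) supports low-n comparisons.

The phase-reset statistic is the across-trial circular variance
(1 minus the resultant length) of the instantaneous theta phase at every
sample; a reset appears as a variance dip just after odor onset.

## Field detection and selectivity

Rates are binned at 100 ms over the odor-delay interval (odor 1 onset to
delay end, 6 s), five-point smoothed, z-scored per trial, and split by
first-odor identity.  The observed statistic per odor is the maximum
over bins of the trial-mean rate.  The null circularly shifts each
trial's rate vector independently by a uniform whole-bin offset up to
half the axis, 1000 times; significance requires the observed maximum to
exceed the null's 95th percentile strictly (ties conservative, argmax
ties resolve to the earliest bin).  Cells significant for both odors are
non-odor-specific, with the final bin the mean of the two per-odor bins
when they are closer than 1 s and otherwise the bin of the larger
maximum.  The selectivity index SI = (R_A - R_B)/(R_A + R_B) uses the
smoothed firing rates (Hz) at the field bin; initially odor-specific
cells with |SI| < 0.42 are reclassified non-odor-specific.  Chance
selectivity repeats the formula over 1000 random trial splits.  A
config switch reuses the same detector for extracellular rates (300-ms
Gaussian smoothing) and deconvolved calcium signals (no conditioning).

Because the null is calibrated to 5% per odor, about 5% of genuinely
single-odor cells acquire a spurious second-odor field and are forced
into the non-specific category; the power criterion therefore tallies
those separately rather than counting them against specificity.

## Bayesian decoding of odor-specific time

The decoder works on a doubled time axis: the cell's mean 100-ms rate
template over odor-A trials concatenated with odor-B trials (12 s).  The
first two-thirds of trials train, the last third decode; recordings need
at least 10 trials and 2 training trials per odor.  Per-trial rates are
scaled so each trial's maximum equals the global maximum; bins with no
training activity are dropped.  At step $j$ the decoded bin is

$$\hat T_j = \arg\max_t \; K(t)\,
\frac{(\tau R_m(t))^{s_j} e^{-\tau R_m(t)}}{s_j!}\,
e^{-|t-\hat T_{j-1}|^2 / 2\sigma^2},$$

with $\tau$ = 100 ms, $K$ proportional to training odor frequencies and
$\sigma$ = 3 s.  The continuity factor is implemented with a negative
exponent: the printed source formula carries a positive sign, which
would reward discontinuity and contradicts its own description as a
continuity constraint, so the sign is corrected here.  The first step
omits the continuity term ($\hat T_{-1}$ undefined); normalisation does
not affect the argmax and is skipped; template rates are floored at
1e-6 Hz so the likelihood is defined at silent bins.  Decoded-time error
is the mean absolute within-trial distance (irrespective of odor half);
odor accuracy the fraction of steps decoded into the correct half;
chance baselines come from 500 circular-shift surrogates of each decoded
trial.  `decode_trial()` is proven equal to exhaustive posterior
maximisation on enumerable toy problems.

## Multiday turnover and correlations

For each consecutive tracked session pair: stable = share of day-d
odor-field cells that had a field on day d-1; inflow = the complement;
outflow = share of day-(d-1) field cells that lost theirs.  Cells
tracked over more than two sessions contribute each consecutive pair.
Delay-to-odor-field transitions count as inflow.  Cross-day similarity
is the mean Pearson correlation over all trial pairs of per-trial
z-scored rates, with a cohort-level Spearman trend against session
distance.

## Extracellular companion procedures

LFPs are decimated to 2.5 kHz behind an anti-alias lowpass and notched
at 60/120/180 Hz (2nd-order zero-phase bandstops).  Ripples: 120-200 Hz
bandpass, 10-ms binned RMS, events above 10 s.d. with boundaries at the
2 s.d. crossings (sub-bin interpolated), gaps under 50 ms concatenated
and events under 40 ms discarded.  Units: after a 0.5-Hz rate floor, the
peak-trough distance, peak-trough ratio and mean rate are z-scored,
projected on principal components and split by k-means (k = 2, 100
restarts); the short/fast cluster is labelled narrow (putative
interneuron).  Odor responses: 10-ms rates smoothed by a 50-ms Gaussian
window, averaged over trials, normalised by the 1-s pre-odor baseline of
that average (per-trial normalisation would be undefined for sparse
units), and averaged over the first odor; responses strictly above 1 are
odor-excited, and peak latency before/after 200 ms separates early from
late responders.

## The synthetic world

`generate_cell_session()` states a world rather than tuning one:

* **Subthreshold trace** — a 7-Hz theta oscillation (amplitude 1 dF/F
  s.d. unit with Ornstein-Uhlenbeck amplitude jitter), 1/f noise
  (sd 0.5), white measurement noise (sd 1), and an exponential
  photobleaching drift (tau 50 s, asymptote 0.5).  These reproduce a
  4-10 Hz spectral peak over a pink background without modelling
  conductances.
* **Spikes** — an inhomogeneous Poisson process (per-ms thinning, 2-ms
  refractory) with rate = baseline x field bump x von-Mises theta
  modulation x onset-burst and rebound envelopes x hyperpolarization
  suppression.  Spike waveforms (difference of exponentials with an
  after-hyperpolarization lobe, spanning the de-spiking window) are
  added linearly.
* **Hyperpolarization events** — per-trial Bernoulli occurrences with
  onset ~20 ms after odor onset, duration ~190 ms and amplitude ~-4.5
  baseline s.d. (population means of the phenomenon being emulated),
  injected as a cosine-edged box scaled to the smoothed pre-odor
  baseline s.d. of that very trace, so "amplitude in s.d. units" means
  what the detector measures.  Ground truth records both the nominal
  draw and the event's observable extent (the S < -1 run of the
  noise-free smoothed dip), since the latter is the estimand.  The theta
  oscillator phase snaps to a fixed reset phase at the event trough,
  reproducing the post-onset drop in across-trial phase variance.
* **Multiday** — field status follows a stationary birth-death chain
  (retain with probability `retention_prob`, gain with
  `field_gain_prob`, session 0 drawn from the stationary prevalence).
  Under stationarity the turnover "stable" percentage equals the
  retention probability in expectation, which is what the turnover
  criterion exploits.
* **Ephys** — two unit classes with separable waveform/rate features; an
  LFP of 1/f noise with Gaussian-envelope ripple bursts.  Ripple
  amplitudes are calibrated per event against the post-injection binned
  RMS distribution — including the exactly-known background cross-term
  and the detector's own bandpass response to the short burst — so "a
  ripple at 12 s.d." is a statement about what the detector's statistic
  will see; ground-truth boundaries are where the known filtered burst
  RMS crosses the 2-s.d. level.

What the generator does **not** emulate: shot-noise statistics of
imaging, motion artefacts, cell-to-cell waveform variability, behavioural
correlations between locomotion and spiking, non-Poisson spike-history
structure beyond the refractory period, and drift in event timing across
a session.  A green calibration therefore establishes correctness of the
detectors under the stated statistical structure, not robustness to every
failure mode of real recordings.

## Acceptance battery choices

The acceptance properties are exercised at the protocol's stated sizes
(200 null cells, 100 field cells, 500 trials, 100 sessions, 500 tracked
cells, 25 ripples, 200 units).  Where the protocol leaves a knob open,
the choice and its reason:

* Field-power cells carry 30 trials (recordings span 1-3 sets of 20
  trials; 30 is mid-range) and the injected centre sits on a bin centre
  so "the truth bin" is well defined.
* The phase-reset battery enables a reset on every trial: it probes the
  variance statistic's sensitivity, not occurrence realism (occurrence
  rates are probed separately by the hyperpolarization battery).
* The decoder's "tuned cell" is an idealised strongly time-informative
  unit — a broad (2-s) high-gain field through the odor and early delay
  on both odors, 15 Hz baseline, 45 trials — because beating half of
  chance error requires rate structure that spans the axis; a narrow
  field bounds the achievable mean error near chance regardless of its
  strength.
* The turnover battery reads field status from generator ground truth:
  it scores the turnover arithmetic and the chain's stationarity, not
  field detection (criteria 1-2 cover that).

## Numerical notes and limitations

Zero-phase filtering uses odd-reflection padding with steady-state
initial conditions; traces must exceed three filter lengths.  Circular
shifts in every null wrap within the analysis axis only, preserving
within-trial rate statistics.  Strict inequalities at percentile
thresholds make ties conservative.  Degenerate inputs (zero baseline
s.d., all-zero rates, constant features) raise structured errors or
warnings rather than propagating NaNs.  The de-spiking stand-in matches
local second-order statistics but not the phase structure of the removed
segment, so phase estimates within 12 ms of a spike peak inherit
interpolation bias; spike-phase statistics evaluate the analytic signal
at the spike peak itself, which lies inside the replaced window — at
theta frequencies the bias is small (the band-power criterion bounds it)
but it is not zero.  The SVM odor classifier and population-level
decoding are out of scope.
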