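---
title: "Tracking rhythmic covert attention: models, conventions and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracking rhythmic covert attention}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(attnrhythm)
```

This vignette documents the science implemented by `attnrhythm`: the
encoding model and its inversion, the attentional-vector readout, the
event and rhythm analyses, the oculomotor chain, and — because several
steps admit more than one defensible convention — the numerical choices
the package makes and why.

## 1. The inverted encoding model

Sensor data during the localizer task are modeled as a weighted sum of three
information channels tuned to the angular stimulus positions plus noise:

$$\mathrm{MEG} = W\,C + N .$$

Each channel is a half-wave rectified sinusoid over angular position,

$$f(\theta;\mu) = \bigl|\cos^{\alpha}\!\bigl(0.5\,(\theta-\mu)\,\pi/180\bigr)\bigr|,
\qquad \alpha = 5,$$

with preferred angles $\mu \in \{0^\circ, 120^\circ, 240^\circ\}$ (top,
left, right; $0^\circ$ points up, angles increase counter-clockwise). The
angular difference is wrapped to $(-180^\circ, 180^\circ]$ before
evaluation; $f$ is 1 at the preferred angle, 0 opposite it, and
$0.5^5 = 0.03125$ at the 120° separation of neighboring targets — the
design matrix of the three-position task is therefore nearly, but not
exactly, orthogonal.

**Per-channel estimation.** The weights are fit one channel at a time,
$w_k = \mathrm{MEG}\,c_k^\top (c_k c_k^\top)^{-1}$, exactly as the estimator
is defined, rather than as a joint multichannel GLM. On a correlated design
the two differ: the marginal estimator leaks a small fraction
(of order the 0.03125 off-diagonals) of each channel's pattern into its
neighbors, while the joint pseudoinverse reproduces noiseless data exactly.
Both are available (`fit_weights(..., joint = TRUE)`); the per-channel form
is the default because it is the printed estimator, and the tests bound the
leakage it incurs.

**Noise normalization.** Neighboring sensors are not independent (volume
conduction), so each $w_k$ is pre-whitened with the channel's residual noise
covariance $E_k$ (residuals $\varepsilon_k = \mathrm{MEG} - w_k c_k$):

$$g_k = E_k^{-1} w_k\,(w_k^\top E_k^{-1} w_k)^{-1},$$

which enforces $g_k^\top w_k = 1$ as an algebraic identity — the package
tests this to $10^{-8}$ on every fitted model. $E_k$ is regularized by
shrinkage toward its diagonal with the analytic intensity that minimizes the
expected squared loss of the estimator,
$\gamma = \sum_{i \ne j}\widehat{\mathrm{Var}}(s_{ij}) / \sum_{i \ne j} s_{ij}^2$
clamped to $[0,1]$ (`shrink_covariance()`). Shrinkage strictly reduces the
condition number whenever observations are scarce relative to sensors.

**Training epoch.** Training observations are per-trial sensor vectors
averaged over a training window (default 0.14–0.17 s post stimulus onset,
where decodability peaks). `select_training_epoch()` chooses the window by
leave-one-block-out cross-validation; the held-out decoding score of a trial
is the decoded response of the true-position channel minus the mean of the
other two. That score definition is this package's own (no canonical formula
exists for it); ties break toward the earlier window. Localizer trials with
a detected (micro)saccade in the first 0.2 s, and flicker-task trials, are
excluded from training.

Decision epochs are decoded sample by sample, $C = G^\top \mathrm{MEG}$,
with no temporal smoothing.

## 2. The attentional vector

The three decoded channel responses are summed as planar vectors along their
target directions. Vector length indexes attention strength; the vector
angle the attention locus; and the maximum angular similarity
$\mathrm{MAS} = \max_k \cos(\mathrm{angle} - \mu_k)$ the selectivity for one
alternative. With three equally spaced targets the MAS is bounded below by
0.5, attained exactly midway between two targets — the package's reference
constant, verified both analytically and by brute-force minimization.

Two conventions worth noting:

* **Signed responses.** Negative channel responses flip their
  contribution's direction; they are *not* rectified (a `rectify` flag
  exists for sensitivity analysis). How timepoints with negative responses
  should be treated is genuinely open; the signed sum is the algebraically
  neutral choice.
* **Degenerate angles.** Where the vector length is below $10^{-12}$
  (e.g., exactly symmetric responses) the angle and MAS are flagged `NA`
  rather than letting `atan2` amplify noise.

`zscore_strength()` normalizes the strength trace with one mean/sd pooled
over all trials' stimulus-on samples, so between-trial amplitude structure
is preserved.

## 3. Spectral analysis of attention strength

`bandlimited_amplitude()` implements a filterbank with quarter-octave
center frequencies $2^{1.5} \ldots 2^{6.5}$ Hz (2.83–90.5 Hz), passband
center $\times 2^{\pm 0.5}$, 4th-order Butterworth filters, and the
amplitude envelope as the magnitude of the FFT-based analytic signal. Two
cycles of each center frequency are marked missing at each trial edge; the
missing samples propagate as `NA`, never as zeros.

* Filtering is **zero-phase** (forward–backward, `signal::filtfilt`), so
  the effective order doubles. The alternative — causal filtering — would
  shift event-relative timing by a frequency-dependent group delay; timing
  fidelity matters more here than matching an unspecified convention.
* Baseline normalization divides each frequency by its trial-averaged
  amplitude in a pre-stimulus window and converts to dB as
  $20\log_{10}(r)$ — the amplitude convention, since the quantity being
  normalized is an amplitude envelope; the factor is configurable.

`wavelet_tfr()` provides Morlet transforms with bandwidth
$f/\sigma_f = 5.83$ (half an octave) and the kernel truncated at
$\pm\sigma_t$ — a deliberately short kernel that trades frequency precision
for temporal locality.

`stratified_condition_compare()` contrasts correct and error trials while
matching difficulty: within each contrast-triplet × framing stratum, correct
trials are subsampled to the error count, 100 times by default, and the
average over subsamples enters the percent-change map
$(\text{correct} - \text{error})/\text{correct} \times 100$. Strata whose
error trials outnumber their correct ones cannot be matched and are dropped
with a warning.

## 4. Attentional events and the rhythm

`detect_events()` records an attentional event when MAS and vector length
simultaneously exceed their thresholds: MAS at a percentile (default 90) of
*all stimulus-on samples of the dataset*, vector length at a percentile
(default 90) *within each trial* — the deliberately asymmetric rule.
Conventions the detector must fix:

* **Re-arming.** The onset is a rising edge of the conjunction (both true
  now, not both true one sample earlier) *or* a change of the nearest
  target while the conjunction stays true. Without the second clause a
  sustained suprathreshold excursion spanning a locus change would hide the
  reorientation.
* **Refractory rule.** Onsets within 0.025 s of the previously accepted
  onset are discarded, applied to onsets only.
* **Ties.** Exact similarity ties between targets break toward the
  previously attended locus — conservative against spurious switches.

Events are labelled `stay` or `switch` by comparison with the previous
event's locus in the same trial; the first event of a trial is labelled
`first` and excluded from stay/switch statistics.

**IEI histograms.** Intervals between consecutive onsets within a trial are
binned at single-sample resolution over 0.025–0.5 s. The probability
denominator is the *total* interval count, including intervals longer than
the displayed range: no canonical convention exists for the denominator, and
including the tail keeps probabilities comparable across conditions with
different tail mass.

**Trial-shuffle null.** At every timepoint the set of trials holding the
events observed there is resampled without replacement; per-timepoint event
counts — and hence the task-locked event-rate profile — are preserved
exactly (a tested invariant), while within-trial temporal structure is
destroyed. 1000 randomizations by default; labels are recomputed after each
reassignment so the null is also defined for stay/switch and second-order
classes.

**Modes and cycle length.** The null mean is subtracted, bins not
significantly above the null are zeroed, the truncated difference is
smoothed twice with a 0.01 s boxcar (edges padded to the first/last value),
and local maxima are extracted; the cycle length is the first-to-second mode
latency. One inferential substitution is made for single synthetic
"participants": significance is a one-sided z-test of each bin against its
shuffle-null mean and sd at $\alpha$ (default 0.01), standing in for the
across-participant t-test that requires a cohort. The z-approximation on
near-zero probabilities is slightly liberal, which the null-calibration test
accounts for by bounding the significant-bin fraction rather than expecting
the nominal rate exactly.

**Second-order sequences.** Intervals classed by (previous label, current
label) discriminate two hypotheses: if events passively follow a
free-running oscillation, repetition histograms (stay-after-stay,
switch-after-switch) sit a half cycle away from alternations; if each event
resets the oscillation, the four histograms collapse onto the first-order
ones. The package's tests exercise both regimes of the generator and check
the discrimination on the stay-conditioned classes, which are the cleanly
detectable ones (switch events at free-running troughs ride a lower drive
pedestal and are detected less reliably — an asymmetry the real analysis
would share).

**Threshold sweep.** `threshold_sweep()` re-runs detection over percentiles
{50, 55, …, 95, 97.5, 99} × the same list (144 cells). Per cell, interval
probabilities are log-transformed (zero bins become missing and are bridged
by linear interpolation before smoothing), linearly detrended, smoothed
twice with a 0.025 s (10-sample) boxcar, and the *modulation intensity* is
the standard deviation of the detrended values between the first two local
maxima — near zero for exponential (memoryless) interval statistics, raised
by rhythmic structure. The log-domain statistic is noisy when histograms are
sparse; the tests therefore compare typical (median) null intensity against
planted-rhythm intensity rather than single cells.

**Choice regression.** `choice_regression()` fits one binomial logit per
outcome (chosen vs not) on the six per-trial event counts
({stay, switch} × {high, mid, low value}). Constant predictors are dropped
with a warning; complete separation triggers a ridge-penalized fallback
(`glmnet`, $\lambda = 0.01$, flagged in the result). Group-level
aggregation across participants is left to the caller (`paired_t`,
`fdr_correct`).

## 5. Peri-event analysis

`event_triggered_average()` z-scores each event's ±0.2 s strength trace on
the pooled pre (−0.2…−0.03 s) and post (0.03…0.2 s) samples — the ±0.03 s
peri-event zone is excluded because the event is by construction the local
maximum and would skew the normalization — then averages per label.
`perievent_frequency()` detrends and smooths (0.025 s boxcar) the average
separately within the pre and post intervals (−0.2…−0.05 and 0.05…0.2 s),
takes strict local maxima (plateaus take their leftmost sample; boundary
samples are never peaks), and estimates the dominant frequency as the
inverse of the latency between the *two peaks closest to the event* in each
interval, missing when fewer than two peaks exist. With exactly two peaks
the "average peak-to-peak latency" reduces to a single latency; when more
candidates exist, proximity to the event decides, ties toward the earlier
peak. `pre_post_ratio()` compares raw mean strength around switch vs stay
events in the −0.15…−0.05 and 0.05…0.15 s windows.

## 6. Oculomotor chain

`detect_microsaccades()` computes gaze velocity as the Euclidean norm of the
first difference of (x, y) times the sampling rate (the per-axis-maximum
norm is available behind a flag, as the printed definition is ambiguous),
smooths it with a 0.02 s-sd Gaussian kernel, and thresholds at 6× the
trial's median smoothed velocity. One timing subtlety: zero-phase smoothing
makes the smoothed velocity cross the threshold up to half a kernel before
an instantaneous gaze step, so using the first suprathreshold *smoothed*
sample as the onset would systematically antedate saccades. The package
instead delimits excursions on the smoothed velocity (robustness) and
records the onset at the first sample within the excursion whose *raw*
velocity exceeds the threshold (precision), falling back to the
smoothed-velocity peak if no raw sample crosses. Construction tests show
this recovers planted step onsets to ±1 sample. The displacement used for
the micro (<1°) classification is measured from 0.01 s before to 0.03 s
after onset — a package convention, as only the 1° criterion itself is
given. Detection counts are invariant to offsetting or rescaling gaze
(the threshold is tied to the median).

`event_saccade_coupling()` aligns saccade trains to attentional-event onsets
(±0.3 s), subtracts a trial-shuffled null rate, reports the proportion of
events preceded by a saccade in a stated pre-window (default −0.3…0 s), and
z-scores saccade-triggered attention strength on the 0.4 s before each
saccade. `saccade_split_iei()` classifies each inter-event interval by
whether a saccade onset falls strictly inside it. `normalize_pupil()` maps
the 5th/95th percentiles to 0/1 (values outside may exceed the unit
interval) and differentiates by adjacent-sample subtraction.

## 7. The synthetic-data generator

The generator defines the study conditions under which every downstream
stage is validated; its defaults are fixed, not tuned per analysis.

* **Task design.** `enumerate_design()` reproduces the full factorial:
  2 framings × ordered assignments of a contrast triplet (drawn without
  replacement from 5 linearly spaced levels; 10 unordered triplets) to the
  3 locations × 9 orientation conditions = 1080 unique trials.
  `enumerate_localizer_block()` yields 90 presentations with 9 flicker
  trials per block.
* **Latent process** (`attention_process()`): an 11 Hz strength oscillation
  of depth 0.5. Stay events sit at oscillation peaks, integer cycles after
  the previous event; switch events at troughs, half-integer cycles after
  (switch probability 0.37). Occasional extra cycles (geometric
  within-cluster skips plus Poisson-distributed longer gaps, mean 4 cycles,
  probability 0.35) make the trains bursty — clusters of short intervals
  separated by pauses — at an overall rate of roughly 4 events/s, while
  keeping every interval phase-locked. Event-timing jitter (sd 2.5 ms,
  truncated at 3 sd) keeps planted events within 10% of a cycle of their
  nominal phase. With `reset_on_switch = TRUE` the phase restarts at its
  peak at every event; with `FALSE` it free-runs, making interval structure
  history-dependent — the two regimes the sequence analysis must
  discriminate.
* **Signal model.** Channel drive = constant baseline on all channels
  (cancels in the vector sum) + the oscillation on the attended channel
  (gain 1.5) + a brief Gaussian burst (amplitude 3, sd 5 ms) on the event's
  channel + white drive noise (sd 0.5) on every channel. The drive noise is
  *attentional* variability, deliberately separate from sensor noise: the
  decoded angle must wander between events even when sensors are noiseless,
  otherwise the MAS saturates and its percentile threshold degenerates. The
  burst-to-oscillation balance matters: if the oscillation pedestal rivals
  the bursts, un-bursted oscillation peaks cross the percentile thresholds
  and contaminate event timing. Sensor data = orthonormalized random
  patterns × drive + correlated Gaussian noise of sd 1/SNR.
* **Gaze.** Fixational jitter is low-pass-filtered Gaussian noise rescaled
  to 0.05° — temporally smooth, as white per-sample position noise would
  give a velocity floor that blinds any multiple-of-median detector.
  Background saccades (1 Hz, amplitudes 0.3–0.8°, three-sample ramps) keep
  a 0.15 s serial-delay floor, matching the empirically late inter-saccade
  interval mode; coupled saccades precede a fraction *p* of switch events
  by 0.15 s. The pupil is a slow smooth drift.

**What the generator does not emulate** — and hence what green tests do
*not* establish about real recordings: 1/f sensor noise and line noise
(noise is white or a fixed SPD covariance, per-trial stationary), evoked
stimulus transients and their alpha suppression, head movement, artifacts
(blinks, muscle), source-space structure, between-participant variability,
and any behavioral reaction-time process. Parameter recovery here shows the
*pipeline* is correct, not that real data satisfy the model.

## 8. Problem sizes and determinism

The validation suite uses problem sizes chosen to make the statistics
stable: 500 simulated decision trials (4.3 s epochs at 400 Hz, 16 sensors)
for the rhythm-recovery check with the full 1000-shuffle null, 300 trials
per phase-policy regime for the sequence discrimination, 200–400 trials for
null calibrations, and 80–150 trials for unit-level recovery. All
randomness flows through explicit integer seeds; shuffle nulls are
bit-reproducible given the seed.

## 9. Known limitations

* Sample-resolution histograms need the event-rich regime the generator
  provides; with sparse events the log-domain modulation intensity is noisy
  and mode detection benefits from pooling (as the across-participant
  analysis would).
* The per-bin z-test against the shuffle null is a single-session
  substitute for cohort-level inference and is mildly liberal at very small
  probabilities.
* The detector's percentile thresholds adapt to whatever trace they are
  given; they mark the top decile of engagement, so planted events can only
  be recovered completely when their rate × duration stays below that
  decile — a property of the method, not an implementation artifact.
* Generalization beyond three angular channels is implemented but untested
  against any reference.
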