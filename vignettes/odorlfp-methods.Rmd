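---
title: "Methods: value coding in olfactory-bulb LFP band power"
author: "odorlfp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: value coding in olfactory-bulb LFP band power}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The experimental design this package models

A water-restricted mouse pokes into an odor port; 1–1.5 s after port entry
one of two odorants is delivered for 2.5 s. If it is the rewarded odorant
(S+) the mouse must lick the water spout at least once in each of four
consecutive 0.5 s intervals to receive water; for the unrewarded odorant
(S−) it withholds licking. Odorants are presented in randomized 20-trial
blocks of 10 S+ and 10 S−, performance is scored as percent correct in
20-trial windows, and a mouse counts as *proficient* once it reaches 80%
correct over the final 40 trials in at least two sessions. LFPs are recorded
continuously from a multi-electrode implant in the olfactory bulb;
optogenetic experiments add a laser pulse spanning 3.5 s from port entry,
delivered in animals that either do (opsin) or do not (control) express an
inhibitory opsin in noradrenergic fibers.

Everything downstream is built on one per-trial statistic and one
classification measure, described next.

# Δ power

For each electrode the package computes a sliding-window short-time power
spectral density: 1 s windows (1 Hz resolution), Hann taper, 0.1 s step by
default, expressed as 10·log₁₀(PSD) with a floor at −120 dB so silent
channels stay finite. PSD scaling is one-sided with window-power
normalization, so integrating the linear PSD over frequency recovers the
signal variance (checked by a Parseval test).

**Δ power** for a trial, electrode, and band is the mean of the dB values
over time bins in the 2 s odorant window minus the same mean over the
baseline window 2.1–0.6 s before odorant onset. Averaging is done **on the
dB scale**; a linear-scale average is not what the definition above says,
and dB averaging is also what makes Δ power exactly invariant to any
constant gain applied to the signal (the gain cancels in the subtraction).

Numerical conventions, stated because they matter at the edges:

* A time bin belongs to an interval iff its **window center** lies in the
  half-open interval `[start, end)`. Consequently windows centered just
  after odorant onset extend up to 0.5 s *before* onset, and the latest
  baseline windows extend up to 0.1 s *after* the baseline bound. For an
  instantaneous power step this dilutes the recovered step by roughly
  0.2–0.4 dB of its programmed 6.02 dB — visible in the worked examples,
  and inside every tolerance used in the tests. Alternative rules
  (full-window inclusion) shrink the usable bin count sharply at these
  window lengths; the center rule is the default and the windows are
  configurable.
* The step defaults to 0.1 s; any step up to 0.25 s gives the same results
  to within the test tolerances, and the heavier simulation studies in the
  test suite use 0.25 s.
* Hann is the default taper (Hamming is available via an argument); with dB
  averaging and band-mean statistics the choice is immaterial at the 0.1 dB
  level.
* Input sampled above 1 kHz is decimated (anti-aliased FIR) to 1 kHz before
  spectral analysis — all analysis bands lie at or below 95 Hz.
* Band-pass filtering (used for theta phase, not for Δ power) is an
  order-4 Butterworth applied forward and backward (`filtfilt`), i.e.
  zero-phase; its stability and ≥40 dB stopband attenuation one octave out
  are asserted by tests.

# Recentered auROC and its inference

Classification of S+ vs S− (or Hit vs CR, FA vs CR) from per-trial Δ power
uses the area under the empirical ROC curve, recentered by −0.5 so that 0 is
chance and ±0.5 is perfect separation in either direction. It is computed
from the Mann–Whitney U statistic with midranks, so ties get half credit —
and computed *directly* on the centered scale, which makes the antisymmetry
`auroc(A, B) = −auroc(B, A)` exact to the last bit (this antisymmetry is the
mechanism behind the reward-reversal analysis). The recentered auROC is
invariant under any strictly monotone transform of the scores.

Significance is a two-sided z-test, `z = auroc / SE`, with the
Hanley–McNeil variance of the uncentered area. At perfect separation that
variance degenerates to zero; the implementation then falls back to the
exact Mann–Whitney tail `2/C(n₁+n₂, n₁)` rather than dividing by zero. All
scores identical gives auROC 0 and p = 1 with a warning. The z-test is a
large-sample approximation; its null calibration is itself checked by
simulation in the test suite rather than assumed.

Multiple comparisons across an electrode family use the Benjamini–Hochberg
step-up rule. The implementation reports `p_fdr`, the largest p-value
declared significant, because that threshold is how results of this kind
are customarily reported; the significance mask is cross-checked against
`p.adjust(..., "BH")` in the tests. Families are defined per band across
all electrodes of a condition and are configurable.

Hit/CR/FA comparisons use d′: Δ power divided by the unweighted mean of the
per-class standard deviations, which is exactly invariant to positive
rescaling of the signal.

# Resampling statistics

* **Permutation ANOVA** (epoch and session comparisons): the observed
  one-way F is compared with its distribution under random relabelings;
  `p = (1 + #{F* ≥ F}) / (1 + n_perm)` (add-one rule, never zero, valid
  under exchangeability). For two groups an exhaustive mode enumerates all
  assignments; the 5-vs-5 disjoint case gives p = 2/252 exactly. The default
  permutation count is 10,000; the type-I-error simulation in the test
  suite uses 399 permutations, at which `p ≤ 0.05` corresponds to exactly
  the 5% tail for a continuous statistic.
* **Interaction ANOVA** (genotype × laser): two-way fixed-effects ANOVA,
  analytic interaction F by default, with a residual-permutation variant
  (shuffling residuals of the additive model) for small samples. The
  interaction F is invariant to adding arbitrary main effects.
* **Chi-squared** on two proportions (percent-significant contrasts),
  without continuity correction by default; degenerate tables (pooled
  proportion 0 or 1) return χ² = 0, p = 1.
* **Rank-sum / paired t** for behavioral contrasts; a paired test on
  identical vectors returns statistic 0, p = 1 rather than an error.

A deliberate and documented limitation, shared with the experimental
literature this models: electrodes from one animal are pooled as
observational units, which pseudoreplicates with respect to animals. The
generator is constructed so that electrodes are at least exchangeable
units (see below).

# Lick-aligned analysis

Lick onsets come either from an event list or from a contact signal
(half-range threshold, rising edge), with a 70 ms debounce. The
lick-triggered average (LR-LFP) is the mean of raw-LFP snippets over lags
−0.5 to +0.5 s around each onset, with a percentile bootstrap 95% band from
resampling licks (not time points), 1000 replicates, seeded. Theta phase of
a lick is the angle of the analytic signal (FFT Hilbert) of the zero-phase
theta-filtered LFP at the onset sample; phase 0 sits at the oscillation
peak and increases with time. Zero-phase filtering is what makes the phase
estimate delay-free: shifting LFP and licks together leaves it unchanged
(tested).

**LR-LFP Δ power** extends the Δ power idea to lick-locked signals: per
trial, average the LFP over the trial's odor-window lick onsets, take the
sliding-window spectrogram of that average (0.5 s windows — the trace is
only ~1 s plus margins), read off band power at a chosen lag from lick
onset (0.3 s by default), and subtract the same quantity computed from
baseline alignment events in the pre-odorant window.

The baseline and the no-lick trials are the genuinely open design choice
here, because trials where the animal correctly withholds licking (CR) have
no alignment events, yet the Hit/CR contrast needs them. The package's
convention, isolated in one function:

* baseline events are theta-peak times in the baseline window, offset by
  phases resampled from the trial's own lick phases, and **count-matched**
  to the odor-window events;
* lickless trials use surrogate odor-window events built the same way from
  the session-wide lick phase distribution, thinned to the median per-trial
  lick count.

The count matching and phase matching make the subtraction compare
like with like: a locked average over n events carries an averaging-noise
power term that scales as 1/n and a coherent term that scales with the
alignment sharpness, and if the two classes are aligned on events with
different statistics, those terms masquerade as an odorant effect. With raw
theta-peak surrogates the null Hit/CR auROC sat around +0.12; with
like-for-like surrogates it is statistically indistinguishable from zero
(the test suite asserts the averaged null and the recovery of a programmed
lick-locked theta effect).

ΔauROC profiles ((laser − pre) change in opsin animals minus the same
change in controls, per band and lag) are computed from per-electrode auROC
tables with a bootstrap CI over electrodes, the interaction ANOVA p per
cell, and FDR over the band × lag grid. Swapping genotype labels negates
the profile exactly, and identical genotype groups give exactly zero.

# The synthetic-session generator

`simulate_session()` produces sessions whose statistical structure matches
the design above, with every effect a parameter:

* **Trials**: randomized 20-trial blocks (10 S+/10 S−), onset uniform in
  [1.0, 1.5] s after port entry, 2.5 s odorant, one trial per 6 s slot so
  that every baseline window is clean of the previous trial's effect.
* **Behavior**: the response is drawn from a programmable per-trial
  accuracy `p_correct` (scalar, vector, or function — a learning curve);
  go responses produce theta-locked lick trains over the 2 s response
  window, with at least one lick forced into each 0.5 s criterion interval
  so the programmed response *is* the classified outcome; no-go responses
  produce no licks. False alarms produce S+-like lick trains.
* **LFP**: per electrode, 1/f background (spectral synthesis, default
  exponent 1, 10 µV RMS) plus four band-limited oscillators (FFT-masked
  Gaussian noise; default RMS 20/15/10/8 µV for theta/beta/low-/high-gamma)
  whose amplitude steps by the realized per-trial dB change over the 2.5 s
  odorant interval with 100 ms cosine ramps. The ramps prevent the spectral
  splatter an abrupt gate would spread across bands (a rectangular-gated
  band oscillator measurably leaks into distant bins; the ramped one does
  not — both facts are exercised in the tests).
* **Effects**: per band, a (S+, S−) pair of dB changes, optionally scaled
  per trial (learning ramps), locked to value, identity, or response, and —
  on laser trials — the S+/S− *contrast* is multiplied by a per-genotype
  factor (`control` fixed at 1, `opsin` default 0, i.e. complete silencing
  of the value contrast). Trial-to-trial variability of the evoked change
  (`effect_sd_db`, default 2 dB) is drawn **independently per electrode**:
  a shared draw would correlate the per-electrode auROCs and make any test
  that treats electrodes as observations anti-conservative under the null,
  so exchangeable electrodes are a deliberate property of the study
  conditions, not an accident.
* **Theta and licking**: one frequency-modulated theta oscillator (8 Hz
  center, slow jitter) is shared by the whole session; it drives lick
  timing and enters every electrode's theta component at weight 0.7
  alongside electrode-specific narrowband noise. Full sharing would make
  theta-band p-values degenerate across the FDR family; zero sharing would
  break the lick–theta locking the lick-aligned analysis is built to
  detect.
* **Lick trains**: one candidate lick per theta cycle, thinned to the
  target rate (7 Hz default), phase offset drawn von Mises around the theta
  peak with concentration `theta_lock_kappa` (default 2, resultant length
  ≈ 0.70), 70 ms refractory. The thinning probability is corrected by a
  small Monte-Carlo estimate of the refractory collision rate so the
  realized rate matches the requested one. For `kappa < 0.5` — essentially
  unlocked licking — the generator switches to a refractory renewal process,
  which has exactly the requested rate and exactly uniform phases; the
  cycle-based construction with refractory dropping would bias both.

Identical seed and configuration reproduce the session byte for byte.

What the generator deliberately does **not** emulate: biophysical
olfactory-bulb circuitry, a respiration signal distinct from theta,
cross-frequency coupling, spike activity, inter-animal variance structure
beyond electrode gains, or artifacts (movement, line noise). Passing the
recovery tests therefore demonstrates that the *statistics* do what they
claim under the stated generative assumptions — not that any particular
biological claim holds in real recordings.

# Epochs, pipelines, and problem sizes

Epoch conventions follow the task's figure-level analyses: naive = first 30
trials of the first session, proficient = last 30 of the last session,
pre-laser = last 20 of the last no-laser session, laser = first 20 of the
first laser session; all counts configurable, and sessions shorter than the
requested epoch are an error, never a silent truncation. Percent correct
uses a trailing 20-trial window (a centered variant would shift the curve
by half a window; trailing matches how the criterion is applied online
during training), with the disjoint block summary also available.

The simulation studies in the test suite and the acceptance script run at a
250 Hz sampling rate with 40–60-trial sessions and 1–96 electrodes. 250 Hz
comfortably exceeds twice the highest analysis frequency (95 Hz), and at
these sizes the full suite runs in minutes on one CPU; the sampling rate is
an ordinary config field (`sampling_rate_hz`), so higher-fidelity runs are
a parameter change, and the session-format reader accepts any rate at or
above 200 Hz (higher-rate input is decimated for spectral analysis).

# Known limitations

* The z-test for auROC is asymptotic; for very small trial counts the
  permutation ANOVA is the more defensible tool, and both are provided.
* Electrode pooling pseudoreplicates across animals (see above); a
  per-mouse aggregation path exists in the opto behavioral comparison but
  the LFP statistics deliberately mirror the field's per-electrode usage.
* The LR-LFP baseline construction is a convention, stated and isolated; a
  different surrogate scheme would change per-trial values (though not the
  null behavior, which is what the tests pin down).
* The spectrogram offers one taper family and no multitaper or wavelet
  estimators; band definitions are fixed by the four canonical bands but
  arbitrary bands can be passed anywhere a band table is accepted.
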