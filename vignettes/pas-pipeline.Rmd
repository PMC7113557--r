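---
title: "Modeling closed-loop PAS assessment of corticospinal plasticity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling closed-loop PAS assessment of corticospinal plasticity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pasrat)
```

## The experiment being modeled

Paired associative stimulation (PAS) delivers repeated pairs of stimuli - one
to the motor cortex, one to a target muscle - at a fixed interstimulus
interval (ISI), with the aim of driving Hebbian spike timing-dependent
plasticity (STDP) at the synapses of the corticomotor pathway. In a freely
behaving rat with chronically implanted cortical and intramuscular
electrodes, corticomotor excitability is assessed before and after PAS with a
*closed-loop probe*: cortical stimulation is triggered in real time whenever
the rectified-EMG peak envelope sits in a prescribed activity window, so that
motor evoked potentials (MEPs) are always collected at comparable, low levels
of voluntary activation. The analysis endpoint is the normalized MEP ratio
(each post-PAS probe measure divided by the mean of the three pre-PAS
measures), analyzed with a repeated-measures mixed-design ANOVA.

`pasrat` is a synthetic re-implementation of this entire pipeline. Because
the plant's plasticity is configurable ground truth, both a *null world* (no
STDP, in which the pipeline should report nothing) and *STDP-positive
counterfactuals* (in which it should recover the programmed effects) can be
exercised and tested end to end.

## The corticospinal plant

The latent state ([plant_state()]) holds two dimensionless synaptic gains,
`g_spinal` and `g_cortical`, whose product scales the expected MEP size, plus
the conduction latencies and signal-generator parameters.

**Conduction latencies.** Defaults follow the measured physiology of the rat
forelimb system: 9 ms from cortical stimulus to the motoneurons (including
synaptic integration), 3 ms between motoneurons and muscle (used for both
efferent and antidromic conduction), 16 ms from muscle stimulus to the
evoked-potential extremum in motor cortex, and 12 ms from cortical stimulus
to MEP onset. The constructor enforces the consistency identity
`12 = 9 + 3`; both the spinal and the cortical evoked potentials are modeled
as negative-going deflections (troughs), as observed in the acute recordings.

**STDP rule.** `stdp_delta(dt, w)` is the canonical double exponential:
`+A⁺·exp(-dt/τ⁺)` for pre-before-post (`dt > 0`), `-A⁻·exp(dt/τ⁻)` for
post-before-pre. The two branches are discontinuous at zero in general; we
return 0 at `dt = 0` (simultaneous arrival has no consistent order). Updates
are additive per pair by default, with a multiplicative variant behind a
switch; nothing in the analysis depends on the choice, and additive makes the
n-pair update equal a closed form that the tests check against an explicit
loop. A per-cortical-pulse depression term (default 0, i.e. off, so the null
world is exactly null) can emulate the LTD-like trend of slow repetitive
cortical stimulation.

**EMG synthesis.** The generator emits white noise scaled by a behavior-state
envelope (rest, low contraction, strong contraction; state multipliers 1, 2
and 12 times the 10 uV baseline SD). The carrier is *uniform* (compact
support, unit variance) rather than Gaussian, a deliberate choice: the
trigger floor is `mean + 2 SD` of the rectified baseline, which for a
Gaussian carrier (~2.0 sigma) lies *below* the upper peak envelope of the
baseline itself (~2.2 sigma), so a Gaussian-noise plant would fire the
closed-loop probe spuriously at rest. With a crest-limited carrier the
resting peaks are bounded at sqrt(3) sigma = 1.73 sigma, strictly below the
1.87 sigma floor, reproducing the empirical behavior of the preparation - the
probe fires during contractions, never at rest. The analysis consumes only
envelope statistics and rectified areas, which are insensitive to the carrier
distribution. Low contractions land mid-window; strong contractions exceed
the 12 SD ceiling and are (correctly) vetoed.

**Evoked responses.** The MEP is a biphasic single-period sine of 8 ms
duration with onset exactly at the configured latency, so onset detection on
noise-free averages recovers 12.0 ms to within one sample. Evoked potentials
are raised-cosine deflections centered at their latencies. Single-trial
amplitudes are lognormal with unit mean; the coefficient of variation depends
on the behavior state at stimulation time, and the constructor enforces
CV(low contraction) <= CV(rest) - the stated rationale for probing during low
contraction. Lognormal keeps amplitudes positive.

**What the generator does not emulate.** Motor-unit structure,
volley collision at very short ISIs (the two pathways are treated as
independent), polysynaptic temporal dispersion, volume conduction, and
electrode impedance. Tests passing on this plant therefore validate the
*pipeline* - triggering, quantification, design calculus, statistics - not
biophysical realism of the signals.

## The closed-loop trigger

The activity estimate is the upper peak envelope: local maxima of the
rectified trace, thinned so each retained maximum is the largest within the
trailing 32-sample window, connected by interpolation and sampled at the
input rate. We use a shape-preserving piecewise-cubic Hermite interpolant
rather than a global spline: it is local (each segment depends only on
adjacent maxima), which keeps the envelope causal up to a short lookahead
horizon - truncating the input a few windows after the k-th trigger provably
leaves triggers 1..k unchanged, a property the tests assert. Degenerate
inputs (shorter than one window, or fewer than two maxima, e.g. a constant
signal) fall back to the rectified input.

A stimulus is emitted at the first instant at which the envelope (i) has
remained *continuously* within `[mean + 2 SD, mean + 12 SD]` of the rectified
baseline for at least 50 ms - brief dropouts reset the clock, and excursions
above the ceiling veto the trigger, since the window is two-sided; (ii)
entered the window on a rising phase, operationalized as a non-negative
first difference at entry (the intent is to stimulate as contraction is
being initiated, not while the muscle relaxes from a larger one; no formula
exists for this, so entry slope is our reading); and (iii) at least 1 s has
elapsed since the previous stimulus. A probe ends at 30 stimulations or
5 min, whichever comes first. The baseline (mean and SD of the rectified
signal over a 2 s fully relaxed window) is recalibrated per session, never
within one. A brute-force reference that evaluates all three conditions at
every sample independently is kept in the test suite as an oracle.

## ISI timing calculus

With cortical stimulation at t = 0 and muscle stimulation at t = ISI
(positive ISI = muscle after cortex), arrival times are: orthodromic volley
at the motoneurons at 9 ms; antidromic volley at ISI + 3 ms; afferent volley
in cortex at ISI + 16 ms. Hence

- spinal offset = (ISI + 3) − 9  (positive if orthodromic arrives first),
- cortical offset = −(ISI + 16)  (positive if the afferent arrives before
  cortical stimulation).

Both are affine in the ISI with slopes +1 and −1. An exhaustive scan over
ISI in [−600, +600] ms confirms the structural consequence: no ISI is
predicted to produce LTP at both sites simultaneously (LTP at the spinal
site needs ISI > 6; at the cortical site ISI < −16), the opposing-plasticity
property of this pathway. The experiment tested 11 ISIs, of which only −15,
+6 and +505 ms are documented; [default_isi_list()] ships a plausible
*reconstruction* spanning spinal offsets of about −31 to +15 ms plus
cortically relevant timings. It is fully overridable and no test or
acceptance quantity depends on the reconstructed values. Synaptic
integration time is folded into the 9 ms cortex-to-motoneuron latency, with
no separate parameter.

## MEP quantification

Trials are peri-stimulus segments (−50 to +100 ms). Manual trial review is
replaced by automated screening rules: a pre-stimulus RMS ceiling (default
4x the cohort median over −50..−5 ms) and an amplitude-saturation ceiling
flag artifacts; an optional response floor flags signal-free trials. Trials
are flagged, never removed, and excluded trials never contribute to
measures.

Three measures are implemented over a response window (default 8-30 ms,
bracketing the 12 ms onset; the real experiment tailored windows per muscle,
which are not documented, so the window is per-muscle configuration): (1)
mean peak-to-peak amplitude; (2) mean of per-trial rectified integrals; (3)
integral of the pointwise average of rectified trials. Methods 2 and 3 are
algebraically identical (both linear in the rectified trials); both are kept
and their exact equality is asserted as a standing guard on the
implementation. Integration is trapezoidal at the native sampling rate
(exact for piecewise-linear reconstructions). Filtering is the zero-phase
acquisition cascade (50-1000 Hz bandpass + 60 Hz notch + 10 Hz high-pass for
EMG; 1-300 Hz + notch for LFP); zero phase preserves latencies, and the
amplifier gain is metadata, not a rescaling.

## Experiment orchestration and statistics

A session is three 5 min pre-probes (10 min apart), PAS (300 pairs at
0.5 Hz, ~10 min, at 1.25x cortical / 1.5x muscle motor threshold; thresholds
are defined operationally as the minimal intensity giving a response more
than half the time and recovered by a bisection staircase with 20 trials per
level), then three post-probes at 2, 17 and 32 min after PAS. Sessions with
a zero-kept-trial probe are flagged and excluded downstream. The design is a
randomized block (independent permutation per rat), with support for
appending a late-added condition for a subset of subjects.

The analysis model is the study's: normalized ratio ~ CONDITION * SESSION
with a random rat intercept, REML estimation, type-III F tests with
Satterthwaite denominator degrees of freedom (the fractional denominator dfs
reported by the original analysis indicate some such approximation; the
exact method is not documented, so Satterthwaite is our default and is named
in the output).

Two statistical properties of the *normalization itself* surfaced during
validation and are worth knowing:

- Each post measure is divided by the *shared* mean of the three pre
  measures. This induces (a) a small Jensen bias (E[ratio] ~ 1 + CV^2/3 ~
  1.014 at the default probe CV of 0.2) and (b) a record-level correlation
  among the three ratios of a session. Under the rat-only random-effect
  model this correlation makes the between-records CONDITION test
  anticonservative and the within-record SESSION and interaction tests
  conservative in the end-to-end simulation. Type-I calibration of the test
  is therefore checked against a model-matched null world
  ([simulate_null_records()]: ratio = 1 + rat effect + i.i.d. noise), where
  all three terms reject at ~5%; the end-to-end null world is separately
  checked to be centered at ratio 1.
- The carryover analysis correlates within-session change (post/pre, day N)
  with next-day baseline change (pre(N+1)/pre(N)). The two share the day-N
  baseline denominator, so even a memoryless plant produces a positive raw
  correlation (regression to the mean). The null behavior of the statistic
  is therefore tested on constructed records with genuinely independent
  ratios. Consecutive-day pairs are excluded whenever stimulation
  parameters changed between the days, and the correlation is recomputed
  after 5% per-tail winsorization (the original level is not documented).

## Numerical choices and reduced problem sizes

Sampling rates default to 5 kHz (EMG) and 1 kHz (LFP); neither is documented
for the original acquisition, so both are configurable, and all latency
checks are asserted to within one sample period. Onset detection reports the
last sample before the averaged rectified trace exceeds 5% of its peak;
evoked-potential latency is the extremum of the median-centered average.
Gains are clamped to a tiny positive floor after updates. Simulation studies
in the test suite use reduced problem sizes chosen to keep the full suite
fast while leaving comfortable statistical margins: 10-30 s probes for
waveform-fidelity sessions, 500 replicates for null calibration, 200
measure-fidelity sessions (4 conditions x 50 subjects) for ground-truth rank
recovery, and 40 replicates at a large programmed effect (net gain ~1.5) for
power, where rejection exceeds 80%.

## A worked pass through the pipeline

```{r example, eval = FALSE}
st <- plant_state(rng_seed = 1L)
cfg <- calibrate_trigger_config(st)
probe <- run_probe(st, cfg)
measure <- quantify_mep(screen_trials(probe$trials))

tab <- build_condition_table()
des <- randomize_design(9, tab, seed = 1)
rec <- simulate_experiment(des, tab, stdp_window(0, 0), seed = 1)
fit_mixed_anova(rec)
carryover_analysis(rec)
```

Under the null window the ANOVA returns non-significant terms (the package's
analogue of the original null result); replacing `stdp_window(0, 0)` with a
positive window makes the programmed conditions detectable, which is the
STDP-positive counterfactual the pipeline exists to exercise.
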