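# pasrat

Paired associative stimulation (PAS) pairs a motor-cortex stimulus with a
muscle stimulus at a fixed interstimulus interval (ISI), aiming to drive
Hebbian spike timing-dependent plasticity (STDP) of the corticospinal
pathway. Whether this works in a freely behaving animal is assessed with a
closed-loop probe: cortical stimulation is triggered whenever the rectified
EMG peak envelope has stayed within 2-12 SDs above the resting baseline for
at least 50 ms on a rising contraction (minimum 1 s between stimuli; a probe
ends at 30 stimulations or 5 min), and the evoked MEPs are quantified and
normalized against pre-intervention baselines.

`pasrat` is a synthetic, fully testable re-implementation of that entire
experiment for computational neurophysiologists who want to study the
pipeline itself: a corticospinal plant with ground-truth spinal and cortical
synaptic gains and configurable STDP, the EMG-controlled trigger, MEP
screening and quantification, the ISI-to-synaptic-timing design calculus,
and the repeated-measures mixed-model analysis. Because plasticity is a
programmable parameter, the pipeline can be run in a *null world* (no
plasticity - the analysis should find nothing) and in *STDP-positive
counterfactuals* (the analysis should recover the programmed effects).

## The model in brief

Per stimulus pair, a synaptic gain changes by the STDP rule

    dw(dt) = +A+ exp(-dt / tau+)   dt > 0  (pre before post)
             -A- exp(+dt / tau-)   dt < 0
             0                     dt = 0

evaluated at the timing offsets implied by the ISI and the conduction
latencies (9 ms cortex-to-motoneurons, 3 ms motoneuron-muscle, 16 ms
muscle-to-cortex afferent, 12 ms cortical-stimulus-to-MEP-onset):

    spinal offset   = (ISI + 3) - 9
    cortical offset = -(ISI + 16)

Expected MEP size scales with `g_spinal * g_cortical`; the analysis endpoint
is each post-PAS probe measure divided by the mean of the three pre-PAS
measures, modeled as `ratio ~ CONDITION * SESSION + (1 | rat)` with REML and
type-III Satterthwaite F tests.

## Worked example

```r
library(pasrat)

st  <- plant_state(rng_seed = 1L)          # ground-truth preparation
cfg <- calibrate_trigger_config(st)        # 2 s resting baseline calibration
probe <- run_probe(st, cfg)                # one closed-loop 5 min probe
probe$log
#> trigger_log: 30 triggers, terminated by stim_quota
#>   min inter-trigger interval: 1.000 s
quantify_mep(screen_trials(probe$trials))
#> mep_measure [integral_of_average]: 1.1909 uV s over 8-30 ms (n = 30 trials)

isi_to_offsets(c(-15, 6, 505))             # timing design calculus
#>   spinal_offset_ms cortical_offset_ms
#> 1              -21                 -1
#> 2                0                -22
#> 3              499               -521

tab <- build_condition_table()             # 11 ISIs + 4 controls = 15 rows
des <- randomize_design(9, tab, seed = 1)  # 9 rats, randomized block
rec <- simulate_experiment(des, tab, stdp_window(0, 0), seed = 1)  # null world
fit_mixed_anova(rec)
#> Mixed-effects ANOVA on normalized MEP ratios (type III, REML, Satterthwaite ddf)
#>                 term df_num df_den     F     p
#>  session x condition     28    352 0.480 0.989
#>            condition     14    352 1.506 0.106
#>              session      2    352 0.198 0.820
```

The probe delivered its full 30-stimulation quota without ever violating the
1 s refractory period; the closed-loop trials average to a ~1.2 uV s
rectified MEP integral; and with plasticity disabled the mixed ANOVA finds
no condition, session, or interaction effect - the null world behaves like a
null experiment. Passing `stdp_window(a_plus = 2e-3, a_minus = 0)` instead
programs a ~1.5x potentiation at spinal-LTP timings, which the same analysis
then detects.

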