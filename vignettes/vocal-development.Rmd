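---
title: "Self-organizing vocal development by competence-progress goal babbling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Self-organizing vocal development by competence-progress goal babbling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

`vocadev` simulates an agent that learns to vocalize by curiosity-driven
goal babbling. One vocalization lasts 800 ms and is driven by two 9-dim
motor commands (seven articulatory positions in [-3, 3], glottal pressure
and voicing in [-1, 1]): the first command acts from 0 to 250 ms, the
second from 250 to 800 ms, so the policy space *M* is 18-dimensional. Each
motor dimension follows the overdamped spring-mass law

x'' + 2 zeta omega0 x' + omega0^2 (x - m) = 0,

with zeta = 1.01 and omega0 = 2 pi 0.8 rad/s, solved in closed form per
segment with state continuity at the switch. Commands far from the current
state are undershot, and the end state depends on both commands
(coarticulation).

A surrogate articulatory synthesizer maps each instantaneous configuration
to acoustics through an area function: 20 tube sections whose areas are an
affine function of the seven articulators around a positive neutral
profile. The first basis column is a jaw/lip-constriction axis calibrated
so the tract closes exactly at art1 = 1 with the others neutral; columns
2-3 are tongue-body shifts and 4-7 progressively smaller local
deformations. Phonation occurs iff pressure > 0, voicing > 0 and the tract
is open; when phonating, the two lowest resonances of the lossless
concatenated-tube chain (closed at the glottis, open at the lips; computed
by characteristic-function sign scan plus bisection, exact for uniform
tubes against the quarter-wave series) are scaled affinely onto [-1, 1]
from F1 in [200, 1000] Hz and F2 in [500, 3000] Hz. Without phonation the
formants are set to 0.

Perception averages the phonation indicator and the scaled formants over
two 150 ms windows (250-400 and 650-800 ms), yielding the 6-dim outcome
s = [I1, I2, F11, F12, F21, F22], to which i.i.d. Gaussian observation
noise (sd 0.01) is added. Window phonation levels classify each command
into phone types (V above 0.9, N below 0.1, C between), the pair into 9
vocalization types, and the types into 3 classes: `no_phonation` (NN),
`unarticulated` (VN, NV, CN, NC), `articulated` (VV, VC, CV, CC).

The agent learns a joint 28-component Gaussian mixture over the
24-dimensional (m, s) space, updated by incremental EM every 400
vocalizations with a learning rate decaying logarithmically from 0.1 to
0.01 over the planned run. Inverse control is Bayesian conditioning,
G(M | s_g), followed by sampling and clipping to the motor ranges. Goals
come from a 6-component interest mixture fit on recent (time, goal,
competence) records, where competence is exp(-||s_g - s||); each
component's weight is biased by its time-competence covariance (its
empirical competence progress), components with non-positive progress are
suppressed by a negligible factor (1e-6), and the goal marginal of the
biased mixture is sampled. In strategic runs a 0/1 strategy coordinate
(autonomous exploration vs social guidance) joins the interest space; when
social guidance is drawn the goal is replaced by a random demonstration
from the ambient-language teacher (emulation).

## Design choices where the design was open

**Pressure/voicing onset (`pv_onset = "command"`).** The articulators start
each vocalization at the neutral position 0; the source states only this
for articulators. We treat pressure and voicing as fast glottal/respiratory
parameters that hold their first command value from onset, rather than
relaxing from their -0.25 resting value through the articulator dynamics.
With the relaxation variant (available as `pv_onset = "neutral"`), the
first-window intensity is almost never close to 1 (the parameters cross
zero mid-window), the initialization produces no vowel-like examples for
the interest model to build on, and the second window is structurally
easier to phonate than the first — all at odds with the developmental
phenomenology the model is meant to produce (vowel-first unarticulated
stage, intensity goals near 0 and 1). With the fast-onset variant the
first window is governed by the first command, and the canonical VN-then-VV
progression can emerge.

**omega0 reading.** The printed value "2 pi 0.8" is ambiguous between
2\*pi\*0.8 and 2\*pi/0.8 rad/s. The default is the literal product
(~5.03 rad/s, a sluggish motor plant that undershoots distant commands
within a segment); the faster reading is available via `omega0`.

**Interest window.** The interest mixture is refit every 400 vocalizations
on the most recent 2000 records (5 update cycles). With a window equal to
the refit cadence each refit sees only goals it generated itself, the goal
distribution contracts, and runs lock into a single developmental stage;
the longer window retains enough goal diversity for stage transitions to
occur at the desk scale.

**Interest initialization.** The first interest fit uses all initialization
records with uniform competence and the progress bias disabled, so the
agent's first goals reproduce the distribution of sounds it has already
produced (mostly silence, some phonation).

**Strategic initialization.** Initialization records are produced without
any strategy, so for strategic runs they are assigned uniformly random
strategy labels; otherwise the fitted interest mixture would place zero
mass on social guidance and emulation could never be sampled.

**Automatic stage segmentation.** The original analysis placed stage
boundaries by hand at sharp transitions. We label each proportion window
by its dominant content — `articulated` when that class has the largest
share, otherwise the mixed `no_phonation_unarticulated` label when the
no-phonation share is at least 0.25, else `unarticulated` — and take
maximal runs of the label as stages, merging runs shorter than 3 windows
into their larger neighbour; boundaries fall midway between adjacent
windows of different label.

**Surrogate calibration.** The neutral area profile tapers from 2.6 at the
glottis to 1.24 near the lips (arbitrary units); the basis amplitudes
(0.35 for tongue columns, down to 0.10 for the smallest deformation) were
chosen once so that the formant image of open configurations is genuinely
two-dimensional, F1 decreases monotonically with jaw closing, and extreme
tongue positions alone cannot occlude the tract. The packaged teachers
produce consonant-vowel-like sounds: the first command holds
pressure/voicing just below the phonation threshold (-0.1) and the second
drives them to 1, so voicing switches on inside the first perception
window (partial, consonant-like intensity whose exact level requires
delicate timing to emulate) and fills the second (a vowel); per-teacher
second-command articulations give distinct formant patterns. This makes
the demonstrations genuinely hard for a naive agent, so emulation is
unproductive early in development, as intended.

## Study conditions and problem sizes

Reference simulations use 2000 initialization vocalizations sampled around
the neutral command (sd 0.3), then 60,000 goal-directed vocalizations
(desk-scale; the full-scale protocol of 240,000 is available behind the
command-line `--full` flag), with class-proportion windows of n/8 sliding
by a fifth of a window. Strategic (emulation) runs use 30,000
vocalizations. The toy 1-D demonstration uses 1500 experiments, 50
initialization points N(0, 1), observation noise sd 0.5, a 6-component
joint mixture refit every 400 experiments, and reports the location error
|median f(draws) - goal| at t = 500 and 1500 for goals {-9, 0, 8}.

## What the simulations show — and what they do not

Under these conditions the class composition of a run complexifies over
time: initialization is mostly silent; runs begin in a mixed
no-phonation/unarticulated regime, move to unarticulated vocalizations
(one window silent), and often reach an articulated-dominant stage within
the desk-scale budget; strategic runs shift from self-exploration toward
emulation once the ambient sounds become reachable, and their mature
outcome clouds depend on the teacher. Which unarticulated flavour
dominates (VN vs NV, and vowel vs consonant first phones) varies across
seeds — the stage sequence is the robust object, the per-stage type tables
are properties of individual runs. The surrogate synthesizer reproduces
the contract properties of a real articulatory synthesizer (closure,
phonation gating, plausible formant ranges) but not its detailed
articulatory-acoustic geometry, so per-stage percentages are expected to
match reference values only loosely. None of this bears on real infant
data: the simulations probe the self-organization mechanism, not speech
acoustics.

## Numerical notes

EM uses k-means++ initialization, full covariances with an eigenvalue
floor of 1e-6 (rank-deficient data never crash a fit), a relative
log-likelihood tolerance of 1e-6 and at most 200 iterations; incremental
updates run 5 E/M sweeps per batch and components receiving negligible
responsibility keep their parameters. Conditioning computes component
weights in log space with max-subtraction, so conditioning far in the
tails cannot produce NaN. Resonance search scans 20-4500 Hz in 20 Hz
steps with 40 bisection iterations per sign change; a degenerate tract
with fewer than two resonances in range reports the scan edge (clipped to
1 after scaling). Boundary phone types (I exactly 0.1 or 0.9) fall into C.
Phonation ties (pressure exactly 0) do not phonate. Model updates that
fail numerically are caught and the previous model retained, so a run
never aborts mid-stream.

## Quick example

```{r}
library(vocadev)
run <- run_sagg_riac(8000, vd_config(n_init = 500), seed = 1)
p <- windowed_class_proportions(run)
plot_class_proportions(p)
segment_stages(p)
```
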