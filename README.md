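# vocadev

Why do infants babble the way they do — first learning to phonate, then
playing with unarticulated proto-vowels, then producing well-timed
articulated proto-syllables, and only late imitating the speech around
them? `vocadev` implements a computational model in which this
developmental sequence is not programmed in, but self-organizes from
curiosity-driven exploration: an agent that drives a simulated vocal tract
picks its own auditory goals (and, optionally, chooses between
self-exploration and emulating ambient sounds) to maximize its empirical
*competence progress*. The package is aimed at computational modellers of
development and intrinsically motivated learning.

## The model in brief

* **Motor system.** A vocalization lasts 800 ms and is driven by two
  9-dimensional commands (7 articulators, glottal pressure, voicing), the
  first until 250 ms, the second until 800 ms. Each dimension follows the
  overdamped spring-mass law `x'' + 2ζω₀x' + ω₀²(x − m) = 0` (ζ = 1.01,
  ω₀ = 2π0.8), so distant commands are undershot and the second segment
  depends on both commands (coarticulation). The policy space *M* is
  18-dimensional.
* **Surrogate synthesizer.** An area function (20 tube sections, areas
  affine in the articulators) gates phonation — pressure > 0, voicing > 0,
  tract open — and yields the two lowest lossless-tube resonances, scaled
  to [−1, 1]. Silent configurations have formants 0.
* **Perception.** Phonation level and formants are averaged in two 150 ms
  windows, giving the 6-dim outcome `s = [I₁, I₂, F1₁, F1₂, F2₁, F2₂]`
  plus Gaussian noise (sd 0.01). Window intensities classify each
  vocalization into 9 types (VV, VN, …) and 3 classes: *no phonation*
  (NN), *unarticulated* (one window silent), *articulated*.
* **Learning.** A 28-component joint Gaussian mixture over *M* × *S* is
  updated by incremental EM every 400 vocalizations (learning rate 0.1 →
  0.01); inverse control is Bayesian conditioning `G(M | s_g)`. Goals come
  from a 6-component interest mixture over (time, goal, competence) with
  `competence = exp(−‖s_g − s‖)`, each component re-weighted by its
  time–competence covariance (competence progress). In strategic runs a
  strategy coordinate chooses between autonomous exploration and emulating
  a random demonstration from an ambient-language teacher.

## Worked example

```r
library(vocadev)
run <- run_sagg_riac(8000, vd_config(n_init = 500), seed = 1)
print(run)
#> <voc_run> sagg, 8000 vocalizations (seed 1)
#> classes: no_phonation 60.6%, unarticulated 35.8%, articulated 3.7%

p <- windowed_class_proportions(run)
seg <- segment_stages(p)
seg
#>   stage                      label from   to
#> 1     1 no_phonation_unarticulated    1 8000
round(stage_tables(run, seg), 1)
#>                              NN  CN   NC  VN NV VV  CV  VC  CC
#> no_phonation_unarticulated 60.6 1.8 12.7 5.3 16  2 0.7 0.9 0.1
```

The agent starts mostly silent (NN) — its resting pressure/voicing do not
phonate — and, by selecting goals where its competence improves fastest,
discovers phonation (VN/NV vocalizations appear) and later articulated
sounds. At the reference scale (60,000 vocalizations) runs segment into
developmental stages whose composition mirrors this progression; a
strategic run against `teacher(1)` additionally shifts from
self-exploration toward emulation once the ambient sounds become
reachable:

```r
ts <- run_sgim_acts(30000, teacher(1), vd_config(), seed = 1)
sc <- strategy_curves(ts, window = 10)
```

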