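---
title: "Models and methods behind recalibr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind recalibr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(recalibr)
```

recalibr analyses unsupervised visual-vestibular recalibration in
heading-discrimination experiments: a monkey (or a simulated observer)
judges "left or right of straight ahead" from inertial motion (vestibular),
optic flow (visual), or both; a systematic discrepancy between the two cues,
introduced without any feedback about it, drags the unisensory percepts --
and, in cortex, the unisensory tuning curves -- toward each other. This
vignette explains the generative model behind the package's synthetic data,
the estimators, their numerical details, and the choices made where the
design was genuinely open. All quantitative statements here are properties
the test suite or the reproduction script computes; nothing is quoted from
recordings.

## The paradigm and its simulator

One session has three blocks. *Pre*: single-cue vestibular and visual
trials, ten log-spaced signed headings (±1, ±2, ±4, ±8, ±16 deg), randomly
interleaved, a fixed number of repetitions per (cue, heading). *Recal*: only
combined-cue trials; the vestibular and visual headings are offset by ±Δ/2
around the nominal heading, and |Δ| ramps up in 2-degree steps to 10 degrees
(sign fixed per session), then holds; the observer only fixates, no choices.
*Post*: single-cue trials again, interleaved with combined trials at the
maximal Δ that maintain the recalibrated state. Reward follows the paradigm's
asymmetry-avoiding rule: post-block single-cue headings whose implied
other-cue partner would fall on the opposite side of straight ahead are
rewarded stochastically (70% regardless of choice) instead of
deterministically (95% for correct). `paradigm_config()` holds these knobs
and `build_trial_schedule()` expands them; repetition defaults (8 per ramp
increment, 12 extra at the maximum, 10 per heading per block) sit inside the
ranges such experiments report.

The motion stimulus is a 1-s Gaussian velocity profile with 13 cm
displacement and 0.41 m/s peak velocity; those three numbers fix the
temporal SD of the bell (`0.13 / (0.41 * sqrt(2*pi))` ≈ 0.1265 s) and imply
a peak acceleration of ≈ 1.97 m/s², consistent with the nominal 2 m/s².
`stimulus_profile()` checks these identities rather than taking them on
faith.

**Behavior.** Choices come from a cumulative-Gaussian observer:
`P(right | h) = λ/2 + (1-λ)·Φ((h - μ)/σ)` per cue and block. Recalibration
is modelled as a *step* of μ between the pre and post blocks -- the analyses
only ever compare pre with post, so within-block dynamics are out of scope
(a ramp flag could be added without touching any estimator). For combined
trials the observer weights the cues (`w_vest` = 0.6 by default, reflecting
the larger vestibular shifts seen behaviorally, i.e. treating the vestibular
cue as the more trusted one); nothing downstream depends on this choice
because combined trials are excluded from every estimator -- they exist to
maintain recalibration. Across sessions, both cues' generative shifts are
scaled by a shared adaptation gain `g ~ N(1, 1)` plus small per-cue noise:
the same conflict drives both cues, so vestibular and visual shifts are
anti-correlated across sessions, and some sessions recalibrate strongly
while a minority move the "wrong" way -- the regime such experiments
report, with across-session SDs comparable to the mean shift.

**Neurons.** A neuron's rate is
`baseline + [slope·(h_cue - shift_cue,block) + gain_cue,block·C]·m(t)`,
with choice `C` ∈ {-1, +1}, truncated at zero, Poisson counts per 100-ms
bin on a fixed grid from -1.0 to +1.3 s around stimulus onset (so the 1-s
baseline window, the 1-s stimulus window and all 200-ms sliding windows are
bin-aligned). `m(t)` is either the normalized stimulus velocity
("velocity" mode) or a leaky integration of it with τ = 0.5 s ("sustained"
mode) whose activity outlasts the stimulus. The three `make_area_population()`
profiles encode qualitatively different relations between tuning shifts and
the session's perceptual shifts: MSTd-like (each cue follows its own
percept, visual slopes dominate), PIVC-like (vestibular follows the
vestibular percept, visual drive is negligible), VIP-like (both cues follow
the *vestibular* percept, choice gains halve post-recalibration, sustained
dynamics).

Two generator parameters deserve justification. *Tuning-shift gain*: tuning
shifts follow `shift_gain ×` the perceptual shift (default 2.5). Example
sessions in this literature show neuronal PSE shifts roughly two- to
four-fold larger than the simultaneous perceptual shifts, and a 1:1 coupling
would bury the between-session signal under the per-neuron neurometric noise
floor (see below), making correlation analyses powerless at realistic
session counts. The gain preserves signs, so every sign-pattern and
correlation property is gain-invariant. *Choice gains*: modest (1 Hz) in the
sensory-dominant profiles, strong (6 Hz, halving to 3) in the VIP-like
profile. Because choices covary with heading, any choice gain leaks into
heading-tuning regressions; the PIVC-like profile therefore carries no
visual-cue choice gain at all, keeping its visual responses below
tuning-screen detectability -- that profile's defining feature.

What the generator does **not** emulate: eye movements and fixation breaks,
adaptation dynamics within blocks, correlated noise across neurons,
non-Poisson spiking statistics, and nonlinear (non-sloped) tuning shapes.
Passing tests therefore show that the *estimators* do what they claim on
data with the assumed structure -- not that real cortex satisfies the
assumptions. One known generator artifact: with high choice gains and steep
slopes the zero truncation of rates bites asymmetrically between blocks; the
VIP-like profile uses moderate slopes and elevated baselines to stay in the
linear regime.

## Psychometrics

`fit_psychometric()` is a binomial maximum-likelihood fit of the cumulative
Gaussian above. With the lapse fixed at zero the model is exactly a probit
GLM in `(-μ/σ, 1/σ)`; its likelihood is concave, so `glm.fit` finds the
global optimum directly. The free-lapse model (λ ∈ [0, 0.1]) and any case
the GLM cannot handle (for example complete separation, where σ → 0) go to
a box-constrained quasi-Newton optimizer with analytic gradients, restarted
from five deterministic initializations (a probit-regression start plus a
fixed μ-σ grid), ties broken by likelihood then smaller σ. A fitted curve
whose unconstrained optimum is *non-increasing* has no identified PSE and is
flagged non-converged rather than returned with an arbitrary mean. Boxes:
|μ| < 200 deg, σ ∈ [0.01, 200] deg; estimates pinned at the boxes are
treated as non-identified. Since the paradigm's lapse handling is a genuine
unknown, both treatments are available (`lapse = "fixed"` or `"free"`) and
shifts should always difference fits with matching treatment; the pipeline
default is λ = 0, which is also the generative default to within 0.01.

`pse_shift()` is post-minus-pre μ; positive means the psychometric curve
moved rightward (a leftward perceptual shift). `behavioral_summary()`
aggregates per (cue, Δ sign) with paired t-tests and compares
vestibular-versus-visual magnitudes after `pool_signed_shifts()`, which
flips vestibular shifts from Δ⁻ sessions and visual shifts from Δ⁺ sessions
so that positive always means "conflict-reducing".

## Reference-anchored neurometrics

Classical neurometrics compare responses to +h versus -h, which silently
assumes the decoder's neutral point is at 0. To *measure* a shift of that
neutral point, all rates (pre and post) are z-scored against the
pre-recalibration mean and SD -- pooled over all pre-block single-cue trials
of that cue, the only pooling under which "z = 0 is the pre-recalibration
mean" is well defined -- and each heading's z-scores are compared with the
fixed reference z = 0 by ROC. The criterion moves from the minimum to the
maximum z-score in 100 steps; the steps follow the sample quantiles of the
observed z-scores (so that for ≤100 trials every response value is visited)
with the reference always included as a criterion. With strict "exceeds"
comparisons the trapezoidal area then equals the fraction of z-scores above
zero with ties counted half (`auc_reference_exact()`), exactly up to n =
100 and to within ~0.005 beyond; an equal-width criterion grid would
half-credit any response falling inside the grid cell adjacent to zero and
can err by 0.5/n. The AUC is mapped to P(rightward) using the neuron's
preferred side -- fixed from the *pre*-block tuning slope so that a
post-block sign flip cannot masquerade as a shift -- and a no-lapse
cumulative Gaussian, weighted by trials per heading, gives the neurometric
PSE.

Rates entering neurometrics are raw; baseline-subtracted rates (per-block
baseline over the second before onset) are used for tuning curves and the
tuning regression, where the subtraction is conventional and harmless.
Both behaviors sit behind the same `trial_firing_rates()` accessor.

**Screening.** A (neuron, cue) enters shift analyses iff (1) the linear
tuning regression over the presented range is significant (p < 0.05) in at
least one block, and (2) the bootstrap SD of the neurometric PSE --
trial resampling stratified within heading, preserving the design balance --
is below 10 degrees in *both* blocks. Resamples whose refit is
non-identified are dropped; more than 20% drops counts as unreliable
(SD = ∞). The noise floor mentioned above comes from the pooled z-scoring:
the pooled pre-block SD contains the tuning-induced variance across
headings, so the neurometric σ cannot fall below roughly the heading SD
(~10 deg for this design), which puts the per-neuron PSE standard error
near 2.5-4 deg at 10 repetitions per heading -- the reason screened
reliability, not tuning strength, limits what population correlations can
resolve.

`sliding_window_shifts()` repeats the whole construction in 200-ms windows
at centers 0.1-1.2 s (12 windows, all bin-aligned), recomputing the
reference statistics per window from the pre block.

## Choice analysis

`partial_correlations()` computes Pearson partials
`R_h = corr(FR, heading | choice)` and `R_c = corr(FR, choice | heading)`
from the standard three-variable identity, choices coded -1/+1, p-values
from the t transform with n-3 degrees of freedom. Conditioning matters:
heading and choice are strongly correlated, and the partials attribute to
each variable only its unique variance; squared partials are used for
pre/post comparisons for exactly that "unique variance" reading.
`choice_conditioned_tuning()` gives the per-choice tuning curves (cells
under 3 trials masked, the overall curve is exactly the count-weighted mean
of the conditioned ones), and `baseline_fr_comparison()` checks that shifts
are not secretly baseline changes.

## Population statistics

`neuronal_perceptual_correlation()` correlates raw signed neuronal and
perceptual shifts across sessions (both Δ orientations in one cloud).
`mixed_model_comparison()` fits the pooled regression and an lme4 mixed
model with by-monkey random intercepts and slopes; REML estimates are
reported, but AIC/BIC for the pooled-versus-mixed comparison come from an
ML refit, since the models share fixed effects and only ML likelihoods are
comparable; the mixed model is "preferred" only when both criteria agree.
A singular random-effects fit falls back to random intercepts, flagged --
note that if slopes are heterogeneous while intercepts are exactly
homogeneous, this fallback hides the slope heterogeneity; with any realistic
intercept spread the full model fits fine.

## Problem sizes and reproduction

The validation studies (`study_*` functions) run at these sizes, chosen as
the package's own balance of statistical resolution and desk-scale runtime:
1000 random instances for the ROC oracle check; 200 sessions × (10 headings
× 20 reps) for psychometric recovery; 100 neurons per injected ±3°
neurometric shift; 50 sessions per Δ orientation for the behavioral sign
pattern; 40 sessions × 1 neuron per area profile with B = 100 bootstrap
resamples; 100 replicate populations of 50 single-session neurons for the
choice-gain reduction; 1000 untuned neurons (B = 100) for screen
calibration; 50 sessions × 6 neurons for the sliding-window time course.
`scripts/acceptance.R` reruns all of them from a single seed and writes the
headline numbers as JSON. The bootstrap default in the analysis functions
remains B = 1000; the studies use B = 100, and pilot runs between B = 100
and B = 500 show no systematic B-dependence of the screen's behavior on
untuned neurons beyond sampling noise.

## Known limitations

* The combined-cue observer (weights, combined σ) is a stand-in; no claim
  is made about how combined-cue choices are actually formed.
* The step model of recalibration cannot describe within-block drift.
* The bootstrap-reliability screen excludes most but not all untuned
  neurons (~85-88% at this design's trial counts); the remainder that survive are
  those whose sampled responses happen to carry stable apparent structure,
  and the tuning criterion is the screen's first line of defense against
  them.
* Partial correlations are linear; strongly nonlinear tuning would call for
  a rank-based variant, deliberately not included.
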