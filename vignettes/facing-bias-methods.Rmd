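---
title: "Models and methods behind the facingbias pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind the facingbias pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(facingbias)
```

## The scientific problem

An orthographically projected point-light walker seen from the front or
back is depth-ambiguous: the same dot pattern is anatomically consistent
with a figure *facing the viewer* (FTV) and with one *facing away* (FA).
Observers nevertheless report FTV far more often than chance — the
*facing bias*. One way to probe this bias is to inject graded perspective
information: project the 3D walker centrally rather than in parallel,
with the center of projection (the convergence point) at a finite
distance, so that the relative positions and motions of the dots carry a
subtle cue about the walker's in-depth orientation. Crucially, the dots
themselves keep a constant shape and size at every perspective level, so
no local cue survives — only the global dot configuration is informative.

`facingbias` implements that paradigm end to end as a simulation and
analysis pipeline: stimulus geometry, randomized experimental design, a
generative observer model, cumulative-Gaussian psychometric fitting with
a Monte-Carlo goodness-of-fit test, and the group-level statistics
(probit repeated-measures ANOVA, reaction-time polynomial analysis,
reaction-time/certainty correlation).

## Stimulus geometry

### Signed field-of-view angle

Each perspective level is indexed by a *signed field-of-view (FOV)
angle*. Its magnitude is fixed by the convergence-point distance $D$ (in
walker heights) through the projection window of height $w = 4$ walker
heights:

$$\mathrm{fov} = 2\arctan\!\left(\frac{w/2}{D}\right),$$

so the six standard distances $D \in \{16, 8, 6, 4, 3, 2\}$ map to FOV
angles that round to 14, 28, 37, 53, 67 and 90 degrees, and $D = \infty$
is the orthographic limit (0°). The window-height convention is the only
one that reproduces this distance-to-angle table, which is why the
package adopts it. The *sign* encodes which interpretation the cue
supports: negative FOV places the convergence point on the far side of
the walker, producing a dot pattern consistent with a figure facing the
viewer; positive FOV places it on the near side (facing-away cue); 0 is
perfectly ambiguous. (The opposite sign convention exists in parts of the
literature; the package follows the one under which the psychometric
slope of a canonical observer is negative and the reaction-time slope
positive, and states it in every I/O header.)

### Projection

`project()` performs a central projection onto the frontoparallel plane
through the walker's depth midpoint. Placing the plane at the midpoint is
a design choice (the geometry does not dictate it): it keeps the figure
centered and makes the $\pm$FOV pair an exact mirror-image in depth,
which is the geometric content of the FTV/FA ambiguity and is verified as
a property test. A marker at or behind the convergence point is a
geometry error naming the offending frame and marker. Dot radius (15
arcmin by default) is metadata: it never enters the projection math,
which is the point of the constant-dot-size technique.

### The walker

The paradigm's original walker comes from a motion-capture-derived gender
continuum whose coefficients are not public. The package instead ships a
*parametric* gender-neutral walker: 15 standard anatomical markers, each
marker's trajectory a mean position plus up to two harmonics of the gait
cycle (117 frames per cycle), walking in place facing the depth axis.
Left-side limb markers are constructed from the right side by the
contralateral relation $x_L(\theta) = -x_R(\theta + \pi)$,
$(y,z)_L(\theta) = (y,z)_R(\theta + \pi)$, so bilateral symmetry and the
half-cycle phase offset hold exactly by construction. Amplitudes and
phases were chosen once as anatomically plausible for a treadmill gait
(leg swing at the fundamental, arm swing in antiphase, trunk bounce at
the second harmonic) and are not otherwise special: every downstream
geometric and statistical result depends only on having *some* periodic
3D dot pattern, and arbitrary `gait_parameters` can be supplied from a
JSON config. The figure is normalized so the mean-pose vertical extent is
exactly 1, which makes "distance in walker heights" well defined.
Whether the original stimulus translated or walked in place is not
documented; walking in place is the standard choice for frontal/back-view
ambiguity experiments and is what the package implements.

## Experimental design

`build_schedule()` reproduces the standard session: 13 signed FOV levels
× 40 repetitions = 520 trials, one global uniformly random permutation,
split into 13 consecutive blocks of 40. Blocks are treated as rest pauses
only (not per-level strata), the simplest reading of a randomized trial
order divided into blocks. The gait start phase of each trial is drawn
uniformly on the integer frame grid 0..116, since a "start position of
the animation cycle" is naturally a frame. A practice block is generated
by the same operation under a `practice` flag and never analyzed.

## The synthetic observer

Observers are generative models with two parts.

**Responses.** A cumulative-Gaussian psychometric function
$$p_{\mathrm{FTV}}(x) = \gamma + (1 - \gamma - \lambda)\,
\Phi\!\left(\frac{\mathrm{psa} - x}{\sigma}\right)$$
with PSA (point of subjective ambiguity) $\mathrm{psa}$, spread
$\sigma$, guess rate $\gamma$ and lapse rate $\lambda$, both bounded by
0.06 following the standard constrained-fitting convention. The slope at
the PSA, in proportion per degree, is
$-(1-\gamma-\lambda)/(\sigma\sqrt{2\pi})$ — e.g. $\sigma = 54.66$°
(with $\gamma = \lambda = 0$) gives $-0.0073$. Responses are Bernoulli
draws.

**Reaction times.** No distributional form for RTs is dictated by the
paradigm; the package uses the minimal model consistent with everything
the analysis stage measures: a second-order polynomial trend in FOV plus
a certainty discount,
$$\mu(x) = c + b\,x + a\,x^2 - \kappa\,|z(x)|, \qquad
z(x) = \Phi^{-1}\!\big(p_{\mathrm{FTV}}(x)\big)\ \text{clipped at}\ |z|\le 3,$$
multiplied by lognormal noise $e^{\varepsilon}$,
$\varepsilon \sim N(0, \sigma_{RT}^2)$. The clip at $|z| = 3$
(configurable) prevents infinite certainty at saturated levels; the
lognormal is a pragmatic choice for a positive, right-skewed RT
distribution, flagged as such. A configuration whose mean RT is
non-positive at any scheduled level is rejected outright.

**Cohort calibration.** `cohort_defaults()` encodes the study
conditions: 11 observers per sex group; group-mean slope magnitudes
0.0068 (male) and 0.0034 (female) with 25% lognormal between-observer
variation; PSA normal around 47.3° (the facing bias: positive PSA means
the orthographic walker is usually seen as FTV) with SD 15°; RT constants
around 2012 ms (male) and 1780 ms (female) with SD 250 ms; RT slope
1.5 ± 0.5 ms/deg, curvature −0.020 ± 0.008 ms/deg²; certainty coupling
κ = 150 ms per |z| unit; RT noise σ = 0.25. The slope, PSA and RT
constants are the paradigm's published group values; the dispersions and
κ are plausible one-time choices, documented here and not revisited. A
female observer is an "inverse" phenotype (mirrored, increasing
psychometric curve) with probability 1/11 — such stable observers are a
real, documented phenomenon.

What this generator does *not* emulate: sequential dependencies and
adaptation across trials, drift-diffusion-style RT mechanics, eye
movements, learning, or any figure-gender dimension (the walker is fixed
neutral). Passing tests therefore demonstrate that the *analysis
pipeline* behaves correctly on data with the assumed structure, not that
real observers satisfy that structure.

## Psychometric fitting

`fit_psychometric()` maximizes the binomial log-likelihood over
(psa, log σ, λ, γ) with L-BFGS-B under box constraints, from a
deterministic multistart grid (the empirical 50% crossing plus range
quantiles, crossed with three spread scales); ties are broken by first
found, so re-runs are stable. Fitted probabilities are clamped away from
0/1 by 10⁻¹² for likelihood evaluation. Because inverse observers exist,
the default fit tries both curve orientations and keeps the better
likelihood; the mirrored orientation simply flips the sign of the
reported slope. A fitted |PSA| beyond the largest stimulated |FOV| (90°
in the standard design) is flagged `extreme_psa`: such values mean no
available perspective cue was strong enough to cancel the observer's
bias, and have no further quantitative interpretation.

**Deviance and the Monte-Carlo test.** Goodness of fit is the binomial
deviance — twice the log-likelihood gap to the saturated model — whose
null distribution is simulated: `mc_goodness_of_fit()` parametrically
resamples counts from the fitted curve, refits, and reports the fraction
of simulated deviances at least as large as the observed one. Refits
inherit the parent fit's constraints and orientation but use a reduced
multistart budget (default 3 starts; the calibration experiments in the
test suite use 1), each seeded individually so any subset of simulations
is reproducible. Deviance comparisons carry a 10⁻⁹ guard so that exact
fits (deviance at float-noise level) get p = 1 rather than an arbitrary
rank among other float-noise values.

**Pooling and intervals.** `pooled_fit()` implements
reliability-weighted pooling as likelihood pooling: each observer's
counts enter the joint likelihood (optionally with user weights,
normalized to mean 1), which is equivalent to fitting weighted per-level
sums of n and k — levels and observers contribute in proportion to their
trial counts. `bootstrap_slope_ci()` is a parametric percentile
bootstrap of the slope at the PSA.

Numerical choices worth knowing: optimization tolerance `factr = 1e4`
(log-likelihood resolution far below any decision threshold used here);
spread is fitted on the log scale within [10⁻³, 10³] × level range; PSA
within ±20 level ranges of the data, wide enough to represent extreme
biases without letting the optimizer wander to infinity.

## Group statistics

* **Probit transform** of per-cell proportions uses the boundary-safe
  correction $(k + 0.5)/(n + 1)$, so empty and full cells stay finite.
  How boundary proportions entered historical analyses is generally
  unstated; this standard correction is the package's choice and is
  configurable by pre-transforming counts.
* **Mixed RM-ANOVA** (`mixed_rm_anova()`) is the classical balanced
  sums-of-squares decomposition, implemented directly from cell means so
  that its arithmetic is transparent and testable against an independent
  `stats::aov()` error-strata oracle. The between effect is tested
  against subjects-within-groups, within and interaction against the
  level × subjects-within-groups stratum. With 2 × 11 observers and 13
  levels the df pairs are (1, 20) and (12, 240). Note that published
  reports of this design sometimes print the within main effect with a
  numerator df of 20; with 13 levels the correct numerator df is 12, and
  that is what the package reports. No sphericity correction is applied
  by default (matching reports with uncorrected dfs);
  `gg_correct()` provides Greenhouse–Geisser-adjusted p values.
* **RT polynomials** are per-observer OLS fits of per-level mean RT on
  FOV and FOV². `group_ttests()` reports, per coefficient, a one-sample
  t across all observers, a Welch two-sample test between sexes, and a
  *paired-by-rank* variant (groups sorted, then paired) — the convention
  that yields df = 10 with 11 observers per group, included because
  between-group comparisons in this literature have been reported with
  paired dfs. Both are labeled; the reader chooses.
* **RT–certainty correlation** uses |z| of the FTV proportion as the
  certainty index and Spearman rank correlation with average-rank ties;
  p from the t approximation on n − 2 df. No multiple-testing correction
  is applied anywhere — every p value is raw, as is conventional for
  this analysis.
* **Boxplot summaries** use interpolated (type-7) quartiles, whiskers at
  the most extreme data within 1.5 IQR, and the standard notch
  $\mathrm{median} \pm 1.57\,\mathrm{IQR}/\sqrt{n}$ as the 95% interval
  around the median.

## Problem sizes used by the test suite

The acceptance-style experiments in `tests/testthat/test-acceptance.R`
run at the study's own scale where that is cheap (13 levels × 40
repetitions, 22-observer cohorts) and at deliberately chosen simulation
sizes where the quantity of interest is a rate: 100 simulated observers
for PSA recovery with a 300-draw slope bootstrap each; 200 observers ×
500 Monte-Carlo simulations for the type-I calibration of the deviance
test (the classic analysis uses 10,000 simulations per observer — the
calibration *rate* is insensitive to this, only the granularity of a
single p value is); 12 seeded cohort replicates for the qualitative
signature. These sizes are the package's chosen balance between
Monte-Carlo resolution and suite runtime.

## Known limitations

* The gait is stylized; it carries the correct symmetries and
  periodicity but no biomechanical fidelity beyond them.
* The RT model is phenomenological. It reproduces the analyzed
  *features* (quadratic trend, certainty coupling) by construction, so
  tests of the RT analysis stage are consistency checks, not evidence
  about mechanism.
* Pooled fits over heterogeneous observers are systematically shallower
  than the mean of individual fits (a mixture of displaced Gaussians is
  flatter than its components); pooled-slope numbers should be compared
  only with other pooled numbers.
* The ANOVA requires a complete balanced design and refuses anything
  else; there is no missing-cell imputation.
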