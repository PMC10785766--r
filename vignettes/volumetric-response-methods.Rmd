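---
title: "Methods: volumetric response criteria, concordance statistics, and the growth model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: volumetric response criteria, concordance statistics, and the growth model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(volresp)
```

This vignette is the package's own account of its methods: the measurement
model, the threshold rule sets and their boundary conventions, the
concordance statistics, the mechanistic growth model and its estimation, the
synthetic cohort generator, and the numerical and design choices made where
the design was genuinely open.

## Measurements

A *solid tumor volume* is a segmentation-based volume on the sequence that
best visualises the solid component, minus the volume of cysts contained
inside the solid region; *whole tumor volume* (FLAIR) additionally includes
cysts and peritumoral edema. The 2D quantity is the product of the longest
diameter and its perpendicular, in cm². Multiple lesions are summed per
image before any comparison to baseline. Percent change is always
`100 * (current - baseline) / baseline`.

The baseline image is the earliest pretreatment image (`t_days <= 0`); with
two pretreatment images the earlier is used. When a series has no
pretreatment image the earliest available image serves as baseline, with a
warning — the situation does occur in real trials and silently refusing the
series would be worse. Zero solid volume (a fully cystic residual) is
representable but flagged, because percent change from a zero baseline is
undefined. Missing 2D at an image where 3D exists (and vice versa) is
representable; downstream operations propagate an explicit `NA` rather than
dropping or imputing the image, so outputs stay aligned with the series.

## Response criteria and boundary conventions

`response_criteria()` builds the six rule sets. The volumetric-extrapolated
cutoffs come from the perfect-sphere map `v = (1 + a)^(3/2) - 1`: a +25%
2D-product increase corresponds to +39.75% in volume, a 50% decrease to
−64.64%, a 25% decrease to −35.05%. Two conventions needed fixing:

* **Rounding.** Trial practice applies the *rounded* thresholds (+40 / −65 /
  −35%), and that is the default; `exact_extrapolation = TRUE` switches to
  the unrounded values for sensitivity analyses. Whether a given study used
  exact or rounded thresholds is rarely stated, so both are supported.
* **Boundary inclusivity.** Thresholds are inclusive toward the non-stable
  label: PD at `pct >= +25`, PR at `pct <= -50`, and the minor-response band
  owns its upper boundary (a decrease of exactly 25% is MinR under RAPNO;
  PR owns exactly 50%). This is the only reading consistent with every cell
  of the printed rule tables (`>=` thresholds inclusive, `<` stable bounds
  exclusive) simultaneously.
* **New lesions** force PD under every rule set regardless of measured
  change.

BT-RADS scores map to categories as: `1a` → PR (improvement attributed to
decreasing tumor burden), `1b`, `2`, `3a`, `3b` → SD (improvement or
worsening plausibly treatment-related), `3c`, `4` → PD (worsening attributed
to tumor). BT-RADS has no minor-response notion, so where criteria
distinguish MinR it is grouped with PR before comparison.

## Concordance statistics

Scores entering ROC analysis are signed percent changes; for detecting PD
the score is the change itself, for detecting PR its negation, so one
orientation convention (higher score = more positive) covers both. The AUC
is computed by the Mann–Whitney rank formulation (ties count one half) and
equals the trapezoidal area under the empirical curve to machine precision.

Confidence intervals use a **stratified** bootstrap: positives and negatives
are resampled separately with replacement, preserving class counts, so no
replicate degenerates to a single class; 2,000 replicates and percentile
2.5/97.5 bounds by default. Percentile rather than BCa was chosen because it
is simple, transparent at these sample sizes, and stated plainly in the
documentation; the difference is well below the width of the intervals at
n ≈ 65.

The paired DeLong test uses placement values (per-positive and per-negative
mean placements) to estimate the variance of the AUC difference of two
scores measured on the same images, with a two-sided normal p-value. A zero
estimated variance with a nonzero difference is reported as p = 0 with a
warning. The test is cross-checked in the test suite against both an
independent implementation (pROC) and an exhaustive paired-permutation
oracle.

Threshold sweeps report, per grid threshold, the bootstrap median
sensitivity and specificity with percentile CIs; a threshold is *selected*
when its sensitivity CI contains the target sensitivity of 0.80 (inclusive
at the bounds). The conventional grids are +15..+40% (PD) and −15..−65%
(PR) in 5% steps: thresholds below the assumed 10% measurement uncertainty
are not meaningful, and the grids end at the extrapolated cutoffs.
Sensitivity uses `score >= threshold`, mirroring the rule tables' `>=`
convention.

Weighted kappa uses linear distance weights over the ordinal BT-RADS scale
by default; study reports often say only "weighted kappa", so the quadratic
scheme is exposed too and the choice is recorded in the result. Friedman
tests are computed with the standard tie correction (fully tied data give
statistic 0, p = 1); base R's `friedman.test` omits the correction, so the
statistic is computed directly and cross-checked against base R on tie-free
data, where they coincide. One-way ANOVA and the Wilcoxon rank-sum test wrap
`stats::oneway.test(var.equal = TRUE)` and `stats::wilcox.test` (exact
enumeration when both groups have ≤ 10 untied observations); fully tied
Wilcoxon input returns p = 1 rather than the 0/0 of the tie-corrected normal
approximation.

## The growth model

Longitudinal solid-volume trajectories are described by the
regression–regrowth model

$$\frac{dV}{dt} = \left(\lambda - \gamma_0\, e^{-\varepsilon t}\right) V,$$

with exponential growth rate $\lambda$ (1/day), initial treatment-induced
shrinkage rate $\gamma_0$ (1/day), and resistance-onset rate $\varepsilon$
(1/day): the treatment effect decays exponentially, producing an optional
initial dip followed by regrowth. The ODE integrates in closed form,

$$V(t) = V_b \exp\!\left(\lambda t - \frac{\gamma_0}{\varepsilon}
  \left(1 - e^{-\varepsilon t}\right)\right),$$

with $V_b$ the volume at treatment start; $\varepsilon = 0$ is handled by
its limit $V_b e^{(\lambda-\gamma_0)t}$. This is the canonical minimal form
combining exponential growth, treatment-induced shrinkage and resistance
onset, and it produces the characteristic dip-then-regrow trajectory shape;
it is stated here prominently as the package's modelling choice. When
$\gamma_0 > \lambda > 0$ the net growth rate crosses zero exactly once, at

$$t_{V\min} = \frac{\ln(\gamma_0/\lambda)}{\varepsilon},$$

the time of minimum volume and the pivot of the trajectory classification;
$\gamma_0 \le \lambda$ gives $t_{V\min} = 0$ (no shrinkage phase), and
$\lambda = 0$ with $\gamma_0 > 0$ a monotone decrease ($t_{V\min} = \infty$).

### Estimation

Observations are lognormal around the model curve:
$\log V_{\text{obs}} \sim N(\log V(t), \sigma)$ with $\sigma$ equal to the
assumed measurement coefficient of variation (default 0.10). Priors, chosen
to be weakly informative over clinically plausible rates and configurable
via `growth_priors()`: log-uniform $\lambda \in [10^{-5}, 0.05]$/day,
uniform $\gamma_0 \in [0, 0.2]$/day, log-uniform
$\varepsilon \in [10^{-4}, 0.1]$/day, and lognormal $V_b$ centred on the
first observed volume with CV 0.2.

Sampling uses a Goodman–Weare affine-invariant ensemble sampler (stretch
move, $a = 2$), the standard ensemble MCMC for low-dimensional
ODE-parameter posteriors; it is authored in the package because no installed
R package provides one. Sampling runs on
$(\log\lambda, \gamma_0, \log\varepsilon, \log V_b)$. Defaults are 32
walkers and 2,000 steps with the first half discarded as burn-in; the
package's own tests use 16–24 walkers and 300–1,200 steps, which the
parameter-recovery checks show to be sufficient at these data sizes (about
10 observations per series). An acceptance fraction outside [0.1, 0.9] is
flagged, not fatal. Identical seeds give bit-identical chains.

Measurement uncertainty beyond fit uncertainty is propagated by a
**measurement-noise bootstrap** (`bootstrap_refits()`): each of `n_boot`
(default 200) replicates multiplies every observed volume by an independent
lognormal factor with unit mean and CV equal to the measurement uncertainty,
refits, and the posteriors are pooled. Derived $t_{V\min}$ samples are
computed per pooled draw; pooling MCMC and bootstrap draws into one
distribution (rather than bootstrapping point estimates) was chosen because
the downstream classification consumes a single quantile of $t_{V\min}$.

### Trajectory classification

An image at time $t_{\text{eval}}$ is classified with precedence PD → SD →
PR:

* **PD** if $t_{\text{eval}}$ exceeds the 75th percentile (linear
  interpolation) of the pooled $t_{V\min}$ distribution — the tumor has
  clearly passed its minimum, regardless of whether its volume has regrown
  past baseline yet;
* **SD** if every observed volume up to and including $t_{\text{eval}}$
  stays within the measurement-uncertainty band (±100·CV %, i.e. ±10% by
  default) around the pretreatment volume;
* **PR** otherwise.

Only images with at least 3 images strictly before the evaluated one
(baseline included in the count, i.e. at least 4 observations in the fit)
are model-classified; with fewer the dip-and-regrowth shape is not
constrained. "Prior images" is interpreted here as all earlier images
including baseline — the natural reading for a fit that needs the
pretreatment anchor.

Responder/resistant comparisons split fits at posterior-median
$t_{V\min} \ge$ 1 year and compare per-parameter posterior medians between
groups with Wilcoxon rank-sum tests; a lower $\varepsilon$ among responders
is the signature of durable treatment effect.

### Cohort-shared growth rate

Treating $\lambda$ as constant across patients is implemented as a
two-stage profile in `fit_growth_cohort()`: every series is first fitted
with free $\lambda$; the cohort value is the median of the per-series
posterior medians; each series is then refitted with $\lambda$ fixed at
that value. A single joint MCMC over all per-participant parameters plus the
shared $\lambda$ (≈130 dimensions for a 43-participant cohort) would mix
poorly under an ensemble sampler and is disproportionate to the role the
shared rate plays; the two-stage profile keeps the constraint while staying
inspectable per series. The free-λ mode remains available
(`lambda_mode = "free"`).

## The synthetic cohort generator

`simulate_cohort()` generates cohorts with the statistical structure the
analysis assumes, so every pipeline stage is testable without any patient
data. Its defaults encode the study conditions the package targets: 43
participants on a 61-day (≈2-month) imaging cadence up to 700 days, 10%
multiplicative lognormal measurement noise on solid volume, 65 assessment
images (one early ≈6-month image per participant, one late last-follow-up
image for 22 of them) with an exact PR/SD/PD mix of 14/23/28, ≈79% of
participants with cysts, and a median of about 4 follow-ups per participant
(range 3–9).

Per-participant growth parameters are drawn from class-conditional ranges
and rejection-sampled until the *noiseless* trajectory yields the intended
class at each assessment time under the volume-extrapolated RAPNO rules
(MinR grouped with PR). For participants with two assessments the class
pair must be dynamically feasible under the model: a tumor already
progressing at the early visit cannot later be stable or responding, and a
deep early response regrowing past +40% within the horizon is excluded. The
latent parameters, classes and $t_{V\min}$ are returned as ground truth,
under both the threshold rule and the trajectory-model rule.

Secondary channels:

* **2D proxies.** The volume-equivalent sphere diameter $(6V/\pi)^{1/3}$ is
  multiplied by per-lesion lognormal distortion factors (CV 0.15, fixed
  across visits) and per-visit jitter (CV 0.24). The jitter is what makes 2D
  change a noisy proxy of volume change; its default was calibrated once so
  that roughly 7 in 10 follow-ups show sign-congruent 2D and 3D change,
  the degree of congruence such trials report. At zero distortion the
  2D-area change is exactly the sphere-collapse of the volume change.
* **Whole volume** is 1.2 × solid + cyst (a stable edema margin diluting
  solid change) observed with CV 0.20 — larger than the solid-volume CV
  because FLAIR whole-tumor segmentations include edema and are less
  reproducible. Both mechanisms together reproduce the ordering in which
  whole volume underperforms solid volume as a classifier.
* **Cysts** follow a near-static multiplicative random walk (per-visit log
  step SD 0.03), matching the observation that cystic volume changes little
  regardless of response group.
* **Readers.** Reader 1 maps the true class to a consistent BT-RADS score;
  reader 2 disagrees with probability 11/65, and discordant reads cross into
  the adjacent response category (stable vs responding/progressing) — the
  pattern real blinded double reads show. One-ordinal-step perturbations
  were tried first and rejected: they leave linear-weighted kappa near 0.94,
  not in the "substantial agreement" range (≈0.78) the generator is meant to
  emulate.
* **New lesions** appear in a progressing participant's series with
  probability 0.15 from its PD assessment onward.

What the generator does **not** emulate: scanner/site effects,
slice-thickness and acquisition variability, segmentation-boundary ambiguity
(contouring variation), correlated multi-lesion dynamics, enhancement or
mass-effect reasoning behind BT-RADS scores (readers see the true class plus
noise), and informative dropout. Passing pipeline tests on synthetic cohorts
therefore demonstrate correctness and calibration of the *statistical
machinery*, not clinical performance on real measurements.

## Numerical choices and degenerate inputs

* Lognormal noise with CV $c$ uses $\sigma_{\log} = \sqrt{\log(1+c^2)}$ and
  mean-one factors ($\mu_{\log} = -\sigma_{\log}^2/2$).
* Quantiles (bootstrap CIs, the $t_{V\min}$ 75th percentile) use R's default
  linear interpolation (type 7).
* Ties in scores are grouped into single ROC operating points and count one
  half in the AUC; fully tied score vectors give the two-point diagonal
  curve and AUC 0.5.
* Degenerate label vectors (a single class) are an error for ROC/AUC, not a
  silent NaN; stratification makes degenerate bootstrap replicates
  impossible.
* Zero within-group variance with distinct group means reports F = ∞, p = 0.
* All randomness flows from explicit integer seeds; reports isolate the
  timestamp in one metadata field so byte-level determinism of everything
  else is testable.

## Problem sizes used by the test suite

The suite exercises the ODE/closed-form agreement on 1,000 random parameter
draws (tolerance 10⁻⁶ relative), the $t_{V\min}$ closed form against a
0.5-day grid argmin on 1,000 draws, parameter recovery on 20 seeded
replicates of a 10-visit series at 5% noise (posterior medians of $\gamma_0$
and $\varepsilon$ within 25% in ≥ 90% of replicates), exhaustive AUC
pair-counting oracles at n ≤ 8, an exhaustive 2¹² paired-permutation oracle
for the DeLong test at n = 12, and full-pipeline runs on cohorts of 12–43
participants with 200–2,000 bootstrap replicates and 16–24 walker / 300–1,200
step chains. These sizes were chosen as the smallest at which each property
is sharply testable.

## Known limitations

* The growth model assumes a single lesion-level volume signal;
  multi-lesion series are summed before fitting, which blurs heterogeneous
  per-lesion dynamics.
* The two-stage shared-λ profile is not a joint posterior: per-series
  credible intervals do not propagate uncertainty in the shared rate.
* The trajectory classification consumes one quantile of $t_{V\min}$; very
  diffuse posteriors (short series, weak dips) make the PD rule
  conservative.
* Percentile bootstrap CIs can undercover at very small n or AUC near 1.
* The generator's class-conditional parameter ranges are calibration devices
  for producing the intended class mix, not estimates of biological rate
  distributions.
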