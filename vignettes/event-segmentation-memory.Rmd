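---
title: "Event segmentation, everyday memory, and mediation: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Event segmentation, everyday memory, and mediation: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(eventmem)
library(dplyr)
```

## The scientific problem

People parse continuous everyday activity into discrete events, and the
moments they mark as boundaries ("a meaningful unit of activity just
ended") anchor later memory for that activity. In clinical case-control
designs this is measured with a button-press task: participants watch
videos of everyday activities and press whenever an event ends. A
participant segments *normatively* when their presses line up with where
the group as a whole presses. The question this package's analysis chain
addresses is whether a clinical condition (here PTSD versus trauma-exposed
controls) is associated with less normative segmentation and poorer free
recall of the same activities, and — centrally — whether the segmentation
deficit *mediates* the memory deficit.

The package implements the full chain as tested code: a synthetic cohort
generator with an explicit exposure → mediator → outcome structure and
known ground truth; segmentation-agreement scoring; recall scoring and
coder-validation kappa; crossed random-intercept mixed models; and a
quasi-Bayesian causal mediation estimator. Because the original raw data
are not bundled, the generator *is* the study population here: its
defaults encode the published sample statistics as generating truth, and
the tests check that the pipeline recovers them.

## Segmentation agreement

Time in each video is divided into 1-s bins (half-open intervals; a press
at exactly the video end is assigned to the last bin). A participant's
binned indicator is 1 where at least one press fell. The norm profile of a
video is the per-bin proportion of participants marking that bin,
including the index participant by default (a leave-one-out flag is
provided). Agreement is the Pearson correlation `r` between indicator and
norm profile, rescaled to

\[
\mathrm{scaled} = \frac{r - r_{\min}(k)}{r_{\max}(k) - r_{\min}(k)},
\]

where \(r_{\max}(k)\) places the participant's \(k\) marks in the \(k\)
highest-norm bins and \(r_{\min}(k)\) in the \(k\) lowest (ties broken by
lowest bin index). For a fixed \(k\), the correlation is a monotone
function of the summed norm mass over marked bins, so the top-\(k\)
(bottom-\(k\)) placement is exactly the best (worst) achievable — the
tests verify this against exhaustive enumeration of all \(\binom{n}{k}\)
subsets for short vectors. The rescaling controls for individual
differences in the *number* of boundaries marked: a sparse and a dense
segmenter can both reach 1.0. Degenerate cases (no presses, every bin
pressed, constant norms) have no defined score; they are returned as
missing, counted in a warning, and dropped listwise downstream.

No smoothing is applied to the norm profiles; norms are computed per video
across all participants regardless of narrative condition, since each
participant sees a given video only once.

## The synthetic cohort generator

The generator is first-class, tested code, and its defaults are the study
conditions: 63 PTSD and 64 control subjects; six videos of 329, 376, 354,
249, 263 and 327 s split three per narrative session; session order
(trauma narrative first versus positive first) counterbalanced by
alternating assignment; 11 anxiety ratings per session on a 1–10 scale;
40 A1 action units per video (a plausible count for ~5-minute everyday
activities; the true number is not published and is configurable).

The generative chain is:

* **Symptom severity.** PCL totals are drawn per group from a *censored*
  normal: a normal draw rounded to an integer and clipped to the
  instrument range 17–85. Censoring (rather than truncation) is
  deliberate: the published control moments — mean 20.81, SD 6.21 with
  floor 17 — are unreachable by any floor-truncated normal, whose SD
  cannot exceed roughly the mean-to-floor gap, but are matched exactly by
  a censored normal, which concentrates a realistic point mass at the
  instrument floor. The latent parameters (PTSD N(54.66, 13.88), control
  N(15.16, 11.71)) were solved so the censored sample moments equal the
  published 54.60 (13.66) and 20.81 (6.21).
* **Segmentation fidelity.** Each subject has a latent ability
  \(\in (0,1)\): `plogis(2.0655 - 0.00183 (pcl - 37.7) - 0.5415 \cdot
  1[\mathrm{PTSD}] + u)`, `u ~ N(0, 1.05^2)`. Both a per-point severity
  slope and a diagnosis offset are needed: because diagnosis is nearly a
  deterministic function of the checklist total in this design, a model
  with only a PCL slope cannot reproduce the published group-mediation
  and severity-mediation decompositions simultaneously. The diagnosis
  offset represents the clinical information the interview carries beyond
  the checklist score.
* **Latent boundaries.** Each video has boundaries from an exponential
  renewal process (mean gap 11 s) with per-boundary salience drawn from
  Beta(5, 2). These are what the sample norms estimate.
* **Presses.** Each boundary is marked with probability
  \(q^{1/\mathrm{salience}}\) with \(q = \mathrm{clamp}_{[0,1]}(\mathrm{base}
  + \mathrm{slope}\cdot \mathrm{ability})\) — increasing in both ability
  and salience, exactly 1 in the noiseless limit — jittered by N(0, 1.5 s)
  truncated to the video; false alarms arrive as a Poisson process with
  rate \(0.1196 (1 - \mathrm{ability})\) per second. This is the simplest
  mechanism that makes agreement rise monotonically with a single ability
  parameter (verified by simulation over an ability grid) while producing
  the published mean of ~28.7 presses per subject-video.
* **Recall.** Each A1 unit is recalled independently with probability
  `plogis(-2.4944 + 2.0574 * scaled_agreement - 0.0973 * 1[PTSD]
  - 0.00018 * (pcl - 37.7) - 0.07 * 1[TRAUMATIC] + noise)`, with a
  subject-level logit noise (SD 0.247) shared across videos. Group and
  severity act on recall only through these explicit direct terms, so the
  generator's true indirect effect is exactly zero when the agreement
  slope is switched off — the null the mediation tests exercise.
* **Anxiety.** Trial ratings follow a cell-means model with subject,
  trial and residual Gaussian components, clipped to [1, 10]. The latent
  cell means were solved *through* the clipping so that the clipped means
  reproduce the published group effects (B = 1.05), condition effect
  (B = 0.83) and interaction (B = 1.01).

### Calibration procedure

Defaults were solved numerically, once, by simulation: ability and press
parameters against the published press count and group agreement means
(0.63 control, 0.59 PTSD, i.e. a group effect of −0.04 on scaled
agreement); recall coefficients by Newton iteration against the published
recall means (0.23 / 0.20), the mediation decompositions (45% of the
group effect and 46% of the severity effect carried through agreement) and
the outcome-regression \(R^2\) (27%) — evaluated with the same estimator
and the same cohort size (n = 127) as the analysis itself, because the
published proportions are finite-sample estimator outputs, not asymptotic
truths, and the ratio estimator carries a few percentage points of
finite-sample bias on the near-null severity contrast. The solved values
live in `cohort_config()` and are not meant to be tweaked; every other
parameter is exposed for sensitivity work.

Randomness uses one root seed; per-record sub-seeds are drawn from a
deterministic stream of that root, so a subject's data do not change when
other subjects are added and identical configurations are byte-identical.

### What the generator does *not* emulate

Real press logs are far more overdispersed (the published range is 1–142
presses per video with SD ~19.7; the generator's spread is narrower), real
recall coding has coder noise (here kappa validation is provided but the
synthetic coder is exact), condition effects on pressing are set to zero
by default (the original analysis found none; the parameter exists), and
no eye-movement, interview or free-text data are simulated. Passing tests
therefore demonstrate that the *pipeline* is correct and well-calibrated,
not that the generator is a complete model of the real data.

## Mixed models

Six analyses: Group × Narrative-condition and Severity × Narrative-condition
models for trial-level anxiety (crossed random intercepts for subject and
trial), scaled agreement and recall proportion (crossed random intercepts
for subject and video). Decisions such an analysis leaves open are fixed
here and recorded in each fit's metadata: REML estimation, treatment
coding with CONTROL and POSITIVE as reference levels, Wald z tests (no
degrees-of-freedom approximation), severity mean-centered over the
distinct subjects of the analysis sample before the interaction is formed.
Anxiety is modelled at trial level with a trial random intercept; a
`session_average` flag reproduces the session-mean variant. Zero
random-effect variance reduces the fit to OLS (tested at 1e-6), and
non-convergence is flagged on the returned object, never silent.

```{r models, warning = FALSE, message = FALSE}
coh <- generate_cohort(cohort_config(n_ptsd = 20, n_control = 20, seed = 1))
tidy(run_group_model(coh, "agreement"))
```

## Mediation

Following the aggregation used in the original analysis (one score per
subject, because the mediation machinery admits a single random effect),
scaled agreement and recall proportion are averaged per subject over all
non-missing videos, pooling both narrative conditions. The estimator is
quasi-Bayesian: fit M ~ X and Y ~ X + M by least squares, draw `n_draws`
coefficient vectors from each fit's asymptotic normal approximation, and
per draw compute ACME = a·b, ADE = c′, total = a·b + c′ — the
decomposition is exact in every draw. Intervals are percentile; p-values
are two-sided Monte-Carlo sign probabilities; a nonparametric bootstrap
(subject resampling) is available as `method = "boot"`.

The headline proportion mediated is the ratio of the ACME point estimate
to the total-effect point estimate, truncated to [0, 1]; the mean of
per-draw ratios is also reported (`prop_mediated_draw_mean`) but is not
the headline because the ratio is convex in the draws and measurably
biased (several percentage points downward at this design's n). When the
total effect is indistinguishable from zero the ratio is unstable; it is
still reported, flagged, with the untruncated value in metadata.

```{r mediation, warning = FALSE}
s <- aggregate_per_subject(coh$agreement, coh$recall, coh$subjects)
estimate_mediation(s, "group", n_draws = 1000, seed = 7)
```

## Numerical choices and degenerate inputs

* Bins are half-open `[b, b+1)`; a press at exactly the duration goes to
  the final bin; presses outside `[0, duration]` are input errors naming
  the offending rows.
* `scaled` is clamped to [0, 1] against floating-point spill only; ties in
  the norm ordering break deterministically by lowest bin index.
* `r_max - r_min` below machine tolerance (constant norms) yields a
  missing score rather than a 0/0.
* Kappa with chance agreement 1 (both coders constant and identical) is
  an explicit error, not NaN.
* Mediation requires ≥ 20 subjects and a non-constant predictor; subjects
  with no scoreable videos are excluded with a warning and a count.
* All Monte-Carlo seeds are mandatory or derived from the configuration
  seed; repeated runs are bit-identical.

## Problem sizes used in the tests

The test suite uses study-sized cohorts (127 subjects, six videos) where
calibration is being checked — 16 replicate cohorts, chosen to keep
Monte-Carlo error on the mediation proportions near 4–5 percentage points
— and miniature cohorts (4–30 subjects, two short videos) everywhere the
property under test does not depend on scale. `scripts/acceptance.R`
averages 150 replicate cohorts, which puts ~1.5 percentage points of
Monte-Carlo error on the reported mediation proportions. The per-cohort
spread of an estimated proportion mediated at n = 127 is large (SD ~17–22
percentage points); any single cohort's estimate is expected to be noisy,
exactly as a single real study's would be.

## Known limitations

* The agreement statistic assumes a common bin width (1 s) and binary
  marking; graded or hierarchical (coarse/fine) segmentation is out of
  scope.
* The mediation estimator assumes sequential ignorability and linear
  mediator/outcome models on the aggregated scores; no sensitivity
  analysis is provided.
* The generator's press model ties hit probability and false alarms to a
  single ability scalar; real participants plausibly vary in style
  (sparse vs. dense markers) independently of fidelity.
* Calibration targets published *sample* statistics from one study of
  n = 127; the defaults inherit that study's sampling noise.
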