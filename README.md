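# eventmem

Event segmentation, everyday memory, and causal mediation for clinical
case-control cohorts.

## What problem this addresses

Observers spontaneously parse continuous everyday activity into discrete
events, and the boundaries they perceive anchor later memory. In clinical
designs this is measured with a button-press segmentation task: watch a
video of an everyday activity, press whenever a meaningful unit of
activity ends, then freely recall the activity. Segmenting *normatively*
(pressing where the group presses) predicts recalling more. `eventmem` is
for researchers studying whether a clinical condition — the motivating
design contrasts a PTSD group with trauma-exposed controls, primed with
traumatic or positive autobiographical narratives — is associated with
less normative segmentation and poorer recall, and how much of the memory
deficit is *mediated* by segmentation.

The package provides, as one tested tidyverse-style pipeline:

* a **synthetic cohort generator** with an explicit exposure → mediator →
  outcome structure and known ground truth, calibrated so its defaults
  reproduce the motivating study's published sample statistics;
* **segmentation-agreement scoring**: per-1-s-bin indicators, group norm
  profiles, and the min-max rescaled norm correlation;
* **recall scoring** (proportion of A1 action units recalled) and Cohen's
  kappa for coder validation;
* **crossed random-intercept mixed models** (subject × video, subject ×
  trial) for group and symptom-severity analyses, via `lme4`;
* **quasi-Bayesian causal mediation** (ACME, ADE, total effect,
  proportion mediated, Monte-Carlo intervals);
* a one-call **pipeline** producing a structured report and delimited
  artifact files.

## The statistics at the core

**Segmentation agreement.** With a video divided into 1-s bins, a
participant's binary indicator `x` (k marked bins) is correlated with the
norm profile `y` (per-bin proportion of participants marking). The score
is rescaled against the best and worst correlations achievable with the
same k:

    scaled = (r − r_min(k)) / (r_max(k) − r_min(k)),   r = cor(x, y)

with `r_max` from placing the k marks in the k highest-norm bins and
`r_min` from the k lowest. This controls for how many boundaries a person
marks, isolating *where* they mark them.

**Mediation.** With per-subject means of agreement (M) and recall (Y) and
a predictor X (diagnosis, or mean-centered PCL symptom severity), fit
`M ~ X` and `Y ~ X + M`, draw coefficients from each fit's asymptotic
normal approximation, and decompose per draw: ACME = a·b (indirect, via
segmentation), ADE = c′ (direct), total = a·b + c′. The proportion
mediated is ACME/total.

## Worked example

```r
library(eventmem)

# a study-sized synthetic cohort: 63 PTSD + 64 control subjects, 6 videos
coh <- generate_cohort(cohort_config(seed = 1))
coh
#> Synthetic cohort: 127 subjects ( 63 PTSD / 64 control ), 6 videos
#>   presses: 19880 | mean presses per subject-video: 26.09
#>   mean scaled agreement: 0.597 | mean recall proportion: 0.217

# group mixed model on scaled agreement (crossed subject/video intercepts)
tidy(run_group_model(coh, "agreement"))
#> # A tibble: 4 x 5
#>   term                         estimate std_error statistic   p_value
#>   <chr>                           <dbl>     <dbl>     <dbl>     <dbl>
#> 1 (Intercept)                   0.623     0.0126     49.4   0
#> 2 groupPTSD                    -0.0546    0.0136     -4.00  0.0000628
#> 3 conditionTRAUMATIC           -0.00269   0.00631    -0.427 0.670
#> 4 groupPTSD:conditionTRAUMATIC  0.0113    0.00896     1.26  0.207

# mediation of the group -> recall effect through segmentation agreement
s <- aggregate_per_subject(coh$agreement, coh$recall, coh$subjects)
estimate_mediation(s, "group", n_draws = 1000, seed = 7)
#> Causal mediation (quasi-bayes, 1000 draws)
#> Predictor: GROUP | mediator: segmentation agreement | outcome: recall
#>   ACME  (indirect):  -0.0129  [-0.0227, -0.0050]  p = 0.001
#>   ADE   (direct):    -0.0264  [-0.0440, -0.0082]  p = 0.001
#>   Total effect:      -0.0392  [-0.0574, -0.0220]  p = 0.001
#>   Proportion mediated: 32.8%
#>   Outcome R-squared: 0.235 | n = 127 subjects
```

The Group coefficient on agreement (here −0.055) estimates the generating
deficit of −0.04 on the 0–1 agreement scale; the mediation decomposition
splits the group's recall deficit into the part flowing through
segmentation (ACME) and the residual direct part — on this seed about 33%
is carried by segmentation, estimating a generating share of 45%. Any
single cohort's proportion mediated is noisy (SD ≈ 17 percentage points
at n = 127); averages over replicate cohorts recover the generating
values.

The full chain, including all six mixed models, both mediations, report
files and CSV artifacts:

```r
rep <- run_pipeline(cohort_config(seed = 1), out_dir = "results/run1")
```

## Package layout

| Module | Files |
|---|---|
| cohort generator & config | `R/config.R`, `R/generate.R` |
| segmentation agreement | `R/segmentation.R` |
| recall scoring & kappa | `R/recall.R` |
| mixed models | `R/models.R` |
| mediation | `R/mediation.R` |
| pipeline & IO | `R/pipeline.R` |
| plots | `R/plots.R` |

The methods vignette (`vignettes/event-segmentation-memory.Rmd`) documents
the generative model, the calibration procedure, numerical edge cases, and
known limitations.
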