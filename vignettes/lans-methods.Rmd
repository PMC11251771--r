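---
title: "Operationalizing LANS: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Operationalizing LANS: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lans)
```

## The clinical problem

A progressive amnestic syndrome in an older adult can be driven by
neocortical Alzheimer-type degeneration (ADNC: amyloid plaques plus
neurofibrillary tau) or by degeneration largely confined to the limbic
system, most often limbic-predominant age-related TDP-43 encephalopathy
neuropathological change (LATE-NC). The two differ in prognosis and in
eligibility for amyloid-directed therapy, but overlap heavily in
presentation. The limbic-predominant amnestic neurodegenerative syndrome
(LANS) construct addresses this with a tiered set of clinical criteria:
a *core* requirement (a slow, predominant amnestic syndrome progressing
over two or more years), *standard* supportive features obtainable in
routine practice, *advanced* supportive features requiring molecular or
metabolic imaging, and an ordered *degree of certainty* (low, moderate,
high, highest) derived from how many features are met.

This package is a computational operationalization of those criteria: it
turns per-patient clinical, imaging and fluid measurements into tri-state
feature flags (met / not met / unavailable), assigns the likelihood
category, and implements the validation analyses around the criteria —
disproportionate-atrophy scoring through a longitudinal mixed model,
ROC-derived cut-points, a logistic classifier of LATE-NC presence, and
mixed models of clinical trajectories — together with a calibrated
synthetic cohort generator so the whole pipeline is exercisable without
access to the original clinicopathological data.

## Feature operationalization

**Standard features.**

* *Older age at evaluation*: age at first visit at or above 75 years.
  The boundary is inclusive and configurable (`age_cutoff`); 75 is an
  operational convention, not a biological constant.
* *Mild clinical syndrome*: a diagnosis of amnestic MCI, or amnestic
  dementia with first-visit CDR-SB at or below 4 (of 18). A dementia
  case without a baseline CDR-SB is *unavailable*, not failed.
* *Disproportionate hippocampal atrophy*: see the mixed model below.
* *Impaired semantic memory* is carried as a clinical flag but excluded
  from likelihood counts by default (`include_semantic_feature = FALSE`),
  because no standardized operationalization is established; when
  enabled it becomes a fourth standard feature.

**Advanced features.**

* *Limbic hypometabolism*: the FDG-PET inferior-to-medial temporal (IMT)
  ratio — inferior temporal SUVR divided by the volume-weighted mean
  SUVR of amygdala and hippocampus — at or above a data-derived cut.
  Template region volumes weight the denominator; the default weights
  are hippocampus:amygdala = 4:1, roughly the ratio of the template
  region sizes. Subject-specific volumes can be supplied per record.
* *Absence of a neocortical degenerative pattern*: FDG-PET Alzheimer
  meta-ROI SUVR strictly above the abnormality cut (1.47 Mayo-pipeline,
  1.21 ADNI-pipeline; at or below the cut is the hypometabolic,
  Alzheimer-pattern side).
* *Low likelihood of neocortical tau*: a prioritized cascade.
  (i) A negative amyloid-PET establishes it (amyloid negativity is a
  surrogate for absent neocortical tau). (ii) If amyloid-PET is positive,
  a negative tau-PET establishes it and a positive one fails it; if
  amyloid-PET is positive and tau-PET is missing the feature is *not
  met* — fluid markers only rule out amyloidosis and are fallbacks for
  the PET-unavailable situation, so a positive amyloid scan without tau
  imaging leaves neocortical tau unresolved and calls for further
  workup. (iii) With no PET, CSF meets the feature only when every
  present measure is negative (Abeta42 > 1026 pg/ml, P-tau181 < 22
  pg/ml, P-tau/Abeta42 < 0.023) — a conservative conjunction, chosen
  because the assay literature gives three cut-points but no
  combination rule. (iv) With no PET or CSF, plasma pTau181 below its
  assay-specific cut (2.56 pg/ml Mayo assay, 17.7 pg/ml ADNI assay)
  meets it. (v) Otherwise the feature is unavailable.

The printed ratio cut of 0.023 is implemented as P-tau181/Abeta42 >=
0.023 marking positivity: the source material names the ratio both ways,
and only this orientation is dimensionally consistent with the printed
Elecsys threshold.

All cut-points live in a `lans_config` (two dialects, `MAYO` and `ADNI`,
reflecting different PET pipelines and tracers) and every boundary is
included on the abnormal side exactly as printed.

## Likelihood assignment

With S = standard features met (of 3 operationalized; 4 with the
semantic flag) and A = advanced features met (of 3):

* not LANS if the core feature fails;
* **highest** if S = S_max and A = 3;
* **high** if S >= 3 and A >= 1, or S >= 2 and A >= 2;
* **moderate** if S >= 3, or S >= 2 and A >= 1;
* **low** otherwise.

Rules are evaluated top-down and the first satisfied wins; this resolves
combinations the prose definitions leave implicit (e.g. S = 1, A = 3 is
*low*, because every higher category requires at least two standard
features). *Unavailable* counts as not met: missing data caps the
reachable category, it never disqualifies, and the highest category is
reachable only when every operationalized feature is affirmatively met.
The test suite verifies the engine against an independently hand-written
(S, A) rule table over every feature combination, and verifies
monotonicity: promoting any single feature to met never lowers the
category.

## Disproportionate hippocampal atrophy

Hippocampal volume (hemispheres summed) is first adjusted for head size
by taking residuals from per-sex OLS regressions of volume on total
intracranial volume fit in a control sample. Severity-adjustment then
uses a linear mixed model fit by maximum likelihood:

  adjusted volume ~ CDR-SB + (1 | patient)

The random intercept absorbs intra-individual correlation across serial
MRIs; a random CDR-SB slope is available behind a flag but off by
default because most subjects contribute few visits. Each patient is
scored at the *last* visit with a volume (the most recent MRI), as the
residual of the observed volume from the **fixed-effects-only**
prediction at that visit's CDR-SB. Using only fixed effects is what
makes the model transferable: a model fit in one cohort can score
another cohort without that cohort's random effects. Residuals are
scaled by the model residual SD and then Z-scored across the scored
cohort; Z-scoring is per scored cohort (a pooling flag is not provided —
scoring runs are independent by construction). A more negative Z means a
hippocampus smaller than the severity-expected value. The abnormality
cut on Z is derived by ROC against autopsy LATE-NC status with
lower-is-positive orientation and installed into the configuration as
`hippo_z_abnormal_max`.

## ROC machinery

AUC is all-pairs concordance with ties counting one half (computed via
midranks; the suite checks it against a brute-force O(n^2) count).
The operating threshold maximizes Youden's J over midpoints between
adjacent unique scores — midpoints make the cut invariant to monotone
jitter below the data's resolution — with ties in J broken toward higher
sensitivity and then toward the lower threshold. Youden's J is the
conventional reading of an "optimal" ROC threshold; distance-to-corner
alternatives were considered and rejected for simplicity.

## LATE-NC classification and validation analyses

The logistic classifier regresses LATE-NC presence (pure LATE-NC or
comorbid, versus ADNC) on age at examination, baseline CDR-SB, adjusted
hippocampal volume at the last MRI, IMT ratio and FDG meta-ROI SUVR as
continuous predictors plus binary tau positivity from the cascade. The
fit is maximum likelihood on complete cases only, mirroring the reduced
denominators that biomarker availability imposes; predicted probability
above 0.5 (configurable) calls LATE-NC. Balanced accuracy is the
unweighted mean of sensitivity and specificity. (Quasi-)separation is
detected and reported as a warning rather than silently accepted.

Likelihood-by-pathology structure is tested on the contingency table of
groups against categories with highest and high collapsed into a single
bin, an omnibus chi-square, and pairwise two-proportion post hoc tests
gated on omnibus significance. Post hoc p-values are raw by default
(matching how pairwise comparisons are conventionally reported for these
tables), with a `p_adjust` argument for Holm or other corrections.

Clinical progression is modelled as CDR-SB on group, time from baseline
(years) and their interaction with a per-subject random intercept and
slope (the slope can be disabled); the interaction coefficients are the
group differences in annual CDR-SB slope against a chosen reference.

## The synthetic cohort generator

The generator emulates the *structure* the analyses assume, calibrated
to the published distributional anchors:

* group sizes 75 / 81 / 9 (ADNC, comorbid, pure LATE-NC);
* per-group feature positivity and availability equal to the published
  feature-frequency fractions (e.g. ADNC limbic hypometabolism 9/53 with
  53/75 FDG availability);
* age spread from the published per-group interquartile ranges
  (IQR / 1.349 as the normal scale), with the location calibrated so
  that P(age >= 75) equals the published age-feature rate — the printed
  medians and the printed rates are mutually inconsistent by one to two
  years, and the rate is the quantity the downstream analyses consume;
* MCI/dementia mix from the published diagnosis counts, with baseline
  CDR-SB drawn in half-point steps consistent with the mild-syndrome
  flag (mild dementia at or below 4, non-mild above).

Features are generated through two latent severities per patient
(limbic and neocortical): each feature draws a standard-normal latent
correlated at `latent_rho` (default 0.6) with its driving severity, and
the continuous biomarker is an affine function of that latent anchored
at the abnormality cut, so marginal threshold positivity matches the
configured rate exactly in expectation while features sharing an axis
are positively correlated — the correlation structure ROC machinery and
the classifier actually face. Setting `latent_rho = 0` gives an
independence mode for analytic checks (category probabilities then
enumerate exactly over weighted feature combinations). The tau feature
is realized through one of three measurement routes (PET 80%, CSF 10%,
plasma 10%) whose values are placed on the correct side of the printed
assay cuts.

CDR-SB trajectories are linear with per-subject slopes around
group-dependent means — defaults 1.4 (ADNC), 1.0 (comorbid), 0.45
(LATE-NC) points/year, sd 0.35, visit noise sd 0.5, clipped to [0, 18] —
encoding the reported *ordering* (LATE-NC slowest, ADNC fastest,
comorbid intermediate); slope magnitudes are not published and are free
parameters. Adjusted hippocampal volume follows
`0 - 0.05 * CDR-SB + subject intercept (sd 0.5) - 1.2 * atrophy + noise
(sd 0.2)` in volume-residual units, so truly atrophic patients sit about
two residual SDs below expectation. Baseline CDR-SB means end up close
but not identical across groups (the pure LATE-NC group is mildest),
consistent with the published baseline medians; exact equality is
incompatible with reproducing the per-group mild-syndrome rates, and the
generator favours the rates.

What the generator does **not** emulate: real measurement pipelines
(no images are simulated), time-varying biomarkers (the biomarker panel
is a last-scan snapshot), informative missingness (availability is
masked independently of disease severity), APOE and other covariates,
and any nonlinearity in clinical decline. Passing tests therefore show
that the pipeline recovers known structure from data *shaped like* the
cohorts, not that it would perform identically on real patients.

## Numerical choices and degenerate inputs

Missing values are empty CSV cells and become `NA`; sentinel codes are
rejected at parse time so they can never be compared against thresholds.
All-tied ROC scores return AUC 0.5. Rates of exactly 0 or 1 requested
from the generator are clamped into (0, 1) with a warning, since no
continuous biomarker placement can realize them. Mixed models are ML
(not REML) fits so fixed effects are comparable across nested
specifications; non-convergence and singular fits are surfaced as
warnings carrying the optimizer messages. The likelihood engine is pure
integer arithmetic with no tolerance issues.

## Problem sizes

The suite fits the volume model at 85 subjects and roughly 420-435
observations (the published operating size) with 100-replicate coverage
checks; ROC oracle comparisons run 200 random instances at n <= 50; the
end-to-end synthetic run uses about 10,000 patients for rate
calibration checks. `scripts/acceptance.R` runs cohorts at four times
the published group sizes (660 patients per cohort), which keeps
complete-case classifier fits stable while finishing in seconds.

## Known limitations

The package evaluates criteria from quantitative inputs; in clinical
use several of these features are visual-read judgements, and the
quantitative operationalization exists to give the criteria construct
validity, not to replace clinical assessment. The pure LATE-NC stratum
is tiny in the published cohorts (n = 9), so any quantity conditioned
on it is noisy both in reality and in the calibrated simulator. The
published in-sample sensitivity/specificity pair and true-positive /
true-negative counts are mutually inconsistent (their evaluation subsets
are not stated); the package reports both computation paths and does not
attempt to reconcile them.
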