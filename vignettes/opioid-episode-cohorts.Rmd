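---
title: "Prescription episodes, ordinal cohorts and many-to-one inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prescription episodes, ordinal cohorts and many-to-one inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(opicohort)
```

## The problem

Claims databases record what was dispensed, not what was taken or why.
Reconstructing opioid exposure for cancer patients therefore rests on
three conventions, each of which this package makes explicit and
configurable:

1. **Coverage.** A prescription of `days_supplied` days starting on
   `start_date` covers the closed interval
   `[start_date, start_date + days_supplied − 1]`. All day counts are
   inclusive (a one-day prescription has duration 1).
2. **Persistence.** Exposure is treated as continuous across uncovered
   runs shorter than a persistence gap of 30 days, across drug switches,
   and across overlapping prescriptions. The episode ends at the last
   covered day before the first uncovered run of 30 days or more.
3. **Potency.** Doses are pooled on the oral morphine equivalent (OME)
   scale via multiplicative factors (oral morphine ≡ 1). Formulations
   without an accepted factor contribute no milligrams; an episode made
   exclusively of such drugs has no calculable dose and is excluded
   rather than imputed.

## Cohort definition

With episode duration $D$ (days) and mean daily dose
$\bar{m}$ = total OME / $D$ (covered-gap days count in the denominator,
so a sparse episode has a lower mean than its prescriptions' daily dose):

| group | rule |
|---|---|
| control | $D < 183$ |
| case I | $D \ge 183$, $\bar m \ge 120$ mg/day, $D < 730$ |
| case II | $D \ge 183$, $\bar m \ge 120$ mg/day, $D \ge 730$ |
| excluded (long, low dose) | $D \ge 183$, $\bar m < 120$ |
| excluded (dose not calculable) | no convertible opioid in the episode |

All three cut-offs (183 days ≈ six months of continuous therapy, 120
mg/day OME as the accepted high-dose bound, 730 days for the very-long
split) are parameters of `cohort_thresholds()`; the boundaries are
inclusive on the case side, and the control is defined by duration alone —
a short, very-high-dose patient is a control. Eligibility additionally
requires 730 days of follow-up, measured as the plain date difference
between the index date and the end of data; the boundary case (exactly
729 days) is excluded.

### Decisions where the convention is genuinely open

* **Gap measurement.** The 30-day gap is measured from the end of
  coverage to the next start (uncovered days strictly between intervals),
  the standard persistence-window convention; a run of exactly 30
  uncovered days terminates the episode.
* **No stockpiling.** Overlapping prescriptions merge; surplus supply is
  not appended to the episode tail, because the episode end is defined by
  the last *covered* day.
* **Death during an episode** caps the end date at the end of data.
* **Injectable opioids** carry the dictionary role `other`: they neither
  index an episode nor bridge a gap.
* **Windows.** "Before" means strictly before the index date; "during"
  is the closed interval from index date to episode end, so a record on
  the index date counts as on-episode. Comorbidity and site flags use any
  record up to the episode end.
* **Rescue counting.** The "number of rescue uses" is the dispensed
  dose-unit count (`n_units`) — claims cannot observe ingestion. Units of
  non-convertible rescue drugs count toward frequency but contribute no
  milligrams.
* **Treatment records.** The clinical-records table carries ICD-10
  diagnosis codes plus declared treatment tokens (default
  `OPER`/`RADI`/`CHEM`/`NBLK`); both vocabularies live in the
  overridable `code_map`, as does the comorbidity/site prefix map, which
  is a declared default rather than a canonical list.

## Inference

**Many-to-one comparisons.** Each case group is compared with the single
control. For continuous factors, Dunnett's procedure: pooled-variance t
statistics with familywise-adjusted two-sided p-values
$p_i = 1 - P(|T_1| \le |t_i|, |T_2| \le |t_i|)$ under the central
bivariate t with correlation $\rho_{12} = \sqrt{\lambda_1\lambda_2}$,
$\lambda_i = n_i/(n_i + n_0)$. For categorical factors, the Steel
procedure: midrank Wilcoxon statistics against the control with
tie-corrected variance, adjusted under the bivariate normal with the same
correlation. Both rectangle probabilities are computed with deterministic
algorithms (TVPACK via inclusion–exclusion for the t; Miwa for the
normal), so repeated runs give identical p-values; a joint max-|Z|
permutation mode is available as a check on the normal approximation.
Applied to a 0/1 indicator the Steel statistic is a comparison of
proportions, which is how the categorical table columns are tested.

**Proportional-odds regression.** The ordered outcome (control = 0 <
case I = 1 < case II = 2) is modelled as
$P(Y \ge k \mid x) = \operatorname{logistic}(\alpha_k + x^\top\beta)$,
one common $\beta$ per covariate across both cutpoints, so positive
coefficients mean higher odds of case membership and the intercepts are
strictly decreasing ($P(Y\ge1) \ge P(Y\ge2)$). The likelihood is
maximized by Newton iteration with analytic scores, a finite-difference
observed-information matrix, and step-halving, so the log-likelihood is
non-decreasing across iterations. Covariates are standardized internally
and the estimates, together with the information matrix, are mapped back
to the original scale — estimates are invariant to covariate units.
Iteration targets a score max-norm of `tol` (default 1e-8) and stops when
the likelihood ceases to improve at floating-point scale; the fit is
flagged non-converged only if the final score max-norm exceeds
`max(tol, 1e-7 n)`, a per-observation criterion that near-separated fits
with huge but finite standard errors still satisfy. Standard errors come from the observed information;
confidence intervals are Wald intervals exponentiated to the odds-ratio
scale. The intercept-only model has the closed-form maximum
$\hat\alpha_k = \operatorname{logit} \widehat{P}(Y \ge k)$, which the
test suite uses as an exactness check.

**Variable selection** mirrors a two-step filter: step 1 keeps variables
significant (p < 0.05) in *both* case-vs-control comparisons,
additionally requiring categorical variables to reach 5% incidence in the
control or either case group. The conjunction of the two conditions is
the default reading; the disjunction is exposed as
`categorical_rule = "or"` because the prose rule is ambiguous. Step 2 is
judgment-based and cannot be fully automated, so it is configuration:
declared collinear pairs (e.g. bone metastasis dropped in favour of
distant metastasis) and forced inclusions/exclusions, every decision
written to an audit log with its reason. Episode duration is never a
candidate explanatory variable — it defines the outcome — while the mean
daily OME is retained as one, mirroring the factor tables this design
follows; expect its association to be partly definitional.

## The synthetic-claims generator

`generate_bundle()` exists so that the full pipeline can be tested
without any proprietary data. It works backwards from the analysis:

1. Binary covariate flags are drawn per patient from configured
   prevalences (defaults: back pain 45%, distant metastasis 33%,
   pre-index non-opioid analgesics 75%, on-episode non-opioids 80%,
   gabapentinoids 12%, antiepileptics 4%, pre-index radiotherapy 31%,
   on-episode chemotherapy 70% — magnitudes of a hospital cancer-pain
   cohort).
2. The group label is drawn from the cumulative-logit model on those
   flags. The default intercepts (−4.51, −4.68) were calibrated once, by
   Monte-Carlo inversion of the marginal probabilities, so that group
   shares loosely echo a large claims cohort (≈ 71% control, 0.6% case I,
   3.5% case II of dose-calculable patients); a quarter of patients are
   planted as long-duration/low-dose exclusions and 0.4% as episodes of
   non-convertible opioids only.
3. An episode consistent with the group's band is materialized: duration
   from a truncated log-normal for the band; prescriptions of 14–30 days
   tiling the span with uncovered gaps below 30 days (probability 0.35
   per refill boundary, `gap_prob = 0` gives contiguous coverage); the
   daily dose is solved *after* the gaps and rescue dispensings are
   known, so the episode's mean daily OME equals the planted value
   exactly. Post-episode prescriptions, when planted, start at least 30
   uncovered days after the episode end.
4. Records carrying the covariate flags are placed in the correct
   window, and death/censoring dates guarantee the 730-day follow-up.

Each patient's stream is seeded from `(seed, patient index)`, so output
is byte-stable under changes of `n_patients`.

Because dose and span are planted exactly, classification recovery is
100% at the default settings, not merely ≥ 99% — a deliberate property:
any mismatch is a pipeline defect, not generator noise. The generator
consequently does *not* emulate several features of real claims data —
dose titration within an episode, database-boundary censoring of ongoing
episodes, care fragmented across hospitals, miscoded records — so
passing tests demonstrate the correctness of the reconstruction and the
inference, not robustness to real-world measurement error.

## Problem sizes and numerical checks

The test suite exercises: the interval-merge episode builder against a
brute-force day-grid oracle on 10,000 random prescription sets (including
exact 29/30-day boundary gaps); label recovery on a 5,000-patient
zero-gap cohort; parameter recovery of the proportional-odds fitter at
n = 50,000 (β within ±0.05 of log 2) and 95% CI coverage over 500
replicates at n = 2,000; familywise error of both many-to-one tests over
10,000 simulated nulls with unbalanced groups (100/20/60), checked
against three Monte-Carlo standard errors of the nominal 0.05; and
agreement of the Steel normal approximation with a 40,000-draw
permutation oracle to within 0.01. Cross-checks against independent
implementations (`multcomp::glht` for Dunnett, `MASS::polr` for the
ordinal model) pin the estimates, standard errors and adjusted p-values.

## Limitations

* Only the first, index-anchored episode per patient is analysed.
* Percentages follow the half-up, one-decimal table convention
  (`round_half_up()`), not banker's rounding.
* The Steel adjustment relies on the large-sample bivariate normal;
  for very small or extremely tied groups use the permutation mode.
* Step 2 of variable selection encodes judgment as configuration; it
  cannot discover collinearity it was not told about beyond the
  declared pairs.
* Claims semantics (suspected-diagnosis flags, DPC billing detail,
  drug-price data) are out of scope; diagnoses are taken at face value.
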