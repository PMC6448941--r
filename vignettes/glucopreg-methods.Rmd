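---
title: "Methods: glucose-regulation indices, inference and simulation in glucopreg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: glucose-regulation indices, inference and simulation in glucopreg}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glucopreg)
```

glucopreg analyses frequently sampled oral and intravenous glucose
tolerance tests in pregnancy cohorts with a gastric-bypass (RYGB) arm, an
obese control arm and a normal-weight control arm. This vignette documents
the models and procedures, the tunable constants and their defaults, the
numerical choices, what the synthetic-cohort generator does and does not
emulate, and the package's known limitations.

## Data model

Measurements live in long/tidy tables — one row per (subject, visit,
analyte, time) — because the test batteries are sparse in practice: single
samples are lost to haemolysis, whole experiments to missed appointments.
An empty value field encodes a missing sample; an explicit zero is rejected
as an integrity error, since a concentration of zero is never a valid assay
result. Times are integer minutes since the glucose dose and must lie on
the declared protocol grid (OGTT: 0–180 by 30; IVGTT:
0/3/4/5/6/8/10/15/20/30/40/50/60). Concentrations are stored in the
clinical units of this field (glucose mmol/l, insulin pmol/l, C-peptide
nmol/l); all unit conversions happen inside the index functions, never at
I/O. Glucagon has no unit stated by the assay convention adopted here and
is carried as "assay units", excluded from all index mathematics.

## Indices

**QUICKI.** Fasting (predominantly hepatic) insulin sensitivity,
$1/(\log_{10} I_0 + \log_{10} G_0)$ with $I_0$ in µU/ml and $G_0$ in
mg/dl. Conversions are configuration constants
(`units$glucose_mgdl_per_mmol = 18.016`,
`units$insulin_pmol_per_uu = 6.0`) because the insulin convention varies
between 6.0 and 6.945 pmol/l per µU/ml across laboratories; the default
reproduces the expected population scale (for example
`quicki(4.15, 47)` = `r round(quicki(4.15, 47), 3)`).

**OGIS (2-h form).** A formula-based glucose-clearance estimate from
glucose at 0/90/120 min and insulin at 0/90 min, scaled to body surface
area (DuBois). The formula constants (`ogis$p1 … p6`, distribution volume
$V = 10^4$ ml/m², clamp reference $G_{cl} = 90$ mg/dl, oral dose 75 g) are
held in the configuration. When height and weight are not recorded — they
rarely are in covariate exports — body surface area is derived from BMI at
the first visit and a configurable default height (1.66 m); this choice
affects OGIS only through the dose-per-area term and shifts values by a
few per cent at most. Sanity properties enforced in the tests: more
insulin at identical glucose lowers OGIS; a higher 120-min glucose at
fixed insulin lowers OGIS; a normal-weight subject lands in the 400–650
ml min⁻¹ m⁻² population range.

**Glucose shape (variability) index.** The discrete second-order
derivative of the 3 h glucose curve, aggregated as the mean *absolute*
central second difference divided by the squared 30-min sampling step and
then by a fixed normalisation level, `whosh$norm = 2.24e-3` mmol/l min⁻²,
so a typical curve scores near 1. The absolute-value aggregation is a
design decision: the index must be non-negative, vanish exactly for affine
curves, and grow with curvature of either sign; squared-difference
aggregation would satisfy the same constraints but change the scale, so
the choice is documented here and fixed. The index is invariant to adding
any linear trend and scales linearly under positive scaling of the curve
(before normalisation).

**IVGTT indices.** AIRg is the mean incremental insulin
$\overline{I(t) - I(0)}$ over the 3–10 min window, which by construction
ends before the 20–25 min exogenous insulin infusion, so it measures pure
endogenous first-phase secretion. A negative AIRg (insulin falling below
fasting after the bolus) is pathological input; it is passed through with
a warning and propagates its sign into the disposition index. CSI, the
empirical calculated sensitivity index, is defined in this package as

$$\mathrm{CSI} = k \cdot 10^4 \cdot K_G \,/\, \bar{\Delta I},$$

where $K_G$ (min⁻¹) is the negative least-squares slope of log glucose
over the 10–50 min window and $\bar{\Delta I}$ (pmol/l) is the
time-averaged incremental insulin over 0–60 min. The exposure window
deliberately includes the exogenous infusion: the quantity measured is
glucose disposal per unit of circulating insulin, whatever its source,
which is what makes the index comparable across subjects with different
endogenous responses. The scale factor $k$ (default 1) and both windows
are configuration constants, and the function refuses to run if any is
unset rather than defaulting silently. On this definition a
normal-sensitivity pregnant subject scores ~0.3–0.5 on the
×10⁻⁴ min⁻¹ (pmol/l)⁻¹ reporting scale, an insulin-resistant obese
subject ~0.1–0.2, matching the published population scale of such
indices. The disposition index is the bilinear product
$\mathrm{DI} = \mathrm{CSI} \times \mathrm{AIRg}$ (reported on the ×10⁻⁴
scale); the worked check `disposition_index(0.404, 521)` =
`r round(disposition_index(0.404, 521), 1)` rounds to the published
matched-subgroup median of 210.

**Secretion ratios.** AUC(insulin)/AUC(glucose) over 0–60 (early), 60–180
(late) and 0–180 min (total), in pmol/mmol. AUCs use the linear trapezoid
rule on the protocol grid; a fine-grid oracle in the tests pins this
semantics (the AUC of the piecewise-linear interpolant), and additivity
over adjacent windows holds to 1e-12.

**Classifications.** Gestational diabetes screening is the inclusive OR
rule — fasting ≥ 5.1, 60 min ≥ 10, 120 min ≥ 8.5 mmol/l — returning which
components fired. Post-load hypoglycaemia is a *strict* nadir < 2.78
mmol/l among samples at t > 0 only: the fasting value is never a nadir,
so a low fasting level alone cannot trigger the flag. Boundary behaviour
(inclusive vs strict) is asserted at the exact threshold values in the
test suite.

## Statistical inference

All tests are two-sided at α = 0.05 with no multiplicity adjustment — the
design target is an explorative observational comparison, and adjusted and
unadjusted conclusions are left to the reader of the report tables.

**Brunner–Munzel.** The primary two-sample tool, chosen for validity with
small, tied, heteroscedastic samples. The estimand is the relative effect
p̂ = P(X < Y) + ½P(X = Y) via mid-ranks; inference uses the studentised
statistic with Satterthwaite-type degrees of freedom (the standard
small-sample t-approximation, not the permutation variant). Orientation:
`brunner_munzel(x, y)` estimates the probability that a `y` observation
exceeds an `x` observation, and p̂(x,y) + p̂(y,x) = 1 exactly. When the
samples are completely separated the rank variances vanish and the
studentised statistic degenerates; the function then reports the boundary
relative effect (0 or 1) with an infinite statistic rather than failing,
and errors only in the genuinely uninformative all-tied case. The
empirical size of the test at nominal 0.05 is verified by simulation
(10,000 null replicates, n = 15 vs 20 with doubled variance in one arm)
to lie in [0.03, 0.07].

**Paired rank test.** For pregnancy-vs-postpartum contrasts. Zero
differences are dropped; for ≤ 14 informative pairs the null distribution
is obtained by exact enumeration of all sign assignments on the mid-ranks
(so ties, including the all-equal-shift case, are handled exactly);
larger samples fall back to the usual normal approximation.

**Spearman correlation.** Mid-rank ρ with the t-approximation p-value and
a Fisher-z confidence interval using the rank-correlation variance
1.06/(n−3) (the variance inflation relative to Pearson's 1/(n−3) is a
configuration-documented choice).

**ANOVA + protected LSD.** Three-group omnibus F, with pairwise
pooled-variance least-significant-difference t tests evaluated only when
the omnibus p ≤ 0.05; otherwise the pairwise slots are returned `NA` and
flagged not-evaluated. With two groups the procedure reduces exactly to
the pooled-variance t test.

**Hyperbolic regression.** `hyperbolic_fit()` fits
$y = a + b/x$ by ordinary least squares on the transformed predictor
$1/x$ and returns a classed model object with `coef`, `predict`,
`residuals`, `fitted`, `summary` and `plot` methods. Noiseless data on
the curve are recovered exactly (to numerical precision), which is the
basis of the acceptance check on the published sensitivity–secretion
line.

## Matching and imputation

**Propensity matching.** Treatment (RYGB) is regressed on the matching
covariates (default: BMI at the first visit) by logistic regression;
treated subjects are matched 1:1 to controls greedily in descending
propensity order (hardest-to-match first, ties broken by subject id for
determinism), without replacement, keeping a pair only when the
propensity distance is within 0.25 SD of the score. The caliper is
applied on the response (probability) scale by default with the logit
scale as an option. If the logistic fit separates, matching falls back to
standardised covariate distance with a warning rather than failing.
Standardised mean differences before/after are returned for balance
diagnostics. Age is deliberately not in the default covariate set:
adding it is possible via the configuration but does not generally
improve balance in cohorts of this structure.

**Missingness rule and imputation.** An "experiment" is one analyte curve
within one test occasion. Experiments missing ≥ 50 % of their grid are
excluded outright; those below the ceiling are eligible for
chained-equation imputation: per (test, visit, analyte) the subject ×
timepoint matrix is cycled through per-column linear regressions on the
other timepoints with normal-noise draws (10 burn-in cycles), m = 50
completed matrices are averaged cellwise, and observed cells are never
altered. Imputation runs on the log scale so draws stay positive. With
few observed rows the conditional model degrades gracefully (row-mean
regression, then mean/SD draws). The whole procedure is deterministic
given its seed, which is recorded in the imputation log. Because adjacent
OGTT timepoints are strongly linearly related on the log scale, interior
samples are recovered to within a few per cent and the downstream
mean-glucose bias under 10 % MCAR masking is below 2 % (asserted in the
tests); fasting samples, which have no left neighbour, carry the largest
imputation error.

## The synthetic cohort generator

No subject-level data are distributed with studies of this design, so the
generator is the package's test bed: it produces cohorts with *known
ground truth* whose group-level behaviour carries the structure the
analysis assumes.

**Latent curves.** Each subject's OGTT glucose curve is piecewise
log-linear through (0, fasting) → (peak time, peak) → (nadir time, nadir)
→ (180, recovery), evaluated exactly on the protocol grid. This family
was chosen over differential-equation models for transparency: the
ground-truth index panel is computed by the package's own index functions
from the latent curves, so noiseless simulated subjects reproduce their
truth panels *exactly*, and noisy recovery is a pure measurement-error
question. RYGB subjects peak at 30 min and fall to a sub-fasting nadir at
90 min (median 2.36 mmol/l); both control arms peak at 60 min and decay
monotonically to their post-load minimum at 180 min (obese 4.67, normal
3.83 mmol/l). Insulin and C-peptide follow the glucose excursion
(anchored at their fasting levels at t = 0) with group-specific fasting
and peak levels reproducing the published ordering of medians, not their
exact values. Glucagon is generated shape-only (an early rise in the RYGB
arm) and excluded from all quantitative checks. IVGTT glucose decays
exponentially from a ~9.5 mmol/l bolus rise at the subject's disappearance
rate (accelerated after the 20-min insulin infusion); IVGTT insulin is a
first-phase exponential hitting the subject's target AIRg plus an
exogenous infusion bump.

**Between-subject variation** is lognormal on fasting, peak and nadir
levels (and on the IVGTT parameters), with log-SDs calibrated once so the
simulated cohort SDs approximate the published group SDs — the
calibration is approximate by design and is not revisited. The RYGB
template couples the insulin-peak score negatively (loading −0.5) to the
nadir score: stronger post-load secretion drives deeper hypoglycaemia,
which is the physiological mechanism the study design attributes to the
operated gut.

**Noise** is multiplicative lognormal per sample at the assay CVs:
glucose 1.3 %, insulin 5.5 % (midpoint of the 4–7 % assay range),
C-peptide 3.5 %, glucagon 5 %. `noise_model(0)` switches it off.

**Neonatal outcome.** Birthweight percentiles are produced by a Gaussian
copula on the latent normal scores: the percentile score loads 0.90 on
the subject's nadir score within the RYGB arm (0.30 in the control arms)
and 0.20 on the BMI score, plus a group-level location shift calibrated
to the published group means (42.8 / 67.1 / 42.0). A Pearson loading of
0.90 implies a Spearman rank correlation of 6/π·asin(0.45) ≈ 0.886, the
generator's stated target for the within-RYGB nadir association; the
cohort-wide BMI association emerges mostly from the group structure.

**What the generator does not emulate** — and hence what passing tests do
*not* establish about real data: curves are unimodal with fixed knot
times, so the within-group variation in peak/nadir *timing* seen in real
cohorts is absent (one consequence: simulated RYGB subjects essentially
never meet the 60-min GDM criterion, whereas real RYGB pregnancies often
do, because real peaks sometimes persist to 60 min); missingness is
injected MCAR or as whole-visit dropout, not by the informative
mechanisms of clinical attrition; postpartum visits redraw subject-level
effects rather than following individual trajectories, so paired analyses
see the group-level shift (e.g. the built-in postpartum CSI improvement
and fasting-glucose rise) with realistic but not subject-faithful
within-pair correlation.

## Problem sizes and determinism

All stochastic procedures take explicit integer seeds, and identical
seeds give bit-identical output. The validation suite uses arm sizes
scaled to what each property needs: exact-recovery and structural checks
run at 3–25 subjects per arm; median-recovery and copula-targeting checks
at 200 per arm; the directional three-arm contrasts at 50 per arm over 20
seeds; and the Brunner–Munzel size check at 10,000 null replicates.
Pre-registered tolerances: noisy group-median indices within 10 % of the
noiseless truth medians at n = 200/arm; the within-RYGB nadir–percentile
Spearman within 0.06 of its copula target (and inside its own 95 % CI in
the end-to-end check); directional contrasts in the expected direction in
at least 19 of 20 seeds.

## Known limitations

- The CSI and OGIS constants are configuration values transcribed into
  this package; sites using different IVGTT sampling schedules or 3-h
  OGIS variants must supply their own constants (the CSI code refuses to
  run with unset constants for exactly this reason).
- The multiple-contrast analogue of the pairwise Brunner–Munzel tests
  (simultaneous rank-based contrasts) is not implemented; pairwise tests
  without adjustment are applied uniformly.
- Optimal (network-flow) matching and predictive-mean-matching imputation
  variants are out of scope; greedy caliper matching and normal-draw
  chained equations are the implemented defaults.
- Only two visits (pregnancy, postpartum) are modelled; there is no
  gestational-age trajectory within pregnancy.
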