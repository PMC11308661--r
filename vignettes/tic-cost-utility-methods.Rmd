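---
title: "Methods: utility mapping and the aripiprazole cost-utility model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: utility mapping and the aripiprazole cost-utility model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ticonomics)
```

## Overview

`ticonomics` implements a two-stage pharmacoeconomic analysis for children and
adolescents with tic disorders:

1. **Utility mapping.** The Yale Global Tic Severity Scale (YGTSS) — motor and
   vocal subscales (each 0–25) summing to a total tic score $YT$ (0–50) — is
   mapped onto EQ-5D-Y health utilities with two regression families crossed
   with four predictor sets.
2. **Cost-utility model.** A 52-week decision tree compares low-dose
   (5 mg/day) and high-dose (10 mg/day) oral aripiprazole (and placebo) from a
   healthcare-system perspective, reporting expected costs, QALYs, responder
   counts, the ICER and net monetary benefit, with one-way (tornado) and
   probabilistic sensitivity analysis.

Because the underlying survey data are not available, a synthetic-cohort
generator reproduces the statistical structure the mapping stage assumes, so
every stage is testable end to end.

## The mapping stage

### Model

For patient $i$ with utility $Y_i$ and covariates $x_i$:

* **Gaussian identity** (ordinary least squares): $Y_i = x_i^\top\beta +
  \varepsilon_i$, $\varepsilon_i \sim N(0, \sigma^2)$. Predictions are the
  linear predictor and are deliberately *not* clipped to $[0,1]$; a mapping
  evaluated at $YT=0$ therefore returns exactly its intercept.
* **Beta regression** (logit mean link, constant precision $\phi$):
  $Y_i^* \sim \mathrm{Beta}(\mu_i\phi, (1-\mu_i)\phi)$ with
  $\mathrm{logit}(\mu_i) = x_i^\top\beta$. The beta likelihood requires
  responses in the open interval $(0,1)$, while EQ-5D-Y utilities pile up at
  the ceiling value 1 ("ceiling effect"), so observed utilities are first
  compressed with the affine boundary transform
  $$Y^* = \frac{Y\,(N-1) + 0.5}{N},$$
  where $N$ is the number of participants entering the fit (configurable via
  `boundary_N`; 144 in the reference analysis). The map is order-preserving,
  fixes $0.5$, and sends $[0,1]$ onto $[0.5/N,\, 1-0.5/N]$.

The four predictor sets are: (1) $YT$; (2) motor + vocal subscales; (3) $YT$ +
sex; (4) subscales + sex (sex coded 0 = female, 1 = male). Rows missing a
required covariate are dropped for that fit only, and `n_used` is reported.

The beta family is fitted by direct maximum likelihood over
$(\beta, \log\phi)$ (BFGS, relative tolerance $10^{-12}$), with standard
errors from the observed information matrix. The test suite cross-checks
coefficients and $\phi$ against `mgcv::gam(..., family = betar("logit"))` as
an independent implementation.

### Fit and validation metrics

AIC and BIC come from the respective likelihoods ($\phi$ counts as a
parameter for the beta family, $\sigma^2$ for the Gaussian). Adjusted $R^2$
for the Gaussian family is the usual OLS statistic; for the beta family a
pseudo-$R^2$ is used — the squared Pearson correlation between
$\mathrm{logit}(Y^*)$ and the fitted linear predictor, degree-of-freedom
adjusted the same way. MAE and RMSE are computed on the **original** utility
scale for both families (beta predictions are inverse-linked but the boundary
adjustment is not inverted; `invert_boundary = TRUE` switches this, and the
difference is $O(1/N)$). This choice matches how the published predicted means
are compared directly with observed utilities.

Covariate screening follows the "keep demographics with $p<0.05$" rule, but
the sex-included fits (models 3–4) are always reported as well, since the
reference analysis itself retains sex at $p \approx 0.06$–$0.08$.

### The published predictor

The mapping consumed by the decision tree is the selected total-score linear
model

$$\widehat{U} = 0.9881 - 0.0035 \times YT,$$

available as `published_mapping()` and used to derive (i) the baseline
utility at the trial's baseline severity ($YT = 30.37 \Rightarrow \widehat U =
0.881805$) and (ii) the adverse-event disutility, assumed to be 10% of that
baseline utility: `disutility_from_baseline(30.37)` $= -0.0881805$. The
published parameter table rounds this to $-0.090$; both are accepted inputs
and the literal $-0.090$ is the default.

## The synthetic cohort

### What it emulates

`cohort_config()` defaults encode the survey summaries: $n = 144$, 86.99%
male, age 9.01 (SD 2.47) years, YGTSS motor 11.28 (SD 5.07), vocal 4.95
(SD 6.36), and a negative linear utility–severity relationship with intercept
0.9881 and slope $-0.0035$ — the published mapping itself is taken as the
generating truth. Gaussian noise (SD 0.07) is added and the result is censored
above at 1 (the ceiling) and truncated below at the value-set floor
(default 0). `noise_sd = 0.07` was chosen once so that
$\text{slope}^2\mathrm{Var}(YT) + \text{noise}^2 \approx 0.0832^2$, the
printed utility variance, before censoring.

Subscale scores are independent truncated normals on $[0,25]$ rounded to
integers; the total is their exact per-record sum (printed means are
consistent with summation: $11.28 + 4.95 \approx 16.24$). **Numerical
choice:** the truncated-normal *location* is solved (by `uniroot` on the
truncated-mean equation) so that the *realized* truncated mean equals the
configured mean. With the vocal scale's SD (6.36) exceeding its mean (4.95),
naive truncation at 0 would inflate the realized mean by about $+2.4$ points
and push the total score far from its target. The realized SD is consequently
somewhat below the printed SD — the price of matching means under a hard
floor.

Height (1/144) and weight (2/144) missingness rates mirror the incomplete
questionnaires in the survey table; fits drop incomplete rows only for models
that use the missing covariate (the four canonical models use only YGTSS
scores and sex, so these defaults are inert there).

### What it does not emulate

* Correlation between motor and vocal scores (none is reported; they are
  drawn independently).
* The exact shape of the ceiling mass: censoring a Gaussian at 1 produces a
  point mass whose size falls with severity, but the real mixture of health
  states does not follow from any printed quantity. An explicit extra point
  mass (`ceiling_prob_at_zero`, decaying linearly to zero at $YT=50$) exists
  for stress tests, default off.
* Real 5-digit EQ-5D-Y health states. `toy_value_set()` is an interface stub
  with a synthetic additive value set, for plumbing tests only.

A green mapping test therefore establishes that the estimators recover a
known generating process of the assumed form — not that the published
coefficients are re-derivable from real data.

**Censoring and parameter recovery.** Censoring at 1 biases OLS toward a
flatter slope (about 19% of $|b|$ at these settings), so parameter-recovery
simulations disable the ceiling (`utility_ceiling = Inf`). Recovery targets
(coefficients within 2 SE; mean slope bias below 10% of $|b|$ over 50 seeds at
$n=1000$) are asserted against the uncensored generator.

## The decision tree

Each arm is a two-level chance tree over a 52-week horizon: discontinue due to
adverse events (probability $p_{AE}$) versus continue; continuers split into
post hoc response ($>50\%$ YGTSS reduction), partial response (25–50%) and
non-response ($<25\%$), **conditionally on not discontinuing** — this reading
reproduces all four published responder counts per 1000 patients exactly
(rounded half away from zero).

### Costs

* Direct medical costs: \$31.50/week accrued by **all** patients for the full
  52 weeks (\$1638.00/patient, the entire placebo-arm cost).
* Drug costs: \$0.72 per 5 mg, scaled linearly by dose; continuers are exposed
  for a 364-day drug-year ($52\times7$), AE-discontinuers for 8 weeks (the
  source trial's treatment period) and nothing after.

These conventions reproduce the published totals to the cent (\$1894.98
low dose, \$2092.97 high dose, increment \$197.99); with a 365-day year or
other AE exposure durations they do not. No within-horizon discounting is
applied by default (1-year model); `discount_rate` is stored for scenario
work.

### QALYs and the AE-branch convention

Continuers accrue the expectation of their response-state utility (0.934 /
0.919 / 0.902) over the year. The published inputs do not pin down which
utility AE-discontinuers accrue, and no single reading reproduces the
published QALYs (0.909/0.910) — with these inputs the high-dose arm has
*lower* expected QALYs than low dose under every reading, because its
15.6% discontinuation rate outweighs its response advantage. Three explicit
conventions are implemented and surfaced in configuration and reports:

| convention | AE-branch utility |
|---|---|
| `baseline_minus_disutility` (default) | mapped baseline utility $+$ disutility |
| `nonresponse_minus_disutility` | non-response utility $+$ disutility |
| `response_mix_minus_disutility` | continuers' expected utility $+$ disutility |

Under all three, with baseline inputs, high dose is **dominated** (more
costly, fewer QALYs), so the qualitative conclusion — high-dose aripiprazole
is not cost-effective at a willingness-to-pay of \$36,832.95/QALY (three times
2022 per-capita GDP) — is convention-invariant, and that property (dominated
*or* ICER above threshold), rather than any printed QALY value, is what the
acceptance suite asserts. `icer()` classifies dominance explicitly and
reports no ratio when $\Delta QALY \le 0$ would make it meaningless.

## Sensitivity analysis

### Ranges

`default_ranges()` reproduces the published ranges: costs and the baseline
YGTSS score at $\pm20\%$, probabilities at $\pm10\%$ (as printed, i.e.
rounded to three decimals), AE disutility at $\pm50\%$, and the drug price
over its printed market spread \$0.32–\$1.52 (which is wider than $\pm20\%$
and is used verbatim). Response-state utilities carry no published range and
are held fixed; baseline severity, which drives the AE disutility through the
mapping, *is* varied. Placebo parameters are excluded from the pairwise
comparison by default.

### Tornado (one-way)

Each parameter is set to its low and high bound with all others at base, and
the high-vs-low incremental result is recomputed. Because the base case is
dominance (negative $\Delta QALY$), an "ICER swing" is ill-defined there:
dominated scenarios are flagged, the ICER swing is reported only when both
ends yield a defined ratio, and entries are **ordered by the net-monetary-
benefit swing** $|\Delta NMB|$ at the WTP threshold, which is well-defined in
every scenario and preserves the usual tornado reading. The direct medical
cost has zero swing by construction (it hits both arms identically).

### PSA, CEAC and scatter

Each range is read as a 95% interval: draws have mean `base` and SD
$(\text{high}-\text{low})/3.92$, with gamma (costs, scores) or beta
(probabilities; disutility on its magnitude scale, then negated) parameters
from the method of moments, drawn independently. Infeasible moment matching
(SD too large for a beta mean) errors naming the parameter. Drawn sets whose
response probabilities would sum past 1 within an arm are rejected and
redrawn inside the seeded stream, keeping runs bit-reproducible.

The CEAC computes, at each WTP, the fraction of iterations with positive
high-dose net monetary benefit; ties (NMB exactly 0) go to the cheaper
strategy, and the two strategies' probabilities sum to 1 by construction.
NMB rather than per-iteration ICERs avoids division blow-ups when
$\Delta QALY$ crosses zero. With baseline inputs the low-dose strategy is
cost-effective in essentially all iterations at the \$36,832.95 threshold —
more extreme than the published 87.3%, which presupposes the positive
base-case $\Delta QALY$ discussed above. The scatter export flags each
$(\Delta QALY, \Delta\text{cost})$ point as `above`, `below` or
`on-threshold` relative to the WTP ray (`above` $\iff \Delta\text{cost} >
\text{WTP}\times\Delta QALY$, i.e. high dose not cost-effective).

## Degenerate inputs and numerical conventions

* Mapping fits require $\ge 10$ complete rows and non-constant predictors;
  they refuse rather than regularize.
* The boundary transform requires $N \ge 2$.
* Responder counts round half away from zero (base R's `round()` is
  banker's rounding); costs are reported to cents.
* Beta-regression starting values: OLS on $\mathrm{logit}(Y^*)$ for $\beta$,
  method-of-moments for $\phi$; non-convergence or a singular information
  matrix is an error, not a silent fallback.
* Configuration is JSON (YAML accepted when the `yaml` package is present);
  every missing field is filled from the published defaults with a logged
  notice, and schema violations name the offending keys.

## Known limitations

* The mapping stage is validated against synthetic data only; nothing here
  re-derives the published coefficients from patient data.
* The published QALY totals and ICER are not reproducible from the published
  inputs (see above); this package reports the convention-resolved results
  and flags the discrepancy rather than calibrating toward the printed
  figures.
* No cross-validation, tobit/two-part mapping models, Markov extensions,
  comparator drugs, societal costs, or EVPI.
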