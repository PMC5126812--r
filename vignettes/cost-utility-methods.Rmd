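---
title: "Methods: EQ-5D-5L analysis and the cost-utility simulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: EQ-5D-5L analysis and the cost-utility simulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rareboneqol)
```

This vignette documents the models and the numerical and design choices
behind `rareboneqol`: how EQ-5D-5L health states are scored, how the
between-disease statistics are computed, what the synthetic-cohort generator
emulates (and what it does not), and how the 10-year cost-utility simulation
and willingness-to-pay tables are defined.

## Scoring EQ-5D-5L health states

The EQ-5D-5L describes health on five dimensions (mobility, self-care,
usual activities, pain/discomfort, anxiety/depression), each at five levels,
giving $5^5 = 3125$ states, plus a 0–100 visual analogue scale (VAS). A value
set assigns each (dimension, level) pair a non-negative utility decrement,
zero at level 1; the utility of state $s$ is

$$U(s) = 1 - \sum_{d} \delta_d(\ell_d(s)).$$

Value sets are data, not code: a CSV with columns `dimension,level,decrement`
(see `read_value_set()`). The packaged England set has floor
$U(55555) = -0.285$; negative utilities denote states worse than dead. The
package never rounds utilities during computation — three decimals is a
display convention only. Missing VAS values are allowed (VAS never enters the
utility); missing dimension levels are a hard error, because an unscored
state cannot be imputed defensibly.

For contingency analyses the five levels collapse into three problem
categories: levels 1–2 "no/slight", level 3 "moderate", levels 4–5
"severe/extreme" (`collapse_level()`).

## Descriptive and inferential statistics

`build_contingency()` cross-tabulates the three disease groups against the
three collapsed categories of one dimension. `fisher_exact()` computes the
two-sided exact p-value under the fixed-margins hypergeometric null, defined
as the total probability of all tables whose point probability does not
exceed the observed table's (ties within a $10^{-7}$ relative tolerance).
This is the convention of standard statistical software; the exact
computation uses the network-algorithm enumeration in `stats::fisher.test()`,
and a seeded Monte-Carlo sampler over fixed-margin tables
(`method = "monte_carlo"`) is available for tables too large to enumerate.
The tests cross-check the exact route against an independent Monte-Carlo
estimator.

The exact test is run on the 3×3 *collapsed* tables. Running it on the raw
5×3 tables is a defensible alternative, but the collapsed reading is the one
consistent with the published p-values, so it is the default and the only
implemented route.

Group means are compared with classical one-way ANOVA (`anova_oneway()`),
associations with age by simple least squares plus the Pearson coefficient
(`fit_linear()`). Summaries use the sample SD ($n-1$ denominator); a
single-observation group reports SD 0 with an explicit `sd_defined = FALSE`
flag rather than `NA`, so downstream tables stay numeric.

`split_tertiles()` sorts patients by ascending utility — ties broken by
patient id, a stable, reproducible rule — and cuts three contiguous blocks.
A remainder is allocated from the lowest tertile upward, so 43 patients
split 15/14/14. The low-loaded remainder is forced by the simulation design:
the treated group must be the 15 patients with the lowest utilities.

## The synthetic cohort generator

The study's patient-level data are not publicly deposited, so every
downstream stage is exercised against a seeded generator calibrated to the
published group-level summaries:

* **Sizes and demographics.** 43 OI / 42 FD / 24 XLH; ages truncated normal
  at the published mean/SD within the published ranges (only these three
  quantities are published, which a truncated normal matches exactly in
  spirit and nearly in moments); sex Bernoulli at the published female
  shares (77/69/79%).
* **Responses.** Independent per-dimension multinomials with the published
  level frequencies (packaged as `extdata/table2_counts.csv`). Only marginal
  frequencies are published, so dimensions are drawn independently.
* **VAS.** Truncated normal on [0, 100] at the published mean/SD, rounded to
  integers. Truncation pulls the realised mean slightly below the nominal
  parameter (about 66 for a nominal 69.4); the nominal values are used as
  parameters, not as targets. Two slightly different VAS mean/SD sets appear
  in the source report; the generator uses the results-section values.
* **Utilities.** A two-component truncated-normal mixture on the value-set
  range $[-0.285, 1]$, reflecting the clearly bimodal published
  distributions. Defaults: weights 0.46/0.54, components
  $N(0.43, 0.24^2)$ and $N(0.87, 0.105^2)$.

The mixture constants are a *calibration*, not published quantities. They
were fitted (scripts/calibrate-mixture.R in the source tree) to the two
moments the economic results depend on: an overall mean utility of about
0.65, and a mean of about 0.339 over the lowest 15 of a 43-person sample —
the lower-tertile mean implied by the published base-case QALY gain of 2.47
toward target 0.745 at 75% attainment. The realised mixture SD (≈0.27) is
slightly below the published 0.283; matching the two decision-relevant
moments was preferred over matching the SD, and the gap is accepted and
documented rather than tuned away.

Within the OI group, age is coupled to usual-activity level (Pearson
$r = 0.39$), VAS ($r = -0.42$) and utility (via the published utility-on-age
slope of $-0.005$ per year) through a Gaussian copula: a latent 4-variate
normal with a star-shaped correlation structure around age, each margin
transformed by its own quantile function. A copula is the natural choice
when only pairwise correlations are published. The slope target is converted
to a latent correlation through the configured marginal SDs
($r = \beta\,\sigma_{\mathrm{age}}/\sigma_u$); monotone marginal transforms
attenuate the realised Pearson correlation by a few percent, well inside the
±0.1 (correlations) and ±0.002 (slope) recovery tolerances the tests assert.
Requested couplings are rejected as infeasible when the squared correlations
with age sum to ≥ 1.

Two utility modes are exposed because no *joint* distribution of responses
and utilities is published: `"mixture"` draws utilities directly from the
calibrated mixture (the distribution the economic simulation assumes), while
`"valueset"` scores the generated responses with a value set. The two are
deliberately not forced to agree.

Randomness is routed through one master seed; each stream (per disease:
latent copula, responses, sex) derives a fixed child seed, so adding a
stream never perturbs the others and cohorts are byte-identical across runs
of the same spec.

What passing tests on this generator show — and what they do not: they show
the *pipeline* reproduces the published aggregate results when fed data with
the published group-level structure. They cannot validate person-level
features the publication does not constrain (joint response patterns,
within-person VAS–utility agreement, comorbidity structure), so agreement on
real patient data is a separate question.

## The cost-utility simulation

A hypothetical treatment is applied to the lower utility tertile of the OI
group over a 10-year horizon with annual cycles $t = 0, \dots, 9$, the first
cycle undiscounted. Per patient with baseline utility $u_0$:

* **Potential improvement**: $\Delta_0 = \max(0, u^\* - u_0)$ with target
  $u^\* = 0.745$, the observed middle-tertile mean. The target is a fixed
  configuration constant, not recomputed per synthetic cohort, so the
  simulation conditions stay those of the original analysis;
  `middle_tertile_target()` reproduces the empirical procedure for users'
  own data.
* **Treatment effect**: $\delta = a\,\Delta_0$ with attainment $a$ (base
  case 0.75, sensitivity grid 0.55–0.95). The effect ramps linearly over the
  first year — contributing $\delta/2$ in cycle 0, the average of a 0→$\delta$
  ramp — and stays at $\delta$ thereafter.
* **Ageing**: both arms lose 0.005 utility per year (the observed
  utility-on-age slope), applied as $u_0 - 0.005\,t$ and clamped to the
  value-set range. Because the decrement is common to both arms, the QALY
  gain is invariant to it whenever clamping does not bind — a property the
  tests assert by rerunning with decrement 0.
* **Discounting**: 3.5% per year on utilities and costs. The timing
  convention (first cycle undiscounted, annuity
  $A = \sum_{t=0}^{9} 1.035^{-t} = 8.60769$) is fixed by the published
  arithmetic: £14,355 × 8.60769 ≈ £123,561 at the £50,000 threshold.

Discounted QALYs per arm are summed over the horizon; the gain is their
difference, $\delta\,(A - 1/2)$ in closed form absent clamping, hence
exactly linear in attainment and in the potential improvement. Mortality is
excluded by construction over the short horizon. The dispersion interval
reported with the mean gain is mean ± 1.96 SD of the per-person gains —
the convention matching the published interval (2.47, SD 1.66, −0.78 to
5.72), which is a dispersion interval rather than a standard-error-based
confidence interval.

Willingness-to-pay: at threshold $\lambda$ per QALY, the maximum constant
annual cost is $\lambda G / A$, the price at which the discounted 10-year
payment stream divided by the QALY gain $G$ equals $\lambda$ exactly (the
ICER identity). `build_wtp_table()` evaluates the grid of nine thresholds
(£20,000–£100,000) by five attainment fractions; cells are exact and rounded
to whole currency units only when printed. Each row is exactly linear in the
threshold and each column proportional to its gain; the published
sensitivity gains deviate from exact linearity by up to ~1.6%, attributable
to rounding in the source report, and are not reverse-engineered.

## Numerical choices and degenerate inputs

* Utilities, QALYs and WTP cells carry full double precision end to end;
  rounding (3 decimals for utilities, whole pounds for WTP, whole percent
  for shares) happens only in print methods and reports.
* Truncated-normal sampling is by inverse CDF, exact up to `qnorm`; the
  mixture quantile inverts the mixture CDF on a 4096-point grid, monotone by
  construction with interpolation error far below any asserted tolerance.
* Degenerate inputs fail loudly: empty treatment groups, fewer than three
  patients at a tertile split, zero within-group variance in ANOVA, constant
  covariates in regression, non-positive margins in the exact test, and
  mixture components with non-positive SD are all hard errors.
* `run_pipeline()` aborts with the failing stage's name and records the
  master seed and a configuration hash in every output bundle, so a results
  file is always traceable to its exact inputs.

## Problem sizes

The package's own test and reproduction runs use desk-scale sizes chosen to
make Monte-Carlo error negligible relative to the asserted tolerances:
$2\times10^5$ draws for marginal-moment checks, $10^4$-patient cohorts for
correlation/slope recovery, 500 replicates of 43-patient cohorts for the
simulation reproduction, and $4\times10^5$–$10^6$ resampled tables for the
exact-test cross-checks. All complete in seconds to a few minutes on one
core.

## Known limitations

* Dimensions are generated independently within patients; real EQ-5D
  profiles are correlated across dimensions.
* The two utility modes (mixture vs value-set scoring) are not mutually
  consistent, by design; choose the one matching your question.
* The exact test's enumeration is practical for 3×3 tables at this cohort
  size; very large sparse tables need the Monte-Carlo method.
* No multiple-testing correction is applied (none was applied in the source
  analysis); no probabilistic sensitivity analysis beyond the attainment
  grid, no half-cycle correction, no mortality, no discontinuation.
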