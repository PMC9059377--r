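---
title: "Methods: MF-BIA prediction of appendicular lean mass"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: MF-BIA prediction of appendicular lean mass}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(leanmass)
```

## The measurement model

Whole-body bioimpedance treats the conducting tissue of the body as a
cylindrical volume: conductive volume is proportional to length² /
impedance, which motivates the impedance index

$$ZI_{@f} = \frac{\mathrm{Ht}^2}{Z_{@f}} \quad [\mathrm{cm}^2/\Omega],$$

with height in cm and the impedance magnitude $Z$ (or, for $RI$, the pure
resistance $R$) in ohm at measurement frequency $f$. Low-frequency current
travels around cells through extracellular fluid; at frequencies of 1 MHz
and above it penetrates cell membranes and samples intracellular water,
which dominates skeletal muscle. That is why an ALM-specific index is
sought at the high end of the device grid (1 kHz – 3 MHz, eight fixed
frequencies), and why the package's frequency scan ranks the bivariate
regressions of DXA-measured ALM on each frequency's index by both
R² and SEE.

Prediction equations are affine maps

$$\widehat{\mathrm{ALM}} = b_0 + \sum_j b_j x_j, \qquad
x_j \in \{ZI_{@f},\, RI_{@f},\, Xc_{@f},\, \mathrm{sex},\,
\mathrm{weight},\, \mathrm{height},\, \mathrm{age},\, \mathrm{BMI}\},$$

with sex coded 1 for men and 0 for women. Affinity has a consequence the
tests exploit: the cohort mean of predictions equals the prediction at the
cohort's covariate means, exactly, so group-level agreement can be checked
from published summary tables without subject-level data.

## Equation development

`stepwise_select()` implements the classic p-value stepwise procedure:
repeatedly, the excluded candidate with the smallest partial-F p-value
enters if it falls below `alpha_enter`, then included terms whose
p-values exceed `alpha_remove` are removed (largest first), until a
fixpoint. For adding a single variable the partial-F test is identical to
the coefficient's two-sided t-test, which is what is computed. Defaults
`alpha_enter = 0.05`, `alpha_remove = 0.10` are the long-standing
defaults of the mainstream statistics packages for this procedure; both
are exposed. Ties in entry p-values are broken by the larger partial F
and then by candidate declaration order, so selection is deterministic.

Two properties of the procedure are worth stating plainly. First, with
many near-collinear null candidates (here: seven other frequencies'
indices, each the 2 MHz index times noise), the chance that *some* null
candidate clears a per-test α of 0.05 in any given round is substantial,
so on development subsamples the selected set occasionally includes a
neighbouring frequency or swaps 2 MHz for one — exactly the instability
stepwise selection is known for. Second, the returned model satisfies a
verifiable fixpoint: every included term's p-value is below
`alpha_remove` and no excluded candidate would enter at `alpha_enter`;
the test suite checks this exhaustively.

Multicollinearity is screened with variance-inflation factors,
$VIF_j = 1/(1 - R^2_j)$, $R^2_j$ from regressing predictor $j$ on the
others; perfect collinearity is reported as `Inf` rather than an error.
Degenerate bivariate inputs (a constant channel) yield a flagged
zero-slope fit so a frequency scan never aborts mid-way.

## The validation battery

For measured $y_i$ and predicted $\hat y_i$ (kg):

* **SEE** $= \sqrt{\sum (y_i - \hat y_i)^2 / (n - p - 1)}$, $p$ = number
  of predictors — development-context accuracy.
* **TE** $= \sqrt{\sum (y_i - \hat y_i)^2 / n}$ — holdout-context
  accuracy. The identity $SEE^2 (n-p-1) = TE^2\, n$ on shared residuals
  ties the two and is asserted in the tests.
* **CV** $= 100 \cdot \mathrm{error} / \bar y$, with SEE as the error in
  a development context and TE in a cross-validation context.
* **PIA** — percent of subjects with $|y_i - \hat y_i|$ within ±1.45 kg
  (men) / ±1.16 kg (women); the boundary counts as within.
* **Subjective rating** — sex-specific half-open bands on SEE/TE:
  men ideal [0.72, 0.90), excellent [0.90, 1.09), very good [1.09, 1.27),
  good [1.27, 1.45); women [0.54, 0.65), [0.65, 0.83), [0.83, 1.01),
  [1.01, 1.16). Values below the ideal band are rated ideal; values at or
  above the good band's upper bound are rated "below-good", because the
  source criteria leave the finer fairly-good/fair/poor bounds unstated.
* **Bland–Altman** — bias = mean difference, LoA = bias ± 1.96·SD of the
  differences (sample SD), plus the correlation of differences with
  per-subject means as a proportional-bias screen. The difference
  direction is a parameter and is stamped on every report: both
  measured − predicted and predicted − measured conventions are current
  in the method-comparison literature, and published reports mix them.
* **Line of best fit** — by default the *measured* values are regressed
  on the *predicted* ones. This is a deliberate choice: for an unbiased
  predictor, measured = predicted + independent noise, so that
  regression has expected slope 1 and intercept 0 — the calibration
  check. The reverse regression (predicted on measured) has expected
  slope equal to the shared R² (≈ 0.93 here) purely by attenuation and
  would "fail" calibration for any imperfect equation; it remains
  available via `response = "predicted"`.

## Sarcopenia classification

ASMI = ALM / (Ht in m)²; a subject is sarcopenic when ASMI is *strictly*
below 7.0 kg/m² (men) or 5.4 kg/m² (women) — the boundary value is
non-sarcopenic. Agreement between the BIA- and DXA-derived
classifications is summarised by the 2×2 table (DXA as reference,
sarcopenic as positive), overall agreement, Cohen's kappa
$\kappa = (p_o - p_e)/(1 - p_e)$ with marginal-based expected agreement,
and sensitivity/specificity/PPV/NPV. Kappa bands use the conventional
scale (slight ≤ 0.20 < fair ≤ 0.40 < moderate ≤ 0.60 < substantial
≤ 0.80 < almost perfect); the published scale is stated with open
intervals, so a deterministic rule is needed at the knots — boundary
values are assigned to the lower band, with a 1e-9 guard so that
floating-point noise cannot flip a band. Rates with zero denominators
(e.g. PPV when nothing tests positive) are reported as undefined, not 0.

## What the synthetic generator emulates

`generate_cohort()` draws, per sex, a correlated multivariate normal over
(height, weight, age, ZI@2MHz, Xc@5kHz, Xc@50kHz) with the published
sex-stratified development-group means and SDs (94 men with ZI@2MHz
67.3 ± 7.9 cm²/Ω, 101 women with 47.6 ± 5.6, and so on), then sets

$$\mathrm{ALM} = 0.247\,ZI_{@2\,\mathrm{MHz}} + 1.254\,\mathrm{sex}
 + 0.067\,Xc_{@5\,\mathrm{kHz}} + 1.739 + \varepsilon,\qquad
 \varepsilon \sim N(0,\, 0.97\ \mathrm{kg}).$$

Generating ALM from the shipped final equation — rather than from an
independent physiological model — is the standard synthetic-stand-in
pattern: it gives every development-stage operation a known truth to
recover (the test suite refits the model at n = 10 000 and requires the
2 MHz coefficient back within 3 standard errors).

Choices where the published moments are silent, fixed once:

* **Cross-frequency structure.** $ZI_{@f} = ZI_{@2\,\mathrm{MHz}} \cdot
  r_f \cdot e^{\eta}$, with $r_f$ the ratio of the published per-sex mean
  at $f$ to the 2 MHz mean, and $\eta \sim N(0, 0.02)$ log-normal jitter
  (positive by construction). Because every other frequency is the 2 MHz
  index plus independent noise, 2 MHz is the best single predictor by
  construction, which the frequency scan must rediscover.
* **Correlations.** Weight–ZI@2MHz 0.6 within sex (a realistic
  anthropometric confounder for stepwise selection to reject);
  reactance–ZI 0.1 (no joint moments are published; the value is weak and
  exposed in the config). Heights are drawn independently of ZI within
  sex — a documented calibration approximation, since the published
  tables give no ZI–height joint distribution.
* **Spectrum consistency.** Z@f = Ht²/ZI@f; the reactance profile uses
  the generated 5 kHz and 50 kHz values, published per-sex mean ratios at
  250 kHz, and a plausible declining beta-dispersion profile at the
  uncalibrated frequencies (reactance peaks near 50 kHz); then
  R = √(Z² − Xc²), so Z² = R² + Xc² holds exactly on generated data. On
  *read* data the identity is only warned about (1% relative tolerance),
  since real devices report independently rounded channels.
* **Truncation.** Normal tails are floored at 0.5 (units of the
  variable) so reactances cannot go non-positive; at the calibrated
  moments this affects well under 0.1% of draws.

What the generator does **not** emulate: Cole–Cole dispersion (the jitter
is frequency-independent), non-normal anthropometry, ZI–height
dependence, body-water compartments, and measurement rounding. Passing
tests therefore demonstrate that the pipeline's statistics behave
correctly under the stated joint-normal structure, not that any equation
generalises to a new human population.

## Numerical and reproducibility choices

* Sample SDs use the n−1 denominator throughout, matching survey-table
  conventions.
* All randomness flows through explicit integer seeds; `generate_cohort()`
  restores the caller's RNG state, and the pipeline derives fixed
  per-stage child seeds from one global seed so stages can be re-run in
  isolation. Identical config + seed gives bit-identical cohorts and
  JSON reports (timestamps are deliberately omitted from reports).
* The development/cross-validation split takes the nearest integer to
  `dev_fraction · n` for the development group (130/65 at n = 195 and
  fraction 2/3) with the remainder to cross-validation.
* Problem sizes in the shipped tests: cohorts of n = 195 for pipeline
  and calibration checks, 20 seeds for across-seed stochastic assertions,
  n = 10 000 for parameter recovery, 100 seeds × n = 200 for the stepwise
  level check — sizes at which the asserted quantities' sampling noise is
  comfortably inside the asserted bands.
* Stochastic test assertions are placed on across-seed means at the
  quantity's expected value, with individual draws bounded at roughly
  4 standard deviations of their sampling distribution.

## Known limitations

* Stepwise p-value selection is supported because it is the field's
  development procedure, with its known instability under collinearity
  (see above); no AIC/BIC or best-subset alternatives are offered.
* Phase angle and Cole–Cole model fitting, segmental impedance, and
  repeated-measures Bland–Altman are out of scope.
* The six external published equations are supported only as
  user-supplied registry entries; their coefficients are not shipped.
* Current amplitude (e.g. 300 µA) plays no computational role and is not
  modelled.
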