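---
title: "Harmonizing child BMI prevalence rates across growth references"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Harmonizing child BMI prevalence rates across growth references}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prevharm)
```

## The model

Child thinness, overweight and obesity are defined as fixed z-score
cut-offs on an LMS growth reference. The LMS representation describes
the BMI distribution at each age and sex by three parameters — the
Box-Cox power L (unitless, governs skewness; negative for child BMI),
the median M (kg/m²) and the coefficient of variation S (unitless) —
with

$$z = \frac{(x/M)^L - 1}{L\,S}, \qquad x = M\,(1 + L S z)^{1/L},$$

and the logarithmic limit $z = \log(x/M)/S$ when $L = 0$. If the LMS
model holds, z is standard normal, so a cut-off at z defines a tail
prevalence $\Phi(-z)$ above it (or $\Phi(z)$ below it, for thinness).

Two cut-offs $z_A$ and $z_B$ defined on *different* references are not
directly comparable: the references' L, M and S curves differ. The
package places them on a common scale by back-transforming each cut-off
to its BMI value at the given age and sex and re-scoring that BMI on the
other reference, giving cross z-scores $z_{A,B}$ and $z_{B,A}$. Each
cut-off then has a symmetric position $\bar z_A = (z_A + z_{A,B})/2$,
$\bar z_B = (z_B + z_{B,A})/2$, and the cut-off distance is

$$dz_{A,B} = \bar z_B - \bar z_A
  = \tfrac12\left[(z_B - z_A) + (z_{B,A} - z_{A,B})\right],$$

which is antisymmetric by construction: $dz_{B,A} = -dz_{A,B}$.

Averaging over both references matters because neither reference is
privileged: scoring only on A or only on B gives two different
distances, and the mean is the symmetric compromise that makes the
conversion direction-free. The sign convention is fixed by the worked
example built into `worked_example_fixture()`: for the WHO +1 / IOTF 25
overweight pair in boys aged 8, with cross z-scores 0.91 (WHO cut-off on
IOTF) and 1.47 (IOTF cut-off on WHO), the means are 0.955 and 1.39 and
$dz = 0.435$.

## The conversion and its key assumption

An observed prevalence $p_A$ beyond cut-off A maps to a probit
$Z_A = -\mathrm{sign}(z_A)\,\Phi^{-1}(p_A)$; the sign factor makes the
same formula serve upper-tail (overweight, obesity) and lower-tail
(thinness) categories. The conversion assumes the target population's
BMI distribution differs from both references **only by a shift on the
z-score scale** — same L, same S, shifted location. Under that
assumption the probit difference between the two observed rates equals
the cut-off distance, $Z_B - Z_A = dz_{A,B}$, so

$$p_B = \Phi\!\left(-\mathrm{sign}(z_B)\,(Z_A + dz_{A,B})\right),$$

implemented in `convert_prevalence()`. The reverse direction uses
$-dz_{A,B}$, and with slope multiplier $b = 1$ forward followed by
reverse is the identity to floating precision — the reversibility that
regression-based conversions lack. Prediction errors in the two
directions are equal and opposite on the z-score scale, though slightly
different on the prevalence scale because the probit is nonlinear.

Overweight must be counted *inclusive of obesity*
(`overweight_including_obesity()`), because a cut-off defines a tail
area: everyone above the overweight cut-off belongs in the overweight
tail, obese children included.

## Tunable parameters

* **`b` (slope multiplier, default 1).** Multiplies dz before the
  shift. `b = 1` is the plain, assumption-driven conversion;
  `bias_adjusted_b` (0.84) is the preset compensating for target
  populations whose BMI distribution has a heavier upper tail than the
  references — a secular-trend effect that makes the probit difference
  flatter than the cut-off distance. Any `b < 1` breaks exact
  reversibility at the margin but can reduce prediction error.
* **Cut-off registry.** `default_cutoffs()` preloads the standard
  definitions: IOTF thinness grades 1–3 (z = −1.01/−1.88/−2.56 boys,
  −0.98/−1.79/−2.44 girls), IOTF overweight/obesity (+1.31/+2.29 boys,
  +1.24/+2.19 girls) over ages 2–18; WHO −2/+1/+2 from age 5 and
  −2/+2/+3 below 5 (ages 2–19); CDC −1.64/+1.04/+1.64 (ages 2–20).
  Users can define any registry via `cutoff_spec()` or a CSV file.
* **Look-up grid.** `build_lookup_table()` defaults to half-year ages
  2–18 (33 points per sex), the granularity at which reference tables
  are published; any grid can be requested. `lookup_dz()` uses the grid
  age nearest the target group's mean age.

## Numerical choices

* **Branch switch at |L| < 1e−7.** The power-branch numerator
  $(x/M)^L - 1$ cancels catastrophically as $L \to 0$; below the switch
  the exact logarithmic limit is used. The branch gap at the switch is
  $O(L \log^2(x/M)/2S) \approx 10^{-8}$, far below any reported
  precision; the tests verify the first-order convergence rate.
* **Boundary prevalences.** $\Phi^{-1}$ is infinite at 0 and 1. With a
  known denominator n, observed rates of 0 and 1 are
  continuity-corrected to $1/(2n)$ and $1 - 1/(2n)$; without a
  denominator they are an error rather than a silent guess.
* **LMS interpolation** is linear in age, applied to L, M and S
  separately, with no extrapolation beyond the tabulated span.
  Published tables are dense (monthly to half-yearly), so higher-order
  interpolation changes nothing material, and linearity is exactly
  testable against a linear generating curve.
* **Nearest-age ties** in `lookup_dz()` break to the younger age —
  deterministic and documented.
* **Presentation rounding** is half-away-from-zero (`round_half_up()`),
  the convention of the surveillance literature: prevalences print at
  1 dp, z-scores at 2 dp. The printed 2-dp cut-off distance is the
  difference of the 2-dp mean z-scores (0.96 and 1.39 give 0.43 in the
  worked example), while all computation keeps full precision — the
  full-precision 0.435 drives the conversions.
* **Age-band boundaries.** Where two registry entries share a boundary
  age (the WHO switch at exactly 5 years), the boundary resolves to the
  older band.

## The validation regression

To test the shift assumption on paired data — groups with prevalence
observed under *both* cut-offs — `stack_records()` builds one record per
(group × pair), oriented so dz > 0 (each pair can be read in either
direction; the positive orientation avoids double counting, and
`orientation = "both"` retains the mirror records for residual
summaries). `fit_slope()` then fits

$$g(p_B) = Z_A + b\,dz_{A,B} + \varepsilon,
  \qquad g(p) = -\mathrm{sign}(z_B)\,\Phi^{-1}(p),$$

by maximum likelihood on the counts $y_B = p_B n$, with no intercept —
an intercept would break exchangeability of A and B, hence
reversibility. Three model shapes: `fixed_b1` evaluates the likelihood
at b = 1 (the conversion as-is), `common_slope` estimates one b, and
`grouped_slopes` estimates one b per (data source × category) cell,
which is how between-survey heterogeneity shows up in practice.
`average_slope()` collapses grouped slopes with equal weight by default,
so a large survey does not dominate the consensus multiplier; record- and
denominator-weighted means are available for comparison.

The error model is beta-binomial: binomial sampling noise plus
overdispersion that grows with the extrapolation distance. We
parameterize the extra variation as an intraclass correlation
$\rho = c\,|dz|$ with c ≥ 0 estimated — the simplest reading of
"error proportional to |dz|" — so records with dz = 0 collapse exactly
to binomial. Optimization is bounded L-BFGS-B from fixed starts (b = 1,
c = 0.1) with a derivative-free polish if the line search stalls;
convergence is judged on the log-likelihood at about 1e−8. The 95% CI is
Wald, from the numerically differentiated observed information. BIC uses
the number of estimated parameters and the record count.

`residual_summary()` works on the prevalence scale: predict each rate
from its partner in both directions, and compare the residual SD to the
SD of the raw difference $p_A - p_B$ over both orientations;
`variance_explained()` is $100\,(1 - (\mathrm{RSD}/\mathrm{SD_{base}})^2)$.
`bland_altman()` returns difference-versus-mean pairs for the
observed/predicted and raw-pair comparisons.

## What the synthetic data do and do not emulate

The generators exist so that every operation is testable without the
copyrighted reference tables or the original surveillance datasets.

* `make_reference()` evaluates smooth L/M/S curves (polynomials or
  functions of age) on a half-year grid. `synthetic_references()`
  provides three BMI-like references with a median dipping near age 5
  and rising to ~22 kg/m² at 18 and S rising from ~9% to ~14% —
  realistic magnitudes for child BMI.
* The study-condition pair (refA, refB) lives in the L = 0 (log-normal)
  family with a shared S curve and medians differing by an exact
  age-dependent z-shift (0.51 at age 2 falling to 0.19 at 18, mirroring
  how real cut-off distances shrink with age). In this family the shift
  assumption is *exactly* satisfiable: the simulated probit difference
  equals dz identically, giving an analytic oracle for every simulated
  prevalence and a sharp target (b = 1) for slope recovery. Real
  references have L < 0 and differing S curves, so real data can only
  approximate this.
* refC inflates S by 15% at the same median, the controlled violation:
  a wider (heavier-tailed) distribution. Populations simulated with
  `s_inflation > 1` yield fitted slopes below 1, reproducing the
  mechanism by which secular trends in skewness bias the conversion.
* `simulate_prevalence_dataset()` draws group counts binomially around
  exact tail probabilities; `simulate_slope_dataset()` generates
  directly under the validation regression at a chosen true b and
  dispersion, for parameter-recovery tests. Seeds are mandatory
  arguments and the global RNG state is left untouched.

The generators produce group-level prevalences only — no individual BMI
values, no secular-trend time series, no reporting artefacts (digit
preference, varying age grouping) of real surveillance data. Passing
tests therefore demonstrate the algorithm's internal correctness and its
behaviour under its own assumption and controlled violations, not its
accuracy on any particular real survey pair.

Problem sizes used in the test suite were chosen to make Monte-Carlo
noise negligible relative to the tolerance being asserted: 300 groups of
~1300 children for CI-coverage checks, 200 groups of 5000 for the
pure-shift slope (asserted within [0.98, 1.02]), 20 replicates of 100
groups for unbiasedness (mean slope within 0.02 of truth), and a single
group of 10⁶ for agreement between empirical and analytic tail
probabilities (within 3 binomial SDs).

## Design decisions on genuinely open points

* **Cross-z subscript convention.** The two natural readings of
  $z_{A,B}$ (A's cut-off scored on B, versus B's scored on A) give
  distances of opposite sign. The package fixes the convention so each
  cut-off's mean averages *that cut-off's* z-score on both references —
  the reading under which the worked example's numbers (0.96, 1.39,
  0.43) are reproduced.
* **Generic "IOTF thinness"** resolves to grade 2 (BMI 17 at age 18,
  z = −1.88 boys), with a warning naming grade 1. Grade 2 is the grade
  closest to the WHO and CDC thinness cut-offs, so it needs the least
  extrapolation; a user wanting grade 1 names `"IOTF 18.5"` explicitly.
* **WHO below age 5** is handled as BMI-for-age with cut-offs ±2/±3 and
  the band switch at exactly 5 years. The under-5 standard is formally
  defined on weight-for-height; the two indices are highly correlated
  but distinct, and this approximation is documented rather than
  modelled.
* **IOTF z values** are stored at the published two-decimal precision.
  If a loaded IOTF table includes age 18, the exact z at which BMI
  reaches 25/30 at 18 could be computed on the fly; the tabled values
  are the default because they are what surveillance reports use.
* **Dispersion link.** Only the proportionality of the extra error to
  |dz| is specified by the method; the intraclass-correlation reading
  ρ = c·|dz| is one of several possible links, and fitted dispersion is
  reported as such rather than as a canonical quantity.

## Known limitations

* No confidence intervals for converted prevalences: the conversion is
  a deterministic map, and the dominant uncertainty (violation of the
  shift assumption) is not estimable from a single observed rate.
* The bias-adjustment preset 0.84 derives from two European datasets
  and is not universally representative; it is exposed as an explicit
  opt-in, never a default.
* Accuracy degrades with the distance |dz|: converting between nearby
  cut-offs (e.g. WHO +1 and CDC 85) is safer than between far ones
  (IOTF grade-1 thinness and WHO −2).
* Fitted BIC and dispersion values depend on likelihood bookkeeping and
  are comparable within this package, not across implementations with
  different beta-binomial parameterizations.
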