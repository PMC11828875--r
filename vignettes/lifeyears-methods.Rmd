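---
title: "Methods: life tables, cause-deleted YLL and Latin hypercube uncertainty"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: life tables, cause-deleted YLL and Latin hypercube uncertainty}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lifeyears)
```

This vignette documents the models behind `lifeyears`, the choices made
where the methodology was genuinely open, and what the package's
validation does and does not demonstrate.

## The estimation problem

The input is a vital-registration extract — one row per death with sex,
integer age at death, ICD-10 cause, municipality and date — and a
resident-registry population table by district, sex, single year of age
and calendar year (the March-31 registry convention). Deaths are pooled
into multi-year analysis periods (defaults: 2006–2010, 2012–2015,
2016–2018, with 2011 excluded so that the disaster year itself does not
blur the pre/post contrast), and municipalities are consolidated into
districts large enough for stable rates (the default layout maps 59
municipality codes to 14 districts, with districts 2–4 flagged as
containing evacuation-order zones).

## Life-table construction

For ages 0–94 the death rate is estimated as
$m_x = d_x / (\bar N_x \cdot k)$, where $d_x$ is the pooled death count,
$\bar N_x$ the period-average registry population, and $k$ the period
length in years. Two conversions to the probability of dying are
provided:

* `method = "central"` (default for registry data): the standard
  occurrence–exposure conversion
  $q_x = m_x / (1 + (1 - a_x) m_x)$, appropriate when $\bar N_x \cdot k$
  approximates person-years lived;
* `method = "direct"`: $q_x = d_x / (\bar N_x \cdot k)$, appropriate
  when the denominator enumerates persons at the start of each year of
  exposure — which is exactly how the package's synthetic generator
  produces deaths, so validation against the generator uses `direct`.

$a_x$ is the average fraction of the year of age lived by those dying
in it: 0.5 everywhere except $a_0 = 0.1$, since infant deaths
concentrate in the first weeks of life. Both are configurable.

**Open ages.** Official old-age estimation parameters for ages 0 and
95+ are not published, so the package uses a documented approximation:
a Gompertz regression $\log m_x = a + b x$ fitted by least squares over
ages 80–94 (back-computing $m$ from $q$), extrapolated over 95–110 and
closed with $q_{110} = 1$; extended ages carry an `estimated-tail`
flag. Plugging exact rates through this chain reproduces the analytic
life expectancy of the generating model to better than 0.01 years, so
the approximation contributes negligibly at the table level. Ages with
zero population *and* zero deaths (possible in small districts) are
filled by log-linear interpolation from the nearest observed ages and
flagged; zero population with positive deaths is an error.

The table columns follow the usual recurrences: $l_{x+1} = l_x (1 -
q_x)$ from radix 100,000, $d_x = l_x q_x$, $L_x = l_{x+1} + a_x d_x$,
$T_x = \sum_{y \ge x} L_y$, $e_x = T_x / l_x$. The table is closed at
$\omega = 110$ with everyone dying inside the final interval
($L_\omega = a_\omega l_\omega$). With $a_x = 0.5$ everywhere, $e_0$
equals the trapezoidal integral of the survival curve, which is the
"area between survival curves" framing used for YLL below; the test
suite also checks $e_0$ against a brute-force death-age expectation to
1e-10.

## Cause-deleted tables and YLL

Cause groups are defined as inclusive ICD-10 3-character ranges (heart
I05–I09, I20–I25, I30–I52; cerebrovascular I60–I69; pneumonia J12–J18;
cancer C00–C97); subcodes never affect membership, the groups are
validated to be pairwise disjoint, and each death is assigned to the
first matching group, else "other". All deaths count toward the
all-cause margin regardless of group.

The method does not prescribe a particular cause-elimination formula,
so the package adopts Chiang's proportional elimination as the standard
construction of a survival curve "without" a cause:

$$q_x^{(-i)} = 1 - (1 - q_x)^{1 - f_x},$$

with $f_x$ the cause's fraction of deaths at age $x$. If the cause is a
proportional share $s$ of a constant-within-year hazard, this is exact:
$1-(e^{-h})^{1-s} = 1-e^{-(1-s)h}$. It guarantees $\mathrm{YLL} \ge 0$
and is monotone in $f$ (both property-tested). A naive subtraction
variant ($q^{(-i)} = q(1-f)$) is available behind a switch for
sensitivity only. Because cause-specific counts are sparse in the open
ages, fractions above age 94 carry forward the pooled 90–94 fraction.
YLL at ages 40 and 65 uses the conditional expectancies $e_{40}$,
$e_{65}$ from the same pair of tables — a structural by-product, not a
separate method.

## Latin hypercube Monte Carlo

Annual variation within a period is summarised per age 0–94 by the
mean and sample SD (n−1) of the yearly population counts and crude
mortality rates, and modelled as independent normal dimensions. Each
dimension is sampled by Latin hypercube: the $n$ trials occupy each
probability stratum exactly once, uniformly within the stratum by
default (midpoint placement is available); the stratified uniforms come
from `lhs::randomLHS` and are mapped through the normal inverse CDF.
Uniform-within-stratum is the default because midpoints never visit the
tails beyond $\pm\Phi^{-1}(1-1/2n)$.

Choices the source method leaves open, resolved as follows:

* **Truncation.** Normal draws can go negative; populations are
  truncated at 0 and rates into [0, 1]. Rejections (all-zero population
  draws) are logged and more than 1% is an error.
* **What is perturbed.** Crude rates $m_x$ at ages 0–94 are perturbed
  (not $q_x$); age 0 uses its perturbed rate directly and the 95+ tail
  is re-fitted *per trial* from the perturbed ages 80–94.
* **Population draws.** For a single stratum the life table depends on
  the rates alone (the population cancels from deaths/population), so
  population draws affect results only where strata are aggregated by
  population weight; they are still drawn, used for the rejection
  check, and reported for death-count reconstruction.
* **Independence.** Distinct draw sets are used for all-cause and for
  each cause's rates, and period differences are computed trial-wise
  between *independently* drawn trial sets — no pairing. Rates and
  populations are independent dimensions.

Defaults: 10,000 trials (scaled to 1,000 in the calibration tests so
the suite stays fast); results report the point estimate (unperturbed
means), trial median and the 2.5th–97.5th percentile 95% UI. District
point estimates are compared between groups via the mean ± 1.96·SE
normal CI across districts.

**Calibration design.** The 95% UI is the percentile band of the LE (or
YLL) induced by the assumed normal law of annual inputs. Its clean
frequentist check: a *fresh* draw from that law is exchangeable with the
trials, so the band must cover the LE of a realized annual rate vector
95% of the time. The test suite runs 200 replicates at 1,000 trials and
requires empirical coverage in 90–99%. Covering the *long-run mean*
rate vector instead would be nearly certain (the UI uses the annual SD,
not SD/√years) and would not discriminate a broken sampler; that is a
property of the method, inherited from its sources, not a defect of the
implementation.

## Effect sizes

Municipal characteristics (2010 values) are aggregated to districts by
population-weighted means, except the financial capability index, which
is a simple mean of municipal values. Changes are plain differences
versus the pre-disaster period. Continuous characteristics are related
to district changes by Pearson r with $t = r\sqrt{df/(1-r^2)}$,
$df = n - 2$; the evacuation indicator by a pooled-variance two-sample
Student t (df $= n_1 + n_2 - 2$) with point-biserial
$r = t/\sqrt{t^2 + df}$, oriented so $r > 0$ means the evacuation group
is larger. The pooled (not Welch) form is used because it is the
algebraic identity partner of the point-biserial correlation — the two
are property-tested to agree to 1e-12 — and it reproduces published
group-summary effect sizes of this design to ±0.01. The |r| > 0.5 rule
flags large effects; no multiple-testing correction is applied, and raw
p values are carried alongside. A `groupCompareFromSummary()` entry
point computes the same quantities from printed group means/SDs, which
is all that is needed to reconstruct a published comparison table.

## The synthetic generator

The restricted registry data cannot be redistributed, so validation
rests on a generator with the same structure: Gompertz–Makeham hazards
$h(x) = \lambda + \alpha_{sex} e^{\beta x}$ (defaults $\lambda = 3
\times 10^{-4}$, $\alpha$ = 2.2e-5 male / 1.0e-5 female, $\beta =
0.102$, giving life expectancies near 77 and 84 years), an optional
additive infant bump (default 0), per-district hazard multipliers, an
age-band cause mix shaped like an aged industrial-country profile, and
optional period × cause × district multipliers for scenario work (e.g.
a post-disaster cerebrovascular improvement concentrated in evacuated
districts). Deaths are Binomial(count, $1 - e^{-h}$) per
district–sex–age–year cell, with a lognormal year effect (SD 0.02) and
a population year effect (SD 0.01) supplying the annual variation the
uncertainty module estimates; ICD-10 codes are drawn uniformly from the
assigned group's ranges; dates are uniform within the year. The age
pyramid is a beta(2, 1.8) shape tempered by the model's own survival
curve. All randomness descends from one seed.

What the generator deliberately does *not* emulate: migration and
evacuation-driven registry mismatch, cohort effects, garbage-coded
causes, seasonality, and municipality-level heterogeneity beyond
district multipliers. Consequently, passing tests show the estimators
are correct for data satisfying the model's assumptions — they say
nothing about registry artefacts in real data, and the generator is not
calibrated to reproduce any published life expectancy.

## Problem sizes and numerical choices used in validation

* Life-expectancy recovery compares the full simulate→aggregate→
  estimate chain to the analytic LE (numeric integral of the survival
  function under piecewise-constant hazard) at ~8 million person-years
  per sex stratum, tolerance 0.2 years; the year effect is disabled
  there so the realized hazards coincide with the analytic model. The
  recovery uses `method = "direct"` to match the generator's
  start-of-year enumeration semantics (see above).
* Monte Carlo calibration: 200 replicates × 1,000 trials (the default
  10,000 trials is exercised functionally, not in calibration loops).
* The scenario check for the evacuation contrast uses the default
  14-district, ~2-million-person layout with cerebrovascular hazard
  multipliers 0.80/0.55 (early/late) in evacuated vs 0.95/0.85 in
  non-evacuated districts, chosen once as a plausible magnitude of a
  concentrated post-disaster improvement.
* Gompertz tail fits floor rates at 1e-10 before taking logs; LHS
  probabilities never hit 0 or 1 by construction; quantiles are R's
  default type 7.

## Known limitations

* The infant separation factor $a_0 = 0.1$ and the Gompertz tail stand
  in for unpublished official parameters; both are configurable, and
  tail ages are flagged so downstream code can treat them differently.
* Cause fractions above age 94 inherit the 90–94 band; if the true
  cause mix shifts after 95, YLL at very old ages is approximate.
* The Monte Carlo treats ages as independent dimensions; real annual
  shocks are correlated across ages, so the UIs are best read as
  input-variation bands, not full sampling distributions.
* District point estimates from small districts are noisy; the
  group CI (mean ± 1.96·SE over districts) treats districts, not
  persons, as the sampling unit.
* `deltaVsPre()` differences point estimates; published differences
  built from Monte Carlo medians can differ in the second decimal.
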