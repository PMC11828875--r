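# lifeyears

Period life tables, cause-deleted life expectancy and years of life lost
(YLL) from vital-registration data, with Latin hypercube Monte Carlo
uncertainty intervals and district-level effect-size comparisons.

The package is aimed at epidemiologists and demographers studying how a
population's mortality changed across multi-year periods — for example
before and after a large-scale disaster — using individual death records
(sex, age at death, ICD-10 cause, municipality, date) and registry
population counts by single year of age.

## What it computes

**Life tables.** For each stratum (district or whole prefecture, sex,
period), age-specific death rates are estimated as
m_x = d_x / (N̄_x · years) from pooled deaths and period-average
populations, converted to probabilities q_x = m_x / (1 + (1 − a_x) m_x)
(a "direct" q_x = d_x / exposure estimator is also available), and
extended into the open ages 95–110 by a Gompertz regression
log m_x = a + b·x fitted over ages 80–94, closing with q₁₁₀ = 1. The
life-table columns l_x, d_x, L_x, T_x give the life expectancy
e_x = T_x / l_x.

**Cause-deleted tables and YLL.** For a cause group i with per-age death
fractions f_x (ICD-10 groups: heart I05–I09, I20–I25, I30–I52;
cerebrovascular I60–I69; pneumonia J12–J18; cancer C00–C97), the
cause-deleted schedule is Chiang's proportional elimination

    q_x^(−i) = 1 − (1 − q_x)^(1 − f_x)

and YLL(x) = e_x^(−i) − e_x, reported at ages 0, 40 and 65: the area
between the cause-deleted and all-cause survival curves.

**Uncertainty intervals.** Populations and crude mortality rates at ages
0–94 vary from year to year within a period; their per-age means and
sample SDs drive normal perturbations sampled by Latin hypercube
(exactly one draw per probability stratum per dimension). Each trial
rebuilds the schedule (tail re-fitted), giving the 2.5th–97.5th
percentile uncertainty interval (95% UI) over 10,000 trials by default.
Period differences use independently drawn trial sets; district groups
get normal CIs (mean ± 1.96·SE across districts).

**Effect sizes.** District characteristics versus changes from the
pre-disaster period are summarised by Pearson r (t = r·√(df/(1−r²)),
df = n−2); evacuation vs non-evacuation districts by a pooled-variance
two-sample t with point-biserial r = t/√(t²+df). |r| > 0.5 is flagged
as a large effect.

A synthetic vital-registration generator (Gompertz–Makeham hazards,
age-band cause mixes, binomial deaths on a 59-municipality /
14-district layout with three analysis periods) provides data with the
structure the analysis assumes, and analytic oracles for validation.

## Worked example

```r
library(lifeyears)

# packaged prefecture-level death counts by period, sex and age bin
tab <- makeTable1Fixture()
tapply(tab$deaths, tab$period, sum)
#>    pre  early   late
#> 107827  94770  73717

# a synthetic scenario end to end
cfg <- defaultRunConfig(seed = 1, nTrials = 1000)
cfg$scenario <- list(use = TRUE, nDistricts = 14L)
res <- runPipeline(cfg, "out")
subset(res$prefecture, quantity == "LE_0" & sex == "male")
#>   sex period quantity    value
#>  male    pre     LE_0 76.83975
#>  male  early     LE_0 76.88099
#>  male   late     LE_0 76.85530

res$mc[["male pre"]]$LE_0
#> MCResult male_pre:LE_0: point 76.84, median 76.81 (95% UI 76.53-77.07), 1000 trials

# reconstruct a published-style effect size from group summaries:
# district mean change in LE 1.64 (SD 0.458) in 3 evacuation districts
# vs 0.88 (SD 0.422) in 11 others
groupCompareFromSummary(1.64, 0.458, 3, 0.88, 0.422, 11)[, c("r", "t", "p")]
#>           r        t          p
#> 1 0.6182562 2.724893 0.01844001
```

The life expectancies above are for the synthetic generator's default
mortality model, so the three periods differ only by sampling noise;
`r = 0.62` says the evacuation-district group's LE gain exceeds the
others' by about 2.7 pooled standard errors (p ≈ 0.018), a large effect
under the |r| > 0.5 rule.

## Command line

A thin front-end lives at `inst/scripts/lifeyears.R`:

```sh
Rscript inst/scripts/lifeyears.R synth --out demo --seed 7
Rscript inst/scripts/lifeyears.R fixture table1 --out table1.csv
Rscript inst/scripts/lifeyears.R run --config run.yaml --out out/
```

See `vignettes/lifeyears-methods.Rmd` for the modelling choices, their
rationale and known limitations.
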