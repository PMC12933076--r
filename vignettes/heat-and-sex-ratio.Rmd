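---
title: "Estimating temperature effects on the sex ratio at birth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating temperature effects on the sex ratio at birth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(heatsrb)
```

## The question and the model

The sex ratio at birth (SRB, male live births per 100 female live births)
responds to prenatal stressors through two quite different channels. Under
the frail-male (Trivers–Willard) reading, male fetuses are more vulnerable
to adverse in-utero conditions, so maternal heat stress raises male
prenatal mortality and lowers the SRB. In populations practising
sex-selective abortion of female pregnancies, heat can also act on
*behaviour*: if hot spells around the second trimester make an intended
abortion less likely (mobility, income, access), heat again lowers the SRB,
but only in the strata where such abortions happen at all — higher-order
births to mothers without a son, in regions with strong son preference.

`heatsrb` implements the estimation machinery for both questions. The
design is a linear probability model of the male indicator on gestational
temperature-bin exposures with high-dimensional fixed effects:

$$
\mathrm{Male}_{icrmy} \;=\; \sum_{j}\sum_{k} \beta_{kj}\,
\mathrm{Days}^{(j)}_{c,\,t-k} \;+\; \mathrm{rain}_{cm} \;+\;
\alpha_{rm} \;+\; \delta_{ry} \;+\; \varepsilon_{icrmy},
$$

where the exposure $\mathrm{Days}^{(j)}_{c,t-k}$ counts the days at survey
cluster $c$'s grid cell whose daily maximum temperature falls in 5 °C bin
$j$ (below 15, 15–20, 20–25, 25–30, above 30 °C) during gestational window
$k$. The gestational period is approximated by the birth month plus the
nine preceding calendar months: the third trimester is the birth month and
lags 1–3, the second trimester lags 4–6, the first trimester lags 7–9.
Lags 10–11 enter as autocorrelation controls (the same four non-reference
bin counts per lag month), and ten monthly rainfall totals cover the birth
month and its nine lags. The 15–20 °C bin is the omitted reference in
every window: each $\beta_{kj}$ is the change in the probability of a male
birth from one additional day in bin $j$ relative to a 15–20 °C day.
$\alpha_{rm}$ (region × calendar month) absorbs region-specific
seasonality — in birth timing, climate and composition — and $\delta_{ry}$
(region × year) absorbs regional shocks and trends, so identification
comes from year-to-year fluctuations of temperature within a region and
calendar month.

## The estimator

`felpm()` fits the model without ever materialising fixed-effect dummies:

1. **Singleton pruning.** Observations alone in any fixed-effect cell
   (after iteratively intersecting groups) would be fitted perfectly by
   their own effect; they are removed and counted.
2. **Absorption** (`absorb_fe()`): alternating within-group demeaning of
   the outcome and every regressor, cycling over the groups until the
   largest cell change on unit-scaled columns falls below `tol`
   (default 1e-10) or `max_iter` (default 10,000) cycles; non-convergence
   is an error carrying the last delta, never a silent result. One group
   converges in a single pass, nested groups in two.
3. **Least squares** on the demeaned columns via rank-revealing (pivoted)
   QR; collinear columns are dropped by name and reported.
4. **Inference**: one-way cluster-robust sandwich variance with the CR1
   small-sample factor $\frac{G}{G-1}\frac{N-1}{N-K}$, where $K$ counts
   retained regressors plus absorbed degrees of freedom
   $\sum_g L_g - (n_{\text{groups}} - 1)$ ($L_g$ = levels of group $g$).
   This $K$ ignores any additional rank overlap between crossed groups
   beyond the shared constant, which is the conservative direction.
   p-values and confidence intervals use a $t$ distribution with $G-1$
   degrees of freedom, $G$ the number of clusters (regions). The
   literature states the clustering level but not the small-sample or
   degrees-of-freedom convention; CR1 with $t(G-1)$ is the common
   area-level-clustering default and is documented here so results are
   reproducible bit for bit, without attributing the convention elsewhere.

Standard errors clustered at the region level allow arbitrary error
correlation within regions — the exposure varies at the cluster-month
level, well below the clustering level, so this is the conservative
choice. Mother fixed effects can be added as a third absorption group
(`fe = c("region_month", "region_year", "mother")`); single-birth mothers
then drop out as singletons. A region-specific linear trend can replace
the region × year group (`region_trend = TRUE`).

Survey weights are deliberately not part of the canonical analysis; a
`weights` argument exists but is flagged experimental.

## Exposure construction

Bin edges are half-open, $[\ell, u)$: a day at exactly 15.0 °C is a
15–20 °C day and 30.0 °C falls in the top bin. This convention is pinned
by tests; the field's prose ("<15 °C", ">30 °C") does not settle
boundaries, so the package documents one and sticks to it. Months are
exact calendar months (leap-aware), never a 30-day approximation, and the
per-month counts over all five bins must sum to the calendar days of the
month — an invariant asserted across every generated dataset.

Grid cells are half-open in both coordinates; a point on a shared edge
belongs to the cell whose lower/left edge it lies on, and a point outside
the grid is an error rather than a silent nearest-cell fallback.

Relative (location-specific) exposures are supported as per-PSU decile
bins: `longterm_deciles()` computes the nine cutpoints of a long-term
daily-maximum distribution with the linear-interpolation quantile
definition (R type 7), and `bin_spec("relative", ...)` turns them into ten
bins with a configurable reference decile (default: the lowest). The
reference *period* is an argument, not a default — published accounts
differ on it (1979–2022 vs 1997–2022) — and the reference decile is
likewise configurable because no convention is settled. With cutpoints
manually tied to the absolute edges the relative design reproduces the
absolute one exactly, which the tests exploit.

The analysis sample keeps births by mothers aged 15–45 at childbirth who
did not migrate in the year before birth (both restrictions address
exposure misclassification, since past exposure is assigned from the
current residence).

## The synthetic generator

Real DHS birth records and the daily temperature product cannot be
redistributed, so the package ships a generator whose output mimics their
statistical structure and carries a *known* ground truth:

* **Climate**: daily maxima on a 0.5° grid as regional mean + seasonal
  sinusoid (phase flipped for southern-hemisphere regions) + linear
  warming trend + AR(1) noise whose *marginal* SD equals
  `daily_noise_sd` regardless of the autocorrelation; monthly rainfall is
  an analogous sinusoid truncated at zero. Twelve lead-in months
  guarantee 11 lag months for every birth.
* **Births**: mothers with sibship sizes 1–6, seasonal birth months,
  maternal ages generated over 10–55 so the 15–45 filter is testable,
  education/urban composition, and a male-birth probability
  $p_0 + \sum\beta^{\mathrm{true}}_{kj}\,\mathrm{count}_{kj} +
  \alpha^*_{rm} + \delta^*_{ry}$, with the counts computed by the *same*
  counting engine the analysis uses (one source of truth) and Gaussian
  region-month / region-year effects. Configurations that could push the
  probability outside $[0,1]$ are rejected at validation, and any
  realised violation is an error naming the configuration. Baselines are
  calibrated to the two study populations: $p_0 = 0.5087$ (sub-Saharan
  Africa mode, SRB ≈ 103.5) and $p_0 = 0.5237$ (India mode,
  SRB ≈ 109.95).
* **Sex selection**: for eligible pregnancies — live parity ≥ 4, no
  previous son, northern region — that drew a female sex, the birth is
  removed with probability $q = \max(0,\, q_0 - \gamma H)$, $H$ the
  number of second-trimester days above 20 °C. Selection operates on the
  female draw after sex assignment (the demographic mechanism of
  sex-selective abortion), removals re-index subsequent parities, and the
  returned table contains live births only. Hotter second trimesters
  therefore *lower* the male share exactly and only in the eligible
  stratum.

The generator's true fixed effects are Gaussian draws rather than
arbitrary fixed patterns — sufficient for recovery tests and parametric;
hemisphere phase is a per-region flag rather than latitude-derived;
births are singletons only (no twins, which published counts do not
resolve); and an optional ±1-month gestation jitter (default off) exists
to study exposure misclassification. An optional `beta_modifier` restricts
the biological effect to one covariate stratum, which the heterogeneity
tests use. What the generator does **not** emulate: DHS spatial
displacement of cluster coordinates, the joint covariate distribution of
any real survey, climate-zone structure, humidity, or heatwave run
lengths. Passing tests therefore demonstrate that the *machinery* —
linkage, counting, absorption, inference, translation — is correct under
a known data-generating process, not that any particular field estimate
is right.

## Reporting units

Coefficients are estimated in probability units and scaled only at the
reporting layer: `effect_table()` multiplies by 100 (percentage points),
by the sample SD of each exposure column (per-SD effects), and converts
to SRB units via `srb_shift()`, which moves the baseline proportion male
by the per-SD effect and re-expresses it as males per 100 females.
Displayed effects are rounded half away from zero to 2 decimals; the
unrounded values are always retained because published roundings are not
consistent at the last digit. `project_scenario()` applies a uniform
temperature shift (or explicit per-bin day-count deltas), recounts bin
days, and pushes the count changes through the fitted coefficients,
reporting a per-bin decomposition: in hot geographies most gestational
days already sit above 30 °C, so warming moves few days across the 20 °C
threshold where effects begin — the saturation logic behind
"warming will not further depress the SRB" claims — and the decomposition
makes that inspectable.

## Numerical and design choices

* Absorption tolerance 1e-10 on unit-scaled columns; QR rank tolerance
  1e-7; vcov symmetrised before use.
* Reference bin 15–20 °C everywhere; changing it relabels coefficients
  but leaves contrasts between retained bins identical (tested exactly on
  a fixed-window design).
* Subgroup regressions rebuild fixed-effect groups *within* each subgroup
  — the only estimable choice — and subgroups below a configurable
  minimum size are skipped with a log message. No cross-subgroup test is
  computed; the contrast tables state that interval overlap is not a
  test.
* Northern-state membership is a data column, set by the generator as a
  per-region flag; no geographic lookup is embedded.
* The problem sizes in the test-suite simulations are chosen for quick,
  stable calibration checks: estimator calibration uses 100 replicates of
  ~55,000 filtered births over 50 regions (calibration properties —
  CI coverage, within-2-SE rates, type-I error — do not depend on the
  per-replicate sample size). The simulated world spreads PSUs over eight
  grid cells per region: cluster-robust inference needs exposure to vary
  across many locations *within* each cluster, as it does in real survey
  geometry, and collapsing a region to one grid cell biases the sandwich
  variance downward. The selection-channel detection run uses
  ~576,000 births so its eligible stratum (~5,500 births) gives
  comfortably more than 80% power for its pre-sized channel
  ($q_0 = 1$, $\gamma = 0.02$ per hot day).

## Limitations

Calendar-month gestation windows misclassify exposure for preterm or
post-term births; the jitter option quantifies but does not remove this.
The estimator is one-way clustered only, linear-probability only (no
fixed-effects Poisson/logit), and its absorbed-degrees-of-freedom count
is conservative for heavily overlapping groups. The scenario engine is a
back-of-the-envelope translation — uniform shifts, fitted coefficients
held fixed — not a projection ensemble. Published headline coefficients
from the restricted survey microdata are not reproducible from this
package; they serve only as calibration anchors for the generator's
baselines.

## A worked run

```{r, eval = FALSE}
cfg <- sim_config(seed = 1, mode = "ssa", n_regions = 10,
                  psus_per_region = 20, births_per_psu = 200,
                  year_range = c(2006, 2012),
                  beta_true = {b <- matrix(0, 3, 5); b[1, 5] <- -2e-4; b})
climate <- simulate_climate(cfg)
psus <- simulate_psus(cfg)
births <- filter_sample(simulate_births(cfg, climate, psus))
x <- build_exposure(births, climate, psus)
fit <- srb_fit(x)
summary(fit)
effect_table(fit, x)
project_scenario(fit, climate, psus, births, shift = 2)
```

`run_pipeline()` wraps the same chain with plain-text artifacts, content
hashes and stage resumption; `smoke_config()` is a two-region
configuration that completes end to end in seconds.
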