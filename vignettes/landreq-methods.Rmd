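---
title: "Cropland requirement accounting and projection: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cropland requirement accounting and projection: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(landreq)
```

# The accounting identity

`landreq` treats national cropland as the land needed to balance a
country's crop ledger in kilocalories. Production is yield times area;
consumption is per-capita crop demand times population, scaled by a
net-export ratio; equating the two and solving for area gives

$$A \;=\; \frac{C \cdot P \cdot R}{Y}, \qquad
R \;=\; 1 + \frac{E - I}{C \cdot P},$$

where $C$ is annual per-capita crop demand (kcal person⁻¹ yr⁻¹, stored as
a daily value and annualised with a 365-day year at the accounting
boundary), $P$ population, $E$ and $I$ gross crop exports and imports in
kcal, and $Y$ yield in kcal ha⁻¹ yr⁻¹. "Crop demand" is all crop use —
food, feed, waste, biofuel, and other products — so high-income values run
far above dietary need. The identity is exact, homogeneous of degree −1
in yield, and linear in each demand-side driver; those properties are
asserted in the test suite at 10⁻¹² relative tolerance.

Two unit conventions matter. Historical cereal yields are carried in
Mg ha⁻¹ and converted with a single generic-cereal energy density
(`KCAL_PER_MG_CEREAL`, 3.56 × 10⁶ kcal Mg⁻¹, i.e. 3,560 kcal kg⁻¹); a
per-crop table can replace the single factor where that is too coarse.
The net-export ratio is floored at zero: a country whose imports exceed
its entire domestic use would otherwise need negative land, which the
accounting frame does not define, so the value is clamped and a warning
raised.

# Historical drivers: the fixed-effects panel model

The historical decomposition regresses log cropland area on the logs of
its drivers with country and year fixed effects:

$$\log A_{it} = \beta_P \log P_{it} + \beta_C \log C_{it}
  + \beta_Y \log Y_{it} + \beta_E \log E_{it} + \beta_I \log I_{it}
  + \alpha_i + \tau_t + \varepsilon_{it},$$

with population entered in billions, demand as daily kcal per person,
yield in Mg ha⁻¹, and trade as export and import values (2010 USD) —
values, not kcal, because historical trade is reported in monetary terms.
Observations are weighted by a time-invariant suitability weight (the
area of land well suited to rainfed cereals), and standard errors are
clustered by country.

Implementation choices:

* **Estimator.** Weighted least squares after a two-way within
  transformation, computed by alternating weighted demeaning over
  countries and years to a 10⁻¹² convergence tolerance (exact in one
  sweep for balanced panels). The tests prove coefficient-for-coefficient
  equivalence with explicit dummy-variable WLS at 10⁻⁸ on random small
  panels. Note that with five slopes and absorbed effects a $G \times T$
  panel identifies the model only when $GT - G - T + 1 > 5$; test panels
  respect that bound.
* **Clustered covariance.** The standard sandwich with finite-sample
  correction $\tfrac{G}{G-1}\cdot\tfrac{N-1}{N-k}$, where $k$ counts the
  slopes plus all absorbed effects. This matches the common HC1-type
  cluster correction, and the suite verifies numerical agreement with an
  independent sandwich implementation.
* **Zero trade values.** Logs require positive values. The policy is
  configurable: `"offset"` (default) adds 1 USD before logging, so a true
  zero enters as log(1) = 0; `"drop"` removes the row. Either action is
  reported. The choice is a genuine free parameter of the method; the
  offset keeps small open economies in the sample.
* **Estimation sample.** Countries with a complete series over the span,
  population of at least one million in every year, and not on a
  user-supplied exclusion list (border-change countries). The default
  span is 1961–2016; the span is configurable because the source data
  nominally extend to 2018.
* **Within-R².** Share of weighted variance of the doubly demeaned
  outcome explained by the slopes — the within-country variation
  explained, not the overall fit.

The estimated yield elasticity $\beta_Y$ has a direct reading: a
proportional yield gain reduces cropland by $|\beta_Y|$ of its size, and
the remaining $1-|\beta_Y|$ is absorbed by induced demand (the rebound
effect). `yield_passthrough_share()` performs exactly this split and
warns outside the interpretable range $[-1, 0]$.

Descriptive group trends (`group_trend_report()`) aggregate each variable
by income group and divide by the base-year value. The weighting of group
means is not uniquely defined by the descriptive figures it mirrors, so
it is a configuration choice: sums for area and population, a
population-weighted mean for per-capita demand, an area-weighted mean for
yield, with an unweighted option.

# Projection components

## GDP and demand

Per-capita GDP follows annual compounding $y_{t+1} = y_t(1+g(y_t))$ with
a convergence-style growth equation $g(y) = a + b\log y$ ($b<0$ so poorer
countries grow faster). The functional form is a modelling choice; both
parameters can be estimated from a historical panel
(`fit_growth_model()`) or set directly. The accelerated-development
variant applies a uniformly higher growth equation (default: the
baseline intercept plus 0.04 yr⁻¹, a stand-in pending calibration)
whenever current GDP is below the acceleration threshold of $8,100
(2010 USD) per capita, and reverts to the baseline once a country crosses
it. Growth is clamped to configurable bounds (default −2% to +15% per
year) as a divergence guard; clamping is reported.

Daily per-capita demand follows a log-log curve per income group,
$C = \exp(a_g + b_g \log y)$, estimated over a recent window (the 2014–
2018 analog: the last five panel years) and clipped to a subsistence
floor (1,500 kcal) and a saturation cap (20,000 kcal). The log-log form
is a choice; demand–income curves could also be fit in levels.

The reduced-demand rule limits higher-income countries ("higher income"
= upper-middle, escaped upper-middle, and high) to the 2018 global
average of 5,000 kcal person⁻¹ day⁻¹ by 2100. Only the 2100 endpoint is
prescribed; the trajectory is our choice and is implemented as a linear
ramp from each country's observed 2018 demand, so the 2050 value is the
ramp midpoint region rather than an immediate cut. Countries already at
or below the target keep their model-projected demand.

Population is exogenous: median and accelerated variants per country and
horizon are lookup tables, mirroring how demographic projections enter
the analysis. The engine never models fertility itself.

## Yields

Attainable-yield ceilings are estimated per unit as a high conditional
quantile (default $\tau = 0.95$; the level is configurable and our
default is a stand-in, as the source method's quantile is specified in
supplementary material we do not reproduce) of observed yields on a
linear time trend plus optional covariates. Because no quantile-
regression package is assumed, the pinball-loss minimisation is
implemented in the package: for up to three coefficients the optimum is
found exactly by enumerating all non-singular $p$-point bases (an optimal
quantile hyperplane interpolates $p$ observations); wider designs use a
logistic smoothing of the check loss with a decreasing bandwidth and
BFGS, started from least squares. Exactness implies the count of points
above the surface is within $p$ of $n(1-\tau)$, which the tests assert.
Ceilings extrapolate linearly in time but are held constant past 2050 so
they stay bounded, and are floored at a small positive value.

Business-as-usual yields extrapolate the observed linear trend (OLS over
the most recent 30 years, anchored at the observed base-year yield),
capped at the same-horizon ceiling, then scaled by an exogenous
per-country climate multiplier (default 1.0 — the stand-in for
moderate-warming impacts, which enter as inputs, not as a climate model)
and floored at a positive epsilon.

The accelerated rule applies to countries below the $8,100 threshold at
the base year. For 2050 it takes the maximum of twice the 2018 yield
(capped at the ceiling) and the average of the climate-adjusted BAU
projection and the ceiling ("projected yield" is read as the
climate-adjusted projection). For 2100 it averages the accelerated 2050
yield with the 2100 ceiling. Because a fast BAU trend can reach the
ceiling by 2100 while that average sits below it, the 2100 value is
additionally guarded never to fall below the BAU projection — the
accelerated scenario is defined as weakly dominating BAU yields — and
never to exceed the ceiling. Country aggregation from unit-level
projections is a harvested-area-weighted mean with an optional national
normalisation factor applied at the base year.

## Trade

Projected net exports arrive in dollars from an exogenous table (the
trade-model stand-in; the general-equilibrium model that produces them
is out of scope and replaceable by any table with the same schema) and
are converted to kcal with per-country base-year ratios; countries with
no base-year trade fall back to the income-group median ratio with a
warning. The frictionless counterfactual does not re-allocate production
country by country: following its stated computation, it aggregates
global demand, computes base-area production at horizon yields, and
expands or contracts total area at the global average yield, so implied
production equals global demand exactly. A "production where yields are
highest" re-allocation would generally need even less land and could be
added as a separate mode; the two readings are deliberately not
conflated.

## Scenario engine

Four named scenarios are toggle sets over three accelerated-development
factors (income-driven demand growth, low-fertility population variant,
accelerated yield rule) plus the higher-income demand cap: BAU (nothing
on), reduced demand (cap only), accelerated development (three factors),
equitable development (all four). Factor-permutation runs re-run the
engine with arbitrary toggle subsets; the empty set reproduces BAU
bit-for-bit and the full set reproduces the accelerated scenario
bit-for-bit, with the exogenous trade table following the full-set
boundary (accelerated trade only when all three factors are on, since
intermediate permutations have no trade-model run of their own).

The base year for areas, demand ramps, and conversion ratios is
centralised at 2018. Countries lacking any projection input are excluded
from **all** scenarios symmetrically, so cross-scenario differences are
never driven by sample composition. Results carry country-level areas
and deltas, per-group additions (sum of positive deltas) and reductions
(sum of negative deltas, reported non-positive) whose group sum equals
the global delta exactly, and global totals with the frictionless total
alongside when requested. Runs are deterministic given inputs.

In a world whose drivers are frozen at base-year values
(`freeze_world()`), the BAU projection returns every country's base-year
area exactly — the engine's end-to-end identity check. The policy
scenarios deliberately move drivers even then (the demand cap lowers
demand, the accelerated rule raises yields), so the identity is a BAU
property.

# The synthetic world

The generator fabricates the study's input universe with known ground
truth. Seven income groups (the four classes plus "escaped" variants)
differ in initial GDP, growth premium, demand level, yield level and
trend, and area scale. Per country, GDP compounds under the group growth
equation; population growth follows the demographic transition
$\max(0, g_0 - g_1 \log y)$ (defaults $g_0 = 0.09$, $g_1 = 0.0095$,
chosen so poor-country growth is near 3% yr⁻¹ and rich-country growth
near zero); demand follows the group log-log curve with elasticity 0.30;
yields trend linearly with group-specific slopes (near-flat for
low-income, steep for high-income); export and import values are
GDP-scaled with independent random-walk shares so both trade margins
carry independent within-country variation. Log area is then assembled
from the driver model with the planted elasticities — defaulting to the
all-countries historical estimates (0.763, 0.351, −0.298, 0.065,
−0.022) — drawn fixed effects, and i.i.d. noise (σ = 0.1 on the log
scale).

Closure: a per-year common rescaling of areas forces world production to
equal world use every year; the factor is absorbed by the year fixed
effects, so the planted elasticities remain exactly recoverable, and
per-country net exports in kcal are the production-minus-use residual,
summing to zero by construction. Base-year consistency of this residual
is what makes the frozen-world identity exact. Dollar net exports derive
from the kcal residuals through drawn positive per-country conversion
ratios, guaranteeing sign agreement. Projected population variants
continue the demographic transition under baseline versus accelerated
GDP growth, so the accelerated variant is automatically at or below the
median and equal for countries above the threshold. Per-scenario trade
tables scale the base-year positions (with a modest boost to lower-income
positions under accelerated development) and are re-closed to zero.

With a single root seed fanned out to per-country sub-seeds, generation
is deterministic and stable under partial regeneration. Default
calibration targets the stylised record: low-income cropland roughly
doubles over the span with near-flat yields and population roughly
tripling, high-income cropland declines while yields more than triple,
2018 higher-income demand averages near 11,500 kcal day⁻¹ and the world
average sits near 5,000.

What the generator does **not** emulate — and hence what passing tests
do not show about real data: measurement error and revisions, border
changes and missing years, heterogeneous within-group dynamics beyond
lognormal dispersion, crop composition (a single generic cereal stands
in for the multi-crop structure, though the schemas accept crops),
price-mediated demand feedbacks, and any climate signal (multipliers
default to 1). Tests on this world certify the machinery —
identification, identities, rule logic — not the empirical magnitudes of
any real-world projection.

# Numerical choices and degenerate inputs

* Alternating demeaning: tolerance 10⁻¹², capped at 1,000 sweeps.
* Rank deficiency after the within transformation raises an error naming
  the collinear columns rather than silently dropping one.
* Pinball enumeration skips singular bases by a determinant test scaled
  to the data magnitude; ties in the loss keep the first minimiser.
* Intercept-only quantile fits use the type-1 sample quantile, a valid
  minimiser of the check loss.
* Ratios, ceilings, and projected yields are floored (at 0 and at machine
  epsilon respectively) rather than allowed to go non-positive; every
  clamp warns or is documented.
* GDP growth clamps to configured bounds with a message.
* All stochastic procedures take explicit integer seeds; derived seeds
  stay within the 32-bit range.

# Problem sizes used by the checks

The test-suite worlds are deliberately modest: the cached scenario world
uses 3 countries per group (21 countries) over 1990–2018; the
parameter-recovery study uses 100 countries over 56 years with σ = 0.1
and 200 replicates; estimator-equivalence checks use panels up to 6 × 6;
quantile-coverage checks use 50 simulations of 100 points. These sizes
were chosen as the smallest that make each property sharp.

# Known limitations

* Harvested versus physical area is not distinguished: the identity's
  area and the yield denominator are treated as the same surface, so
  multi-cropping intensity is implicitly constant.
* The demand cap, growth premium, quantile level, and climate
  multipliers are documented stand-ins where the source method's exact
  values live outside the main text; all are configuration, not code.
* Net exports are inputs. The engine cannot respond to the endogenous
  trade adjustments a general-equilibrium model would produce, except
  through the frictionless counterfactual.
* Group-level demand curves ignore within-group heterogeneity in the
  demand–income relationship.
* The frictionless mode defines only a global total; country-level
  allocation under frictionless trade is intentionally left undefined.
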