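---
title: "Building a social-ecological resilience index for stock-managed fisheries"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building a social-ecological resilience index for stock-managed fisheries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fishres)
library(dplyr)
```

## The model

fishres measures the resilience of stock-managed commercial fisheries —
their capacity to absorb a disturbance such as a climate-driven
distribution shift without collapsing into a different state — as a
hierarchical composite indicator over three dimensions:

* **ecological** (per stock): potential distribution area today and at
  end of century, relative linear trends of spawning stock biomass (SSB),
  fishing mortality (F) and recruitment (R), the species' preferred
  median temperature and thermal range, overexploitation status relative
  to MSY and limit reference points, and the time the stock needs to
  recover from below-limit biomass excursions;
* **socioeconomic** (per country and species): gear diversity, fleet
  mobility (ICES areas accessed recently and the change since EU
  accession), catch dependency on individual stocks and on the species,
  and investment in fisheries research and management;
* **institutional** (per country and species): producer organizations
  (co-management), quota-swap earnings (property rights), catches above
  the recommended TAC, and compliance with regulation.

Each indicator carries a direction: `+` if more of it supports
resilience, `-` if more of it erodes it (overexploitation, recovery
time, dependency, TAC overshoot, the F trend). `indicator_hierarchy()`
is the frozen indicator → factor → dimension table; it is the single
source of truth for directions and for the deterministic ordering used
in tie-breaks.

The construction is deliberately simple and fully auditable:

1. **Normalize.** Each indicator is min–max rescaled to $[0,1]$,
   $s = (x - \min)/(\max - \min)$, and reversed ($1 - s$) for
   negative-direction indicators, so higher is always better. Bounds
   default to the observed min/max across entities of the same level and
   species; a fixed bounds table can be supplied to reproduce a frozen
   normalization scale, in which case out-of-range values are clipped.
2. **Prune.** Within each dimension, indicators whose pairwise Pearson
   correlation (on raw values, pairwise-complete) exceeds 0.75 in
   absolute value are redundant; keeping both would double-count one
   signal in the averages. We drop greedily: among the indicators
   involved in an offending pair, remove the one with the highest mean
   absolute correlation to the other retained indicators; break ties
   toward the later hierarchy row; repeat until no pair offends. The
   drop log records every removal with the correlation that triggered it.
3. **Aggregate.** Unweighted means, stepwise: indicators → factor,
   factors → dimension, dimensions → overall index. Every tier averages
   its *non-missing* children only; nothing is imputed, and a
   completeness fraction is recorded per node. Optional nonnegative
   weights are accepted at every tier and renormalized over the
   available children; equal weights reproduce the unweighted result
   exactly.
4. **Roll up.** Ecological scores live at the stock level; the social
   scores at the country level. A country's ecological dimension is the
   catch-share-weighted mean of the ecological scores of the stocks it
   fishes (a simple-mean mode is available), so dependence on depleted
   stocks pulls a country's overall index down.

## Key design choices

Several operational details are genuinely open in this kind of index,
and we fixed them as follows.

**Trend windows.** Relative trends are OLS slopes divided by the
in-window mean, making them comparable across stocks of very different
magnitude. SSB gets both a historic (full series, by default
1950–2010-style extents) and a recent trend (the trailing 31-year
window); F and R use the historic window. Trends are fitted on raw
values by default; a `log_trends` flag fits on logs instead, for users
who read stock dynamics multiplicatively. Fewer than 3 in-window points,
or a zero mean, yields a *missing* value with a recorded reason — never
a zero, because zero is a meaningful trend.

**Overexploitation.** `overmsy_index()` is
$(F/F_{MSY})/(B/B_{MSY})$ at the final assessment year, so values
above 1 mean pressure is high while biomass is low; with its negative
direction, larger values reduce resilience. The final year is used
because latest status is the management-relevant one. `kobe_status()`
scores the limit-reference-point quadrants of the Kobe plane ordinally
(1, 2/3, 1/3, 0); the 4-level mapping is this package's choice.

**Recovery.** `recovery_time()` enumerates maximal runs of years with
SSB below the limit. A completed episode lasts until the first year back
at or above the limit; an episode still open at the series end counts
its observed years and is flagged censored. The reported value is the
*worst* (maximum) episode; the full episode table rides along as an
attribute for users who prefer the most recent or mean episode.

**Dependency at the country–species level.** The within-species
dependency of a country–species entity is the catch-share-weighted mean
of its per-stock dependencies, which is algebraically the Herfindahl
concentration of the country's within-species catch: 1 for a
single-stock fleet, $1/n$ when catch is spread evenly over $n$ stocks.
The species-level dependency is the species' share of the country's
total catch. Both use the trailing 5 years of the catch table by
default (`dependency_years`), the same window as fleet mobility.

**Normalization level.** Normalization happens at the indicator level
before averaging into factors (factors then inherit $[0,1]$); this
preserves each indicator's direction from the hierarchy. Observed
bounds are computed within entity level and species, so stocks are
scaled against stocks and countries against countries of the same
fishery.

**Degenerate cases.** An indicator with identical values across all
entities cannot be scaled; it scores 0.5 everywhere with a warning.
Zero-variance columns are excluded from the correlation matrix but
retained. Countries with no catch records lose only their dependency
rows. The overall index is missing when a dimension is missing
(`require_all_dimensions`), or the mean of the available dimensions if
the user relaxes that.

## The synthetic study system

`synthetic_scenario()` + `generate_dataset()` emulate the shapes of the
real inputs — multi-decadal assessment series, reference points,
species traits, catch tables, country records — with a *planted latent
resilience score* $u \in [0,1]$ per country as ground truth. The raw
data distributions of the original study system are not described
anywhere, so every distributional choice here is an artifact choice,
aimed only at the features the downstream statistics consume:

* SSB follows a linear trend line (relative slope interpolating between
  $-$ and $+$ with $u$, amplitude chosen to keep the series strictly
  positive) times multiplicative AR(1) log-noise with autocorrelation
  0.5; F is a declining/rising line through a final value of
  $0.5(1-u)$ against $F_{MSY} = 0.25$; recruitment mirrors SSB.
* Below-limit episodes are planted explicitly as a multiplicative dip
  (depth 0.2) whose duration shrinks with $u$ (up to 20 years at
  $u = 0$); for the lowest scores the dip sits at the series end and is
  left unrecovered (censored), for intermediate scores it recovers five
  years before the end, and for $u \ge 0.75$ there is none.
* Country fields are monotone transforms of $u$ plus field-specific
  Gaussian noise: monetary fields on a log scale, count fields
  integer-rounded, negative-direction fields decreasing in $u$.
* Catches are constructed so the pipeline's dependency indicators hit
  planted values exactly: the species' share of total catch encodes the
  total dependency and the concentration across stocks (solved from a
  target Herfindahl) encodes the within-species dependency.
* The dataset ships with a **bounds table**: the realized indicator
  values of the deterministic $u = 0$ and $u = 1$ constructions. It
  plays the role of a fixed normalization-values table, and it is what
  makes the boundary archetypes score exactly 0 and 1 end to end —
  with purely observed bounds an all-identical archetype cohort would
  be degenerate.

What the generator deliberately does *not* model: stock–recruitment
dynamics, spatial distributions, climate forcing, or realistic
cross-country correlation structure. Passing the recovery tests
therefore shows that the pipeline faithfully inverts *monotone* signal
under moderate noise — not that the index is a validated measurement of
real-world resilience.

One wrinkle worth knowing: because every synthetic field derives from
the same latent score, within-dimension correlations are high and the
pruning stage removes many indicators in latent scenarios. That is the
method behaving correctly on redundant inputs, and the planted ranking
is still recovered from the survivors (median Spearman ≈ 0.99 at 20
countries, noise 0.1).

## Attribution analyses

`factor_importance()` regresses the overall index on the factor scores
with a 500-tree regression random forest (features per split
$\lceil p/3 \rceil$, seeded) and reports permutation importance — mean
decrease in accuracy — as the increase in out-of-bag MSE when a factor
is shuffled, expressed as a **percentage of the response variance**.
The scaled importance that randomForest prints by default is a
t-statistic, not a percentage; normalizing by the response variance
gives a quantity that is stable across seeds, near zero for an
irrelevant factor, and far above 100 for a factor that alone determines
the index. Duplicated (perfectly correlated) factors split importance
between themselves, which is exactly why the index pipeline prunes
correlated indicators before aggregation.

`latitude_effect()` fits score ~ s(latitude) by penalized regression
under a quasibinomial family with logit link, the natural choice for a
bounded score, and returns the smooth's effective degrees of freedom,
approximate significance, and the fitted curve on a latitude grid. An
exactly constant response makes the smooth unidentifiable (the
underlying fitter fails), so that case returns its penalized limit
explicitly: an intercept-only quasibinomial fit, edf 1, flat curve. At
least 10 entities and 2 distinct latitudes are required; the basis
dimension is capped at one below the number of distinct latitudes.

## Problem sizes and numerical tolerances

The validation suite works at sizes where brute-force oracles are
practical and the statistical checks are stable: 200 random instances
of at most 5 entities × 6 indicators for exact (1e-12) agreement with a
loop-written mean-of-means oracle; 1,000 single-value perturbations for
monotonicity; 100 random series for the trend (lm oracle, 1e-10) and
recovery-time (run-enumeration oracle, exact) checks; 20 countries ×
10 seeds at noise 0.1 for latent-ranking recovery; 10 forest seeds and
100 GAM replicates for the attribution checks. Importance tests use
n = 200 entities so the chance correlation between a pure-noise factor
and the response stays negligible.

One acceptance-relevant caveat: the classic three-indicator pruning
illustration with $r_{12} = 0.9$, $r_{13} = 0.8$ and a *small*
$r_{23}$ is infeasible — given the first two correlations, a valid
correlation matrix forces $r_{23} \ge 0.46$. The pruning trace is
therefore validated at $r_{23} = 0.5$, built with an exact-correlation
construction (orthonormalized Gaussian basis colored by the Cholesky
factor), where the greedy rule's hand trace is unambiguous.

## Worked example

```{r example}
scenario <- synthetic_scenario(seed = 1, n_countries = 8, n_stocks = 4,
                               noise_sd = 0.1)
dataset <- generate_dataset(scenario)
res <- compute_resilience(dataset)
glance(res)
tidy(res, "overall") |> arrange(desc(score)) |> head(4)
res$pruned
```

```{r plots, fig.width = 6, fig.height = 3.5}
autoplot(res)
```

## Limitations

The index inherits the usual composite-indicator caveats: equal
weighting is a normative choice (expert weights are accepted but not
elicited), min–max scaling is sensitive to the bounds used, and the
greedy pruning order — while deterministic and logged — is one of
several defensible rules. Stock-to-country ecological rollup by catch
share is this package's bridge between the stock-level and
country-level analyses; a simple mean is provided as the alternative
reading. No uncertainty is propagated through the hierarchy; treat
score differences within a few hundredths as ties.
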