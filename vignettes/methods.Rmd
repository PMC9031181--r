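---
title: "Measuring green-space accessibility and its equity: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring green-space accessibility and its equity: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ugsaccess)
```

This vignette is the package's own account of what it computes, the
assumptions behind it, and the design choices made where more than one
reasonable option existed.

## The accessibility model

The two-step floating catchment area method (2SFCA) treats accessibility as
the outcome of supply and demand competing over overlapping catchments.
Communities are demand points carrying households $H_i$; green spaces are
supply points carrying area $S_j$ in m². Within a catchment radius $d_0$,
interaction is discounted by a truncated Gaussian kernel

$$G(d, d_0) = \frac{e^{-\frac12 (d/d_0)^2} - e^{-\frac12}}{1 - e^{-\frac12}},
\qquad 0 \le d \le d_0,$$

which equals 1 at the facility door, falls smoothly, and reaches exactly 0
at the catchment boundary (and stays 0 beyond it, so the truncation is
continuous). Step one assigns every green space a supply-to-demand ratio
$R_j = S_j / \sum_k G(d_{kj}, d_0) H_k$ over the demand inside its
catchment — its "busyness". Step two gives every community
$A_i = \sum_l G(d_{il}, d_0) R_l$, the decay-weighted sum of reachable
ratios, in m² of green space per household.

Two consequences of this algebra are used as standing invariants in the
test suite:

* **Mass conservation.** $\sum_i H_i A_i = \sum_{j \in J^*} S_j$, where
  $J^*$ is the set of green spaces whose catchment contains at least one
  positively weighted household. Every m² of serving green area is
  allocated to exactly one household-weighted share.
* **Degenerate supply.** A green space whose catchment holds no demand (or
  only demand sitting exactly on the boundary, where the kernel is 0) has
  an undefined ratio. It is flagged unused rather than set to infinity; it
  can contribute to no community's score, so excluding it is lossless.

On the kernel's exponent: the squared ratio $(d/d_0)^2$ is the standard
Gaussian-2SFCA form and the one implemented here; it is the natural choice
that satisfies both boundary facts (unit weight at distance zero,
continuous vanishing at $d_0$).

Distances are straight-line: great-circle on a sphere of radius 6,371,000 m
for longitude/latitude inputs, or planar Euclidean when coordinates are
already projected meters (the `distance_metric` config flag declares
which). No road network or travel-time routing is attempted — the method's
inputs are bare point coordinates, and which projection underlies
"meters" in any given source dataset is the user's declaration, not
something the package guesses. Catchment membership is boundary-inclusive
($d \le d_0$), which is harmless since the kernel weight at the boundary is
zero. A grid-bucket spatial index is available for large planar point sets;
it is contract-tested to return exactly the dense-matrix catchments.

The default radii are 1,000, 2,500, 5,000 and 10,000 m — walking/cycling
scales and driving scales. All radii are analysed in one pipeline pass; the
distance matrix is computed once per city.

## The equity measure

Equity of access is the household-weighted Gini coefficient of
per-household accessibility across a city's communities, each community one
group weighted by its households. Writing $p_i$ for group $i$'s household
share and $y_i$ for its share of the city's total accessibility mass
($H_i A_i$ over the sum), the grouped form

$$GC = \sum_i p_i y_i - 2 \sum_i \Big(\textstyle\sum_{k \le i} p_k\Big) y_i + 1$$

is evaluated with groups ordered by per-household accessibility
**descending**. Ordering matters for this formula's sign: on the two-group
half-split case the descending order gives $+0.5$ and ascending gives
$-0.5$. Before implementation, the descending form was verified numerically
to agree to machine precision with two independent definitions — the
pairwise weighted mean-absolute-difference Gini
$\sum_i \sum_j w_i w_j |x_i - x_j| / (2 W^2 \mu)$ and one minus twice the
trapezoid area under the grouped Lorenz curve — on hundreds of random
instances; both remain as oracles in the test suite. The statistic is scale
invariant, replication invariant, and lies in $[0, 1)$.

Classification follows the conventional bands: Good $[0, 0.3)$, Normal
$[0.3, 0.4)$, Warning $[0.4, 0.6]$, Dangerous $(0.6, 1)$. The printed
convention is "< 0.3" and "> 0.6", so the boundary ties 0.3 and 0.4 go to
the upper band while 0.6 stays in Warning.

A Gini is only reported for cities where it means something. Cities whose
total accessibility is zero (typically a handful of sampled communities,
none within any radius of a green spot) are excluded with reason
`"zero accessibility"`; single-community cities are excluded as
`"insufficient groups"` (inequality across one group is vacuous; the
minimum is configurable, default 2, since no standard minimum exists); an
optional `min_nonzero_share` threshold can additionally require a minimum
fraction of communities with nonzero access (default 0, i.e. off).

## The demand-blind baseline and its ratio

The "traditional" comparison method considers supply but not demand. No
canonical formula exists for it, so the package defines the default variant
as the decay-weighted reachable green area divided by the community's own
households:

$$A^{trad}_i = \sum_{l:\, d_{il} \le d_0} G(d_{il}, d_0)\, S_l \,/\, H_i.$$

This was chosen because it shares units with $A_i$, differs from 2SFCA
precisely by dropping cross-community competition for supply, and lets the
city-level ratio $\bar A / \bar A^{trad}$ fall on either side of 1 — which
is the diagnostic the ratio exists for (above 1: the demand-blind method
underestimates real access; below 1: overestimates). A second variant
(`"decayed_supply"`, no household normalisation) is selectable in the
config. One subtlety is worth recording: for a community that shares its
supply cluster with no other community, 2SFCA's kernel cancels
($A_i = \sum_l S_l / H_i$) while the baseline keeps it, so lone-community
ratios are always $\ge 1$, with equality exactly when the community
co-locates with its spots. Competition from other communities is the only
force that pushes the ratio below 1.

City mean accessibility is the unweighted mean over communities (the
average community's experience); a household-weighted mean is also emitted.
Group comparisons (cities with ratio above vs below 1, on green area and
mean house price) use Welch's unequal-variance t-test — the robust default
when group sizes and variances differ, and nothing suggests equal
variances here. Price-tier analysis assigns each city's mean price to
contiguous closed bands (defaults 500–5,500, 5,501–7,640, 7,641–11,038,
11,039–23,902, 23,903+ yuan/m², boundary values to the lower tier) and fits
per-tier OLS of the city Gini on price; a quantile mode splits into
equal-count tiers instead, which is the sensible choice for synthetic data
whose price range need not resemble those bands. Tiers with fewer than 3
cities or constant price are flagged, not fitted. No multiple-testing
correction is applied across tiers or radii.

## The synthetic-data generator

Real inputs of this kind — web-scraped community listings and green-space
extractions — are proprietary and undeposited, so the package carries a
generator that emulates their statistical shape. Its defaults describe a
typical prefecture-level city: Poisson counts around 315 communities and 33
green spots per city; spot areas lognormal (log-scale sd 1.2) truncated at
1 ha with the log-mean solved numerically so the *truncated* mean is
14.96 ha; household counts lognormal (median 800, log-sd 0.8, floored at
1); house prices centred on 16,368 yuan/m². Counts, areas and the price
centre are population means worth targeting; the corresponding published
spread statistics are internally inconsistent (a std of 8,497 against a max
of 1,220 cannot be a standard deviation), so only the means are treated as
targets and the spread parameters are the package's own choices.

Structure is controlled by three dials:

* `layout` — uniform, monocentric (community density decays exponentially
  from the centre, mean displacement a fifth of the city side) or clustered
  (parent–child clusters, ~40 communities per parent).
* `green_cluster` $\kappa$ — 0 places green spots uniformly; $\kappa > 0$
  concentrates them around a random focus with Gaussian spread
  `extent_m / (2κ)`. Mean Gini rises monotonically in $\kappa$ across
  seeds, which is tested.
* `price_gamma` $\gamma$ — house price is
  `price_base × exp(γ·z + ε)`, where z is the within-city standardized
  decay-weighted green supply at 2.5 km and ε is normal noise (sd 0.2).
  This operationalises a green premium: residents pay more near well-served
  locations. $\gamma = 0$ decouples price from green access (tested:
  correlations collapse toward 0); the default $\gamma = 0.3$ makes the
  signal comfortably detectable at 500 communities.

`generate_country()` jitters the template lognormally across cities (log-sd
0.2) and can inject *degenerate* cities — their green spots displaced
20,000 m beyond the largest analysis radius — to exercise the exclusion
rule deterministically; the injected ids are returned so tests can assert
the rule fires on exactly those cities. All generated data satisfy the
input filters by construction (areas ≥ 1 ha, complete attributes, ids
unique), so reading back the generator's CSV output drops zero rows.

What the generator does **not** emulate: road networks and barriers (real
travel distance exceeds straight-line), irregular administrative
boundaries, spatially autocorrelated household sizes, multi-polygon parks,
and measurement error in scraped listings. Passing tests on synthetic data
therefore demonstrate the *algorithms'* correctness and the pipeline's
recovery of designed structure, not empirical claims about any real city.

## Numerical choices and edge cases

* Kernel at the boundary: computed exactly 0 by construction
  ($e^{-1/2} - e^{-1/2}$); a `pmax(·, 0)` guards against sub-epsilon
  negatives just inside.
* The Gini rejects all-zero accessibility (degenerate signal routed to the
  exclusion rule) rather than returning 0/0.
* Ratios for unused green spaces are `NA`, never `Inf`; accessibility sums
  treat them as absent.
* Hectare→m² conversion is the exact factor 10⁴; the ≥ 1 ha filter is
  boundary-inclusive, since published minima report exactly-1 ha spots as
  present.
* Result CSVs are written with fixed column order, stable row sort
  (city, radius, community) and full precision, making repeated runs
  byte-identical — tested through the command-line interface.
* Test and acceptance problem sizes — 20 cities of ~300 communities for the
  country-scale checks, ≤ 200 × 50 points for conservation, ≤ 50 points for
  the double-loop oracle — are chosen so the whole suite completes in well
  under a minute while still exercising every code path at realistic
  densities.

## Known limitations

Straight-line distance understates real impedance in cities with rivers or
rail corridors. The Gaussian kernel's shape parameter is tied to $d_0$
rather than estimated from travel behaviour. The grouped Gini treats each
community as internally homogeneous. The per-tier OLS is across cities, so
its slopes are not comparable to within-city hedonic estimates; with few
cities per tier the fits are fragile, and the package deliberately refuses
them below 3 cities. None of these limit the package's scope of validity
so much as define it: point-pattern accessibility and its distributional
summary, under declared, reproducible assumptions.
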