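---
title: "Methods: index-based coastal vulnerability assessment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: index-based coastal vulnerability assessment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coastvuln)
```

# The model

`coastvuln` implements a relative, index-based assessment of vulnerability
to coastal change along a shoreline sampled at fixed spacing (1 km by
default, one point representing one kilometre of coast). It has three
layers.

**Index of exposure (IE).** Six biophysical variables are each ranked into
five classes, 1 (very low exposure) to 5 (very high), and combined as a
geometric mean:

$$IE = \left(R_{relief}\, R_{waves}\, R_{wind}\, R_{surge}\, R_{habitats}\,
R_{shoreline\ change}\right)^{1/6}.$$

The geometric mean makes the index multiplicative: a single protective
factor (say, a fringing coral reef, $R_{habitats}=1$) pulls the index down
much harder than an arithmetic mean would, which is the intended behaviour
for habitat-mediated protection. IE is bounded by the smallest and largest
of the six ranks and is invariant to their order.

Ranking rules per variable:

* **Relief** (m) and **wave exposure** (model units of weighted-average
  wave power) use fixed class edges — relief 2, 4, 8, 12 m (descending:
  low-lying coast is most exposed), wave 0.75, 3, 18.75, 48 (ascending).
  Fixed edges differentiate highly skewed distributions better than
  quantiles. Intervals are closed at the lower edge, open at the upper,
  and out-of-range values clamp to the extreme class (a 30 m cliff ranks
  1; a negative elevation ranks 5).
* **Wind exposure** and **surge potential** (distance to the 30-m depth
  contour, a proxy for shelf width) are ranked by region-wide quintiles in
  one pass over all points: the assessment is a supra-regional comparison,
  so pooling rather than per-country ranking keeps ranks comparable
  across borders. Breakpoints sit at the 20/40/60/80th percentiles
  (type-7 linear interpolation); a value equal to a breakpoint goes to the
  lower class, and a constant input degenerates to rank 1 everywhere.
* **Shoreline change rates** (m/yr, available only on sandy shores) use
  the conventional erosion classes: accretion above +2 ranks 1, (+1, +2]
  ranks 2, the stable band [-1, +1] ranks 3, [-2, -1) ranks 4, erosion
  below -2 ranks 5. Missing rates (non-sandy shores) default to the
  neutral rank 3, configurable — a deliberate choice to avoid biasing
  rocky coasts toward either extreme.
* **Habitats**: coral reefs and mangroves rank 1, seagrass 4, no habitat
  in range 5. A point is protected by a habitat class when the nearest
  polygon of that class is within the class's protective distance; where
  several classes are in range the most protective (minimum) rank wins.
  The protective radii are not settled in the literature we follow; the
  package defaults — coral 2,000 m, mangrove 1,000 m, seagrass 500 m —
  are explicit assumptions, configurable per layer.

The continuous IE is collapsed to discrete classes by nearest-integer
rounding (half up, so class 4 — and hence "higher exposure" — starts at
IE ≥ 3.5), then to three reporting classes: lower (classes 1–2), moderate
(3), higher (4–5). Rounding is the simplest fixed rule consistent with
regional higher-exposure fractions far from the 40% that quintile classing
would force; a quantile-based rule is available via
`classify_ie(rule = "quantile")` for sensitivity analysis.

**Habitat scenarios.** Five scenarios isolate each habitat's protective
contribution: S1 keeps all habitats (current conditions), S2 removes coral
reefs, S3 mangroves, S4 seagrasses, and S5 removes everything, forcing
$R_{habitats}=5$. Only the habitat rank changes between scenarios, so
exposure under S1 is a pointwise lower bound and S5 a pointwise upper
bound — a monotonicity the test suite asserts for IE, class, percent of
coastline at higher exposure, and population at higher exposure.

**Population at higher exposure.** People within 5 km (configurable) of
higher-exposure shoreline are counted on a gridded population layer: a
cell contributes its full count when its center falls inside the union of
buffer disks around the H-class points, and is never double-counted
however many disks cover it. Cell-center membership (rather than
area-weighted overlap) keeps the computation deterministic and matches
common gridded-population practice. Union semantics apply per reporting
unit: a cell near two districts' H-points counts in both districts but
once in their shared province, so district figures may legitimately sum to
more than the province figure.

**Social vulnerability index (SVI).** Eight district-level census
indicators (shares of under-4s and over-65s, annual population growth,
density, illiteracy, natural-material housing, unimproved water and waste
collection) are each transformed with a natural logarithm and z-scored
across the included districts, summed with their direction of influence
(+1 for all eight defaults: larger values mean more vulnerable), and the
scores ranked 1–5 by the same quintile rule used everywhere else. Details
that the aggregation literature leaves open, fixed here: the log uses an
offset of +1 so zero-valued percentages are admissible (set `offset = 0`
for strictly positive data — only then is the transform scale-invariant);
the standard deviation is the sample (n−1) one; z-scoring pools all
districts across countries rather than per country, consistent with a
cross-border comparison. Districts with incomplete indicators are excluded
and reported, not failed — the same behaviour as dropping a country whose
census is too old to compare.

**IVCC.** The index of vulnerability to coastal change is the plain sum
of the SVI and the unit's mean IE, so it lives in [2, 10]. At province
level the SVI term is the mean of the district *ranks* (not raw scores) —
this is what makes reported province values like 4.6 possible — and the
IE term averages all points in the province rather than averaging district
means, which would weight small districts up. Units without an SVI
propagate an absent IVCC; nothing is imputed. Districts with IVCC
strictly above 7 are areas of priority concern; those also having strictly
more than 90% of their coastline at higher exposure under S1 are critical
areas. Both thresholds are strict by the wording they implement.

**Validation protocol.** Where an inventory of per-district coastal
hazard events (and events causing fatalities) exists, the indices are
validated by (a) splitting units into "exposed" vs "less exposed" at
thresholds of 20, 25, 30 and 50% of shoreline points at higher exposure —
inclusive ≥ at the threshold, following the convention this protocol
extends — and comparing event counts between groups with Mann-Whitney U
tests; and (b) Spearman rank correlations of the percent-higher measure
and of the IVCC against both outcomes. The U statistic is computed from
midranks; p-values are exact (full enumeration of rank assignments, valid
under ties) when $n_a n_b \le 20$ and otherwise use the tie-corrected
normal approximation with continuity correction, mirroring common
statistical-package defaults. Spearman's rho is the product-moment
correlation of midranks with the t approximation on n−2 degrees of
freedom; two-sided p-values are reported throughout and significance
levels are left to the caller.

# The synthetic-region generator

`generate_region()` produces a complete, seeded study region so the whole
pipeline runs and is testable without any external data. What it emulates,
and how:

* **Coastline**: a smooth random polyline built from 0.5-km steps whose
  heading wanders within ±60° of east. Keeping the coast x-monotone lets
  district polygons be exact vertical slabs that provably partition the
  coastal strip — the partition-conservation property (district lengths
  sum to province, country and region totals exactly) is then testable
  without geometric tolerance.
* **Fields**: relief, wave power, wind exposure and shelf distance are
  lognormal transforms of moving-average-smoothed Gaussian noise with a
  25-km correlation length — smoothed noise rather than an exact Gaussian
  process, which is dependency-light and sufficient for pipeline realism.
  A shared latent "openness" field couples them the way open versus
  sheltered coasts do: open stretches pair high wave and wind energy with
  low-lying shores, wide shallow shelves and faster erosion. Without this
  coupling, independently drawn fields almost never align into
  higher-exposure coast and the region degenerates to uniformly moderate
  exposure; with it, defaults give regions with roughly 5–15% of coastline
  at higher exposure with habitats and 25–40% without, and district-level
  fractions spanning 0–100%.
* **Habitats**: along-coast ribbons just offshore of contiguous covered
  stretches. Coverage fractions default to the regional shares typical of
  the western Indian Ocean coasts this emulates (mangrove 0.60, coral
  0.34, seagrass 0.08 of coastline). Mangroves and seagrasses are biased
  toward sheltered (low-openness) coast, as they require shelter from
  wave action to develop; corals are placed independently.
* **Shoreline-change availability**: "sandy" rate-bearing points form
  contiguous runs (a thresholded smooth field), not i.i.d. picks,
  mimicking real beach stretches; 60% of the coast is sandy by default.
* **Population**: an axis-aligned grid (2-km cells) whose counts decay
  exponentially with distance to the nearest shoreline point (3-km
  e-folding), normalised to a 2-million total.
* **Census**: correlated lognormal indicators (common-factor correlation
  0.5) with location/scale chosen to give realistic means — e.g. ~70%
  natural-material housing, ~40% unimproved water — and percentage
  indicators capped at 100.
* **Events**: district counts are Poisson with
  $\log \lambda = \beta_0 + \beta_1\, \mathrm{pct\_higher}/100$ computed
  from the district's *true* S1 exposure (defaults $\beta_0 = 0.5$,
  $\beta_1 = 2$); fatal events are a binomial thinning (p = 0.4).
  Setting $\beta_1 = 0$ gives the exposure-independent null model used
  for type-I calibration.

What the generator does **not** emulate: real oceanography (no fetch or
hindcast computation), real demography, multi-country census
heterogeneity, non-monotone coastlines (islands, deep embayments), or any
calibration to actual East African statistics. Tests passing on synthetic
regions therefore demonstrate the pipeline's internal correctness and its
statistical behaviour under the stated generating model — not agreement
with any real coastline.

# Numerical choices and degenerate inputs

* Quantile breakpoints use R's type-7 percentile; ties go to the lower
  class everywhere (exposure quintiles and SVI quintiles share one rule).
* Admin attribution tie-break: a point on a shared district boundary goes
  to the smaller `unit_id` (polygons visited in id order) — a convention,
  chosen for determinism.
* The wave class edges treat the published 18.70/18.75 gap as a typo and
  use contiguous edges 0.75, 3, 18.75, 48; a total ranking needs
  contiguous intervals.
* Report tables round half-up to one decimal (`round_half_up`), so
  100·2620/10237 prints 25.6; CSV outputs keep full precision.
* Degenerate cases are defined, not errors: constant quantile input →
  rank 1; zero-variance Spearman input → flagged `NA`; two-unit
  Mann-Whitney runs with n = 1 per group and returns a wide p; a census
  district with missing indicators is excluded and listed.

# Problem sizes

The test suite and acceptance script run entirely on generated regions:
150–300-km coastlines for unit and invariant tests, a 1,000-km coastline
with 100 districts for the validation calibration and power simulations
(200 event replicates each). These sizes give stable statistical
behaviour — the null rejection rate sits inside the binomial 99% band
around 0.05 and the slope-2 event model is detected in essentially every
replicate — while the whole suite completes in well under a minute.

# Known limitations

* Geometry is planar; reprojection is upstream of the package.
* Habitat protection is all-or-nothing within the protective distance; no
  attenuation with distance or habitat condition (a degraded reef protects
  like a pristine one), and the multi-habitat rule is "most protective
  wins" rather than an empirical attenuation formula.
* The IE-to-class rounding rule is a modelling choice; published
  InVEST-based assessments do not state theirs, and different rules shift
  the higher-exposure fraction.
* The SVI is a relative measure across the analysed districts only, and
  district aggregation hides within-district inequality.
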