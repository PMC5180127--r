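---
title: "Models and methods behind resight"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind resight}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(resight)
```

`resight` analyses multi-year photo-identification catalogues from seasonal
wildlife aggregations and asks how much between-site migration such
catalogues could detect. This vignette documents the statistical models, the
parameter choices and their defaults, the numerical decisions, and what the
synthetic-data validation does and does not establish.

## The data model

A catalogue row is one encounter: `individual_id`, `site`, `date`, `sex`
(male / female / indeterminate) and `flanks` (`L`, `R` or `LR` — which
flanks were photographed). Identities are assumed final: the package does
no image matching, and "year" everywhere means the calendar year of the
encounter date.

Because the two flanks of a shark carry independent marking patterns, an
individual photographed left-only on one occasion and right-only on another
cannot be linked without a both-flank photo. All analyses therefore run on
two views of the catalogue: **LB** (records whose photos include the left
flank, codes `L` and `LR`) and **RB** (`R` and `LR`). A both-flank record
belongs to both views, so `|LB| + |RB| - |both| = |records|`. When a test
gives the same significance category on both views,
`report_side_selection()` reports the LB result (left-flank catalogues are
typically slightly larger); discordant results are returned flagged rather
than silently resolved.

A **resight** is strictly across years: an individual recorded at the same
site in a previous *sampled* year. A second encounter within the same year
does not count, and each site's first sampled year is removed before
resight proportions are computed, since no resight is possible there.

## Permutation inference

`perm_anova_oneway()` tests for site differences in a univariate yearly
metric (e.g. unique individuals identified per year). The pseudo-F is
computed from the Euclidean distance-matrix partition

$$SS_{total} = \frac{1}{n}\sum_{i<j} d_{ij}^2, \qquad
  SS_{within} = \sum_g \frac{1}{n_g}\sum_{i<j \in g} d_{ij}^2,$$

with $F = (SS_{between}/df_b)/(SS_{within}/df_w)$. For univariate data and
Euclidean distance this partition is algebraically identical to the
classical one-way ANOVA decomposition; the test suite exploits that
identity as an oracle (`aov()` computes the same F by a different route)
rather than assuming it. The null distribution comes from unrestricted
permutation of the raw observations across groups, 999 permutations by
default, with the add-one convention $p = (b+1)/(m+1)$ so a sampled p-value
is never exactly zero. For two small groups `exhaustive = TRUE` enumerates
all $\binom{n}{n_1}$ assignments and the p-value is exact (the identity
assignment counts itself, so no add-one is applied). Ties in the permuted
statistic are counted as "at least as extreme" with a `1e-12` float guard.
Zero total variance makes the pseudo-F undefined; the fit returns $p = 1$
with a warning rather than erroring, since identical observations carry no
evidence of a group difference.

Post-hoc `pairwise_perm_tests()` are two-group permutation tests of the
same statistic. No multiplicity correction is applied by default — the
pairwise p-values are reported as computed, mirroring common practice in
the field's software — but `p_adjust = "holm"` is available.

`chisq_return_years()` compares sites on the distribution of the number of
years individuals returned, over a six-consecutive-year window per site
(windows need not be identical across sites; they are configuration). The
top two categories (5 and 6 years) are pooled by default so that more than
80% of cells keep expected counts above five; `assumption_ok` reports
whether the rule is met after pooling. The statistic is the Pearson
chi-square without continuity correction — the appropriate form for tables
larger than 2×2, and the one consistent with quoting 12 degrees of freedom
for a 4×5 pooled table.

## The migration-detection power model

Consider a **source** aggregation of size $P_{source}$ from which a
proportion $MR$ relocates each year into a **sink** of size $P_{sink}$, and
suppose $N_{source}$ individuals are catalogued yearly at the source.
Migrants then make up $MR \cdot P_{source}/(P_{sink} + MR \cdot P_{source})$
of the augmented sink pool, of whom a fraction $N_{source}/P_{source}$ are
already catalogued. A yearly sink sample of $N$ individuals therefore yields

$$E[\text{matches}] = N \cdot \frac{MR \cdot N_{source}}
{P_{sink} + MR \cdot P_{source}}$$

expected catalogued-migrant matches. Setting this equal to a detection
demand $DP$ and solving gives the kernel

$$N_{sink} = DP \cdot \frac{P_{sink} + MR \cdot P_{source}}
{MR \cdot N_{source}}.$$

Two design decisions deserve note:

* **Orientation.** The kernel is the *requirement* form: individuals that
  must be identified at the sink, decreasing in MR, increasing in
  $P_{sink}$, linear in DP — the form whose curve an observed-effort line
  crosses from below as MR grows. The algebraic reciprocal (expected match
  yield per identification) is available as `orientation = "yield"` for
  diagnostics; it is not a sample size and is never used by the solver.
* **DP semantics.** DP enters multiplicatively as an *expected-match*
  demand, not as a true probability of at least one match. The two agree
  when expected matches are small ($P(\ge 1) = 1 - e^{-E} \approx E$) and
  diverge as $E$ grows. Rather than silently substituting one convention,
  the package ships an agent-based oracle,
  `simulate_detection_oracle()`, which simulates cataloguing, relocation
  and sink sampling directly (hypergeometric draws) and reports both the
  empirical $P(\ge 1\ \text{match})$ and the mean match count, quantifying
  the gap for any configuration. The test suite pins the oracle's mean to
  the hypergeometric expectation and brackets its detection probability
  between $1 - e^{-E}$ and $\min(1, E)$ up to Monte Carlo error.

### Monte Carlo propagation

Published inputs are uncertain: population estimates come with 95% CIs, and
yearly identification counts vary between years. `migration_power()` draws
$N_{source} \sim \mathcal{N}(\mu, se)$ and $P_{source}, P_{sink}$ likewise,
evaluates the kernel per draw across the migration-rate grid, and reports
the per-rate median and 2.5/97.5 percentiles. Numerical choices:

* **SE from a 95% CI**: $se = (ci_{high} - ci_{low}) / (2 \times 1.96)$,
  the symmetric-normal assumption — the CI is the only dispersion published
  for these estimates. Where an interval is really a pair of alternative
  point estimates rather than a CI (this ambiguity exists for one site),
  the midpoint is the same either way and `population_estimate(se = )`
  lets the user override the dispersion.
* **SE of $N_{source}$**: year-to-year variation in identification counts
  is rarely published; the default is 10% of the mean
  (`n_source_se`), overridable. Threshold medians are insensitive to this
  choice because the perturbation is symmetric around the mean.
* **Truncation**: negative or zero draws are rejected and resampled rather
  than clamped to zero — clamping would pile mass at zero and bias the
  median. A configuration whose normal is negative more than half the time
  (rejection rate above 50%) is refused as degenerate.
* **Shared draws**: one set of `n_draws` triples is reused across the whole
  MR grid, so each draw's requirement curve — and hence every reported
  quantile curve — is strictly decreasing in MR. Drawing independently per
  grid point would add jitter that could produce non-monotone medians near
  the crossing.
* **Defaults**: `dp = 0.8`, `n_draws = 10000`, grid 0.5%–25% in 0.5% steps.
  The defaults are the study conditions of the motivating system (80%
  detection demand; migration rates of interest up to a quarter of the
  source population per year); the grid ceiling is configurable, and the
  detection solver flags, rather than extrapolates, a crossing beyond it.

### The detection threshold

`detection_threshold()` returns the smallest grid MR at which the median
required sink sample does not exceed the observed yearly identification
count, refined by linear interpolation of the (monotone) median between the
bracketing grid points. Two boundary cases are explicit states, not errors:
an observed line above the entire curve saturates at the smallest grid rate
(`saturated = TRUE`: even the smallest considered rate is detectable), and
an observed line below the entire curve yields `detectable = FALSE`
(migration at any gridded rate is expected to go unnoticed at current
effort).

For the bundled Indian Ocean inputs (`indian_ocean_sites()`: per-site
population estimates with 95% CIs and average yearly identification counts
104, 77, 59 and 28 for Ningaloo, Mozambique, Seychelles and the Maldives),
the solved thresholds at DP = 0.8 with 10 000 draws are approximately 5.3%
(Seychelles → Ningaloo), 2.7% (Ningaloo → Maldives), 10.7%
(Maldives → Ningaloo) and, on a grid extended to 40%, 26%
(Maldives → Seychelles) — the last meaning migration into the Seychelles
below roughly a quarter of the Maldives population per year would likely
escape detection at current effort. One site (Mozambique) has no published
population estimate; the fitter refuses an `NA` population rather than
inventing one, and requires an explicit user-supplied estimate.

## The synthetic world generator

`simulate_world()` exists so every downstream stage is testable with known
truth. It emulates: closed per-site populations linked only by migration;
per-year identification of each present individual with a site-specific
`annual_sighting_prob`; male-biased (configurable) sex composition fixed
per individual; and flank coverage drawn per sighting from
(both, left-only, right-only) probabilities. Migration is permanent
relocation — migrants join the sink pool, matching the kernel's
$P_{sink} + MR \cdot P_{source}$ denominator — and the per-year migrant
count is binomially drawn with a fixed-count mode (`fixed_migrants`) for
variance-controlled oracle comparisons. Within a simulated year the
sighting season precedes the relocation, i.e. individuals move between
seasons, as fits a seasonal-aggregation system. Return migration is not
modelled.

The generator deliberately omits: births, deaths and open-population
turnover (population estimates are treated as inputs, not
re-modelled), sex-specific movement or sighting behaviour, within-season
encounter dynamics (an individual contributes at most one record per site
per year), spatial paths, and any image-level error — identities are exact.
Passing tests on synthetic worlds therefore validate the bookkeeping and
the sampling mathematics, not robustness to misidentification or to
non-closure of real populations.

`naive_split_ids()` inverts the LB/RB safeguard for study purposes: it
rewrites identities as a single-flank matching process would see them
(an individual with left-only and right-only records and no linking
both-flank photo becomes two IDs), letting users quantify the
double-counting bias the dual-view protocol avoids.

## Validation design and problem sizes

The suite validates each layer against an independent route: the
distance-partition pseudo-F against `aov()`; sampled permutation p-values
against exhaustive enumeration (all 20 splits of 6 observations into two
triples) and against uniformity under a simulated global null
(500 replicates, Kolmogorov–Smirnov); the Pearson statistic against the
direct $\sum (O-E)^2/E$ formula; the Monte Carlo median against the
closed-form kernel (collapsing exactly when all SEs are zero, and within 2%
at $10^5$ draws); the sampling oracle's mean matches against the
hypergeometric expectation over a 3×3 (MR, $N_{sink}$) grid; and the full
pipeline against planted truth — zero-migration worlds yield zero
cross-site matches, and a planted 10% migration rate across 200 replicate
two-site worlds is detected at the frequency the kernel predicts, within a
binomial confidence interval, at a parameterisation where the
expected-match and probability conventions coincide. Simulation sizes
(10 000 power draws, 200 pipeline replicates, 500 calibration replicates)
keep the whole suite under a minute while leaving Monte Carlo error well
inside the asserted tolerances.

## Known limitations

* The power model treats a single year of sink sampling; accumulating
  effort across years would detect lower rates.
* Detection demands expressed as expected matches overstate true
  detection probability once expected matches approach 1; use the oracle
  to translate between conventions at your configuration.
* Cross-site distances are user-supplied straight-line kilometres; the
  implied `min_travel_speed()` is a lower bound on swimming speed, not an
  estimate.
* Sex conflicts across records resolve to the earliest determinate value
  with a warning; the package does not model sex misclassification.
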