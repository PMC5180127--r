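# resight

Photo-identification resight analysis and migration-detection power for
seasonal wildlife aggregations.

Many marine megafauna species — the motivating case is whale sharks
(*Rhincodon typus*) at Indian Ocean coastal aggregations — can be identified
individually from photographs of stable natural markings. Multi-year
catalogues of such photo-IDs support two kinds of questions:

1. **Description and inference.** How many unique individuals are identified
   per year at each site? What fraction are *resights* (individuals already
   recorded at the same site in a previous sampled year)? Do sites differ in
   yearly abundance of identified individuals or in how many years
   individuals keep returning? `resight` computes these metrics and tests
   them with a one-way permutational ANOVA on Euclidean distances
   (unrestricted permutation of the raw data) and a pooled Pearson
   chi-square on years-returned contingency tables. Because left and right
   flank patterns differ, every analysis runs on both the left-plus-both
   (LB) and right-plus-both (RB) catalogue views, with a reporting rule that
   prefers LB when both views agree.

2. **Power to detect migration.** If a proportion MR of a *source*
   population P_source relocates each year to a *sink* population P_sink,
   and N_source individuals are catalogued yearly at the source, migrants
   make up MR·P_source/(P_sink + MR·P_source) of the augmented sink pool and
   a fraction N_source/P_source of them are already catalogued. The number
   of individuals that must be identified at the sink in one year to expect
   DP catalogued-migrant matches is therefore

   N_sink = DP · (P_sink + MR·P_source) / (MR · N_source).

   `migration_power()` propagates uncertainty in N_source, P_source and
   P_sink through this kernel by Monte Carlo (normal draws truncated at
   zero), returning the median and 2.5/97.5 percentile curve of required
   sink identifications across a grid of migration rates.
   `detection_threshold()` solves for the smallest MR at which the median
   requirement drops below the observed yearly identification count — the
   smallest migration rate the current sampling effort can expect to
   detect. An independent agent-based sampling oracle
   (`simulate_detection_oracle()`) and a synthetic multi-site catalogue
   generator with known migration truth (`simulate_world()`) validate the
   kernel end to end.

## Worked example

How much migration from the Seychelles aggregation (59 individuals
identified/yr, population 513, 95% CI 469–557) could be detected at
Ningaloo Reef (population 380, 95% CI 320–440, 104 identifications/yr)?

```r
library(resight)

sey <- population_estimate("seychelles", 469, 557)
nin <- population_estimate("ningaloo", 320, 440)
fit <- migration_power(n_source = 59, p_source = sey, p_sink = nin,
                       dp = 0.8, n_draws = 10000, seed = 42, sink_obs = 104)
fit
#> Monte Carlo migration-detection power curve (seychelles -> ningaloo)
#>   DP = 0.8, 10000 draws, MR grid 0.5%-25.0% (50 points)
#>   median required sink identifications: 1039.2 at MR=0.5%, 27.6 at MR=25.0%
#>   observed sink identifications/yr: 104

detection_threshold(fit)
#> Detection threshold: MR* = 5.33% of source population per year (DP=0.8,
#>   grid crossing at 5.50%, observed 104 sink identifications/yr)
```

Detecting a 0.5%/yr migration rate with an expected-match demand of 0.8
would require identifying over a thousand sharks at Ningaloo in a single
year; at the observed effort of 104 identifications/yr, migration becomes
detectable from about a 5.3%/yr rate upward. `plot(fit)` draws the median
curve, its 95% percentile band and the observed-effort line whose crossing
defines the threshold.

The deterministic kernel is available directly:

```r
required_sink_sample(0.8, 0.05, n_source = 59, p_source = 513, p_sink = 380)
#> [1] 110.0068
```

and descriptive metrics work on any catalogue CSV
(`individual_id, site, date, sex, flanks`):

```r
records <- read_catalogue("catalogue.csv")
views   <- build_flank_views(records)
summ    <- site_year_summaries(views$LB)
perm_anova_oneway(summ$n_unique, summ$site, n_perm = 999, seed = 1)
min_travel_speed(3000, 221)   # 13.6 km/day: one real between-site resight
```

A command-line wrapper (`inst/cli/resight`) exposes the pipeline as
`simulate`, `metrics`, `tests` and `power` subcommands; see `?cli_main`.

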