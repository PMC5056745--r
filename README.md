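# camtrapcoex

Co-occurrence and activity analysis for camera-trap surveys of carnivore
communities.

Sympatric carnivores that share prey and habitat are expected to partition
their niches in space and time. Baited camera-trap grids are the standard
field instrument for studying this in forest mesocarnivore guilds, and the
resulting photo streams support three complementary analyses: *where*
species occur (two-species occupancy with a species interaction factor),
*when in the year* they are active (effort-corrected monthly activity
indices), and *when in the day* they are active (circular activity
densities, diel time budgets and activity overlap). `camtrapcoex`
implements that full pipeline for ecologists working from tabulated photo
records — every stage is a tibble-in/tibble-out function, so the pieces
compose with the pipe and slot into ordinary tidyverse workflows.

## What it computes

**Independent detections and effort.** Photographs of a species at a
station are collapsed into independent detection events whenever
consecutive photos are more than 30 min apart (configurable); multiple
animals in one frame are a single detection. Survey effort is accounted in
camera-days from deployment spans, apportioned pro-rata to calendar
months, and the relative activity index for month *j* is
RAI_j = 1000 · D_j / E_j (detections per 1,000 camera-days).

**Solar-anchored diel activity.** Each event's clock time is transformed
to *sun time*: sunrise maps to 06:00 and sunset to 18:00, removing the
seasonal photoperiod signal (solar events come from the NOAA low-precision
geometry, checked against an independent ephemeris to ±2 min). Activity is
estimated by circular kernel density with a von Mises kernel whose
concentration follows the plug-in rule

> κ_kernel = [ 3 n κ̂² I₂(2κ̂) / (4 √π I₁(κ̂)²) ]^{2/5} / adjust,

with κ̂ the maximum-likelihood von Mises concentration and `adjust = 1`
by default. Pairwise temporal overlap is the coefficient of overlap
Δ̂ ∈ [0, 1] — the area under the pointwise minimum of two activity
densities — estimated by Δ̂₁ (grid integration) for small samples and Δ̂₄
(density ratios at the observed points) for larger ones, with
smoothed-bootstrap percentile confidence intervals.

**Diel time budgets.** The 24-h cycle is split into crepuscular
(astronomical dawn→sunrise, sunset→astronomical dusk), diurnal and
nocturnal periods. Use versus availability is summarised by Manly
selection ratios w_i = o_i / π̂_i (o_i = share of detections in period
*i*, π̂_i = share of surveyed time), tested by χ² against random use and
by a 10,000-draw multinomial randomization with direction-tagged
one-sided p-values.

**Spatial co-occurrence.** Detection histories on 15-day occasions feed a
two-species occupancy model parameterised by the marginal occupancies
ψ_A, ψ_B and the species interaction factor γ = ψ_AB / (ψ_A ψ_B): γ < 1
indicates spatial avoidance, γ = 1 independence, γ > 1 aggregation.
Detection is modelled on the logit scale with optional scent-lure-age
(`Lr`) and camera-trigger-class (`Cam`) covariates, and with separate
probabilities p (other species absent) and r (both present). The standard
16-model set — {γ free, γ = 1} × {detection covariates} × {r = p, r ≠ p}
— is fitted by maximum likelihood and ranked by AIC; the SIF is read from
the ΔAIC < 2 top set.

A synthetic-survey generator (`simulate_survey()`) with known occupancy,
co-occurrence, diel archetypes and seasonal structure makes every stage
testable without field data.

## Worked example

Simulate a small two-year survey (60 stations, four species, a built-in
avoidance pair with γ = 0.6) and run the full analysis:

```r
library(camtrapcoex)

sim <- simulate_survey(minshan_mini_config(seed = 7))
a <- run_full_analysis(
  sim$photos, sim$deployments,
  focal_pairs = list(c("masked_palm_civet", "hog_badger")),
  n_boot = 500, n_reps = 1000, cooccur_years = 2013:2014, seed = 3
)
a
#> Camera-trap community analysis
#>   1068 photos -> 525 independent events; 2428 camera-days (2046 warm / 382 winter)
#>   species: hog_badger, masked_palm_civet, siberian_weasel, yellow_throated_marten
#>   SIF masked_palm_civet_x_hog_badger: gamma = 0.60 +/- 0.14 (unclear)
```

The 1,068 photographs collapse to 525 independent events over 2,428
camera-days. The diel overlap matrix separates the two nocturnal species
(high Δ̂) from the nocturnal–diurnal pairs (low Δ̂):

```r
dplyr::select(a$overlap, species_a, species_b, delta, ci_low, ci_high)
#>   species_a         species_b              delta ci_low ci_high
#> 1 hog_badger        masked_palm_civet      0.879  0.785   0.940
#> 2 hog_badger        siberian_weasel        0.562  0.519   0.673
#> 3 hog_badger        yellow_throated_marten 0.312  0.260   0.456
#> 4 masked_palm_civet siberian_weasel        0.547  0.507   0.695
#> 5 masked_palm_civet yellow_throated_marten 0.299  0.245   0.444
#> 6 siberian_weasel   yellow_throated_marten 0.718  0.620   0.828
```

and the co-occurrence ranking recovers the generating interaction factor
(the top γ-free model estimates γ̂ = 0.605 ± 0.139 against a simulated
truth of 0.6; with only 60 stations the γ = 1 models remain inside the
ΔAIC < 2 set, so the hypothesis-level interpretation is "unclear"):

```r
glance(a$cooccurrence$masked_palm_civet_x_hog_badger)
#>   species_a          species_b  gamma_hat gamma_se interpretation n_top_models n_models
#> 1 masked_palm_civet  hog_badger     0.605    0.139 unclear                   4       16
```

Fitted objects come with `tidy()`, `glance()` and `autoplot()` methods;
`write_analysis()` serialises the whole bundle as CSV/JSON.

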