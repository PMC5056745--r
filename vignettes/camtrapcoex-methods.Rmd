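---
title: "Models and methods behind camtrapcoex"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind camtrapcoex}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(camtrapcoex)
```

`camtrapcoex` analyses baited camera-trap surveys of sympatric carnivore
communities along the three classical niche axes that photo records can
resolve: space (two-species occupancy with a species interaction factor),
season (effort-corrected monthly activity), and time of day (circular
activity densities, overlap, and time budgets). This vignette documents
the models, the tunable parameters and their defaults, the synthetic-data
generator, and the numerical and design choices a user or reviewer should
know about.

## From photographs to detection events

Camera streams autocorrelate strongly: one animal lingering at a lure can
trigger dozens of frames. The package collapses photographs into
*independent detection events*: within each station-by-species stream
sorted by time, a new event starts when the gap to the previous photograph
strictly exceeds `gap_minutes` (default 30 min). Multiple individuals in a
frame are one detection, and frames with identical timestamps collapse
before gap evaluation. Two consequences worth noting: the event count is
invariant to the order of rows in the input file, and increasing the gap
can only decrease the number of events.

All clock times are treated as local standard time with no daylight-saving
rules (the default zone is UTC+8) and are stored internally as
UTC-labelled `POSIXct` so no timezone database is ever consulted. Rows
that fail to parse are collected in a rejects table attached to the parsed
tibble — auditable, never silently dropped.

Survey effort is computed from deployment spans, not from photo coverage:
each deployment contributes its full `end - start` duration in fractional
camera-days, apportioned pro-rata to the calendar months it overlaps.
Seasons follow the warm = March–November, winter = December–February
convention throughout. The relative activity index for month $j$ pools
years: $\mathrm{RAI}_j = 1000\, D_j / E_j$ with $D_j$ events and $E_j$
camera-days in month $j$; months with effort but no events report 0, and
months with no effort are flagged undefined rather than divided by zero.

## Solar geometry and sun time

Diel analyses at mid-latitudes must deal with a photoperiod that shifts
sunrise by about two hours over the year. The package computes per
station-date solar events with the NOAA low-precision geometry — solar
declination and the equation of time from a fractional-year expansion,
then the hour angle $\cos H = (\sin h_0 - \sin\varphi \sin\delta) /
(\cos\varphi \cos\delta)$ — at two altitude thresholds: $-0.833^\circ$
(apparent sunrise/sunset: refraction plus the solar radius) and
$-18^\circ$ (astronomical twilight). The implementation was checked
against an independent Meeus-style ephemeris; agreement is within ±2
minutes across seasons, which is immaterial at the temporal resolution of
camera-trap data. Dates where the sun never crosses a threshold (polar
day/night) are flagged explicitly; at the supported mid-latitudes they do
not occur.

Each event's clock time is transformed to *sun time*: the day interval
$[\text{sunrise}, \text{sunset})$ maps linearly onto $[06{:}00, 18{:}00)$
and the night interval (that evening's sunset to the next morning's
sunrise) onto the complementary half-cycle, making the transform a
continuous, strictly increasing circular bijection with exact anchors.
The diel cycle is partitioned into crepuscular (dawn twilight plus dusk
twilight), diurnal, and nocturnal periods.

Period *availability* $\hat\pi_i$ is the summed duration of period $i$
over all active station-dates divided by the total active time, with the
first and last survey days clipped to the deployment interval. Summing
over station-dates (rather than using one representative schedule) lets
stations surveyed in different seasons contribute their actual light
regimes; the availability vector always sums to 1.

## Circular activity densities and overlap

Detections are treated as a random sample from the species' continuous
diel activity distribution on the sun-time circle. The density is
estimated with a von Mises kernel,
$\hat f(\theta) = n^{-1} \sum_i \exp\{\kappa_h \cos(\theta - \theta_i)\} /
\{2\pi I_0(\kappa_h)\}$, with the plug-in kernel concentration

$$\kappa_h = \left[ \frac{3 n \hat\kappa^2 I_2(2\hat\kappa)}
{4 \sqrt{\pi} I_1(\hat\kappa)^2} \right]^{2/5} \big/ \; \mathrm{adjust},$$

where $\hat\kappa$ solves $A_1(\kappa) = \bar R$ (the ML von Mises
concentration, capped at 500 for degenerate samples; uniform samples fall
back to a small positive kernel concentration with a warning). The
smoothing multiplier `adjust` divides the plug-in concentration, so
values above 1 smooth more; the default is 1, the convention in diel
activity work. Densities are evaluated on a 128-point grid for plotting
and integration and can be evaluated at arbitrary angles; the trapezoid
integral over the cycle equals 1 to $10^{-6}$ for any realistic
concentration.

Temporal overlap between two species is the coefficient of overlap
$\hat\Delta = \int_0^{2\pi} \min\{\hat f(\theta), \hat g(\theta)\}
d\theta \in [0, 1]$. Two estimators are computed: $\hat\Delta_1$
integrates the minimum on the shared grid, and $\hat\Delta_4$ averages
bounded density ratios at the observed points,
$\tfrac12 [ n_1^{-1}\sum_i \min\{1, \hat g(x_i)/\hat f(x_i)\} +
n_2^{-1}\sum_j \min\{1, \hat f(y_j)/\hat g(y_j)\} ]$. Following the
standard recommendation, $\hat\Delta_1$ is selected automatically when the
smaller sample has fewer than 75 events and $\hat\Delta_4$ otherwise;
both are always reported, and the choice can be overridden. Densities are
floored at $10^{-12}$ inside ratios to guard against underflow.

Confidence intervals come from a *smoothed bootstrap*: each replicate
draws samples of the original sizes from the fitted densities (resample
the data, add von Mises kernel noise), refits both densities, and
recomputes $\hat\Delta$; the default interval is the percentile interval
at 95% (normal and basic intervals are available behind a flag, since no
single convention dominates the literature). One caveat is documented
deliberately: when the two input samples are identical, the point
estimate is exactly 1 while bootstrap replicates compare two *finite*
redraws and therefore concentrate below 1 — the percentile upper bound
then sits just below the point estimate (about 0.95 at $n = 100$). This
boundary bias of percentile intervals at $\hat\Delta = 1$ is logged as a
warning, not treated as an error.

## Diel time budgets

Whether a species is crepuscular, diurnal or nocturnal is asked as a
use-versus-availability question. With $n_i$ events in period $i$,
$N = \sum_i n_i$, use $o_i = n_i / N$ and availability $\hat\pi_i$, the
Manly selection ratio is $w_i = o_i / \hat\pi_i$: above 1 the period is
used more than its share of surveyed time. Random use across the three
periods is tested by $\chi^2 = \sum_i (n_i - N\hat\pi_i)^2 / (N\hat\pi_i)$
on 2 df, and per-period departures by a multinomial randomization test:
`n_reps` (default 10,000) multinomial draws of $N$ events under
$\hat\pi$, reporting for each period the upper-tail p-value when
$n_i > N\hat\pi_i$ ("more than expected") and the lower-tail otherwise,
with the add-one correction $(1 + \#\text{extreme})/(n_\text{reps} + 1)$
so p-values are never exactly 0. Because the reported p is one-sided in a
direction chosen by the data, a size-$\alpha$ decision should compare the
*doubled* p-value with $\alpha$; the type-I-error simulation in the test
suite does exactly that and confirms the nominal 5% size. Warm and winter
seasons are analysed separately, and a species-season cell enters the
output only with at least `min_n` events (default 25), mirroring the
practice of excluding winter rows for species that are dormant or barely
detected then. No multiplicity adjustment is applied across species.

## Two-species occupancy and the species interaction factor

Spatial co-occurrence is modelled on detection histories built by tiling
each deployment into `segment_days` occasions (default 15 days) from its
start; a trailing remnant is kept when it covers at least half a segment.
A species is detected in an occasion if any independent event falls in
it. By default only warm-season occasions from 2011–2015 are used — the
survey subset in which site closure is defensible (winter dormancy of one
focal species would violate it). Two occasion covariates are carried:
the scent-lure age bin (days since the most recent lure application,
evaluated at the occasion midpoint and binned 0–15 / 16–30 / 31–45 / >45)
and the camera trigger-speed class (fast ≤ 1 s vs slow). An occasion
whose deployment lure schedule begins only after its midpoint is treated
as the stalest bin.

The joint model assigns each site one of four latent states with
probabilities derived from the marginal occupancies and the species
interaction factor $\gamma = \psi_{AB} / (\psi_A \psi_B)$:
$\psi_{AB} = \gamma\psi_A\psi_B$ (both), $\psi_A - \gamma\psi_A\psi_B$
(A only), $\psi_B - \gamma\psi_A\psi_B$ (B only), and the complement
(neither). Conditional on the state, detections are independent Bernoulli
draws per occasion with probability $p$ for a species alone and $r$ where
both are present, on the logit scale with species-specific intercepts and
covariate effects shared across species (`Lr` contributes three
contrasts against the freshest bin, `Cam` one). A detected species
contributes zero likelihood to states where it is absent; missing
occasions contribute a factor of one. The likelihood is maximised by BFGS
from one data-informed start plus random restarts; $\gamma$ is optimised
through a logistic transform onto its feasibility interval
$[\max(0, \psi_A + \psi_B - 1), \min(\psi_A, \psi_B)] / (\psi_A\psi_B)$,
which keeps all four state probabilities in $[0, 1]$ by construction.
Standard errors come from the numerically differentiated observed
information, and the SIF's standard error by the delta method through its
transform.

The 16-model set crosses {γ free, γ = 1} × {p(S), p(S+Lr), p(S+Cam),
p(S+Lr+Cam)} × {r = p, r separate}. Models are ranked by
AIC = −2LL + 2K, where K counts this package's parameters: 2 occupancy
intercepts, +1 if γ is free, 2 + (number of contrasts) for p, and again
for r when separate — so the full model has K = 15. Published tables in
this literature sometimes count K differently (and not always
self-consistently), so −2LL and the SIF, not K, are the comparable
quantities. The SIF is summarised from the ΔAIC < 2 top set:
*avoidance*/*aggregation* when a single γ-free top model estimates γ
below/above 1, *independence* when every top model fixes γ = 1, and
*unclear* when the top set mixes hypotheses. Non-converged fits are
excluded from ranking with a warning.

Two properties anchor the implementation's correctness and are enforced
in the test suite: the likelihood equals an exhaustive latent-state
enumeration oracle to $10^{-10}$ on random small instances, and with
γ = 1 and shared detection parameters it factorises exactly into the
product of two single-species occupancy likelihoods.

## The synthetic-survey generator

`simulate_survey()` emulates the design of a multi-year baited grid
survey of a five-species mesocarnivore guild in mountain forest at about
33°N: 495 stations scattered around a configurable centroid, deployments
of 4–6 weeks (normal, mean 35 d, truncated to 21–56 d) with starts spread
across 2004–2015, scent lure applied at setup, and a fast/slow camera mix.
Latent occupancy for a focal pair is drawn from the four-state
distribution under a configurable γ (default: an avoidance pair at
γ = 0.6); other species occupy sites independently. Detection is
simulated *at the event level* — a Poisson process with a per-species
daily rate modulated by monthly multipliers — rather than as per-occasion
Bernoulli draws, so simulated data exercise the same filtering,
annotation and history-construction code paths as real data. The implied
per-occasion detection probability is $1 - \exp(-\lambda \cdot 15)$ for
rate $\lambda$, which is how configurations can target a specific $p$.
Default rates and occupancies were chosen once to land the per-species
event counts at the scale a survey of this effort actually yields (on the
order of 100–250 events per species over ~17,000–23,000 camera-days).

Each event receives a sun time from the species' diel archetype — a von
Mises mixture; built-ins cover nocturnal (means 22:00 and 04:00, κ = 3),
diurnal (09:00/15:00, κ = 4), crepuscular (05:30/18:30, κ = 10) and
arrhythmic (κ = 0.2) shapes, with an optional winter archetype switch to
emulate a seasonal activity shift — and is converted to clock time
through the station's solar schedule. Monthly multipliers of 0 emulate
winter dormancy (the default civet-like species has zero December–February
rates). Some events spawn duplicate photographs within the independence
gap so the event filter has real work. A master seed makes the output
byte-identical across runs; the 60-station `minshan_mini_config()` ships
as a YAML fixture for fast checks.

What the generator deliberately does *not* emulate: spatial
autocorrelation between stations, animal movement and home ranges,
detection heterogeneity beyond the two modelled covariates, and lure
decay affecting true (rather than modelled) detectability. Passing tests
therefore demonstrate statistical correctness of the estimators under the
stated model, not robustness to every field reality.

## Numerical choices and problem sizes

Bessel-function expressions use exponentially scaled `besselI`
throughout, so densities and the plug-in bandwidth stay finite up to the
κ = 500 cap. The κ̂ inversion brackets the monotone $A_1$ on
$[10^{-12}, \kappa_{\max}]$. Likelihood computation is vectorised in
log-space with a per-site log-sum-exp over the four states and state
probabilities floored at $10^{-300}$. Occupancy optimisation uses three
starts by default; ties between estimators or models break by list order
(the first model at ΔAIC = 0 is "the" best). The randomization and
bootstrap machinery derives per-cell child seeds deterministically from
the master seed, so adding a species pair does not shift another pair's
stream.

The test suite and acceptance script size their simulations to run on a
single CPU in minutes: the likelihood oracle uses 100 instances of up to
6 sites; parameter recovery uses 100 simulations of 500 sites × 6
occasions; the type-I simulation uses 2,000 datasets of 1,000
randomization draws; bootstrap intervals in examples use 500–2,000
replicates (the package default remains 10,000, the convention in the
literature, and is what an analysis of real data should use).

## Known limitations

Occupancy is modelled without site covariates (constant ψ per species) —
appropriate for guild-level co-occurrence screening, not for habitat
modelling. The two-species likelihood assumes detections of the two
species are conditionally independent within an occasion given the latent
state; a detection-level interaction would need an additional parameter
the supported model set does not include. Sun-time availability is
computed in clock time over active station-dates, which weights periods
by when cameras were actually deployed; surveys concentrated in one
season inherit that season's light regime. The solar geometry ignores
topographic horizons and lunar illumination. Winter analyses for
low-detection species are intentionally suppressed by the `min_n`
threshold rather than reported with unusable precision.
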