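---
title: "Models and methods behind pinnitrack"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind pinnitrack}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

pinnitrack analyses satellite-relay biologging data from seals carrying
GPS-Argos-CTD tags: positions, individual dives, 6-hour activity summaries,
haul-out events and water-column profiles. This vignette documents the
models the package implements, the choices made where a method description
leaves latitude, and what the synthetic data generator does and does not
emulate. It states no empirical result that the test suite does not itself
compute.

## Coordinate system

All geometry is planar, in kilometres, under an azimuthal equidistant
projection on a sphere (R = 6371 km) centred on the dataset. Distances from
the centre are exact under this projection and distortion is negligible at
fjord scale (tens of km). Latitude/longitude survive only in the raw
streams; `project_aeqd()` / `unproject_aeqd()` convert. Depths are
positive-down everywhere — dive depths and bathymetry share the sign
convention — and all timestamps are UTC.

## Track model (CTCRW)

`fit_ctcrw()` fits the continuous-time correlated random walk: velocity is
an Ornstein-Uhlenbeck process with autocorrelation parameter $\beta$ (1/h)
and scale $\sigma$ (km h$^{-1/2}$), position its integral, observed with
isotropic GPS error (36 m default). The exact discrete-time transition of
the integrated OU state is Kalman-filtered, so the likelihood is exact for
irregular fix times; x and y are independent coordinates sharing
parameters.

Haul-outs are handled with a *stopping* constraint: within a reported
haul-out interval the velocity state is pinned to zero and the position
does not diffuse. The original formulation estimates a continuous stopping
process from wet/dry data; here haul-out events are directly observed, so
hard constraints are simpler and make the contract testable (positions
inside an interval are exactly constant).

Numerical choices: optimisation on $(\log\beta, \log\sigma)$ with L-BFGS-B,
box $[10^{-4}, 10^3] \times [10^{-6}, 10^3]$, five seeded random restarts
around a moment-based centre (median apparent speed). Initial state: first
fix with variance equal to the measurement variance, velocity zero with the
stationary variance $\sigma^2/2\beta$. `predict_positions()` runs the
Rauch-Tung-Striebel smoother over the union of fix, requested and haul-out
boundary times; requested times must lie within 6 h of the fix record.
Prediction grids are hourly for home ranges and two-hourly for the
behavioural analysis.

## Home ranges (dynamic Brownian bridge)

`estimate_motion_variance()` estimates the Brownian motion variance
$\sigma^2_m$ (km²/h) in a sliding window of 35 locations with margin 11,
by maximum likelihood over the leave-one-out bridge likelihood of the odd
interior points. Within each window a single mean change in $\sigma^2_m$
is allowed (candidate breakpoints at least one margin from the ends);
constant and one-break models are compared by BIC. Locations covered by
several windows take the mean across windows.

One deliberate deviation from the textbook bridge likelihood: the focal
point's own location error is added to the bridge variance during
*estimation* (variance $T\alpha(1-\alpha)\sigma^2_m +
(1+\alpha^2+(1-\alpha)^2)\delta^2$). Without that term a stationary track
observed with error $\delta$ yields a spurious positive $\sigma^2_m$ of
order $\delta^2$; with it, the estimate collapses to zero, which is what a
motionless animal should produce. The UD *accumulation* in `compute_ud()`
uses the standard bridge variance
$T\alpha(1-\alpha)\sigma^2_m + ((1-\alpha)^2+\alpha^2)\delta^2$.

UDs are accumulated on a 500 m grid (location error 50 m) over the track
bounding box padded by three times the largest bridge sd, with ten bridge
integration steps per segment. Home-range areas use cumulative-mass cell
counting: cells ranked by density and accumulated to the 50%/95% level, so
areas are multiples of 0.25 km². This is deterministic and exactly
testable against the Gaussian closed form $\pi s^2 \chi^2_2(p)$ for a
stationary point; at 100 m cells the agreement is within 5% once the error
sd is a few cell widths. Monthly ranges require at least 20 distinct
transmission days in the month (inclusive at 20); motion variances are
estimated once on the full track and subset per month.

## Habitat covariates and summaries

Per location: exact point-to-segment distance to the nearest coastline and
tidal-glacier-front polyline, bilinear bathymetry, and ice concentration
from the field nearest in date. Ice categories are half-open above 10:
[0,10], (10,40], (40,90], (90,100], with a land-fast flag that dominates;
the source material prints overlapping bin labels without boundary rules,
so the half-open convention is this package's.

Monthly means use a nonparametric bootstrap (10,000 replicates via the
boot package, percentile intervals, type-6 quantiles, seeded). Seasonal
trends are OLS on a running day index (1 = first transmission day); the
transform policy is: log for strictly positive responses with skewness
greater than 1, identity otherwise — the source states only "transformed
as necessary". Cook's-distance and residual diagnostics are the analyst's
business; the package never auto-removes points.

The environmental-space UD is a product-Gaussian kernel density over
(distance to coast, distance to glacier, depth) on a 32³ grid spanning the
data range ± 1 bandwidth, with per-axis normal-reference bandwidths
($s_j (4/(5n))^{1/7}$, the d = 3 rule). "Top 25%" is read as the top
quartile of evaluated density *values* (cells at or above the 75th
percentile), not a 25% probability region; the figure-caption wording the
analysis mirrors supports the value reading, and the probability-mass
alternative would give systematically larger regions. A zero-variance axis
is collapsed with a warning rather than failing.

## Behavioural states and specialization

`fit_hmm()` is a 3-state hidden Markov model on two-hourly steps and
turning angles: gamma step lengths, von Mises angles, and transition
probabilities depending on the standardised proportions of time diving and
hauled out through a multinomial logit (diagonal reference). The forward
recursion and Viterbi decoding are compiled; the likelihood is maximised
by BFGS from seeded restarts initialised by quantile-split moments of the
step distribution. States get labels by rule: haul-out is the state with
the highest mean hauled-out covariate, foraging the shorter-stepped of the
rest. A forward-vs-exhaustive-enumeration identity at T = 8 and decoding
accuracy on data simulated from a known model guard the implementation.

Foraging areas: Viterbi-decoded foraging positions are clustered in
3-day intervals with DBSCAN (min_pts = 5). The epsilon is the sorted
k-nearest-neighbour mean distance (k = min_pts − 1) at its single mean
changepoint — Gaussian-cost, at-most-one-change, accepted when it beats
the no-change model by the penalty $2\log n$; when no change is accepted
the median kNN distance is used, with a message. min_pts, k and the
penalty are not stated in the source; these defaults are declared, not
inferred, and are config-exposed. The area for the interval is the member
of the largest cluster closest to that cluster's centroid.

The similarity index compares each unordered pair of a seal's foraging
areas with the *cross* differences between that seal's areas and all other
seals' areas: the index is the proportion of reference differences
strictly smaller than the pair's difference (ties excluded), so 0 marks a
specialist and 1 a generalist. The source wording is ambiguous about
whether pairs *among* other seals' areas join the reference set; both
variants are implemented (`reference = "within_others"`), cross is the
default because it keeps the index a per-seal quantity. The index is
invariant to shifting or positively rescaling the variable for all seals.

## Dives and water masses

A dive is benthic when its maximum depth is within 25 m of the charted
seafloor *or* exceeds the charted depth; the two clauses are jointly
equivalent to `max_depth >= bathy - 25`, and the single branch-free
inequality is what ships (the margin reflects charted-bathymetry error and
is config-exposed). Dive shape splits the profile at the 80%-of-maximum
depth threshold: bottom time is the linearly interpolated time at or below
threshold, descent ends at first entry, ascent starts at last exit;
brief mid-dive excursions above the threshold are counted as bottom time
(first-entry/last-exit convention). The three fractions always partition
the dive. Monthly dive variables feed a standardised PCA (`prcomp`), with
the sign convention that each component's largest-magnitude loading is
positive.

Water masses use the six-box T/S scheme for west-Svalbard waters,
evaluated in the order WCW, LW, GW, IntW, TransAW, AW (first match): WCW
T < −0.5; LW −0.5 ≤ T < 1; then for T ≥ 1 by salinity, GW S < 34, IntW
34 ≤ S < 34.65, and above 34.65 TransAW 1 ≤ T < 3 versus AW T ≥ 3. The
printed description of TransAW ("1 ≤ temp > 3") is read as 1 ≤ T < 3, the
only reading consistent with AW's T ≥ 3 and a clean partition (likewise
for the IntW and LW upper bounds). The partition is property-tested on
10⁶ random pairs and at ±10⁻⁹ around every threshold.

Dive T/S assignment is a three-way weighted average over the seal's own
CTD casts within 10 days: each cast is depth-interpolated to the target
(surface 1.5 m and maximum dive depth; a cast may be extended to a target
at most ζ below its deepest sample, carrying the gap into the weight), and
weighted by Gaussian kernels `exp(−Δt²/2τ²)·exp(−Δx²/2ρ²)·exp(−Δz²/2ζ²)`
with defaults τ = 48 h, ρ = 25 km, ζ = 10 m over the K = 10 best casts.
The source specifies only that weight decreases with the three gaps; the
kernel form and scales are this package's declared convention, all
config-exposed, and shrinking them recovers nearest-cast assignment.

## The synthetic generator

`simulate_population()` provides the study conditions every downstream
stage is tested against. Defaults: 4 seals (half specialists with tight
habitat-preference spreads and distinct glacier-distance targets, half
generalists with wide spreads), 60 days from 19 July, 15 GPS fixes, 18
dives and 2 CTD casts per seal per day — the reported daily observation
rates for the tagged animals, with the tracking season's start date. Test
problem sizes (60-day tracks, T = 2000 HMM sequences, 20 recovery seeds,
5 population seeds) are the package's standing choices and are what the
acceptance suite runs.

The movement process is a 3-state semi-Markov switch (travelling,
foraging, hauling out) on an hourly grid: exponential dwell times (means
10/30/5 h), gamma steps and von Mises headings while travelling,
mean-reversion to a bout target while foraging, frozen position while
hauled out. Bout targets are drawn from grid cells weighted by a Gaussian
kernel around the seal's preference centre in environmental space
(distance to glacier, distance to coast, depth), so a small spread makes a
repeatable specialist. Dwells are semi-Markov rather than per-step Markov
deliberately: the HMM fitted downstream is then misspecified-but-close,
as with real animals. Dives tie to local bathymetry (benthic dives end
within 20 m of the seabed; pelagic dives are uniform mid-water); CTD casts
sample a two-layer seasonal water column whose layer properties traverse
all six water-mass boxes over a year; GPS error is 36 m. All draws flow
from R's Mersenne-Twister via one seed per seal derived from the master
seed, so output is fully reproducible.

What the generator does **not** emulate: Argos-class location error,
tag duty cycling beyond Poisson thinning, tides and currents, real
Svalbard geography, prey fields, or autocorrelated measurement error.
Passing tests therefore demonstrate the correctness and calibration of the
estimators under known, well-behaved conditions — not field performance on
deposited animal data, whose population-level tables are out of scope
here.

## Known limitations

- The CTCRW assumes one $(\beta, \sigma)$ per seal; behaviourally
  switching variants are out of scope.
- Border points in DBSCAN join the first cluster that reaches them, the
  classic order dependence; the tests treat any valid core assignment as
  correct.
- The changepoint penalty ($2\log n$) is a convention; sorted kNN
  distances are not i.i.d. Gaussian, so the rule is a heuristic, as in
  the tooling it mirrors.
- Percentile bootstrap intervals undercover slightly for very skewed
  variables at small n; the calibration test uses normal data at n = 200.
- `assign_ts()` weights are a declared convention, not a reconstruction
  of the original (unstated) weighting.
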