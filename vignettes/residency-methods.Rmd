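---
title: "Residency and movement analysis for acoustic telemetry arrays: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Residency and movement analysis for acoustic telemetry arrays: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

sharktrace analyses detection logs from fixed arrays of acoustic receivers
(VR2W-style) monitoring coded tags on marine animals — the motivating system
is scalloped hammerhead sharks aggregating at Eastern Tropical Pacific
islands. This vignette documents the models and procedures, the conventions
and tunable parameters, the synthetic data generator the test suite relies
on, and the numerical choices made where the design was genuinely open.

## The observation process

A tagged animal carries a transmitter that pings with a pseudorandom delay
drawn uniformly between 60 and 90 s (collision avoidance). A receiver
records (tag, timestamp) whenever the animal is in range; range tests at
these sites show reliable detection inside ~150 m, a steep fall-off beyond,
and no detections past ~300 m. Receivers are deployed and recovered in
windows, so the data carry structural gaps. Detections are therefore an
intermittent, range-thinned, downtime-censored trace of presence — every
method below is designed against that process.

All timestamps are stored in UTC. Behavioural quantities (days present,
diel timing) are computed in local time via a fixed `utc_offset_hours`
(default −6; no daylight saving at these latitudes). All intervals —
deployment windows, events, days — are half-open `[start, end)`, which
makes adjacency unambiguous. Exact duplicate records are collapsed, not
errored, because receiver downloads can overlap. Sorting is total:
timestamp ties break by station, then input order, so every downstream
result is deterministic.

## Residence events

`segment_events()` groups each tag's stream into *residence events* at
single receivers using three thresholds:

* `min_pings = 2` — detections at a receiver required before an event is
  recorded (singletons are likely noise and are rare in practice);
* `timeout_s = 900` — the maximum inter-ping gap within an event;
* `other_station_pings = 2` — detections at a single other receiver that
  terminate an open event (the animal has demonstrably moved).

A sweep maintains at most one open event. An event at station S opens when
`min_pings` detections at S accumulate with same-station gaps ≤ the
timeout; it extends with further S detections inside the timeout; it closes
on timeout, on accumulation of `other_station_pings` detections at one
other receiver (which then seed the candidate event there), or at stream
end. Start and end are the first and last member detections, so duration is
a lower bound on the true bout.

Two readings of the rule were open. First, whether the terminating
detections at the other receiver must themselves satisfy the gap rule: we
require it, because those detections seed a candidate event under the same
rule. Second, whether termination pools detections across other receivers:
we require a *single* other receiver ("detected twice or more at a
different receiver" — singular). When a detection arrives beyond
`last + timeout`, timeout closure takes precedence over other-station
closure, since the gap was exceeded before the detection arrived. The test
suite checks the sweep against an independently coded brute-force
implementation on fuzzed streams.

`classify_visits()` flags events shorter than `transit_min = 15` minutes as
*transits*: at a cruising speed of ~0.5 m/s an animal needs about 15 min to
cross a receiver's detection range, so shorter strings indicate passage
rather than residence. The threshold is strict (`duration < 15 min`); an
event of exactly 15 minutes is a visit. The boundary is tested explicitly.

## Residency index

For each tag, `track_summaries()` computes the monitoring duration — the
count of calendar days from tagging through the last detection, inclusive
of both — and the residency index

RI = (# distinct local days with ≥ 1 detection at the island) / (monitoring duration),

so RI = 1 means detected every day from tagging to last detection. The
inclusive convention makes a shark tagged and detected only on one day have
RI = 1/1, consistent with monitoring durations being reported from 2 days
upward when tagging and last detection differ by one day. Days are local
days; both conventions are configurable. RI is invariant to detection
multiplicity within a day. Because an array never covers a whole island, RI
is conservative: absence of detections is not absence from the island.

`summarize_ri()` reports the cohort mean ± sample (n−1) standard deviation,
optionally restricted to tags monitored at least `min_monitoring_days`
(long tracks dilute the tagging-day inflation), together with the Pearson
correlation between monitoring duration and RI.

## Tagging-bias correction

Animals are tagged where they happen to aggregate, so the first stretch of
every track over-represents the tagging site. `correct_tagging_bias()`
starts the analysed track at the earlier of

(a) the start of the first visit at any station other than the tagging
    station, or
(b) the start of the first tagging-station visit following an absence of at
    least `absence_h = 24` hours from that station,

dropping all earlier visits; if neither rule ever fires the whole track is
discarded (`none_applicable`). The returned object carries
`analysis_start` and the rule applied as attributes, and re-applying the
correction to a corrected track is the identity *by recognising those
attributes*: a literal re-application of rule (b) would look for a 24 h gap
inside the retained window and move the start later, because the gap that
triggered the correction lies before the first retained visit. Marking the
output was the cleanest way to make the operation idempotent without
changing its definition on raw tracks.

## Site-preference mixed model

Visit durations are modelled on the natural-log hour scale:

log(duration_h) = site effect + animal intercept + noise,

with the animal intercept N(0, σ²_g) and noise N(0, σ²_r). The log
transform matches the right-skewed, multiplicative character of dwell
times (and is the scale on which the synthetic generator draws them); the
response is configurable (`identity` hours as the alternative). The
reference site is the alphabetically first — Alcyone in the Cocos array —
so the intercept is the Alcyone mean log-duration. All residence events of
the corrected tracks enter by default; excluding transits is a flag.

`fit_lmm()` is a self-contained random-intercept fit: for a given variance
ratio λ = σ²_g/σ²_r the marginal covariance is block diagonal with
V_i = I + λJ, so V_i⁻¹ and log|V_i| have closed forms, the GLS coefficients
and residual variance are profiled analytically, and the (restricted)
log-likelihood is maximised by a one-dimensional bounded search over λ ≥ 0
(interior search on log λ over e^±12, explicit comparison with the λ = 0
boundary, which is preferred on ties so unidentifiable designs collapse to
OLS). REML is the default for reported variance components;
likelihood-ratio tests of the site effect use ML fits of both models, as
REML likelihoods are not comparable across fixed-effect structures. The
test suite cross-checks coefficients, variance components, standard errors
and log-likelihoods against lme4, and against a direct numerical
maximisation of the exact likelihood.

Degrees of freedom for t- and contrast tests use the Satterthwaite
approximation: df = 2v²/(g'Ag) with v the contrast variance, g its numeric
gradient in (σ²_g, σ²_r) and A the inverse observed information of the
(restricted) likelihood, computed by central differences. If the
information matrix is numerically singular the code falls back to the
normal approximation and flags it with `NA` df. All 15 pairwise site
contrasts are Wald tests with a Holm adjustment — conservative and
assumption-free, chosen because the family is small and the cost of a
false "sites differ" claim is high.

## Diel statistics

`hourly_counts()` bins detections (or distinct tags, `by = "sharks"`) into
consecutive local hours. The periodogram of the mean-removed series,
I(f_k) = |Σ x_t e^(−2πif_k t)|²/n at the Fourier frequencies, locates the
dominant period as the reciprocal of the peak frequency; a diel presence
rhythm appears as a sharp 24 h peak. The tags-per-hour series is the
default for the periodogram, because one animal parked beside a receiver
contributes thousands of pings and would dominate a detection-count
spectrum; circular statistics use the detections themselves, each mapped to
an angle (hour + minute/60 + second/3600) × 15°, i.e. minute resolution
rather than bin centres — binning is needed only by the FFT.

`circular_stats()` reports the mean resultant length r, the mean angle,
the Rayleigh test (Z = nr², with the standard large-sample p
approximation) and Rao's spacing test U = ½Σ|T_i − 360/n| over the sorted
circular gaps. Rao's p-value is computed by seeded Monte-Carlo under
circular uniformity rather than from printed critical-value tables: tables
are quantised, while the Monte-Carlo null is exact up to sampling error and
itself testable (the suite checks the null p-values are uniform). A window
of presence symmetric about noon (06–18 h) centres the circular mean near
12:00, which the generator tests exploit.

## Movement networks

`movement_matrix()` counts, per tag, every consecutive pair of residence
events at distinct stations as one directed movement. Elapsed time between
the events is ignored by default (an optional `max_gap_h` suppresses
transitions across long absences); same-station pairs are ignored unless
self-loops are requested. Node degree is the number of distinct partner
stations; strength is total movements through the node. Transits count as
events by default. Networks can be aggregated to island-level nodes.
Exports are an edge-list CSV and GraphML (via igraph); community detection
and layout are out of scope.

## Inter-island transfers

`detect_transfers()` scans each tag's island-labelled detection sequence
and emits one transfer per change of island, with departure the last
detection at the origin and arrival the first at the destination — the
only travel time computable from detections, and a lower bound on the true
at-sea time (a "transfer" spanning a long detection gap is a gap-inflated
bound and is reported as-is). Straight-line speed is the configured
great-circle distance divided by that time; the published distances
(Cocos–Galapagos 710 km, Cocos–Malpelo 627 km) take precedence for
reproducibility, with a haversine fallback from station coordinates for
unlisted pairs. Route summaries use the midpoint convention for the median
of an even trip count, and the maximum speed is attained on the fastest
trip by construction.

## The synthetic generator

`simulate_detections()` emulates the observation process so every stage is
testable without field data. Per shark and day: presence is
Bernoulli(`p_res`), optionally modulated by a length-12 monthly multiplier
(a March–May trough mimics the seasonal absences of this system); on
present days the shark chains visits through the island's stations
(uniform over the other stations by default, or a supplied Markov matrix),
with dwell times lognormal — site mean + shark intercept + noise on the
log-hour scale, the same model the LMM fits — clipped to the 06:00–18:00
presence window; a small `night_leak` adds occasional nocturnal visits.
Within a visit, pings fire at Uniform(60, 90) s intervals; each is detected
with probability 1 inside 150 m, decaying linearly to 0 at 300 m, for a
per-visit distance drawn Uniform(0, `dist_range_m`) — the simplest draw
consistent with a steep fall-off past 150 m, since the range test informs
only the two radii. Detections during receiver downtime are discarded.
Rare migrations relocate the shark to another island after a lognormal
travel time. Ground truth (presence days, visits, transitions, migrations)
is returned alongside.

Defaults mirror the study conditions: 17 sharks (the site-analysis
cohort), a 790-day window, tagging sites weighted 14/2/1 to
Alcyone/Roca Sucia/Manuelita, `p_res = 0.52` (the observed overall
residency proportion, read as a daily presence probability), dwell-model
parameters from the fitted site model (Alcyone mean 1.228 log-hours, site
offsets −1.460 to −0.469, σ²_g = 0.2912, σ²_r = 1.0636), and the 60–90 s /
150–300 m observation constants. Each shark consumes its own seeded
substream, so enlarging a cohort never perturbs existing trajectories and
every dataset is byte-reproducible from `rng_seed`.

What the generator does *not* emulate — and hence what passing tests do
not show about field data: continuous-space movement (distance to the
receiver is per-visit, not a trajectory), acoustic propagation physics,
tides and currents, receiver clock drift over 6–9-month download
intervals, tag shedding and battery failure, and density-dependent ping
collisions. One consequence worth knowing: because true dwells are clipped
to the diel window and events are split at 900 s detection gaps, the
*end-to-end* site-effect estimates are attenuated relative to the dwell
model's parameters; parameter-recovery claims are therefore tested at the
records level (the dwell submodel), while the end-to-end path is tested
for residency, visit and transition recovery.

## Numerical choices and problem sizes

Degenerate inputs: empty streams segment to empty results; unsorted
streams are an error, not silently sorted; constant hourly series return a
no-peak sentinel; r = 0 leaves the circular mean undefined rather than
reporting an arbitrary angle; an empty cohort summary is an explicit
sentinel row. Likelihood convergence uses a 1e−9 tolerance on the
1-D search with closed-form profiles, so successive log-likelihoods agree
far below 1e−10 at the optimum.

The test suite runs simulation checks at deliberately modest sizes chosen
to make sampling error negligible relative to the tolerances: 1,000 fuzzed
streams for the segmentation oracle, 1,000 null replicates for
likelihood-ratio calibration, 200 replicates of the 17-shark × 6-site ×
~120-visit design for coverage, cohorts of 8–25 simulated sharks over
10–120-day windows elsewhere. The acceptance script re-runs the pipeline
end to end on a 17-shark, 120-day synthetic dataset.

## Known limitations

* RI conflates absence from the island with absence from the array.
* Event durations and transfer times are lower bounds by construction.
* The mixed model assumes independent visits within shark; serial
  dependence of consecutive visits is not modelled (no random slopes, no
  temporal autocorrelation).
* Rayleigh and Rao tests treat detections as independent angular
  observations; autocorrelated pings inflate their statistics, which is
  why effect sizes (r, the spectral peak) matter more than p-values at
  telemetry sample sizes.
* No clock-drift correction and no positional estimation are attempted.
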