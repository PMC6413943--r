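# sharktrace

Residency and movement analysis for passive acoustic telemetry arrays.

Fixed arrays of acoustic receivers record coded pings from tagged marine
animals — here, scalloped hammerhead sharks (*Sphyrna lewini*) aggregating
at oceanic islands in the Eastern Tropical Pacific. How strongly such
animals are tied to an island, which sites within it they prefer, when
during the day they are present, and how often they move between islands
all determine whether a marine protected area drawn around the island
actually protects them. sharktrace turns raw detection logs (tag,
receiver, timestamp) into those answers, end to end, and ships a seeded
synthetic-data generator that emulates the whole observation process so
every stage is testable without field data.

## What it computes

* **Residence events** — each tag's detection stream is segmented into
  bouts at single receivers: an event needs ≥ 2 pings with gaps ≤ 900 s,
  and terminates on timeout, on ≥ 2 pings at another receiver, or at
  stream end. Events shorter than 15 min (the time to cross a receiver's
  detection range at ~0.5 m s⁻¹) are classed as transits.
* **Residency index** — RI = (days detected at the island) / (days from
  tagging through last detection, inclusive), in (0, 1]; cohort
  mean ± SD, daily presence matrices, and a tagging-bias correction that
  starts each track when the animal first leaves its tagging site (or
  returns after ≥ 24 h absence).
* **Site preference** — a random-intercept linear mixed model of
  log visit duration, `log(dur_h) = site + (1 | shark) + ε`, fitted by a
  profiled (restricted) likelihood written for this package and
  cross-checked against lme4; ML likelihood-ratio test of the site
  effect; all 15 pairwise site contrasts with Satterthwaite df and Holm
  adjustment.
* **Diel pattern** — hourly binning, an FFT periodogram of tags present
  per hour (a diel rhythm shows as a 24 h peak), and circular statistics
  on detection times: mean resultant length r, Rayleigh Z = nr², and
  Rao's spacing test with a seeded Monte-Carlo p-value.
* **Movement networks** — directed counts of consecutive residence
  events at distinct receivers; node degree and strength; edge-list CSV
  and GraphML export.
* **Inter-island transfers** — island changes in pooled detection
  sequences, travel times (lower bounds) and straight-line speeds from
  great-circle distances (Cocos–Galapagos 710 km, Cocos–Malpelo 627 km).

## Worked example

Simulate a cohort at the default study conditions (scaled to 8 sharks and
90 days) and run the full pipeline:

```r
library(sharktrace)

cfg <- sim_config(n_sharks = 8, study_days = 90, rng_seed = 42)
sim <- simulate_detections(cfg)
res <- run_pipeline(sim$detections, sim$stations, sim$tags,
                    rao_reps = 2000, rao_seed = 43)

res$ri_summary
#> # A tibble: 1 × 7
#>       n mean_ri  sd_ri single_tag cor_duration_ri cor_df cor_p
#>   <int>   <dbl>  <dbl> <lgl>                <dbl>  <int> <dbl>
#> 1     8   0.539 0.0592 FALSE                0.181      6 0.669

res$site_lrt
#> # A tibble: 1 × 3
#>    chi2    df  p.value
#>   <dbl> <int>    <dbl>
#> 1  211.     5 1.10e-43

res$diel$summary
#> # A tibble: 1 × 9
#>   period_h      n mean_angle mean_hour     r rayleigh_Z rayleigh_p rao_U   rao_p
#>      <dbl>  <int>      <dbl>     <dbl> <dbl>      <dbl>      <dbl> <dbl>   <dbl>
#> 1     24.1 122840       185.      12.3 0.660     53480.          0  206. 5.00e-4
```

Reading the output: the cohort's mean residency index is 0.54 — close to
the generator's daily presence probability of 0.52, as it should be under
full detection. The likelihood-ratio χ²(5) = 211 says visit durations
differ strongly between sites (the generator gives Alcyone the longest
dwells). The diel summary finds the injected 24 h rhythm (dominant period
24.1 h), detections centred at 12.3 h local time with concentration
r = 0.66, and both uniformity tests reject. `tidy(res$site_fit)` and
`glance(res$site_fit)` expose the mixed model in broom layout;
`autoplot(res$site_fit)`, `plot_presence()`, `plot_diel()` and
`plot_periodogram()` draw the standard figures.

## Package layout

Analysis functions take a data frame first and return tibbles, so stages
chain with the pipe; `vignettes/residency-methods.Rmd` documents the
models, conventions and numerical choices in full.
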