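# cpfmove

Movement metrics for central-place foragers from GPS tracks.

`cpfmove` is an R package for quantifying how people (or other
central-place foragers) use the landscape around a home base. It takes
per-person-day GPS tracks, a camp boundary polygon and a person-metadata
table, cleans and resamples the trajectories, and computes the standard
movement-ecology measures used to compare landscape use between groups —
in the motivating application, between male and female hunter-gatherers:

- **Daily distance** — summed planar segment lengths of the whole
  person-day (km).
- **Land visitation** — the track is overlaid on a raster of square
  cells (default 10 m × 10 m, area *A* = 100 m²); with *N<sub>i,i</sub>*
  the unique cells intersected on day *i* and *N<sub>1,i</sub>* the
  unique cells over days 1…*i*, daily land visited is
  *N<sub>i,i</sub>* × *A* and cumulative land explored is
  *N<sub>1,i</sub>* × *A*. Cell sets are computed by supercover
  rasterisation (every cell the segment geometrically intersects).
- **Geographic segregation** — union/intersection of male- and
  female-visited cell sets per camp: total, per-gender and both-gender
  areas (km²), the male:female ratio, and overlap as a percentage of
  the total.
- **Home ranges** — 95% minimum convex polygons (centroid-exclusion
  convention) by camp and gender.
- **Sinuosity** — for each day's principal out-of-camp bout (apex at
  least 500 m from camp, split at the point farthest from the camp
  centroid), outbound and inbound sinuosity = path length ÷
  straight-line chord (≥ 1); plus a *geographically weighted* variant
  that scores each raster cell by the mean sinuosity of the passes
  through it and counts cells above the population mean ("high") and
  99th percentile ("very high").
- **Sociality** — a stratified sample of ≤ 100 out-of-camp fixes per
  person-day, each annotated with the nearest-neighbour distance among
  campmates with a fix within ±60 s and a within-5 m indicator, with
  empirical probability-by-distance curves.
- **Summary statistics** — camp-by-gender tables with an unweighted
  cross-camp mean row, the exact Wilcoxon signed-rank test (enumeration,
  for camp-level *n* ≤ 25), and Cohen's *d* with bootstrap CIs.

Because field GPS data of this kind are typically access-restricted, the
package includes a synthetic central-place-forager generator
(`simulate_camp()`): camp-anchored out-and-back forays built from a
biased von Mises random walk whose concentration parameter κ controls
sinuosity (expected sinuosity ≈ 1/(I₁(κ)/I₀(κ))), with gendered day
ranges, party cohesion, autocorrelated GPS noise, errant fixes and
vehicle contamination. Every downstream stage is tested against this
generator's recorded ground truth.

## Worked example

```r
library(cpfmove)

sim <- simulate_camp(sim_config(seed = 42))          # 10 men + 10 women, 5 days
an  <- forage_analysis(sim$tracks, sim$camp, sim$persons, seed = 42)
summary(an)
```

```
Per-gender movement summary (100 person-days):
  gender n_person_days mean_daily_km mean_daily_m2 mean_outbound mean_inbound
1 female            50          8.49         88722          1.18         1.18
2   male            50         14.28        131084          1.69         1.69
  median_nn_m p_within_5m mcp_km2
1        2.34       0.877    29.8
2     1024.15       0.000    60.0
<cpf_segregation> camp simcamp: total 7.1 km2, male 5.9, female 1.6 (ratio 3.7), both 0.4 km2 (6.2% of total)
```

Men (simulated at a 14 km mean day range, low heading concentration,
solitary) walk farther, visit more land, and travel more sinuous routes;
women (8 km, high concentration, parties of four spaced ~2 m) stay
close to a nearest neighbour (median 2.3 m, 88% of sampled fixes within
5 m) while men's nearest tracked neighbour is typically a kilometre
away. The male:female ratio of visited land (3.7 here) and the MCP
ratio agree in direction.

Aggregating the bundled published camp-level land table reproduces its
mean row:

```r
tab <- read.csv(system.file("extdata", "hadza_camp_land.csv", package = "cpfmove"))
summary_mean_row(tab)      # total 578.0, male 515.1, female 141.6, ratio 3.9, both 78.7, overlap 13.6%
wilcoxon_exact(tab$male_km2, tab$female_km2)  # V = 78, exact p = 0.00049
```

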