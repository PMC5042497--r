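# nichekit

Tools for measuring how sympatric carnivores partition their niche in
space and time, from radio-telemetry and camera-trap data.  The package
implements the standard analysis chain for mid-sized carnivore communities
(ocelots, crab-eating foxes, coatis, raccoons and the like):

* **Home ranges** — fixed bivariate Gaussian kernel utilization
  distributions (UD) with per-axis Sheather–Jones direct plug-in
  bandwidths; 95% / 50% highest-density isopleths; minimum convex polygons
  and MCP accumulation curves; median/min/max summaries per species.
* **Space sharing** — PHR, the probability of animal *j* being inside
  animal *i*'s home range, `∫_{H_i} f_j` (asymmetric), and UDOI, the
  utilization distribution overlap index
  `A_ij · ∫_{H_i ∩ H_j} f_i f_j` (0 = disjoint, 1 = two coincident uniform
  UDs, > 1 for concentrated joint use).
* **Habitat selection** — compositional analysis at second order (home
  range vs study area) and third order (locations vs home range): log-ratio
  differences `d_i = ln(U_i/U_r) − ln(V_i/V_r)` per individual, Wilks'
  `Λ = |E|/|T|` with `χ² = −N ln Λ` on D−1 df, an exact sign-flip
  randomization alternative, and pairwise paired-t ranking matrices.
* **Activity** — clock times rescaled to sun time (sunrise ↦ 06:00,
  sunset ↦ 18:00, NOAA solar equations), von Mises circular kernel
  densities with likelihood-cross-validated concentration, 95%/50%
  activity isopleths, and intersection-over-union overlap percentages.
* **Simulation** — seeded generators for patchy landscapes,
  habitat-weighted telemetry and activity-thinned camera records with
  analytic ground truth (`true_ellipse_area()`,
  `true_activity_density()`), so every estimator has a parameter-recovery
  test.

See `vignettes/niche-partitioning.Rmd` for the models, assumptions and
numerical choices.

## Worked example

```r
library(nichekit)

# two simulated foxes with a shared 600 m-scale range, savanna-weighted
cfg <- sim_config(seed = 42, individuals = list(
  list(species = "fox", animal_id = "F1", centre = c(5000, 5000),
       sigma = diag(c(600^2, 600^2)), weights = c(1, 2, 1, 1, 1),
       n_locations = 60),
  list(species = "fox", animal_id = "F2", centre = c(5600, 5200),
       sigma = diag(c(600^2, 600^2)), weights = c(1, 2, 1, 1, 1),
       n_locations = 60)))
map  <- generate_landscape(cfg)
f1   <- generate_individual(cfg$individuals[[1]], map, seed = 43)
ud1  <- estimate_ud(f1)           # plug-in bandwidth, 50 m grid
hr1  <- isopleth(ud1, 0.95)
hr1
#> <home_range> F1: 95% isopleth, 6.3 km2 (2521 cells)
attr(f1, "truth")$ellipse95_km2   # analytic truth for this animal
#> [1] 6.776187
100 * phr(ud1, hr1)               # a UD over its own 95% range
#> [1] 95.00046
```

The kernel area (6.3 km²) sits a little below the analytic 95% ellipse
(6.8 km²) for this n = 60 draw; at n = 500 the estimate lands within ±15%
of truth in ≥ 90% of replicates (tested).  The self-PHR of 95.0 is the
diagonal any PHR matrix must reproduce.

Published summary tables from a Pantanal mesocarnivore study ship with the
package as worked-example inputs:

```r
tab <- pantanal_homeranges()
summarize_home_ranges(tab$ud_km2, tab$species)
#>             species n median_km2 min_km2 max_km2
#> 1 brown-nosed coati 7        1.5     0.6     3.6
#> 2   crab-eating fox 7        1.4     0.9     2.3
#> 3            ocelot 6        7.5     3.8    16.1
```

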