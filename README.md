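# reefhr

Individual-based simulation of coral reef fish home-range movements, a
simulated passive acoustic receiver array, and the home-range estimators and
diagnostics used on acoustic telemetry data.

## The problem

No-take marine reserves protect a fish only while it is inside them, so
reserve design needs honest estimates of home-range size. Passive acoustic
arrays — the workhorse of reef fish tracking — only observe fish within
detection range of a fixed grid of receivers, which truncates movements
beyond the array, piles detections onto a handful of sites, and excludes the
most mobile individuals from "valid" estimates. `reefhr` is for movement
ecologists who want to measure those biases instead of arguing about them:
it simulates fish whose true paths are known, simulates what an array would
have detected of those paths, and runs the standard estimators on both.

## The model

Fish movement is a three-step kernel per 5-minute interval:

- **move probability** ψ — a discernible move occurs with probability ψ;
- **move distance** d ~ Exponential(λ), clamped at 6000 m per move and
  suppressed (no move) below 200 m, the grid/positioning resolution;
- **move direction** θ ~ von Mises(θ̄, κ), where θ̄ is the bearing from the
  current position to the fish's fixed home-range center:

  f(θ | θ̄) = exp{κ cos(θ − θ̄)} / (2π I₀(κ)).

Larger κ means stronger affinity to the home-range center; κ = 0 is an
unbiased random walk. Positions snap to 200 m grid cells. Packaged
parameter sets: red grouper (ψ = 0.0080, λ = 561 m, κ = 3.67), black
grouper (0.0056, 456, 1.19), mutton snapper (0.0576, 608, 3.20).

Around the movement kernel the package provides:

- a synthetic staggered receiver grid, a logistic detection-probability
  model (expected detections = interval/ping-rate × p(distance)), and
  convex-hull-based core/peripheral receiver classification;
- a two-pass inverse-probability weighted-centroid positioning estimator
  on 5-minute detection batches;
- home-range estimators: 100% MCP (convex hull, with "Linear" degeneracy
  flagging) and Gaussian-kernel 50/90/95% volume contours on a 20 m grid
  with a full 2×2 bandwidth matrix selected by smoothed cross-validation
  (binned, FFT-accelerated, with explicit failure detection);
- model fitting from position-fix series (`fit_movement()`, a classed fit
  with `print`/`summary`/`coef`/`simulate` methods), bootstrap
  sensitivity procedures, cumulative-area asymptote diagnostics, cohort
  experiments comparing true-path ("Sim-Actual") and detection-derived
  ("Sim-Detect") home ranges, and filter analyses of a packaged per-fish
  tracking table (44 red grouper, 2 black grouper, 2 mutton snapper).

## Worked example

```r
library(reefhr)

p <- species_params("red_grouper")
p
#> Movement parameters (red_grouper)
#>   psi    = 0.0080  (move probability per 300-s interval)
#>   lambda = 561.0 m  (mean move distance)
#>   kappa  = 3.67  (center-bias concentration)
#>   moves clamped at 6000 m, suppressed below 200 m

tr <- simulate_tracks(data.frame(fish_id = "rg1", home_x = 100, home_y = 100),
                      p, duration = 180 * 86400, seed = 42)$rg1

fit_movement(tr, species = "red_grouper")
#> Three-step movement model fit (red_grouper)
#>   284 moves over 51839 intervals
#>   psi    = 0.0055
#>   lambda = 596.1 m (SE 35.4), left-truncated at 200 m
#>   kappa  = 3.81 (SE 0.32)

mcp_area(tr)
#> MCP home range: 9.780 km2 (n = 119)

kd_homerange(tr, levels = 95)[["95"]]
#> 95% KD home range: 2.415 km2 (n = 51840, cell 20 m)
#>   bandwidth: h_xx 1209, h_yy 1748, h_xy -161 m2
```

The fitted ψ of 0.0055 is the *realised* discernible-move rate
ψ·e^(−200/λ) ≈ 0.0056 — sub-200 m draws are suppressed — and λ is
recovered within its standard error. The 100% MCP (9.8 km²) dwarfs the 95%
KD area (2.4 km²): with exponential step lengths the hull is dominated by a
few long excursions while the KD tracks the bulk of the occupation
distribution. That gap is a property of heavy-tailed movement, and it is
why detection-derived MCPs (which cannot see excursions beyond the array)
underestimate true ranges most for fish centered at peripheral receivers.

Filtering the packaged per-fish table under the most conservative criteria:

```r
rg <- subset(load_table3(), species == "RG")
res <- apply_filters(rg, filter_criteria(min_days = 60, min_detections = 1000,
                                         asymptote_in = "Yes",
                                         peripheral_in = "Low"))
sprintf("N = %d fish pass; mean MCP = %.2f km2 (SE %.2f)", res$n,
        res$mcp$mean, res$mcp$se)
#> "N = 12 fish pass; mean MCP = 2.46 km2 (SE 0.76)"
```

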