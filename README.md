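# treelinetopo

Tools for explaining local-scale variability in alpine treeline
elevation from terrain and hourly mountain meteorology.

Treelines are set globally by growing-season temperature, but locally
they sit anywhere from 0 to ~500 m below the climatic limit. This
package is for landscape ecologists and topoclimate researchers who
want to quantify why. It computes, per treeline point:

* a **response**, the elevation deviation
  `d_i = max_j(elev_j) − elev_i` from the site-level maximum treeline
  elevation (m, ≥ 0, one zero per study area);
* **landform metrics** from DEMs — Horn slope (%) and
  Zevenbergen–Thorne general curvature (1/100 m, positive = convex)
  on 3 × 3 windows, plus a mountain-mass index (km² above 1,200 m);
* **topoclimatic indices** from hourly temperature `T`, wind `WS`,
  humidity `RH`, shortwave `SolRad` and net radiation `NetRad`, for
  January and July:

  | index | definition |
  |---|---|
  | photoinhibition | `Σ_day (T_max − T)·SolRad / N_day` |
  | summer desiccation | `Σ_day T·WS·(100 − RH) / N_day` |
  | winter desiccation | `Σ (T_max − T)·WS·(100 − RH) / N_total` |
  | frost | `Σ_night (T_max − T)·(WS_max − WS)·(−NetRad) / N_night` |
  | insolation | `Σ_day SolRad` |

  where `T_max`, `WS_max` are site-level maxima that reverse-scale the
  hourly values (cold/calm hours weigh most);
* an **explanatory chain**: correlation-matrix PCA of twenty monthly
  meteorological summaries, random-forest %IncMSE variable importance
  with quantile-grid partial dependence over seventeen explanatory
  factors, and a conditional inference tree whose every split must
  pass a Monte-Carlo permutation test (|Pearson r| statistic,
  Bonferroni-adjusted, α = 0.05) — implemented here from its
  definition.

Seeded synthetic generators (terrain, hourly meteorology, treeline
points with a known deviation-generating process, regional covariates)
make the whole chain testable end to end with known truth.

## Worked example

```r
library(treelinetopo)
out <- file.path(tempdir(), "demo")
cfg <- pipeline_config(out_dir = out, n_sites = 2, points_per_site = 25,
                       terrain = terrain_spec(n_rows = 20, n_cols = 20),
                       met_jan = met_spec("Jan", n_days = 10),
                       met_jul = met_spec("Jul", n_days = 10),
                       forest = forest_config(n_trees = 150),
                       n_permutations = 499, min_node = 10, seed = 11)
run_pipeline(cfg, quiet = TRUE)

head(read.csv(file.path(out, "importance.csv")))
#>              variable pct_inc_mse rank
#> 1           curvature   168.61732    1
#> 2     desiccation_jul    50.80457    2
#> 3      insolation_jan    32.23821    3
#> 4 photoinhibition_jul    25.36582    4
#> 5           frost_jan    25.10884    5
#> 6      insolation_jul    22.71401    6

cat(readLines(file.path(out, "ctree.txt")), sep = "\n")
#>  node 1: curvature (p = 0.034)
#>   [curvature <= 0.2055] node 2: curvature (p = 0.034)
#>     [curvature <= -0.08946]* node 4: n = 14, median = 183.3
#>     [curvature > -0.08946] node 5: annual_precipitation (p = 0.034)
#>       [annual_precipitation <= 5695]* node 6: n = 13, median = 141.5
#>       [annual_precipitation > 5695]* node 7: n = 12, median = 106.3
#>   [curvature > 0.2055]* node 3: n = 11, median = 29.0
```

The fixture plants a negative curvature effect on deviation, and both
stages find it: curvature ranks first in the forest importances
(out-of-bag R² = 0.68 on this run, `forest_summary.json`), and the
tree partitions the points into concave (node 4, median deviation
183 m) through convex (node 3, median 29 m) landforms, with a
precipitation split inside the intermediate group. Terminal-node
medians, rule paths, partial-dependence curves and PCA loadings are
written alongside as CSV/JSON.

A thin CLI over the same functions is installed at
`inst/cli/treelinetopo`
(`treelinetopo run-all --config cfg.yaml --seed 1 --out results/`),
with one subcommand per stage.

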