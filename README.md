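# worldseasons

A two-tier seasonal classification of the global land surface from monthly
climate normals, for anyone whose analysis should be framed by *seasons*
rather than calendar years: comparative climatology, phenology, harvest and
monsoon studies, wildfire or flood seasonality.

Annual aggregates dilute inherently seasonal signals, and the standard
four meteorological seasons are meaningless in the tropics, deserts and
polar regions. `worldseasons` instead:

1. assigns every land grid cell to one of four **climate zones** by fixed
   threshold rules —
   * **desert** if the annual aridity index AI = ΣP / ΣPET < 0.2,
   * **arctic / high montane** if max_m tmin_m ≤ 10 °C,
   * **tropical** if (max_m P_m − min_m P_m) > θ_P **and**
     (max_m T_m − min_m T_m) < θ_T **and** min_m T_m ≥ 18 °C,
     with calibrated thresholds θ_P = 81.972 mm, θ_T = 7.52 °C and
     T the monthly midpoint (tmin + tmax)/2,
   * **temperate** otherwise;
2. clusters each cell's twelve months into named **seasons** by weighted
   k-means on zone-specific, z-normalized variables (each column scaled by
   √w so a weight w multiplies its share of squared distance):
   temperate k = 4 (temperature, precipitation lag, temperature lag, NDVI
   lag; weights 3.521 / 3.237 / 2.031 / 0.312) → winter, spring, summer,
   autumn; tropical k = 2 (temperature, precipitation lag, NDVI lag;
   weights 3.958 / 3.72 / 1.713) → wet, dry; arctic k = 2 (temperature,
   solar radiation) → winter, summer; desert k = 2 (temperature, aridity)
   → cooler, hotter. Outside the tropics seasons are forced to be
   temporally contiguous (one circular run of months each) by an exact
   search over all contiguous partitions.

The package also ships the calibration machinery: a capped per-city error
against reference season calendars (1 per mismatched month, capped at 6
under temperate/tropical zone confusion), a 70/30 train/test split, a
budgeted 9-parameter bounded search with elite selection on held-out
cities, a synthetic archetype generator with analytic ground truth,
categorical focal smoothing, Equal Earth reprojection, and raster/text
output writers. See the methods vignette
(`vignettes/worldseasons-methods.Rmd`) for the full model description.

## Worked example

```r
library(worldseasons)

# a noisy synthetic mid-latitude pixel and its season calendar
mp  <- make_pixel(archetype_spec("temperate", noise_sd = 1, seed = 42))
cal <- classify_pixel(mp$pixel)
print(cal)
#> <season_calendar> zone: temperate
#>      Jan      Feb      Mar      Apr      May      Jun      Jul      Aug
#> "winter" "spring" "spring" "spring" "summer" "summer" "summer" "summer"
#>      Sep      Oct      Nov      Dec
#> "autumn" "autumn" "winter" "winter"
```

Winter is the coldest circular run of months (here Nov–Jan), and each
season is one unbroken arc. The calibrated defaults are inspectable:

```r
print(default_params())
#> <ws_params>
#>        temp_diff_thresh      precip_diff_thresh w_temperate.temperature
#>                   7.520                  81.972                   3.521
#>  w_temperate.precip_lag    w_temperate.temp_lag    w_temperate.ndvi_lag
#>                   3.237                   2.031                   0.312
#>  w_tropical.temperature   w_tropical.precip_lag     w_tropical.ndvi_lag
#>                   3.958                   3.720                   1.713
#> fixed: tropical_min_temp = 18 degC; arctic_tmin_ceiling = 10 degC; desert_ai_thresh = 0.2
```

Scoring predictions against reference calendars (here synthetic records
with 10% label noise, so the expected error is 12 × 0.1 = 1.2 months):

```r
ref <- make_reference_set(n_per_archetype = 5, label_flip_p = 0.1, seed = 8)
e   <- evaluate_params(default_params(), ref$records, ref$pixel_lookup)
cat("mean error:", round(as.numeric(e), 3), "months\n")
#> mean error: 0.85 months
print(attr(e, "histogram"))
#>  0  1  2  3  4  5  6  7  8  9 10 11 12
#>  7 10  2  1  0  0  0  0  0  0  0  0  0
```

The mean is the average number of months per city whose predicted season
disagrees with the reference; the histogram counts cities at each error
score. Raster workflows mirror the per-pixel ones
(`zone_map()`, `classify_raster()`, `focal_smooth()`,
`reproject_equal_earth()`, `write_outputs()`), and `exec/worldseasons`
exposes them as `zones`, `classify`, `synth` and `optimize` shell
subcommands.

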