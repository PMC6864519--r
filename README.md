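# pmroutes

Robust statistical analysis of mobile PM2.5 route measurements.

Walking a fixed route with a portable particle monitor yields a short,
time-ordered series of PM2.5 concentrations (mg/m³) per route. These
series are strongly right-skewed and heavy-tailed — occasional traffic
spikes an order of magnitude above the typical level, exact zeros where
the air is clean — so means and standard deviations are dominated by a
handful of observations. `pmroutes` implements the analysis such data
call for, end to end:

- **Descriptives**: per-route count, mean, median, SD, skewness,
  non-excess kurtosis (`route_summary()`); Tukey-hinge quartiles,
  box-plot fences, and centered moving-average smoothing that preserves
  the series ends (`smooth_routes()`).
- **Exact median inference**: the sign test (`sign_test()`) and the
  order-statistic confidence interval for the median
  (`median_ci()`, `route_median_ci()`). With K ~ Bin(n, ½), k′ is the
  largest integer with P(K ≤ k′) ≤ α/2 and k the smallest with
  P(K ≥ k) ≤ α/2; the interval [X₍k′+1₎, X₍k₎] has guaranteed coverage
  1 − P(K ≤ k′) − P(K ≥ k) ≥ 1 − α, with no distributional assumptions.
- **Air-quality classification**: the Quito Air Quality Index (QAQI)
  bands — Desirable [0, 0.025), Acceptable [0.025, 0.050), Caution
  [0.050, 0.150), Alert, Alarm, Emergency — with candidate-set and
  conservative upper-endpoint labelling of each route's median interval
  (`classify_routes()`), the group-by-band contingency table
  (`band_contingency()`), and a one-sided tie-corrected Wilcoxon
  rank-sum comparison of route groups on the band ordinal scale
  (`compare_band_groups()`), using midranks, the tie-corrected variance
  var(W) = (n_x n_y / 12)[(N+1) − Σ(t³−t)/(N(N−1))], and a 0.5
  continuity correction.
- **Robust location**: the α-trimmed mean family
  x̄(α) = Σ X₍i₎ / (n − 2⌊nα⌋) over i = ⌊nα⌋+1 … n−⌊nα⌋
  (`trimmed_mean()`), the trimean (Q₁ + 2Q₂ + Q₃)/4 (`trimean()`), and
  sweep curves with the median CI band attached
  (`route_trimmed_curve()`).
- **Robust scale**: seven estimators — mean absolute deviation, sample
  SD, unscaled MAD, semi-interquartile range, the biweight midvariance
  family S_bi(c), the normalized subrange family C_nα, and the
  least-median-of-squares scale ½·min|X₍i+⌊n/2⌋₎ − X₍i₎|
  (`route_scale_table()`, `route_scale_curves()`).
- **Synthetic routes**: a generator for nonnegative heavy-tailed route
  series (lognormal body, additive trend segments clipped at zero,
  multiplicative Bernoulli spikes) and a bundled six-route study preset
  (`route_spec()`, `generate_study()`, `six_route_study()`).

Everything takes a data frame in and returns a tibble, composes with
the pipe, supports `tidy()`/`glance()` on test objects and
`autoplot()` on sweep results, and `run_full_analysis()` orchestrates
the whole pipeline into a reproducible report.

## Worked example

```r
library(pmroutes)

data <- generate_study(six_route_study(), seed = 1)

route_median_ci(data, alpha = 0.05)
#> # A tibble: 6 × 8
#>   route_id     n lower_index upper_index   lower   upper  length coverage
#>   <chr>    <int>       <int>       <int>   <dbl>  <dbl>   <dbl>    <dbl>
#> 1 X1         156          66          91 0.0296  0.0382  0.00858    0.955
#> 2 X2          83          33          51 0.0358  0.0377  0.00186    0.952
#> 3 X3         102          41          62 0.00683 0.00926 0.00244    0.963
#> 4 Y1          70          27          44 0.00666 0.0103  0.00359    0.959
#> 5 Y2          70          27          44 0.0297  0.0395  0.00981    0.959
#> 6 Y3          82          32          51 0.0425  0.0605  0.0180     0.965
```

Each route gets the exact order-statistic interval: for X1 (n = 156)
the median lies in [X₍₆₆₎, X₍₉₁₎] = [0.0296, 0.0382] mg/m³ with
guaranteed 95.5% coverage. Classifying the intervals against the QAQI
bands and comparing the X routes (parallel to the park) with the Y
routes (perpendicular):

```r
labels <- classify_routes(route_median_ci(data))
band_contingency(labels, tibble::tibble(route_id = labels$route_id,
                                        group = substr(labels$route_id, 1, 1)))
#> # A tibble: 3 × 5
#>   group Desirable Acceptable Caution Total
#>   <chr>     <int>      <int>   <int> <dbl>
#> 1 X             1          2       0     3
#> 2 Y             1          1       1     3
#> 3 Total         2          3       1     6

report <- run_full_analysis(study = six_route_study(), seed = 1)
report$comparison
#> One-sided Wilcoxon rank-sum (ties: midranks, continuity correction)
#>   W = 11.5, E(W) = 10.5, var(W) = 4.5, z = 0.2357, p = 0.4068
```

One X route and one Y route sit at Desirable, two X and one Y at
Acceptable, and one Y route (the busiest avenue) at Caution. The
rank-sum statistic for the Y group, W = 11.5 against an expectation of
10.5 (p = 0.41), does not reject the hypothesis that pollution along
the two groups of routes is the same.

Robust versus classical dispersion on the same data:

```r
route_scale_table(data)
#> # A tibble: 6 × 6
#>   route_id mad_mean      sd     mad     sir     lms
#>   <chr>       <dbl>   <dbl>   <dbl>   <dbl>   <dbl>
#> 1 X1        0.0410  0.109   0.0143  0.0188  0.0129
#> 2 X2        0.00358 0.00526 0.00240 0.00235 0.00231
#> 3 X3        0.00529 0.00713 0.00351 0.00405 0.00281
#> 4 Y1        0.00988 0.0140  0.00462 0.00532 0.00314
#> 5 Y2        0.0205  0.0393  0.00907 0.00858 0.00853
#> 6 Y3        0.0322  0.0442  0.0203  0.0204  0.0184
```

On the spike-contaminated X1 route the SD (0.109) is more than seven
times the MAD (0.014): the classical estimate is carried by a few
extreme observations while the high-breakdown estimates describe the
bulk of the exposure.

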