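# pondwi

Mapping potential malaria-vector larval habitats from ponding persistence.

`Anopheles` mosquitoes need standing water that persists long enough —
about 10 days under stressed (critical) conditions, 15 days under normal
conditions — for larvae to develop into adults. `pondwi` turns daily
gridded surface-layer soil saturation into maps and time series of
potential larval habitat, and quantifies how dry-season sprinkler
irrigation of farm parcels reshapes them. It is aimed at vector-control
planners and environmental modellers studying agricultural settings where
irrigation sustains mosquito breeding through the dry season.

## The method

A cell is **ponded** on a day when its surface-layer saturation reaches a
threshold θ. The **Wetness Index** counts consecutive ponded days:

    WI(x,y,t) = WI(x,y,t−1) + 1   if S(x,y,t) ≥ θ
              = 0                 otherwise

θ is calibrated against a survey of observed aquatic habitats by
maximising the probability of detection (POD), selecting the *largest*
threshold that still detects every usable point, with bootstrap resampling
for robustness. From the index the package computes, per scenario
(baseline vs irrigation):

* **P(WI > T)** — per-cell fraction of a period's days with ponding runs
  longer than T ∈ {10, 15}: the probability of potential habitat
  occurrence, mapped for year, dry and rainy seasons;
* **F(WI > T)** — daily fraction of a region's cells (e.g. inside farms)
  with runs longer than T, with monthly means and 95% CIs;
* **stability classes** — non-habitat / temporary / semi-permanent /
  permanent from each cell's maximum ponding duration
  (< 15 / 15–90 / 90–180 / ≥ 180 days);
* **scenario tests** — one-sided Wilcoxon rank-sum on per-cell
  probabilities and one-sided Welch t-tests on monthly coverage.

Persistently fast-flowing cells (flowrate > 0.01 m³/s on ≥ 90% of days)
are masked out: larvae do not survive in moving water.

Because the original driving data (a physically based land-surface
simulation plus a field survey) are not redistributable, the package
includes a first-class synthetic hydrology generator: a conservative daily
bucket model with D8 routing over a synthetic valley — clay-rich flats,
freely draining uplands, a perennial stream, four farm parcels with
rotating 10 mm/day sprinkler irrigation — whose mass balance closes to
1e−6 relative error on every run. See the methods vignette
(`vignettes/habitat-mapping.Rmd`) for the model, its assumptions, and
every tunable parameter.

## Worked example

```r
library(pondwi)
res <- run_pipeline(default_config(), out_dir = "run1")
res$calibration
#> <calibration_result> theta* = 0.480 (n = 102 points, 200 resamples)
#>   POD at theta*: calibration 1.000, validation 1.000
```

The threshold recovered from the synthetic survey is 0.48: every usable
survey point's cell reaches saturation 0.48 during the rainy season, and
no stricter threshold detects them all. Dry-season habitat probabilities
inside vs outside the irrigated farms (T = 10 days):

```r
s <- res$summary
s[s$T == 10 & s$period == "DRY",
  c("region","scenario","mean","p25","median","p75","wilcoxon_p")]
#>         region   scenario   mean p25 median    p75 wilcoxon_p
#>   INSIDE_FARMS   BASELINE 0.0817   0  0.000 0.0401   6.57e-78
#>   INSIDE_FARMS IRRIGATION 0.4364   0  0.395 0.8674   6.57e-78
#>  OUTSIDE_FARMS   BASELINE 0.0279   0  0.000 0.0000   5.00e-01
#>  OUTSIDE_FARMS IRRIGATION 0.0279   0  0.000 0.0000   5.00e-01
```

Without irrigation the dry season offers essentially no habitat inside the
farms (median 0); the rotating sprinkler scheme raises the median
occurrence probability to 0.395 (rank-sum p ≈ 1e−78), while outside the
farms nothing changes (p = 0.5). Irrigation also stabilises habitats:

```r
res$stability
#> baseline:   NON_HABITAT 16.4% TEMPORARY 8.5% SEMI_PERMANENT 28.5% PERMANENT 46.6%
#> irrigation: NON_HABITAT 16.3% TEMPORARY 8.6% SEMI_PERMANENT 19.2% PERMANENT 55.9%
```

Cells that held water 90–180 days under the baseline hold it ≥ 180 days
with irrigation, because dry-season ponding connects to the rainy season
across the April–May boundary.

`run_pipeline()` writes every artifact (exceedance maps, coverage series,
stability histograms, survey, calibration, summary table, config) as plain
CSV/JSON/YAML plus a `manifest.json` with MD5 checksums; re-running the
same configuration reproduces the checksums byte for byte. A thin CLI
wrapper with `simulate` / `calibrate` / `wi` / `metrics` / `compare` /
`run-all` / `make-fixtures` subcommands lives at `inst/cli/pondwi.R`.

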