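---
title: "Mapping malaria-vector larval habitats with a ponding-persistence wetness index"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping malaria-vector larval habitats with a ponding-persistence wetness index}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pondwi)
```

## The problem

*Anopheles* mosquitoes breed in shallow, slow-moving or standing water:
rain pools, stream shorelines, drainage ditches, irrigation canals. A pond
only produces adult mosquitoes if it persists long enough for the aquatic
stages to complete — roughly 10 days under stressed ("critical") conditions
and 15 days under normal conditions for *Anopheles arabiensis*. Mapping
*where* and *for how long* water ponds therefore maps potential larval
habitat, and predicts how an intervention such as dry-season sprinkler
irrigation of a sugarcane plantation reshapes malaria risk.

`pondwi` implements this analysis as a tested pipeline over daily gridded
surface-layer soil saturation:

1. a **synthetic hydrology generator** producing daily saturation and
   surface flowrate cubes for a baseline and an irrigation scenario,
2. the **wetness index** (WI), a per-cell count of consecutive ponded days,
3. **threshold calibration** of the saturation level that defines ponding,
   against a survey of observed aquatic habitats,
4. **habitat metrics**: exceedance-probability maps, stream masking,
   fractional-coverage series, monthly means, stability classes,
5. **scenario statistics**: summary tables and one-sided rank-sum and
   Welch tests of the irrigation effect.

## The wetness index

A grid cell is *ponded* on day $t$ when its surface-layer (25 cm) relative
saturation satisfies $S(x,y,t) \ge \theta$. The wetness index is the running
count of consecutive ponded days,

$$
WI(x,y,t) =
\begin{cases}
WI(x,y,t-1) + 1 & \text{if } S(x,y,t) \ge \theta\\
0 & \text{otherwise,}
\end{cases}
$$

with $WI = 0$ before the first simulated day. A dry day resets the count:
the habitat has drained and any larvae are lost. The index is computed once
over the full simulated year; seasonal analyses *window* the year-long
index rather than restarting the recurrence at season boundaries, so a run
that begins in April and survives into May is credited to the rainy season
at its full accumulated length.

Two derived statistics summarise the index. The **probability of potential
habitat occurrence** for a cell over a period (year, dry season
January–April plus November–December, rainy season May–October) is

$$
P(WI > T) = \frac{D\big(WI(x,y,t) > T\big)}{D_{\text{period}}},
\qquad T \in \{10, 15\},
$$

the fraction of the period's days on which the cell's current ponding run
strictly exceeds the larval development time $T$. The **fractional
coverage** of a region (e.g. the irrigated farms) on a day is

$$
F(WI > T) = \frac{C\big(WI(x,y,t) > T\big)}{C_{\text{region}}},
$$

the fraction of the region's cells whose run exceeds $T$ that day. We use
the strict comparator ($>$) in both statistics for internal consistency;
`coverage_series(..., comparator = "geq")` switches the coverage statistic
to $\ge$, since usage in the field varies on whether "exceeds $T$ days"
owns the boundary. At $T = 10$ the two differ by a single day of
persistence and the difference is immaterial in practice.

Cells where water *flows* rather than stands are poor habitat. Cells whose
simulated flowrate exceeds 0.01 m³/s for at least 90% of the year's days
are masked out (`stream_mask()`), and the mask is applied to all per-cell
statistics, not only maps — an analysis choice exposed as
`mask$apply_to_stats` in the configuration.

**Stability classes.** The longest run a cell achieves in the year
classifies it as non-habitat (< 15 days), temporary ([15, 90)),
semi-permanent ([90, 180)) or permanent (≥ 180 days). The class boundaries
are left-closed; the sources describing these field categories give ranges
without stating boundary ownership, so the convention here is that a
maximum duration of exactly 15 days is already a temporary habitat and 180
days is already permanent. Histograms use 15-day bins with a final open bin
at 360 days and above.

## Threshold calibration

$\theta$ is not a physical constant: it absorbs the mismatch between a
50 m grid-cell average saturation and the sub-grid ponds surveyors actually
see. It is calibrated against survey points — locations where ponding was
observed — by maximising the **probability of detection** (POD): the
fraction of points whose cell reaches $\theta$ on at least one day of the
rainy season. Points with habitat types a terrestrial hydrologic model
cannot represent (man-made ponds, tire tracks, animal footprints) are
removed first, as are dry-season observations, which are dominated by the
real — and here simplified — irrigation practice.

POD alone is maximised by $\theta = 0$, so the selection rule is the
**largest** $\theta$ on the grid $\{0, 0.01, \dots, 1\}$ attaining the
maximal POD: the strictest threshold that still detects every usable point,
which minimises overprediction (unmeasurable here because the survey covers
only locations *with* ponding). Detection uses "at least one day in the
season window" — the weakest temporal matching rule consistent with a
survey of ponds observed at unrecorded times within the season.

Robustness comes from a bootstrap: points are resampled with replacement,
the threshold selected per resample, and $\theta^\*$ reported as the
grid-rounded median of the selections; out-of-bag points give a validation
POD per resample (resamples with an empty out-of-bag set are recorded as
missing, not zero). The protocol — 1000 resamples by default, grid step
0.01, median aggregation — is this package's own fixed choice, exposed in
the configuration.

The synthetic survey generator plants a recoverable threshold: every
sampled cell ponds at `theta_true` during the rainy season, and at least
one *anchor* point lies within one grid step above it, so the strictest
all-detecting threshold is `theta_true` itself. Parameter-recovery tests
plant 0.30, 0.48 and 0.70 and recover each to within one grid step.

```{r calibration-demo}
cfg <- default_config()
cfg$domain$n_rows <- 40L; cfg$domain$n_cols <- 32L
cfg$survey$n_points <- 50L; cfg$calibration$n_bootstrap <- 50L
sim <- simulate_scenarios(cfg)
survey <- filter_survey(make_survey(sim$baseline$saturation, sim$domain,
                                    theta_true = 0.48, n_points = 50,
                                    seed = 1))
calibrate_theta(sim$baseline$saturation, survey, n_bootstrap = 50, seed = 1)
```

## The synthetic hydrology generator

The statistics above need a year of daily saturation and flowrate on a
grid. The generator supplies one with the *statistical structure* of a
physically based land-surface simulation over an East African agricultural
valley, without solving the physics. It is first-class, tested code: every
downstream module is exercised against it.

**Domain** (`make_domain()`). A smooth random elevation surface forms a
southward-draining valley with a meandering perennial channel; flow
directions are steepest-descent D8 with a deterministic tie-break (lowest
direction code). Clay-rich, slowly draining soil (`SLOW`, the Ustert
analogue) occurs in patches over the flat valley floor; freely draining
soil (`FAST`, the Ustoll analogue) covers the rest; a `RIPARIAN` band lines
the channel. Four contiguous rectangular farm parcels are centred on the
valley floor and straddle both soil types, as the real plantation does.
Default grids are desk-scale (80 × 60 cells at 50 m); the full 332 × 248
study-scale grid runs unchanged, just slower.

**Forcing** (`make_forcing()`). Daily rainfall is a two-state mixture
(wet-day occurrence × gamma depths) with a within-season intensity profile
that builds to a mid-season peak — without it, marginal cells either pond
all season or never accumulate long runs, and the intermediate 90–180-day
stability class that dominates the real landscape is empty. A seven-day
storm is planted on days 5–11 of the first rainy month, emulating the
multi-day event that opens the rainy season, and the series is rescaled to
an annual total of 1477 mm, the local climatology. Potential
evapotranspiration is a smooth seasonal cosine peaking in the dry season
(4.5 ± 1.3 mm/day).

**Water balance** (`run_bucket_model()`). Each cell is a single bucket of
capacity `effective porosity × 250 mm` (112.5 mm for clay at porosity 0.45,
100 mm for fast-draining soil at 0.40). Daily, in order: inputs (rain,
irrigation, run-on, boundary supply) are added; evapotranspiration
(`et_coeff × PET × S`) and drainage
(`drainage_coeff × (1 + slope_gain × slope) × W`) are removed; riparian
cells are topped up to a saturation floor of 0.95 (a stream boundary
supply, counted as an input); storage above capacity spills as runoff,
routed one cell down the D8 direction per day (an explicit lag that removes
any within-day ordering dependence); runoff at pits leaves the domain.
Channel cells receive a constant 400 mm/day boundary baseflow representing
the river entering the domain, which gives every channel cell a perennial
flowrate above the 0.01 m³/s masking threshold. Flowrate is the runoff
volume a cell exports divided by 86 400 s. Every flux is accumulated, and
the run fails loudly if the global balance (storage change + water in
transit = inputs − ET − drainage − outlet outflow) misses by more than
1e−6 relative; in practice it closes to ~1e−15.

A static lognormal multiplier (sd 0.5 on the log scale) on each cell's
drainage coefficient represents sub-grid soil heterogeneity. It is what
spreads maximum ponding durations across the stability classes — a
homogeneous clay either holds the whole rainy season everywhere or nowhere.

**Parameter choices.** The defaults were fixed once, to reproduce the
qualitative hydrology reported for the study system, and are not tuned per
run: a storm saturates most of the domain (> 85%) and fast-draining cells
dry within about five days (`FAST` drainage 0.18/day); clay cells hover
near the ponding threshold in the rainy season (`SLOW` drainage 0.035/day,
`et_coeff` 0.5), so their exceedance probabilities sit in the 0.4–0.9
range inside farms while fast-draining cells stay near zero; and streams
remain wet year-round. Irrigation (10 mm/day, 10-day turns alternating
between farm groups {1,3} and {2,4} through the dry months, group A first
from the year's first active day) then raises dry-season ponding inside
farms from a median of zero to ~0.2–0.4 and extends maximum durations
across the April–May boundary, shifting semi-permanent cells to permanent.

**Irrigation phase.** The rotation counts calendar days from the first
active day of the year, group A first. The real schedule's phase is not
documented, so this is a fixed convention; November's resumption inherits
the calendar-day phase rather than restarting the cycle.

**The 22-hour application window** of the sprinklers is recorded in the
schedule as metadata but not resolved: all analysis operates on daily
fields, so sub-daily structure has no observable effect.

## Scenario statistics

Per-cell exceedance probabilities inside and outside the farms are
summarised by mean and quartiles (type-7 linear interpolation between
order statistics). The irrigation effect is tested with a one-sided
Wilcoxon rank-sum test (null: irrigation did not increase the
probabilities; exact enumeration for untied samples of ≤ 20, otherwise
normal approximation with tie correction), and monthly coverage with a
one-sided Welch two-sample t-test on the month's daily coverage values —
Welch rather than pooled-variance because scenario variances have no
reason to be equal, one-sided because the hypothesis is directional.
Samples in which every value is identical are reported as p = 0.5 with a
degenerate flag rather than as an error or a spurious rejection.

Per-cell values are treated as independent observations, mirroring how
such tables are typically produced; spatial autocorrelation inflates the
effective significance and is deliberately not corrected. The p-values
should be read as descriptive strength-of-separation summaries, not
calibrated field-level inference. No multiple-testing correction is
applied across the table's cells.

## Problem sizes and runtime

The default configuration (80 × 60 × 365, two scenarios, 200 bootstrap
resamples) runs the full pipeline in a few seconds. Property tests use
50 × 50 × 365 random cubes for the recurrence oracle and 60 × 48 domains
for parameter recovery; these sizes give stable statistics while keeping
the whole suite around two minutes.

## What the generator does and does not emulate

Passing tests establish that the *analysis* — recurrence, calibration,
metrics, tests — is correct, and that the pipeline reproduces the expected
directional responses to irrigation on data with realistic structure. The
generator is not a hydrologic model: there is no Richards-equation
infiltration, no groundwater, no channel hydraulics, no energy balance,
and rainfall has no spatial structure within the domain (a single daily
value everywhere, where real storm fronts move). Absolute values of the
habitat statistics on synthetic data therefore carry no field meaning;
only their internal relationships do. The semi-permanent → permanent
stability shift under irrigation, in particular, depends on dry-season
ponding connecting to the rainy season across the April–May boundary and
does not materialise under every random realisation of the forcing.

## Degenerate inputs and numerical conventions

* `theta = 0` makes every cell pond every day ($S \ge 0$ always);
  `compute_wi` then returns $WI(t) = t$.
* Empty regions, empty periods, empty filtered surveys, and surveys whose
  points fall outside the grid raise immediate, named errors.
* Masked cells are `NA` in maps — never zero, which would read as
  "habitat never occurs".
* Partial months are flagged in monthly summaries, not silently averaged.
* Quantiles use R's default type 7; with it, the four-cell example
  $\{0,0,1,1\}$ gives P25 = 0, median = 0.5, P75 = 1.
* All randomness flows from one root seed, expanded with fixed per-stage
  offsets; identical seeds give bit-identical outputs, including file
  checksums in the run manifest.
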