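# ruralflight

Grid cell-level estimation of rural depopulation from daily gridded
counts of mobile location requests around the Chinese New Year.

## The problem

Most of China's rural-to-urban migrant workers are invisible to official
statistics: the hukou (household registration) system counts them at
their registered origin, not where they actually live. Once a year,
however, they make themselves visible — during Chunyun, the New Year
travel season, hundreds of millions return to their home villages. Daily
counts of mobile location requests (`N`), aggregated on a ~1 km grid,
therefore jump upward in rural cells and drop in urban cells around the
festival. `ruralflight` turns that natural experiment into a per-cell
estimator of rural depopulation, for quantitative geographers and
demographers working with gridded human-activity proxies.

## The method

For each grid cell with daily counts `y_t` over a 29-day window (Julian
days 16–44; New Year's Day = day 39):

1. **Activity filter** — cells with mean `N` < 2 counts/day are excluded
   as remote land.
2. **Urban/rural partition** — nighttime-light radiance classifies cells:
   rural iff radiance ≤ 0.738 (the 1-D Mahalanobis boundary between the
   rural-village class, 0.377 ± 0.27, and the small-city class,
   11.71 ± 7.97; `deriveRuralThreshold()` reproduces the equal-distance
   construction, ≈ 0.7483).
3. **Turning point (TP)** — a minimum-t structural-break search in the
   Zivot–Andrews spirit: for every candidate break `b` in the trimmed
   interior, OLS of

   `Δy_t = μ + θ·1[t ≥ b] + β·t + α·y_{t−1} + e_t`

   and `TP = argmin_b t(α)`. The TP day opens the "after" regime.
4. **Shift confirmation** — a Mann–Whitney U test between the
   before/after sub-series (exact by enumeration for n ≤ 14 even with
   ties, tie- and continuity-corrected normal approximation otherwise).
5. **Tier rulebook** — nested rural-depopulation estimates:
   *upper*: `NR_b < NR_a`; *medium*: + significant at α = 0.05;
   *lower*: + `TP ≤ 39` and ≥ 1 rural settlement site in the cell.
   Urban cells with a significant decrease are flagged separately.
6. **Aggregation** — regional net increase `Σ (NR_a − NR_b)`, prevalence
   `PR` (share of rural cells with increased `N`), country-level domain
   time series, log-linear fits against census-inferred out-migrants
   (`registered − resident-with-hukou`), and source/sink labels via the
   deviation rule `y > 3x` / `x > 3y` on national shares.

The proprietary inputs (location-request feed, VIIRS composites, census
yearbooks) are emulated by a synthetic-data generator
(`simulateMobilityGrid()`) with recorded ground truth, so every stage is
testable end to end.

## Worked example

```r
library(ruralflight)

g <- simulateMobilityGrid(generatorConfig(seed = 42))
f <- partitionGrid(filterLowActivity(g))
f
#> MobilityGrid: 1050 cells x 29 days (Julian days 16..44)
#>   domains: rural=659, urban=391
#>   simulated object with recorded ground truth

tp    <- detectTurningPoints(f)
rural <- tp[tp$domain == "rural", ]
tiers <- assignTiers(rural, cellInfo(f)[rural$cell_id, "settlements"])
summarizeTiers(tiers)
#>     tier n_cells n_settlements settlement_share
#> 1  lower     246           402        0.5982143
#> 2 medium     375           402        0.5982143
#> 3  upper     525           549        0.8169643
```

Of 1,200 simulated cells, 150 low-activity cells are dropped and the
remaining 1,050 split into 659 rural / 391 urban. Among rural cells, 525
show an increase across their turning point (upper estimate), 375 of
those significantly (medium — the headline estimate), and 246 also break
by New Year's Day in a cell containing a settlement site (lower bound).
The medium tier covers ~60% of settlement sites. The full pipeline —
including regional summaries, census validation and a JSON manifest — is
one call:

```r
man <- runPipeline(pipelineConfig(generator = generatorConfig(seed = 42),
                                  outdir = "run1"))
```

or from a shell, `Rscript inst/scripts/ruralflight-cli.R demo --seed 42
--outdir run1`.

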