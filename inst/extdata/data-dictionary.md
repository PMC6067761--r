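# File formats

All pipeline inputs and outputs are plain text. Coordinates live in the
grid's abstract planar frame: cells are axis-aligned unit squares with
half-open extents `[col, col+1) x [row, row+1)`; `row`/`col` are 0-based.
Julian day = 1-based day-of-year (Feb 8, 2016 -> 39).

## grid.csv (long-format counts)
- `cell_id`   opaque cell identifier
- `row`, `col` 0-based grid indices of the cell
- `julian_day` day-of-year of the observation
- `N`         daily aggregate count of mobile location requests (>= 0);
              absent cell-days are simply missing rows (never imputed)

## radiance.csv
- `cell_id`
- `radiance`  nighttime-light radiance, 1e-9 W cm-2 sr-1 (>= 0)

## settlements.csv / settlements GeoJSON
- `id`        settlement point identifier
- `x`, `y`    point coordinates in the grid frame

## region_map.csv
- `cell_id`
- `county_id`, `city_id`, `province_id` nested region membership
  (each cell belongs to exactly one county; cities and provinces are
  unions of counties)

## census.csv
- `county_id`, `city_id`, `province_id`
- `registered_pop`      persons registered (hukou) in the county
- `resident_hukou_pop`  persons with local hukou still resident
- `agri_share`          resident agricultural population share, [0, 1]
- `nonhukou_ratio`      inhabitants without hukou / with hukou

## truth_cells.csv (simulated data only)
- `cell_id`
- `true_domain`     urban | rural | empty
- `true_break_day`  implanted break day (empty if none)
- `true_effect`     implanted multiplicative step factor (1 if none)

## truth_regions.csv (simulated data only)
- region ids as above
- `true_out_migrants`, `registered_pop`, `resident_hukou_pop`,
  `agri_share`, `nonhukou_ratio`
- `implanted_effect_mass` summed implanted daily net increase over the
  county's affected rural cells (counts/day)

## Pipeline outputs
- `partition.csv`        `cell_id,label` (urban | rural)
- `turning_points.csv`   `cell_id,tp_day,t_min,mean_before,mean_after,`
                         `u_stat,p_value,no_break[,domain]`
- `tiers.csv`            `cell_id,in_lower,in_medium,in_upper,`
                         `settlement_count`
- `region_summary_*.csv` one row per region: `region_id,level,`
                         `n_rural_cells,n_increased,net_increase,PR,`
                         `net_decrease,rural_share,urban_share,label`
- `country_series.csv`   `julian_day` + one daily-sum column per domain
- `summary.json`         tier summaries (both settlement universes),
                         rural peak day/share, census-validation fits
- `manifest.json`        config hash, seed, stage row counts, version
- `net_increase.tif(.json)`, `relative_rate.tif(.json)` single-band
  rasters with affine rescaling sidecars (value = offset + scale*sample)
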