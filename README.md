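# vegshift

Quantify how plant communities change between repeat visits to permanent
vegetation monitoring plots surveyed with the point-intercept method.

Long-running plot networks (such as the Australian rangeland surveillance
plots) revisit one-hectare sites every few years, recording every species
touched at 1010 point intercepts (10 transects x 101 metre marks). The
scientific questions such data answer — how fast does composition drift
from baseline, do herbaceous and woody vegetation types change at
different rates, is dominance concentrating or relaxing, is the structure
(growth-form mix, vegetated area) shifting — all require a chain of
standardised computations. vegshift implements that chain as tested,
composable functions:

* **Community profiles** per visit: cover (`PIs/1010`), transect
  frequency (1-10), and the importance value index
  `IVI = relative cover (%) + relative frequency (%)`, which sums to 200
  across the species of a visit and is the default abundance currency.
* **Temporal beta diversity**: Sorensen (Bray-Curtis) distance
  `1 - 2 Σ min(a_i, b_i) / (Σ a_i + Σ b_i)` and Simpson beta
  `min(b, c) / (min(b, c) + a)` between each revisit and its baseline;
  OLS of distance on interval (fractional years); annualised turnover
  rates `distance / interval` for revisits more than 4 years after
  baseline, compared across vegetation groups by one-way ANOVA.
* **Dominance shifts**: lognormal fits to each visit's species abundance
  distribution; the ML shape parameter sigma falls when abundance
  concentrates (increased dominance) and rises when it relaxes; plots are
  classified by the first-to-last sigma change and summarised per group.
* **Structural shifts**: eight merged growth forms (Trees, Shrubs,
  Sedges, Hummock Grass, Tussock Grass, Chenopods, Forbs/Herbs, Others)
  with growth-form IVIs, Bray-Curtis distances between growth-form
  spectra, wooded/herbaceous/bare cover-shift tallies, and vegetated-area
  trend fits.
* **A seedable survey simulator** with known turnover, dominance and
  bare-ground dynamics, used to validate every stage by parameter
  recovery; and an end-to-end report pipeline (`run_report()`) emitting
  every table as CSV plus a JSON manifest, byte-identical given a seed.

## Worked example

```r
library(vegshift)

# a simulated 73-plot campaign: six vegetation groups, visits near
# 0, 3 and 6 years, herbaceous turnover 0.10/yr vs woody 0.05/yr
sim  <- generate_dataset(simulation_config(seed = 7))
diss <- baseline_dissimilarities(sim$dataset, metric = "sorensen")
fit_trajectory(diss, group_by = "physiognomy")
#> # A tibble: 2 × 5
#>   group          n  slope intercept r_squared
#>   <chr>      <int>  <dbl>     <dbl>     <dbl>
#> 1 herbaceous    24 0.0497     0.244     0.334
#> 2 wooded       122 0.0379     0.144     0.402

ann <- annualized_shifts(diss, min_interval_years = 4)
oneway_anova(ann, value = "rate", group = "physiognomy")
#> One-way ANOVA by physiognomy: F(1,71) = 38.608, P = 3.135e-08
#> # A tibble: 2 × 4
#>   group          n   mean      se
#>   <chr>      <int>  <dbl>   <dbl>
#> 1 herbaceous    12 0.0909 0.00553
#> 2 wooded        61 0.0618 0.00178
```

The herbaceous-dominated plots depart from baseline faster than the
wooded ones (fitted slope 0.050 vs 0.038 dissimilarity units per year),
and their annualised turnover rate is higher (0.091 vs 0.062 per year,
strongly significant) — recovering the two-fold turnover contrast planted
in the generator (saturation of the replacement process compresses the
fitted slope ratio below 2 at multi-year windows; see the methods
vignette). The intercepts estimate the resampling noise floor of a
1010-point survey, not real change.

Dominance and structure follow the same pattern:

```r
summarize_dominance(dominance_shifts(sim$dataset))   # per-MVG sigma shifts
tally_cover_shifts(sim$dataset)                      # wooded/herbaceous/bare tallies
run_report("report", sim_config = simulation_config(seed = 7))  # everything, as CSV
```

Field data enter through a documented two-file CSV format
(`read_survey_table()`: one row per intercept hit, plus visit metadata
with a Major Vegetation Group label per visit); see
`inst/scripts/vegshift-report.R` for a shell-level entry point.

## Documentation

The methods vignette (`vignettes/vegshift-methods.Rmd`) describes the
survey model, each statistic and its assumptions, the simulator's design
and its limits, and every numerical convention (tie-breaking, tolerances,
degenerate inputs).
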