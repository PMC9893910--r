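# basinfef

Basin-scale water footprints, midpoint/endpoint damage accounting, and
the **food environmental footprint (FEF)** — a single dimensionless index
comparing the cumulative environmental damage of agricultural production
against the nutrition it delivers, built for evaluating farm
best-management practices (BMPs) such as fertilizer/irrigation reduction
and vegetated filter strips.

## Who this is for

Watershed and water-quality modellers who already have land-use-level
outputs from a calibrated basin model — annual N and P loads delivered to
the receiving water, evapotranspiration with and without irrigation, crop
yields — and want to turn scenario runs into comparable environmental
damage and nutrition numbers, rather than stopping at "BMP2 removes X%
of the load".

## The accounting chain

For each land use, scenario and year:

```
WF   = GnWF + BWF + GWF          water footprint (m³)
GnWF = 10·ETa                    green (rain-fed ET, mm → m³/ha)
BWF  = 10·(ETb − ETa)            blue (irrigation ET)
GWF  = max_i( L_i / (Cmax_i − Cnat_i) )   grey (dilution volume of the
                                 worst pollutant; L in kg/yr, C in mg/L)
```

Loads and total WF are then characterized linearly (ReCiPe-style):

```
Q = T·M      midpoints: freshwater eutrophication (kg P-eq),
             marine eutrophication (kg N-eq), water consumption (m³)
D = Q·E      endpoint damages: human health (DALY), ecosystems (species·yr)
R = D/N      normalized per-person scores, summed into R_health, R_ecosystem
C = Σ W·R    cumulative impact; W from fixed EPI weights (0.4/0.6) or
             entropy weights (dispersion-driven, data-derived)
S = T_cal/(B·P)   nutrition index: daily calories over a 2,000 cal/day
             baseline × global population
FEF = C/S    environmental damage per unit normalized nutrition
```

All coefficient tables (characterization factors, damage factors,
normalization references, TN/TP water-quality standards) are bundled as
editable CSVs and overridable per call. A seeded synthetic-basin
generator produces full multi-year, three-scenario datasets so the whole
chain is testable without a watershed model; a CLI
(`inst/cli/basinfef`, subcommands `synth`, `wf`, `lcia`, `fef`,
`compare`) wraps the same functions.

## Worked example

Desk-scale accounting from the bundled study tables (ten land uses,
three scenarios, reported multi-year endpoint averages):

```r
library(basinfef)
rep <- fef_from_fixtures()
as.data.frame(rep)[, c("scenario", "method", "c_value", "s", "fef",
                       "fef_reduction_pct")]
#>  scenario  method   c_value         s    fef fef_reduction_pct
#>      base entropy 7.649e-07 1.258e-06 0.6080             0.000
#>      BMP1 entropy 7.240e-07 1.237e-06 0.5853             3.735
#>      BMP2 entropy 6.875e-07 1.211e-06 0.5678             6.610
#>      base     epi 9.492e-07 1.258e-06 0.7545             0.000
#>      BMP1     epi 9.000e-07 1.237e-06 0.7276             3.571
#>      BMP2     epi 8.568e-07 1.211e-06 0.7076             6.216
```

Reading the base entropy row: the cumulative per-person impact
C = 0.44 × 1.41e−6 + 0.56 × 2.58e−7 = 7.65e−7, the nutrition index
S = (7,117 MCal/yr → cal/day) / (2,000 × 7.75e9) = 1.258e−6, so
FEF = 0.61 — about 0.6 units of environmental damage per unit of
normalized nutrition production. Both BMP scenarios lower the footprint
(the damage avoided outweighs the 1.7–3.8% nutrition lost), i.e. the
BMPs are more environment-friendly than nutrition-menacing.

End-to-end on a synthetic basin (same structure, generated data):

```r
ds  <- generate_basin(synthetic_config(seed = 1))
run <- run_fef_pipeline(ds)
run$weights$entropy
#> <impact_weights [entropy]> health = 0.435, ecosystem = 0.565
as.data.frame(run$comparison)[, c("scenario", "method", "tn_load_kg_yr",
                                  "tn_load_kg_yr_reduction_pct")]
#>  scenario  method tn_load_kg_yr tn_load_kg_yr_reduction_pct
#>      base entropy        2472.1                         0.0
#>      BMP1 entropy        1636.5                        33.8
#>      BMP2 entropy         991.3                        59.9
#>      ...
```

The recovered TN reductions (33.8% / 59.9%) equal the scenario
multipliers configured in `synthetic_config()` — the generator's
parameter-recovery identity under shared climate coupling.

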