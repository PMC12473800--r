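# sedrisk

Contamination indices and ecological / human health risk assessment for
heavy metals in river sediments.

`sedrisk` is aimed at environmental scientists assessing metal-contaminated
fluvial sediments — typically in mining-impacted watersheds — who need the
standard battery of sediment-quality indices and EPA-style exposure
modelling in one tested, scriptable pipeline. Everything takes a tidy data
frame of per-sample element concentrations (mg/kg dry weight) and returns
tibbles, so analyses chain with the pipe.

## What it computes

**Contamination indices** per element against a geochemical background
`C_b` (two built-in baselines: Taylor & McLennan 1995 upper continental
crust, the default, and the Turekian & Wedepohl 1961 average shale):

- Contamination factor `Cf = C / C_b` (low < 1 ≤ moderate < 3 ≤ high < 6 ≤ very high)
- Geoaccumulation index `Igeo = log2(C / (1.5 C_b))`, seven Müller classes
- Enrichment factor `EF = (C/Fe) / (C_b/Fe_b)` with Fe as the stable
  reference element; EF > 1.5 flags anthropogenic enrichment
- Pollution load index `PLI = (∏ Cf)^(1/n)` and modified contamination
  degree `mCd = mean(Cf)` per site

**Ecological risk** (Hakanson lineage): per-element risk factor
`Er = T × Cf` with configurable toxic response factors `T`, the potential
ecological risk index `RI = Σ Er` with four bands (≤ 95 low, ≤ 190
moderate, ≤ 380 considerable, > 380 very high), and a rank-based Site
Ranking Index `SRI = (Σ n_i / Σ i) / S × 100` over `S` contaminants with
median ± SD categories across sites.

**Human health risk** for child and adult receptors via ingestion,
inhalation and dermal contact: chronic daily doses, e.g.

    CDD_ing = C × IR × ED × EF / (ABW × AET) × CFU   (mg/kg/day)

hazard quotients `HQ = CDD / RfD`, the hazard index `HI = Σ HQ` (HI > 1
flags possible chronic effects), carcinogenic risk `CR_ing = CDD × SF`,
`CR_inh = CDD × IUR`, dermally adjusted `CR_derm = CDD × SF/GIABS`, the
total `TCR = Σ CR` classified against the 10⁻⁶–10⁻⁴ acceptability band,
and per-metal contribution shares. All exposure and dose–response
constants ship as editable YAML configs under `inst/extdata/`.

**Supporting machinery**: CSV sample I/O with validation and LOQ
substitution, an exact Wilcoxon rank-sum zone comparison, a seedable
lognormal synthetic-data generator moment-matched to per-zone mean/SD
targets, ggplot2 `autoplot()` methods, broom-style `tidy()`/`glance()`,
and a CLI script (`inst/cli/sedrisk.R`).

## Worked example

```r
library(sedrisk)

# synthetic two-zone, six-site survey (three upstream, three downstream
# stations; concentrations moment-matched to the built-in zone statistics)
samples <- generate_samples(default_cunas_spec(), seed = 42)

eco <- assess_ecological_risk(samples)
eco$sites
#> # A tibble: 6 × 6
#>   site              zone     ri ri_category    sri sri_category
#>   <chr>             <chr> <dbl> <chr>        <dbl> <chr>
#> 1 Angasmayo         lower 263.  considerable  6.09 high
#> 2 Colpa             upper 122.  moderate      3.10 moderate
#> 3 La Perla          lower 283.  considerable  6.09 high
#> 4 San Blas          lower 261.  considerable  6.20 high
#> 5 San Juan de Jarpa upper 115.  moderate      2.67 low
#> 6 Yanacancha        upper  78.5 low           2.78 low

hh <- assess_health_risk(samples)
head(hh$summary, 4)
#> # A tibble: 4 × 7
#>   site      zone  receptor     hi        tcr hi_category   tcr_category
#>   <chr>     <chr> <chr>     <dbl>      <dbl> <chr>         <chr>
#> 1 Angasmayo lower adult    0.0782 0.0000126  insignificant acceptable
#> 2 Angasmayo lower child    0.706  0.0000282  insignificant acceptable
#> 3 Colpa     upper adult    0.0494 0.00000798 insignificant acceptable
#> 4 Colpa     upper child    0.446  0.0000178  insignificant acceptable

compare_zones(samples, elements = c("Zn", "Cd", "As"))
#> # A tibble: 3 × 6
#>   element n_upper n_lower statistic   p_value method
#>   <chr>     <int>   <int>     <dbl>     <dbl> <chr>
#> 1 Zn           12      12         9 0.000308  normal approximation
#> 2 Cd           12      12         1 0.0000469 normal approximation
#> 3 As           12      12        14 0.000901  normal approximation
```

The downstream (lower-zone) sites carry considerable ecological risk —
driven by Cd and As, whose contamination factors exceed 4 and 10 — while
upstream sites stay low-to-moderate. Health-risk hazard indices stay below
1 for both receptors under the default exposure profiles, with children
closer to the threshold, and total carcinogenic risk sits inside the
10⁻⁶–10⁻⁴ acceptability band. The rank-sum tests confirm the zone
contrast for Zn, Cd and As.

One-off index calls work on plain numbers too:

```r
contamination_factor(0.4, 0.1)   # Cf = 4, "high"
geoaccumulation_index(0.4, 0.1)  # Igeo = 1.42, "moderately polluted"
```

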