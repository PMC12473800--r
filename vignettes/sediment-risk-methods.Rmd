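---
title: "Methods: sediment contamination indices and risk models in sedrisk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sediment contamination indices and risk models in sedrisk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sedrisk)
```

`sedrisk` implements the standard assessment battery for heavy-metal
contamination of river sediments: per-element contamination indices, the
Hakanson potential ecological risk model, a rank-based site ranking index,
and EPA-style human health exposure modelling. This vignette documents the
models, their assumptions, the parameter tables the package ships, and the
design choices made where the conventions in the applied literature are
genuinely ambiguous.

## Input model

The measured input is a tidy table of sediment samples: one row per
(site, month, replicate) with a `zone` label (`upper`/`lower`, reflecting
the common upstream/downstream contrast in mining-impacted basins) and one
column per element, in mg/kg dry weight. Concentrations must be
non-negative; missing values are explicit `NA`s, never silent zeros.
Values below an element's limit of quantification can be substituted by
LOQ/2 (default when enabled), LOQ, zero, or dropped — substitution for
censored values is the pragmatic default in this literature, and the
choice is exposed because it matters for elements near their LOQ. The
shipped LOQ table (0.01 mg/kg for As, Cd, Cr, Cu, Mn, Ni; 0.02 for Pb,
Sb; 0.05 for Mo; 0.10 for Zn; 0.50 for Fe) reflects ICP-MS practice with
0.5 g digests.

Unless stated otherwise, indices and risk quantities are computed on
**site means** — the dispersion across replicates is deliberately not
propagated (point-estimate assessment, as is standard for these indices);
`stat = "max"` gives a worst-case variant, and `per = "sample"` computes
indices per row. Zone summaries use the sample SD convention (n − 1),
matching mainstream statistics software.

## Contamination indices

For element concentration $C$ and geochemical background $C_b$:

* **Contamination factor** $Cf = C / C_b$.
* **Geoaccumulation index** $I_{geo} = \log_2\!\big(C / (1.5\,C_b)\big)$;
  the 1.5 buffers natural lithological variability. The identity
  $I_{geo} = \log_2(Cf/1.5)$ is exact and is regression-tested at
  $10^{-12}$ relative tolerance.
* **Enrichment factor** $EF = (C/Fe)\,/\,(C_b/Fe_b)$, with Fe as the
  geochemically stable reference element. $EF > 1.5$ (strictly) flags
  anthropogenic enrichment.
* **Pollution load index** $PLI = (\prod_i Cf_i)^{1/n}$ and **modified
  contamination degree** $mCd = \frac1n \sum_i Cf_i$ per site, over the
  twelve-element default index set (Hg is measured but excluded, mirroring
  the usual twelve-element battery). By AM–GM, $mCd \ge PLI$ always — a
  property test guards both implementations.

**Band closure.** The applied literature prints ranges like "Cf 1–3"
without stating closure. The package uses left-closed/right-open bands
(`[a, b)`) except where a classification is conventionally quoted in
strict form: `Cf < 1` is low (so `Cf = 1` is moderate), `EF > 1.5` is
strict, and Igeo uses the right-closed Müller classes
($\le 0$, $(0,1]$, ..., $> 5$). Every boundary case has a unit test. A
zero concentration makes $I_{geo} = -\infty$; rather than erroring, the
category is the sentinel `"below scale"`.

**Backgrounds.** Two baselines ship as YAML configs: the upper continental
crust averages (Taylor & McLennan 1995; the default, more sensitive to
anthropogenic enrichment for As, Cd, Sb) and the average-shale standard
(Turekian & Wedepohl 1961). User baselines load from the same format;
element symbols are validated against a canonical list and values must be
strictly positive since they sit in denominators.

## Ecological risk

Per element, $E_r = T \times Cf$, with dimensionless toxic response
factors $T$ in the Hakanson lineage (Hg 40, Cd 30, As 10, Cu/Pb/Ni 5,
Sb 7, Cr/V 2, Zn/Mn/Mo 1; shipped as an editable config with per-element
provenance). The **potential ecological risk index** is $RI = \sum E_r$
over the risk element set, banded low ($\le 95$), moderate ($\le 190$),
considerable ($\le 380$), very high ($> 380$) — the printed inequalities
are honoured literally at the boundaries even though they differ from
Hakanson's original 150/300/600 bands. The default RI element set is the
ten elements of the index battery with defensible published $T$ factors
(As, Cd, Cr, Cu, Mn, Ni, Pb, Sb, V, Zn — Fe and Mo excluded); it is a
plain config list because the ten-element choice is an interpretation, not
a law.

**Site ranking index.** The SRI formula
$W = \sum n_i / \sum i, \; SRI = (W/S) \times 100$ is under-determined as
usually quoted: it does not fix what the ascending ranks $n_i$ are taken
over. The package isolates the bare formula in `site_ranking_index()`
(rank table in, SRI out; $n_i$ averaged over the Cf-based and Igeo-based
orderings, ties by average rank), so alternative conventions can be
swapped, and a brute-force enumeration oracle over all rank assignments of
size $\le 5$ guards it. For data, `assess_ecological_risk()` derives each
site's ranks **across the site collection**: for each contaminant, sites
are ranked ascending by site-mean Cf (and by Igeo — the two orderings
coincide because Igeo is monotone in Cf, but both are computed and
averaged as the definition asks). A purely within-site ranking would make
$\sum n_i = \sum i$ identically and collapse SRI to the constant $100/S$;
the cross-site convention preserves the identity-ranking special case
($n_i = i \Rightarrow SRI = 100/S$) while actually discriminating sites.
SRI categories are assigned across the site collection by median ± SD
(low < median − SD ≤ moderate < median ≤ high ≤ median + SD < severe);
with identical sites the SD is 0 and all sites collapse to the median
rule, a documented degenerate case. The categorisation is scale-free:
median and SD scale together.

## Human health risk

Chronic daily doses (mg/kg body weight/day) for receptor profiles:

$$CDD_{ing} = \frac{C \cdot IR \cdot ED \cdot EF}{ABW \cdot AET} \cdot CFU,\quad
CDD_{inh} = \frac{C \cdot IHR \cdot ED \cdot EF}{ABW \cdot AET \cdot PEF},\quad
CDD_{derm} = \frac{C \cdot SA \cdot SAF \cdot DAF \cdot ED \cdot EF}{ABW \cdot AET} \cdot CFU$$

A note on symbols: in parts of the applied literature the mass-unit
conversion factor ($10^{-6}$ kg/mg) is also written "Cf", colliding with
the contamination factor. The package names it **CFU** throughout.

The default exposure profiles are EPA RAGS-style values for incidental
sediment exposure, shipped as an editable YAML config (adult: ABW 70 kg,
IR 100 mg/day, IHR 20 m³/day, SA 5700 cm², SAF 0.07 mg/cm²·day, ED 24 y;
child: 15 kg, 200 mg/day, 10 m³/day, 2800 cm², 0.2, 6 y; both EF 350
days/y, PEF 1.36×10⁹ m³/kg, DAF 0.03 for As and 0.001 otherwise). Two
averaging-time conventions coexist: non-carcinogenic doses use
$AET_{nc} = ED \times 365$ (so ED cancels — a property test asserts it),
carcinogenic doses the 70-year lifetime $AET_{ca} = 25{,}550$ days. Both
are profile fields, so other conventions are one config edit away.

Non-carcinogenic risk: $HQ = CDD/RfD$ per element and route,
$HI = \sum HQ$; HI ≤ 1 is labelled insignificant (boundary included, per
the strict ">1" exceedance convention). Carcinogenic risk from
carcinogenic-averaged doses: $CR_{ing} = CDD \cdot SF_{ing}$,
$CR_{inh} = CDD \cdot IUR$, $CR_{derm} = CDD \cdot SF_{ing}/GIABS$. The
dermal term deserves a note: the formula battery in this literature often
prints a truncated dermal line; the package defaults to the standard
dermally adjusted slope factor ($SF_{ing}/GIABS$ — this is precisely what
the gastrointestinal absorption fraction exists for) and offers
`dermal_sf = "unadjusted"` for the plain $CDD \cdot SF_{ing}$ reading.
$TCR = \sum CR$ is classified no significant risk (< 10⁻⁶), acceptable
(10⁻⁶–10⁻⁴), unacceptable (> 10⁻⁴). IUR values are stored pre-converted
to (mg/kg/day)⁻¹ (unit risk per µg/m³ × 1000 × 70 kg / 20 m³/day) so the
inhalation product needs no further conversion; the conversion is
documented in the config's source note.

The shipped dose–response table covers the five priority metals As, Cd,
Cr, Ni, Pb with IRIS/RAIS-lineage values. Cd and Ni carry no oral slope
factor, so their ingestion/dermal cancer routes are skipped and flagged
(`routes_skipped`) rather than silently zeroed without record. The
health-risk element list is user-extensible by supplying a larger config;
five elements is the defensible core, since published oral/inhalation
constants for the remaining battery elements are inconsistent across
sources. Every health-risk number is a function of the configs — nothing
is hard-coded.

Contribution shares are $100 \cdot x_i / \sum x$ per element, separately
for HI and TCR; they sum to 100% whenever the total is positive and are
reported `NA` otherwise. All doses, HQ, CR, HI, TCR are homogeneous of
degree 1 in concentration — a property test scales a whole table and
checks the outputs scale identically.

## Zone comparison

`zone_compare()` tests an element's concentrations between zones with the
Wilcoxon rank-sum test: the exact two-sided distribution when the combined
n is ≤ 20 and tie-free, otherwise the normal approximation with tie and
continuity correction (delegated to `stats::wilcox.test`; an independent
full-enumeration oracle in the test suite verifies all splits with
n ≤ 8). Raw p-values are reported by default — multiplicity correction is
deliberately opt-in (`adjust = "holm"`) because the per-element tests are
descriptive here, not a confirmatory family.

## Synthetic data generator

The generator emulates the sampling design the package targets: six
stations in two altitudinal zones (three upstream, three downstream),
monthly wet-season replicates, thirteen elements. Concentrations are drawn
per (zone, element) from a lognormal moment-matched to target mean $m$ and
SD $s$:

$$\mu = \ln\!\frac{m^2}{\sqrt{m^2+s^2}}, \qquad
\sigma^2 = \ln\!\big(1 + s^2/m^2\big)$$

The lognormal was chosen because trace-element concentrations are
non-negative and right-skewed — in the built-in zone statistics several
elements have SD ≈ mean (As, Zn, Cd upstream), which a normal model would
violate with negative draws; a rejection-sampled truncated normal is
selectable (`distribution = "truncnorm"`), with the caveat that truncation
biases its realised mean upward when $s \sim m$. A zero target SD
degenerates to a point mass, so deterministic fixtures are exact.
Site-level heterogeneity is available as a multiplicative lognormal effect
(mean-one parameterisation) but **defaults to off**, so zone-level moment
tests are clean; the built-in statistics are zone-level and per-site
targets would be an interpolation the data does not support.

The built-in target table (`cunas_zone_stats()`) is the per-zone mean/SD
compilation for a mining-impacted Andean river (the Cunas basin); one
wrinkle: the compiled sources print the lower-zone Zn mean both as 101
(rounded) and 101.3 — the package uses 101.3 throughout. The V maxima are
absent from the source compilation and carried as `NA`.

What passing generator-based tests do **not** show: real sediment data
have spatial autocorrelation along the channel, seasonal hydrological
dynamics, inter-element correlation from shared sources (the generator
draws elements independently), and site-level systematic effects. The
generator is a statistical stand-in for pipeline testing, not a
geochemical model; conclusions about real rivers require real
measurements.

## Numerical and testing choices

* Tables written by `run_full_assessment()` round to 6 significant digits
  so re-runs are byte-identical and golden-file comparisons are stable;
  in-memory results are full precision.
* Kernel identities (Igeo–Cf, dose formulas vs independently coded
  single-expression oracles) are asserted at $10^{-12}$ relative
  tolerance; additivity properties at the same tolerance.
* Stochastic tests use fixed seeds and tolerances from standard-error
  arithmetic: the moment-recovery test draws n = 10,000 values (mean
  within 2%, ≈ 3.5 standard errors; SD within 5%) and the zone-contrast
  test uses 250 replicates per site per month. These sizes keep the whole
  suite under half a minute while leaving comfortable stochastic margins.
* Ranking ties (SRI, rank-sum test) break by average rank.
* Degenerate inputs fail loudly and early: empty tables, non-positive
  backgrounds, zero Cf in a geometric mean, missing toxicity/DAF/
  dose–response entries all raise errors naming the offending element.

## Known limitations

* Point estimates only — no probabilistic (Monte Carlo) exposure
  assessment, and replicate dispersion does not propagate into the
  indices.
* No fish-consumption or drinking-water pathways; incidental sediment
  contact only.
* The SRI convention, while oracle-guarded and isolated, is one reading
  of an under-specified formula; comparisons of absolute SRI values across
  software should not be expected to agree.
* Sediment-quality guideline columns (TEL/PEL) are carried in the
  reference statistics for context but no TEL/PEL-based quotient index is
  computed.
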