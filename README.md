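# nibam — acute nickel bioavailability normalization

`nibam` derives **site-specific acute hazard thresholds for nickel in
freshwater** (the HC5<sub>L(E)C50</sub>: the dissolved Ni concentration at
which 5 % of species experience at least 50 % effect). It is aimed at
ecotoxicologists and environmental risk assessors who need to normalize
heterogeneous acute L(E)C50 data to a common water chemistry before fitting a
species sensitivity distribution (SSD) — the machinery behind
bioavailability-based short-term quality standards such as a MAC-EQS or
PNEC<sub>intermittent</sub>.

## The model

Acute Ni toxicity is described with generalized bioavailability models
(gBAM), one per trophic level. For taxon *y* in water *i*:

```
L(E)C50_Ni2+ = 10^-(Q50_y + S_pH,y · pH term) · (1 + Σ_z K_CatzBL,y · (Cat_z^2+)_i)
```

* `L(E)C50_Ni2+` — the toxic level expressed as **free Ni²⁺ activity** (mol/L);
* `Q50` — the species' intrinsic sensitivity (−log₁₀ mol/L), stripped of
  chemistry effects;
* `S_pH` — piecewise log-linear pH slopes (no pH effect on invertebrates up to
  pH 8.0, slope 1.006 above it; algae 0.143 then 0.906 above pH 8.2; fish a
  single slope 0.324), accumulated segment-by-segment so predictions are
  continuous in pH;
* `K_CatBL` — biotic-ligand competition constants for Ca²⁺ and/or Mg²⁺. The
  **average invertebrate model** uses log K<sub>CaBL</sub> = 3.80 and
  log K<sub>MgBL</sub> = 3.32, obtained by averaging the three cladoceran
  models' constants on the linear K scale.

The pipeline: observed dissolved L(E)C50s are speciated to free-ion activities
(a transparent inorganic equilibrium engine with Davies corrections and a
documented single-site DOC binding model — or imported activities from an
external speciation code), inverted to per-record Q50s (**Direction 1**),
averaged per species (most sensitive endpoint retained), projected into a
target water (**Direction 2**), translated back to dissolved concentrations,
and summarized by an SSD: six candidate families fitted by maximum likelihood
to the log₁₀ values, best fit selected by the minimum Anderson–Darling
statistic, HC5 uncertainty from a seeded bootstrap (HC5-50 with a 90 % CI).

## Worked example

Every stage is testable offline through the synthetic generator, which draws
species sensitivities and test-water chemistries with known ground truth:

```r
library(nibam)
sim <- synthetic_toxdb(n_species = 24, records_per_species = 2, seed = 7)
db  <- screen_records(sim$records)     # retention rules + reasons
res <- derive_hc5(db, ecoregion_waters(), B = 500, seed = 7)
res
#> Site-specific acute HC5 thresholds (ug dissolved Ni/L)
#>                water_id n_species best_family hc5_best hc5_50  hc5_5 hc5_95
#>     Lake Monate (Italy)        24        norm    8.207  8.562  3.595  26.44
#>     Rhine (Netherlands)        24      gumbel   32.376 34.696 15.146  92.03
#>  Otter (United Kingdom)        24     weibull   24.190 24.237 11.014  71.87
#>   Teme (United Kingdom)        24     weibull   30.794 32.577 15.947  90.80
#>   Swedish Lake (Sweden)        24        norm    6.193  7.006  2.846  17.45
#>            Ebro (Spain)        24     weibull   36.399 37.624 16.205  92.96
#>   Ditches (Netherlands)        24       gamma   43.495 48.237 21.722 114.53
```

Each row is one target water: the SSD is refitted to the database normalized
to that chemistry, `best_family` is the minimum-AD distribution, `hc5_best`
the best-fit HC5 and `hc5_50 (hc5_5–hc5_95)` the bootstrap median and 90 % CI
in µg dissolved Ni/L. The soft, circum-neutral Swedish Lake scenario is the
most bioavailable (lowest threshold); the hard, DOC-rich Dutch Ditches
scenario the least. Absolute values here describe the *synthetic* database,
not any published one. Inspecting one water's fitted model:

```r
res[["Swedish Lake (Sweden)"]]$fit
#> Species sensitivity distribution: 24 species
#>  family converged     ad   hc5 note  best
#>    norm      TRUE 0.4319 6.193       TRUE
#>   logis      TRUE 0.4360 4.750      FALSE
#>  ...
#> Best fit: norm (min Anderson-Darling); HC5 = 6.193 ug/L
```

A thin command-line interface (`inst/cli/nibam.R`) exposes the same pipeline
as `speciate`, `screen`, `evaluate`, `normalize`, `hc5` and `simulate`
subcommands with seeded, manifest-stamped outputs.

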