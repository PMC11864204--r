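---
title: "Methods: acute Ni bioavailability normalization and site-specific HC5 derivation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: acute Ni bioavailability normalization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nibam)
```

## Scope and model structure

`nibam` turns a heterogeneous collection of acute nickel L(E)C50s — measured
in waters of very different pH, hardness and dissolved organic carbon (DOC)
— into a single site-specific hazard threshold, the HC5~L(E)C50~, for any
target water inside the approach's applicability window (pH 5.7–8.7,
hardness 12–290 mg CaCO~3~/L, the intersection of the three underlying
models' validated ranges).

Toxicity is modelled at the free-ion level with a generalized
bioavailability model (gBAM) per trophic level:

$$\mathrm{L(E)C50}_{\mathrm{Ni}^{2+}} =
  10^{-\left(Q50 + \sum_s S_{\mathrm{pH},s}\,\Delta_s(\mathrm{pH})\right)}
  \left(1 + \sum_z K_{\mathrm{Cat}_z\mathrm{BL}}\,(\mathrm{Cat}_z^{2+})\right)$$

where $Q50$ is the taxon- (or dataset-) specific intrinsic sensitivity on a
$-\log_{10}$ mol/L scale, $(\mathrm{Cat}^{2+})$ are free Ca^2+^/Mg^2+^
activities, and the pH effect enters as piecewise log-linear slopes
$S_{\mathrm{pH},s}$ with $\Delta_s$ the overlap of segment $s$ with
$(-\infty, \mathrm{pH}]$. **Anchoring the slopes cumulatively at the segment
bounds is a deliberate design choice**: it reproduces the two-step
normalization used for chronic Ni models (normalize to the breakpoint with
the low-pH model, then apply the high-pH slope on top) and guarantees the
predicted LC50 is continuous in pH. Applying the high slope on an absolute
pH scale instead would introduce a jump at the breakpoint and was rejected.
For the single-segment fish model the anchor (its lower applicability bound)
is arbitrary because $Q50$ absorbs any constant offset; what matters is that
one convention is used for both Direction 1 and Direction 2.

The shipped parameter sets (JSON, user-replaceable) are:

| model | log K~CaBL~ | log K~MgBL~ | S~pH~ segments | pH range | hardness |
|---|---|---|---|---|---|
| avg_invertebrate | 3.80 | 3.32 | 0 (5.6–8.0), 1.00635 (8.0–8.9) | 5.6–8.9 | 6.2–339 |
| algae | – | 3.30 | 0.143 (5.7–8.2), 0.906 (8.2–8.7) | 5.7–8.7 | 6.3–315 |
| fish | 3.60 | 3.60 | 0.324 (5.5–8.8) | 5.5–8.8 | 12–290 |
| d_magna | 3.10 | 2.47 | 0 | 5.7–8.1 | 6.2–292 |
| d_pulex | 4.20 | 3.60 | 0 | 5.6–8.3 | 16–161 |
| c_dubia | 3.30 | 3.30 | 0 | 6.3–8.1 | 15–253 |

The average invertebrate constants are the linear-scale means of the three
cladoceran models' constants (`average_constants()`: $\log_{10}$ of the
arithmetic mean of $10^x$), and its high-pH slope is stored at full
precision 1.00635 — the mean of the two source slopes 1.095 and 0.9177 —
and displayed as 1.006; a printed 1.01 elsewhere is treated as display
rounding. Two modelling assumptions are inherited as stated and not
re-derived here: Ca/Mg competition is taken as pH-independent above the
breakpoint (not evaluable from available data), and the algae model's Mg
competition is applied over its full pH range. Taxon assignment: algae →
algae model; fish and amphibians → fish model; all invertebrate groups and
plants → average invertebrate model (plants follow invertebrates because
multicellular plants show a Ca effect that the algae model lacks).

## Speciation engine

The original normalization work delegated speciation to a humic speciation
code whose settings are not reproducible here, so speciation is a
*pluggable* interface with two implementations:

1. **Reference engine** (`speciation_engine()`): inorganic 1:1 equilibria of
   Ni^2+^, Ca^2+^ and Mg^2+^ with OH^−^, CO~3~^2−^, HCO~3~^−^, SO~4~^2−^
   and Cl^−^ from a versioned, cited constants table
   (`stability_constants()`; 25 °C, infinite dilution; a van 't Hoff
   temperature correction was considered and deliberately left off), Davies
   activity coefficients ($A = 0.509$ at 25 °C with a small linear
   temperature adjustment), and an optional single-site DOC binding model:
   site density 6.5 µmol per mg C (0.65 active-fulvic fraction × 2 g FA per
   g C × 5 mmol sites per g FA), intrinsic log K = 5.1 for the deprotonated
   site with proton competition at an effective pKa of 8.0. The proton
   competition makes the conditional constant rise with pH (≈10^3.8^ at pH
   6.7, 10^4.5^ at pH 7.5, 10^4.9^ at pH 8.3), the qualitative behaviour
   humic binding models predict and the feature that makes soft, low-pH,
   moderate-DOC waters the most bioavailable scenarios. These DOC defaults
   are documented stand-ins, flagged by the engine id in every result.
2. **External adapter** (`speciation_result()`, `read_activities()`): free
   activities computed elsewhere pass through the pipeline identically.

Numerics: mass balances are solved by a damped multiplicative update
(equivalent to a diagonal Newton step in log concentrations, exact for the
1:1 stoichiometry used) to a relative residual of 10^−12^, inside an outer
iteration that makes the ionic strength self-consistent with the converged
species table; non-convergence raises an error carrying the residuals.
Dissolved inorganic carbon, when not measured, is derived from pH and
alkalinity assuming an open system (CO~2(aq)~ fixed by atmospheric pCO~2~;
carbonate alkalinity floored at zero). Hardness-only records are split
3:1 Ca:Mg on a molar basis. `dissolved_from_activity()` inverts the engine
by a monotone fixed-point iteration (relative tolerance 10^−9^), and
Direction-2 predictions are made *self-consistent*: the Ca^2+^/Mg^2+^
activities entering the gBAM are evaluated at the predicted LC50 level
itself, since mg/L-scale Ni contributes to ionic strength — this is what
makes Direction 1 the exact inverse of Direction 2 through the chemistry
layer (round trips hold to 10^−6^ relative in the tests).

Deliberate simplifications (documented limits, not bugs): no redox, no
solid phases, no Al/Fe competition for DOC sites, no Ca/Mg binding to DOC,
chloride treated as non-complexing except toward Ni, and no full
humic-ion-binding model.

## Screening and aggregation rules

`screen_records()` annotates, never raises, and applies in order: a
pre-screened reliability flag (judgement calls such as "insufficiently
described methodology" are an input column, not inferred); total-basis
values accepted only in artificial media (there total = dissolved);
taxon-specific acute duration windows (cladocerans exactly 48 h, algae
72 h, molluscs 96 h with glochidia at 48 h, anostraca 24 h, amphipods
48–168 h, insects/annelids/ostracods ≤ 96 h, plants 96–168 h, vertebrates
48–96 h — the nominal vertebrate duration is 96 h and the accepted window
follows the cited test guidelines); minimum chemistry (pH, DOC, Ca or
hardness); and the assigned model's pH/hardness applicability range. The
first failing rule becomes the single machine-readable rejection reason;
screening is idempotent. When a mollusc record lacks a life-stage column
the adult/juvenile 96-h window is used and the gap is visible in the
provenance.

Aggregation (`aggregate_species()`) averages record-level Q50s
arithmetically within (endpoint × duration) groups per species, then keeps
the group with the highest mean Q50 — the most sensitive endpoint, and for
multiple durations the most sensitive duration (highest Q50 ≡ lowest LC50).
Life stages are pooled.

## Performance metrics

`model_performance()` reports $r^2 = \max(0, 1 - SSR/SST)$ on log~10~
values (clamping keeps the metric in [0, 1]; constant observations leave it
undefined and reported missing), the factor of agreement (fraction within
2-fold; the boundary counts as *within* — the convention is unstated in the
source literature, so the inclusive choice is flagged here), residual
scores, and their mean, the MPS (displayed to two decimals). The residual
score formula used by the original evaluation lives in a reference we do
not reproduce; the package's **stand-in definition** is
$RS_f = 1 - |\mathrm{Pearson}\ r(\text{residuals}, f)|$ with factors pH,
DOC, Ca, Mg on their raw scales and arithmetic-mean aggregation. It
preserves the documented semantics (bounded [0, 1], 1 = unbiased) but
published Tot RS values are *not* comparison targets for it — only the MPS
aggregation arithmetic is. `calibrate_q50()` implements the dataset-level
calibration rule: the arithmetic mean Direction-1 Q50 over waters with Ca
and Mg each below 3 mmol/L.

## SSD fitting, selection and uncertainty

Six families (normal, log-normal, logistic, gamma, Weibull, Gumbel) are
fitted by maximum likelihood — via `fitdistrplus`, with in-package Gumbel
d/p/q/r functions — to the **log~10~-transformed** normalized values.
Families needing positive support are marked *inapplicable* whenever any
log~10~ value is ≤ 0 (i.e. values ≤ 1 µg/L); shifting the data would
silently change quantiles and is refused. Selection uses the
Anderson–Darling statistic computed from the fitted CDF (parameters
estimated from the same data); it weights the tails, which is where the HC5
lives. p-values are not used for selection and not reported. Exact AD ties
are broken by a fixed preference order (normal, log-normal, logistic,
gamma, Weibull, Gumbel) for determinism. The HC5 is $10^{q_{0.05}}$ of the
fitted distribution.

The uncertainty phrasing in the source approach ("parametric bootstrap …
with replacement") is internally contradictory. The default here is
**nonparametric**: resample the n species values with replacement, refit
the selected family (held fixed across resamples — redoing selection per
resample is the other reading of an ambiguous text and is intentionally not
the default), and report the 5th/50th/95th percentiles of the resampled
HC5; a parametric mode (sample n values from the fitted distribution) is
available behind `method = "parametric"`. B = 1000 by default, a seed is
required, and results with more than 20 % refit failures are flagged
unreliable. The reported point estimate is the bootstrap median HC5-50; the
full-data best-fit HC5 is also emitted for transparency.

## Synthetic data: what it does and does not emulate

`synthetic_toxdb()` emulates the *structure* of a curated acute Ni
database: ~40 species across a realistic taxon mix, a few records per
species, heterogeneous test chemistry spanning the applicability window
(pH 5.7–8.7, hardness 12–290 mg CaCO~3~/L, DOC 0–20 mg/L), and replicate
noise. Defaults, chosen once: Q50 ~ N(5.5, 0.7) — the sd matches the
roughly 0.7 log~10~ spread of species sensitivities seen in acute Ni data
and the mean puts dissolved LC50s near 10^3^ µg/L in typical waters — and
replicate noise sd $\log_{10}(2)/z_{0.95} \approx 0.183$, so that the 95 %
range of repeated tests is a factor of two. Minor ions follow a
reconstituted-water-style recipe with alkalinity scaled to hardness.
Records are generated through the *same* forward chemistry the pipeline
inverts, so noise-free generation is recovered exactly; that is a strong
self-consistency check but deliberately not evidence about real data,
where the speciation model is itself an approximation, sensitivities are
not normal, chemistry covaries (hard waters tend to have high pH) and
record counts per species are very unbalanced. `ecoregion_waters()`
provides the seven named European scenario chemistries for target-water
use.

Test problem sizes (the package's own choices, stated here for
reproducibility): round-trip identities use 1000 random model pairs and
150 random waters; parameter recovery uses 40 species × 3 records at seed
42 with a homogeneous invertebrate mix, so the generating dissolved
distribution in a fixed water is one monotone transform of the Q50 normal;
bootstrap coverage uses 200 replicate experiments at B = 1000 (the normal
family refits in closed form, vectorized); the ecoregion ordering property
uses 24 species × 2 records and B = 200. At n = 40 species the fitted HC5
carries a sampling SE of about 0.17 log~10~ units
($\sigma\sqrt{1/n + z^2/(2(n-1))}$), i.e. roughly ±50 % — single-database
HC5 point comparisons at much tighter tolerances are dominated by which 40
species were drawn, which is worth remembering when comparing any two SSD
exercises.

## Known limitations

The reference speciation engine is transparent but simplified; absolute
HC5 values in DOC-rich waters shift with the humic model used, which is
why externally computed activities can be injected and why engine ids are
stamped into results. Plant bioavailability is an acknowledged open issue
upstream (plants are normalized with the invertebrate model by decision,
not by demonstrated fit). The residual score is a labelled stand-in. No
assessment factors are applied: the HC5~L(E)C50~ is the scientific
quantity; turning it into a MAC-EQS or PNEC~intermittent~ is a regulatory
step outside this package.
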