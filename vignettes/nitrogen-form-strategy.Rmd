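---
title: "Quantifying nitrogen-form acquisition strategies with in-situ 15N labeling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying nitrogen-form acquisition strategies with in-situ 15N labeling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nitroform)
```

## The measurement model

Plants in mixed-N soils can acquire nitrogen as ammonium or nitrate, and the
balance between the two — and how plastically it tracks soil availability —
is an ecological trait in its own right. The in-situ design this package
analyses labels, in each quadrat and for each species, one individual with
¹⁵NH₄⁺, one with ¹⁵NO₃⁻, and leaves one as an unlabeled control. Forty-eight
hours later the plants are harvested and their whole-plant δ¹⁵N and N
concentration measured, together with the NH₄⁺ and NO₃⁻ pools of each
plant's own rhizosphere soil.

The tracer chain rests on three assumptions worth keeping in view:

* **Linearity in time.** Uptake over the incubation window is treated as
  linear, so amounts divide by `root biomass × time` to give rates. Nothing
  in the chain models depletion of the added label.
* **A well-mixed labeled volume.** The added ¹⁵N is assumed evenly dispersed
  in a soil cylinder of known geometry, so the added-tracer concentration is
  `dose / (π r² h × bulk density)`. With the defaults (360 μg, r = 5 cm,
  h = 15 cm, BD = 1.273 g cm⁻³) that is ≈ 0.240 mg ¹⁵N kg⁻¹ — small against
  typical native pools, which is what justifies the next point.
* **Tracer-level addition.** The pool-dilution step
  `actual = tracer uptake × C_available / C¹⁵N_added` reads the plant's
  uptake of the added label as a proportional sample of its uptake from the
  pre-existing pool. It ignores gross mineralization/nitrification during the
  window; the field protocol suppresses nitrification chemically, and the
  package treats that suppression as complete.

Two printed-formula issues in the source methodology are resolved here as
deliberate design choices. First, the tracer-uptake equation as usually
printed multiplies two percent-valued quantities by biomass and a bare
`× 1000`, which is off by a factor of 10 from its declared μg output; the
package uses the dimensionally consistent `(APE/100) × biomass × (N%/100) ×
10⁶` μg. Second, the percentage-similarity formula is implemented in its
standard form `PS = 100(1 − ½Σ|f − p|)`, which satisfies the calibration that
PS = 100 exactly when uptake fractions equal soil proportions.

## Parameters that matter

| parameter | unit | default | why |
|---|---|---|---|
| `dose_15N` | μg/plant | 360 | 0.5 mmol ¹⁵N L⁻¹ × 48 mL × 15 g mol⁻¹; consistency is checked by `dose_from_solution()` |
| `enrichment_nh4` / `enrichment_no3` | atom% | 99.12 / 99.21 | tracer-salt certificates; feasibility ceiling for simulated signals |
| `cylinder_radius`, `cylinder_depth` | cm | 5, 15 | labeled volume = harvested root volume |
| `bulk_density` | g cm⁻³ | 1.273 | makes the default cylinder hold ≈ 1500 g of soil, consistent with the protocol's per-gram dosing asides; override per site if measured |
| `incubation_time` | h | 48 | labeling-to-harvest window |
| `atm_at_percent` | atom% | 0.3663 | air-N₂ natural abundance; the δ↔atom% conversion uses 15R = 0.0036765 |
| `delta15N_sd` | ‰ | 0.2 | EA-IRMS analytical precision |
| `relative_sd_biomass`, `relative_sd_soilN` | CV | 0.25, 0.3 | between-quadrat heterogeneity typical of field mosaics; free parameters, not estimates |
| `alpha` | — | 0.05 | gate for letters, t tests, and the SMA elevation/shift sequence |

Whether `C¹⁵N_added` should come from nominal cylinder geometry or from a
measured soil mass per sample is not decidable from the protocol alone; the
geometry route is the default and every term of it is overridable.

## The indices and one interpretation choice

Per quadrat, the NH₄⁺- and NO₃⁻-labeled individuals are distinct plants, so
the proportional contribution `f` is computed from their actual uptake
*rates* (per gram of root), not amounts — rates are comparable across the
pair, amounts are not. The soil proportion `p` needs a single composition per
quadrat while each plant has its own rhizosphere measurement; the package
averages the two labeled plants' own records (`soil_scope = "pair"`), with
`"quadrat"` (all plants, including the control) as the alternative. Under
either choice the identities `f_nh4 + f_no3 = 1`, `β_nh4 + β_no3 = 0`, and
`PS = 100 − 100|β_nh4|` hold exactly and are enforced by tests.

β is tested against zero on its raw scale. The group comparisons
(ANOVA, between-species t tests, the mixed screen) run on inverse-normal
transformed β, but the transform does not preserve the zero point, so a
one-sample test on the transformed scale would not address "is this form
preferred?" — this is the one place the package departs from
"transform before all analyses".

PS is computed per quadrat pair and then averaged (the replicate count of the
cell means is the quadrat count), rather than on cell-mean fractions; the
per-quadrat route matches the replication the design actually has.

## What the simulator emulates — and what it does not

`simulate_dataset()` inverts the analysis: per-cell true actual uptake rates,
soil pools, biomass, and N concentration generate each labeled plant's atom%
by running the chain forward, then noise is added where measurement puts it —
normally in δ space (instrument precision), log-normally (mean-preserving)
for biomass and soil pools (positivity). Controls scatter around natural
abundance. The truth table `default_truth()` is *illustrative*: NH₄⁺-dominant
farmland/wasteland and NO₃⁻-dominant roadside soils; an invader that matches
soil proportions in farmland, prefers NH₄⁺ in wasteland and NO₃⁻ in
roadside; a native that prefers NO₃⁻ everywhere; a larger, lower
root:shoot invader. Rates were chosen so every labeled plant's expected APE
is ≥ 0.05 atom%, i.e. a signal-to-noise regime where the 0.2 ‰ δ precision
perturbs recovered rates by well under 1%.

The generator does **not** emulate: plant-to-plant heterogeneity in the true
uptake rates (within a cell, all plants share the cell's true rate — so the
within-cell spread of `f` under default noise is much smaller than a real
field study would show, and group tests on `f` are correspondingly
optimistic); spatial diffusion of the label; uptake dynamics within the
48-h window; organic-N uptake; and isotope-dilution corrections for N
transformations. A green parameter-recovery test therefore establishes that
the arithmetic chain and its inversion are correct and that the design's
replication is handled properly — not that the noise structure matches any
particular field system.

## Numerical and statistical mechanics

* **Negative APE** (control above labeled, possible under noise) is clamped
  to zero, flagged per row, counted in a warning, and the affected quadrat is
  excluded from the indices with an explicit reason — visible QC, never
  silent.
* **Degenerate tests**: zero-variance t-test inputs return the `t = 0, p = 1`
  (equal means) or `t = ∞, p = 0` (constant offset) conventions with a
  `degenerate` flag; a constant response downgrades the mixed screen to a
  degenerate report; all-tied input is an error for the quantile transform.
* **Quantile transform**: Blom scores `(r − 3/8)/(n + ¼)` with average ranks
  for ties — a deterministic function of ranks only.
* **Compact letter display**: insert-and-absorb on the Tukey-HSD p matrix;
  the letters satisfy "share a letter ⇔ pairwise p ≥ α", which is asserted as
  a property test against random p matrices.
* **Mixed screen**: `nlme::lme` with random intercepts for quadrats nested in
  sites. With one observation per physical quadrat the quadrat variance is
  confounded with the residual, so the quadrat level is dropped (site-only
  random intercept); with one site the screen downgrades to fixed-effects
  ANOVA, with a warning either way.
* **SMA comparison**: the slope is `sign(r)·sd(y)/sd(x)`. The common-slope
  test exploits the defining property that at a group's own SMA slope the
  residual axis `y − bx` and fitted axis `y + bx` are uncorrelated: the
  Bartlett-weighted profile `Σ −(nᵢ − 2.5)·log(1 − r²ᵢ(b))` is minimized
  over `b` (on the log scale, within a generous bracket around the group
  slopes) and referred to χ² with g − 1 df. A development-time Monte-Carlo
  check found weights `n`, `n − 2`, and `n − 2.5` all near-nominal at n = 50;
  the Bartlett convention was kept. Elevation (intercepts at the common
  slope) and shift (means of fitted-axis scores) are inverse-variance Wald
  tests using the asymptotic slope variance `b²(1 − r²)/(r²(n − 2))`; both
  are reported only when the common slope is not rejected, since neither is
  meaningful otherwise. Lines are screened for reporting at r² > 0.1 with
  p < 0.05, matching the field convention.
* **No multiplicity correction** is applied across response variables, by
  design; the output metadata records that.

## Limitations

Everything here is two-form (NH₄⁺/NO₃⁻): the index algebra generalizes to
more N forms, but `β` and `PS` are implemented for the dissolved-inorganic
pair only. The mixed screen is a contract around `nlme`, not a bespoke REML
implementation. The SMA elevation/shift tests use asymptotic Wald
approximations that ignore the covariance among group intercept estimates
induced by the shared common slope; their null calibration is checked by
simulation in the test suite but is approximate at small n. Simulated
datasets are a stated world, not a fitted one — none of the default truth
values estimate any real study's quantities.
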