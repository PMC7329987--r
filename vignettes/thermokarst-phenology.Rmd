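---
title: "Decomposing thermokarst effects on high-Arctic plant phenology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decomposing thermokarst effects on high-Arctic plant phenology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenokarst)
```

## The question and the design

Ice-wedge thermokarst subsides polygon troughs, collects meltwater and snow,
and — counterintuitively — cools the root zone through the short high-Arctic
summer. `phenokarst` implements the analysis chain for a fully factorial
plot survey of that gradient: two crossed factors, **ground state**
(control polar desert vs actively degrading thermokarst) and **polygon
feature** (elevated top vs subsided trough), with soil-temperature loggers
at 10 cm and plot-level phenophase censuses (initial leaf growth, first
leaf out, first flower bud, first open flower; Julian day of first
occurrence per species per plot). Plots submerged all season carry no
usable phenology and are removed up front (`filter_flooded()`).

Because troughs are rarer than tops in any real transect layout, the cell
sample sizes are unequal, which drives several choices below.

## Thermal metrics

Daily mean soil temperature per plot is the plain average of hourly
readings within a Julian day. **Thaw degree days** (TDD, °C·day) are the
sum of daily means strictly above 0 °C over the logged window; a day at
exactly 0 °C contributes nothing. Because loggers go in after snowmelt and
come out mid-season, TDD is interpreted as a *relative* measure of warmth
between microtopographies over a common window, never as a seasonal total.

**Cumulative TDD to a phenophase** takes the community-weighted date
(real-valued), floors it to a whole Julian day, and sums the positive daily
means up to *and including* that day. Inclusion of the cutoff day is a
design decision: the phenophase was already underway on the day it was
first recorded, so that day's warmth belongs to the accumulation. A cutoff
before the first logged day returns 0 with a warning rather than an error,
since early phenophases genuinely can precede logger installation.

## Community-weighted means: specific, fixed, intraspecific

Relative abundances are percent covers standardized to sum 1 within each
plot (`vegan::decostand(method = "total")`). For one plot and phenophase:

* **specific CWM** = Σ *w′ₛ xₛ* with *xₛ* the species' date observed in
  that plot,
* **fixed CWM** = Σ *w′ₛ x̄ₛ* with *x̄ₛ* the species' unweighted site-wide
  mean date,
* **intraspecific component** = specific − fixed.

The weights *w′ₛ* are renormalized over the *observed* species set, and —
crucially — the same set and weights are used for both variants. A species
with cover but no record for a phenophase drops out of both sums. This
keeps specific − fixed a pure within-species contrast; if the fixed CWM
kept unobserved species, composition and observation gaps would leak into
the "intraspecific" signal. How a field study handled this is typically
unstated, so the package takes the conservative reading and applies it
consistently everywhere. Plots with no observation at all for a phenophase
are simply absent from that phenophase's analyses, which is why residual
degrees of freedom differ between phenophases.

## Inference on an unbalanced factorial

All models are ordinary least squares on plot-level responses with
`ground_state * polygon_feature` (reference levels: control, top).
**Type II sums of squares** (`car::Anova`) are used throughout because the
design is unbalanced: each main effect is adjusted for the other, and the
interaction for both, equivalent to nested-model RSS differences. The test
suite verifies this equivalence against a hand-built QR/projection oracle,
and that type I = II = III on balanced data.

**Estimated marginal means** (`emmeans`) give cell means (covariate, if
any, at its grand mean over the analyzed plots) and main-effect means that
average cells with equal weight — not sample-size weight — per level of the
other factor. Pairwise cell contrasts use Tukey-Kramer adjustment
(studentized range, k = 4 cells, residual df from the full model). For two
means the adjustment collapses exactly to the unadjusted two-sided t-test,
which the suite checks to 1e−10. p-values are never adjusted across
phenophases or analyses; only within a contrast family.

The **ANCOVA** places cumulative TDD first
(`value ~ cum_tdd + ground_state * polygon_feature`) and asks whether the
factors explain residual variation once the thermal driver is accounted
for. The **regressions** are OLS of each phenophase CWM on (by default ln)
cumulative TDD. Transforms follow two config flags: `sqrt_ilg` applies a
square-root transform to the initial-leaf-growth CWM response (its
variance grows with its early-season mean), `ln_tdd` log-transforms the
cumulative-TDD predictor. Both default to on; both can be switched off to
probe sensitivity.

The **transect check** refits each two-way model with a transect random
intercept (`lme4`) and compares AIC. Maximum likelihood is used for both
fits — REML likelihoods are not comparable across models with different
fixed effects represented this way, and the fixed-model AIC comes from an
ML fit; REML remains available via an argument. A variance component
estimated at the boundary (0) is reported as a singular fit, not an error,
and costs the mixed model exactly 2 AIC.

## The variance decomposition

The central quantity: for each ANOVA term, how much of the specific CWM's
SS is species turnover, how much intraspecific change, how much their
covariation? The identical type II ANOVA is fitted three times — on the
specific CWM (**total**), the fixed CWM (**turnover**; fixed averages can
only vary through composition), and on specific − fixed
(**intraspecific**) — and **covariation** is the remainder per term. Each
type II SS is a quadratic form *yᵀAy* with a term-specific PSD matrix *A*
fixed by the design, so with *y*spec = *y*fix + *y*intra,

SS_total = SS_turnover + SS_intraspecific + 2·*y*fixᵀA*y*intra,

and the covariation column is exactly the cross term: additivity holds to
machine precision for every term, including residuals and the column-sum
"total" row. Covariation is negative when compositional and within-species
shifts pull the community date in opposite directions. When the sqrt
transform applies, specific and fixed are transformed first and
intraspecific is their transformed difference, so the identity holds on
the analyzed scale. A constant response (e.g. the fixed CWM when every
plot has identical composition) is assigned zero SS in every cell of its
column rather than being an error, since it genuinely carries no
variation.

One caution for readers of such tables: swapping the roles of specific and
fixed swaps the turnover and total columns and leaves intraspecific
unchanged, but the covariation column is *not* simply negated — it picks up
−2·SS_intra as well. The suite asserts the parts of the symmetry that
actually hold.

## The synthetic landscape generator

The generator exists so the full chain — including its statistical
guarantees — runs with no field data. Its defaults *are* the emulated study
conditions, chosen once from the design being modeled and not tuned:

* 80 plots, 20 per 2×2 cell, on 5 transects; 5 flooded thermokarst troughs.
* Julian window 179–200 (22 days), matching a post-snowmelt logger season.
* Control-top daily means ramp 1→11 °C (window TDD ≈ 132 °C·day);
  thermokarst −1.1 °C, troughs −1.4 °C, per-plot offsets (sd 0.6 °C),
  hourly noise sd 1.5 °C around a 3 °C diurnal sine. These place the four
  cell TDD means near 135/103/111/80, the ordering and rough magnitudes a
  polar-desert thermokarst site shows.
* 22-species pool, 5 unique to each ground state via moisture preference;
  one dominant widespread willow (`salix_arctica`: occupancy 0.8, mean
  cover 60% where present).
* Phenophase dates arise from a **cumulative-TDD threshold mechanism**:
  species-level thresholds (base 8/30/45/65 °C·day for the four
  phenophases, per-species offsets sd 6, wet-preferring species later by up
  to ~8 °C·day) are crossed by each plot's realized cumulative TDD; the
  crossing day plus a cell-level intraspecific shift, transect intercept
  and observation noise (sd 1.5 d), floored to an integer day, is the
  recorded date. Events not reached within the window stay unobserved.
  This construction builds in the ANCOVA's premise — dates track
  accumulated warmth — so the covariate stages are meaningfully testable
  rather than vacuously linear.
* A single seeded stream is split into four substreams (design, thermal,
  cover, phenology) in fixed order, so regenerating one table never
  perturbs another and bundles are byte-identical under a fixed
  (config, seed).

Named scenarios isolate mechanisms: `turnover_only` (thermal and
intraspecific habitat effects off; state differences arise purely from
composition, with a sharpened moisture–timing coupling and reduced
incidental noise so the compositional signal clearly dominates — the
dominant species, identical in both states, otherwise damps it),
`intraspecific_only` (identical composition everywhere;
fixed CWM exactly constant), `null` (no effects; used to calibrate the
interaction test's type-I error), and `paper_like` (depressed thermokarst
and trough TDD plus a +1 d thermokarst-trough shift; troughs end up 1–3 d
late through both channels).

What the generator does *not* emulate: spatial autocorrelation beyond the
transect intercept, snowmelt timing as a separate driver, hydrology,
species interactions, or observer error structure (censuses every second
day, misidentification). Passing tests therefore demonstrate the
*statistical machinery* — identities, calibration, recovery of configured
effects — not that any particular field system behaves like the generator.

## Numerical choices and degenerate inputs

* Julian dates are 1-based integers; CWM dates are real-valued.
* Strict inequality (> 0 °C) for TDD inclusion; cumulative cutoff day
  inclusive (see above).
* Renormalized weights are checked to sum to 1 within 1e−12; the
  decomposition additivity is asserted at 1e−8 relative.
* Degenerate designs fail loudly: empty cells (inestimable interaction),
  single-level factors, constant responses, constant covariates,
  all-flooded datasets, all-zero cover rows. Missing phenophase records are
  represented by absence, never sentinels.
* Problem sizes in the test suite: identities are exercised on 100 random
  landscapes at 10 plots per cell; scenario-recovery checks use 100 seeds
  of the 80-plot design; the null calibration uses 1000 seeds; the type II
  oracle 50 random unbalanced datasets. These sizes give Monte-Carlo
  precision comfortably inside the asserted bands (e.g. ±0.014 at rate
  0.05 with 1000 seeds).

## Limitations

* The decomposition follows the fixed/specific-average framework; it does
  not provide within/between-community trait-gradient partitions, nor
  bootstrap intervals on components.
* TDD is the only thermal index (no growing degree days — these communities
  leaf out below 5 °C), and the window is whatever the loggers covered.
* The AIC comparison evaluates a single random-intercept structure; no
  spatial correlation models.
* With real field data, exact reproduction of published tables can hinge on
  undocumented choices (weight renormalization, transform scope); the
  relevant flags (`sqrt_ilg`, `ln_tdd`) are exposed so both readings can be
  run side by side.
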