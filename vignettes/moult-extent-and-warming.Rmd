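---
title: "Modelling post-juvenile moult extent against climate warming"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling post-juvenile moult extent against climate warming}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(moultclim)
```

## The scientific problem

Juveniles of most Western-Palearctic passerines moult only part of their
nest-grown plumage in their first months. The extent of this partial moult
is limited by time and food, both of which are reshaped by a warming
climate: earlier breeding and delayed or shortened autumn migration
lengthen the window available for moult. `moultclim` provides the full
chain of analysis for testing whether moult extent has increased with
global mean temperature anomalies (GMTA), whether the two sexes respond
differently, and whether the sex difference scales with plumage
dichromatism — together with a synthetic-data generator that makes every
link of the chain verifiable by simulation.

## From feather scores to areas

A specimen record holds 0/1 moult indicators for 48 discrete wing and
tail feathers in eight tracts, plus continuous moulted proportions for the
lesser and median coverts whose many small feathers cannot be scored
individually. The moulted plumage area is the weighted sum of per-tract
moulted fractions and species-specific tract areas (mm²). Three choices
deserve note:

* **Per-tract areas are totals shared equally by the tract's feathers.**
  Only tract-level areas are available, so each greater covert carries a
  tenth of the GC area, and so on. The brute-force per-feather oracle in
  the test suite checks exactly this interpretation.
* **Missing scores rescale the denominator.** Museum skins are often
  damaged; a missing feather reduces the number of observed feathers in
  its tract rather than counting as non-moulted, so damage does not drag
  extent estimates toward zero. A tract with *no* observed feathers is an
  error, never a silent zero.
* **The annual index weights species equally.** Yearly means are means of
  species means, not of specimens, so heavily collected species do not
  dominate the cross-species trend. The index is min–max normalised; a
  series with fewer than two years, or with identical yearly means, is
  rejected rather than divided by zero. Years contributed by few species
  are retained by default (`min_species` = 1) and no smoothing is
  applied.

## The climate covariate

GMTA is an annual, global index expressed relative to the 1951–1980
reference mean. Two sources are composited: an instrumental record from
1880 and a pre-instrumental reconstruction for earlier years, with the
instrumental value taking precedence wherever both exist and a strict
no-gap requirement on the union. Lookup is exact by year — no
interpolation and no monthly structure, because a global annual index
cannot support inference at finer scales. Anomalies are used as published;
no re-baselining of the reconstruction is attempted.

## Per-species Gamma models

Moulted area is positive and right-skewed, with dispersion that scales
with the mean, so each species is modelled as Gamma with an *identity*
link: the mean is the linear predictor itself, and coefficients stay in
interpretable units (mm² per °C). The fitter is IRLS — for the identity
link, weighted least squares of the raw response with weights 1/µ² — with
step-halving whenever a step would make any fitted mean non-positive,
convergence declared at a relative log-likelihood change below 1e-10 (200
iterations cap). Because the Gamma likelihood factorises, the coefficient
estimates do not depend on the shape ν; ν is then estimated by solving its
score equation log ν + 1 − ψ(ν) = mean(y/µ − log(y/µ)), and the reported
log-likelihood is the full Gamma likelihood at the joint optimum. The
parameter count k includes ν so that AICc compares full likelihoods.

Candidate sets are hierarchical: monomorphic species (where sex cannot be
determined from plumage) get {intercept, +GMTA}; dichromatic species add
{+sex, +GMTA+sex, +GMTA×sex}, with the interaction only ever appearing
alongside both main effects. Sex is coded female = 0, male = 1, so a
negative interaction means a steeper female response to warming. A model
is *selected* only when the runner-up's ΔAICc strictly exceeds 2.00;
otherwise the selection is reported as `none`. The threshold is the
conventional ΔAICc ambiguity bound and is exposed as a parameter.

Operational rules: records with zero moulted area fall outside the Gamma
support and are dropped with a logged count; in dichromatic species
unknown-sex records are dropped and *all* candidates refitted on the
common sexed subset so AICc values stay comparable; a dichromatic species
with under 90% sexed records falls back to the monomorphic candidate set
(sex is untestable there, matching how unsexable species are treated)
rather than being discarded. Calendar year can be swapped in for GMTA via
`covariate = "year"` with identical machinery.

## The comparative stage

Species are not independent observations: closely related species share
evolutionary history. Cross-species regressions therefore use generalised
least squares under σ²·V(λ), where V is the Brownian-motion covariance of
the phylogeny (shared root-to-tip path lengths) and Pagel's λ multiplies
its off-diagonal entries — λ = 0 is phylogenetic independence, λ = 1 full
Brownian structure. λ is estimated by maximising the profile
log-likelihood (residual variance profiled out) over [0, 1]: a 21-point
grid locates the basin, golden-section search refines it, and ties break
toward the smaller λ because the profile can be flat or even bimodal at
ten species. λ is capped at 1; no extension toward the positive-definite
limit is attempted. Non-ultrametric trees are accepted with a warning
(the Brownian covariance stays well defined, but λ's interpretation
weakens).

Two summaries serve different purposes and both are reported: the residual
variance on n − p degrees of freedom keeps the F statistic consistent
with its OLS analogue (F = (r²/df1)/((1−r²)/df2), with df = (1, 8) for
ten species and one predictor), while the ML log-likelihood is the
quantity profiled over λ. r² compares the fit against the GLS
intercept-only model under the *same* V(λ̂). p-values are two-tailed at
α = 0.05. With λ fixed at 0 on an equal-depth ultrametric tree the whole
machinery collapses to OLS, which the test suite checks to 1e-8; λ = 1 on
an ultrametric tree is the independent-contrasts limit, so contrasts are
not implemented separately.

Two open choices were resolved as follows. The response trait for the
migration-strategy contrasts is the GMTA coefficient from the
best-supported GMTA-containing candidate of each species — using the
selected model alone would leave species with `none` undefined, and using
the full model in monomorphic species is impossible. The ornamentation
regression instead always takes the interaction coefficient from the full
GMTA×sex model, because the question itself is about that interaction and
coefficients must be comparable across species regardless of which
candidate won.

## What the generator emulates — and what it does not

The synthetic module generates the five inputs with the statistical
structure the analysis assumes: a pure-birth (Yule) ultrametric tree;
species intercepts, GMTA slopes and interaction deviations drawn from
multivariate normals with covariance sd²·V*(λ_true), V* normalised to unit
diagonal so λ_true sets correlation without inflating variance; a
quadratic-in-time anomaly series rising ≈ 2.0 °C over 1805–2016, centred
exactly on the 1951–1980 window; and Gamma specimen areas with
identity-link means, realised into per-feather scores by a deterministic
fill order (LC, MC, GC, CC, AL, T, R, PC, S, P — a coarse abstraction of
the typical passerine moult sequence) so that re-scoring a generated
record recovers the drawn area to within one feather's area.

Defaults were set once from the study design and a pre-run power
calculation, and describe a museum-scale dataset: 12 species of which 10
are dichromatic (mirroring the ten dichromatic species a comparative
ornamentation regression realistically has), 200 specimens per species
(collection-scale studies average ~200 per species), species start years
drawn from 1805–1864, intercept 1500 ± 150 mm² of ~7700 mm² total, GMTA
slope 400 ± 100 mm²/°C, male effect 100 mm², Gamma shape 20 (CV ≈ 0.22),
interaction noise 25 mm²/°C, and an ornamentation effect of −12 mm²/°C
per score unit across a 0–30 male−female score spread. With these values
the per-species interaction coefficient carries a sampling error of
roughly 90 mm²/°C, giving the ten-species ornamentation regression a
slope standard error near 3.4 and ~85% power at α = 0.05 — strong enough
to demonstrate end-to-end recovery, weak enough that the specimen-level
noise still matters. λ_true defaults to 0, matching the phylogenetic
signal actually estimated for this trait in comparative practice.

The generator does **not** emulate: real moult-sequence biology beyond the
fill-order abstraction; collection-effort biases over time (years are
uniform within each species' span, whereas real museum series are thin
early on); latitude or any spatial structure; aging or sexing error.
Passing recovery tests therefore shows the *estimators* are sound under
the assumed data-generating process, not that real moult data satisfy
those assumptions.

## Numerical choices and degenerate inputs

* Gamma fitting starts from OLS (falling back to a flat mean if OLS
  predicts a non-positive value), and aborts if no step-halving keeps all
  means positive. Responses ≤ 0 and rank-deficient designs error
  immediately with the offending observation or column named.
* AICc requires n > k + 1; smaller fits are legal but carry `NA` AICc,
  and the per-species driver skips species too small for the largest
  candidate with a warning.
* The shape score equation is solved on the log scale by bisection within
  [1e-8, 1e8]; exactly noiseless data (y ≡ µ) would push ν to infinity and
  is capped at 1e8.
* GLS solves use the Cholesky factor of V(λ); a singular V errors rather
  than being regularised. Profile evaluations at λ grid points reuse the
  same path, so the reported optimum provably dominates the grid.
* Determinism: every generator stage derives its stream from the master
  seed via `withr`, outputs carry no timestamps, and rerunning an
  identical configuration writes byte-identical files; each result table
  carries the manifest hash of the run configuration.

## Problem sizes

The validation experiments use deliberately moderate sizes chosen to make
the Monte-Carlo statements sharp while staying interactive: slope-recovery
and selection-calibration runs use 300 specimens per species over 50 and
200 simulated species respectively; λ-recovery uses 100 replicates of
50-tip trees per regime; the end-to-end experiment runs the complete
pipeline on 50 replicates of the default 12-species configuration.

## Known limitations

* The identity link admits negative fitted means for extreme covariates;
  step-halving guarantees positivity only at the data, so extrapolated
  predictions can be negative.
* Model-selection inference is conditional on the selected model; no
  post-selection correction is applied, in keeping with the ΔAICc
  reporting convention.
* With ten species, λ̂ is noisy (its profile is flat near small n);
  reported λ values at that scale should be read as regularisation, not as
  estimates of phylogenetic signal.
* The migration contrast treats distance as a two-level class at a
  configurable 2000 km cutoff when no class column is supplied; the
  underlying continuous distance is not modelled.
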