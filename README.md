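# moultclim

Passerine juveniles replace only part of their nest-grown plumage in the
post-juvenile moult, and how much they replace depends on the time and
resources available to them — both of which shift as the climate warms.
`moultclim` implements a complete, testable pipeline for asking whether
moult extent has tracked global mean temperature anomalies (GMTA) across
two centuries of museum specimens:

1. **Moult scoring.** Each specimen carries 0/1 moult indicators for 48
   wing and tail feathers (greater coverts GC1–10, carpal covert CC, alula
   AL1–3, primary coverts PC1–9, primaries P1–10, secondaries S1–6,
   tertials T7–9, rectrices R1–6) plus moulted proportions for the lesser
   and median coverts. The moulted plumage area of individual *i* is the
   tract-area-weighted sum

   A_i = Σ_t f_{it} · a_{st},

   where f_{it} is the moulted fraction of tract *t* (share of moulted
   feathers among those observed; the recorded proportion for LC/MC) and
   a_{st} the species-specific tract area in mm². A year-averaged,
   species-equal-weighted and min–max normalised **moult index** summarises
   the cross-species trend (lowest yearly mean = 0, highest = 1).
2. **Climate covariate.** An annual GMTA series (°C relative to the
   1951–1980 reference mean) composited from an instrumental record (1880
   onwards) and a pre-instrumental reconstruction, instrumental values
   taking precedence.
3. **Per-species models.** Identity-link Gamma GLMs, µ_i = x_i'β, fitted by
   IRLS with positivity-preserving step-halving and joint ML estimation of
   the Gamma shape. Candidates (intercept; +GMTA; in dichromatic species
   also +sex, +GMTA+sex, +GMTA×sex) are compared by
   AICc = −2ℓ + 2k + 2k(k+1)/(n−k−1), and a model is *selected* only when
   the runner-up trails by ΔAICc > 2.00.
4. **Comparative stage.** Phylogenetic generalised least squares under
   σ²·V(λ), where V is the Brownian covariance of the tree and Pagel's λ ∈
   [0,1] rescales its off-diagonals; λ is estimated by profile maximum
   likelihood (21-point grid plus golden-section refinement). This tests
   (a) whether the per-species GMTA response differs between migration
   strategies and (b) whether the GMTA×sex interaction coefficient declines
   with the male−female plumage-ornamentation difference.
5. **Synthetic data.** A generator that emulates all five inputs —
   pure-birth tree, phylogenetically correlated species coefficients,
   accelerating anomaly series, tract areas, Gamma-distributed per-specimen
   areas realised into per-feather scores — so every stage of the pipeline
   can be validated by parameter-recovery experiments without access to
   collection data (which, for the original study system, are available
   only on request).

The package is aimed at comparative ecologists working with museum moult
records or analogous per-specimen trait scores.

## Worked example

```r
library(moultclim)

d   <- simulate_moult_dataset(synth_config(seed = 42))
res <- run_full_analysis(d)
res
#> Moult-vs-warming analysis: 2400 specimens, 12 species analysed (0 excluded)
#>   GMTA-containing model selected for 8/12 species; 'none' for 4
#>   Ornamentation regression: slope = -9.217, r2 = 0.565, F1,8 = 10.37, P = 0.0122, lambda = 0.00

dplyr::select(res$species_fits, species_id, n_used, selected, gmta_coef, interaction_coef)
#> # A tibble: 12 × 5
#>   species_id n_used selected gmta_coef interaction_coef
#>   <chr>       <int> <chr>        <dbl>            <dbl>
#> 1 sp01          200 gmta*sex      423.            -527.
#> 2 sp02          200 gmta*sex      308.            -216.
#> 3 sp03          200 none          444.            -101.
#> # …

res$ornamentation_fit
#> PGLS fit (lambda ML = 0.000), n = 10 species
#>               estimate        se          t          p
#> (Intercept) -35.322636 64.439617 -0.5481509 0.59854644
#> orn_diff     -9.216943  2.862028 -3.2204239 0.01223141
#> r2 = 0.565, F1,8 = 10.371, P = 0.0122, logLik = -58.669
```

Reading the output: every species' `gmta_coef` is the change in moulted
area (mm²) per °C of warming — positive throughout, and decisively
supported (a GMTA-containing model selected) for 8 of 12 species. In the
dichromatic species the negative `interaction_coef` means females respond
more steeply than males, and the PGLS slope of −9.2 mm² · °C⁻¹ per
ornamentation unit (P = 0.012, λ̂ = 0) shows this female bias growing with
the ornamentation gap between the sexes — the structure the generator
built in, recovered end to end.

`autoplot(res$moult_index)`, `autoplot(res$species_fits$selection[[1]])`
and `autoplot(res$ornamentation_fit)` draw the index trend, a ΔAICc
candidate comparison, and the ornamentation regression; `tidy()` and
`glance()` give broom-style summaries of the fitted objects.

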