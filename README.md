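# burnadjoint

Receptor-oriented attribution of PM2.5 population exposure to
crop-residue-burning emissions, with the downstream health and economic
chain: adjoint sensitivities of a linear transport model, an
integrated-exposure-response (IER) mortality estimate with Monte Carlo
uncertainty, a benefit-transferred Value of Statistical Life (VSL), and
intervention experiments (within-day timing shifts of a triangular burning
profile, marginal per-region reductions, two-axis district
categorization). Everything runs on a fully synthetic, seeded world, so
the whole chain is testable offline — the package is for method
development and teaching, not for reproducing observed impact magnitudes.

**Who it is for.** Air-quality and health-impact modellers who want a
small, fully verifiable implementation of the adjoint attribution pattern:
exposure cost function → transpose sensitivities → inner-product
attribution → IER deaths → VSL cost, with every linear-algebra identity
and conservation law under test.

## The method in brief

The exposure metric is
`J = Σ_ijt ρ_ij χ_ijt` (person·µg m⁻³), for population ρ and surface
PM2.5 χ, optionally masked to one country or to cells above 400 or
1000 people km⁻² density. The forward model is linear
(`χ_t = M χ_{t−1} + c_t E_t`: upwind advection, diffusion, deposition, and
emission injection diluted by a diurnal mixing-depth cycle peaking at
13:00–14:00), so sensitivities `S_ijt = ∂J/∂E_ijt` come from one backward
sweep with the exact transpose `Mᵀ`, and the contribution of every
emission element is the inner product `ΔP_ijt = S_ijt · E_ijt`. Deaths per
cause follow `RR(χ) = 1 + α(1 − e^{−β(χ−χ₀)^δ})` via the attributable
fraction `[RR(χ) − RR(χ−Δχ)]/RR(χ)`, and the monetized cost is
deaths × VSL with `V_y = V_US1990 (G_y/G_1990)^0.7 (D_y/D_1990) R_y^1.5`,
all propagated over 1000 paired Monte Carlo draws.

## Worked example

```r
library(burnadjoint)

w  <- make_world(world_config(seed = 1))            # 6x6 grid, 60 days, hourly
Ed <- make_emissions(w$crops, w$regions, w$grid, seed = 1, seasons = w$seasons)
k  <- build_triangular_kernel()                     # 95% in 06:30-19:30, peak 14:30
Eh <- apply_kernel(Ed, k)

mask    <- w$regions$country_id == 1                # receptor: the main country
S       <- build_adjoint(w$transport, w$grid, w$pop, mask)
contrib <- attribute_exposure(S, Eh)
aggregate_contribution(contrib, w$regions, "state")
#>        key delta_P_person_ugm3 share_percent
#> 1 state_01           1.225e+11        83.885
#> 2 state_02           2.298e+10        15.729
#> 3 state_03           5.638e+08         0.386
```

The upwind breadbasket (state_01) holds 84% of the attributable exposure:
cutting its emissions by 1% cuts total impacts by 0.84%. The adjoint
estimate is verified against paired forward runs:

```r
consistency_check(w, Eh, mask)$rel_discrepancy
#> 4.18e-16          # exact-transpose adjoint; anything <= 0.10 would pass
```

Health and valuation (synthetic magnitudes — the structure, not the size,
is the point):

```r
dchi <- contrib$total / (sum(w$pop[mask]) * w$grid$n_steps)  # 2.55 ug/m3
base <- sum(w$background_chi[mask] * w$pop[mask]) / sum(w$pop[mask]) + dchi
attributable_deaths(dchi, base, w$demography, w$ier, sum(w$pop[mask]))
#> <mortality_estimate> 1081 premature deaths (95% CI: 907-1252)

monetize(.Last.value, vsl_transfer(w$econ, 2015, 1000, seed = 1))$cost_mean / 1e9
#> 0.73   # billion USD (95% CI: 0.07-1.90)
```

Shifting the burning peak one hour earlier — onto the early-afternoon
mixing-depth maximum, where fresh emissions dilute into a deeper boundary
layer — reduces impacts; burning later increases them:

```r
timing_shift_experiment(S, Ed, k, shifts = c(-2, -1, 1))
#>   shift_hours pct_change_mean pct_change_min pct_change_max
#> 1          -2          0.0126         0.0126         0.0126
#> 2          -1         -3.7025        -3.7025        -3.7025
#> 3           1         10.7724        10.7724        10.7724
```

One command runs the whole chain and writes all tables, gridded fields and
a manifest:

```r
run_pipeline(NULL, out_dir = "out")    # or a JSON config path
```

or from the shell: `Rscript inst/cli/burnadjoint.R run --config cfg.json --out out`.

## Layout

- `R/world.R` — synthetic world generator (grid, population, regions,
  crops, transport config, demography, IER draws, econ series)
- `R/transport.R` — forward model, dense operator, exact adjoint
- `R/diurnal.R` — triangular kernel: build, shift, disaggregate
- `R/attribution.R` — cost function, masks, inner product, aggregation,
  per-unit metrics, efficacy, consistency check
- `R/health.R`, `R/valuation.R` — IER mortality and VSL monetization
- `R/interventions.R` — timing shifts, categorization, ranking
- `R/io.R`, `R/pipeline.R` — file contracts, config, end-to-end runner
- `vignettes/adjoint-attribution-methods.Rmd` — model, assumptions,
  parameter choices, limitations
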