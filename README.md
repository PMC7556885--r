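# hydrosub

Anomalous sub-diffusion analysis of biomolecular hydration water.

Water at protein surfaces, in crowded solutions and inside cells shows
sub-diffusive translational motion: its mean-squared displacement grows as
⟨x²(t)⟩ ∼ t^β with β < 1. `hydrosub` is an R package for researchers who
quantify this behaviour from two kinds of data:

* **quasi-elastic neutron scattering spectra** S(q, ν) on a (wave vector,
  frequency) grid, and
* **particle trajectories** (from molecular dynamics or simulation), as
  time-ordered coordinates.

It implements the full analysis chain:

1. **Susceptibility conversion** — χ″(q, ν) = S(q, ν) / n_B(ν), with the
   Bose factor n_B(ν) = 1/(exp(hν/k_B T) − 1).
2. **Cole–Cole fitting** per q:

   χ″(ν) = χ₀ (2πντ)^(1−α) cos(πα/2) / [1 + 2(2πντ)^(1−α) sin(πα/2) +
   (2πντ)^(2(1−α))]

   yielding the relaxation time τ (peak at ν = 1/(2πτ)) and the
   heterogeneity parameter α.
3. **q-scaling** — a power-law fit τ ∼ q⁻ⁿ gives the sub-diffusion
   exponent β = 2/n (n = 2 is Fickian; n > 2 sub-diffusive), plus ᾱ
   averaged over the 0.7–1.5 Å⁻¹ band and bulk-like water fractions
   (h − 1.2)/h from the bound-water budget.
4. **Residence times** — sequential first passage of each particle to a
   3.5 Å displacement threshold gives P(τ_res), its log-binned
   distribution, second moments, and per-hydration-layer (3.5 Å shells)
   versions above a planar surface.
5. **Random-jump CTRW simulator** — an event-driven 1-D walk with constant
   jump length and waiting times from exponential, Pareto or *empirical*
   P(τ_res) distributions, whose ensemble MSD is refitted for β. Driving
   the simulator with an extracted residence-time distribution and
   comparing with the directly fitted MSD exponent tests the claim that
   mobility heterogeneity causes the sub-diffusion.
6. **Synthetic data** — generators for Cole–Cole spectra (optionally in
   raw structure-factor form, with noise) and CTRW/layered trajectories
   with known ground truth, so the whole chain is testable end to end.

## Worked example

Synthesise susceptibility spectra that encode a sub-diffusion exponent
β\* = 0.8 (τ(q) = τ₀ q^(−2/β\*), α = 1 − β\*, 2% noise), fit them back,
and recover β via the scaling route:

```r
library(hydrosub)

spec <- subdiffusion_spectra_spec(0.8, q_values = seq(0.7, 1.5, 0.2),
                                  noise_level = 0.02, seed = 1)
fits <- fit_cole_cole_all(gen_cole_cole_spectra(spec))
fits
#>     q    tau  alpha   chi0   resid converged
#> 1 0.7 24.559 0.2010 0.9974 0.02167      TRUE
#> 2 0.9 13.017 0.2006 1.0000 0.02039      TRUE
#> 3 1.1  7.868 0.2002 1.0005 0.01944      TRUE
#> 4 1.3  5.184 0.2000 0.9965 0.01997      TRUE
#> 5 1.5  3.642 0.1993 1.0029 0.02065      TRUE

fit_power_law_tau_q(fits)
#> <scaling_result> n = 2.505 +/- 0.006 (R^2 = 1.0000, 5 points,
#>   q in [0.7, 1.5]) -> beta = 2/n = 0.798
```

The fitted τ fall from 24.6 ps at q = 0.7 Å⁻¹ to 3.6 ps at 1.5 Å⁻¹ —
relaxation is faster over shorter distances — and the log-log slope gives
n = 2.505, i.e. β = 0.798, recovering the encoded 0.8. The recovered
α ≈ 0.200 matches the generating 1 − 0.8.

The packaged table of published relaxation times works the same way:

```r
tab <- qens_relaxation_table()
fit_power_law_tau_q(tab[tab$sample == "h4.0", ])
#> <scaling_result> n = 2.164 +/- 0.291 (R^2 = 0.9823, 3 points,
#>   q in [0.9, 1.3]) -> beta = 2/n = 0.924

bulk_like_fraction(2.0); bulk_like_fraction(4.0)
#> [1] 0.4
#> [1] 0.7
```

A heavy-tailed random-jump simulation shows the mechanism directly —
Pareto waiting times with tail exponent 0.5 produce MSD ∼ t^0.5:

```r
simulate_rj(waiting_model("pareto", tail_exponent = 0.5, t_min = 0.05),
            step_length = 1, n_particles = 5000, t_max = 2000, seed = 2)
#> <rj_result> 5000 walkers, l0 = 1 Angstrom, t_max = 2000 ps: beta = 0.503
```

A YAML-configured end-to-end run (generate → convert → fit → scale →
residence → RJ) is available through `run_all()`; see
`inst/extdata/demo_config.yaml` and the command-line wrapper
`inst/scripts/hydrosub-cli.R`.

## Package layout

* `R/synthetic.R` — spectra/trajectory generators and waiting-time models
* `R/spectra.R` — Bose factor, susceptibility conversion, Cole–Cole fits
* `R/scaling.R` — τ ∼ q⁻ⁿ, β = 2/n, MSD computation and exponent fits
* `R/residence.R` — first-passage residence times, distributions, layers
* `R/ctrw.R` — random-jump simulator and β tables
* `R/pipeline.R` — config validation, orchestration, JSON report
* `vignettes/hydration-water-subdiffusion.Rmd` — models, assumptions,
  numerical choices and limitations
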