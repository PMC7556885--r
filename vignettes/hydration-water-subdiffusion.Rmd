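---
title: "Quantifying anomalous sub-diffusion of hydration water"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying anomalous sub-diffusion of hydration water}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hydrosub)
```

## The problem

Water at a biomolecular surface does not diffuse like bulk water. Its
mean-squared displacement grows as a fractional power of time,
$\langle x^2(t)\rangle \sim t^{\beta}$ with $\beta < 1$ — anomalous
sub-diffusion — and the effect strengthens as the water content drops, from
concentrated protein solutions down to hydrated powders with a single
monolayer of surface water. `hydrosub` implements the quantitative chain
that connects three observable levels of this phenomenon:

1. **Spectra.** Quasi-elastic neutron scattering measures the dynamic
   structure factor $S(q, \nu)$. Dividing by the Bose occupation factor
   $n_B(\nu) = 1/(e^{h\nu/k_B T} - 1)$ yields the susceptibility
   $\chi''(q, \nu)$, in which a relaxation process on timescale $\tau$
   appears as a peak at $\nu_{peak} = 1/(2\pi\tau)$.
2. **Scaling.** $\tau$ measured at wave vector $q$ is roughly the time to
   diffuse a distance $2\pi/q$. A power law $\tau \sim q^{-n}$ therefore
   implies $\langle x^2(t)\rangle \sim t^{2/n}$, i.e. $\beta = 2/n$:
   $n = 2$ is Fickian diffusion, $n > 2$ sub-diffusion.
3. **Mechanism.** At the single-molecule level, mobility is characterised
   by the residence time $\tau_{res}$ a molecule needs to move 3.5 Å (the
   radius of water's first coordination shell). A broad, heavy-tailed
   distribution $P(\tau_{res})$ — heterogeneous mobility — produces
   sub-diffusion, as formalised by the continuous-time random walk (CTRW):
   a walker making fixed-length jumps separated by waiting times with tail
   $\psi(t) \sim t^{-(1+\beta)}$, $0 < \beta < 1$, has
   $\langle x^2(t)\rangle \sim t^{\beta}$.

## The susceptibility model

Each $q$ slice is fitted with the Cole–Cole form

$$\chi''(\nu) = \chi_0\,
  \frac{(2\pi\nu\tau)^{1-\alpha}\cos(\pi\alpha/2)}
       {1 + 2(2\pi\nu\tau)^{1-\alpha}\sin(\pi\alpha/2)
          + (2\pi\nu\tau)^{2(1-\alpha)}},$$

a symmetric broadening of the Debye spectrum. $\alpha = 0$ recovers a
single relaxation timescale; larger $\alpha$ corresponds to a broader
underlying distribution of relaxation times, i.e. greater dynamical
heterogeneity. Two properties anchor the fit and are enforced by tests:
the peak sits at $1/(2\pi\tau)$ for *every* $\alpha$, and the peak
amplitude $\chi_0 \cos(\pi\alpha/2) / (2(1+\sin(\pi\alpha/2)))$ decreases
monotonically in $\alpha$.

### Fitting protocol

No standard fitting protocol exists for this model on neutron data, so the
package fixes one and documents it:

* weighted least squares; weights $1/\sigma^2$ when an error matrix is
  present, otherwise proportional to the local $\Delta\ln\nu$ so that a
  linearly spaced grid is weighted as if uniform in log-frequency;
* bounded Levenberg–Marquardt (`minpack.lm`) in
  $(\log\tau, \alpha, \log\chi_0)$ with $\tau \in [10^{-3}, 10^{6}]$ ps and
  $\alpha \in [0, 0.99]$;
* starting values $\tau_0 = 1/(2\pi\,\nu_{argmax})$, $\alpha_0 = 0.2$,
  $\chi_{0,0} = 2\times$ the observed peak, with fallback starts
  $\alpha_0 \in \{0.05, 0.5\}$;
* the convergence flag is false when the optimiser fails, the relative
  residual norm exceeds 0.25, the solution sits at a bound, or the slice
  has no interior maximum.

No additive background term is included and $\chi_0$ is free per $q$;
both are deliberate choices where the analysis convention is genuinely
open, and both are easy to revisit because the fit surface is a single
function. Energy-transfer axes in μeV are converted with
$E = h\nu$, $h = 4.135668$ μeV/THz; $k_B = 86.17333$ μeV/K.

## Units and key parameters

| Parameter | Unit | Default | Meaning |
|---|---|---|---|
| frequency | THz | — | spectral axis (μeV accepted via `energy_to_frequency`) |
| $\tau$ | ps | — | Cole–Cole relaxation time |
| $\alpha$ | — | — | heterogeneity (0 = Debye), $[0, 1)$ |
| q band for $\bar\alpha$ | Å⁻¹ | 0.7–1.5 | single-molecule translation window |
| MSD fit window | ps | 5–1000 | power-law fit range for $\beta$ |
| displacement threshold | Å | 3.5 | first coordination shell; defines $\tau_{res}$ |
| layer thickness | Å | 3.5 | hydration-layer shells above the surface |
| bound water | g/g | 1.2 | first two layers; sets the bulk-like fraction |
| temperature | K | 280 | Bose factor |

The bulk-like fraction at hydration level $h$ (g water / g protein) is
$\max(0, (h - 1.2)/h)$: 40% at $h = 2.0$, 70% at $h = 4.0$.

## The synthetic-data module

There are no deposited neutron datasets or MD trajectories to ship, so
every stage is validated against generated data with known ground truth.

**Spectra.** `gen_cole_cole_spectra()` evaluates the Cole–Cole model on a
(q, frequency) grid, optionally multiplies by $n_B(\nu)$ to emulate the raw
structure factor (so the conversion step is exercised as a true inverse),
and applies multiplicative Gaussian noise $(1 + \epsilon\,\mathcal N(0,1))$
truncated at zero. Multiplicative noise mimics the scaling of counting
error without a full Poisson model; the generated error matrix stores the
known noise scale so weighted fits are exact. What this does **not**
emulate: instrument resolution functions, detector-group artifacts, elastic
line contamination, or multi-component (rotational + translational)
spectra. A passing recovery test therefore shows the fitting machinery is
correct, not that resolution treatment on a real instrument is.

`subdiffusion_spectra_spec()` builds a series that encodes a target
exponent $\beta^{*}$: $\tau(q) = \tau_0\,q^{-2/\beta^{*}}$ and
$\alpha = 1 - \beta^{*}$. The $\tau(q)$ law makes the scaling route exact
by construction; the $\alpha$ mapping is a convenient monotone link
(heavier mobility tails, broader spectra) used to test *direction*, not a
claimed physical identity.

**Trajectories.** `gen_ctrw_trajectories()` is an event-driven CTRW:
fixed-length jumps along lattice axis directions (uniform over the $2d$
axis directions, not the sphere — this keeps the analytic MSD oracle
$\langle x^2 \rangle = l_0^2\,E[N(t)]$ exact), waiting times from an
exponential, Pareto ($\psi(t) = \beta\,t_{min}^{\beta} t^{-(1+\beta)}$,
inverse-CDF sampling) or empirical log-binned model, positions held
constant between jumps (wait-then-jump). `gen_layered_trajectories()` adds
a reflecting plane at $z = 0$ and selects the waiting-time model by the
walker's current 3.5 Å layer, emulating layer-dependent surface mobility.

## Numerical choices that matter

* **Observation grids.** The default grid is log-spaced (64 points from
  1 ps to $t_{max}$) plus a 0.25 ps uniform grid over the first 10 ps,
  because MSD fits span decades. For *residence-time extraction* a uniform
  grid must be used instead: on a log grid the late-time spacing (tens of
  ps) floors every late residence sample at the local frame spacing and
  manufactures a spurious heavy tail. The analysis functions accept any
  grid; the package's own studies use 0.5 ps uniform frames for residence
  work, like the MD they stand in for.
* **Ensemble vs time-averaged MSD.** `compute_msd()` averages over time
  origins on uniform grids (origins capped at $10^4$ per lag, subsampled
  evenly). For heavy-tailed CTRW ensembles this time average is *not* the
  quantity the theory predicts (aging/ergodicity breaking), so the RJ
  analysis uses `compute_msd_ensemble()`, the displacement from $t = 0$.
* **Asymptotic regime for Pareto waits.** The CTRW prediction
  $\langle x^2\rangle \sim t^{\beta}$ holds for $t \gg t_{min}$; the
  renewal-function corrections decay like $(t/t_{min})^{-\beta}$. With the
  5–1000 ps fit window the package's studies set $t_{min} = 0.05$ ps
  (a librational attempt timescale), putting the whole window 2–4 decades
  above the cutoff. Fitting with $t_{min}$ of order the window's lower
  edge measures a transient, not the exponent.
* **First passage.** Sequential reset (one sample stream per particle):
  the reference position resets at each threshold crossing, matching the
  CTRW picture of successive jumps. Crossings are recorded at the first
  frame at or beyond the threshold (no interpolation), so every sample
  carries up to one frame of quantisation. The trailing, never-completed
  interval of each particle is counted as censored and excluded from
  $P(\tau_{res})$ — including it would bias the tail. Censoring still
  truncates the observable tail at the trajectory length, which is why the
  RJ-vs-direct comparison below uses trajectories several times longer
  than the fit window.
* **Empirical waiting-time sampling.** A bin is chosen by mass, then the
  value drawn log-uniformly within the bin (bins are log-spaced;
  10 bins/decade by default).
* **Degenerate inputs.** All-zero or too-short spectra slices, single-frame
  trajectories, empty q bands and sub-surface coordinates raise typed
  errors; an RJ ensemble in which no particle jumps is returned flagged
  `degenerate` rather than fitted.

## The closure argument, tested synthetically

The package's central claim mirrors the experimental one: *the
distribution of microscopic mobility determines the sub-diffusion
exponent*. The test is a closed loop run entirely on synthetic data:

1. generate heterogeneous 1-D walks (exponential, Pareto 0.75, Pareto
   0.55 waiting times; 1200 walkers, 8000 ps at 0.5 ps frames);
2. fit $\beta$ directly from the ensemble MSD (window 5–1000 ps);
3. independently extract $P(\tau_{res})$ with the 3.5 Å threshold, drive
   the RJ simulator with it ($l_0 = 3.5$ Å, 3000 walkers), and fit
   $\beta$ again.

The two routes agree within 0.08 at every heterogeneity level, and across
a four-level series of increasing tail weight the recovered $\bar\alpha$
rises while $\beta$ falls with perfect rank correlation. At the same time
these remain *synthetic* demonstrations: lattice walks with literal
power-law waits, a planar surface, no spatial correlation between
successive jumps — real hydration water adds rotational coupling, surface
roughness and finite-instrument effects that no passing test here speaks
to.

## Problem sizes

The shipped studies are sized for a single CPU: $10^4$ walkers for the
CTRW asymptotics checks, 1200 × 16000 frames for the closure loop,
$10^5$ draws for distribution-level checks, 200-point frequency grids and
50 replicates for fit-recovery statistics. All are set in one place in the
tests and the acceptance script and scale linearly if more precision is
wanted.

## Worked example

```{r example, eval = FALSE}
# spectra with a known sub-diffusion exponent, fitted back
spec <- subdiffusion_spectra_spec(0.8, q_values = seq(0.7, 1.5, 0.2),
                                  noise_level = 0.02, seed = 1)
fits <- fit_cole_cole_all(gen_cole_cole_spectra(spec))
res <- fit_power_law_tau_q(fits)
res$n; beta_from_n(res$n)          # ~2.5, ~0.8

# published relaxation-time table: h = 4.0 triples
tab <- qens_relaxation_table()
fit_power_law_tau_q(tab[tab$sample == "h4.0", ])
```

## Known limitations

* No instrument-resolution convolution: spectra are treated as
  resolution-corrected.
* No multi-Lorentzian (elastic + quasielastic + background) decomposition.
* The RJ model is strictly one-dimensional with uncorrelated jump signs,
  as in the coarse-grained picture it implements; exponent comparisons are
  therefore exponent-only, never amplitude comparisons against 3-D MSD.
* Layer geometry is a plane; mapping residence statistics onto a real
  protein surface requires the original MD coordinates, which are out of
  scope.
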