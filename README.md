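# cyanogate

Stochastic modelling and inference of circadian-clock-modulated cell size
control in the cyanobacterium *Synechococcus elongatus*.

Cyanobacteria divide under two interacting controls: a cell size control
mechanism that couples the decision to divide to how much length a cell has
added since birth, and the circadian clock, which modulates the division rate
across the 24 h day. cyanogate implements a phenomenological model in which
the single-cell division rate is the product

```
Γ(L, L0, t) = S(Δ0) · G(τ(t)) · dL/dt,          Δ0 = L − (1 + a)·L0
```

of a Weibull-form size-control hazard `S(Δ0) = (k/λ)(Δ0/λ)^(k−1)` in the
birth-length-independent added length, a positive, smooth, 24 h-periodic
coupling function `G` (`G ≡ 1` for clock-deletion strains), and exponential
elongation `dL/dt = ζ α(t) L`. Around that core the package provides:

- **light environments and elongation models** — constant light, graded
  light–dark (LD) cycles flux-matched via `Imax = 24Aπ/(2TL)`, circadian
  oscillations of elongation rate, light-tracking growth (`light_profile()`,
  `elongation_model()`, `effective_coupling()`);
- an **exact stochastic simulator** of growing and dividing lineages and
  colonies (thinning with a monotone-hazard bound), plus the discrete
  time-lapse observation model with its previous-frame/next-frame recording
  convention (`simulate_lineage()`, `generate_dataset()`);
- **size-control estimation** from birth/division tables: life-table hazard
  estimates with bootstrap intervals, and a maximum-likelihood fit of
  `(a, k, λ)` with half-frame and measurement-noise bias corrections
  (`empirical_hazard()`, `fit_size_control()`, `regress_added_vs_birth()`);
- **Bayesian inference of the coupling function** from single-cell length
  traces via the analytical division likelihood, under a smoothness prior on
  a periodic spline, with a division-time-only variant (`infer_coupling()`,
  `infer_coupling_division_time()`);
- **population analyses**: fast/slow subpopulation detection, size-control
  classification (adder / sizer-like / timer-like), division-time windows
  after dawn, added-length-versus-birth-time trends
  (`cluster_subpopulations()`, `division_time_window()`, ...);
- a **pipeline driver** (`run_pipeline()`, YAML-configured) and CSV
  readers/writers for the cell-table and trace-table exchange schemas, plus a
  thin command-line wrapper in `inst/scripts/cyanogate.R`.

It is intended for quantitative microbiologists and modellers studying
cell-cycle/clock coupling in single-cell time-lapse data, and for
simulation-based validation of such analyses.

## Worked example

Simulate a clock-deletion population under constant light, estimate its size
control, then infer the coupling function of a wild-type population with those
parameters fixed:

```r
library(cyanogate)

cd <- generate_dataset("clockdel_constant", seed = 2)
#> Synthetic dataset 'clockdel_constant': 1555 cells (17 censored), 40934 trace points

fit <- fit_size_control(cd$cells, noise_sd = cd$config$noise_sd)
fit
#> Size-control MLE (half_frame correction), n = 1538 (+17 censored):
#>   a    =  -0.069  [ -0.136,  -0.020]
#>   k    =   2.864  [  2.682,   3.078]
#>   lam  =   3.543  [  3.371,   3.763]
```

The generator's truth is `a = -0.1, k = 3, λ = 3.7 µm`; each parameter is
recovered within its 95% profile-likelihood interval. The small negative `a`
means size control is close to an adder with a slight sizer-like tilt.

```r
wt <- generate_dataset("WT_constant", seed = 1)
post <- infer_coupling(wt$cells, wt$traces, fit$params,
                       dawn_offset = wt$profile,
                       n_iter = 3000, n_chains = 2, seed = 1)
post
#> Posterior coupling function at knots (mean [95% CrI]):
#>   tau =  0.0 h:  2.14 [ 1.86,  2.47]
#>   tau =  3.0 h:  0.89 [ 0.73,  1.09]
#>   tau =  6.0 h:  0.34 [ 0.25,  0.44]
#>   tau =  9.0 h:  0.23 [ 0.18,  0.31]
#>   tau = 12.0 h:  0.28 [ 0.22,  0.35]
#>   tau = 15.0 h:  0.47 [ 0.40,  0.53]
#>   tau = 18.0 h:  1.33 [ 1.21,  1.46]
#>   tau = 21.0 h:  2.67 [ 2.37,  2.96]
#> min ESS 116, max Rhat 1.031, acceptance 0.24/0.24
coupling_peak_time(post)
#> [1] 21.75
```

Time of day uses the entrainment convention dawn = 12, so the inferred
coupling is at a low basal level through subjective night and early day
(τ ≈ 3–15) and peaks near the end of subjective day (τ ≈ 22, close to the
generating peak), where it is roughly threefold the clock-deletion reference
level of 1.

```r
cluster_subpopulations(wt$cells, wt$profile, seed = 1)
#> Subpopulation clustering: 2 component(s) selected by BIC
#>      mean_birth_tau mean_duration_h   n
#> fast       21.03270        18.85289 831
#> slow       17.66675        20.32792 693
```

The same call on the clock-deletion table selects a single component: the
fast/slow split is a clock phenomenon.

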