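# gietr

Graphene-induced energy transfer (GIET) analysis of supported lipid
bilayer thickness, for membrane biophysicists and fluorescence
spectroscopists who want nanometer-resolved axial distances from
fluorescence lifetime data.

A fluorophore within ~25 nm of a single graphene sheet is quenched by
near-field energy transfer, so its fluorescence lifetime encodes its
height above the substrate. With both leaflets of a supported lipid
bilayer (SLB) carrying a small fraction of Atto655-labeled lipids, a
biexponential fit of the photon decay yields two lifetimes — bottom and
top leaflet — and the bilayer thickness follows as the difference of the
two inverted heights. gietr implements the complete chain:

* **Calibration** — the lifetime-versus-distance curve τ(z) from
  first-principles dipole electrodynamics above the stratified
  glass / graphene / 10 nm SiO₂ / water stack: the normalized decay rate
  S(z) is computed from wavevector-resolved reflection integrals
  (transfer-matrix reflection coefficients, s/p polarizations, horizontal
  dipole), spectrally averaged over the dye emission, and converted via
  τ(z) = τ₀ / (1 − φ + φ·S(z)) with τ₀ = 2.6 ns, φ = 0.36.
* **TCSPC fitting** — photon streams split into bunches of 10⁶ photons;
  each bunch's histogram fitted by Poisson maximum likelihood with an
  IRF-convolved double exponential plus constant background.
* **Iterative inversion** — z_top from the long lifetime on the bare
  curve; z_bottom from the short lifetime on the below-SLB curve, whose
  shape depends on the thickness d = z_top − z_bottom itself, solved by
  fixed-point iteration from d = 0 (converges in 3–5 iterations).
* **Synthetic data** — a seeded generator drawing photon streams from the
  exact forward model, so the whole pipeline is testable without raw
  measurement data.
* **Aggregation & trends** — mean ± SD of thickness over bunches, and a
  descriptive least-squares parabola of thickness versus cholesterol
  content.

## Worked example

```r
library(gietr)

# calibration curves for the default stack and Atto655 emitter
curve <- giet_calibration("none")
autoplot(curve)

# simulate a DOPC-like SLB: bottom leaflet 1 nm above the spacer,
# thickness 5.4 nm, 3 bunches of 1e6 photons
design <- scenario_design(lipid = "DOPC", true_z_bottom = 1,
                          true_thickness = 5.4, n_bunches = 3, seed = 11)
sim <- simulate_measurement(design)
round(c(sim$truth$tau_short, sim$truth$tau_long), 3)
#> [1] 0.868 1.748

# fit one bunch and invert the lifetime pair
hist1 <- bunch_photons(sim$stream)[[1]]
fit <- fit_biexponential(hist1)
fit
#> <giet_biexp> Poisson ML biexponential fit
#>   tau_short = 0.8664 ns (amp 4.85e+05), tau_long = 1.7392 ns (amp 4.95e+05)
#>   background = 6.44 counts/bin, 1000000 photons in 3125 bins

curves <- giet_curves()   # top curve + below-SLB family (cached)
estimate_heights(fit$tau_short, fit$tau_long, curves)
#> # A tibble: 1 × 5
#>   z_bottom z_top     d iterations converged
#>      <dbl> <dbl> <dbl>      <int> <lgl>
#> 1    0.995  6.34  5.34          3 TRUE

# or run the whole measurement at once
res <- analyze_scenario(scenario_design(n_bunches = 20, seed = 101),
                        curves = curves)
res
#> <giet_thickness>
#>   mean d = 5.401 nm, sd = 0.058 nm over 20 of 20 bunches (0 dropped)
```

The recovered thickness (5.40 nm) matches the simulated ground truth
(5.4 nm) to a few hundredths of a nanometer; the bunch-to-bunch standard
deviation (0.058 nm) is the photon-statistics floor at 10⁶ photons —
real measurements scatter more because of sample heterogeneity. Note the
reported heights include the dye/linker offset (~0.5 nm versus
headgroup-to-headgroup distances from scattering methods).

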