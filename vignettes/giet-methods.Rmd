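---
title: "Measuring lipid bilayer thickness with graphene-induced energy transfer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring lipid bilayer thickness with graphene-induced energy transfer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The measurement principle

A fluorophore near a single sheet of graphene is quenched by near-field
energy transfer, with an efficiency that falls off steeply over roughly
25 nm. Its fluorescence lifetime therefore encodes its distance from the
graphene: fully quenched on contact, bulk-like beyond ~25 nm. gietr
implements the full analysis chain that turns this effect into a thickness
measurement for supported lipid bilayers (SLBs): a first-principles
lifetime-versus-distance calibration, per-bunch biexponential lifetime
fitting of TCSPC photon streams, and an iterative inversion of the two
leaflet lifetimes into leaflet heights and bilayer thickness.

The substrate is a glass coverslip carrying the graphene sheet under a
10 nm SiO~2~ spacer; the SLB sits in water above the spacer, with a small
fraction of lipids carrying an Atto655 headgroup label in both leaflets.
All heights `z` are measured from the top surface of the spacer.

## The electrodynamic calibration model

The dye is treated as an ideal oscillating electric dipole at height `z`
in the aqueous medium. Its normalized total decay rate S(z) — dissipated
power relative to the same dipole in unbounded water — follows from the
classical theory of dipole emission near stratified media: S equals 1 plus
an integral over the normalized in-plane wavevector `q` of the
reflected-field correction, with the standard s/p-polarized integrands for
horizontal and vertical dipoles and effective reflection coefficients of
the half-spaces above and below the emitter obtained by the Parratt
transfer-matrix recursion. Square roots defining normal wavevector
components take the branch with non-negative imaginary part, so evanescent
waves decay. The near-field (`q > 1`) part of the integral is absorbed by
the graphene sheet; this is the energy-transfer channel that makes the
rate distance dependent.

The lifetime follows from the free-space lifetime and quantum yield of the
dye: only the radiative fraction of the free-space decay is modified by
the environment,

    tau(z) = tau0 / (1 - phi + phi * S(z)),

with the Atto655 defaults tau0 = 2.6 ns, phi = 0.36, and a horizontal
dipole (headgroup labels lie in the membrane plane). Because dye emission
is spectrally broad and graphene is dispersive, S is computed per
wavelength and averaged over the emission spectrum (resampled to 2 nm
steps, weights normalized) before the lifetime is formed once — rates
average, not lifetimes.

Key numerical choices:

* **Wavevector integral.** The integration variable is transformed
  (`q = sin(theta)` on the propagating branch, `q = cosh(t)` on the
  evanescent branch) so the 1/sqrt(1 - q^2) singularity at `q = 1`
  cancels. The evanescent tail is truncated where its exponential factor
  falls below 1e-12, with a hard cap `q <= 50`. Two integration paths
  exist: an adaptive quadrature (reference, tolerance 1e-10) and a fixed
  Gauss–Legendre rule whose panel edges are aligned with the square-root
  branch points of the stack's lossless materials (the SiO~2~ and glass
  indices), which is vectorized over heights and wavelengths and agrees
  with the adaptive path to better than 1e-6 relative. Curves and curve
  families use the fast path; tests cross-check both against a 10^6-node
  trapezoid oracle.
* **Graphene optical constants.** The packaged default dispersion table is
  computed from graphene's universal optical sheet conductivity (the
  pi-alpha ~ 2.3% single-pass absorption) mapped onto a homogeneous
  0.34 nm slab, eps = 1 + i alpha lambda / (2 t). Its absorptive part
  2nk agrees with published visible-range ellipsometry of graphene to a
  few percent. The table is an explicit, replaceable input
  (`read_dispersion()`), because computed distances — in particular the
  sub-nanometer displacement of the below-SLB curve — inherit some
  dependence on it.
* **Fixed default indices.** Glass 1.52, SiO~2~ 1.46, water 1.333, SLB
  slab 1.46; all overridable in `giet_stack()`.

## Membrane geometry variants

Calibration curves come in three variants. For dyes labeling the *top*
leaflet the membrane lies below the emitter; the computed curve differs
from the no-membrane curve by at most ~10 ps in lifetime (under half a
percent, below single-bunch fit precision), so the two are practically
indistinguishable and top-leaflet lifetimes are inverted on the bare
curve. For dyes labeling
the *bottom* leaflet the membrane slab (index 1.46, thickness d) sits
directly above the emitter and displaces the calibration curve to the
left — by up to ~0.6 nm at d = 8 nm — so bottom-leaflet inversion must
know the membrane thickness.

That creates the implicit problem the iterative inversion solves:
z_top is inverted once from tau_long on the bare curve; then, starting
from d = 0, z_bottom is inverted from tau_short on the below-SLB curve at
the current d and d is updated to z_top - z_bottom, until d changes by
less than 0.01 nm (iteration cap 20; in practice 3-5 iterations). The
below-SLB curves are precomputed on a d-grid (0-10 nm in 0.25 nm steps)
and interpolated linearly in d, which makes each iteration an
interpolation rather than a fresh electrodynamics solve and the fixed
point deterministic. Inversion itself uses a monotone (Hyman) cubic
interpolant of the sampled curve and bisection, restricted to the rising
branch up to the first local lifetime maximum; lifetimes beyond the
branch are reported as out-of-range errors rather than resolved by
tie-breaking, because the method operates entirely on the rising branch.

Two related design choices deserve a note. First, the horizontal
displacement between two curves (`calibration_shift()`) is evaluated only
up to 95% of the branch-maximum lifetime: on the approach to the plateau
the slope d tau/d z vanishes, and the horizontal distance between two
nearly flat curves degenerates into an ill-conditioned ratio that no
longer measures anything physical. Second, reported heights contain the
dye-linker offset: the label sits roughly 5 Å outside the headgroup
plane, so thickness values are systematically larger by about 0.5 nm than
headgroup-to-headgroup distances from X-ray or neutron scattering. No
offset subtraction is applied.

## TCSPC model and fitting

Decays are histogrammed micro-times (default: 50 ns window, 16 ps bins —
typical TCSPC hardware settings, both configurable). The fit model is a
double exponential convolved with a Gaussian instrument response (default
sigma = 100 ps, pulse offset 2 ns; sigma = 0 gives the idealized
delta-IRF limit) plus a constant background, integrated over each bin via
the closed-form exponentially-modified-Gaussian CDF evaluated on a log
scale for numerical safety. A constant background term is always
included: real TCSPC data have a dark/afterpulsing floor, and with 10^6
photons it is well identifiable.

Fitting maximizes the Poisson likelihood (not least squares, which is
wrong in the low-count tail). Parameters are optimized on the log scale
with `nlminb`; starting values come from the data (background from the
pre-pulse region, the long lifetime from a weighted log-linear tail fit,
the short lifetime from the early-time residual), and a second, perturbed
start guards against the shallow valley that closely spaced lifetimes
produce. Lifetimes are relabeled so tau_short <= tau_long; fits with
lifetimes closer than 1% are flagged as effectively mono-exponential and
excluded from aggregation, as are unconverged fits and lifetime pairs
falling outside the calibration branch (dropped, not clamped — clamping
would bias the mean).

## The synthetic-data generator

No raw photon data are distributed, so the generator stands in for the
microscope: it draws photon micro-times from the exact forward model of
the analysis chain. A scenario fixes the ground truth — bottom-leaflet
height z_bottom and thickness d — from which the two leaflet lifetimes
follow via the calibration model; photons are then background (uniform
over the window) with probability 0.02, otherwise bottom- or top-leaflet
(probability 0.5 each) with micro-times from the window-truncated
IRF-convolved exponential, sampled by exact inverse-CDF (fine-grid
interpolation polished with two Newton steps on the closed-form CDF).
Streams are reproducible from a single scenario seed with per-bunch
sub-seeds derived by a fixed offset.

Default study conditions mirror the experimental design: bunches of 10^6
photons, 20 bunches per scenario, a 3-lipid-by-4-cholesterol-level panel
with plausible true thicknesses in the 3.7-6.4 nm range, symmetric
leaflet labeling (0.5 — implied but not quantified experimentally; the
parameter is free), and 2% background (realistic yet small enough not to
distort the short component). The default ground-truth bottom-leaflet
height is 1 nm above the spacer: a supported bilayer rests on its
substrate across a thin (~1 nm) hydration layer. At that geometry the two
leaflet lifetimes (roughly 0.9 and 1.8 ns for d = 5.4 nm) are well
separated and carry high Fisher information; placing the membrane many
nanometers higher would push both lifetimes onto the flat part of the
calibration curve, where the biexponential fit can no longer distinguish
the leaflets at 10^6 photons.

What the generator does *not* emulate — and what passing tests therefore
do not show about real data: lateral sample heterogeneity (domains),
photobleaching, detector afterpulsing and dead-time, IRF misestimation,
and leaflet-dependent brightness. The observed bunch-to-bunch scatter of
recovered thickness (~0.06 nm at 10^6 photons) is accordingly an
instrument-statistics floor; the ~0.4-0.5 nm scatter of real measurements
is dominated by sample heterogeneity the simulation deliberately omits.

## Aggregation and trends

Each bunch is fitted and inverted independently; a measurement's
thickness is reported as mean ± sample standard deviation over retained
bunches, with dropped bunches counted and annotated. The dependence of
thickness on cholesterol content is summarized by an ordinary
least-squares parabola d(x) = c0 + c1 x + c2 x^2 — a descriptive guide to
the condensing (thickening) and thinning regimes, not a physical model.
The fit is unweighted by default (weighting is not part of the reference
procedure); an inverse-variance weighted option is available.

## Problem sizes and verification

The default calibration grid is 0-30 nm at 0.05 nm (601 points, ~66
spectral nodes after resampling); the below-SLB family holds 41 curves
and builds in well under a minute, cached per session. The test suite
verifies each component against an independent oracle: closed-form
Fresnel/Airy reflections, a 10^6-node trapezoid for the rate integral,
the textbook EMG CDF for the convolved decay, a profile-likelihood grid
scan for the fit optimum, Monte-Carlo recovery over 50 seeded histograms,
the normal equations for the parabola, and hand-computed sample
statistics for aggregation. End-to-end, a DOPC-like scenario (20 bunches
of 10^6 photons) recovers its true thickness to a few hundredths of a
nanometer with bunch-to-bunch scatter well below 0.5 nm, and the
iterative inversion converges in at most five iterations across the
plausible geometry range.

## Known limitations

* Absolute distances depend on the graphene optical-constant table and on
  the fixed layer indices; a measured dispersion table should replace the
  packaged default when available.
* The emission spectrum shipped with the package is a smooth synthetic
  stand-in for the measured Atto655 spectrum.
* Only the emission-rate/lifetime channel is modelled; excitation-field
  enhancement and detected intensities are out of scope, as are
  magnetic-dipole emitters and curved substrates.
* Inversion is restricted to the rising branch (~0-25 nm); lifetimes
  beyond it are reported as out-of-range.
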