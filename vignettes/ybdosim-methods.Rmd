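---
title: "Methods: Monte Carlo dosimetry of an HDR 169Yb seed"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Monte Carlo dosimetry of an HDR 169Yb seed}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ybdosim)
```

## The problem

High-dose-rate (HDR) brachytherapy sources must be characterized with the
AAPM TG-43U1 two-dimensional dose formalism (extended to high-energy sources
by the HEBD report) before clinical use:

$$\dot D(r,\theta) = S_K\,\Lambda\,
\frac{G_L(r,\theta)}{G_L(r_0,\theta_0)}\,g_L(r)\,F(r,\theta),$$

with reference point $(r_0,\theta_0) = (1\,\mathrm{cm}, 90^\circ)$. The
package characterizes an M42-type ytterbium-169 seed — a
0.6 cm Yb$_2$O$_3$ core in titanium and stainless-steel capsules with a
delivery cable — by (i) simulating photon transport from the encapsulated
seed through a 50 cm spherical water phantom and a vacuum/air-ring air-kerma
geometry, and (ii) extracting $G_L$, $g_L$, $F$, $S_K$, $\Lambda$ and the
fifth-order polynomial representation of $g_L$ from polar dose-rate tables,
whether simulated, synthetic, or the packaged published reference tables.

$^{169}$Yb decays by electron capture ($T_{1/2}\approx 32$ d) and emits a
~93 keV mean-energy photon spectrum: thulium K x-rays near 50–59 keV plus
gamma lines from 63 to 308 keV. The packaged line list
(`yb169_spectrum()`) is compiled from published nuclear-data evaluations;
its intensity-weighted mean is 93.6 keV and the total yield is 3.26
photons per decay. The dose-rate normalization assumes exactly
$3.7\times 10^{7}$ decays/s per mCi of contained activity.

## Source model

Only the active length (0.6 cm) of the characterized seed is published.
The remaining dimensions are package defaults on the scale typical of HDR
seeds, all overridable through `build_default_m42(config = ...)`:

| parameter | default | note |
|---|---|---|
| core radius | 0.025 cm | Yb$_2$O$_3$, 7.1 g/cm$^3$ |
| core (active) length | 0.6 cm | fixed by the characterized model |
| Ti capsule wall/cap | 0.01 cm | 4.51 g/cm$^3$ |
| SS-304 capsule wall/cap | 0.01 cm | 7.80 g/cm$^3$, published composition |
| cable stub | 0.045 cm radius × 0.2 cm | SS-304, on the $\theta=180^\circ$ side |

The choice matters mostly through self-absorption of the ~50 keV x-ray
complex in the dense core and capsule filtration; the stochastic validation
tolerances (10% on absolute dose quantities) absorb the residual dimension
uncertainty, and the TG-43 extraction itself is dimension-independent. The
cable is placed at $\theta = 180^\circ$; the published polar table shows
clear dose suppression toward 170–180°, which fixes this orientation
convention even though it is not stated explicitly alongside the tables.

## Photon interaction data

No cross-section library is assumed at run time. Per-element tables
(10–400 keV, ~50 log-spaced nodes with K-edge doublets for Mo and Yb) are
shipped as text under `inst/extdata/xsec/` and were generated by the
committed script `tools/make_xsec_tables.py`:

* **photoelectric** — from Cromer–Liberman imaginary anomalous scattering
  factors, $\sigma_{pe} = 2 r_e \lambda f''(E)$; this reproduces the Yb K
  edge at 61.33 keV with its jump ratio;
* **incoherent** — free-electron Klein–Nishina times $Z/A$;
* **coherent** — numerical integration of the Thomson cross section
  modulated by squared IT92 atomic form factors (continued as
  $F \propto s^{-2}$ beyond the fit validity);
* **$\mu_{en}/\rho$** — local photoelectric deposition (minus mean
  K-fluorescence escape above the K edge) plus the Klein–Nishina
  energy-transfer integral; radiative losses are neglected (<0.5% below
  400 keV).

Compound coefficients use the standard mass-fraction mixture rule.
Spot checks against well-known published values give agreement within
0.3% for $\mu_{en}/\rho$ of water and air above 60 keV and within ~2–3%
for total attenuation at the low end of the range, where neglecting
electron binding in the incoherent channel (a few %, largest below
50 keV) and the coherent form-factor continuation dominate the error
budget. These are fidelity limits of the physics model, stated here
because they propagate into the absolute simulated dose rates at roughly
the percent level — well inside the stochastic validation bands.

Compton scattering is sampled exactly from the free-electron
Klein–Nishina distribution with Kahn's composition–rejection method; the
scattered energy obeys the Compton kinematic relation for the sampled
angle exactly. Rayleigh scattering redirects the photon with an angle
sampled from the squared molecular form factor times the Thomson angular
factor (tabulated inverse-CDF in the squared momentum transfer, then a
$(1+\cos^2\theta)/2$ rejection). Doppler broadening, polarization, and
bound-Compton corrections are out of scope.

## Transport and scoring

Analogue transport (no variance reduction), single-threaded on R's random
stream, so a fixed seed gives bit-identical results. Photons below 10 keV
are absorbed on the spot; sub-10 keV photons have sub-millimetre range in
water and cannot reach the nearest scoring shell. Fluorescence after
photoelectric absorption is off by default (`fluorescence = TRUE` enables
a mean Yb K x-ray above the edge): capsule fluorescence falls below the
cutoff, and the Tm K x-rays that follow electron capture are already part
of the source spectrum.

Geometry is tracked by surface stepping: inside a bounding cylinder
around the seed, the free path competes against the distance to the
nearest region surface (nested finite cylinders, first-match priority);
outside it, against entry into the bounding cylinder and the phantom
sphere. A lost-particle counter guards the stepping loop and is asserted
to be zero in the tests.

**Water phantom.** Collision kerma is scored on spherical-shell ×
polar-cone bins (collision estimator: at each real collision in water the
expected transferred energy $E\,\mu_{en}/\mu$ is tallied; dose is taken
equal to collision kerma since the secondary electrons at these energies
are absorbed locally). The canonical grid matches the published tables:
radial nodes $\{0.5, 1, 2, \ldots, 10\}$ cm with ±0.25 cm shells, polar
nodes every 10° with ±2° apertures and full 3° cones at the two poles.
Shells are centred on the nodes (whether the original detector shells
were centred on or bounded by the reported radii is not stated; centred
is assumed). Bins are disjoint but not exhaustive — collisions in the
gaps are simply not scored. The two polar-cap bins at $r = 0.5$ cm
geometrically overlap the capsule ends; only water collisions are
tallied, so those bins carry a small (~4%) dead-volume bias, documented
rather than corrected. An alternative cylindrical $(R,Z)$ mesh scoring
mode is provided and re-binned onto the polar grid by volume-weighted
averaging (duplicate cells merged by inverse-variance weights;
$\theta$-mirror cells are never merged because the cable breaks the
transverse symmetry).

**Air kerma.** The seed sits in vacuum surrounded by an air ring
(shells 97.5/102.5 cm ∩ cones 88°/92°). Air kerma is scored with a
track-length estimator, $\sum \mathrm{d}l\, E\, (\mu_{en}/\rho)_{air}$,
each path element weighted by $(r/d)^2$ to reference the result to
$d = 100$ cm; $S_K = \dot K_\delta(d)\, d^2$. An analogue collision
estimator would see ~$10^{-4}$ collisions per history in the thin air
ring and be unusable at desk scale. The ring is treated as a
non-perturbing detector (attenuation across 5 cm of air, ~0.1%, is
neglected — consistent with the in-vacuo definition of $S_K$). Photons
below $\delta$ = 10 keV are excluded; the spectrum has no lines below
49 keV, so $\delta$ is inert here.

Per-bin relative uncertainties come from batch means (default 25
batches). The estimator is only trusted where each batch holds many
collisions; the $1/\sqrt N$ scaling property is verified in that regime.

## Extraction and reconstruction

`geometry_function_line()` evaluates $\beta/(L r \sin\theta)$ with the
exact on-axis limit $1/(r^2 - L^2/4)$, validated against brute-force
numerical line integration to $10^{-6}$ relative. `radial_dose_function()`
and `anisotropy_function()` apply the defining ratios and are exactly 1 at
their reference arguments by construction. Reconstruction interpolates
$g_L$ log-linearly in $r$ and $F$ bilinearly in $(r,\theta)$ — the
treatment-planning convention; the published work is silent on
interpolation — and refuses to extrapolate. Extraction followed by
reconstruction is the identity on grid nodes for any positive table
(exact algebra, no Monte Carlo involved), which the tests exploit.

The fifth-order polynomial fit of $g_L(r)$ is ordinary least squares with
$R^2$ against the mean model, computed directly from the residuals. When
published values are validated, the fit is applied to the *published*
radial-dose column: recomputing $g_L$ at $r \ge 5$ cm from the printed
dose-rate table is unreliable because those entries carry only 2
significant figures (the recomputed $g_L(10)$ deviates by ~5% for that
reason alone), which is also why the deterministic radial-dose checks are
restricted to $r \le 3$ cm.

The dose-rate constant is validated to ±0.01 against the printed
2-decimal value: the printed reference dose rate and air-kerma strength
reproduce $\Lambda = 1.229/1.082 = 1.136$, which rounds to the printed
1.14.

## Synthetic data

`generate_polar_dose_table()` builds tables with the exact separable
structure of the formalism —
$C\,G_L\,g^*(r)\,F^*(r,\theta)(1+\varepsilon)$ with known $\Lambda^*$, a
fifth-order $g^*$, a polar-dip anisotropy
$F^* = 1 - A(r)\cos^2\theta$ (amplitude decreasing with $r$,
qualitatively like an encapsulated seed), and i.i.d. relative Gaussian
noise. It validates every extraction stage without transport: at
$\sigma = 0$ recovery is exact to machine precision; at $\sigma = 1\%$
the mean recovered $\Lambda$ over 50 replicates is within 0.5% of truth.
What synthetic tables deliberately do not emulate: correlated MC noise
between bins, volume-averaging bias, and capsule shadowing structure —
passing the synthetic recovery tests therefore demonstrates correctness
of the extraction algebra, not fidelity of the transport physics, which
is validated separately against closed-form oracles and the published
tables.

## Problem sizes and tolerances

Deterministic checks run in milliseconds from the packaged tables. The
stochastic validation uses desk-scale history counts chosen so the MC
uncertainty is well below the comparison bands: $1.2$–$1.5\times 10^{7}$
histories for the water phantom (sub-1% at the reference bin, ~2 minutes
single-threaded), $2\times 10^{6}$ for the air-kerma geometry (~0.5%).
The published characterization used $3\times 10^{8}$ histories with
statistical errors down to $10^{-4}$%; reproducing that is not a goal —
the $1/\sqrt N$ scaling test plus the tolerance bands replace it.
Comparison bands: 10% on absolute simulated dose-rate quantities
(spectrum-data plus cross-section model allowance vs the reference code),
5% on the dose-rate constant, where the activity normalization and most
physics-model biases cancel in the ratio.

## Known limitations

* Free-electron Compton and form-factor-tail approximations bias water
  attenuation high by ~1–3% below 100 keV (partially self-cancelling in
  scored dose because scattered photons are transported, not discarded).
* Electrons are not transported anywhere; kerma = dose is assumed at all
  scoring points.
* Seed dimensions other than the active length are package defaults, so
  simulated anisotropy near the poles need not match the reference seed
  cell-by-cell (the published pole cells themselves scatter strongly:
  neighbouring entries differ by up to 0.3).
* The printed intermediate air-kerma rate in the reference publication is
  dimensionally inconsistent with its own air-kerma strength under
  $S_K = \dot K d^2$; the package validates against $S_K$ and $\Lambda$
  only.
* The published statistical errors lack a stated estimator definition;
  batch means is this package's choice.
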