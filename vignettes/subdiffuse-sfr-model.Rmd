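---
title: "A subdiffuse scattering model for single fiber reflectance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A subdiffuse scattering model for single fiber reflectance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sfrsub)
```

## The measurement and the model

Single fiber reflectance (SFR) spectroscopy delivers and collects light
through one fiber in contact with tissue. Because source and detector
overlap, the typical distance between the point where a photon enters the
tissue and the point where it is collected is smaller than the transport
mean free path $1/\mu_s'$: the measurement is *subdiffuse*. The collected
signal mixes photons that scattered many times (diffuse) with photons that
experienced exactly one backscatter event plus any number of
forward-scattering events (*semiballistic*). `sfrsub` models the
absorption-free reflectance as

$$R_0 = (1 + X)\, R_{SFR,dif}, \qquad
  R_{SFR,dif} = a_1 \sin^2\!\theta_{acc}\; R_{dif}(\mu_s' d), \qquad
  X = a_2\!\left[\frac{p_{sb}}{(\mu_s' d)^2}\right]^{a_3},$$

with $\theta_{acc} = \arcsin(\mathrm{NA}/n_{sample})$ the acceptance angle
inside the sample and $d$ the fiber diameter.

**Diffuse component.** $R_{dif}$ is the classical dipole (pencil-beam)
solution for spatially resolved reflectance with $\mu_a = 0$, averaged
over the distance distribution between two uniform points on the fiber
face (the disk chord-length problem of geometric probability, Eq. in
`?chord_length_pdf`). It depends on scattering only through $\mu_s' d$,
rises as $(\mu_s' d)^2$, and saturates at 1. The refractive-index mismatch
at the probed surface enters through the internal-reflection parameter
$A$; for the default tissue/fiber pair 1.35/1.45,
`boundary_parameter_A()` gives 1.027. The tissue--fiber interface is the
one the diffuse model sees; the tissue--air interface outside the fiber
face only matters photon-by-photon in the Monte Carlo.

**Semiballistic component.** Diffuse photons forget the phase function
(only $g_1$ survives), but semiballistic photons do not. The scalar that
best summarises the phase-function influence is
$$p_{sb} = \frac{p_b(1^\circ)}{1 - p_f(23^\circ)},$$
the probability of scattering within $1^\circ$ of exactly backward,
inflated by the probability of scattering forward within $23^\circ$. The
two angles are *constants of the model*, selected (for NA 0.22 probes, the
common case) by minimising the relative dispersion of
$\log_{10} R_p(\theta_b, \theta_f)$ across a large ensemble of tissue-like
phase functions at fixed reflectance; `scan_integration_angles()`
reproduces that experiment. Older moment-based parameters
($\gamma$, $\delta$, $\sigma$) and the acceptance-angle ratio $R_{pNA}$
are provided for comparison (`subdiffuse_parameters()`).

**Constants.** `sfr_constants()` carries the calibrated values
($a_1 = 1.11$ shared; $a_2, a_3$ per NA for 0.10 / 0.22 / 0.50). They are
deliberately not interpolated to other NAs: the calibration is per NA and
silent extrapolation would be unfounded. `calibrate_constants()` refits
them from any Monte Carlo ensemble with the two-stage protocol (free
$a_1$ per NA first, then a shared $a_1$ with $a_2, a_3$ refit).

Below $\mu_s' d = 0.1$ the diffusion-based component is no longer an
adequate description and predictions are flagged
(`below_validity_limit`), not refused.

## Phase-function families and the candidate grid

Four families cover the phase functions that have been measured in
tissue: Henyey--Greenstein (HG), modified HG (HG mixed with a
$\cos^2\theta$ lobe), two-term HG (forward plus backward lobe) and
Reynolds--McCormick (Gegenbauer kernel; equal to HG at exponent
$\alpha = 0.5$). Legendre moments are computed by Gauss--Legendre
quadrature in $\cos\theta$ with order doubling until two successive
orders agree to $10^{-10}$; closed-form moments of the HG mixtures are
used by the grid builder and cross-checked against quadrature in the
tests. Angle sampling inverts a tabulated CDF on a $2^{14}$-point uniform
grid in $\theta$, which resolves the forward peak of the narrowest
kernels in the grid; the sampled first moment is biased by less than
$10^{-4}$.

`tissue_phase_function_grid()` enumerates the published parameter grids
and keeps candidates with $g_1 \ge 0.5$ and $g_2 < 0.9$. Two readings of
the TTHG weight grid are possible from the published table; we use
$\alpha \in \{0.5, \ldots, 0.9\ \text{by}\ 0.1\} \cup
\{0.91, \ldots, 0.99\ \text{by}\ 0.02\}$, which reproduces the published
MHG and RMC family counts (15 and 46) exactly and yields 145 TTHG
members, 206 in total, against the published 146/207. The single
difference is a knife edge: the cluster $g_f = 0.95$, $g_b = -0.95$ has
*exactly* $g_2 = 0.9025$ for every $\alpha$, so exact moments exclude it,
while any per-mille numerical underestimate of the second moment of the
sharply peaked forward lobe (as a tabulated phase function would produce)
flips the $\alpha = 0.99$ member in. We keep the exact-arithmetic count
and document the edge rather than engineering the boundary to match.

## The Monte Carlo simulator

`run_simulation()` drives a compiled photon random walk in a semi-infinite
medium probed by a single fiber (disk of diameter $d$ at the surface):

* launch: position uniform over the disk; the polar launch angle is drawn
  uniformly on $[0, \theta_{acc}]$ (the literal reading of "a uniform
  angular distribution within the acceptance angle"), with
  `launch = "uniform_solid_angle"` as the alternative convention. At both
  $\mu_s' d = 0.1$ and $\mu_s' d = 300$ the two conventions give
  reflectances that agree within statistical error, so the choice is not
  critical;
* steps: exponential with mean $1/\mu_s$; no absorption, unit weights, no
  roulette;
* surface: inside the fiber footprint the photon faces the tissue--fiber
  interface (1.35/1.45) — if it passes unpolarised Fresnel transmission
  and arrives within $\theta_{acc}$ it is detected, otherwise it is lost;
  outside the footprint it faces the tissue--air interface (1.35/1.00)
  with Fresnel reflection including total internal reflection, and
  transmitted photons are lost. Reflected photons continue;
* termination: a photon is killed when its distance from the fiber-face
  centre exceeds the termination distance. Auto mode starts at
  $\max(2/\mu_s', 20 d)$ and doubles until at least 99.9% of detected
  photons stayed within 75% of the distance; the quantile check, not the
  starting value, is the guarantee. The start was chosen small because
  detected photons at subdiffuse optical depths stay within a few hundred
  micrometers of the fiber, and tracking photons many transport lengths
  deep costs time without affecting detection;
* tags: per detected photon the number of scattering events, the number
  of backscatter events (polar angle $> 90^\circ$), the pathlength and
  the maximum excursion; a detected photon with exactly one backscatter
  event is semiballistic. The scattering angles of detected photons
  accumulate into the *effective phase function*, whose backward lobe
  switches on near $180^\circ - 2\theta_{acc}$.

The RNG is xoshiro256++ seeded from the user seed inside the kernel, so a
simulation is bit-reproducible regardless of R's RNG state.

## Spectral synthesis and the two-diameter inversion

`synthesize_spectra()` is the package's synthetic-data generator. It
emulates an MDSFR acquisition: $\mu_s'(\lambda) = a(\lambda/600)^{-b}$
over 400--900 nm in 5-nm steps, a smooth $p_{sb}(\lambda)$, fibers of 300
and 600 µm, and optional multiplicative Gaussian noise (2% in the noisy
tests, matching the precision criterion used for the Monte Carlo
ensembles). It exercises the forward model only — it does not emulate
chromophore absorption, instrument response, or wavelength-dependent
phase-function families, so passing round-trip tests demonstrate
correctness of the inversion, not robustness to those real-data effects.

With a single fiber a spectrum has $\lambda_n$ data points but
$2 + \lambda_n$ parameters ($a$, $b$, one $p_{sb}$ per wavelength);
`fit_mdsfr()` therefore requires exactly two diameters ($2\lambda_n$
points) and refuses one. The least squares runs on log reflectance
(multiplicative errors) and is solved by variable projection: for fixed
$(a, b)$ the optimal $p_{sb}$ at each wavelength is an independent
one-dimensional problem, solved to $10^{-10}$; the outer two-parameter
problem uses Nelder--Mead. This is the same minimum as a joint
103-parameter trust-region solve, at a fraction of the conditioning
trouble. $p_{sb}(\lambda)$ is fitted freely with positivity bounds and no
smoothness penalty, because no wavelength model for it is established.

A limitation worth knowing: with a free $p_{sb}$ per wavelength the slope
$b$ is only weakly identified. On noiseless data the round trip is exact
to optimizer tolerance, but at 2% multiplicative noise the objective is
nearly flat in $b$ over a range of $\pm 0.2$, and the fitted $(a, b)$ can
drift several percent while $p_{sb}(\lambda)$ stays within a few percent.
The noise tests assert these honest bounds.

## Problem sizes and numerical choices

The test-suite reproductions are scaled down to run routinely: the
stratified Monte Carlo ensemble uses 20 grid members at $4\times 10^5$
photons, the diffusive-limit check runs at $\mu_s' d = 300$ with
$6\times 10^4$ photons, and the acceptance script's semiballistic
ensemble uses 10 members at $10^7$ photons. Where a comparison is
stochastic, tolerances are expressed in standard errors of the actual
run, not in the (smaller) errors a full-size run would achieve. The
angle-scan regression uses ±35% reflectance bands instead of the
full-ensemble ±10% so that each band keeps at least two members at the
reduced ensemble size. The dispersion surface of
`scan_integration_angles()` is shallow in the forward angle near its
minimum, so the location of the optimum is a demanding statistic: at the
reduced ensemble sizes and photon budgets the tests can afford, the
measured forward optimum scatters several degrees below the nominal
23°, and sharpening it requires both the full candidate ensemble and
millions of photons per member.

Quadratures: adaptive Gauss--Kronrod (`integrate`) at relative tolerance
$10^{-10}$ throughout; the overlapping-fiber integral is split at the
kernel width for $\mu_s' d > 30$ so the peak near zero separation is
resolved. The $\sigma$ series is truncated when the next term falls below
$10^{-10}$ (terms decay like $2^{-i}$); an insufficient moment budget is
an error, not a silent truncation. Repeated $\mu_s' d$ values are
de-duplicated before quadrature in batch predictions.

## What the package does not do

No absorption (the pathlength machinery needed for $\mu_a$ is future
work), no layered media, no polarisation or time-of-flight, no
wavelength model for $p_{sb}$, no Mie-theory phase functions, and no
interpolation of the calibration constants between NAs.
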