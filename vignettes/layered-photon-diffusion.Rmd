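---
title: "Photon diffusion in layered turbid media: methods and numerics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Photon diffusion in layered turbid media: methods and numerics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(layerfluence)
```

## The model

Near-infrared light in biological tissue is dominated by scattering
(`mu_s' ~ 5-80 /cm`) over absorption (`mu_a ~ 0.02-0.6 /cm`), so the
radiative transfer equation can be approximated by the diffusion equation

    D grad^2 Phi(r) - mu_a Phi(r) = -S(r),      D = 1/(3 mu_s'),

for the fluence rate `Phi` (cm^-2, or cm^-2 ns^-1 in the time domain).
Many tissues are effectively stacks of homogeneous layers (skin/fat/muscle,
scalp/skull/CSF/brain), which this package models as a cylinder of radius
`a` made of `N` layers, each with its own `mu_a`, `mu_s'` and thickness and
a common refractive index `n_r` (1.4 by default, air outside). A collimated
beam hitting the centre of the top face is represented by an isotropic
point source at depth `z0 = 1/mu_s'_1`, the transport mean free path, which
must lie inside the top layer. Boundaries use the extrapolated-boundary
condition: the fluence vanishes on fictitious surfaces a distance
`z_b = 2 A D` outside the physical faces, where `A` encodes internal
Fresnel reflection at the index mismatch. `a_coefficient()` computes `A` by
integrating the unpolarised Fresnel reflectance moments over the hemisphere
(`A(1.4) = 2.9485`); an override is available to pin a literature value.
All lengths are cm, coefficients 1/cm, times ns, with
`c0 = 29.9792458` cm/ns fixed; there is no unit-conversion layer.

## Steady state: a finite Hankel transform

On a disk of extrapolated radius `a' = a + z_b`, a radially symmetric field
expands in Bessel modes whose transverse frequencies are
`s_n = j_{0,n} / a'`, with `j_{0,n}` the zeros of `J0`. The surface fluence
is the inverse finite Hankel transform

    Phi_k(rho) = 1/(pi a'^2) * sum_n G_k(s_n, z) J0(s_n rho) / J1(j_{0,n})^2,

where `G_k` solves, per frequency, the one-dimensional two-point boundary
value problem in depth: `G'' - alpha_k^2 G = -delta(z - z0)/D_1` with
`alpha_k^2 = (mu_a_k + s_bar/c)/D_k + s^2`, fluence and flux `D_k dG/dz`
continuous at interfaces, and `G = 0` at the extrapolated planes.
`Phi_1(z = 0)` is the reflectance-side quantity, `Phi_N(z = L)` the
transmittance side; interior depths are deliberately not part of the public
surface (an internal depth query exists solely to register against Monte
Carlo bin centres).

### Overflow-free Green's functions

Written in hyperbolic functions, `G_k` overflows once `alpha_k l_k`
exceeds ~700 - routine for thick, highly scattering layers and large roots.
The package instead assembles `G` by a reflection-coefficient sweep from
the bottom boundary upwards: in layer `k` the bottom-satisfying solution is

    w_k(zeta) = A_k [ exp(-alpha_k zeta) - R_k exp(-alpha_k (2 l_k - zeta)) ],

with `R_N = exp(-2 alpha_N z_b)` and a Moebius recursion in
`beta_k = D_k alpha_k` for `R_k`. Every stored exponent has non-positive
real part, so nothing can overflow, for any layer thickness, scattering
level, or root index; exponentials below the double range return exactly 0
rather than subnormal noise. For equal-property stacks the construction
collapses algebraically to the classical single-slab closed form, which the
test suite verifies to 1e-13 relative, and a stack of 8 identical layers
reproduces the 2-layer result to the last bit.

### Bessel machinery

Base R's `besselJ()` runs out of range near `x ~ 1e5`, while 50,000 roots
need `J1` up to 1.6e5. `bessel_j0()`/`bessel_j1()` therefore switch to the
Hankel asymptotic P/Q series above `x = 50` (~1e-16 absolute, checked
against 30-digit references). Roots come from McMahon's expansion polished
by Newton steps; tables carry the Hankel weights `1/J1^2`, are cached per
session, and can be persisted as plain text (`write_root_table()`). For
elevated working precision the roots are refined in the
arbitrary-precision backend, which drives the residual `|J0(root)|` from
~1e-16 (double) to ~1e-35 (quadruple) - necessary, because root error maps
directly onto the smallest fluence values resolvable.

### Convergence control

The sum is truncated dynamically: it stops once the magnitudes of the last
10 consecutive terms each fall below `rel_tol` (default 1e-12) times the
accumulated sum, with bounds `n_min = 50`, `n_max = 50000`. A run-length
rule is used because individual terms pass through the zeros of `J0`; a
single-term test would stop early. Convergence slows as the decay scale of
`G(s)` shortens: more terms are needed for larger `rho`, larger first-layer
`mu_s'` (since the terms decay like `exp(-s z0)` with `z0 = 1/mu_s'_1`
at `z = 0`), and larger radius (smaller spacing of `s_n`); deeper detectors
and the other optical parameters barely matter. The acceptance suite
quantifies exactly this ordering against a quadruple-precision brute-force
reference at `n = 50,000`.

### Fast reflectance approximation

At `z = 0` the slow `exp(-s z0)` decay comes entirely from the particular
(source) part of `G_1` together with its top-boundary image. Both can be
summed exactly in real space as the semi-infinite dipole
`[exp(-mu_eff r1)/r1 - exp(-mu_eff r2)/r2]/(4 pi D_1)`. What remains in the
Hankel sum decays like `exp(-s (2 l_1 - z0))` - orders of magnitude faster
whenever the top layer is thicker than a transport mean free path.
`approx_reflectance_ss()` implements this split; at `mu_s' = 80 /cm` it
needs ~1000x fewer terms at 1e-12 agreement with the exact sum. The
closed-form part absorbs the lateral boundary only approximately, so the
approximation assumes `a >> rho`; it is valid for `mu_s'_1 > 2 /cm` and
falls back to the exact sum (with a warning) outside that domain. Its
convergence test measures residual terms against the full fluence, not
against the (tiny) residual itself.

## Time domain: inverse Laplace transform on a hyperbola

Time-resolved curves follow from the same kernel via
`mu_a -> mu_a + s_bar/c` and a Bromwich integral, discretised on the
left-opening hyperbola `s(x) = mu_c (1 + sin(ix - phi))`. Because the
integrand decays doubly exponentially along the contour, a midpoint rule
with a handful of nodes suffices, and one contour serves every time point
in a window `(t1, t2)`. For `Lambda = t2/t1` the parameters balance the
truncation error (worst at `t1`) against the discretisation strip errors
(one amplified like `exp(2 mu_c t)`, worst at `t2`):

    A = acosh( ((pi-2 phi) Lambda + 4 phi - pi) / ((4 phi - pi) sin phi) ),
    mu_c = (4 pi phi - pi^2) N / (A t2),     h = A / N,

with `N` midpoint nodes on the upper half-contour; the lower half is the
complex conjugate, so a real signal costs exactly `N` kernel evaluations.
`N_evals` throughout the package counts these kernel evaluations. At
`Lambda = 1` the formulas reduce to the classical single-time optimum
(`phi = 1.1721`, `h = 1.0818/N`, `mu_c = 4.492 N/t`).

The angle default is `phi = 1.09`, a robust window compromise. For
elevated-precision runs the package instead uses the rate-optimal angle
`argmax_phi 2 pi (pi/2 - phi)/A(phi, Lambda)` (`contour_phi_optimal()`):
at large `N` the asymptotic rate governs the error floor, and on the
extreme-dynamic-range benchmark this choice lowers the floor by roughly
three orders of magnitude. At small `N` in double precision the fixed
default is as good or better in practice, because the diffusion kernel's
own decay in the left half-plane dominates the generic error estimate.

Node count maps to usable dynamic range: ~12 evaluations reconstruct
roughly 3 orders of magnitude of fluence below the curve peak, ~24 give 6
or more (`choose_n_laplace()` linearises this calibration). Errors are
roughly uniform in absolute terms across the window, so relative errors
grow where the signal is smallest - the practical advice is to choose `t1`
as late as the experiment allows and `N` from the dynamic range needed.

## Precision contexts

The double-precision path is pure R. Quadruple (34 significant digits) and
octuple (71 digits) contexts run in an mpmath worker shipped with the
package (`inst/python/hp_kernel.py`) that implements the identical root
refinement, asymptotic Bessel series, Green's-function sweep, Hankel sum
and contour; `fluence_ss_hp()`, `fluence_td_hp()` and the semi-infinite
`_hp` references drive it. The two backends agree to 1.8e-16 on the
homogeneous benchmark. In mp arithmetic there is no overflow to guard
against; the motivation for high precision is purely the error floor -
reconstructing fluence 50 orders of magnitude below peak needs roots,
Bessel values and quadrature carried at ~70 digits.

## The Monte Carlo validator

`run_mc()` is a minimal layered-slab photon Monte Carlo used as the
physical oracle: exponential optical-depth steps, Henyey-Greenstein
scattering (`g = 0.8` in all validation runs, so `mu_s = mu_s'/(1-g)`),
Fresnel reflection at the external boundaries, index-matched internal
interfaces, Russian roulette (threshold 1e-3, survival factor 10), and a
collision estimator (`w/mu_t` per bin volume) for fluence. Time of flight
is path length times `n_r/c0`. Histograms use the registration
`dr = 0.99 mm`, `dz = 0.27 mm`, `dt = 0.02 ns`; the time-domain histogram
scores a 3 mm surface slab because the tiny `(rho, t)` bins would otherwise
be unusably noisy at desk-scale photon counts. Standard errors come from 32
photon batches.

What it emulates and what it does not: the diffusion model's cylinder wall
is absent (the slab is laterally infinite), which is negligible at the
large radii used; the source is the same isotropic point source as the
diffusion model, not a collimated beam (a collimated mode exists for
analytic attenuation checks); all layers share one refractive index. A
passing comparison therefore validates the transport physics and the
layered structure, not detector numerical aperture, polarisation, or any
instrument response.

Comparisons (`mc_compare_ss()`, `mc_compare_td()`) evaluate diffusion at
bin centres - including in depth (`z = dz/2` for the steady state): at
`dz = 0.27 mm` the near-surface fluence gradient otherwise introduces a
systematic ~6 % bias, larger than the 5 % agreement being tested. The
time-domain comparison integrates diffusion over the scored surface slab
(Simpson rule), matching what the histogram actually measures. Bins with
`rho < 0.5` cm are excluded (diffusion theory is invalid that close to the
source) and only bins whose MC standard error is below 1 % of the value
participate. Validation problem sizes: 5e6 photons for the homogeneous
steady-state and time-domain comparison, 2e6 for the 3-layer muscle model
(scaled from the 5e7 a full study would use; the standard-error filter
automatically restricts the compared range accordingly). The time-domain
arm registers at `rho = 1.5` cm; at `rho ~ 1` cm and `t ~ 0.3` ns photons
have undergone too few scattering events and diffusion genuinely
overestimates the Monte Carlo fluence by 6-10 %.

## Numerical choices and degenerate inputs

* Negative fluence from roundoff cancellation is clamped to zero and
  flagged (`clamped`); the noise floor is documented, not hidden.
* `rho = 0` is allowed (the `J0(0) = 1` path); `rho = a` is allowed but
  warned about (lateral-boundary proximity); `rho > a` errors.
* Wavenumbers use the principal square root with the sign flipped onto
  `Re(alpha) > 0`, selecting decaying solutions for any contour point.
* Mixed internal refractive indices are rejected: the interface conditions
  implemented (continuity of `Phi` and `D dPhi/dz`) hold only for matched
  indices.
* `z0 >= l_1` (source below the first interface) is rejected as
  unsupported geometry rather than silently approximated.
* Media are value-objects: rebuilding one yields bit-identical derived
  parameters, and repeated evaluations are deterministic, including the
  fixed reduction order over contour nodes.

## Known limitations

* The windowed-hyperbola contour reaches ~5e-8 absolute error at
  `N = 20` for very wide windows (`Lambda = 500-5000`) on the benchmark
  4-layer medium, not the 1e-8 achievable at moderate windows; `N = 24-32`
  restores 1e-9-1e-10. Reconstruction accuracy at an interior time of a
  very wide window is limited by the uniform-over-window error balance;
  tightening it would require a contour tailored to the queried times
  rather than to the window.
* On the extreme-dynamic-range benchmark (`mu_a = 0.6 /cm`, octuple
  precision, `N = 168`, `n = 600`), the contour error floor after the
  rate-optimal angle is ~1e-54, which tracks the reference over ~46 orders
  of magnitude; the closed-form span of those curves over `t` in
  `[0.1, 6]` ns is itself ~48 orders.
* The fluence (not a Fick's-law surface flux) is the compared quantity
  throughout; no instrument-response convolution is provided.
* Diffusion theory itself fails for `rho < 0.5` cm, at sub-transport-length
  top layers, and in low-scattering gaps (CSF); the brain scenario follows
  the standard practice of an effective CSF `mu_s' = 3.5 /cm` on the
  diffusion side.

## A worked example

```{r, eval = FALSE}
medium <- layered_medium(mu_a = c(0.2, 0.1), mu_sp = c(13, 12),
                         thickness = c(0.6, 9.0), radius = 20)
reflectance_ss(medium, rho = c(1, 2, 3))
fluence_td(medium, rho = 1.5, times = seq(0.1, 4, by = 0.05),
           n_laplace = 24, t1 = 0.1, t2 = 4)
```
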