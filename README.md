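# layerfluence

Fast, numerically stable forward solver for the photon diffusion equation
in an N-layered turbid cylinder — the standard tissue model of diffuse
optical spectroscopy and time-domain near-infrared measurements
(skin/fat/muscle, scalp/skull/CSF/brain). It is written for researchers who
need accurate steady-state and time-resolved reflectance/transmittance
curves from layered media fast enough to sit inside inverse fits, together
with the machinery to *prove* the numbers are right: closed-form
semi-infinite references, an arbitrary-precision computation path, and a
layered Monte Carlo validator.

## The model

Light transport is approximated by the diffusion equation
`D ∇²Φ − μa Φ = −S`, `D = 1/(3 μs′)`, in a cylinder of radius `a` made of
layers with independent absorption `μa` [cm⁻¹], reduced scattering
`μs′` [cm⁻¹] and thickness [cm] (shared refractive index `n_r`, air
outside). The beam is an isotropic point source at depth `z0 = 1/μs′₁`;
boundaries are of extrapolated type, `Φ = 0` at distance `z_b = 2AD`
outside the faces, with `A` from the Fresnel reflectance integral.

* **Steady state** — inverse finite Hankel transform over the zeros of
  `J0`: `Φ_k(ρ) = (π a′²)⁻¹ Σₙ G_k(sₙ, z) J0(sₙρ) J1⁻²(a′sₙ)`, with
  `sₙ = j₀,ₙ/a′` and `a′ = a + z_b`. The transform-domain Green's function
  `G_k` is evaluated by a reflection-coefficient sweep in which every
  stored exponential decays, so nothing overflows even for 30 cm layers at
  `μs′ = 80 cm⁻¹` and 50,000 roots.
* **Time domain** — inverse Laplace transform `μa → μa + s̄/c` along a
  left-opening hyperbolic Bromwich contour shared by all time points in a
  window `(t1, t2)`; ~12 kernel evaluations resolve 3 decades of dynamic
  range, ~24 resolve 6.
* **References** — closed-form semi-infinite dipole solutions, a
  quadruple/octuple-precision backend, and a Henyey–Greenstein layered
  Monte Carlo engine for physical validation.

## A worked example

```r
library(layerfluence)

medium <- layered_medium(mu_a = c(0.2, 0.1), mu_sp = c(13, 12),
                         thickness = c(0.6, 9.0), radius = 20)
reflectance_ss(medium, rho = c(1, 2, 3))
#> # A tibble: 3 × 7
#>     rho     z   fluence terms_used converged clamped at_lateral_boundary
#>   <dbl> <dbl>     <dbl>      <int> <lgl>     <lgl>   <lgl>
#> 1     1     0 0.0436          2217 TRUE      FALSE   FALSE
#> 2     2     0 0.000903        2533 TRUE      FALSE   FALSE
#> 3     3     0 0.0000455       2766 TRUE      FALSE   FALSE

fluence_td(medium, rho = 1.5, times = c(0.5, 1, 2),
           n_laplace = 24, t1 = 0.4, t2 = 2.5)
#> # A tibble: 3 × 4
#>     rho     t   fluence clamped
#>   <dbl> <dbl>     <dbl> <lgl>
#> 1   1.5   0.5 0.00708   FALSE
#> 2   1.5   1   0.000873  FALSE
#> 3   1.5   2   0.0000250 FALSE
```

The steady-state column `fluence` is the surface fluence in cm⁻²
(2-layer skin-like model: 4.4e-2 at 1 cm falling to 4.6e-5 at 3 cm from
the source); `terms_used` records how many Hankel terms the dynamic
stopping rule needed at each distance. The time-domain values are fluence
rates in cm⁻² ns⁻¹ at a 1.5 cm detector: the 0.5→2 ns decay slope is what
time-domain instruments fit for absorption. `glance(medium)` shows the
derived parameters (`A = 2.948`, `z0 = 0.0769 cm`, `z_b = 0.151 cm`,
`a′ = 20.15 cm`).

Other entry points: `transmittance_ss()`, `approx_reflectance_ss()` (the
source-resummed fast path, ~1000× fewer terms at high scattering),
`fluence_ss_semiinf()`/`fluence_td_semiinf()` (homogeneous references),
`run_mc()`/`mc_compare_ss()`/`mc_compare_td()` (Monte Carlo validation),
`fluence_ss_hp()`/`fluence_td_hp()` (quadruple/octuple precision),
`scenario()` (ready-made tissue models), `autoplot()` on every result, and
a command-line wrapper in `inst/cli/layerfluence`.

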