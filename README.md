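# wmnirs

Topographic near-infrared imaging of static absorbing properties is
normally defeated by the unknown, spatially erratic coupling between the
optical probe and the surface — above all by hair. `wmnirs` implements
the wavelength-modulated NIRS (WM-NIRS) answer to that problem: image
the **spectral derivative of attenuation** instead of attenuation
itself. For a source–detector pair at separation *d* on a turbid medium,
the modified Beer–Lambert law gives

```
A(λ) = −ln(I/I₀) = μa(λ) β(λ) d + G(λ) − ln k,
```

with `μa` the absorption coefficient, `β` the differential pathlength
factor (DPF), `G` a scatter-dependent geometric loss and `k` the
coupling efficiency. Because `k` is wavelength-independent, it vanishes
from `∂A/∂λ`, so gradient images are immune to coupling. Prior spectral
knowledge of the absorbers then separates their contributions: with a
dye (or tissue) basis and an eumelanin basis for hair,

```
∂A/∂λ ≈ d⟨β⟩ ( r_dye ∂μa,dye/∂λ + c_m ∂εm/∂λ ) − α λ⁻ᵖ,
```

solved per position by minimum-norm least squares (the `−α λ⁻ᵖ` term
optionally absorbs wavelength-dependent scattering), yields separate
maps of relative dye absorption `r_dye` and effective melanin
concentration `c_m`.

The package is aimed at researchers in diffuse optics who want a tested,
reproducible reference implementation of this processing chain. It
provides:

* **Chromophore models** (`dye_model()`, `melanin_model()`): a
  calibrated Gaussian-plus-constant phantom dye and an exponential
  eumelanin extinction, with analytic derivatives.
* **A synthetic phantom scan generator** (`build_phantom_scene()`,
  `sample_hair_field()`, `generate_scan()`): a 130×190×40 mm
  tissue-like block with eight embedded cylindrical targets (absorption
  ×5/10/20/50 at 15 and 25 mm depth), scanned on a 10×15 grid of
  spectrometer spectra through a correlated random hair layer, via a
  two-path modified Beer–Lambert forward model.
* **The spectrometer pipeline** (`process_scan()`, `assemble_image()`):
  dark subtraction, 12th-order log-spectrum polynomial fits over
  700–840 nm (Chebyshev basis), attenuation / attenuation-gradient /
  broadband images, per-target contrast extraction.
* **Spectral unmixing** (`solve_unmix_linear()`,
  `solve_unmix_scatter()`, `solve_homogeneous()`, `unmix_scan()`) and a
  diffusion-model DPF estimator (`dpf_diffusion()`, `mean_dpf()`).
* **A Monte Carlo photon-transport model** (`simulate_paths()`,
  `replay()`, `mc_sweep()`, `find_extremum_F()`): a slab with a
  spherical target, Henyey–Greenstein scattering in Rcpp, and a
  pathlength-replay estimator that evaluates the whole
  19-wavelength × 15-absorption-factor grid from one path ensemble,
  reproducing the nonlinear relationship between gradient-image
  contrast and target absorption.

Results are tibbles throughout; fitted objects support `tidy()`,
`glance()` and `autoplot()`.

## Worked example

Simulate the hairy-phantom scan, process it, and unmix:

```r
library(wmnirs)

scene    <- build_phantom_scene()
protocol <- scan_protocol()
hair     <- sample_hair_field(protocol, seed = 2)
scan     <- generate_scan(scene, protocol, hair = hair, seed = 1)
#> <nirs_scan> 150 positions x 201 wavelengths (650-850 nm), seed 1, hair on

processed <- process_scan(scan, wavelengths = c(760, 800))
maps      <- unmix_scan(processed)
ct        <- contrast_at_targets(unmix_image(maps, "r_dye"), scene)
ct[, c("target", "depth", "factor", "value", "contrast")]
#> # A tibble: 8 × 5
#>   target depth factor value contrast
#>    <int> <dbl>  <dbl> <dbl>    <dbl>
#> 1      1    15      5 0.810  0.0776
#> 2      2    15     10 0.823  0.0904
#> 3      3    15     20 0.801  0.0688
#> 4      4    15     50 0.741  0.00862
#> 5      5    25      5 0.766  0.0334
#> 6      6    25     10 0.762  0.0302
#> 7      7    25     20 0.762  0.0295
#> 8      8    25     50 0.743  0.0109
```

Despite the hair layer, all eight targets stand out of the `r_dye` map
(background 0.732 ± 0.0033 here), and the melanin map tracks the
generated hair field almost perfectly
(`cor(maps$c_m, hair$c_hair) = 0.999`). Two features are worth reading
off the numbers. First, contrast is **non-monotone** in the target
absorption factor: the ×10 target is brighter than the ×50 one, because
light that meets a very dark target rarely reaches the detector, so the
gradient reverts toward its background value. Second, the background
`r_dye` sits below 1: the generator's background DPF (5.5) is smaller
than the band-mean DPF assumed by the unmixing (≈7.5), and the ratio is
exactly the observed level.

The Monte Carlo module quantifies the non-monotonicity from actual
photon transport. With a 2×10⁵-photon shared ensemble:

```r
sweep <- mc_sweep(n_photons = 2e5, seed = 3)
find_extremum_F(spectral_derivative(sweep, "A", 760))$F_star  # 10.2 (maximum)
find_extremum_F(spectral_derivative(sweep, "A", 800))$F_star  #  9.3 (minimum)
```

i.e. gradient contrast peaks near an absorption factor of ~10 and falls
off on both sides — the caution flag for interpreting gradient images
quantitatively. `autoplot(sweep)` shows A, β and G against F;
`autoplot()` on any image gives the topographic map.

A thin command-line front-end (`inst/exec/wmnirs`) exposes the same
runs as `wmnirs simulate | process | mc` over a YAML configuration; see
`default_run_config()`.

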