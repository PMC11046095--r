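---
title: "Spectral-derivative topographic imaging: models, numerics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spectral-derivative topographic imaging: models, numerics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wmnirs)
```

## The measurement model

A continuous-wave NIRS channel delivers light into a turbid medium at one
point and collects it at another, a distance $d$ away. For a homogeneous
medium the detected intensity follows the modified Beer–Lambert law

$$ I(\lambda) = k\, I_0(\lambda)\, e^{-\mu_a(\lambda)\beta(\lambda) d - G(\lambda)}, $$

so the attenuation is

$$ A(\lambda) = -\ln\frac{I}{I_0} = \mu_a \beta d + G - \ln k, $$

where $\mu_a$ is the absorption coefficient, $\beta$ the differential
pathlength factor (mean detected pathlength over $d$), $G$ a
scatter-dependent geometric loss, and $k$ the coupling efficiency at the
probe–surface interface. $k$ is unknown, large in its variation, and —
for measurements through hair — spatially erratic. Because $k$ is, to a
good approximation, independent of wavelength, it vanishes from the
spectral derivative:

$$ \frac{\partial A}{\partial\lambda}
   = d\left(\beta\frac{\partial\mu_a}{\partial\lambda}
     + \mu_a\frac{\partial\beta}{\partial\lambda}\right)
     + \frac{\partial G}{\partial\lambda}. $$

Topographic images built from $\partial A/\partial\lambda$ are therefore
immune to coupling, which is the package's central, exactly-testable
property: rescaling any measured spectrum by a constant shifts its
fitted attenuation by $-\ln k$ and changes its fitted gradient at the
level of floating-point round-off only (`apply_coupling()` plus the
pipeline tests assert $<10^{-12}\,\mathrm{nm}^{-1}$).

For a homogeneous medium the gradient is modelled empirically as

$$ \frac{\partial A}{\partial\lambda}
   \approx d\,\langle\beta\rangle \sum_n \frac{\partial\varepsilon_n}{\partial\lambda} c_n
   \;-\; \alpha\,\lambda^{-p}, $$

with $\langle\beta\rangle$ a band-mean DPF and the $-\alpha\lambda^{-p}$
term absorbing the wavelength dependence of the transport scattering
coefficient. Solving this at a handful of wavelengths is the unmixing
problem of `solve_unmix_linear()`, `solve_unmix_scatter()` and
`solve_homogeneous()`.

## Chromophore models

**Phantom dye.** The absorbing dye of the solid phantom has a smooth,
unimodal NIR spectrum known through four published anchor values: a
derivative maximum of $+1.7\times10^{-4}$ mm$^{-1}$nm$^{-1}$ at 756 nm,
a minimum of $-1.8\times10^{-4}$ at 808 nm, and absorptions of 0.0102
and 0.01 mm$^{-1}$ at 760 and 800 nm. We model it as a constant plus a
single Gaussian — the minimal smooth four-parameter family consistent
with those anchors — and calibrate by least squares on *relative*
residuals, because gradient and absorption anchors differ by two orders
of magnitude and absolute residuals would let the absorption anchors
dominate.

Two numerical points deserve note. First, the four anchors alone admit
an exact Gaussian solution, but that solution places the derivative
maximum near 749 nm rather than 756 nm: the anchors state the values
*at* the extrema, and fitting values alone does not pin the extremum
locations. Since for this family the derivative extrema are analytically
at $c \pm w$, the default calibration adds two soft location constraints
(scaled by 6 nm). The compromise fit reproduces all four anchors within
4.3% and puts the extrema at 756.0/808.0 nm. Second, the Gaussian is a
stand-in: outside roughly 740–820 nm the true dye spectrum is not
constrained by any anchor, and the model relaxes toward its baseline
(`r round(default_dye_model()$baseline, 4)` mm$^{-1}$). Consequences of
that extrapolation are flagged where they matter below.

**Eumelanin.** Dark hair absorbs predominantly through eumelanin, whose
extinction decreases smoothly and approximately exponentially across the
visible and NIR. The default `melanin_model()` is
$\varepsilon_m(\lambda) = 50\,e^{-0.005(\lambda-650)}$ in
mm$^{-1}$(mg/ml)$^{-1}$. The absolute scale is arbitrary — melanin
concentrations recovered from a surface hair layer are *effective*
volume concentrations in any case — and only the decay constant shapes
the unmixing basis. Users with tabulated extinction data can fit their
own model with `fit_melanin()` (log-linear regression).

## The synthetic scan generator

No public dataset accompanies this class of experiment, so the package
generates its own: `build_phantom_scene()` describes a
130 × 190 × 40 mm tissue-like block ($\mu_s' = 1.0$ mm$^{-1}$ at
800 nm) containing two rows of four cylindrical targets (10 mm long,
10 mm diameter) with absorption 5, 10, 20 and 50 times background,
centred 15 and 25 mm deep; `scan_protocol()` describes a 10 × 15 grid
of probe positions at 10 mm spacing with $d = 20$ mm and a ~1 nm
spectrometer grid over 650–850 nm.

**Two-path closure.** Rather than full photon transport, the forward
model splits detected light into two populations: a fraction $1-f$ that
never meets the target (background DPF $\beta_0 = 5.5$) and a fraction
$f$ that does (longer path, $\beta_1 = 7.0$, plus the target's excess
absorption over a mean in-target pathlength $L_t$, 10 mm for the
shallow row and decaying with depth). $f$ follows a Gaussian kernel
(8 mm width) of the lateral probe–target distance, scaled down with
depth. This is exactly the two-population argument that explains the
nonlinear contrast-versus-absorption relationship, and it keeps scan
generation instant and analytically inspectable: the interaction
branch's weight decays like $e^{-(F-1)\mu_a L_t}$ while its excess
pathlength grows linearly in $F$, so gradient contrast rises, peaks near
$F \approx 1 + (\mu_a L_t)^{-1} \approx 10$, and falls — the same
qualitative shape the Monte Carlo module derives from actual transport.
The defaults are package choices bracketing the diffusion-model DPF, not
measured values.

**Hair.** `sample_hair_field()` draws two independent Gaussian random
fields with squared-exponential correlation (20 mm length): a melanin
areal concentration `c_hair` (mean 0.03 mg/ml·mm, floored at zero, so
the melanin optical depth $2 c_{hair}\varepsilon_m \approx 1.5$ at
770 nm) and a coupling loss $u \ge 0$ with $k = e^{-u}$ (median
$k \approx 0.6$, down to ~0.3). Hair thus acts twice per channel
(factor 2, in and out) through wavelength-*dependent* melanin
absorption and once through the wavelength-*independent* loss $k$ —
precisely the two effects the unmixing must separate.

**Noise.** Each spectrum receives multiplicative intensity noise
(sd 0.3%) and additive dark noise (level 5 counts, sd 0.2). These
defaults are calibrated so repeated acquisitions at one position spread
by less than 0.01 in attenuation and $10^{-4}$ nm$^{-1}$ in gradient —
the repeatability the topographic method presumes — and the test suite
measures both.

**What the generator does not emulate.** Partial-volume blurring beyond
the Gaussian kernel, overlap of two targets in one channel (the
strongest target wins; targets are ≥ 40 mm apart), wavelength-dependent
scattering in the block, stray light and detector nonlinearity, and any
direct source–detector leakage. Passing the synthetic tests therefore
demonstrates the *processing chain* and the method's structural
properties (coupling immunity, unmixing separability, contrast
nonlinearity), not instrument-level performance on real tissue.

## Pipeline numerics

All spectral fitting maps the window to $[-1,1]$ and works in a
Chebyshev basis; a raw 12th-order monomial design at wavelengths near
800 is numerically singular. `fit_log_poly()` fits order 12 over
700–840 nm to the log spectrum; attenuation and gradient are
differences of fitted values / analytic derivatives between the source
fit and each measurement fit. Sub-dark bins are floored at
$\max(\text{dark sd}, 10^{-12}\times\text{peak})$ and counted, since the
logarithm requires positivity. Broadband attenuation integrates
trapezoidally on the native grid. Nearest-grid-node ties in
`contrast_at_targets()` resolve to the lower row/column index.

One honest caveat: with the Gaussian dye stand-in, the order-12 fit's
truncation error on noise-free gradients is about $10^{-5}$ nm$^{-1}$
(the Gaussian contributes ~0.8 log-units of non-polynomial structure
over the 140 nm window), an order of magnitude above machine-level. It
is far below the $10^{-4}$ nm$^{-1}$ noise floor and cancels exactly in
coupling comparisons, but it sets the accuracy floor for round-trip
checks, and the tests assert it at its measured scale ($2\times10^{-5}$)
rather than pretending to machine precision.

## Unmixing

Gradients at $m \ge 2$ wavelengths give a linear system in
$(r_{dye}, c_m)$; `solve_unmix_linear()` returns the minimum-norm
least-squares solution via the SVD pseudo-inverse (exact for two
wavelengths and a full-rank basis; rank deficiency is flagged, not
fatal). The scatter variant adds $-\alpha\lambda^{-p}$ and profiles $p$
over a fixed grid (0.2–3.0, step 0.05): the subproblem is linear given
$p$, and the explicit residual-versus-$p$ profile exposes the
fundamental difficulty that a decaying exponential (melanin) and a
power law (scatter) are nearly collinear over a 140 nm band. On
melanin-only synthetic data the profile is nearly flat and the recovered
melanin/scatter split is ambiguous even at residuals below 1% — the
tests assert this degeneracy rather than hiding it. Negative $c_m$ or
$\alpha$ are returned and flagged (they are a finding, not an error);
`nonneg = TRUE` re-solves with the offending coefficients clamped by a
small active-set enumeration.

**Mean DPF.** `dpf_diffusion()` implements the steady-state diffusion
closed form
$\beta = \tfrac12\sqrt{3\mu_s'/\mu_a}\,[1 - (1 + d\sqrt{3\mu_a\mu_s'})^{-1}]$
with a leading image-source slab correction (negligible, <5%, for the
40 mm block — we verified against a full image-source dipole sum that
the truncation of deep paths changes the band mean by under 1% at this
geometry). At the phantom's nominal absorption (0.010–0.012 mm$^{-1}$,
$\mu_s' = 1$, $d = 20$) it gives $\beta \approx 6.2$–6.8, the ~6
commonly assumed for such phantoms. The *band mean* over 700–840 nm
with the default dye model is larger, $\langle\beta\rangle \approx 7.5$,
purely because the Gaussian stand-in decays toward its baseline at the
band edges where no anchor constrains it and the diffusion DPF grows
like $\mu_a^{-1/2}$. Users reproducing a fixed-$\beta$ analysis should
pass `beta = 6` explicitly (every unmixing function accepts an
override); the package default remains the honest band mean of its own
dye model.

## Monte Carlo transport and the replay estimator

The reduced geometry for studying contrast nonlinearity is a
100 × 100 × 25 mm slab with a single 10 mm spherical target centred
10 mm below the source–detector midpoint, $d = 20$ mm, $\mu_s = 10$
mm$^{-1}$, $g = 0.95$ (so $\mu_s' = 0.5$), refractive-index-matched
boundaries, and a pencil beam. Geometry is continuous with analytic
ray–sphere intersection per step — no voxelisation bias — and the
detector is a 2.5 mm-radius disc (a 5 mm probe aperture; the choice is
a package convention). A 2000 mm total-path cap guards against
pathological walks.

The key design decision is the **pathlength-replay estimator**: the
random walk is absorption-free and records, per detected photon, the
path length outside ($L_{out}$) and inside ($L_{in}$) the target.
Absorption enters analytically at replay,
$w = e^{-\mu_a L_{out} - F \mu_a L_{in}}$, giving
$A = -\ln(\sum w / n)$ and $\beta = \sum w L_{tot} / (d \sum w)$. One
transport run then serves the entire 19-wavelength × 15-factor grid
(sharing is valid exactly when scattering is wavelength-independent;
the power-law variant $\mu_s = 10(\lambda/800)^{-1.2}$ runs one
ensemble per wavelength, and `share_paths = FALSE` allows seed-matched
comparisons). Replay also makes two properties *exact* on a fixed
ensemble rather than statistical: $A$ is monotone in $F$, and the
$F = \infty$ limit (all target-touching photons absorbed) is the
sentinel $w = 0$ for $L_{in} > 0$.

Spectral derivatives of $A(\lambda)$, $\beta(\lambda)$ and $G(\lambda) =
A - \mu_a\beta d$ come from order-8 Chebyshev fits over the 19-point
grid; the extremum of $\partial A/\partial\lambda$ versus $F$ (a maximum
at 760 nm, a minimum at 800 nm) is located on the factor grid and
refined by quadratic interpolation of the three bracketing points on a
log-$F$ axis, with boundary extrema flagged instead of interpolated.
Uncertainty comes from a multinomial bootstrap over detected photons,
drawn once per ensemble so bootstrap surfaces are smooth across the
grid; `extremum_interval()` propagates it to the extremum location.
Note that $G$ here uses the *background* $\mu_a$ with the total
pathlength, so for the heterogeneous slab $G$ absorbs the target's
excess absorption — which is why $G$ tracks $A$ closely as the target
darkens.

**Problem sizes.** The default run uses $10^6$ photons (the detected
fraction at this geometry is ~0.1%, i.e. roughly a thousand recorded
paths, which the shared-ensemble replay turns into smooth curves); the
test suite uses $2\times10^5$ for its property checks and the
acceptance script states its own count. The fast internal RNG
(xoshiro256++) is seeded from R's RNG, so `set.seed()` determines every
run completely.

## Known limitations

* The dye spectrum outside ~740–820 nm is an extrapolation of the
  Gaussian stand-in; quantities that average over the full band (the
  default $\langle\beta\rangle$, band-edge gradients) inherit that
  uncertainty.
* The generator's two-path closure reproduces the *shape* of the
  contrast nonlinearity, but its extremum location depends on the
  chosen $L_t$; the Monte Carlo module is the physics-grounded
  counterpart.
* The downward shift of $\partial A/\partial\lambda$ under power-law
  (negative-gradient) scattering is of order $2\times10^{-3}$ nm$^{-1}$
  in exploratory runs — but per-wavelength ensembles at desk-scale
  photon counts carry derivative noise of the same order, and matched
  seeds do not help because trajectories decorrelate once $\mu_s$
  differs. Resolving the sign at 3$\sigma$ needs roughly $10^7$–$10^8$
  photons per wavelength, so the test suite asserts the seed-matched
  mechanics of the variant rather than the shift's sign.
* Melanin–scatter separation is intrinsically ill-posed on this band;
  the scatter-term solver reports, flags and profiles the degeneracy but
  cannot remove it.
* Topographic maps are qualitative: recovering quantitative absolute
  properties of a heterogeneous medium would require a tomographic
  treatment with overlapping measurements, which is out of scope.
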