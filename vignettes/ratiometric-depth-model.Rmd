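---
title: "Ratiometric dual-wavelength fluorescence depth estimation: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ratiometric dual-wavelength fluorescence depth estimation: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluordepth)
```

## The problem

Chlorin-type photosensitizers (PS) used in photodynamic therapy (PDT) have
two strong absorption bands — the Soret band near 405 nm and the Q band near
660 nm — and fluoresce in the near infrared (detected here around 760 nm).
Blue light is attenuated by skin-like tissue much more strongly than red
light, so fluorescence excited at 405 nm interrogates only the superficial
few hundred micrometres while 660 nm excitation reaches millimetres deep.
The ratio of the two fluorescence responses, each normalized by its
excitation intensity,

$$R_\lambda = \frac{F(\lambda_2)/I_{ex,2}}{F(\lambda_1)/I_{ex,1}},$$

is therefore a monotone function of how deep the fluorophore sits, and —
crucially — is independent of the unknown PS concentration. `fluordepth`
implements the forward model of $R_\lambda$ for four canonical PS depth
profiles, the corresponding inverse depth estimators, a Monte Carlo (MC)
photon-transport simulator used to verify the model and probe its
sensitivity to optical-property errors, and the calibration pipeline that
turns wide-field dual-wavelength image pairs into depth estimates.

## Forward model

The tissue is a semi-infinite, transversely uniform turbid medium with
absorption $\mu_a(\lambda)$, scattering $\mu_s(\lambda)$, anisotropy
$g(\lambda)$ and refractive index $n$ (assumed constant over 400–800 nm).
The excitation fluence follows a semi-empirical description: depth decay
$e^{-\mu_{ex} z}$ at the diffusion attenuation rate
$\mu = \sqrt{3\mu_a\mu_t'}$ (with $\mu_t' = \mu_a + \mu_s(1-g)$), enhanced
by the backscattering factor

$$k_{ex} = 3 + 5.4\,p - 2e^{-17 p}, \qquad
  p = \exp\!\left(-\tfrac{8}{3}\,\mu_{ex}/\mu_t'\right),$$

which accounts for diffusely backscattered excitation light. Fluorescence
emitted isotropically at depth $z$ escapes through the surface with
efficiency $\propto e^{-\mu_{em} z}$ in the diffusion approximation, with a
refractive-mismatch factor entering through
$q = 2\mu_{em} m / (3 \mu_t'(\lambda_{em}))$. The outgoing flux per unit
excitation intensity is

$$F = \phi\, k_{ex} \frac{\sinh q\, e^{-q}}{q}
  \int_0^\infty \mu_{a,PS}(z)\, e^{-(\mu_{ex}+\mu_{em}) z}\, dz .$$

Everything outside the integral except $\phi\,k_{ex}$ cancels in the ratio,
leaving $R_\lambda$ a functional of the PS depth profile only, scaled by the
amplitude/yield factor $(\phi_2\mu_{a,PS,2})/(\phi_1\mu_{a,PS,1})$ and
$k_{ex,2}/k_{ex,1}$.

Four canonical profiles cover the administration routes encountered in
practice (depth $z$ in mm, $z=0$ at the surface):

| kind | shape | scenario | ratio behaviour |
|---|---|---|---|
| `top_uniform` | boxcar of thickness $d$ | topical, saturated layer | saturating growth from $R_0$ to $R_\infty$ |
| `bottom_uniform` | semispace below a PS-free cover $d_b$ | intravenous, vascular delivery | $R_\infty e^{(\mu_{ex,1}-\mu_{ex,2}) d_b}$ |
| `exponential` | $e^{-z/d_{1e}}$ | topical, diffusive penetration | saturating, initial slope twice the boxcar's |
| `shifted_exponential` | exponential under a PS-free cover | surface photobleaching after PDT | exponential factor times the exponential-profile ratio |

The two asymptotes on the default human-dermis preset are
$R_0 \approx 0.239$ and $R_\infty \approx 0.665$, and the exponential growth
rate of the buried-layer case is
$\mu_{ex,1}-\mu_{ex,2} \approx 3.81\ \mathrm{mm^{-1}}$ — a doubling of the
ratio for every 0.18 mm of PS-free cover, which is what makes the
intravenous case so depth-sensitive.

```{r asymptotes}
tm <- dermis_table1()
c(R0 = ratio_limit0(tm), Rinf = ratio_top_inf(tm),
  slope = tm$coef$delta_mu)
```

## Inverse estimators

The buried-layer and exponential cases invert in closed form
(`invert_bottom()`, `invert_exp()`); the top-layer case has no closed
inverse and is solved by bracketed root finding on its strictly monotone
forward relation (`invert_top()`, absolute depth tolerance $10^{-10}$ mm,
default bracket $10 \times 3/(\mu_{ex,2}+\mu_{em})$ because the relation
saturates beyond $z^* = 3/(\mu_{ex,2}+\mu_{em})$ and deeper layers are
indistinguishable). Each inverse checks its admissible ratio interval and
names it in the error; `invert_exp(clamp = TRUE)` clamps slightly
sub-$R_0$ values (measurement noise) to $R_0$ with a warning instead,
which keeps batch scans total. A PDT-induced shift of the PS upper boundary
follows from a pre/post ratio pair alone:
$\Delta d_b = \ln(R_{after}/R_{before}) / (\mu_{ex,1}-\mu_{ex,2})$
(`bleach_depth()`); a negative value means the PS localization became
shallower, which the model family cannot produce by surface bleaching alone
and therefore flags a redistribution mechanism outside the model.

## Monte Carlo verification

The dual-step simulator verifies the analytic model end to end:

1. **Excitation step.** Photons enter at normal incidence; the
   normal-incidence specular loss $((n-1)/(n+1))^2$ is deducted
   deterministically. Transport uses Henyey–Greenstein scattering with the
   preset $g$, continuous Beer attenuation along each sub-step (exact for
   depth-varying absorption, which includes the PS contribution — the model
   therefore contains the PS self-screening that the analytic formula
   neglects), and unpolarized Fresnel reflection/refraction at the top
   boundary. The tally is the depth-resolved absorbed weight on a
   `voxel_dz = 0.01` mm grid down to `max_depth = 20` mm.
2. **Emission step.** The PS-absorbed dose — absorbed weight times
   $\mu_{a,PS}/(\mu_{a,PS}+\mu_{a,base})$ — becomes a distributed isotropic
   source. One photon bundle per source voxel per batch is launched
   (stratified sampling, lower variance than sampling voxels), transported
   at the emission-wavelength properties, and the weight escaping the top
   boundary at any exit angle is the fluorescence response.

Design choices a reader may want to audit:

* **Launch geometry.** A flat normal-incidence beam fills the lateral
  extent of a 30 × 30 mm box and photons crossing the lateral faces are
  terminated as lost — the geometry of the verification study the model is
  compared against. This choice is quantitatively consequential: the
  deeper-penetrating red light wanders farther laterally before absorption,
  so the finite box depresses the simulated ratio by roughly 4% relative to
  the laterally infinite plane-wave limit (which an on-axis pencil launch
  realizes exactly, by translation invariance). The published
  theory-vs-simulation agreement figures this package reproduces are
  properties of the boxed geometry; the infinite-lateral limit shifts the
  ratio upward by about that amount and is available by enlarging
  `lateral_size`.
* **Ratio and error.** `mc_ratio()` runs both excitation wavelengths with
  independent seed sub-streams; the ratio standard error comes from 10
  batch means by default.
* **Variance reduction.** Russian roulette below weight $10^{-4}$ with
  survival probability 0.1 (survivors reweighted, unbiased); a hard floor
  at $10^{-12}$ guards the roulette-off mode used by the conservation
  tests.
* **Randomness.** A self-contained xoshiro256++ stream seeded from the
  configuration makes runs bit-reproducible across platforms; every MC
  step derives a distinct sub-stream from the one seed.
* **Emission fast path.** When the emission-wavelength medium is
  homogeneous (the usual case: the preset PS does not absorb at 760 nm),
  the emission walk skips voxel traversal; the physics is identical.

Known, quantified model-vs-MC discrepancies: the diffusion/semi-empirical
forward model agrees with the transport simulation to within a few percent
in the ratio. The residual bias is positive at saturation thickness
(transport corrections to the $e^{-\mu z}$ depth law and, for dense top
layers, PS self-screening) and makes reconstructed buried-layer depths a
few percent shallow. These are properties of the *model*, reproduced — not
introduced — by the simulator.

## Sensitivity to optical-property errors

`sensitivity_scan()` simulates ratios with the true preset and re-inverts
them with absorption and/or scattering scaled (all derived coefficients
recomputed). Under a *joint* scaling $s$ of $\mu_a$ and $\mu_s$, every
attenuation coefficient scales by $s$ while the backscatter factors are
unchanged, so the buried-layer inversion returns $d_b/s$: overestimating
the properties by 30% underestimates depth by $1 - 1/1.3 \approx 23\%$,
underestimating them overestimates it by $1/0.7 - 1 \approx 43\%$ — the
sign rule "underestimated properties, overestimated depth". Scattering-only
errors barely matter for the exponential case; absorption errors dominate.

## Calibration and the imaging pipeline

Measured ratios contain the source intensities, quantum yields and PS
amplitudes. A reference object (a thin PS layer with no depth structure)
measures exactly that product, so the calibrated ratio
$R_\lambda^c = R_\lambda / R_{\lambda,ref}$ (the proportionality constant
fixed to 1 — any other constant cancels in every difference and
$\Delta d_b$) removes them. Inverting a *calibrated* ratio therefore uses a
unit amplitude/yield factor, i.e. $R_0$ reduces to $k_{ex,2}/k_{ex,1}$;
`depth_report(calibrated = TRUE)` does precisely this, and the same
backreflectance ratio can stand in for $R_0$ when amplitudes are unknown.
ROI processing follows the acquisition convention: the same pixel set in
both channels, dark frame subtracted pixelwise, negative pixels clipped at
zero (deterministic and documented, in preference to dropping them) before
averaging.

## Synthetic fixtures

`fixture_spec()`/`make_image_pair()` emulate the wide-field acquisition:
per-pixel mean counts are analytic flux × excitation intensity ×
`counts_scale`, plus a dark level, with Poisson shot noise and Gaussian
read noise on a 16-bit range. Default intensities 1.4/2.2 mW/cm² mirror a
typical LED epifluorescence setup. The generator reproduces photon-budget
noise and dark offset but deliberately *not* illumination non-uniformity,
autofluorescence, spectral bleed-through or lateral structure — passing the
closed-loop tests shows the pipeline arithmetic is right, not that those
real-world effects are harmless. The `phantom_like()` preset is a
qualitative stand-in for layered agarose phantoms (blue absorption ≫ red)
for exercising code paths; quantitative verification uses the dermis preset
whose properties are fully specified.

## Numerical choices and problem sizes

* Closed forms use `expm1` near $d = 0$ and analytic limits at $d = 0$ and
  $d \to \infty$ (no 0/0 evaluations).
* Tabulated profiles are integrated segment-by-segment against the
  exponential kernel in closed form (the kernel is exponential, so
  piecewise-linear profiles integrate exactly); adaptive quadrature with
  relative tolerance $10^{-11}$, truncated where the kernel falls below
  $10^{-12}$ of its surface value, is available as an independent
  cross-check and agrees to $10^{-8}$.
* Stack voxelization stores exact voxel averages of each profile, so the
  depth-integrated PS amount is preserved by construction (the
  conserved-total exponential profile keeps its integral to <0.5% across
  $d_{1e}$, limited only by the 20 mm depth truncation).
* The verification studies in the test suite and the acceptance script use
  $10^6$ excitation photons per wavelength with an equal emission budget
  ($6 \times 10^5$ for the ±30% sensitivity cells, whose ±10-point
  tolerance is far above the ~1% reconstruction noise at that budget) —
  the package's chosen compromise between a ratio standard error of a few
  tenths of a percent and minutes-scale runtimes; the simulator default of
  $10^7$ reproduces the full-scale study conditions when time permits.
* The $\pm 30\%$ sensitivity analysis uses $d_b \in \{0.2, 0.4, 0.6\}$ mm
  and the inverse-accuracy study $d_{1e} \in \{0.1, 0.25, 0.5, 0.75\}$ mm,
  spanning the depth ranges over which the estimators are advertised.

## Limitations

* All profiles are transversely uniform; there is no lateral heterogeneity
  in the analytic model and the MC marginalizes it out.
* The reconstructed depth is an *effective* parameter of an assumed profile
  family; real distributions shaped by diffusion, vascular anatomy and
  tissue heterogeneity will map onto it only approximately.
* Accuracy is dominated by how well the base-tissue optical properties are
  known — absorption above all. Relative changes within one site survive
  this uncertainty far better than absolute depths.
* The diffusion-approximation forward model is a few percent off the
  transport truth near the surface and at strong absorption; the MC
  quantifies this envelope.
* `m` (the total-internal-reflectance factor) is a configuration constant,
  default 2.76 for $n = 1.37$; the package does not compute it from the
  refractive index.
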