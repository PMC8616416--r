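# fluordepth

Ratiometric dual-wavelength fluorescence depth estimation in turbid media.

## What it is for

During photodynamic therapy (PDT) with chlorin-e6–type photosensitizers
(PS), the drug can be excited in two absorption bands — the Soret band
(~405 nm, "blue") and the Q band (~660 nm, "red") — while its near-infrared
fluorescence (~760 nm) is imaged with one camera. Because blue light
penetrates skin-like tissue far less than red light, the intensity-normalized
ratio of the two fluorescence responses,

    R_λ = (F(λ₂)/I_ex2) / (F(λ₁)/I_ex1),

grows monotonically with the depth at which the PS sits and is independent
of its (unknown) concentration. `fluordepth` turns that observation into a
quantitative tool for physicists and translational PDT researchers: given
the tissue optical properties, it maps measured ratios to PS localization
depths, and maps pre/post-PDT ratio pairs to photobleaching depth shifts.

The package implements:

* **Forward model** — diffusion-approximation fluorescence flux
  `F = φ k_ex sinh(q)e^{-q}/q ∫ μ_a,PS(z) e^{-(μ_ex+μ_em)z} dz`
  and closed-form ratios for four canonical PS depth profiles: a uniform
  top layer (thickness `d`), a uniform semispace under a PS-free cover
  (`d_b`), an exponential profile (`d_1e`), and an exponential profile
  under a PS-free cover (surface photobleaching);
* **Inverse estimators** — closed forms for `d_b` and `d_1e`, numeric
  root-finding for `d`, and `Δd_b = ln(R_after/R_before)/(μ_ex1-μ_ex2)`
  for PDT-induced shifts;
* **A dual-step fluorescence Monte Carlo simulator** (Rcpp) for layered
  semi-infinite media — excitation absorption maps, PS-dose–weighted
  isotropic re-emission, Fresnel boundaries, Henyey–Greenstein scattering —
  used to verify the analytic model and to quantify the sensitivity of the
  reconstruction to ±30% optical-property errors;
* **An imaging pipeline** — dark subtraction, ROI statistics,
  intensity normalization, reference-object calibration (`R_c = R_λ/R_ref`),
  and depth reports per administration route;
* **Synthetic fixtures** — noisy 16-bit dual-wavelength image pairs with
  exact ground truth, and two-layer phantom profile series;
* **A command line** — `forward`, `invert`, `mc`, `sensitivity`, `ratio`
  and `fixtures` subcommands over the same functions.

The built-in `dermis_table1()` preset carries human-dermis optical
properties at 405/660/760 nm (e.g. μ_s' = 7.6 mm⁻¹ at 405 nm) and
chlorin-gel PS amplitudes.

## Worked example

```r
library(fluordepth)
tm <- dermis_table1()

# The two asymptotes of the ratio and the buried-layer growth rate:
c(R0 = ratio_limit0(tm), Rinf = ratio_top_inf(tm), slope = tm$coef$delta_mu)
#>        R0      Rinf     slope
#> 0.2392821 0.6645348 3.8129867

# A PS layer buried 0.3 mm below the surface (intravenous case):
R <- ratio_bottom(tm, d_b = 0.3)
R
#> [1] 2.085957
invert_bottom(R, tm)   # recover the cover depth, mm
#> [1] 0.3

# Monte Carlo verification of the same configuration:
cfg <- mc_config(n_photons = 2e5, seed = 7)
st  <- build_stack(tm, ps_profile("bottom_uniform", d_b = 0.3), cfg)
mc_ratio(st, cfg)
#> <mc_result> R = 1.917 (stderr 0.022), F_blue = 0.006469, F_red = 0.0124, 200000 photons/wavelength

# A post-PDT ratio 1.5x the pre-PDT value means the PS upper boundary
# receded by ~0.11 mm (surface photobleaching):
bleach_depth(R_after = 1.5, R_before = 1.0, tm)
#> [1] 0.1063379
```

Reading the numbers: `R0 = 0.239` is the thin-layer limit of the ratio
(blue and red see the PS equally), `Rinf = 0.665` the thick-layer limit,
and every 0.18 mm of PS-free cover doubles the ratio (`ln 2 / 3.813`). The
simulated ratio 1.92 sits ~8% below the closed form at this depth — the
documented model-vs-transport envelope (diffusion approximation plus the
finite simulation geometry), which the sensitivity analysis accounts for.

The methods vignette (`vignettes/ratiometric-depth-model.Rmd`) documents the
model assumptions, the Monte Carlo design choices and the known limitations.

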