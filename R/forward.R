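#' Forward fluorescence flux
#'
#' Diffusion-approximation flux of fluorescence light leaving the tissue
#' surface per unit excitation intensity,
#' \deqn{F = \phi \, k_{ex} \, \frac{\sinh q \, e^{-q}}{q}
#'   \int_0^\infty \mu_{a,PS}(z) \, e^{-(\mu_{ex} + \mu_{em}) z} \, dz,}
#' where \eqn{k_{ex}} is the backscatter factor at the excitation wavelength,
#' \eqn{q} the emission escape parameter, and \eqn{\mu_{ex}}, \eqn{\mu_{em}}
#' the diffusion attenuation coefficients at the excitation and emission
#' wavelengths. The depth integral is evaluated in closed form for the four
#' canonical profiles; for tabulated profiles the piecewise-linear profile is
#' integrated segment-by-segment against the exponential kernel analytically;
#' `method = "quadrature"` forces adaptive numeric quadrature (useful as an
#' independent cross-check of the closed forms).
#'
#' @param tissue a [tissue_model()]
#' @param profile a [ps_profile()]
#' @param channel excitation channel(s), `"blue"` and/or `"red"`
#' @param amplitude optional amplitude override (named `blue`/`red` pair)
#' @param phi optional quantum-yield override (named pair)
#' @param method `"closed"` (default) or `"quadrature"`
#' @return named numeric vector of fluxes per unit excitation intensity
#' @examples
#' tm <- dermis_table1()
#' forward_flux(tm, ps_profile("top_uniform", d = 1))
#' @export
forward_flux <- function(tissue, profile, channel = c("blue", "red"),
                         amplitude = NULL, phi = NULL,
                         method = c("closed", "quadrature")) {
  stopifnot(inherits(tissue, "tissue_model"), inherits(profile, "ps_profile"))
  channel <- match.arg(channel, several.ok = TRUE)
  method <- match.arg(method)
  phi <- resolve_pair(phi %||% tissue$phi, "phi")
  cf <- tissue$coef
  out <- vapply(channel, function(ch) {
    A <- if (ch == "blue") cf$A1 else cf$A2
    k <- if (ch == "blue") cf$k_ex1 else cf$k_ex2
    I <- kernel_integral(profile, A, tissue, ch, amplitude, method)
    phi[[ch]] * k * cf$S_em * I
  }, numeric(1))
  setNames(out, channel)
}

# \int_0^inf mu_a_ps(z, channel) exp(-A z) dz
kernel_integral <- function(profile, A, tissue, channel, amplitude, method) {
  if (method == "quadrature" || profile$kind == "tabulated") {
    return(kernel_integral_numeric(profile, A, tissue, channel, amplitude))
  }
  a <- profile_amplitudes(profile, tissue, amplitude)[[channel]]
  switch(profile$kind,
    top_uniform = if (is.finite(profile$d)) a * (-expm1(-A * profile$d)) / A else a / A,
    bottom_uniform = a * exp(-A * profile$d_b) / A,
    exponential = if (profile$d_1e > 0) a / (A + 1 / profile$d_1e) else 0,
    shifted_exponential = {
      base <- if (profile$d_1e > 0) a / (A + 1 / profile$d_1e) else 0
      base * exp(-A * profile$d_b)
    }
  )
}

kernel_integral_numeric <- function(profile, A, tissue, channel, amplitude) {
  if (profile$kind == "tabulated") {
    # piecewise-linear profile against the exponential kernel, closed form
    # per segment:  int (a + b z) e^{-Az} dz = -[(a + b z)/A + b/A^2] e^{-Az}
    a_amp <- profile_amplitudes(profile, tissue, amplitude)[[channel]]
    z <- profile$z
    v <- a_amp * profile$value
    if (z[1] > 0) { z <- c(0, z); v <- c(v[1], v) } # flat extension to surface
    seg <- function(z0, z1, v0, v1) {
      b <- (v1 - v0) / (z1 - z0)
      a <- v0 - b * z0
      prim <- function(zz) -((a + b * zz) / A + b / A^2) * exp(-A * zz)
      prim(z1) - prim(z0)
    }
    keep <- exp(-A * z[-length(z)]) > 1e-12 # kernel truncation
    sum(purrr::pmap_dbl(
      list(z[-length(z)][keep], z[-1][keep],
           v[-length(v)][keep], v[-1][keep]),
      seg
    ))
  } else {
    f <- function(zz) {
      ps_density(profile, zz, tissue, channel, amplitude) * exp(-A * zz)
    }
    stats::integrate(f, 0, Inf, rel.tol = 1e-11, abs.tol = 0,
                     subdivisions = 500L)$value
  }
}

# amplitude/yield ratio entering every closed-form ratio
ratio_prefactor <- function(tissue, amplitude = NULL, phi = NULL) {
  amp <- resolve_pair(amplitude %||% tissue$mu_a_ps, "amplitude")
  phi <- resolve_pair(phi %||% tissue$phi, "phi")
  (phi[["red"]] * amp[["red"]]) / (phi[["blue"]] * amp[["blue"]])
}

#' Closed-form fluorescence ratios for the canonical PS profiles
#'
#' The ratio \eqn{R_\lambda} of the red-excited to the blue-excited
#' fluorescence response (each per unit excitation intensity) for the
#' canonical depth profiles, in closed form:
#'
#' * `ratio_limit0()`: the thin-layer limit
#'   \eqn{R_0 = (\phi_2 \mu_{a,PS,2} / \phi_1 \mu_{a,PS,1}) (k_{ex,2}/k_{ex,1})},
#'   the common small-depth asymptote of the top-uniform and exponential
#'   cases;
#' * `ratio_top(d)`: top-uniform layer of thickness `d` -- a saturating,
#'   strictly increasing function of `d` running from `R_0` to `R_inf`;
#' * `ratio_top_inf()`: its thick-layer asymptote
#'   \eqn{R_\infty = R_0 (\mu_{ex,1}+\mu_{em})/(\mu_{ex,2}+\mu_{em})};
#' * `ratio_bottom(d_b)`: buried uniform semispace under a PS-free cover of
#'   thickness `d_b` -- exponential growth
#'   \eqn{R_\infty e^{(\mu_{ex,1}-\mu_{ex,2}) d_b}};
#' * `ratio_exp(d_1e)`: exponential profile with 1/e depth `d_1e` --
#'   \eqn{R_0 \, (1 + (\mu_{ex,1}+\mu_{em}) d_{1e}) / (1 + (\mu_{ex,2}+\mu_{em}) d_{1e})},
#'   independent of the surface concentration, with initial slope twice that
#'   of `ratio_top`;
#' * `ratio_bottom_exp(d_1e, d_b)`: the exponential profile under a PS-free
#'   cover -- `ratio_exp(d_1e)` times the same exponential factor as
#'   `ratio_bottom`.
#'
#' All are vectorized over the depth arguments; depth limits 0 and `Inf` are
#' evaluated analytically.
#'
#' @inheritParams forward_flux
#' @param d top-layer thickness, mm (`>= 0`, may be `Inf`)
#' @param d_b PS-free cover thickness, mm
#' @param d_1e exponential 1/e decay depth, mm (may be `Inf`)
#' @return numeric vector of ratios
#' @examples
#' tm <- dermis_table1()
#' ratio_top(tm, c(0.25, 1, 3))
#' ratio_bottom(tm, 0.3) / ratio_top_inf(tm) # exp(3.813 * 0.3)
#' @name fluorescence-ratios
NULL

#' @rdname fluorescence-ratios
#' @export
ratio_limit0 <- function(tissue, amplitude = NULL, phi = NULL) {
  cf <- tissue$coef
  ratio_prefactor(tissue, amplitude, phi) * cf$k_ex2 / cf$k_ex1
}

#' @rdname fluorescence-ratios
#' @export
ratio_top_inf <- function(tissue, amplitude = NULL, phi = NULL) {
  cf <- tissue$coef
  ratio_limit0(tissue, amplitude, phi) * cf$A1 / cf$A2
}

#' @rdname fluorescence-ratios
#' @export
ratio_top <- function(tissue, d, amplitude = NULL, phi = NULL) {
  if (any(d < 0)) abort("`d` must be >= 0")
  cf <- tissue$coef
  R0 <- ratio_limit0(tissue, amplitude, phi)
  shape <- ifelse(d == 0, 1,
           ifelse(is.infinite(d), cf$A1 / cf$A2,
                  (cf$A1 / cf$A2) * expm1(-cf$A2 * d) / expm1(-cf$A1 * d)))
  R0 * shape
}

#' @rdname fluorescence-ratios
#' @export
ratio_bottom <- function(tissue, d_b, amplitude = NULL, phi = NULL) {
  if (any(d_b < 0)) abort("`d_b` must be >= 0")
  cf <- tissue$coef
  ratio_top_inf(tissue, amplitude, phi) * exp(cf$delta_mu * d_b)
}

#' @rdname fluorescence-ratios
#' @export
ratio_exp <- function(tissue, d_1e, amplitude = NULL, phi = NULL) {
  if (any(d_1e < 0)) abort("`d_1e` must be >= 0")
  cf <- tissue$coef
  R0 <- ratio_limit0(tissue, amplitude, phi)
  shape <- ifelse(is.infinite(d_1e), cf$A1 / cf$A2,
                  (cf$A1 * d_1e + 1) / (cf$A2 * d_1e + 1))
  R0 * shape
}

#' @rdname fluorescence-ratios
#' @export
ratio_bottom_exp <- function(tissue, d_1e, d_b, amplitude = NULL, phi = NULL) {
  if (any(d_b < 0)) abort("`d_b` must be >= 0")
  cf <- tissue$coef
  ratio_exp(tissue, d_1e, amplitude, phi) * exp(cf$delta_mu * d_b)
}

#' Fluorescence result for one profile
#'
#' Computes both forward fluxes and their ratio for an arbitrary profile.
#'
#' @inheritParams forward_flux
#' @return a one-row tibble with `F_blue`, `F_red`, `R_lambda`
#' @export
fluorescence_result <- function(tissue, profile, amplitude = NULL, phi = NULL,
                                method = c("closed", "quadrature")) {
  Fv <- forward_flux(tissue, profile, c("blue", "red"), amplitude, phi,
                     method = match.arg(method))
  tibble::tibble(F_blue = Fv[["blue"]], F_red = Fv[["red"]],
                 R_lambda = Fv[["red"]] / Fv[["blue"]])
}

#' Scan the fluorescence ratio against a depth-parameter grid
#'
#' Evaluates the forward model over a grid of the depth parameter of one
#' canonical profile kind and returns a tidy table, one row per grid point.
#'
#' @param tissue a [tissue_model()]
#' @param kind canonical profile kind
#' @param depths grid of the depth parameter, mm (`d`, `d_b` or `d_1e`
#'   according to `kind`)
#' @param d_b fixed cover thickness for `kind = "shifted_exponential"`
#'   (its scanned parameter is `d_1e`)
#' @param conserve_total,amplitude,phi see [ps_profile()] and
#'   [forward_flux()]
#' @return a `ratio_scan` tibble with columns `kind`, `depth`, `F_blue`,
#'   `F_red`, `R_lambda`
#' @examples
#' scan <- ratio_scan(dermis_table1(), "top_uniform", seq(0.1, 3, by = 0.1))
#' @export
ratio_scan <- function(tissue, kind, depths, d_b = 0,
                       conserve_total = FALSE, amplitude = NULL, phi = NULL) {
  rows <- purrr::map_dfr(depths, function(dd) {
    prof <- switch(kind,
      top_uniform = ps_profile("top_uniform", d = dd),
      bottom_uniform = ps_profile("bottom_uniform", d_b = dd),
      exponential = ps_profile("exponential", d_1e = dd,
                               conserve_total = conserve_total),
      shifted_exponential = ps_profile("shifted_exponential", d_1e = dd,
                                       d_b = d_b,
                                       conserve_total = conserve_total),
      abort(paste0("unknown profile kind '", kind, "'"))
    )
    fluorescence_result(tissue, prof, amplitude, phi)
  })
  out <- dplyr::bind_cols(tibble::tibble(kind = kind, depth = depths), rows)
  class(out) <- c("ratio_scan", class(out))
  out
}

#' @export
autoplot.ratio_scan <- function(object, ...) {
  xlab <- switch(object$kind[1],
                 top_uniform = "layer thickness d (mm)",
                 bottom_uniform = "cover thickness d_b (mm)",
                 "1/e decay depth d_1e (mm)")
  ggplot2::ggplot(object, ggplot2::aes(x = .data$depth, y = .data$R_lambda)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = xlab, y = expression(R[lambda]),
                  title = paste("Fluorescence ratio,", object$kind[1], "profile"))
}

#' Write a ratio scan to CSV
#'
#' @param scan a [ratio_scan()] result
#' @param path output CSV path
#' @return `path`, invisibly
#' @export
write_ratio_scan <- function(scan, path) {
  write.csv(as.data.frame(scan), path, row.names = FALSE)
  invisible(path)
}
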