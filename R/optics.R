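#' Derived optical coefficients of a turbid medium
#'
#' Vectorized helpers computing the transport quantities that the analytic
#' fluorescence model consumes from the elementary optical properties of a
#' tissue: absorption coefficient `mu_a` (1/mm), scattering coefficient
#' `mu_s` (1/mm), scattering anisotropy `g` (dimensionless, `0 <= g < 1`).
#'
#' * `reduced_scattering()`: \eqn{\mu_s' = \mu_s (1 - g)}.
#' * `transport_coefficient()`: \eqn{\mu_t' = \mu_a + \mu_s'}.
#' * `diffusion_attenuation()`: \eqn{\mu = \sqrt{3 \mu_a \mu_t'}}, the decay
#'   rate of diffuse light in the diffusion approximation. Requires
#'   `mu_a > 0`; at `mu_a = 0` the diffusion approximation has no attenuation
#'   scale and an error is raised.
#' * `backscatter_factor()`: the semi-empirical multiplier
#'   \eqn{k = 3 + 5.4 p - 2 e^{-17 p}} with
#'   \eqn{p = \exp(-\tfrac{8}{3} \mu / \mu_t')}, accounting for diffusely
#'   backscattered excitation light enhancing the subsurface fluence.
#' * `q_em_factor()`: the dimensionless emission escape parameter
#'   \eqn{q = 2 \mu m / (3 \mu_t')} evaluated at the emission wavelength,
#'   where `m` is the total-internal-reflectance factor of the
#'   tissue--air boundary (about 2.76 for refractive index 1.37).
#'
#' @param mu_a absorption coefficient, 1/mm
#' @param mu_s scattering coefficient, 1/mm
#' @param g scattering anisotropy factor
#' @param m total-internal-reflectance factor, dimensionless
#' @return numeric vector, same length as the inputs
#' @examples
#' reduced_scattering(38, 0.8) # 7.6 1/mm, human dermis at 405 nm
#' backscatter_factor(0.96, 38, 0.8)
#' @name optical-coefficients
NULL

check_optical <- function(mu_a, mu_s, g, n = NULL) {
  if (any(!is.finite(mu_a)) || any(mu_a < 0)) {
    abort("`mu_a` must be finite and >= 0")
  }
  if (any(!is.finite(mu_s)) || any(mu_s < 0)) {
    abort("`mu_s` must be finite and >= 0")
  }
  if (any(!is.finite(g)) || any(g < 0) || any(g >= 1)) {
    abort("`g` must satisfy 0 <= g < 1")
  }
  if (!is.null(n) && (any(!is.finite(n)) || any(n < 1))) {
    abort("refractive index `n` must be >= 1")
  }
  invisible(TRUE)
}

#' @rdname optical-coefficients
#' @export
reduced_scattering <- function(mu_s, g) {
  check_optical(0, mu_s, g)
  mu_s * (1 - g)
}

#' @rdname optical-coefficients
#' @export
transport_coefficient <- function(mu_a, mu_s, g) {
  check_optical(mu_a, mu_s, g)
  mu_a + mu_s * (1 - g)
}

#' @rdname optical-coefficients
#' @export
diffusion_attenuation <- function(mu_a, mu_s, g) {
  check_optical(mu_a, mu_s, g)
  if (any(mu_a == 0)) {
    abort("`mu_a` must be > 0: the diffusion approximation is invalid in a non-absorbing medium")
  }
  sqrt(3 * mu_a * (mu_a + mu_s * (1 - g)))
}

#' @rdname optical-coefficients
#' @export
backscatter_factor <- function(mu_a, mu_s, g) {
  mu_t <- transport_coefficient(mu_a, mu_s, g)
  mu_d <- diffusion_attenuation(mu_a, mu_s, g)
  p <- exp(-(8 / 3) * mu_d / mu_t)
  3 + 5.4 * p - 2 * exp(-17 * p)
}

#' @rdname optical-coefficients
#' @export
q_em_factor <- function(mu_a, mu_s, g, m = 2.76) {
  if (any(m < 0)) abort("`m` must be >= 0")
  mu_t <- transport_coefficient(mu_a, mu_s, g)
  mu_d <- diffusion_attenuation(mu_a, mu_s, g)
  2 * mu_d * m / (3 * mu_t)
}

#' Add derived transport coefficients to an optical-property table
#'
#' Takes a data frame with one row per wavelength and columns `wavelength`,
#' `mu_a`, `mu_s`, `g`, `n` and appends the derived columns `mu_s_prime`,
#' `mu_t_prime`, `mu_diff` and `k_ex` (see [optical-coefficients]).
#'
#' @param props data frame of optical properties by wavelength
#' @return a tibble with the derived coefficient columns appended
#' @examples
#' dermis_table1()$props
#' @export
optical_coefficients <- function(props) {
  props <- as_properties_table(props)
  dplyr::mutate(
    props,
    mu_s_prime = reduced_scattering(.data$mu_s, .data$g),
    mu_t_prime = transport_coefficient(.data$mu_a, .data$mu_s, .data$g),
    mu_diff = diffusion_attenuation(.data$mu_a, .data$mu_s, .data$g),
    k_ex = backscatter_factor(.data$mu_a, .data$mu_s, .data$g)
  )
}

as_properties_table <- function(props) {
  if (!is.data.frame(props)) {
    abort("`props` must be a data frame with columns wavelength, mu_a, mu_s, g, n")
  }
  need <- c("wavelength", "mu_a", "mu_s", "g", "n")
  missing_cols <- setdiff(need, names(props))
  if (length(missing_cols)) {
    abort(paste0("`props` is missing column(s): ", paste(missing_cols, collapse = ", ")))
  }
  check_optical(props$mu_a, props$mu_s, props$g, props$n)
  tibble::as_tibble(props[union(need, names(props))])
}
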