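#' Dual-wavelength tissue model
#'
#' Bundles the base-medium optical properties at the three working
#' wavelengths (blue excitation, red excitation, emission) with the
#' photosensitizer (PS) spectral amplitudes and fluorescence quantum yields.
#' This object is the first argument of every forward- and inverse-model
#' function in the package.
#'
#' The PS amplitudes `mu_a_ps` are the PS absorption coefficients at the two
#' excitation wavelengths for a unit reference concentration (1/mm); `M0` are
#' the corresponding depth-integrated amplitudes used by the
#' total-amount-conserving exponential profile. Only the red/blue ratio of
#' the amplitudes (and of the quantum yields `phi`) enters any fluorescence
#' ratio, so common rescalings are immaterial there.
#'
#' @param props data frame with columns `wavelength`, `mu_a`, `mu_s`, `g`,
#'   `n`; must contain rows for all three working wavelengths. Units: 1/mm
#'   for coefficients, nm for wavelengths.
#' @param lambda_blue,lambda_red,lambda_em working wavelengths in nm
#'   (defaults 405, 660, 760: the Soret and Q absorption bands of
#'   chlorin-type photosensitizers and the near-infrared emission band)
#' @param mu_a_ps named numeric of PS absorption amplitudes at the two
#'   excitation wavelengths, 1/mm
#' @param M0 named numeric of depth-integrated PS amplitudes (amplitude x mm)
#'   for the conserved-total exponential profile; defaults to
#'   `mu_a_ps * 0.2 mm` if absent from the preset
#' @param phi fluorescence quantum yields at blue and red excitation
#'   (default both 1)
#' @param m total-internal-reflectance factor of the tissue--air boundary
#'   (default 2.76, appropriate for refractive index 1.37)
#' @return an object of class `tissue_model`
#' @examples
#' tm <- dermis_table1()
#' tm$coef$k_ex1 # backscatter factor at 405 nm
#' @export
tissue_model <- function(props,
                         lambda_blue = 405, lambda_red = 660, lambda_em = 760,
                         mu_a_ps = c(blue = 0.1, red = 0.02),
                         M0 = NULL,
                         phi = c(blue = 1, red = 1),
                         m = 2.76) {
  props <- as_properties_table(props)
  if (lambda_red <= lambda_blue) abort("`lambda_red` must exceed `lambda_blue`")
  lambdas <- c(blue = lambda_blue, red = lambda_red, em = lambda_em)
  idx <- setNames(match(lambdas, props$wavelength), names(lambdas))
  if (anyNA(idx)) {
    abort(paste0("`props` lacks rows for wavelength(s): ",
                 paste(lambdas[is.na(idx)], collapse = ", ")))
  }
  mu_a_ps <- resolve_pair(mu_a_ps, "mu_a_ps")
  phi <- resolve_pair(phi, "phi")
  if (any(mu_a_ps <= 0)) abort("`mu_a_ps` amplitudes must be > 0")
  if (any(phi <= 0)) abort("`phi` must be > 0")
  if (is.null(M0)) M0 <- mu_a_ps * 0.2
  M0 <- resolve_pair(M0, "M0")
  props <- optical_coefficients(props)
  tm <- structure(
    list(props = props, lambda = lambdas, mu_a_ps = mu_a_ps, M0 = M0,
         phi = phi, m = m),
    class = "tissue_model"
  )
  tm$coef <- tissue_coefficients(tm)
  # model validity: PS perturbation of the base absorption should be small
  base_ex <- props$mu_a[idx[c("blue", "red")]]
  if (any(mu_a_ps / base_ex > 0.25)) {
    warn("mu_a_ps exceeds 25% of the base-tissue absorption; the weak-PS assumption of the analytic model is strained")
  }
  tm
}

resolve_pair <- function(x, what) {
  if (length(x) != 2) abort(paste0("`", what, "` must have length 2 (blue, red)"))
  if (is.null(names(x)) || !all(c("blue", "red") %in% names(x))) {
    names(x) <- c("blue", "red")
  }
  x[c("blue", "red")]
}

tissue_coefficients <- function(tm) {
  row_at <- function(wl) tm$props[match(wl, tm$props$wavelength), ]
  b <- row_at(tm$lambda[["blue"]])
  r <- row_at(tm$lambda[["red"]])
  e <- row_at(tm$lambda[["em"]])
  q_em <- q_em_factor(e$mu_a, e$mu_s, e$g, tm$m)
  list(
    mu_ex1 = b$mu_diff, mu_ex2 = r$mu_diff, mu_em = e$mu_diff,
    k_ex1 = b$k_ex, k_ex2 = r$k_ex,
    q_em = q_em,
    S_em = sinh(q_em) * exp(-q_em) / q_em,
    A1 = b$mu_diff + e$mu_diff,
    A2 = r$mu_diff + e$mu_diff,
    delta_mu = b$mu_diff - r$mu_diff,
    n_med = e$n
  )
}

#' @export
print.tissue_model <- function(x, ...) {
  cat("<tissue_model> wavelengths", paste(x$lambda, collapse = "/"), "nm\n")
  print(x$props)
  cat(sprintf("PS amplitudes (1/mm): blue %.4g, red %.4g; phi %.3g/%.3g; m = %.3g\n",
              x$mu_a_ps[["blue"]], x$mu_a_ps[["red"]],
              x$phi[["blue"]], x$phi[["red"]], x$m))
  cat(sprintf("mu_ex = %.4f / %.4f, mu_em = %.4f 1/mm; k_ex = %.4f / %.4f; q_em = %.4f\n",
              x$coef$mu_ex1, x$coef$mu_ex2, x$coef$mu_em,
              x$coef$k_ex1, x$coef$k_ex2, x$coef$q_em))
  invisible(x)
}

#' Optical-property presets
#'
#' `dermis_table1()` is the human-dermis set used throughout the package's
#' verification studies: at 405/660/760 nm, absorption 0.96/0.15/0.13 1/mm,
#' scattering 38/14/12 1/mm, anisotropy 0.8, refractive index 1.37, with PS
#' amplitudes 0.1/0.02 1/mm (depth-integrated amplitudes 0.02/0.004) matching
#' a chlorin-e6 gel at 0.1% vol. `phantom_like()` is a deliberately
#' qualitative stand-in for agarose/lipofundin/ink phantoms -- blue absorption
#' much larger than red -- for exercising code paths, not for quantitative
#' comparison.
#'
#' @param ... passed to [tissue_model()] (e.g. `phi`, `m`)
#' @return a [tissue_model()]
#' @examples
#' dermis_table1()
#' @export
dermis_table1 <- function(...) {
  props <- tibble::tibble(
    wavelength = c(405, 660, 760),
    mu_a = c(0.96, 0.15, 0.13),
    mu_s = c(38, 14, 12),
    g = c(0.8, 0.8, 0.8),
    n = c(1.37, 1.37, 1.37)
  )
  tissue_model(props, mu_a_ps = c(blue = 0.1, red = 0.02),
               M0 = c(blue = 0.02, red = 0.004), ...)
}

#' @rdname dermis_table1
#' @export
phantom_like <- function(...) {
  props <- tibble::tibble(
    wavelength = c(405, 660, 760),
    mu_a = c(1.2, 0.12, 0.10),
    mu_s = c(25, 12, 10),
    g = c(0.7, 0.7, 0.7),
    n = c(1.35, 1.35, 1.35)
  )
  tissue_model(props, mu_a_ps = c(blue = 0.1, red = 0.02), ...)
}

#' Read optical properties from a YAML config
#'
#' The file maps wavelengths (nm) to property records, e.g.
#' ```yaml
#' properties:
#'   405: {mu_a: 0.96, mu_s: 38, g: 0.8, n: 1.37}
#'   660: {mu_a: 0.15, mu_s: 14, g: 0.8, n: 1.37}
#'   760: {mu_a: 0.13, mu_s: 12, g: 0.8, n: 1.37}
#' ps:
#'   mu_a_ps: {blue: 0.1, red: 0.02}
#'   M0: {blue: 0.02, red: 0.004}
#' ```
#' A top-level `properties` key is optional (a bare wavelength map is also
#' accepted); `ps`, `phi` and `m` keys, when present, feed the corresponding
#' [tissue_model()] arguments.
#'
#' @param path YAML file path
#' @param ... overrides passed to [tissue_model()]
#' @return a [tissue_model()]
#' @export
read_optical_properties <- function(path, ...) {
  cfg <- yaml::read_yaml(path)
  plist <- if (!is.null(cfg$properties)) cfg$properties else cfg
  wl <- suppressWarnings(as.numeric(names(plist)))
  if (anyNA(wl)) abort("optical-property config keys must be wavelengths in nm")
  props <- purrr::map2_dfr(plist, wl, function(rec, w) {
    tibble::tibble(wavelength = w,
                   mu_a = rec$mu_a, mu_s = rec$mu_s,
                   g = rec$g, n = if (is.null(rec$n)) 1.37 else rec$n)
  })
  args <- list(props = props)
  if (!is.null(cfg$ps$mu_a_ps)) args$mu_a_ps <- unlist(cfg$ps$mu_a_ps)
  if (!is.null(cfg$ps$M0)) args$M0 <- unlist(cfg$ps$M0)
  if (!is.null(cfg$phi)) args$phi <- unlist(cfg$phi)
  if (!is.null(cfg$m)) args$m <- cfg$m
  do.call(tissue_model, modifyList(args, list(...)))
}

#' Scale the base optical properties of a tissue model
#'
#' Multiplies the absorption and/or scattering coefficients at all three
#' working wavelengths and recomputes every derived coefficient. This is the
#' perturbation used by [sensitivity_scan()] to emulate imperfect knowledge
#' of the tissue optical properties during depth reconstruction.
#'
#' @param tissue a [tissue_model()]
#' @param scale_mu_a,scale_mu_s multiplicative factors (> 0)
#' @return a new [tissue_model()]
#' @export
perturb_tissue <- function(tissue, scale_mu_a = 1, scale_mu_s = 1) {
  stopifnot(inherits(tissue, "tissue_model"), scale_mu_a > 0, scale_mu_s > 0)
  props <- tissue$props
  props$mu_a <- props$mu_a * scale_mu_a
  props$mu_s <- props$mu_s * scale_mu_s
  tissue_model(props[, c("wavelength", "mu_a", "mu_s", "g", "n")],
               lambda_blue = tissue$lambda[["blue"]],
               lambda_red = tissue$lambda[["red"]],
               lambda_em = tissue$lambda[["em"]],
               mu_a_ps = tissue$mu_a_ps, M0 = tissue$M0,
               phi = tissue$phi, m = tissue$m)
}
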