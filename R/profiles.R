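#' Photosensitizer depth profiles
#'
#' Constructs one of the canonical in-depth PS distributions (depth `z` in
#' mm, `z = 0` at the tissue surface, increasing downward):
#'
#' * `top_uniform`: constant PS in the layer `0 <= z < d` (topical
#'   application that has penetrated to depth `d`), zero below;
#' * `bottom_uniform`: PS-free cover of thickness `d_b`, constant PS in the
#'   semispace below (intravenous administration, PS delivered by deeper
#'   vasculature);
#' * `exponential`: PS concentration decaying as `exp(-z / d_1e)` from the
#'   surface (diffusive penetration after topical application);
#' * `shifted_exponential`: the exponential profile displaced downward by a
#'   PS-free cover `d_b` (surface photobleaching after a light dose);
#' * `tabulated`: arbitrary user-supplied samples `(z, value)`, interpreted
#'   as piecewise-linear between samples and zero beyond the last one.
#'
#' The spectral `amplitude` (named `blue`/`red`, 1/mm) scales the profile at
#' the two excitation wavelengths; when omitted it is taken from the tissue
#' model at evaluation time. For the exponential kinds,
#' `conserve_total = TRUE` switches the amplitude convention from a fixed
#' surface concentration to a fixed total PS amount: the surface amplitude
#' becomes `M0 / d_1e` so that the depth integral of the profile is `M0`
#' regardless of `d_1e`.
#'
#' @param kind profile variant, see Details
#' @param d top-uniform layer thickness, mm
#' @param d_b PS-free cover thickness, mm
#' @param d_1e 1/e decay depth, mm
#' @param amplitude optional named numeric (`blue`, `red`), PS absorption
#'   amplitude in 1/mm (or `M0` in 1/mm x mm when `conserve_total`)
#' @param conserve_total logical; fix the total PS amount instead of the
#'   surface concentration (exponential kinds only)
#' @param z,value depth samples for `kind = "tabulated"` (value is the
#'   dimensionless profile shape; `amplitude` scales it per wavelength)
#' @return an object of class `ps_profile`
#' @examples
#' ps_profile("top_uniform", d = 1)
#' ps_profile("exponential", d_1e = 0.3, conserve_total = TRUE)
#' @export
ps_profile <- function(kind = c("top_uniform", "bottom_uniform", "exponential",
                                "shifted_exponential", "tabulated"),
                       d = NULL, d_b = NULL, d_1e = NULL,
                       amplitude = NULL, conserve_total = FALSE,
                       z = NULL, value = NULL) {
  kind <- match.arg(kind)
  chk <- function(x, nm, allow_inf = FALSE) {
    if (is.null(x)) abort(paste0("`", nm, "` is required for kind '", kind, "'"))
    if (length(x) != 1 || is.na(x) || x < 0 || (!allow_inf && !is.finite(x))) {
      abort(paste0("`", nm, "` must be a single finite value >= 0"))
    }
    x
  }
  p <- list(kind = kind, conserve_total = isTRUE(conserve_total))
  switch(kind,
    top_uniform = { p$d <- chk(d, "d", allow_inf = TRUE) },
    bottom_uniform = { p$d_b <- chk(d_b, "d_b") },
    exponential = { p$d_1e <- chk(d_1e, "d_1e") },
    shifted_exponential = {
      p$d_1e <- chk(d_1e, "d_1e"); p$d_b <- chk(d_b, "d_b")
    },
    tabulated = {
      if (is.null(z) || is.null(value) || length(z) != length(value) || length(z) < 2) {
        abort("tabulated profiles need matching `z` and `value` vectors (length >= 2)")
      }
      if (any(!is.finite(z)) || any(z < 0) || is.unsorted(z, strictly = TRUE)) {
        abort("`z` must be strictly increasing, finite and >= 0")
      }
      if (any(!is.finite(value)) || any(value < 0)) {
        abort("`value` must be finite and >= 0")
      }
      p$z <- as.numeric(z); p$value <- as.numeric(value)
    }
  )
  if (!is.null(amplitude)) {
    amplitude <- resolve_pair(amplitude, "amplitude")
    if (any(amplitude < 0) || any(!is.finite(amplitude))) {
      abort("`amplitude` values must be finite and >= 0")
    }
    p$amplitude <- amplitude
  }
  structure(p, class = "ps_profile")
}

#' @export
print.ps_profile <- function(x, ...) {
  pars <- x[names(x) %in% c("d", "d_b", "d_1e")]
  cat("<ps_profile>", x$kind,
      if (length(pars)) paste(names(pars), "=", signif(unlist(pars), 4), "mm", collapse = ", "),
      if (x$conserve_total) "(total PS amount conserved)", "\n")
  invisible(x)
}

# surface amplitudes at the two excitation wavelengths for a given tissue;
# returns c(blue=, red=) in 1/mm (already divided by d_1e for conserved-total
# exponential kinds)
profile_amplitudes <- function(profile, tissue, amplitude = NULL) {
  amp <- amplitude %||% profile$amplitude %||%
    if (profile$conserve_total &&
        profile$kind %in% c("exponential", "shifted_exponential")) {
      tissue$M0
    } else {
      tissue$mu_a_ps
    }
  amp <- resolve_pair(amp, "amplitude")
  if (profile$conserve_total &&
      profile$kind %in% c("exponential", "shifted_exponential")) {
    if (profile$d_1e <= 0) abort("conserve_total requires d_1e > 0")
    amp <- amp / profile$d_1e
  }
  amp
}

#' Evaluate a PS depth profile
#'
#' Returns the PS absorption coefficient `mu_a_ps(z)` (1/mm) at the given
#' depths for one excitation channel.
#'
#' @param profile a [ps_profile()]
#' @param z depths, mm
#' @param tissue a [tissue_model()] supplying default amplitudes
#' @param channel `"blue"` or `"red"`
#' @param amplitude optional amplitude override (named pair)
#' @return numeric vector of `mu_a_ps` values
#' @export
ps_density <- function(profile, z, tissue, channel = c("blue", "red"),
                       amplitude = NULL) {
  channel <- match.arg(channel)
  a <- profile_amplitudes(profile, tissue, amplitude)[[channel]]
  if (any(z < 0)) abort("depths `z` must be >= 0")
  switch(profile$kind,
    top_uniform = ifelse(z < profile$d, a, 0),
    bottom_uniform = ifelse(z >= profile$d_b, a, 0),
    exponential = a * exp(-z / profile$d_1e),
    shifted_exponential = ifelse(z >= profile$d_b,
                                 a * exp(-(z - profile$d_b) / profile$d_1e), 0),
    tabulated = {
      v <- stats::approx(profile$z, profile$value, xout = z,
                         yleft = profile$value[1], yright = 0, rule = 1)$y
      v[is.na(v)] <- 0
      a * v
    }
  )
}
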