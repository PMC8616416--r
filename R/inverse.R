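#' Inverse depth estimators
#'
#' Closed-form and numeric inverses of the canonical ratio--depth relations
#' (see [fluorescence-ratios]):
#'
#' * `invert_bottom(R)`: PS-free cover thickness
#'   \eqn{d_b = \ln(R / R_\infty) / (\mu_{ex,1} - \mu_{ex,2})}; requires
#'   `R >= R_inf`.
#' * `invert_exp(R)`: exponential 1/e depth
#'   \eqn{d_{1e} = (R - R_0) / (R_0 (\mu_{ex,1}+\mu_{em}) - R (\mu_{ex,2}+\mu_{em}))};
#'   requires `R0 <= R < R_inf`. `clamp = TRUE` clamps sub-`R0` values
#'   (statistical noise in measured ratios) to `R0` with a warning instead of
#'   erroring.
#' * `invert_top(R)`: top-layer thickness by bracketed root finding on the
#'   strictly monotone top-uniform relation; requires `R0 < R < R_inf` and
#'   reports bracket exhaustion beyond `d_max` (the relation saturates, so
#'   thicker layers are indistinguishable).
#' * `bleach_depth(R_after, R_before)`: change of the PS-free cover depth
#'   from a pre/post light-dose ratio pair,
#'   \eqn{\Delta d_b = \ln(R_{after}/R_{before}) / (\mu_{ex,1}-\mu_{ex,2})};
#'   negative values indicate shallowing of the PS localization.
#'
#' All are vectorized over the ratio argument(s) and return depths in mm.
#'
#' @param R,R_after,R_before measured fluorescence ratio(s)
#' @param tissue a [tissue_model()]
#' @param amplitude,phi optional overrides, see [forward_flux()]
#' @param clamp clamp `R < R0` to `R0` (with warning) in `invert_exp()`
#' @param d_max upper search bracket for `invert_top()`, mm; default
#'   `10 * 3 / (mu_ex2 + mu_em)` (ten times the saturation depth)
#' @param tol absolute root tolerance on depth for `invert_top()`, mm
#' @return numeric vector of depths, mm
#' @examples
#' tm <- dermis_table1()
#' invert_bottom(ratio_bottom(tm, 0.3), tm) # 0.3
#' invert_exp(ratio_exp(tm, 0.25), tm)      # 0.25
#' @name inverse-depth
NULL

#' @rdname inverse-depth
#' @export
invert_bottom <- function(R, tissue, amplitude = NULL, phi = NULL) {
  Rinf <- ratio_top_inf(tissue, amplitude, phi)
  if (any(!is.finite(R)) || any(R < Rinf)) {
    abort(sprintf("ratio out of range for the bottom-uniform inverse: R must lie in [R_inf, Inf) with R_inf = %.6g", Rinf))
  }
  log(R / Rinf) / tissue$coef$delta_mu
}

#' @rdname inverse-depth
#' @export
invert_exp <- function(R, tissue, amplitude = NULL, phi = NULL, clamp = FALSE) {
  R0 <- ratio_limit0(tissue, amplitude, phi)
  Rinf <- ratio_top_inf(tissue, amplitude, phi)
  if (any(!is.finite(R))) abort("`R` must be finite")
  if (clamp && any(R < R0)) {
    warn(sprintf("%d ratio value(s) below R0 = %.6g clamped to R0 (measurement noise)", sum(R < R0), R0))
    R <- pmax(R, R0)
  }
  if (any(R < R0) || any(R >= Rinf)) {
    abort(sprintf("ratio out of range for the exponential inverse: R must lie in [R0, R_inf) = [%.6g, %.6g)", R0, Rinf))
  }
  cf <- tissue$coef
  (R - R0) / (R0 * cf$A1 - R * cf$A2)
}

#' @rdname inverse-depth
#' @export
invert_top <- function(R, tissue, amplitude = NULL, phi = NULL,
                       d_max = NULL, tol = 1e-10) {
  R0 <- ratio_limit0(tissue, amplitude, phi)
  Rinf <- ratio_top_inf(tissue, amplitude, phi)
  if (any(!is.finite(R)) || any(R <= R0) || any(R >= Rinf)) {
    abort(sprintf("ratio out of range for the top-uniform inverse: R must lie in the open interval (R0, R_inf) = (%.6g, %.6g)", R0, Rinf))
  }
  d_max <- d_max %||% (10 * 3 / tissue$coef$A2)
  vapply(R, function(r) {
    f <- function(dd) ratio_top(tissue, dd, amplitude, phi) - r
    if (f(d_max) < 0) {
      abort(sprintf("upper bracket exhausted: R = %.6g is not reached below d_max = %.3g mm (the ratio saturates; deeper layers are indistinguishable)", r, d_max))
    }
    uniroot(f, c(0, d_max), tol = tol)$root
  }, numeric(1))
}

#' @rdname inverse-depth
#' @export
bleach_depth <- function(R_after, R_before, tissue) {
  if (any(!is.finite(R_after)) || any(R_after <= 0) ||
      any(!is.finite(R_before)) || any(R_before <= 0)) {
    abort("`R_after` and `R_before` must be finite and > 0")
  }
  log(R_after / R_before) / tissue$coef$delta_mu
}

#' Depth estimate with diagnostics
#'
#' Inverts one measured ratio for a chosen profile kind and packages the
#' result with its admissible ratio interval and the residual of re-running
#' the forward model at the estimated depth.
#'
#' @inheritParams inverse-depth
#' @param kind profile kind to invert (`"top_uniform"`, `"bottom_uniform"`,
#'   `"exponential"`)
#' @param ... passed to the underlying inverse (e.g. `clamp`, `d_max`)
#' @return an object of class `depth_estimate`; `tidy()` turns it into a
#'   one-row tibble
#' @examples
#' est <- estimate_depth(ratio_exp(dermis_table1(), 0.3), dermis_table1(),
#'                       kind = "exponential")
#' tidy(est)
#' @export
estimate_depth <- function(R, tissue, kind = c("exponential", "bottom_uniform",
                                               "top_uniform"),
                           amplitude = NULL, phi = NULL, ...) {
  kind <- match.arg(kind)
  stopifnot(length(R) == 1)
  R0 <- ratio_limit0(tissue, amplitude, phi)
  Rinf <- ratio_top_inf(tissue, amplitude, phi)
  value <- switch(kind,
    exponential = invert_exp(R, tissue, amplitude, phi, ...),
    bottom_uniform = invert_bottom(R, tissue, amplitude, phi),
    top_uniform = invert_top(R, tissue, amplitude, phi, ...)
  )
  fwd <- switch(kind,
    exponential = ratio_exp(tissue, value, amplitude, phi),
    bottom_uniform = ratio_bottom(tissue, value, amplitude, phi),
    top_uniform = ratio_top(tissue, value, amplitude, phi)
  )
  structure(
    list(kind = kind, value = value, R = R,
         valid_range = switch(kind,
           exponential = c(R0, Rinf),
           bottom_uniform = c(Rinf, Inf),
           top_uniform = c(R0, Rinf)),
         residual = fwd - pmax(R, R0 * (kind != "bottom_uniform"))),
    class = "depth_estimate"
  )
}

#' @export
print.depth_estimate <- function(x, ...) {
  cat(sprintf("<depth_estimate> %s: %.4g mm (R = %.4g, admissible [%.4g, %.4g], residual %.2e)\n",
              x$kind, x$value, x$R, x$valid_range[1], x$valid_range[2], x$residual))
  invisible(x)
}

#' @export
tidy.depth_estimate <- function(x, ...) {
  tibble::tibble(kind = x$kind, depth_mm = x$value, R = x$R,
                 R_min = x$valid_range[1], R_max = x$valid_range[2],
                 residual = x$residual)
}
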