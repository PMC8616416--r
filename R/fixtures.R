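#' Synthetic imaging fixtures
#'
#' `fixture_spec()` describes a synthetic dual-wavelength acquisition: an
#' optical preset, a PS depth profile, detector geometry and noise. The
#' emulated setup is wide-field excitation at the blue/red wavelengths with
#' emission-band detection on a 16-bit monochrome camera: per-pixel mean
#' counts are `flux x excitation intensity x counts_scale + dark_level`,
#' with Poisson shot noise on the signal and Gaussian read noise.
#'
#' @param tissue a [tissue_model()] (default [dermis_table1()])
#' @param profile a [ps_profile()]
#' @param image_shape image dimensions `c(rows, cols)`
#' @param counts_scale detector counts per unit fluorescence flux per unit
#'   excitation intensity
#' @param dark_level mean dark counts
#' @param read_noise_sd Gaussian read-noise standard deviation, counts
#'   (0 disables all noise, shot noise included)
#' @param I_ex excitation intensities `c(blue, red)`, mW/cm^2 (defaults
#'   1.4 / 2.2, a typical LED epifluorescence setup)
#' @param seed RNG seed making the fixture reproducible
#' @return an object of class `fixture_spec`
#' @export
fixture_spec <- function(tissue = dermis_table1(),
                         profile = ps_profile("exponential", d_1e = 0.3),
                         image_shape = c(96, 128),
                         counts_scale = 2e5, dark_level = 100,
                         read_noise_sd = 5,
                         I_ex = c(blue = 1.4, red = 2.2),
                         seed = NULL) {
  stopifnot(counts_scale > 0, dark_level >= 0, read_noise_sd >= 0,
            length(image_shape) == 2, all(image_shape >= 1))
  I_ex <- resolve_pair(I_ex, "I_ex")
  if (any(I_ex <= 0)) abort("excitation intensities must be > 0")
  structure(list(tissue = tissue, profile = profile,
                 image_shape = as.integer(image_shape),
                 counts_scale = counts_scale, dark_level = dark_level,
                 read_noise_sd = read_noise_sd, I_ex = I_ex, seed = seed),
            class = "fixture_spec")
}

#' Generate a synthetic dual-wavelength image pair
#'
#' Computes the forward fluxes for the spec's profile, maps them to mean
#' detector counts, and adds dark level and noise. The returned ground truth
#' carries the exact analytic fluxes and ratio the pipeline should recover.
#'
#' @param spec a [fixture_spec()]
#' @return a list with `img_blue`, `img_red`, `dark` (count matrices) and
#'   `truth` (list: `F_blue`, `F_red`, `R_lambda`, `mean_counts`, and the
#'   spec parameters needed to re-measure)
#' @examples
#' pair <- make_image_pair(fixture_spec(seed = 1))
#' pair$truth$R_lambda
#' @export
make_image_pair <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  Fv <- forward_flux(spec$tissue, spec$profile, c("blue", "red"))
  mean_counts <- Fv * spec$I_ex * spec$counts_scale
  if (any(mean_counts + spec$dark_level > 65535)) {
    warn(sprintf("mean counts (%.0f) exceed the 16-bit range; image saturates",
                 max(mean_counts + spec$dark_level)))
  }
  npx <- prod(spec$image_shape)
  render <- function(mu) {
    counts <- if (spec$read_noise_sd > 0) {
      rpois(npx, mu) + spec$dark_level +
        round(rnorm(npx, 0, spec$read_noise_sd))
    } else {
      rep(mu + spec$dark_level, npx)
    }
    matrix(pmin(pmax(counts, 0), 65535), spec$image_shape[1],
           spec$image_shape[2])
  }
  dark <- if (spec$read_noise_sd > 0) {
    matrix(pmin(pmax(spec$dark_level +
                       round(rnorm(npx, 0, spec$read_noise_sd)), 0), 65535),
           spec$image_shape[1], spec$image_shape[2])
  } else {
    matrix(spec$dark_level, spec$image_shape[1], spec$image_shape[2])
  }
  list(
    img_blue = render(mean_counts[["blue"]]),
    img_red = render(mean_counts[["red"]]),
    dark = dark,
    truth = list(F_blue = unname(Fv[["blue"]]), F_red = unname(Fv[["red"]]),
                 R_lambda = unname(Fv[["red"]] / Fv[["blue"]]),
                 mean_counts = mean_counts, I_ex = spec$I_ex,
                 dark_level = spec$dark_level, seed = spec$seed)
  )
}

#' Write a synthetic image pair to disk
#'
#' Writes the three frames as 16-bit TIFFs plus a JSON ground-truth sidecar.
#'
#' @param pair a [make_image_pair()] result
#' @param dir output directory (created if needed)
#' @param name file-name stem
#' @return the sidecar path, invisibly
#' @export
write_fixture <- function(pair, dir, name = "fixture") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_gray16(pair$img_blue, file.path(dir, paste0(name, "_blue.tif")))
  write_gray16(pair$img_red, file.path(dir, paste0(name, "_red.tif")))
  write_gray16(pair$dark, file.path(dir, paste0(name, "_dark.tif")))
  sidecar <- file.path(dir, paste0(name, "_truth.json"))
  jsonlite::write_json(pair$truth, sidecar, auto_unbox = TRUE, digits = NA)
  invisible(sidecar)
}

#' Two-layer phantom profile series
#'
#' Generates the depth-profile sweeps mimicking structured two-layer
#' phantoms: a PS-containing top layer of varying thickness
#' (`kind = "top_layer"`) or a PS-containing bottom semispace under a
#' PS-free cover of varying thickness (`kind = "bottom_layer"`). The
#' thickness grid is sorted and deduplicated; thicknesses must lie within
#' 0.1--5 mm (a zero `bottom_layer` cover, the uniform semispace, is also
#' accepted).
#'
#' @param kind `"top_layer"` or `"bottom_layer"`
#' @param thicknesses layer thickness grid, mm
#' @return a named list of [ps_profile()] objects
#' @examples
#' phantom_series("top_layer", c(0.34, 1, 3))
#' @export
phantom_series <- function(kind = c("top_layer", "bottom_layer"),
                           thicknesses) {
  kind <- match.arg(kind)
  th <- sort(unique(thicknesses))
  lo <- if (kind == "bottom_layer") 0 else 0.1
  if (any(th < lo) || any(th > 5)) {
    abort("phantom layer thicknesses must lie within [0.1, 5] mm")
  }
  profs <- purrr::map(th, function(t) {
    switch(kind,
      top_layer = ps_profile("top_uniform", d = t),
      bottom_layer = ps_profile("bottom_uniform", d_b = t)
    )
  })
  setNames(profs, sprintf("%s_%g_mm", kind, th))
}
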