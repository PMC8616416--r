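#' Monte Carlo configuration
#'
#' Settings for the dual-step fluorescence Monte Carlo simulator.
#'
#' @param n_photons excitation photons launched per wavelength (default
#'   1e7; reduce for quick runs)
#' @param seed RNG seed; the seed fully determines both MC steps
#' @param voxel_dz depth resolution of the absorption/dose grid, mm
#' @param lateral_size lateral extent of the medium (and of the flat
#'   excitation beam), mm; photons crossing the lateral faces are lost
#' @param max_depth bottom truncation depth of the semi-infinite medium, mm
#' @param roulette enable Russian roulette termination of low-weight photons
#' @param roulette_threshold weight below which roulette applies
#' @param roulette_survival survival probability (surviving photons are
#'   reweighted by its inverse, keeping the walk unbiased)
#' @param n_batches number of batches for standard-error estimation
#' @param emission_photons total emission-photon budget of the second MC
#'   step (default: equal to `n_photons`)
#' @return an object of class `mc_config`
#' @export
mc_config <- function(n_photons = 1e7, seed = NULL, voxel_dz = 0.01,
                      lateral_size = 30, max_depth = 20,
                      roulette = TRUE, roulette_threshold = 1e-4,
                      roulette_survival = 0.1,
                      n_batches = 10, emission_photons = NULL) {
  stopifnot(n_photons >= 1, voxel_dz > 0, lateral_size > 0, max_depth > 0,
            roulette_survival > 0, roulette_survival < 1, n_batches >= 1)
  structure(list(
    n_photons = as.integer(n_photons), seed = seed, voxel_dz = voxel_dz,
    lateral_size = lateral_size, max_depth = max_depth,
    roulette = isTRUE(roulette), roulette_threshold = roulette_threshold,
    roulette_survival = roulette_survival, n_batches = as.integer(n_batches),
    emission_photons = as.integer(emission_photons %||% n_photons)
  ), class = "mc_config")
}

#' Discretize a tissue model and PS profile into a medium stack
#'
#' Builds the depth-voxelized medium the MC kernel transports photons
#' through: per-voxel base and PS absorption at both excitation wavelengths
#' (voxel values are exact layer-overlap / exponential-integral averages, so
#' the depth-integrated PS amount is preserved by construction), plus the
#' emission-wavelength properties.
#'
#' @param tissue a [tissue_model()]
#' @param profile a [ps_profile()] (canonical kinds)
#' @param cfg an [mc_config()]
#' @param amplitude optional amplitude override (named `blue`/`red` pair)
#' @return an object of class `medium_stack`
#' @export
build_stack <- function(tissue, profile, cfg = mc_config(), amplitude = NULL) {
  stopifnot(inherits(tissue, "tissue_model"), inherits(profile, "ps_profile"),
            inherits(cfg, "mc_config"))
  if (profile$kind == "tabulated") {
    abort("build_stack() supports the canonical profile kinds only")
  }
  if (profile$kind %in% c("exponential", "shifted_exponential") &&
      profile$d_1e < cfg$voxel_dz) {
    abort(sprintf("d_1e = %.3g mm is below the voxel resolution %.3g mm", profile$d_1e, cfg$voxel_dz))
  }
  n_vox <- as.integer(ceiling(cfg$max_depth / cfg$voxel_dz))
  dz <- cfg$voxel_dz
  z0 <- (seq_len(n_vox) - 1) * dz
  z1 <- z0 + dz
  amp <- profile_amplitudes(profile, tissue, amplitude)
  # exact voxel averages of mu_a_ps(z)
  avg_one <- function(a) {
    switch(profile$kind,
      top_uniform = a * pmax(0, pmin(z1, profile$d) - z0) / dz,
      bottom_uniform = a * pmax(0, z1 - pmax(z0, profile$d_b)) / dz,
      exponential = a * profile$d_1e *
        (exp(-z0 / profile$d_1e) - exp(-z1 / profile$d_1e)) / dz,
      shifted_exponential = {
        lo <- pmax(z0, profile$d_b)
        v <- a * profile$d_1e *
          (exp(-(lo - profile$d_b) / profile$d_1e) -
             exp(-(pmax(z1, lo) - profile$d_b) / profile$d_1e)) / dz
        ifelse(z1 <= profile$d_b, 0, v)
      }
    )
  }
  ps <- cbind(blue = avg_one(amp[["blue"]]), red = avg_one(amp[["red"]]))
  row_at <- function(wl) tissue$props[match(wl, tissue$props$wavelength), ]
  base <- purrr::map(c(blue = "blue", red = "red", em = "em"), function(ch) {
    r <- row_at(tissue$lambda[[ch]])
    list(mu_a = r$mu_a, mu_s = r$mu_s, g = r$g, n = r$n)
  })
  structure(list(
    tissue = tissue, profile = profile, n_vox = n_vox, dz = dz,
    z_mid = z0 + dz / 2, ps = ps, base = base,
    half_lateral = cfg$lateral_size / 2, ambient_n = 1.0
  ), class = "medium_stack")
}

#' @export
print.medium_stack <- function(x, ...) {
  cat(sprintf("<medium_stack> %d voxels x %.3g mm (depth %.3g mm), profile %s\n",
              x$n_vox, x$dz, x$n_vox * x$dz, x$profile$kind))
  invisible(x)
}

seed_offset <- c(blue_ex = 0, blue_em = 1, red_ex = 2, red_em = 3)

# distinct deterministic sub-stream seed per MC step; when no seed is set,
# one is drawn from R's RNG so set.seed() still governs reproducibility
mc_seed_for <- function(cfg, which) {
  base <- cfg$seed %||% sample.int(.Machine$integer.max, 1)
  base * 10 + seed_offset[[which]]
}

#' Excitation absorption map
#'
#' First MC step: transports excitation photons (normal-incidence flat beam,
#' specular entry loss \eqn{((n-1)/(n+1))^2} deducted deterministically,
#' Henyey--Greenstein scattering, Fresnel top boundary) and tallies the
#' depth-resolved absorbed weight. The per-voxel absorption coefficient is
#' the base tissue value plus the local PS contribution; the PS-absorbed
#' dose is the absorbed weight times `mu_a_ps / (mu_a_ps + mu_a_base)`.
#'
#' @param stack a [build_stack()] result
#' @param channel excitation channel, `"blue"` or `"red"`
#' @param cfg an [mc_config()]
#' @return an object of class `mc_absorption_map`: tibble `map` (columns
#'   `z`, `absorbed`, `ps_dose`, per launched photon), per-batch matrices and
#'   the boundary tallies
#' @export
mc_excitation_map <- function(stack, channel = c("blue", "red"),
                              cfg = mc_config()) {
  channel <- match.arg(channel)
  stopifnot(inherits(stack, "medium_stack"))
  b <- stack$base[[channel]]
  mu_a_tot <- b$mu_a + stack$ps[, channel]
  res <- .mc_excitation_cpp(
    cfg$n_photons, cfg$n_batches, mc_seed_for(cfg, paste0(channel, "_ex")),
    mu_a_tot, rep(b$mu_s, stack$n_vox), rep(b$g, stack$n_vox),
    b$n, stack$dz, stack$half_lateral, stack$half_lateral,
    cfg$roulette, cfg$roulette_threshold, cfg$roulette_survival
  )
  frac_ps <- ifelse(mu_a_tot > 0, stack$ps[, channel] / mu_a_tot, 0)
  absorbed <- rowSums(res$absorbed)
  map <- tibble::tibble(
    z = stack$z_mid,
    absorbed = absorbed / cfg$n_photons,
    ps_dose = absorbed * frac_ps / cfg$n_photons
  )
  structure(list(
    channel = channel, map = map,
    absorbed_batches = res$absorbed, launched = res$launched,
    frac_ps = frac_ps,
    tallies = c(specular = res$specular, escaped = res$escaped,
                transmitted = res$transmitted,
                lateral_lost = res$lateral_lost, residual = res$residual,
                absorbed = sum(absorbed)),
    n_photons = cfg$n_photons
  ), class = "mc_absorption_map")
}

#' Fluorescence response for one excitation wavelength
#'
#' Runs both MC steps: the excitation absorption map, then isotropic
#' re-emission from the PS-absorbed dose transported at the emission
#' wavelength. One emission photon bundle is launched per source voxel and
#' batch (stratified source sampling), with weight equal to the voxel's PS
#' dose. The response `F` is the total fluorescence weight escaping the top
#' boundary per launched excitation photon, times the quantum yield.
#'
#' @inheritParams mc_excitation_map
#' @param exc_map optional precomputed [mc_excitation_map()] for this channel
#' @return an object of class `mc_fluorescence`: `F`, per-batch responses,
#'   and the underlying absorption map
#' @export
mc_fluorescence <- function(stack, channel = c("blue", "red"),
                            cfg = mc_config(), exc_map = NULL) {
  channel <- match.arg(channel)
  if (is.null(exc_map)) exc_map <- mc_excitation_map(stack, channel, cfg)
  dose_b <- exc_map$absorbed_batches * exc_map$frac_ps # n_vox x n_batches
  src <- which(rowSums(dose_b) > 0)
  phi <- stack$tissue$phi[[channel]]
  if (length(src) == 0) {
    warn("PS-absorbed dose is zero everywhere; fluorescence response is 0")
    Fb <- rep(0, cfg$n_batches)
  } else {
    k <- max(1L, as.integer(round(cfg$emission_photons /
                                    (cfg$n_batches * length(src)))))
    e <- stack$base$em
    res <- .mc_emission_cpp(
      as.integer(src - 1L), dose_b[src, , drop = FALSE], k,
      mc_seed_for(cfg, paste0(channel, "_em")),
      rep(e$mu_a, stack$n_vox), rep(e$mu_s, stack$n_vox),
      rep(e$g, stack$n_vox),
      e$n, stack$dz, stack$half_lateral, stack$half_lateral,
      cfg$roulette, cfg$roulette_threshold, cfg$roulette_survival
    )
    Fb <- phi * res$escaped / exc_map$launched
  }
  structure(list(
    channel = channel, F = sum(Fb * exc_map$launched) / sum(exc_map$launched),
    F_batches = Fb, exc_map = exc_map
  ), class = "mc_fluorescence")
}

#' Monte Carlo fluorescence ratio
#'
#' Runs [mc_fluorescence()] at both excitation wavelengths (independent
#' seeds derived from `cfg$seed`) and forms the ratio
#' `R = F(red) / F(blue)` together with a batch-mean standard error.
#'
#' @inheritParams mc_excitation_map
#' @return an object of class `mc_result` with elements `F_blue`, `F_red`,
#'   `R_lambda`, `stderr_R`, `R_batches` and the two `mc_fluorescence`
#'   results; `tidy()` gives a one-row tibble
#' @examples
#' \donttest{
#' st <- build_stack(dermis_table1(), ps_profile("top_uniform", d = 3),
#'                   cfg <- mc_config(n_photons = 2e5, seed = 1))
#' mc_ratio(st, cfg)
#' }
#' @export
mc_ratio <- function(stack, cfg = mc_config()) {
  fb <- mc_fluorescence(stack, "blue", cfg)
  fr <- mc_fluorescence(stack, "red", cfg)
  if (fb$F <= 0) abort("blue fluorescence response is zero; ratio undefined")
  Rb <- fr$F_batches / fb$F_batches
  structure(list(
    F_blue = fb$F, F_red = fr$F, R_lambda = fr$F / fb$F,
    R_batches = Rb,
    stderr_R = stats::sd(Rb) / sqrt(length(Rb)),
    blue = fb, red = fr,
    seed = cfg$seed, n_photons = cfg$n_photons
  ), class = "mc_result")
}

#' @export
print.mc_result <- function(x, ...) {
  cat(sprintf("<mc_result> R = %.5g (stderr %.2g), F_blue = %.4g, F_red = %.4g, %g photons/wavelength\n",
              x$R_lambda, x$stderr_R, x$F_blue, x$F_red, x$n_photons))
  invisible(x)
}

#' @export
tidy.mc_result <- function(x, ...) {
  tibble::tibble(F_blue = x$F_blue, F_red = x$F_red,
                 R_lambda = x$R_lambda, stderr_R = x$stderr_R,
                 n_photons = x$n_photons)
}

#' @export
autoplot.mc_absorption_map <- function(object, zmax = NULL, ...) {
  df <- object$map
  if (!is.null(zmax)) df <- dplyr::filter(df, .data$z <= zmax)
  df <- tidyr::pivot_longer(df, c("absorbed", "ps_dose"),
                            names_to = "quantity", values_to = "weight")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$z, y = .data$weight,
                                   colour = .data$quantity)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "depth z (mm)", y = "absorbed weight per photon",
                  title = paste("Excitation absorption map,", object$channel,
                                "channel"))
}

#' Write an absorption map / MC result to disk
#'
#' @param x an `mc_absorption_map` or `mc_result`
#' @param path CSV path (absorption map) or JSON path (MC result)
#' @return `path`, invisibly
#' @export
write_mc_output <- function(x, path) {
  if (inherits(x, "mc_absorption_map")) {
    write.csv(as.data.frame(x$map), path, row.names = FALSE)
  } else if (inherits(x, "mc_result")) {
    jsonlite::write_json(
      list(F_blue = x$F_blue, F_red = x$F_red, R_lambda = x$R_lambda,
           stderr_R = x$stderr_R, R_batches = x$R_batches,
           seed = x$seed, n_photons = x$n_photons),
      path, auto_unbox = TRUE, digits = NA)
  } else {
    abort("`x` must be an mc_absorption_map or mc_result")
  }
  invisible(path)
}
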