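# Monte Carlo kernel checks run at reduced photon counts; the full-scale
# theory-vs-simulation comparisons live in test-acceptance.R.

cfg_small <- function(n = 2e4, seed = 11, ...) {
  mc_config(n_photons = n, seed = seed, ...)
}

test_that("stack discretization reproduces the canonical profiles voxel-exactly", {
  cfg <- cfg_small()
  st <- build_stack(tm_dermis, ps_profile("top_uniform", d = 1), cfg)
  in_layer <- st$z_mid < 1
  expect_equal(st$ps[in_layer, "blue"], rep(0.1, sum(in_layer)),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_true(all(st$ps[!in_layer, "blue"] < 1e-12))
  expect_equal(st$ps[in_layer, "red"], rep(0.02, sum(in_layer)),
               tolerance = 1e-12, ignore_attr = TRUE)

  # conserved-total exponential: depth-integrated PS amount independent of d_1e
  sums <- sapply(c(0.1, 0.3, 1, 3), function(d1e) {
    s <- build_stack(tm_dermis,
                     ps_profile("exponential", d_1e = d1e, conserve_total = TRUE),
                     cfg)
    sum(s$ps[, "blue"]) * s$dz
  })
  expect_true(all(abs(sums / 0.02 - 1) < 0.005))

  st_sh <- build_stack(tm_dermis,
                       ps_profile("shifted_exponential", d_1e = 0.3, d_b = 0.2),
                       cfg)
  expect_true(all(st_sh$ps[st_sh$z_mid < 0.2, "blue"] == 0))
  expect_gt(st_sh$ps[st_sh$z_mid > 0.2, "blue"][1], 0)

  expect_error(build_stack(tm_dermis, ps_profile("exponential", d_1e = 0.005),
                           cfg), "voxel resolution")
})

test_that("a purely absorbing medium reproduces Beer-Lambert absorption exactly", {
  props <- tibble::tibble(wavelength = c(405, 660, 760),
                          mu_a = c(0.96, 0.15, 0.13),
                          mu_s = c(0, 0, 0), g = c(0, 0, 0), n = 1.37)
  tm <- tissue_model(props, mu_a_ps = c(blue = 1e-6, red = 1e-6))
  cfg <- mc_config(n_photons = 2000, seed = 3, max_depth = 10,
                   roulette = FALSE)
  st <- build_stack(tm, ps_profile("bottom_uniform", d_b = 0,
                                   amplitude = c(blue = 0, red = 0)), cfg)
  m <- mc_excitation_map(st, "blue", cfg)
  r_sp <- ((1.37 - 1) / (1.37 + 1))^2
  z0 <- m$map$z - st$dz / 2
  expected <- (1 - r_sp) * (exp(-0.96 * z0) - exp(-0.96 * (z0 + st$dz)))
  # no scattering: every photon travels straight down, so the map is exact
  expect_equal(m$map$absorbed, expected, tolerance = 1e-9)
  expect_equal(unname(m$tallies["escaped"]), 0)
})

test_that("weight is conserved across all tallies without roulette", {
  cfg <- mc_config(n_photons = 5e3, seed = 5, roulette = FALSE)
  st <- build_stack(tm_dermis, ps_profile("top_uniform", d = 1), cfg)
  for (ch in c("blue", "red")) {
    m <- mc_excitation_map(st, ch, cfg)
    total <- sum(m$tallies)
    expect_lt(abs(total / cfg$n_photons - 1), 1e-3)
    expect_lt(abs(total / cfg$n_photons - 1), 1e-9) # exact up to the weight floor
  }
})

test_that("a matched boundary has zero specular reflection", {
  props <- tm_dermis$props[, c("wavelength", "mu_a", "mu_s", "g", "n")]
  props$n <- 1
  tm <- tissue_model(props)
  cfg <- cfg_small(2000)
  st <- build_stack(tm, ps_profile("top_uniform", d = 1), cfg)
  m <- mc_excitation_map(st, "blue", cfg)
  expect_equal(unname(m$tallies["specular"]), 0)
})

test_that("the same seed reproduces an MC run bit-for-bit", {
  cfg <- cfg_small(5e3)
  st <- build_stack(tm_dermis, ps_profile("exponential", d_1e = 0.3,
                                          conserve_total = TRUE), cfg)
  r1 <- mc_ratio(st, cfg)
  r2 <- mc_ratio(st, cfg)
  expect_identical(r1$R_lambda, r2$R_lambda)
  expect_identical(r1$R_batches, r2$R_batches)
  r3 <- mc_ratio(st, mc_config(n_photons = 5e3, seed = 12))
  expect_false(identical(r1$R_lambda, r3$R_lambda))
})

test_that("zero PS gives zero fluorescence with a warning", {
  cfg <- cfg_small(2000)
  st <- build_stack(tm_dermis,
                    ps_profile("top_uniform", d = 1,
                               amplitude = c(blue = 0, red = 0)), cfg)
  expect_warning(f <- mc_fluorescence(st, "blue", cfg), "zero")
  expect_equal(f$F, 0)
})

test_that("the fluorescence response is linear in small PS amplitudes and the ratio is concentration-invariant", {
  cfg <- cfg_small(3e4)
  amp <- c(blue = 0.01, red = 0.002)
  st1 <- build_stack(tm_dermis, ps_profile("top_uniform", d = 1, amplitude = amp), cfg)
  st2 <- build_stack(tm_dermis, ps_profile("top_uniform", d = 1, amplitude = 2 * amp), cfg)
  f1 <- mc_fluorescence(st1, "blue", cfg)
  f2 <- mc_fluorescence(st2, "blue", cfg)
  # same seed, same paths: deviation from doubling is pure self-screening
  expect_equal(f2$F / f1$F, 2, tolerance = 0.02)

  r1 <- mc_ratio(st1, cfg)
  st_half <- build_stack(tm_dermis,
                         ps_profile("top_uniform", d = 1, amplitude = amp / 2), cfg)
  r_half <- mc_ratio(st_half, cfg)
  expect_lt(abs(r_half$R_lambda - r1$R_lambda),
            3 * (r1$stderr_R + r_half$stderr_R) + 0.01 * r1$R_lambda)
})

test_that("the simulated ratio follows the saturating analytic trend", {
  cfg <- cfg_small(4e4)
  r_thin <- mc_ratio(build_stack(tm_dermis, ps_profile("top_uniform", d = 0.25), cfg), cfg)
  r_thick <- mc_ratio(build_stack(tm_dermis, ps_profile("top_uniform", d = 3), cfg), cfg)
  expect_gt(r_thick$R_lambda, r_thin$R_lambda)
  # both sit between the analytic asymptotes (generous noise margin)
  expect_gt(r_thin$R_lambda, R0_DERMIS)
  expect_lt(r_thin$R_lambda, RINF_DERMIS * 1.1)
})

test_that("the batch standard error scales like one over the square root of the photon count", {
  ns <- c(2e4, 3.2e5)
  ses <- sapply(ns, function(n) {
    cfg <- mc_config(n_photons = n, seed = 21, n_batches = 25)
    st <- build_stack(tm_dermis, ps_profile("top_uniform", d = 1), cfg)
    mc_ratio(st, cfg)$stderr_R
  })
  slope <- diff(log(ses)) / diff(log(ns))
  expect_equal(slope, -0.5, tolerance = 0.1)
})

test_that("MC outputs serialize to CSV and JSON", {
  cfg <- cfg_small(5e3)
  st <- build_stack(tm_dermis, ps_profile("top_uniform", d = 1), cfg)
  m <- mc_excitation_map(st, "blue", cfg)
  csv <- withr::local_tempfile(fileext = ".csv")
  write_mc_output(m, csv)
  expect_equal(nrow(read.csv(csv)), st$n_vox)
  r <- mc_ratio(st, cfg)
  js <- withr::local_tempfile(fileext = ".json")
  write_mc_output(r, js)
  back <- jsonlite::read_json(js, simplifyVector = TRUE)
  expect_equal(back$R_lambda, r$R_lambda, tolerance = 1e-12)
  expect_s3_class(autoplot(m), "ggplot")
  expect_s3_class(tidy(r), "tbl_df")
})
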