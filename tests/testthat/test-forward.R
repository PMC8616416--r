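test_that("thin- and thick-layer asymptotes match their closed forms", {
  expect_equal(ratio_limit0(tm_dermis), R0_DERMIS, tolerance = 1e-12)
  expect_equal(ratio_limit0(tm_dermis), 0.2393, tolerance = 1e-4)
  expect_equal(ratio_top_inf(tm_dermis), RINF_DERMIS, tolerance = 1e-12)
  expect_equal(ratio_top_inf(tm_dermis), 0.6645, tolerance = 1e-4)
  expect_equal(ratio_top(tm_dermis, 0), R0_DERMIS, tolerance = 1e-12)
  expect_equal(ratio_top(tm_dermis, Inf), RINF_DERMIS, tolerance = 1e-12)
  # saturation: beyond z* = 3/(mu_ex2 + mu_em) the ratio is flat
  d_sat <- 10 * 3 / (MU_EX2 + MU_EM)
  expect_equal(ratio_top(tm_dermis, d_sat), ratio_top_inf(tm_dermis),
               tolerance = 1e-6)
})

test_that("the top-uniform ratio is monotone and bracketed by its asymptotes", {
  d <- seq(0.005, 8, by = 0.005)
  R <- ratio_top(tm_dermis, d)
  expect_true(all(diff(R) > 0))
  expect_true(all(R > R0_DERMIS & R < RINF_DERMIS))
})

test_that("the buried-layer ratio grows exponentially with the cover depth", {
  expect_equal(ratio_bottom(tm_dermis, 0), ratio_top_inf(tm_dermis),
               tolerance = 1e-12)
  db <- seq(0, 1.5, by = 0.05)
  logR <- log(ratio_bottom(tm_dermis, db))
  slopes <- diff(logR) / diff(db)
  expect_equal(slopes, rep(DELTA_MU, length(slopes)), tolerance = 1e-9)
  expect_equal(DELTA_MU, 3.813, tolerance = 1e-4)
  # doubling depth for the ratio: ln 2 / (mu_ex1 - mu_ex2)
  d2 <- log(2) / DELTA_MU
  expect_equal(ratio_bottom(tm_dermis, d2) / ratio_bottom(tm_dermis, 0), 2,
               tolerance = 1e-12)
  expect_equal(d2, 0.1818, tolerance = 1e-3)
})

test_that("the exponential-profile ratio shares the top-layer asymptotes with twice the initial slope", {
  expect_equal(ratio_exp(tm_dermis, 0), ratio_top(tm_dermis, 0),
               tolerance = 1e-12)
  expect_equal(ratio_exp(tm_dermis, Inf), ratio_top_inf(tm_dermis),
               tolerance = 1e-12)
  h <- 1e-7
  slope_exp <- (ratio_exp(tm_dermis, h) - ratio_exp(tm_dermis, 0)) / h
  slope_top <- (ratio_top(tm_dermis, h) - ratio_top(tm_dermis, 0)) / h
  expect_equal(slope_exp / slope_top, 2, tolerance = 1e-5)
  d <- seq(0.005, 5, by = 0.005)
  expect_true(all(diff(ratio_exp(tm_dermis, d)) > 0))
})

test_that("the shifted-exponential ratio factorizes exactly", {
  d1e <- c(0.1, 0.3, 1)
  db <- c(0.05, 0.2, 0.6)
  for (i in seq_along(d1e)) {
    expect_equal(
      ratio_bottom_exp(tm_dermis, d1e[i], db[i]) / ratio_exp(tm_dermis, d1e[i]),
      exp(DELTA_MU * db[i]), tolerance = 1e-12)
  }
  expect_equal(ratio_bottom_exp(tm_dermis, 0.4, 0), ratio_exp(tm_dermis, 0.4),
               tolerance = 1e-12)
  expect_equal(ratio_bottom_exp(tm_dermis, Inf, 0), ratio_top_inf(tm_dermis),
               tolerance = 1e-12)
})

test_that("every ratio is invariant under a common amplitude rescaling", {
  for (c_scale in c(0.01, 0.5, 7)) {
    amp <- tm_dermis$mu_a_ps * c_scale
    expect_equal(ratio_top(tm_dermis, 0.7, amplitude = amp),
                 ratio_top(tm_dermis, 0.7), tolerance = 1e-12)
    expect_equal(ratio_bottom(tm_dermis, 0.3, amplitude = amp),
                 ratio_bottom(tm_dermis, 0.3), tolerance = 1e-12)
    expect_equal(ratio_exp(tm_dermis, 0.4, amplitude = amp),
                 ratio_exp(tm_dermis, 0.4), tolerance = 1e-12)
    expect_equal(ratio_top_inf(tm_dermis, amplitude = amp),
                 ratio_top_inf(tm_dermis), tolerance = 1e-12)
  }
})

test_that("forward flux is linear in the PS amplitude and degenerates correctly", {
  prof <- ps_profile("top_uniform", d = 1)
  f1 <- forward_flux(tm_dermis, prof)
  f2 <- forward_flux(tm_dermis, prof, amplitude = 2 * tm_dermis$mu_a_ps)
  expect_equal(f2, 2 * f1, tolerance = 1e-12)
  f0 <- forward_flux(tm_dermis, prof, amplitude = c(blue = 0, red = 0))
  expect_equal(unname(f0), c(0, 0))
  # an infinitely thick top layer is the uniform semispace
  expect_equal(forward_flux(tm_dermis, ps_profile("top_uniform", d = Inf)),
               forward_flux(tm_dermis, ps_profile("bottom_uniform", d_b = 0)),
               tolerance = 1e-12)
})

test_that("numeric quadrature reproduces the closed-form fluxes on all canonical profiles", {
  profiles <- list(
    ps_profile("top_uniform", d = 0.8),
    ps_profile("bottom_uniform", d_b = 0.25),
    ps_profile("exponential", d_1e = 0.35),
    ps_profile("shifted_exponential", d_1e = 0.35, d_b = 0.15)
  )
  for (prof in profiles) {
    fc <- fluorescence_result(tm_dermis, prof)
    fq <- fluorescence_result(tm_dermis, prof, method = "quadrature")
    expect_equal(fq$F_blue, fc$F_blue, tolerance = 1e-8)
    expect_equal(fq$F_red, fc$F_red, tolerance = 1e-8)
    expect_equal(fq$R_lambda, fc$R_lambda, tolerance = 1e-8)
  }
})

test_that("tabulated profiles integrate piecewise-exactly against the kernel", {
  # a triangular profile is exactly piecewise linear: the segment-wise
  # closed form must agree with adaptive quadrature of the same profile
  prof <- ps_profile("tabulated", z = c(0, 0.4, 1.2), value = c(0, 1, 0),
                     amplitude = c(blue = 0.1, red = 0.02))
  fc <- forward_flux(tm_dermis, prof)
  fq <- forward_flux(tm_dermis, prof, method = "quadrature")
  expect_equal(fc, fq, tolerance = 1e-8)
  # and a boxcar-like tabulated profile approaches the top-uniform closed form
  zg <- seq(0, 1, by = 0.001)
  prof2 <- ps_profile("tabulated", z = c(zg, 1 + 1e-9), value = c(rep(1, length(zg)), 0),
                      amplitude = tm_dermis$mu_a_ps)
  expect_equal(forward_flux(tm_dermis, prof2)[["blue"]],
               forward_flux(tm_dermis, ps_profile("top_uniform", d = 1))[["blue"]],
               tolerance = 1e-6)
})

test_that("ratio scans are tidy, ordered and serializable", {
  scan <- ratio_scan(tm_dermis, "bottom_uniform", seq(0, 1, by = 0.1))
  expect_s3_class(scan, "ratio_scan")
  expect_named(scan, c("kind", "depth", "F_blue", "F_red", "R_lambda"))
  expect_true(all(diff(scan$R_lambda) > 0))
  path <- withr::local_tempfile(fileext = ".csv")
  write_ratio_scan(scan, path)
  back <- read.csv(path)
  expect_equal(back$R_lambda, scan$R_lambda, tolerance = 1e-12)
  p <- autoplot(scan)
  expect_s3_class(p, "ggplot")
})
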