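test_that("closed-form inverses round-trip exactly on their forward relations", {
  db <- c(0, 0.05, 0.18, 0.45, 1.2)
  expect_equal(invert_bottom(ratio_bottom(tm_dermis, db), tm_dermis), db,
               tolerance = 1e-12)
  d1e <- c(0, 0.1, 0.25, 0.5, 0.75, 2)
  expect_equal(invert_exp(ratio_exp(tm_dermis, d1e), tm_dermis), d1e,
               tolerance = 1e-10)
})

test_that("inverse examples match hand-derived values on the dermis preset", {
  expect_equal(invert_bottom(ratio_top_inf(tm_dermis), tm_dermis), 0,
               tolerance = 1e-12)
  expect_equal(invert_bottom(2 * ratio_top_inf(tm_dermis), tm_dermis),
               log(2) / DELTA_MU, tolerance = 1e-12)
  expect_equal(invert_bottom(2 * ratio_top_inf(tm_dermis), tm_dermis),
               0.1818, tolerance = 1e-3)
  expect_equal(invert_exp(ratio_limit0(tm_dermis), tm_dermis), 0)
  R_mid <- (R0_DERMIS + RINF_DERMIS) / 2
  d_mid <- (R_mid - R0_DERMIS) /
    (R0_DERMIS * (MU_EX1 + MU_EM) - R_mid * (MU_EX2 + MU_EM))
  expect_equal(invert_exp(R_mid, tm_dermis), d_mid, tolerance = 1e-12)
  expect_equal(d_mid, 0.4661, tolerance = 1e-3)
})

test_that("the numeric top-layer inverse round-trips over its admissible range", {
  d <- c(0.01, 0.05, 0.2, 0.7, 1.5, 3)
  d_back <- invert_top(ratio_top(tm_dermis, d), tm_dermis)
  expect_equal(d_back, d, tolerance = 1e-6)
  # near R0 the top and exponential inverses differ by the slope factor two
  R_near <- ratio_top(tm_dermis, 0.01)
  expect_equal(invert_top(R_near, tm_dermis),
               2 * invert_exp(R_near, tm_dermis), tolerance = 0.02)
})

test_that("inverses reject ratios outside their admissible intervals", {
  expect_error(invert_bottom(0.9 * RINF_DERMIS, tm_dermis), "R_inf")
  expect_error(invert_exp(0.9 * R0_DERMIS, tm_dermis), "out of range")
  expect_error(invert_exp(RINF_DERMIS, tm_dermis), "out of range")
  expect_error(invert_top(ratio_limit0(tm_dermis), tm_dermis), "out of range")
  expect_error(invert_top(ratio_top_inf(tm_dermis), tm_dermis), "out of range")
  # saturation: a ratio not reachable below d_max exhausts the bracket
  expect_error(invert_top(ratio_top(tm_dermis, 5), tm_dermis, d_max = 2),
               "bracket exhausted")
  expect_warning(out <- invert_exp(0.95 * R0_DERMIS, tm_dermis, clamp = TRUE),
                 "clamped")
  expect_equal(out, 0)
})

test_that("bleaching depth recovers the cover thickness from pre/post ratio pairs", {
  expect_equal(bleach_depth(0.5, 0.5, tm_dermis), 0)
  d1e <- 0.3
  for (db in c(0.05, 0.2, 0.5)) {
    expect_equal(
      bleach_depth(ratio_bottom_exp(tm_dermis, d1e, db),
                   ratio_exp(tm_dermis, d1e), tm_dermis),
      db, tolerance = 1e-12)
  }
  expect_equal(bleach_depth(exp(1) * 0.4, 0.4, tm_dermis), 1 / DELTA_MU,
               tolerance = 1e-12)
  expect_equal(1 / DELTA_MU, 0.2623, tolerance = 1e-3)
  # shallowing: post ratio below pre ratio gives a negative shift
  expect_lt(bleach_depth(0.3, 0.4, tm_dermis), 0)
  expect_error(bleach_depth(-1, 0.4, tm_dermis), "> 0")
})

test_that("forward/inverse identities hold across random diffusive media", {
  set.seed(7)
  for (tm in random_tissues) {
    db <- runif(3, 0, 1)
    expect_equal(invert_bottom(ratio_bottom(tm, db), tm), db,
                 tolerance = 1e-10)
    d1e <- runif(3, 0, 1.5)
    expect_equal(invert_exp(ratio_exp(tm, d1e), tm), d1e, tolerance = 1e-8)
    d <- runif(2, 0.02, 2)
    expect_equal(invert_top(ratio_top(tm, d), tm), d, tolerance = 1e-6)
    d1e2 <- runif(1, 0.05, 1)
    db2 <- runif(1, 0, 0.8)
    expect_equal(
      bleach_depth(ratio_bottom_exp(tm, d1e2, db2), ratio_exp(tm, d1e2), tm),
      db2, tolerance = 1e-10)
  }
})

test_that("the exponential inverse is strictly increasing in the ratio", {
  R <- seq(R0_DERMIS, RINF_DERMIS - 1e-6, length.out = 400)
  d <- invert_exp(R, tm_dermis)
  expect_true(all(diff(d) > 0))
})

test_that("depth estimates carry diagnostics and tidy to one-row tables", {
  est <- estimate_depth(ratio_exp(tm_dermis, 0.3), tm_dermis, "exponential")
  expect_s3_class(est, "depth_estimate")
  expect_equal(est$value, 0.3, tolerance = 1e-10)
  expect_lt(abs(est$residual), 1e-10)
  td <- tidy(est)
  expect_equal(nrow(td), 1)
  expect_equal(td$depth_mm, 0.3, tolerance = 1e-10)
  expect_equal(td$R_min, R0_DERMIS, tolerance = 1e-12)
})
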