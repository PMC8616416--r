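# Shared fixtures: the dermis preset and hand-derived reference constants.
# The derived constants below are frozen from direct arithmetic on the preset
# (sqrt(3 mu_a mu_t'), the backscatter fit, etc.), independent of the package
# code paths they are used to check.

tm_dermis <- dermis_table1()

# direct arithmetic oracles
oracle_mu_diff <- function(mu_a, mu_s, g) sqrt(3 * mu_a * (mu_a + mu_s * (1 - g)))
oracle_k_ex <- function(mu_a, mu_s, g) {
  mu_t <- mu_a + mu_s * (1 - g)
  p <- exp(-(8 / 3) * oracle_mu_diff(mu_a, mu_s, g) / mu_t)
  3 + 5.4 * p - 2 * exp(-17 * p)
}

MU_EX1 <- oracle_mu_diff(0.96, 38, 0.8) # 4.965159
MU_EX2 <- oracle_mu_diff(0.15, 14, 0.8) # 1.152172
MU_EM <- oracle_mu_diff(0.13, 12, 0.8)  # 0.993328
K_EX1 <- oracle_k_ex(0.96, 38, 0.8)     # 4.096265
K_EX2 <- oracle_k_ex(0.15, 14, 0.8)     # 4.900814
R0_DERMIS <- 0.2 * K_EX2 / K_EX1                          # 0.239282
RINF_DERMIS <- R0_DERMIS * (MU_EX1 + MU_EM) / (MU_EX2 + MU_EM) # 0.664535
DELTA_MU <- MU_EX1 - MU_EX2                               # 3.812987

# a small pool of random but diffusive optical-property sets for
# property-style tests (fixed seed; g < 1, mu_s' > 2 mu_a)
random_tissues <- local({
  set.seed(42)
  lapply(1:6, function(i) {
    g <- runif(1, 0.6, 0.95)
    mu_a <- c(runif(1, 0.4, 1.5), runif(1, 0.05, 0.3), runif(1, 0.05, 0.3))
    mu_s_prime <- c(runif(1, 4, 10), runif(1, 2, 5), runif(1, 2, 5))
    props <- tibble::tibble(
      wavelength = c(405, 660, 760),
      mu_a = mu_a, mu_s = mu_s_prime / (1 - g), g = g, n = 1.37
    )
    amp_b <- runif(1, 0.02, 0.1)
    suppressWarnings(tissue_model(
      props, mu_a_ps = c(blue = amp_b, red = amp_b * runif(1, 0.1, 0.5))
    ))
  })
})
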