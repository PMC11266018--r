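test_that("cte equals the sum of its four independently computed terms", {
  p <- simulate_cpair("N1", seed = 17)
  val <- cte(p$z1, p$z2)
  tau <- attr(val, "tau")
  a <- as.integer(symbolize(p$z1$magnitude))
  th <- as.integer(symbolize(p$z1$phase))
  b <- as.integer(symbolize(p$z2$magnitude))
  ph <- as.integer(symbolize(p$z2$phase))
  expect_equal(as.numeric(val),
               oracle_te(a, b, tau) + oracle_te(th, ph, tau) +
                 oracle_pte(a, b, th, tau) + oracle_pte(th, ph, a, tau),
               tolerance = 1e-10)
  # and term-wise against the public estimators
  terms <- attr(val, "terms")
  expect_equal(unname(terms["mag_te"]),
               transfer_entropy(a, b, tau), tolerance = 1e-12)
  expect_equal(unname(terms["partial_mag"]),
               partial_transfer_entropy(a, b, th, tau), tolerance = 1e-12)
})

test_that("a fully constant target yields zero coupling", {
  z1 <- complex_series(rnorm(80), rnorm(80))
  z2 <- complex_series(rep(2, 80), rep(0.5, 80))
  expect_equal(as.numeric(cte(z1, z2, tau = 1)), 0)
  expect_equal(as.numeric(scte(z1, z2, tau = 1)), 0)
  expect_equal(as.numeric(ste(z1, z2, tau = 1)), 0)
  expect_equal(as.numeric(hte(z1, z2, tau = 1)), 0)
})

test_that("cte decomposes additively into scte plus the partial terms", {
  p <- simulate_cpair("L2", seed = 23)
  full <- cte(p$z1, p$z2, tau = 2)
  simple <- scte(p$z1, p$z2, tau = 2)
  terms <- attr(full, "terms")
  expect_equal(as.numeric(full) - as.numeric(simple),
               unname(terms["partial_mag"] + terms["partial_phase"]),
               tolerance = 1e-12)
  expect_equal(unname(attr(simple, "terms")),
               unname(terms[c("mag_te", "phase_te")]), tolerance = 1e-12)
})

test_that("constant conditioners collapse partial terms to plain TE", {
  set.seed(29)
  z1 <- complex_series(rnorm(100), rep(1, 100))  # constant source phase
  z2 <- complex_series(rnorm(100) + 0.7 * c(0, rnorm(99)), rnorm(100))
  terms <- attr(cte(z1, z2, tau = 1), "terms")
  expect_equal(unname(terms["partial_mag"]), unname(terms["mag_te"]),
               tolerance = 1e-12)
  expect_equal(unname(terms["phase_te"]), 0)  # constant source phase
})

test_that("the direct-TE ablation uses plain cross-channel TE", {
  p <- simulate_cpair("N1", seed = 37)
  val <- cte_direct(p$z1, p$z2, tau = 1)
  terms <- attr(val, "terms")
  a <- as.integer(symbolize(p$z1$magnitude))
  th <- as.integer(symbolize(p$z1$phase))
  b <- as.integer(symbolize(p$z2$magnitude))
  ph <- as.integer(symbolize(p$z2$phase))
  expect_equal(unname(terms["cross_mag2_phase1"]),
               transfer_entropy(b, th, 1), tolerance = 1e-12)
  expect_equal(unname(terms["cross_mag1_phase2"]),
               transfer_entropy(a, ph, 1), tolerance = 1e-12)
  expect_equal(as.numeric(val), sum(terms), tolerance = 1e-12)
})

test_that("ste is transfer entropy between symbolized magnitudes", {
  p <- simulate_cpair("L1", seed = 43)
  val <- ste(p$z1, p$z2)
  expect_equal(as.numeric(val),
               transfer_entropy(symbolize(p$z1$magnitude),
                                symbolize(p$z2$magnitude),
                                tau = attr(val, "tau")),
               tolerance = 1e-12)
})

test_that("hte matches brute force on its binned representation", {
  set.seed(47)
  z1 <- complex_series(rnorm(8), rnorm(8))
  z2 <- complex_series(rnorm(8), rnorm(8))
  val <- hte(z1, z2, tau = 1)
  ca <- bin_raw(z1$magnitude, z2$magnitude)
  cb <- bin_raw(z2$magnitude, z1$magnitude)
  expect_equal(as.numeric(val), oracle_te(ca, cb, 1), tolerance = 1e-10)
})

test_that("symbolic estimators are scale-invariant, hte is not", {
  p <- simulate_cpair("L1", seed = 53)
  scale_pair <- function(s1, s2) list(
    z1 = complex_series(s1 * p$z1$magnitude, s1 * p$z1$phase),
    z2 = complex_series(s2 * p$z2$magnitude, s2 * p$z2$phase))
  q <- scale_pair(12.5, 0.004)
  expect_equal(as.numeric(cte(q$z1, q$z2, tau = 1)),
               as.numeric(cte(p$z1, p$z2, tau = 1)), tolerance = 1e-12)
  expect_equal(as.numeric(ste(q$z1, q$z2, tau = 1)),
               as.numeric(ste(p$z1, p$z2, tau = 1)), tolerance = 1e-12)
})

test_that("phase-noise families reduce scte to the magnitude channel", {
  p <- simulate_cpair("L3", seed = 59, T = 500)
  s <- scte(p$z1, p$z2, tau = 1)
  terms <- attr(s, "terms")
  mag_only <- transfer_entropy(symbolize(p$z1$magnitude),
                               symbolize(p$z2$magnitude), tau = 1)
  expect_equal(unname(terms["mag_te"]), mag_only, tolerance = 1e-12)
  # the phase term is pure finite-sample bias, far below the magnitude term
  expect_lt(unname(terms["phase_te"]), 0.5 * unname(terms["mag_te"]))
})
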