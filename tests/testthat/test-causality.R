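test_that("shuffle surrogates permute time but preserve marginals", {
  set.seed(3)
  z <- complex_series(rnorm(60), rnorm(60))
  s <- shuffle_surrogate(z, seed = 5)
  expect_equal(sort(s$magnitude), sort(z$magnitude))
  expect_equal(sort(s$phase), sort(z$phase))
  # magnitude and phase move together: the per-sample pairing survives
  expect_setequal(paste(s$magnitude, s$phase), paste(z$magnitude, z$phase))
  expect_equal(shuffle_surrogate(z, seed = 5), s)
  expect_false(identical(shuffle_surrogate(z, seed = 6)$magnitude,
                         s$magnitude))
  zc <- complex_series(rep(1, 10), rep(2, 10))
  expect_equal(shuffle_surrogate(zc, seed = 1), zc)
})

test_that("a linearly coupled pair is detected as forward", {
  p <- simulate_cpair("L1", T = 146, seed = 2024)
  ct <- causality(p$z1, p$z2, estimator = "cte", R = 100, seed = 1)
  expect_s3_class(ct, "cvte_causality")
  expect_identical(ct$direction, "forward")
  expect_gt(ct$delta_c_mean, 0)
  expect_lt(ct$p_value, 0.05)
  expect_length(ct$delta_c_samples, 100)
})

test_that("swapping the pair negates Delta-C and flips the verdict", {
  p <- simulate_cpair("N1", seed = 77)
  fwd <- causality(p$z1, p$z2, estimator = "cte", R = 60, seed = 99)
  rev <- causality(p$z2, p$z1, estimator = "cte", R = 60, seed = 99)
  expect_equal(fwd$delta_c_mean, -rev$delta_c_mean, tolerance = 1e-12)
  expect_equal(fwd$delta_c_samples, -rev$delta_c_samples, tolerance = 1e-12)
  expect_identical(rev$direction,
                   c(forward = "reverse", reverse = "forward",
                     none = "none")[[fwd$direction]])
})

test_that("the pipeline is reproducible from its seed", {
  p <- simulate_cpair("L2", seed = 5)
  a <- causality(p$z1, p$z2, estimator = "scte", R = 40, seed = 123)
  b <- causality(p$z1, p$z2, estimator = "scte", R = 40, seed = 123)
  expect_identical(a$delta_c_samples, b$delta_c_samples)
  expect_identical(a$p_value, b$p_value)
})

test_that("degenerate pairs give a none verdict via the zero-variance rule", {
  z1 <- complex_series(rnorm(50), rnorm(50))
  z2 <- complex_series(rep(1, 50), rep(0, 50))
  ct <- causality(z1, z2, estimator = "cte", tau = 1, R = 20, seed = 1)
  expect_identical(ct$direction, "none")
  expect_equal(ct$delta_c_mean, 0)
  expect_equal(ct$p_value, 1)
})

test_that("verdict fields are internally consistent", {
  set.seed(8)
  for (rep in 1:5) {
    ct <- causality(white_pair(), white_pair(), estimator = "ste",
                    R = 30, seed = rep)
    if (ct$direction == "none") {
      expect_true(ct$p_value >= ct$p_th || ct$delta_c_mean == 0)
    } else {
      expect_lt(ct$p_value, ct$p_th)
      expect_identical(ct$direction,
                       if (ct$delta_c_mean > 0) "forward" else "reverse")
    }
  }
})

test_that("granger estimator integrates with the causality interface", {
  p <- simulate_cpair("L1", seed = 15)
  ct <- causality(p$z1, p$z2, estimator = "granger")
  gc <- granger_causality(p$z1$magnitude, p$z2$magnitude)
  expect_identical(ct$direction, gc$direction)
  expect_identical(ct$tau, gc$order_J)
  expect_identical(ct$direction, "forward")
})

test_that("results round-trip through the data frame and CSV writers", {
  p <- simulate_cpair("L1", seed = 4)
  ct <- causality(p$z1, p$z2, estimator = "cte", R = 30, seed = 2)
  df <- as.data.frame(ct, pair_id = "z1->z2")
  expect_identical(df$direction, ct$direction)
  path <- tempfile(fileext = ".csv")
  write_causality_csv(ct, path, pair_ids = "z1->z2",
                      config = list(seed = 2, estimator = "cte"))
  lines <- readLines(path)
  expect_true(any(grepl("^# seed = 2", lines)))
  back <- read.csv(path, comment.char = "#")
  expect_identical(back$direction, ct$direction)
  expect_equal(back$delta_c_mean, ct$delta_c_mean, tolerance = 1e-12)
})
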