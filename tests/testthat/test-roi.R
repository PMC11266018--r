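make_volumes <- function(nx = 4, ny = 4, nz = 4, Tn = 10, n_roi = 3,
                         seed = 1) {
  set.seed(seed)
  atlas <- array(0L, c(nx, ny, nz))
  vox <- sample(nx * ny * nz)
  per <- floor(length(vox) / (n_roi + 1))  # leave some background
  for (r in seq_len(n_roi))
    atlas[vox[((r - 1) * per + 1):(r * per)]] <- r
  gens <- lapply(seq_len(n_roi), function(r)
    list(mag = 1 + r + sin(2 * pi * r * seq_len(Tn) / Tn),
         ph = cos(2 * pi * r * seq_len(Tn) / Tn) / r))
  mag <- array(0, c(nx, ny, nz, Tn))
  ph <- array(0, c(nx, ny, nz, Tn))
  for (t in seq_len(Tn)) {
    sl_m <- array(0, c(nx, ny, nz))
    sl_p <- array(0, c(nx, ny, nz))
    for (r in seq_len(n_roi)) {
      sl_m[atlas == r] <- gens[[r]]$mag[t]
      sl_p[atlas == r] <- gens[[r]]$ph[t]
    }
    mag[, , , t] <- sl_m
    ph[, , , t] <- sl_p
  }
  list(mag = mag, ph = ph, atlas = atlas, gens = gens)
}

test_that("uniform ROIs are recovered exactly", {
  v <- make_volumes()
  rs <- extract_roi_series(v$mag, v$ph, v$atlas)
  expect_identical(length(rs$series), 3L)
  for (r in 1:3) {
    expect_equal(rs$series[[r]]$magnitude, v$gens[[r]]$mag, tolerance = 1e-12)
    expect_equal(rs$series[[r]]$phase, v$gens[[r]]$ph, tolerance = 1e-12)
  }
})

test_that("voxel averaging is the arithmetic mean", {
  atlas <- array(0L, c(2, 1, 1))
  atlas[1:2] <- 1L
  mag <- array(c(1, 3, 1, 3, 1, 3), c(2, 1, 1, 3))
  ph <- array(c(0.2, 0.4, 0.2, 0.4, 0.2, 0.4), c(2, 1, 1, 3))
  rs <- extract_roi_series(mag, ph, atlas)
  expect_equal(rs$series[[1]]$magnitude, rep(2, 3))
  expect_equal(rs$series[[1]]$phase, rep(0.3, 3))
})

test_that("empty ROI labels are excluded with a warning", {
  v <- make_volumes()
  atlas <- v$atlas
  atlas[atlas == 2L] <- 5L  # labels 2 and 4 now have no voxels
  w <- capture_warnings(rs <- extract_roi_series(v$mag, v$ph, atlas))
  expect_true(any(grepl("no voxels", w)))
  expect_setequal(rs$excluded, c(2L, 4L))
  expect_null(rs$series[[2]])
  expect_equal(rs$series[[5]]$magnitude, v$gens[[2]]$mag, tolerance = 1e-12)
})

test_that("dimension mismatches are rejected", {
  v <- make_volumes()
  expect_error(extract_roi_series(v$mag, v$ph[, , , 1:5], v$atlas),
               "dimensions differ")
  expect_error(extract_roi_series(v$mag, v$ph, v$atlas[1:2, , ]),
               "grid")
})

test_that("connectivity matrices are antisymmetric with zero diagonal", {
  set.seed(33)
  rois <- lapply(1:4, function(i) white_pair(60))
  cm <- connectivity_matrix(rois, estimator = "ste", R = 20, seed = 2)
  expect_equal(cm$delta_c, -t(cm$delta_c))
  expect_true(all(diag(cm$delta_c) == 0))
  expect_true(all(!diag(cm$sig)))
  expect_equal(cm$p, t(cm$p))
})

test_that("magnitude-phase correlation behaves at the extremes", {
  set.seed(41)
  base <- rnorm(50)
  subj <- lapply(1:3, function(k) {
    list(complex_series(base + 0.001 * k, rnorm(50)),
         complex_series(rnorm(50), base + 0.001 * k))
  })
  m <- magphase_correlation(subj)
  expect_equal(dim(m), c(2L, 2L))
  # ROI 1 magnitude is (nearly) ROI 2's phase
  expect_gt(m[1, 2], 0.999)
  expect_true(all(m >= -1 & m <= 1))
  # independent channels: null band shrinks with subjects and T
  subj0 <- lapply(1:20, function(k)
    list(complex_series(rnorm(100), rnorm(100)),
         complex_series(rnorm(100), rnorm(100))))
  m0 <- magphase_correlation(subj0)
  expect_lt(max(abs(m0)), 3 / sqrt(100 * 20) * 5 + 0.1)
})

test_that("constant series give zero correlation with a warning", {
  subj <- list(list(complex_series(rep(1, 30), rnorm(30)),
                    complex_series(rnorm(30), rnorm(30))))
  expect_warning(m <- magphase_correlation(subj), "constant")
  expect_equal(m[1, 1], 0)
  expect_equal(m[1, 2], 0)
})

test_that("identical groups yield no significant edges", {
  set.seed(51)
  g1 <- lapply(1:10, function(i) {
    m <- matrix(rnorm(36), 6)
    m <- m - t(m); diag(m) <- 0; m
  })
  out <- group_edge_test(g1, g1)
  expect_identical(sum(out$sig), 0L)
  expect_true(all(out$t == 0))
})

test_that("planted edge differences are recovered exactly", {
  set.seed(61)
  N <- 10
  n_sub <- 40
  g1 <- lapply(seq_len(n_sub), function(i) {
    m <- matrix(rnorm(N * N), N)
    m <- m - t(m); diag(m) <- 0; m
  })
  planted <- cbind(c(1, 2, 3, 4, 5), c(6, 7, 8, 9, 10))
  g2 <- lapply(g1, function(m) {
    for (r in seq_len(nrow(planted))) {
      i <- planted[r, 1]; j <- planted[r, 2]
      m[i, j] <- m[i, j] + 3 * sqrt(2)   # +3 pooled sd (unit variances)
      m[j, i] <- -m[i, j]
    }
    m
  })
  out <- group_edge_test(g1, g2, p_th = 0.05)
  found <- which(out$sig & upper.tri(out$sig), arr.ind = TRUE)
  expect_identical(nrow(found), 5L)
  expect_setequal(paste(found[, 1], found[, 2]),
                  paste(planted[, 1], planted[, 2]))
  # BH monotonicity: stricter threshold selects a subset
  strict <- group_edge_test(g1, g2, p_th = 0.01)
  expect_true(all(out$sig[strict$sig]))
})

test_that("zero-variance edges shortcut to exact equality", {
  g1 <- lapply(1:3, function(i) matrix(c(0, 1, -1, 0), 2))
  g2 <- lapply(1:3, function(i) matrix(c(0, 2, -2, 0), 2))
  out <- group_edge_test(g1, g2)
  expect_equal(out$p[1, 2], 0)
  expect_true(out$sig[1, 2])
  same <- group_edge_test(g1, g1)
  expect_equal(same$p[1, 2], 1)
})

test_that("network aggregation counts significant block edges", {
  set.seed(71)
  g1 <- lapply(1:20, function(i) matrix(rnorm(16), 4))
  g2 <- lapply(1:20, function(i) matrix(rnorm(16), 4) +
                 matrix(c(0, 5, 0, 0, 5, 0, 0, 0, 0, 0, 0, 0,
                          0, 0, 0, 0), 4))
  out <- group_edge_test(g1, g2, network_map = c("A", "A", "B", "B"))
  expect_identical(dim(out$network_counts), c(2L, 2L))
  expect_gte(out$network_counts["A", "A"], 1L)
})
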