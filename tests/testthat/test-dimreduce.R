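test_that("Achlioptas sampling follows the ternary law deterministically", {
  P <- sample_achlioptas(16L, 201L, seed = 4)
  expect_equal(dim(P), c(16L, 201L))
  expect_true(all(P %in% c(-1L, 0L, 1L)))
  expect_identical(unclass(sample_achlioptas(5, 40, seed = 9)),
                   unclass(sample_achlioptas(5, 40, seed = 9)))
  expect_error(sample_achlioptas(10, 10, 1), "k < d")

  # empirical zero fraction over 10^6 entries within 2/3 +/- 0.002
  big <- sample_achlioptas(1000L, 1001L, seed = 123)
  zf <- mean(big == 0L)
  expect_lt(abs(zf - 2 / 3), 0.002)
})

test_that("signed-accumulation projection equals the dense product exactly", {
  # structural cases
  Pz <- structure(matrix(0L, 3, 10), class = "achlioptas_matrix")
  expect_equal(as.numeric(project_rp(Pz, rnorm(10))), rep(0, 3))
  P1 <- structure(matrix(0L, 2, 6), class = "achlioptas_matrix")
  P1[1, 4] <- 1L
  v <- rnorm(6)
  expect_equal(as.numeric(project_rp(P1, v))[1], v[4])

  # oracle equivalence on random cases
  set.seed(14)
  for (rep in 1:20) {
    P <- sample_achlioptas(4L, 10L, seed = rep)
    v <- rnorm(10)
    expect_equal(as.numeric(project_rp(P, v)),
                 as.numeric(unclass(P) %*% v))
  }
  expect_error(project_rp(sample_achlioptas(4, 10, 1), rnorm(9)), "does not match")
})

test_that("2-bit packing is lossless with the documented layout", {
  P <- sample_achlioptas(16L, 201L, seed = 2)
  buf <- pack_achlioptas(P)
  expect_length(buf, 804L)                     # ceiling(16 * 201 / 4)
  expect_identical(strip_m(unpack_achlioptas(buf, 16L, 201L)), strip_m(P))

  # fixed byte layout: row-major, entry 4i+j in bits 2j..2j+1, 0->00 +1->01 -1->10
  Pk <- structure(matrix(c(0L, 1L, -1L, 0L, 1L, 1L, -1L, -1L),
                         nrow = 2, byrow = TRUE),
                  class = "achlioptas_matrix")
  expect_identical(pack_achlioptas(Pk),
                   as.raw(c(0x01 * 4 + 0x02 * 16,          # 0,+1,-1,0
                            0x01 + 0x01 * 4 + 0x02 * 16 + 0x02 * 64)))

  # property sweep over random shapes, including non-multiple-of-4 sizes
  set.seed(6)
  for (rep in 1:25) {
    k <- sample(1:9, 1)
    d <- sample((k + 1):30, 1)
    P <- sample_achlioptas(k, d, seed = rep + 100)
    expect_identical(strip_m(unpack_achlioptas(pack_achlioptas(P), k, d)),
                     strip_m(P))
  }
  expect_error(unpack_achlioptas(as.raw(1:3), 4L, 10L), "expected")
})

test_that("power-iteration PCA matches a full eigendecomposition", {
  set.seed(31)
  # 1-D subspace plus tiny noise: leading row parallel to the direction
  dir <- rnorm(12)
  dir <- dir / sqrt(sum(dir^2))
  X1 <- outer(rnorm(80, sd = 3), dir) + matrix(rnorm(80 * 12, sd = 0.01), 80)
  fit1 <- fit_pca(X1, 1L)
  expect_gt(abs(sum(fit1$components[1, ] * dir)), 0.999)

  # small data vs brute-force covariance eigendecomposition
  X <- matrix(rnorm(5 * 4), 5, 4)
  fit <- fit_pca(X, 3L)
  S <- crossprod(sweep(X, 2, colMeans(X))) / nrow(X)
  eig <- eigen(S, symmetric = TRUE)
  expect_equal(fit$eigenvalues, eig$values[1:3], tolerance = 1e-6)
  for (j in 1:3) {
    expect_gt(abs(sum(fit$components[j, ] * eig$vectors[, j])), 0.999)
  }

  # orthonormal rows, descending explained variance, sign convention
  G <- fit_pca(matrix(rnorm(60 * 8), 60, 8) %*% diag(c(4, 3, 2, 1, rep(0.2, 4))), 4L)
  expect_equal(G$components %*% t(G$components), diag(4), tolerance = 1e-6)
  expect_true(all(diff(G$eigenvalues) <= 1e-9))
  for (j in 1:4) {
    r <- G$components[j, ]
    expect_gt(r[which.max(abs(r))], 0)
  }
  expect_error(fit_pca(matrix(1, 10, 4), 2L), "degenerate")
  expect_error(fit_pca(matrix(rnorm(8), 2, 4), 2L), "at least")
})

test_that("PCA reconstruction error is non-increasing in k", {
  set.seed(77)
  X <- matrix(rnorm(50 * 10), 50, 10) %*% diag(seq(5, 0.5, length.out = 10))
  errs <- sapply(1:6, function(k) {
    f <- fit_pca(X, k)
    Z <- sweep(X, 2, f$mean_vector)
    sum((Z - Z %*% t(f$components) %*% f$components)^2)
  })
  expect_true(all(diff(errs) <= 1e-8))
})

test_that("PCA projection centers and rotates as documented", {
  set.seed(8)
  X <- matrix(rnorm(40 * 6), 40, 6)
  f <- fit_pca(X, 3L)
  expect_equal(as.numeric(project_pca(f, f$mean_vector)), rep(0, 3))
  u <- project_pca(f, f$mean_vector + f$components[1, ])
  expect_equal(as.numeric(u), c(1, 0, 0), tolerance = 1e-6)
  v <- rnorm(6)
  expect_equal(as.numeric(project_pca(f, v)),
               as.numeric(f$components %*% (v - f$mean_vector)))
  expect_error(project_pca(f, rnorm(5)), "does not match")
})

test_that("feature concatenation is ordered, fixed-length and injective", {
  fpd <- delineate_fpd(generate_beat("N", 360, seed = 1), 360)
  u8 <- structure(rnorm(8), reducer_id = "rp")
  out <- combine_features(u8, fpd)
  expect_length(out, 16L)
  expect_equal(as.numeric(out[1:8]), as.numeric(u8))
  expect_equal(as.numeric(out[9:16]), as.numeric(fpd$offsets))
  expect_equal(as.numeric(combine_features(rep(0, 8),
                                           ecgtriage:::fiducial_set(
                                             stats::setNames(rep(NA_integer_, 8),
                                                             ecgtriage:::FPD_NAMES),
                                             stats::setNames(rep(FALSE, 8),
                                                             ecgtriage:::FPD_NAMES),
                                             201L))),
               rep(0, 16))
  expect_error(combine_features(rnorm(7), fpd), "8 coefficients")
})
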