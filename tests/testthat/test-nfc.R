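test_that("gaussian membership grades behave as gaussians", {
  mf <- membership_function(center = 1.3, sigma = 0.4)
  expect_equal(membership_grade(mf, 1.3), 1)
  expect_equal(membership_grade(mf, 1.3 + 0.4), exp(-1 / 2))
  # |u - c| = S = 2.35 sigma, the linearization breakpoint
  expect_equal(membership_grade(mf, 1.3 + 2.35 * 0.4), exp(-2.35^2 / 2))
  # symmetry, monotone decay, range
  us <- seq(-3, 3, 0.1)
  g <- membership_grade(mf, 1.3 + us)
  expect_equal(g, membership_grade(mf, 1.3 - us))
  expect_true(all(g > 0 & g <= 1))
  expect_true(all(diff(g[us >= 0]) < 0))
  expect_error(membership_function(0, 0), "positive")
})

test_that("fuzzification is the product of per-coefficient grades", {
  fit <- rp16_fit()
  model <- fit$model
  u <- fit$feats[5, ]
  f <- fuzzify(model, u)
  # loop-free oracle: direct product of membership_grade calls
  z <- ecgtriage:::nfc_scale(model, u)[1, ]
  for (cl in c("N", "V", "L")) {
    expected <- prod(vapply(seq_len(model$k), function(kk) {
      membership_grade(membership_function(model$centers[kk, cl],
                                           model$sigmas[kk, cl]), z[kk])
    }, numeric(1)))
    expect_equal(unname(f[cl]), expected)
  }
  # all grades equal 1 at the class's own centers, so f_N = 1 there
  expect_equal(unname(fuzzify(model, model$centers[, "N"],
                              normalized = TRUE)["N"]), 1)
  # two coefficients with grades 0.5 multiply to 0.25
  m2 <- init_model(rbind(matrix(rnorm(20), 10, 2), matrix(rnorm(20, 4), 10, 2),
                         matrix(rnorm(20, -4), 10, 2)),
                   rep(c("N", "V", "L"), each = 10))
  m2$centers[] <- 0
  m2$sigmas[] <- 1
  u_half <- rep(sqrt(2 * log(2)), 2)           # grade exp(-u^2/2) = 0.5
  expect_equal(unname(fuzzify(m2, u_half, normalized = TRUE)["N"]), 0.25)
  expect_error(fuzzify(model, rnorm(3)), "length")
})

test_that("the defuzzification rule assigns argmax or unknown", {
  r <- defuzzify(c(1, 0, 0), 0.5)
  expect_identical(r$label, "N")
  expect_false(r$is_pathological)
  expect_equal(c(r$m1, r$m2, r$s), c(1, 0, 1))

  r2 <- defuzzify(c(0.6, 0.5, 0.4), 0.1)     # 0.1 < 0.1 * 1.5
  expect_identical(r2$label, "U")
  expect_true(r2$is_pathological)

  # alpha = 0 degenerates to argmax whenever m1 > m2
  expect_identical(defuzzify(c(0.2, 0.5, 0.1), 0)$label, "V")
  # ties and all-zero vectors are conservative
  expect_identical(defuzzify(c(0.5, 0.5, 0.1), 0)$label, "U")
  expect_identical(defuzzify(c(0, 0, 0), 0)$label, "U")
  expect_error(defuzzify(c(1, -0.1, 0), 0.2), "nonnegative")
  expect_error(defuzzify(c(1, 0, 0), 1.5), "alpha")
})

test_that("initialization recovers per-class means and floors sigma", {
  # tight clouds (sd 0.05, n = 400): sample means land within 0.01 of truth
  gf <- gaussian_features(n_per_class = 400L, k = 3L, seed = 8, sd = 0.05)
  m <- init_model(gf$X, gf$labels)
  for (cl in c("N", "V", "L")) {
    raw_centers <- m$centers[, cl] * m$scaling$sd + m$scaling$mu
    expect_true(all(abs(raw_centers - gf$centers[[cl]]) < 0.01))
  }
  # permutation invariance
  set.seed(3)
  perm <- sample(nrow(gf$X))
  expect_equal(init_model(gf$X[perm, ], gf$labels[perm]), m)

  # a constant class floors sigma
  Xc <- rbind(matrix(5, 4, 2), matrix(rnorm(8), 4, 2), matrix(rnorm(8, 3), 4, 2))
  labs <- rep(c("N", "V", "L"), each = 4)
  mc <- init_model(Xc, labs)
  expect_true(all(mc$sigmas[, "N"] == 1e-3))
  expect_error(init_model(Xc[1:8, ], labs[1:8]), "absent")
})

test_that("gradient descent matches finite differences and reduces loss", {
  set.seed(9)
  Z <- matrix(rnorm(30 * 2), 30, 2)
  Y <- outer(sample(c("N", "V", "L"), 30, replace = TRUE), c("N", "V", "L"), "==") * 1
  centers <- matrix(rnorm(6), 2, 3)
  sigmas <- matrix(runif(6, 0.5, 1.5), 2, 3)
  lg <- ecgtriage:::nfc_loss_grad(centers, sigmas, Z, Y)
  h <- 1e-5
  for (idx in seq_len(6)) {
    cp <- centers; cm <- centers
    cp[idx] <- cp[idx] + h; cm[idx] <- cm[idx] - h
    fd <- (ecgtriage:::nfc_loss_grad(cp, sigmas, Z, Y)$loss -
             ecgtriage:::nfc_loss_grad(cm, sigmas, Z, Y)$loss) / (2 * h)
    expect_lt(abs(fd - lg$grad_centers[idx]), 1e-6)
    sp <- sigmas; sm <- sigmas
    sp[idx] <- sp[idx] + h; sm[idx] <- sm[idx] - h
    fd_s <- (ecgtriage:::nfc_loss_grad(centers, sp, Z, Y)$loss -
               ecgtriage:::nfc_loss_grad(centers, sm, Z, Y)$loss) / (2 * h)
    expect_lt(abs(fd_s - lg$grad_sigmas[idx]), 1e-6)
  }

  # zero epochs: model unchanged
  gf <- gaussian_features(n_per_class = 60L, k = 2L, seed = 12)
  m0 <- init_model(gf$X, gf$labels)
  expect_equal(train_model(m0, gf$X, gf$labels, epochs = 0L)$centers, m0$centers)

  # separable clusters: near-perfect accuracy at alpha = 0, monotone loss
  mt <- train_model(m0, gf$X, gf$labels, epochs = 100L, learning_rate = 0.01)
  expect_true(all(diff(mt$loss_history) <= 1e-10))
  expect_true(all(mt$sigmas >= 1e-3))
  pred <- ecgtriage:::nfc_predict(mt, gf$X, 0)
  expect_gte(mean(pred == gf$labels), 0.99)

  # conjugate-gradient option optimizes the same objective
  mcg <- train_model(m0, gf$X, gf$labels, epochs = 50L, method = "cg")
  expect_gte(mean(ecgtriage:::nfc_predict(mcg, gf$X, 0) == gf$labels), 0.99)
})

test_that("alpha tuning returns the smallest grid point meeting the bound", {
  fit <- rp16_fit()
  tr <- fit$train
  a <- tune_alpha(fit$model, fit$feats[tr, ], fit$ds$labels[tr], arr_min = 0.95)
  expect_false(attr(a, "warning_flag"))
  expect_gte(attr(a, "arr"), 0.95)
  # the classifier separates the synthetic classes already at alpha = 0
  expect_equal(as.numeric(a), 0)

  # unreachable bound: an abnormal beat so deep inside class N territory
  # that the runner-up fuzzy values underflow to exactly zero, so it wins N
  # by full margin even at alpha = 1
  gf <- gaussian_features(n_per_class = 50L, k = 2L, seed = 3, spread = 60,
                          sd = 0.05)
  m <- train_model(init_model(gf$X, gf$labels), gf$X, gf$labels, epochs = 0L)
  X2 <- rbind(gf$X, gf$centers$N)
  y2 <- c(gf$labels, "V")                      # a V beat at the N center
  expect_warning(a2 <- tune_alpha(m, X2, y2, arr_min = 1.0), "unreachable")
  expect_equal(as.numeric(a2), 1)
  expect_true(attr(a2, "warning_flag"))
  expect_error(tune_alpha(m, gf$X[gf$labels == "N", ],
                          gf$labels[gf$labels == "N"]), "abnormal")
})

test_that("ARR rises and NDR falls monotonically in alpha", {
  fit <- rp16_fit()
  te <- !fit$train
  st <- pareto_sweep(fit$model, fit$feats[te, ], fit$ds$labels[te],
                     alpha_grid = seq(0, 1, 0.05))
  expect_true(all(diff(st$arr) >= 0))
  expect_true(all(diff(st$ndr) <= 0))
})

test_that("classification composes fuzzify and defuzzify", {
  fit <- rp16_fit()
  model <- fit$model
  # a point at the class-N membership centers wins N at alpha = 0
  uN <- model$centers[, "N"] * model$scaling$sd + model$scaling$mu
  expect_identical(classify(model, uN, alpha_test = 0)$label, "N")
  # at alpha = 1 the same point is unknown unless the runner-up fuzzy value
  # vanishes; either way classify() agrees with the bare rule on its values
  r1 <- classify(model, uN, alpha_test = 1)
  expect_identical(r1$label, defuzzify(r1$fuzzy_values, 1)$label)
  expect_true(r1$label %in% c("N", "U"))
  # composition equality against the explicit pipeline
  u <- fit$feats[17, ]
  direct <- classify(model, u, alpha_test = 0.2)
  z <- ecgtriage:::nfc_scale(model, u)[1, ]
  manual <- defuzzify(fuzzify(model, z, normalized = TRUE), 0.2)
  expect_identical(direct$label, manual$label)
})

test_that("trained models recover known membership centers within 2%", {
  gf <- gaussian_features(n_per_class = 1000L, k = 4L, seed = 15)
  m <- train_model(init_model(gf$X, gf$labels), gf$X, gf$labels)
  for (cl in c("N", "V", "L")) {
    raw <- m$centers[, cl] * m$scaling$sd + m$scaling$mu
    truth <- gf$centers[[cl]]
    nz <- truth != 0
    expect_true(all(abs(raw[nz] - truth[nz]) / abs(truth[nz]) < 0.02))
    expect_true(all(abs(raw[!nz]) < 0.02 * max(abs(unlist(gf$centers)))))
  }
})

test_that("model JSON serialization round-trips classification", {
  fit <- rp16_fit()
  path <- tempfile(fileext = ".json")
  write_nfc_model(fit$model, path)
  m2 <- read_nfc_model(path)
  expect_equal(m2$centers, fit$model$centers)
  expect_equal(m2$alpha, fit$model$alpha)
  u <- fit$feats[3, ]
  expect_identical(classify(m2, u, 0.1)$label, classify(fit$model, u, 0.1)$label)
  unlink(path)
})
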