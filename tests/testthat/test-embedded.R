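# quantizer over a 2-coefficient model for direct linearized-MF tests
toy_quantizer <- function() {
  list(lo = c(-4.7, -4.7), hi = c(4.7, 4.7),
       step = c(9.4, 9.4) / 65535, span = 4.7)
}

test_that("linearized membership functions hit the anchor values", {
  qz <- toy_quantizer()
  lmf <- linearize_mf(membership_function(0, 0.5), qz, coef = 1)
  c0 <- lmf$center_int
  s <- lmf$s_int
  gs <- round(65535 * exp(-2.35^2 / 2))
  expect_equal(eval_linearized(lmf, c0), 65535)           # peak
  expect_lte(abs(eval_linearized(lmf, c0 + s) - gs), 1)   # G_S at the break
  expect_equal(eval_linearized(lmf, c0 + 3 * s), 1)       # plateau [2S, 4S)
  expect_equal(eval_linearized(lmf, c0 + 2 * s), 1)
  expect_equal(eval_linearized(lmf, c0 + 4 * s), 0)       # zero beyond 4S
  expect_equal(eval_linearized(lmf, c0 - 4 * s - 10), 0)
  # symmetry
  for (delta in c(1, 5, s %/% 2, s, 2 * s - 1, 3 * s)) {
    expect_equal(eval_linearized(lmf, c0 + delta), eval_linearized(lmf, c0 - delta))
  }
})

test_that("linearized grades are monotone over the exhaustive 16-bit axis", {
  qz <- toy_quantizer()
  for (sigma in c(0.15, 0.6, 1.2)) {
    lmf <- linearize_mf(membership_function(0.4, sigma), qz, coef = 1)
    x <- 0:65535
    v <- eval_linearized(lmf, x)
    expect_true(all(v >= 0 & v <= 65535))
    dlt <- abs(lmf$center_int - x)
    ord <- order(dlt)
    expect_true(all(diff(v[ord]) <= 0 | diff(dlt[ord]) == 0))
  }
})

test_that("the chord approximation stays within its measured error bound", {
  # worst case of the two-chord construction is ~0.0866 * 65535 = 5674 near
  # |c - x| = 0.73 S; assert the exhaustive sweep never exceeds 5700
  qz <- toy_quantizer()
  for (sigma in c(0.3, 0.8)) {
    lmf <- linearize_mf(membership_function(-0.5, sigma), qz, coef = 1)
    x <- 0:65535
    v <- eval_linearized(lmf, x)
    sig_units <- lmf$s_int / 2.35
    truth <- round(65535 * exp(-((lmf$center_int - x) / sig_units)^2 / 2))
    expect_lte(max(abs(v - truth)), 5700)
  }
})

test_that("model quantization maps alpha to Q0.16 and requires training", {
  fit <- rp16_fit()
  expect_error(quantize_model(init_model(fit$feats, fit$ds$labels)), "trained")
  qm0 <- quantize_model(fit$model, alpha = 0)
  expect_equal(qm0$alpha_q16, 0)
  expect_equal(quantize_model(fit$model, alpha = 0.5)$alpha_q16, 32768)
  for (a in c(0.1, 0.25, 0.999, 1)) {
    q <- quantize_model(fit$model, alpha = a)$alpha_q16
    expect_lt(abs(a - q / 65536), 2^-16 + 1e-12)
  }
  expect_equal(length(qm0$lmfs), fit$model$k)
  expect_true(all(vapply(qm0$lmfs, length, 0L) == 3L))
})

test_that("shift-truncate fuzzification preserves fuzzy-value ratios", {
  fit <- rp16_fit()
  qm <- quantize_model(fit$model, alpha = 0)

  # hand-traced worked case, k = 2: per-class grade pairs (65535, 65535),
  # (32768, 32768), (1, 1) -- trace the shift-truncate arithmetic by hand
  acc0 <- c(65535, 32768, 1)
  acc <- acc0 * c(65535, 32768, 1)             # second coefficient, per class
  mx <- max(acc)
  s <- 32 - ecgtriage:::bit_length(mx)
  out <- floor(acc * 2^s / 65536)
  # ratio preservation of the truncation step against float ratios
  float_ratio <- (65535 / 65536)^2 / (32768 / 65536)^2
  expect_lt(abs(out[1] / out[2] - float_ratio) / float_ratio, 2^-14)
  expect_equal(out[3], 0)                      # tiny accumulators truncate to 0

  # random-triple property: common shift + 16-bit truncation changes pairwise
  # ratios by < 2^-14 when shifted values stay within a factor 2 of the max
  set.seed(41)
  for (rep in 1:200) {
    w <- runif(3, 2^31, 2^32 - 1)
    w <- floor(w)
    t <- floor(w / 65536)
    for (i in 1:2) for (j in (i + 1):3) {
      expect_lt(abs((t[i] / t[j]) / (w[i] / w[j]) - 1), 2^-14)
    }
  }

  # end-to-end integer fuzzification: zero grades propagate as zeros
  u_far <- rep(0L, qm$k)                       # far from every center
  stf <- int_fuzzify(qm, u_far)
  expect_length(stf$accumulators, 3L)
  expect_true(all(stf$accumulators >= 0 & stf$accumulators < 2^32))
  expect_error(int_fuzzify(qm, rep(0L, 3)), "length")
})

test_that("integer defuzzification mirrors the float rule without division", {
  expect_identical(int_defuzzify(c(100, 0, 0), 32768)$label, "N")
  expect_identical(int_defuzzify(c(60, 50, 40), 6554)$label, "U")
  expect_identical(int_defuzzify(c(0, 0, 0), 0)$label, "U")
  expect_identical(int_defuzzify(c(7, 7, 1), 0)$label, "U")    # tie rule

  # oracle equivalence over randomized 32-bit triples and alphas: the widened
  # comparison (M1-M2)*2^16 >= a*S must match the float rule at alpha=a/2^16
  # (both sides exact in doubles below 2^53)
  set.seed(19)
  for (rep in 1:500) {
    acc <- floor(runif(3, 0, 2^32))
    a16 <- floor(runif(1, 0, 65536))
    got <- int_defuzzify(acc, min(a16, 65535))$label
    want <- defuzzify(acc / 2^32, min(a16, 65535) / 65536)$label
    expect_identical(got, want)
  }
})

test_that("float and integer pipelines agree on synthetic beats", {
  fit <- rp16_fit()
  model <- fit$model
  qm <- quantize_model(model)
  pa <- parity_audit(model, qm, fit$feats, fit$ds$labels)
  expect_equal(pa$n_agree + sum(pa$float_labels != pa$int_labels), pa$n)
  expect_equal(pa$n, nrow(fit$feats))
  expect_gte(pa$agreement, 0.99)
  expect_lt(abs(pa$ndr_delta), 0.02)
  expect_lt(abs(pa$arr_delta), 0.02)
  # a model audited against itself in float agrees perfectly
  self <- parity_audit(model, qm, fit$feats)
  expect_identical(mean(self$float_labels ==
                          ecgtriage:::nfc_predict(model, fit$feats, model$alpha)), 1)
})
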