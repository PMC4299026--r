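test_that("NDR and ARR count triage decisions correctly", {
  truths <- c("N", "N", "V", "L")
  r <- compute_ndr_arr(truths, truths)
  expect_equal(c(r$ndr, r$arr), c(1, 1))

  # U is a pathological call: discards nothing, recognizes everything
  rU <- compute_ndr_arr(rep("U", 4), truths)
  expect_equal(c(rU$ndr, rU$arr), c(0, 1))

  # hand-counted mixed case, including a V predicted L (still recognized)
  rm <- compute_ndr_arr(c("N", "U", "L", "L"), truths)
  expect_equal(c(rm$ndr, rm$arr), c(0.5, 1))
  expect_equal(sum(rm$confusion), 4)
  expect_equal(sum(rm$triage), 4)

  expect_error(compute_ndr_arr(c("N", "V"), c("N", "N")), "abnormal")
  expect_error(compute_ndr_arr(c("N", "X"), c("N", "V")), "invalid")
  expect_error(compute_ndr_arr("N", c("N", "V")), "equal-length")
})

test_that("pareto sweeps trace the NDR/ARR trade-off monotonically", {
  fit <- rp16_fit()
  te <- !fit$train
  one <- pareto_sweep(fit$model, fit$feats[te, ], fit$ds$labels[te],
                      alpha_grid = 0)
  expect_equal(nrow(one), 1L)
  curve <- pareto_sweep(fit$model, fit$feats[te, ], fit$ds$labels[te])
  expect_true(all(diff(curve$arr) >= 0))
  expect_true(all(diff(curve$ndr) <= 0))
  # at alpha = 1 a beat is kept out of U only if its runner-up fuzzy value
  # is exactly zero
  st <- ecgtriage:::nfc_margins(fit$model, fit$feats[te, ])
  expect_equal(curve$ndr[nrow(curve)],
               mean(st$margin[fit$ds$labels[te] == "N"] >= 1 &
                      st$argmax[fit$ds$labels[te] == "N"] == "N"))
  expect_error(pareto_sweep(fit$model, fit$feats[te, ], fit$ds$labels[te],
                            alpha_grid = numeric(0)), "non-empty")
})

test_that("cross-validation covers the dataset with disjoint test folds", {
  ds <- fixture("cv_ds", function() generate_dataset(record_spec(n_beats = 480, seed = 71)))
  cv <- cross_validate(ds, reducer = "pca", k = 8L, train1_per_class = 10L,
                       epochs = 60L, seed = 2L)
  expect_length(cv$fold_reports, 4L)
  ns <- vapply(cv$fold_reports, `[[`, 0, "n")
  expect_equal(sum(ns), 480L)
  expect_equal(as.integer(ns), as.integer(table(ds$fold)))
  expect_true(all(vapply(cv$fold_reports, `[[`, 0, "arr") >= 0))
  # determinism
  cv2 <- cross_validate(ds, reducer = "pca", k = 8L, train1_per_class = 10L,
                        epochs = 60L, seed = 2L)
  expect_equal(cv$mean_ndr, cv2$mean_ndr)
  expect_equal(cv$alphas, cv2$alphas)
  # the balanced train_set_1 contract: 150 per class needs 600 per class
  expect_error(cross_validate(ds, reducer = "pca", k = 8L,
                              train1_per_class = 10000L), "training beats")
})

test_that("baseline classifiers are compared on identical folds", {
  ds <- fixture("cv_ds", function() generate_dataset(record_spec(n_beats = 480, seed = 71)))
  P <- sample_achlioptas(8L, ds$d, seed = 13)
  feats <- cbind(ecgtriage:::project_rp_batch(P, ds$windows),
                 ecgtriage:::delineate_fpd_batch(ds))
  tab <- baseline_compare(feats, ds$labels, ds$fold, epochs = 60L, seed = 4L)
  expect_setequal(tab$classifier, c("LDA", "SVM-linear", "SVM-gaussian", "NFC"))
  expect_true(all(tab$ndr >= 0 & tab$ndr <= 1))
  expect_true(all(tab$arr >= 0 & tab$arr <= 1))
  # the NFC line reports one gaussian per class-feature pair: 3 x 16 = 48
  expect_equal(tab$parameter_count[tab$classifier == "NFC"], 48L)
  expect_match(tab$operations[tab$classifier == "NFC"], "48 in total")
  # linear models decide with a 16-element combination
  expect_match(tab$operations[tab$classifier == "LDA"], "16 elements")
  expect_match(tab$operations[tab$classifier == "SVM-linear"], "16 elements")
  # on linearly separable features the linear baselines meet the ARR bound
  gf <- gaussian_features(n_per_class = 80L, k = 4L, seed = 9)
  set.seed(10)
  gfold <- stratify_folds(gf$labels, 4L)
  tab2 <- baseline_compare(gf$X, gf$labels, gfold, epochs = 40L, seed = 4L)
  expect_gte(tab2$arr[tab2$classifier == "LDA"], 0.95)
  expect_gte(tab2$arr[tab2$classifier == "SVM-linear"], 0.95)
})

test_that("transmission savings follow the byte-cost model", {
  # all beats flagged abnormal: nothing saved
  expect_equal(transmission_savings(rep("V", 10)), 0)
  # all normal at a 1:9 byte ratio: 8/9 saved
  expect_equal(transmission_savings(rep("N", 10), bytes_normal = 2,
                                    bytes_abnormal = 18), 8 / 9)
  # mixed hand-computed case: 900 normal, 100 abnormal at (2, 18) bytes
  labels <- c(rep("N", 900), rep("V", 100))
  expect_equal(transmission_savings(labels, 2, 18), 0.8)
  # an eval_report carries the same counts
  r <- compute_ndr_arr(labels, c(rep("N", 900), rep("V", 100)))
  expect_equal(transmission_savings(r, 2, 18), 0.8)
  expect_error(transmission_savings(rep("N", 3), 20, 18), "bytes_normal")
  expect_error(transmission_savings(character(0)), "no beats")
})
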