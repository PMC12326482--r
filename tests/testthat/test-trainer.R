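small_pair <- function(seed = 3, ...) {
  synth_domain_pair(synth_recipe(n_per_class = 40, d = 10, separation = 6,
                                 baseline = 4, outlier_fraction = 0,
                                 seed = seed, ...))
}

test_that("convergence test handles constant, geometric and oscillating traces", {
  cv <- converged(rep(5, 10), tol = 1e-6)
  expect_true(cv$converged)
  expect_equal(cv$epoch, 2L)
  # J_t = 1 + 0.5^t: first t with all of the trailing-5 relative changes
  # below tol; change_t = 0.5^(t-1) * 0.5 / (1 + 0.5^(t-1))
  tol <- 1e-6
  tr <- 1 + 0.5^(0:60)
  rel <- abs(diff(tr)) / tr[-length(tr)]
  # the decision needs the whole trailing 5-change window below tol
  expected <- min(which(rel < tol)) + 5
  cv2 <- converged(tr, tol)
  expect_true(cv2$converged)
  expect_equal(cv2$epoch, expected)
  osc <- 5 + 0.1 * (-1)^(1:40)
  expect_false(converged(osc, 1e-6)$converged)
})

test_that("training is bit-reproducible under a fixed seed", {
  pair <- small_pair()
  cfg <- tiny_config(seed = 2, batch_size = 32, max_epochs = 12)
  f1 <- dadpc_fit(pair$source, pair$target, cfg)
  f2 <- dadpc_fit(pair$source, pair$target, cfg)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$params, f2$params)
  expect_identical(f1$pseudo_labels, f2$pseudo_labels)
})

test_that("a copied source as target is labeled perfectly", {
  r <- synth_recipe(n_subjects = 1, n_per_class = 60, d = 10, separation = 8,
                    baseline = 0, outlier_fraction = 0, seed = 3)
  dat <- synth_generate(r)
  feats <- grep("^x", names(dat), value = TRUE)
  src <- dat[, c("class", feats)]
  fit <- dadpc_fit(src, src[, feats], tiny_config())
  expect_equal(mean(fit$levels[fit$pseudo_labels] == src$class), 1.0)
})

test_that("predict agrees with bank pseudo-labels and ignores sample order", {
  pair <- small_pair()
  fit <- dadpc_fit(pair$source, pair$target, tiny_config())
  pred <- predict(fit, pair$target)
  expect_identical(pred$.pred_class, fit$levels[fit$pseudo_labels])
  perm <- sample(nrow(pair$target))
  pred2 <- predict(fit, pair$target[perm, ])
  expect_identical(pred2$.pred_class, pred$.pred_class[perm])
  expect_equal(rowSums(as.matrix(pred[, -1])), rep(1, nrow(pred)))
})

test_that("objective history is finite and the surrogate trace settles", {
  pair <- small_pair()
  fit <- dadpc_fit(pair$source, pair$target, tiny_config(max_epochs = 30),
                   target_truth = pair$target_truth)
  h <- fit$history
  expect_true(all(is.finite(h$surrogate)))
  expect_true(all(is.finite(h$objective)))
  expect_lte(nrow(h), 30)
  expect_true(all(h$target_accuracy >= 0 & h$target_accuracy <= 1))
  # late-phase surrogate is not blowing up
  expect_lt(utils::tail(h$surrogate, 1), h$surrogate[1] * 10)
})

test_that("tidy, glance and autoplot expose the fit", {
  pair <- small_pair()
  fit <- dadpc_fit(pair$source, pair$target, tiny_config(max_epochs = 8))
  td <- generics::tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_true(all(c("epoch", "surrogate", "objective") %in% names(td)))
  gl <- generics::glance(fit)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$n_source, nrow(pair$source))
  expect_s3_class(ggplot2::autoplot(fit), "ggplot")
})

test_that("invalid configurations are rejected", {
  expect_error(dadpc_config(lambda3 = 1e-6), "1e-4")
  expect_error(dadpc_config(lambda1 = -1), "1e-4")
  expect_error(dadpc_config(tau = 0), "tau")
  expect_error(dadpc_config(hidden_dims = c(8, 8)), "odd")
  pair <- small_pair()
  expect_error(dadpc_fit(pair$source, pair$target, tiny_config(),
                         label_col = "missing"), "label column")
})
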