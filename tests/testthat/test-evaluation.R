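manifest_data <- function(n_subjects = 4, n_sessions = 3, npc = 10, d = 6,
                          seed = 11) {
  synth_generate(synth_recipe(n_subjects = n_subjects,
                              n_sessions = n_sessions, n_per_class = npc,
                              d = d, separation = 7, baseline = 3,
                              outlier_fraction = 0, seed = seed))
}

majority_fit <- function(source, target, config, label_col) {
  lv <- sort(unique(source[[label_col]]))
  tab <- table(source[[label_col]])
  rep(lv[which.max(tab)], nrow(target))
}

test_that("protocol folds partition the manifest as defined", {
  dat <- manifest_data()
  cuce <- protocol_folds(dat, "CUCE")
  expect_length(cuce, 4)
  for (f in cuce) {
    expect_length(intersect(f$source, f$target), 0)
    expect_equal(length(unique(dat$subject[f$target])), 1)
    expect_setequal(unique(dat$session[f$target]), 1:3)
  }
  expect_length(protocol_folds(dat, "CUCE", per_session_folds = TRUE), 12)
  cuse <- protocol_folds(dat, "CUSE")
  expect_length(cuse, 4)
  for (f in cuse)
    expect_true(all(dat$session[c(f$source, f$target)] == 1))
  wuce <- protocol_folds(dat, "WUCE")
  expect_length(wuce, 4)
  for (f in wuce) {
    expect_setequal(unique(dat$session[f$source]), 1:2)
    expect_equal(unique(dat$session[f$target]), 3)
    expect_equal(unique(dat$subject[f$source]),
                 unique(dat$subject[f$target]))
  }
  # targets cover the manifest exactly once for CUCE
  expect_setequal(unlist(lapply(cuce, `[[`, "target")), seq_len(nrow(dat)))
})

test_that("cross-database folds use one dataset per side", {
  a <- manifest_data(n_subjects = 1, n_sessions = 1, seed = 1)
  b0 <- manifest_data(n_subjects = 1, n_sessions = 1, seed = 2)
  b0$dataset <- "B"
  dat <- rbind(a, b0)
  folds <- protocol_folds(dat, "CDCV")
  expect_length(folds, 2)
  expect_setequal(vapply(folds, `[[`, character(1), "name"),
                  c("A_to_B", "B_to_A"))
  expect_error(protocol_folds(a, "CDCV"), "two datasets")
})

test_that("a 15-subject single-session manifest gives 15 CUSE folds", {
  dat <- manifest_data(n_subjects = 15, n_sessions = 1, npc = 4)
  res <- run_protocol(dat, "CUSE", fit_fn = majority_fit)
  expect_equal(nrow(res$folds), 15)
})

test_that("a constant majority model reproduces chance accuracy", {
  dat <- manifest_data()
  res <- run_protocol(dat, "CUCE", fit_fn = majority_fit)
  expect_equal(res$mean_acc, 100 / 3, tolerance = 1e-12)
  expect_equal(res$mean_acc, mean(res$folds$accuracy), tolerance = 1e-12)
  # confusion rows conserve per-class target counts
  expect_equal(as.vector(rowSums(res$confusion)),
               as.vector(table(dat$class)))
})

test_that("the full model aces an easy separable manifest", {
  dat <- manifest_data(n_subjects = 3, n_sessions = 1, npc = 15, seed = 21)
  res <- run_protocol(dat, "CUSE", config = tiny_config())
  expect_equal(nrow(res$folds), 3)
  expect_gte(res$mean_acc, 99)
  expect_equal(res$mean_acc, mean(res$folds$accuracy), tolerance = 1e-12)
  gl <- generics::glance(res)
  expect_equal(gl$n_folds, 3)
  expect_s3_class(ggplot2::autoplot(res), "ggplot")
})

test_that("noise sweep reports every level and matches the clean run at 0", {
  pair <- synth_domain_pair(synth_recipe(n_per_class = 30, d = 8,
                                         separation = 6, baseline = 3,
                                         outlier_fraction = 0, seed = 4))
  cfg <- tiny_config(max_epochs = 10)
  sw <- noise_sweep(pair$source, pair$target, pair$target_truth,
                    etas = c(0, 10), config = cfg)
  expect_equal(sw$eta, c(0, 10))
  fit <- dadpc_fit(pair$source, pair$target, cfg)
  acc0 <- 100 * mean(predict(fit, pair$target)$.pred_class ==
                       pair$target_truth)
  expect_equal(sw$accuracy[1], acc0)
})

test_that("confusion counts by true and predicted class", {
  expect_equal(confusion(c(1, 1, 2), c(1, 2, 2), 2),
               matrix(c(1L, 0L, 1L, 1L), 2))
  expect_equal(confusion(1:3, rep(2, 3), 3)[, 2], rep(1L, 3))
  d <- confusion(rep(1:2, 5), rep(1:2, 5), 2)
  expect_equal(d, diag(c(5L, 5L)))
  expect_error(confusion(c(0, 1), c(1, 1), 2), "1..K")
})

test_that("mutual information map recovers a discrete identity and its bounds", {
  set.seed(51)
  n <- 300
  lab <- rep(1:2, each = n / 2)
  x_info <- lab + rnorm(n, sd = 1e-3)
  x_noise <- rnorm(n)
  X <- cbind(x_info, x_noise, rep(1, n))
  mi <- mutual_info_map(X, lab)
  expect_equal(dim(mi$I), c(2, 3))
  expect_true(all(mi$I >= 0 & mi$I <= 1))
  expect_equal(mi$I_raw[1, 1], log(2), tolerance = 0.05)
  expect_equal(mi$I_raw[1, 3], 0)           # constant feature
  # independent feature is indistinguishable from its permuted null
  null_vals <- replicate(30, dadpc:::mi_knn_discrete(x_noise, sample(lab), 3))
  expect_lte(mi$I_raw[1, 2], stats::quantile(null_vals, 1) + 0.02)
  # histogram fallback agrees on the strong signal
  mih <- mutual_info_map(X, lab, method = "histogram")
  expect_equal(mih$I_raw[1, 1], log(2), tolerance = 0.1)
})
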