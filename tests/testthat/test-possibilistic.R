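test_that("membership closed form matches hand values and the 1-D oracle", {
  expect_equal(membership_update(0), 1)
  expect_equal(membership_update(2 * log(2)), 0.5)
  expect_equal(membership_update(1), exp(-0.5))
  expect_error(membership_update(-0.1), "non-negative")
  set.seed(21)
  D <- runif(200, 0, 8)
  oracle <- vapply(D, function(dd)
    stats::optimize(function(v) v^2 * dd + v^2 * log(v^2) - v^2,
                    c(1e-9, 1), tol = 1e-10)$minimum, numeric(1))
  expect_equal(membership_update(D), oracle, tolerance = 1e-6)
})

test_that("memberships live in (0,1] and decrease with distance", {
  set.seed(22)
  D <- matrix(runif(60, 0, 20), 10)
  V <- membership_update(D)
  expect_true(all(V > 0 & V <= 1))
  d <- seq(0, 30, length.out = 100)
  expect_true(all(diff(membership_update(d)) <= 0))
})

test_that("fuzzy entropy penalty matches its closed-form boundary values", {
  expect_equal(fuzzy_entropy_penalty(1), -1)
  expect_lt(abs(fuzzy_entropy_penalty(1e-8)), 1e-12)
  expect_equal(fuzzy_entropy_penalty(exp(-0.5)), -2 / exp(1))
  expect_error(fuzzy_entropy_penalty(1.5), "0, 1")
  expect_error(fuzzy_entropy_penalty(0), "0, 1")
})

test_that("dpc_objective evaluates known cases and is minimized by the update", {
  sp <- sigma_spec(0.001)
  # coincident points: all distances 0, V all ones, each entry contributes -1
  H <- matrix(1, 4, 3)
  C <- matrix(1, 2, 3)
  V <- matrix(1, 4, 2)
  expect_equal(dpc_objective(H, C, V, sp, lambda3 = 2), 2 * 4 * 2 * (-1))
  # single point at sigma-norm distance giving D = 1
  h <- matrix(c(0, 0), 1); cc <- matrix(c(1, 0), 1)
  D <- sigma_norm(h - cc, sp)
  v <- matrix(membership_update(D), 1, 1)
  expect_equal(dpc_objective(h, cc, v, sp, 1), -exp(-D), tolerance = 1e-12)
  # block optimality against perturbed memberships
  set.seed(23)
  H <- matrix(rnorm(30), 10); C <- matrix(rnorm(9), 3)
  D <- dadpc:::latent_distances(H, C, sp)
  Vstar <- membership_update(D)
  base <- dpc_objective(H, C, Vstar, sp, 1)
  for (i in 1:100) {
    Vp <- Vstar * runif(length(Vstar), 0.5, 1)
    Vp <- pmin(pmax(Vp + rnorm(length(Vp), 0, 0.05), 1e-6), 1)
    expect_gte(dpc_objective(H, C, Vp, sp, 1), base - 1e-10)
  }
})

test_that("init_centroids averages classes and rejects empty classes", {
  H <- matrix(c(0, 0, 2, 2, 5, 5), ncol = 2, byrow = TRUE)
  cs <- init_centroids(H, c(1, 1, 2))
  expect_equal(cs$C, matrix(c(1, 5, 1, 5), 2))
  expect_equal(cs$counts, c(2, 1))
  expect_error(init_centroids(H, c(1, 1, 1), K = 2), "empty class")
  # permutation invariance and sampling-error bound
  set.seed(24)
  y <- rep(1:3, each = 50)
  mu <- matrix(c(0, 0, 4, 0, 0, 4), 3, byrow = TRUE)
  X <- mu[y, ] + matrix(rnorm(300), 150)
  p <- sample(150)
  expect_equal(init_centroids(X[p, ], y[p])$C, init_centroids(X, y)$C)
  expect_lt(max(abs(init_centroids(X, y)$C - mu)), 3 / sqrt(50))
})

test_that("mean-discrepancy bound report reproduces the 2-point counterexample", {
  r <- mmd_clustering_bound(matrix(0), matrix(2), delta = 0.5)
  expect_equal(r$mmd, 4)
  expect_equal(r$bound_printed, 2)
  expect_false(r$printed_holds)
  expect_equal(r$bound_corrected, 4)
  # identical sets
  set.seed(25)
  X <- matrix(rnorm(20), 5)
  r2 <- mmd_clustering_bound(X, X)
  expect_equal(r2$mmd, 0)
  expect_gte(r2$bound_corrected, 0)
  expect_error(mmd_clustering_bound(X[0, ], X), "non-empty")
})

test_that("corrected bound dominates the discrepancy on random domain pairs", {
  set.seed(26)
  for (i in 1:200) {
    d <- sample(1:5, 1)
    Xs <- matrix(rnorm(sample(2:20, 1) * d, mean = rnorm(1, 0, 2)), ncol = d)
    Xt <- matrix(rnorm(sample(2:20, 1) * d, mean = rnorm(1, 0, 2)), ncol = d)
    r <- mmd_clustering_bound(Xs, Xt, delta = runif(1))
    expect_lte(r$mmd, r$bound_corrected + 1e-9)
  }
})
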