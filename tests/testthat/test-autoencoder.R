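test_that("forward pass reproduces identity networks and hand values", {
  # linear identity network reconstructs exactly
  p <- ae_init(c(3, 3, 3), K = 2, activation = "linear", seed = 1)
  p$W <- list(diag(3), diag(3))
  p$b <- list(rep(0, 3), rep(0, 3))
  X <- matrix(rnorm(15), 5)
  st <- ae_forward(p, X)
  expect_equal(st$reconstruction, X)
  # 1-1-1 tanh network, hand value at x = 0
  p1 <- ae_init(c(1, 1, 1), K = 2, activation = "tanh", seed = 1)
  p1$W <- list(matrix(2), matrix(1)); p1$b <- list(1, 0)
  st1 <- ae_forward(p1, matrix(0))
  expect_equal(st1$H[[2]][1, 1], tanh(1))
  # bounded activations stay finite for random parameters
  p2 <- ae_init(c(4, 6, 2, 6, 4), K = 3, seed = 9)
  st2 <- ae_forward(p2, matrix(rnorm(40, sd = 5), 10))
  expect_true(all(vapply(st2$H, function(h) all(is.finite(h)), logical(1))))
  expect_error(ae_forward(p2, matrix(0, 2, 3)), "dimension")
})

test_that("reconstruction loss composes the sigma-norm with the printed square", {
  p <- ae_init(c(2, 2, 2), K = 2, activation = "linear", seed = 1)
  p$W <- list(diag(2), diag(2)); p$b <- list(c(0, 0), c(0, 0))
  X <- matrix(c(1, 2), 1)
  st <- ae_forward(p, X)
  expect_equal(reconstruction_loss(st, X, sigma_spec(1)), 0)
  # force residual (3,4): reconstruction = X + (3,4)
  p$b <- list(c(0, 0), c(3, 4))
  st <- ae_forward(p, X)
  expect_equal(reconstruction_loss(st, X, sigma_spec(1)), (25 / 3)^2)
  expect_equal(reconstruction_loss(st, X, sigma_spec(1), square = FALSE), 25 / 3)
})

test_that("sharpening keeps the simplex, lowers entropy, hits hand values", {
  expect_equal(sharpen(c(0.5, 0.5), 0.37), c(0.5, 0.5))
  expect_equal(sharpen(c(0.8, 0.2), 0.5), c(0.64, 0.04) / 0.68)
  expect_equal(sharpen(c(0.8, 0.2), 1), c(0.8, 0.2))
  expect_error(sharpen(c(0.8, 0.2), 0), "positive")
  set.seed(31)
  ent <- function(p) -sum(ifelse(p > 0, p * log(p), 0))
  for (i in 1:25) {
    p <- as.numeric(stats::rgamma(4, 1)); p <- p / sum(p)
    ps <- sharpen(p, runif(1, 0.05, 1))
    expect_equal(sum(ps), 1)
    expect_lte(ent(ps), ent(p) + 1e-12)
  }
  # tau -> 0 converges to a point mass at the argmax
  expect_equal(sharpen(c(0.7, 0.2, 0.1), 0.01)[1], 1, tolerance = 1e-8)
})

test_that("source loss is cross-entropy plus positive regularizers", {
  p <- ae_init(c(2, 2, 2), K = 2, seed = 2)
  st <- list(p_sharp = matrix(c(1, 0), 1))
  Q <- matrix(c(1, 0), 1)
  expect_equal(source_loss(st, Q, p, sigma_spec(1), 0, 0), 0)
  st2 <- list(p_sharp = matrix(c(0.5, 0.5), 1))
  expect_equal(source_loss(st2, Q, p, sigma_spec(1), 0, 0), log(2))
  expect_gt(source_loss(st2, Q, p, sigma_spec(1), lambda1 = 0.1, lambda2 = 0),
            source_loss(st2, Q, p, sigma_spec(1), 0, 0))
})

test_that("total objective is additive in its three terms", {
  toy <- make_toy_surrogate(seed = 5)
  sp <- sigma_spec(0.5)
  st <- ae_forward(toy$params, toy$X, tau = 0.5)
  V <- membership_update(dadpc:::latent_distances(st$bottleneck, toy$C, sp))
  j <- total_objective(toy$params, toy$X, toy$src, toy$Q, V, toy$C, sp,
                       lambda1 = 0.2, lambda2 = 0.1, lambda3 = 0.7)
  j1 <- reconstruction_loss(st, toy$X, sp)
  j2 <- source_loss(dadpc:::subset_states(st, toy$src), toy$Q, toy$params,
                    sp, 0.2, 0.1)
  j3 <- dpc_objective(st$bottleneck, toy$C, V, sp, 0.7)
  expect_equal(j, j1 + j2 + j3, tolerance = 1e-10)
})

test_that("backprop gradients of the surrogate match finite differences", {
  toy <- make_toy_surrogate(seed = 3)
  g <- ae_gradients(toy$params, toy$X, toy$src, toy$Q, toy$C, toy$w,
                    lambda1 = 0.3, lambda2 = 0.2, lambda3 = 0.7, tau = 0.5)
  v0 <- flatten_params(toy$params)
  ganal <- flatten_params(list(W = g$dW, b = g$db, U = g$dU, u0 = g$du0))
  fval <- function(v) ae_gradients(unflatten_params(toy$params, v), toy$X,
                                   toy$src, toy$Q, toy$C, toy$w,
                                   0.3, 0.2, 0.7, 0.5)$value
  h <- 1e-5
  set.seed(32)
  idx <- sample(length(v0), 60)
  for (j in idx) {
    vp <- v0; vm <- v0
    vp[j] <- vp[j] + h; vm[j] <- vm[j] - h
    fd <- (fval(vp) - fval(vm)) / (2 * h)
    expect_equal(ganal[j], fd, tolerance = 1e-4)
  }
})

test_that("full-batch descent with frozen reweighting is monotone", {
  toy <- make_toy_surrogate(seed = 7)
  p <- toy$params
  lr <- 1e-3
  vals <- numeric(60)
  for (it in seq_len(60)) {
    g <- ae_gradients(p, toy$X, toy$src, toy$Q, toy$C, toy$w,
                      lambda1 = 0.1, lambda2 = 0.1, lambda3 = 0.5, tau = 0.5)
    vals[it] <- g$value
    for (m in seq_along(p$W)) {
      p$W[[m]] <- p$W[[m]] - lr * g$dW[[m]]
      p$b[[m]] <- p$b[[m]] - lr * g$db[[m]]
    }
    p$U <- p$U - lr * g$dU
    p$u0 <- p$u0 - lr * g$du0
  }
  expect_true(all(diff(vals) <= 1e-10))
})
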