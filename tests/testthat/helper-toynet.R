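# flatten/unflatten all network parameters for finite-difference checks
flatten_params <- function(p) {
  c(unlist(p$W), unlist(p$b), as.numeric(p$U), p$u0)
}

unflatten_params <- function(p, v) {
  i <- 0
  for (m in seq_along(p$W)) {
    n <- length(p$W[[m]]); p$W[[m]][] <- v[i + seq_len(n)]; i <- i + n
  }
  for (m in seq_along(p$b)) {
    n <- length(p$b[[m]]); p$b[[m]][] <- v[i + seq_len(n)]; i <- i + n
  }
  n <- length(p$U); p$U[] <- v[i + seq_len(n)]; i <- i + n
  p$u0[] <- v[i + seq_len(length(p$u0))]
  p
}

# a small labeled toy problem plus frozen surrogate weights
make_toy_surrogate <- function(seed = 3, d = 6, K = 3, N = 12,
                               hidden = c(5, 4, 5), sigma = 0.5) {
  set.seed(seed)
  params <- ae_init(c(d, hidden, d), K, "tanh", seed = seed)
  X <- matrix(rnorm(N * d), N)
  src <- seq_len(ceiling(N / 2))
  Q <- diag(K)[sample(K, length(src), TRUE), , drop = FALSE]
  C <- matrix(rnorm(K * hidden[(length(hidden) + 1) / 2]), K)
  st <- ae_forward(params, X)
  w <- compute_reweights(params, st, X, C, sigma_spec(sigma))
  list(params = params, X = X, src = src, Q = Q, C = C, w = w)
}

# fast training configuration for protocol-level tests
tiny_config <- function(seed = 1, ...) {
  synth_study_config(seed = seed, hidden_dims = c(16, 8, 16),
                     max_epochs = 25, warmup_epochs = 5, batch_size = NULL,
                     ...)
}
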