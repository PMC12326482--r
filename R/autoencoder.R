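#' Initialize encoder-decoder parameters with a classifier head
#'
#' Builds an (M+1)-layer fully connected encoder-decoder. `layer_dims` is
#' `[d, d_1, ..., d_M]` with `d_M = d` and the bottleneck at index `M/2`; `M`
#' must be even. A dedicated K-logit affine head sits on the bottleneck (the
#' reconstruction layer has dimension `d`, so a K-way softmax cannot index it
#' directly; the head preserves the softmax form while keeping dimensions
#' consistent). Weights are drawn symmetric-uniform scaled by fan-in,
#' `U(-1/sqrt(fan_in), 1/sqrt(fan_in))`, from a caller-fixed seed.
#'
#' @param layer_dims Integer vector of layer widths, first and last equal.
#' @param K Number of classes for the classifier head.
#' @param activation `"tanh"` (default; smooth, bounded), `"relu"`, or
#'   `"linear"`.
#' @param seed Integer seed for the initialization draws.
#' @return Object of class `ae_params`.
#' @export
ae_init <- function(layer_dims, K, activation = c("tanh", "relu", "linear"),
                    seed = 1) {
  activation <- match.arg(activation)
  layer_dims <- as.integer(layer_dims)
  M <- length(layer_dims) - 1
  if (M < 2 || M %% 2 != 0)
    stop("need an even number of layers M >= 2.", call. = FALSE)
  if (layer_dims[1] != layer_dims[M + 1])
    stop("input and output dimensions must agree.", call. = FALSE)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  W <- vector("list", M); b <- vector("list", M)
  for (m in seq_len(M)) {
    fan_in <- layer_dims[m]
    r <- 1 / sqrt(fan_in)
    W[[m]] <- matrix(stats::runif(layer_dims[m + 1] * fan_in, -r, r),
                     nrow = layer_dims[m + 1])
    b[[m]] <- rep(0, layer_dims[m + 1])
  }
  dbt <- layer_dims[M / 2 + 1]
  U <- matrix(stats::runif(K * dbt, -1 / sqrt(dbt), 1 / sqrt(dbt)), nrow = K)
  structure(list(W = W, b = b, U = U, u0 = rep(0, K),
                 layer_dims = layer_dims, M = M, K = K,
                 activation = activation, seed = seed),
            class = "ae_params")
}

# save/restore the global RNG state so seeded helpers are side-effect free
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

act_fun <- function(name) {
  switch(name,
         tanh = list(f = tanh, fprime = function(a) 1 - tanh(a)^2),
         relu = list(f = function(a) pmax(a, 0),
                     fprime = function(a) (a > 0) * 1),
         linear = list(f = identity, fprime = function(a) a * 0 + 1))
}

#' Forward pass through the encoder-decoder
#'
#' Computes \eqn{H^{(m)} = f(W^{(m)} H^{(m-1)} + b^{(m)})} for all layers,
#' plus classifier logits and (sharpened) class probabilities from the
#' bottleneck head. Deterministic given parameters and input.
#'
#' @param params An [ae_init()] object.
#' @param X Numeric matrix, samples in rows, `ncol(X) == layer_dims[1]`.
#' @param tau Sharpening temperature in (0, 1]; `p_sharp` uses exponent
#'   `1/tau` (see [sharpen()]).
#' @return Object of class `hidden_states`: list with `H` (list of per-layer
#'   activations, samples in rows; `H[[1]]` is the input), `A` (pre-
#'   activations), `bottleneck`, `reconstruction`, `logits`, `p`, `p_sharp`.
#' @export
ae_forward <- function(params, X, tau = 0.5) {
  stopifnot(inherits(params, "ae_params"))
  if (is.vector(X)) X <- matrix(X, nrow = 1)
  if (ncol(X) != params$layer_dims[1])
    stop("input dimension ", ncol(X), " does not match layer_dims[1] = ",
         params$layer_dims[1], ".", call. = FALSE)
  act <- act_fun(params$activation)
  M <- params$M
  Ht <- t(X)                       # features x samples internally
  H <- vector("list", M + 1); A <- vector("list", M + 1)
  H[[1]] <- Ht
  for (m in seq_len(M)) {
    A[[m + 1]] <- params$W[[m]] %*% H[[m]] + params$b[[m]]
    H[[m + 1]] <- act$f(A[[m + 1]])
  }
  bt <- H[[M / 2 + 1]]
  logits <- params$U %*% bt + params$u0          # K x N
  p <- t(softmax_cols(logits))
  p_sharp <- t(softmax_cols(logits / tau))
  structure(list(H = lapply(H, t), A = A,
                 bottleneck = t(bt), reconstruction = t(H[[M + 1]]),
                 logits = t(logits), p = p, p_sharp = p_sharp, tau = tau),
            class = "hidden_states")
}

softmax_cols <- function(Z) {
  Z <- sweep(Z, 2, apply(Z, 2, max))
  E <- exp(Z)
  sweep(E, 2, colSums(E), "/")
}

#' Temperature sharpening of class probabilities
#'
#' \eqn{\tilde p_k = p_k^{1/\tau} / \sum_e p_e^{1/\tau}}, applied row-wise.
#' `tau = 1` is the identity; as `tau` approaches 0 the output converges to a
#' one-hot mass at the argmax. Sharpening never increases row entropy for
#' `tau <= 1`.
#'
#' @param p Probability row(s): vector or matrix with rows on the simplex.
#' @param tau Temperature, `0 < tau <= 1`.
#' @return Sharpened probabilities, same shape as `p`.
#' @export
sharpen <- function(p, tau) {
  if (!is.numeric(tau) || length(tau) != 1 || tau <= 0)
    stop("`tau` must be a positive scalar.", call. = FALSE)
  vec <- is.vector(p)
  if (vec) p <- matrix(p, nrow = 1)
  q <- p^(1 / tau)
  out <- q / rowSums(q)
  if (vec) drop(out) else out
}

#' Reconstruction loss under the adaptive sigma-norm
#'
#' \eqn{\|H^{(M)} - X\|_\sigma} with one residual group per sample, squared by
#' default (`square = TRUE` follows the literal objective; `square = FALSE`
#' reproduces common robust-loss practice).
#'
#' @param states An [ae_forward()] result.
#' @param X The input batch (samples in rows).
#' @param spec A [sigma_spec()].
#' @param square Square the scalar sigma-norm?
#' @return Non-negative scalar.
#' @export
reconstruction_loss <- function(states, X, spec = sigma_spec(), square = TRUE) {
  R <- states$reconstruction - X
  s <- sigma_norm(R, spec)
  if (square) s^2 else s
}

#' Source classification loss with sigma-norm weight regularization
#'
#' Cross-entropy of the sharpened source predictions against one-hot labels,
#' plus \eqn{\lambda_1 \sum_m \|W^{(m)}\|_\sigma^2} over all weight matrices
#' (classifier head included; residual groups are rows) and a plain
#' \eqn{\lambda_2 \sum_m \|b^{(m)}\|_2^2} on the biases (biases play no role
#' in feature selection, so their norm is fixed to \eqn{\ell_2}).
#' Probabilities are floored at 1e-12 inside the log.
#'
#' @param states An [ae_forward()] result for the source batch.
#' @param Q One-hot label matrix, `n` x `K`.
#' @param params The [ae_init()] parameters (for the regularizers).
#' @param spec A [sigma_spec()].
#' @param lambda1,lambda2 Non-negative regularization weights.
#' @param square Square the sigma-norm weight penalty terms?
#' @return Scalar loss.
#' @export
source_loss <- function(states, Q, params, spec = sigma_spec(),
                        lambda1 = 0, lambda2 = 0, square = TRUE) {
  P <- pmax(states$p_sharp, 1e-12)
  ce <- -sum(Q * log(P))
  reg_w <- 0
  if (lambda1 > 0) {
    sn <- vapply(c(params$W, list(params$U)),
                 function(W) sigma_norm(W, spec), numeric(1))
    if (square) sn <- sn^2
    reg_w <- lambda1 * sum(sn)
  }
  reg_b <- 0
  if (lambda2 > 0)
    reg_b <- lambda2 * (sum(vapply(params$b, function(b) sum(b^2), numeric(1))) +
                          sum(params$u0^2))
  ce + reg_w + reg_b
}

#' Full training objective: reconstruction + source + clustering
#'
#' \eqn{J = J_1 + J_2 + J_3}: adaptive-loss reconstruction error over both
#' domains, sharpened source cross-entropy with weight/bias regularization,
#' and the fuzzy-entropy-regularized possibilistic clustering term evaluated
#' on the configured layer's features (bottleneck by default).
#'
#' @param params An [ae_init()] object.
#' @param X Batch matrix, samples in rows (source rows first is not required;
#'   `source_idx` selects them).
#' @param source_idx Integer indices of the labeled source rows of `X`.
#' @param Q One-hot labels for the source rows (`length(source_idx)` x K).
#' @param V Membership matrix, `nrow(X)` x K.
#' @param C Centroid matrix, K x latent-dim.
#' @param spec A [sigma_spec()].
#' @param lambda1,lambda2,lambda3 Objective weights.
#' @param tau Sharpening temperature.
#' @param cluster_layer `"bottleneck"` (default) or `"output"`.
#' @param square Square the sigma-norm terms in J1/J2?
#' @return Scalar objective.
#' @export
total_objective <- function(params, X, source_idx, Q, V, C,
                            spec = sigma_spec(), lambda1 = 0, lambda2 = 0,
                            lambda3 = 1, tau = 0.5,
                            cluster_layer = c("bottleneck", "output"),
                            square = TRUE) {
  cluster_layer <- match.arg(cluster_layer)
  states <- ae_forward(params, X, tau = tau)
  j1 <- reconstruction_loss(states, X, spec, square = square)
  src <- subset_states(states, source_idx)
  j2 <- source_loss(src, Q, params, spec, lambda1, lambda2, square = square)
  Hc <- if (cluster_layer == "bottleneck") states$bottleneck else states$reconstruction
  j3 <- dpc_objective(Hc, C, V, spec, lambda3)
  j1 + j2 + j3
}

subset_states <- function(states, idx) {
  out <- states
  out$p <- states$p[idx, , drop = FALSE]
  out$p_sharp <- states$p_sharp[idx, , drop = FALSE]
  out
}

#' Analytic gradients of the reweighted quadratic surrogate
#'
#' With the reweighting coefficients, memberships and centroids frozen, the
#' surrogate objective is
#' \deqn{L = \sum_i a_i \|h_i^{(M)} - x_i\|^2 - \sum_{i \in S}\sum_k q_{ik}
#'   \log \tilde p_{ik} + \lambda_1 \sum_m \sum_r r^w_{mr} \|w^{(m)}_r\|^2 +
#'   \lambda_2 \sum_m \|b^{(m)}\|^2 + \lambda_3 \sum_{ik} e_{ik} v_{ik}^2
#'   \|h_i^{(c)} - c_k\|^2,}
#' smooth in all network parameters. This routine evaluates `L` and its exact
#' gradients by backpropagation; the classifier head attaches to the
#' bottleneck and the clustering term to the configured layer. Weight-penalty
#' reweights `rw` act per row of each weight matrix (one sigma-norm residual
#' group per row).
#'
#' @param params An [ae_init()] object.
#' @param X Batch, samples in rows.
#' @param source_idx Indices of labeled source rows.
#' @param Q One-hot labels for source rows.
#' @param C Centroid matrix (K x latent-dim) for the clustering pull.
#' @param weights Frozen coefficients as returned by [compute_reweights()]:
#'   list with `a` (length `nrow(X)`), `rw` (list over `c(W, U)`, per-row),
#'   `ev2` (`nrow(X)` x K matrix of `e_ik v_ik^2`).
#' @param lambda1,lambda2,lambda3 Objective weights.
#' @param tau Sharpening temperature.
#' @param cluster_layer `"bottleneck"` or `"output"`.
#' @return List with `value` (surrogate objective) and gradients `dW`, `db`,
#'   `dU`, `du0`.
#' @export
ae_gradients <- function(params, X, source_idx, Q, C, weights,
                         lambda1 = 0, lambda2 = 0, lambda3 = 1, tau = 0.5,
                         cluster_layer = c("bottleneck", "output")) {
  cluster_layer <- match.arg(cluster_layer)
  act <- act_fun(params$activation)
  M <- params$M
  N <- nrow(X)
  cl <- if (cluster_layer == "bottleneck") M / 2 else M

  Ht <- t(X)
  H <- vector("list", M + 1); A <- vector("list", M + 1)
  H[[1]] <- Ht
  for (m in seq_len(M)) {
    A[[m + 1]] <- params$W[[m]] %*% H[[m]] + params$b[[m]]
    H[[m + 1]] <- act$f(A[[m + 1]])
  }
  bt <- H[[M / 2 + 1]]
  logits <- params$U %*% bt + params$u0

  # --- surrogate value -------------------------------------------------
  Rrec <- H[[M + 1]] - Ht                               # d x N
  val <- sum(weights$a * colSums(Rrec^2))
  Ps <- softmax_cols(logits[, source_idx, drop = FALSE] / tau)
  val <- val - sum(t(Q) * log(pmax(Ps, 1e-12)))
  Wall <- c(params$W, list(params$U))
  for (j in seq_along(Wall))
    val <- val + lambda1 * sum(weights$rw[[j]] * rowSums(Wall[[j]]^2))
  val <- val + lambda2 * (sum(vapply(params$b, function(b) sum(b^2), numeric(1))) +
                            sum(params$u0^2))
  Hc <- H[[cl + 1]]                                     # latent-dim x N
  z2 <- outer(rep(1, N), rowSums(C^2)) + outer(colSums(Hc^2), rep(1, nrow(C))) -
    2 * t(Hc) %*% t(C)                                  # N x K squared dists
  val <- val + lambda3 * sum(weights$ev2 * pmax(z2, 0))

  # --- backward pass ---------------------------------------------------
  # external gradient injected at the classifier head (w.r.t. logits)
  dZ <- matrix(0, params$K, N)
  dZ[, source_idx] <- (Ps - t(Q)) / tau
  # external gradient on the clustering layer
  wsum <- rowSums(weights$ev2)                          # length N
  Gclu <- 2 * lambda3 * (sweep(Hc, 2, wsum, "*") - t(C) %*% t(weights$ev2))
  # external gradient on the reconstruction layer
  Grec <- 2 * sweep(Rrec, 2, weights$a, "*")

  dW <- vector("list", M); db <- vector("list", M)
  Delta <- NULL
  for (m in M:1) {
    G <- if (m == M) Grec else t(params$W[[m + 1]]) %*% Delta
    if (m == cl) G <- G + Gclu
    if (m == M / 2) G <- G + t(params$U) %*% dZ
    Delta <- G * act$fprime(A[[m + 1]])
    dW[[m]] <- Delta %*% t(H[[m]]) +
      2 * lambda1 * weights$rw[[m]] * params$W[[m]]
    db[[m]] <- rowSums(Delta) + 2 * lambda2 * params$b[[m]]
  }
  dU <- dZ %*% t(bt) + 2 * lambda1 * weights$rw[[M + 1]] * params$U
  du0 <- rowSums(dZ) + 2 * lambda2 * params$u0
  list(value = val, dW = dW, db = db, dU = dU, du0 = du0)
}

#' Reweighting coefficients at the current residuals
#'
#' Applies the closed-form rule of [reweight_coefficient()] to each residual
#' group of the full objective: per-sample reconstruction residuals
#' (`a`), per-row weight-matrix norms (`rw`, classifier head last), and
#' per-sample-per-cluster latent distances (`e`). Also returns the closed-form
#' memberships `V` at the current distances and `ev2 = e * V^2`, the frozen
#' clustering weights of the surrogate. Bias terms are plain ridge and carry
#' no reweighting.
#'
#' @param params An [ae_init()] object.
#' @param states An [ae_forward()] result on the full batch.
#' @param X The batch (samples in rows).
#' @param C Centroid matrix, K x latent-dim.
#' @param spec A [sigma_spec()].
#' @param cluster_layer `"bottleneck"` or `"output"`.
#' @return List with `a`, `rw`, `e`, `V`, `ev2`, `D` (sigma-norm distances).
#' @export
compute_reweights <- function(params, states, X, C, spec = sigma_spec(),
                              cluster_layer = c("bottleneck", "output")) {
  cluster_layer <- match.arg(cluster_layer)
  zrec <- sqrt(rowSums((states$reconstruction - X)^2))
  a <- reweight_coefficient(zrec, spec$sigma)
  rw <- lapply(c(params$W, list(params$U)), function(W)
    reweight_coefficient(sqrt(rowSums(W^2)), spec$sigma))
  Hc <- if (cluster_layer == "bottleneck") states$bottleneck else states$reconstruction
  zc <- euclid_cross(Hc, C)
  e <- reweight_coefficient(zc, spec$sigma)
  D <- sigma_norm_scalar(zc, spec$sigma)
  V <- membership_update(D)
  list(a = a, rw = rw, e = e, V = V, ev2 = e * V^2, D = D)
}
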