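#' Closed-form possibilistic membership update
#'
#' Given a matrix `D` of adaptive-loss distances \eqn{D_{ik} =
#' \|h_i - c_k\|_\sigma \ge 0}, the fuzzy-entropy-regularized possibilistic
#' objective \eqn{v^2 D + v^2 \ln v^2 - v^2} is minimized over \eqn{v \in
#' (0, 1]} at \deqn{v_{ik} = \exp(-D_{ik}/2).}
#' Memberships are per-cluster typicalities: they need not sum to one across
#' clusters, and samples far from every centroid (outliers) receive uniformly
#' small memberships. \eqn{v_{ik} = 1} exactly when the distance is zero.
#'
#' @param D Non-negative numeric matrix (or vector) of distances, samples by
#'   clusters.
#' @return Matrix of memberships in (0, 1], same shape as `D`.
#' @export
membership_update <- function(D) {
  if (!is.numeric(D) || any(!is.finite(D)))
    stop("`D` must be finite numeric.", call. = FALSE)
  if (any(D < 0)) stop("distances must be non-negative.", call. = FALSE)
  exp(-D / 2)
}

#' Fuzzy-entropy penalty of a membership matrix
#'
#' Sum of \eqn{P_e(v) = v^2 \ln v^2 - v^2} over all entries. The penalty is 0
#' in the limit \eqn{v \to 0^+} and \eqn{-1} at \eqn{v = 1}; it rewards
#' confident memberships and prevents the trivial all-zero solution.
#'
#' @param V Numeric matrix or vector with entries in (0, 1].
#' @return Scalar penalty (non-positive).
#' @export
fuzzy_entropy_penalty <- function(V) {
  if (!is.numeric(V) || any(!is.finite(V)))
    stop("`V` must be finite numeric.", call. = FALSE)
  if (any(V <= 0) || any(V > 1))
    stop("membership entries must lie in (0, 1].", call. = FALSE)
  v2 <- V^2
  sum(v2 * log(v2) - v2)
}

#' Possibilistic clustering objective with fuzzy-entropy regularization
#'
#' Evaluates \eqn{\lambda_3 \sum_{ik} ( v_{ik}^2 \|h_i - c_k\|_\sigma +
#' P_e(v_{ik}) )} for latent features `H` (samples in rows), centroids `C`
#' (clusters in rows) and memberships `V`. At `V = membership_update(D)` this
#' is the minimum over memberships; each entry then contributes
#' \eqn{-e^{-D_{ik}}}.
#'
#' @param H Numeric matrix of latent features, samples in rows.
#' @param C Numeric matrix of centroids, clusters in rows (same column count
#'   as `H`).
#' @param V Membership matrix, `nrow(H)` by `nrow(C)`, entries in (0, 1].
#' @param spec A [sigma_spec()].
#' @param lambda3 Balancing coefficient of the clustering term.
#' @return Scalar objective value.
#' @export
dpc_objective <- function(H, C, V, spec = sigma_spec(), lambda3 = 1) {
  if (is.vector(H)) H <- matrix(H, nrow = 1)
  if (is.vector(C)) C <- matrix(C, nrow = 1)
  if (ncol(H) != ncol(C))
    stop("`H` and `C` must have the same feature dimension.", call. = FALSE)
  if (nrow(V) != nrow(H) || ncol(V) != nrow(C))
    stop("`V` must be nrow(H) x nrow(C).", call. = FALSE)
  D <- latent_distances(H, C, spec)
  v2 <- V^2
  lambda3 * sum(v2 * D + v2 * log(v2) - v2)
}

# N x K matrix of per-pair adaptive-loss distances ||h_i - c_k||_sigma
latent_distances <- function(H, C, spec = sigma_spec()) {
  z <- euclid_cross(H, C)
  sigma_norm_scalar(z, spec$sigma)
}

# N x K Euclidean cross-distances, rows of H vs rows of C
euclid_cross <- function(H, C) {
  d2 <- outer(rowSums(H^2), rep(1, nrow(C))) +
    outer(rep(1, nrow(H)), rowSums(C^2)) - 2 * H %*% t(C)
  sqrt(pmax(d2, 0))
}

#' Class-mean centroid initialization from labeled source features
#'
#' Initial centroids are the arithmetic means of the latent features of each
#' source class. Every class must be represented; an empty class raises an
#' explicit error rather than yielding silent NaN rows.
#'
#' @param H_source Numeric matrix of source latent features, samples in rows.
#' @param y_source Integer class labels in `1..K` (or a one-hot matrix with
#'   `K` columns).
#' @param K Number of classes; defaults to `max(y_source)` (or the one-hot
#'   width).
#' @return List of class `centroid_set` with `C` (K x dim matrix) and
#'   `counts`.
#' @export
init_centroids <- function(H_source, y_source, K = NULL) {
  if (is.matrix(y_source)) {
    if (is.null(K)) K <- ncol(y_source)
    y_source <- max.col(y_source, ties.method = "first")
  }
  y_source <- as.integer(y_source)
  if (is.null(K)) K <- max(y_source)
  if (nrow(H_source) != length(y_source))
    stop("labels and features disagree in length.", call. = FALSE)
  counts <- tabulate(y_source, nbins = K)
  if (any(counts == 0))
    stop("empty class: every class needs at least one source sample (missing: ",
         paste(which(counts == 0), collapse = ", "), ").", call. = FALSE)
  C <- rowsum(H_source, y_source)[as.character(seq_len(K)), , drop = FALSE] / counts
  structure(list(C = unname(C), counts = counts), class = "centroid_set")
}

#' Mean-discrepancy versus one-centroid clustering diagnostic
#'
#' Computes the empirical squared mean discrepancy between two domains
#' (identity feature map), \eqn{\mathrm{mmd} = \|\mu_s - \mu_t\|_2^2}, together
#' with two candidate upper bounds built from the blended centroid
#' \eqn{\mu = \delta \mu_s + (1-\delta)\mu_t}:
#' \describe{
#'   \item{`bound_printed`}{\eqn{\sum_k \zeta_k \|x_k - \mu\|^2} with
#'     \eqn{\zeta_k = 1/n_s^2} (source) or \eqn{1/n_t^2} (target). This
#'     version carries no guarantee: for the one-dimensional pair
#'     \eqn{X_s=\{0\}, X_t=\{2\}, \delta = 0.5} it gives 2 while the
#'     discrepancy is 4.}
#'   \item{`bound_corrected`}{\eqn{2[(1/n_s)\sum\|x^s-\mu\|^2 +
#'     (1/n_t)\sum\|x^t-\mu\|^2]}, which provably dominates the discrepancy
#'     (triangle inequality with its factor 2 kept, plus Cauchy-Schwarz).}
#' }
#' The check is diagnostic only; training never uses it numerically.
#'
#' @param Xs,Xt Numeric matrices, samples in rows, equal column counts.
#' @param delta Blend weight in `[0, 1]`; default `0.5` (the equal-size
#'   convention). Use `delta = NULL` for the size-proportional blend
#'   `n_s/(n_s+n_t)`.
#' @return List of class `mmd_bound_report` with fields `mmd`,
#'   `bound_printed`, `bound_corrected`, `printed_holds`, `mu`, `mu_s`,
#'   `mu_t`, `delta`. Errors if the corrected bound ever failed to dominate.
#' @export
mmd_clustering_bound <- function(Xs, Xt, delta = 0.5) {
  if (is.vector(Xs)) Xs <- matrix(Xs, ncol = 1)
  if (is.vector(Xt)) Xt <- matrix(Xt, ncol = 1)
  if (nrow(Xs) == 0 || nrow(Xt) == 0)
    stop("both domains must be non-empty.", call. = FALSE)
  if (ncol(Xs) != ncol(Xt))
    stop("domains must share dimensionality.", call. = FALSE)
  ns <- nrow(Xs); nt <- nrow(Xt)
  if (is.null(delta)) delta <- ns / (ns + nt)
  stopifnot(delta >= 0, delta <= 1)
  mu_s <- colMeans(Xs); mu_t <- colMeans(Xt)
  mu <- delta * mu_s + (1 - delta) * mu_t
  mmd <- sum((mu_s - mu_t)^2)
  ss <- sum(sweep(Xs, 2, mu)^2)
  st <- sum(sweep(Xt, 2, mu)^2)
  bound_printed <- ss / ns^2 + st / nt^2
  bound_corrected <- 2 * (ss / ns + st / nt)
  if (mmd > bound_corrected + 1e-9 * max(1, bound_corrected))
    stop("internal error: corrected bound failed to dominate the discrepancy.",
         call. = FALSE)
  structure(list(mmd = mmd, bound_printed = bound_printed,
                 bound_corrected = bound_corrected,
                 printed_holds = mmd <= bound_printed + 1e-12,
                 mu = mu, mu_s = mu_s, mu_t = mu_t, delta = delta),
            class = "mmd_bound_report")
}

#' @export
print.mmd_bound_report <- function(x, ...) {
  cat("<mmd_bound_report>\n",
      " mmd             ", format(x$mmd), "\n",
      " bound_printed   ", format(x$bound_printed),
      if (x$printed_holds) " (holds)" else " (VIOLATED)", "\n",
      " bound_corrected ", format(x$bound_corrected), " (guaranteed)\n", sep = "")
  invisible(x)
}
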