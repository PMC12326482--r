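#' Training configuration
#'
#' Collects every tunable of the joint objective and its optimizer. The
#' objective weights follow the convention of the joint loss: `lambda1`
#' (weight-matrix penalty), `lambda2` (bias ridge), `lambda3` (possibilistic
#' clustering term); each must be zero or inside the searched range
#' `[1e-4, 1e5]`. `sigma` is the adaptive-loss trade-off (default 0.001, the
#' operating point between the l21 and Frobenius extremes); `tau` the
#' sharpening temperature; `lr` the SGD step size.
#'
#' @param lambda1,lambda2,lambda3 Non-negative objective weights.
#' @param sigma,sigma1 Adaptive-loss parameters (see [sigma_spec()]).
#' @param tau Sharpening temperature in (0, 1].
#' @param lr Learning rate of the gradient steps.
#' @param batch_size Minibatch size (balanced half source / half target), or
#'   `NULL` for full-batch descent.
#' @param max_epochs,tol Epoch cap and relative-change tolerance of the
#'   convergence test (5-epoch window, see [converged()]).
#' @param warmup_epochs Initial epochs trained without the clustering term
#'   (reconstruction + source classification only), the usual deep-clustering
#'   pretraining: the clustering pull only becomes meaningful once latent
#'   distances are informative. Default 20.
#' @param seed Integer seed controlling initialization and batch order.
#' @param hidden_dims Hidden-layer widths (encoder side then decoder side);
#'   default `c(500, 300, 500)` giving the d-500-300-500-d template.
#' @param activation `"tanh"` or `"relu"`.
#' @param cluster_layer Layer carrying the clustering term: `"bottleneck"`
#'   (default) or `"output"`.
#' @param centroid_refresh Refresh cadence for pseudo-labels/centroids:
#'   `"batch"` (default) or `"epoch"`.
#' @param reweight_each Recompute the surrogate weights each `"epoch"`
#'   (default, stable surrogate) or each `"batch"`.
#' @param square_sigma_terms Report the squared sigma-norm reading of the
#'   reconstruction and weight-penalty terms in the true objective.
#' @param standardize Z-score features with pooled statistics before
#'   training.
#' @param empty_policy Empty-cluster policy at refresh: `"keep"` or
#'   `"reseed"`.
#' @param centroid_source Samples entering the centroid refresh: `"target"`
#'   (default; the refresh numerator counts pseudo-labeled target features,
#'   so centroids track the target clusters -- under cosine assignment the
#'   pooled denominator only rescales) or `"pooled"` (source and target
#'   features averaged together). Classes with no target members fall back
#'   to their source means.
#' @param distance Assignment metric for pseudo-labels and prediction:
#'   `"cosine"` (default, suited to unit-normalized deep features) or
#'   `"euclidean"`.
#' @return Object of class `dadpc_config`.
#' @export
dadpc_config <- function(lambda1 = 0.01, lambda2 = 0.01, lambda3 = 1,
                         sigma = 0.001, sigma1 = 0.001, tau = 0.5,
                         lr = 1e-3, batch_size = 64,
                         max_epochs = 200, tol = 1e-6, seed = 1,
                         warmup_epochs = 20,
                         hidden_dims = c(500, 300, 500),
                         activation = c("tanh", "relu"),
                         cluster_layer = c("bottleneck", "output"),
                         centroid_refresh = c("batch", "epoch"),
                         reweight_each = c("epoch", "batch"),
                         square_sigma_terms = TRUE,
                         standardize = TRUE,
                         empty_policy = c("keep", "reseed"),
                         centroid_source = c("target", "pooled"),
                         distance = c("cosine", "euclidean")) {
  for (nm in c("lambda1", "lambda2", "lambda3")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1 || v < 0 ||
        (v != 0 && (v < 1e-4 || v > 1e5)))
      stop("`", nm, "` must be 0 or within [1e-4, 1e5].", call. = FALSE)
  }
  stopifnot(sigma > 0, sigma1 > 0, tau > 0, tau <= 1, lr > 0,
            max_epochs >= 1, tol > 0, warmup_epochs >= 0)
  if (length(hidden_dims) %% 2 == 0)
    stop("`hidden_dims` must have odd length (bottleneck in the middle).",
         call. = FALSE)
  structure(list(
    lambda1 = lambda1, lambda2 = lambda2, lambda3 = lambda3,
    sigma = sigma, sigma1 = sigma1, tau = tau, lr = lr,
    batch_size = batch_size, max_epochs = max_epochs, tol = tol,
    seed = as.integer(seed), warmup_epochs = as.integer(warmup_epochs),
    hidden_dims = as.integer(hidden_dims),
    activation = match.arg(activation),
    cluster_layer = match.arg(cluster_layer),
    centroid_refresh = match.arg(centroid_refresh),
    reweight_each = match.arg(reweight_each),
    square_sigma_terms = isTRUE(square_sigma_terms),
    standardize = isTRUE(standardize),
    empty_policy = match.arg(empty_policy),
    centroid_source = match.arg(centroid_source),
    distance = match.arg(distance)), class = "dadpc_config")
}

# cosine nearest-centroid assignment; ties to the lowest class index
cosine_assign <- function(H, C) {
  Hn <- H / pmax(sqrt(rowSums(H^2)), 1e-300)
  Cn <- C / pmax(sqrt(rowSums(C^2)), 1e-300)
  max.col(Hn %*% t(Cn), ties.method = "first")
}

# metric-configurable nearest-centroid assignment
centroid_assign <- function(H, C, distance = "cosine") {
  if (distance == "cosine") return(cosine_assign(H, C))
  max.col(-euclid_cross(H, C), ties.method = "first")
}

# label-wise means; empty classes keep `prev`
label_means <- function(H, labels, K, prev, empty_policy = "keep", warn = TRUE) {
  counts <- tabulate(labels, nbins = K)
  C <- prev
  for (k in seq_len(K)) {
    if (counts[k] > 0) {
      C[k, ] <- colMeans(H[labels == k, , drop = FALSE])
    } else if (warn) {
      warning("class ", k, " has no members; keeping previous centroid.",
              call. = FALSE)
    }
  }
  list(C = C, counts = counts)
}

#' Fit the domain-adaptive possibilistic clustering model
#'
#' Alternating optimization of the joint objective: (1) the surrogate
#' reweighting coefficients are recomputed from the current residuals,
#' (2) gradient steps update the network weights on batches containing both
#' domains, (3) the memory bank is refreshed and target pseudo-labels and
#' class centroids updated by cosine nearest-centroid, (4) the possibilistic
#' memberships are updated in closed form. Training stops when the objective
#' stabilizes (see [converged()]) or at `max_epochs`.
#'
#' With `lambda3 = 0` the clustering term is ablated and the model reduces to
#' a source-only encoder-decoder classifier: target pseudo-labels are still
#' reported but never pooled into the centroids, which remain source class
#' means in the learned latent space.
#'
#' @param source Data frame of labeled source samples: one label column plus
#'   numeric feature columns.
#' @param target Data frame of unlabeled target samples (same feature
#'   columns; any label column is ignored).
#' @param config A [dadpc_config()].
#' @param label_col Name of the source label column (default `"class"`).
#' @param target_truth Optional true target labels, used only to log
#'   per-epoch pseudo-label accuracy in the history.
#' @return Object of class `dadpc`: trained parameters, feature scaler,
#'   final centroids and memory bank, membership matrix, pseudo-labels, and
#'   a per-epoch `history` tibble (surrogate and true objective,
#'   pseudo-label churn, centroid drift, optional accuracy).
#' @export
dadpc_fit <- function(source, target, config = dadpc_config(),
                      label_col = "class", target_truth = NULL) {
  stopifnot(inherits(config, "dadpc_config"))
  if (!label_col %in% names(source))
    stop("`source` must contain the label column `", label_col, "`.",
         call. = FALSE)
  y_raw <- source[[label_col]]
  levels <- sort(unique(y_raw))
  y <- match(y_raw, levels)
  K <- length(levels)
  feats <- setdiff(names(source)[vapply(source, is.numeric, logical(1))],
                   label_col)
  feats <- intersect(feats, names(target))
  if (length(feats) < 1)
    stop("no shared numeric feature columns between source and target.",
         call. = FALSE)
  Xs <- as.matrix(source[, feats]); Xt <- as.matrix(target[, feats])
  ns <- nrow(Xs); nt <- nrow(Xt); N <- ns + nt
  X <- rbind(Xs, Xt)
  if (config$standardize) {
    ctr <- colMeans(X); scl <- pmax(apply(X, 2, stats::sd), 1e-12)
  } else {
    ctr <- rep(0, ncol(X)); scl <- rep(1, ncol(X))
  }
  X <- sweep(sweep(X, 2, ctr), 2, scl, "/")
  src_idx <- seq_len(ns)
  is_source <- c(rep(TRUE, ns), rep(FALSE, nt))
  Q <- matrix(0, ns, K); Q[cbind(seq_len(ns), y)] <- 1

  spec <- sigma_spec(config$sigma, config$sigma1)
  d <- ncol(X)
  params <- ae_init(c(d, config$hidden_dims, d), K,
                    activation = config$activation, seed = config$seed)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(config$seed + 1L)

  states <- ae_forward(params, X, tau = config$tau)
  cluster_feats <- function(st)
    if (config$cluster_layer == "bottleneck") st$bottleneck else st$reconstruction
  Hc <- cluster_feats(states)
  C <- init_centroids(Hc[src_idx, , drop = FALSE], y, K)$C
  pooled <- config$lambda3 > 0     # lambda3 = 0: source-only centroids
  warmup <- config$warmup_epochs
  labels <- c(y, centroid_assign(Hc[-src_idx, , drop = FALSE], C,
                                 config$distance))
  bank <- init_bank(Hc, structure(list(C = C, counts = tabulate(y, K)),
                                  class = "centroid_set"),
                    labels, is_source)

  refresh <- function(Hc, labels, C, pool_now) {
    if (!pool_now) {
      # source-only centroids (warm-up, or the lambda3 = 0 ablation)
      return(label_means(Hc[src_idx, , drop = FALSE], labels[src_idx], K, C,
                         config$empty_policy)$C)
    }
    if (config$centroid_source == "pooled")
      return(label_means(Hc, labels, K, C, config$empty_policy)$C)
    # target-tracking refresh; empty target classes fall back to source means
    Cs <- label_means(Hc[src_idx, , drop = FALSE], labels[src_idx], K, C,
                      config$empty_policy, warn = FALSE)$C
    lab_t <- labels[-src_idx]
    Ht <- Hc[-src_idx, , drop = FALSE]
    label_means(Ht, lab_t, K, Cs, "keep", warn = FALSE)$C
  }

  history <- vector("list", config$max_epochs)
  bs <- config$batch_size
  full_batch <- is.null(bs) || bs >= N
  surrogate_trace <- numeric(0)

  for (epoch in seq_len(config$max_epochs)) {
    l3_eff <- if (epoch <= warmup) 0 else config$lambda3
    pool_now <- pooled && epoch > warmup
    w_full <- compute_reweights(params, states, X, C, spec,
                                config$cluster_layer)
    if (full_batch) {
      batches <- list(seq_len(N))
    } else {
      half <- max(1L, bs %/% 2L)
      n_b <- max(1L, floor(min(ns, nt) / half))
      so <- sample(src_idx); to <- sample(setdiff(seq_len(N), src_idx))
      batches <- lapply(seq_len(n_b), function(j) {
        c(so[((j - 1) * half + 1):min(j * half, ns)],
          to[((j - 1) * half + 1):min(j * half, nt)])
      })
    }
    for (batch in batches) {
      b_src <- which(batch %in% src_idx)
      wb <- list(a = w_full$a[batch], rw = w_full$rw,
                 ev2 = w_full$ev2[batch, , drop = FALSE])
      if (config$reweight_each == "batch") {
        stb <- ae_forward(params, X[batch, , drop = FALSE], tau = config$tau)
        wfb <- compute_reweights(params, stb, X[batch, , drop = FALSE], C,
                                 spec, config$cluster_layer)
        wb <- list(a = wfb$a, rw = wfb$rw, ev2 = wfb$ev2)
      }
      g <- ae_gradients(params, X[batch, , drop = FALSE], b_src,
                        Q[batch[b_src], , drop = FALSE], C, wb,
                        config$lambda1, config$lambda2, l3_eff,
                        config$tau, config$cluster_layer)
      if (!is.finite(g$value))
        stop("objective became non-finite at epoch ", epoch,
             "; snapshot: lr=", config$lr, ", surrogate=", g$value,
             call. = FALSE)
      for (m in seq_len(params$M)) {
        params$W[[m]] <- params$W[[m]] - config$lr * g$dW[[m]]
        params$b[[m]] <- params$b[[m]] - config$lr * g$db[[m]]
      }
      params$U <- params$U - config$lr * g$dU
      params$u0 <- params$u0 - config$lr * g$du0
      if (config$centroid_refresh == "batch") {
        stb <- ae_forward(params, X[batch, , drop = FALSE], tau = config$tau)
        Hc[batch, ] <- cluster_feats(stb)
        bank <- update_bank(bank, Hc[batch, , drop = FALSE], batch)
        labels[-src_idx] <- centroid_assign(Hc[-src_idx, , drop = FALSE], C,
                                            config$distance)
        C <- refresh(Hc, labels, C, pool_now)
      }
    }
    states <- ae_forward(params, X, tau = config$tau)
    Hc_new <- cluster_feats(states)
    bank <- update_bank(bank, Hc_new, seq_len(N))
    C_prev <- C
    labels_prev <- labels
    labels[-src_idx] <- centroid_assign(Hc_new[-src_idx, , drop = FALSE], C,
                                        config$distance)
    C <- refresh(Hc_new, labels, C, pool_now)
    Hc <- Hc_new
    V <- compute_reweights(params, states, X, C, spec, config$cluster_layer)$V

    sur <- ae_gradients(params, X, src_idx, Q, C_prev,
                        list(a = w_full$a, rw = w_full$rw, ev2 = w_full$ev2),
                        config$lambda1, config$lambda2, l3_eff,
                        config$tau, config$cluster_layer)$value
    obj <- total_objective(params, X, src_idx, Q, V, C, spec,
                           config$lambda1, config$lambda2, l3_eff,
                           config$tau, config$cluster_layer,
                           square = config$square_sigma_terms)
    if (!is.finite(obj))
      stop("objective became non-finite at epoch ", epoch, ".", call. = FALSE)
    churn <- sum(labels[-src_idx] != labels_prev[-src_idx])
    drift <- sqrt(mean((C - C_prev)^2))
    acc <- if (!is.null(target_truth))
      mean(labels[-src_idx] == match(target_truth, levels)) else NA_real_
    history[[epoch]] <- tibble::tibble(
      epoch = epoch, surrogate = sur, objective = obj,
      pseudo_label_churn = churn, centroid_drift = drift,
      target_accuracy = acc)
    surrogate_trace <- c(surrogate_trace, sur)
    cv <- converged(surrogate_trace, config$tol)
    if (cv$converged) break
  }
  history <- dplyr::bind_rows(history)

  # final consistency: labels assigned against the final centroids
  labels[-src_idx] <- centroid_assign(Hc[-src_idx, , drop = FALSE], C,
                                      config$distance)
  counts <- tabulate(if (pooled) labels else labels[src_idx], nbins = K)
  bank$labels <- labels
  bank$B[bank$n + seq_len(K), ] <- l2_normalize_rows(C)

  structure(list(
    params = params, config = config, spec = spec,
    center = ctr, scale = scl, features = feats, levels = levels,
    centroids = structure(list(C = C, counts = counts),
                          class = "centroid_set"),
    bank = bank, V = V, history = history,
    pseudo_labels = labels[-src_idx],
    n_source = ns, n_target = nt, K = K,
    converged = converged(history$surrogate, config$tol)), class = "dadpc")
}

#' @export
print.dadpc <- function(x, ...) {
  cat("<dadpc> trained model\n",
      " source/target: ", x$n_source, "/", x$n_target,
      " samples, K = ", x$K, " classes\n",
      " epochs run: ", nrow(x$history),
      "  converged: ", x$converged$converged, "\n",
      " final objective: ", format(utils::tail(x$history$objective, 1)),
      "\n", sep = "")
  invisible(x)
}

#' Predict class labels for new samples
#'
#' Passes new samples through the trained encoder and assigns the cosine
#' nearest centroid on the configured clustering layer; scores are a softmax
#' over negative cosine distances. Sample order does not affect individual
#' predictions.
#'
#' @param object A fitted [dadpc_fit()] model.
#' @param new_data Data frame containing the training feature columns.
#' @param ... Unused.
#' @return Tibble with `.pred_class` (original label coding) and one
#'   `.score_<level>` column per class.
#' @export
predict.dadpc <- function(object, new_data, ...) {
  X <- as.matrix(new_data[, object$features, drop = FALSE])
  X <- sweep(sweep(X, 2, object$center), 2, object$scale, "/")
  st <- ae_forward(object$params, X, tau = object$config$tau)
  H <- if (object$config$cluster_layer == "bottleneck")
    st$bottleneck else st$reconstruction
  C <- object$centroids$C
  if (object$config$distance == "cosine") {
    Hn <- H / pmax(sqrt(rowSums(H^2)), 1e-300)
    Cn <- C / pmax(sqrt(rowSums(C^2)), 1e-300)
    dd <- 1 - Hn %*% t(Cn)
  } else {
    dd <- euclid_cross(H, C)
  }
  lab <- max.col(-dd, ties.method = "first")
  sc <- exp(-dd); sc <- sc / rowSums(sc)
  colnames(sc) <- paste0(".score_", object$levels)
  tibble::tibble(.pred_class = object$levels[lab], tibble::as_tibble(sc))
}

#' Convergence decision on an objective trace
#'
#' Declares convergence at the first epoch where every relative objective
#' change within the trailing window (up to 5 epochs) is below `tol`.
#'
#' @param history Numeric objective trace, or a fit `history` tibble (its
#'   `surrogate` column is used).
#' @param tol Relative-change tolerance.
#' @param window Window length (default 5).
#' @return List with `converged` (logical) and `epoch` (first epoch of
#'   decision, NA if never).
#' @export
converged <- function(history, tol = 1e-6, window = 5) {
  trace <- if (is.data.frame(history)) history$surrogate else as.numeric(history)
  n <- length(trace)
  if (n < 2) return(list(converged = FALSE, epoch = NA_integer_))
  rel <- abs(diff(trace)) / pmax(abs(trace[-n]), .Machine$double.eps)
  for (t in 2:n) {
    w <- rel[max(1, t - window):(t - 1)]
    if (all(w < tol)) return(list(converged = TRUE, epoch = t))
  }
  list(converged = FALSE, epoch = NA_integer_)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Per-epoch training history in tidy form
#'
#' @param x A fitted `dadpc` model.
#' @param ... Unused.
#' @return The per-epoch history tibble (objective values, pseudo-label
#'   churn, centroid drift, optional target accuracy).
#' @export
tidy.dadpc <- function(x, ...) x$history

#' One-row model summary
#'
#' @param x A fitted `dadpc` model.
#' @param ... Unused.
#' @return A one-row tibble: sample sizes, epochs, convergence flag, final
#'   objective values.
#' @export
glance.dadpc <- function(x, ...) {
  tibble::tibble(
    n_source = x$n_source, n_target = x$n_target, K = x$K,
    epochs = nrow(x$history),
    converged = x$converged$converged,
    final_objective = utils::tail(x$history$objective, 1),
    final_surrogate = utils::tail(x$history$surrogate, 1))
}

#' Objective-trace plot of a fitted model
#'
#' @param object A fitted `dadpc` model.
#' @param ... Unused.
#' @return A ggplot of the surrogate and true objective per epoch.
#' @export
autoplot.dadpc <- function(object, ...) {
  df <- tidyr::pivot_longer(object$history[, c("epoch", "surrogate", "objective")],
                            -"epoch", names_to = "trace", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$value,
                                   colour = .data$trace)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "objective value", colour = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

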