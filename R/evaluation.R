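#' Fold definitions for the validation protocols
#'
#' Builds the train/test partition of a multi-subject dataset for one of the
#' four protocols:
#' \describe{
#'   \item{CUCE}{cross-subject cross-session, leave-one-subject-out: each
#'     fold holds out every session of one subject as target (with
#'     `per_session_folds = TRUE`, one fold per held-out session instead).}
#'   \item{CUSE}{cross-subject single-session: only the first session is
#'     used; one fold per held-out subject.}
#'   \item{WUCE}{within-subject cross-session: per subject, the first two
#'     sessions are source and the third session is target.}
#'   \item{CDCV}{cross-database: one dataset entirely source, the other
#'     entirely target; one fold per direction.}
#' }
#' Folds are disjoint in their targets and cover the manifest exactly once
#' per protocol definition; a WUCE subject missing sessions is skipped with a
#' warning.
#'
#' @param data Tibble with `subject`, `session` (and `dataset` for CDCV)
#'   columns.
#' @param protocol One of `"CUCE"`, `"CUSE"`, `"WUCE"`, `"CDCV"`.
#' @param per_session_folds CUCE granularity switch.
#' @return List of folds, each `list(name, source, target)` with row
#'   indices into `data`.
#' @export
protocol_folds <- function(data, protocol = c("CUCE", "CUSE", "WUCE", "CDCV"),
                           per_session_folds = FALSE) {
  protocol <- match.arg(protocol)
  stopifnot(all(c("subject", "session") %in% names(data)))
  subj <- data$subject; sess <- data$session
  folds <- list()
  if (protocol == "CUCE") {
    for (s in sort(unique(subj))) {
      if (per_session_folds) {
        for (se in sort(unique(sess[subj == s]))) {
          folds[[length(folds) + 1]] <- list(
            name = paste0("subject", s, "_session", se),
            source = which(subj != s),
            target = which(subj == s & sess == se))
        }
      } else {
        folds[[length(folds) + 1]] <- list(
          name = paste0("subject", s),
          source = which(subj != s), target = which(subj == s))
      }
    }
  } else if (protocol == "CUSE") {
    first <- min(sess)
    for (s in sort(unique(subj))) {
      folds[[length(folds) + 1]] <- list(
        name = paste0("subject", s),
        source = which(subj != s & sess == first),
        target = which(subj == s & sess == first))
    }
  } else if (protocol == "WUCE") {
    for (s in sort(unique(subj))) {
      ses <- sort(unique(sess[subj == s]))
      if (length(ses) < 3) {
        warning("subject ", s, " has fewer than 3 sessions; skipped.",
                call. = FALSE)
        next
      }
      folds[[length(folds) + 1]] <- list(
        name = paste0("subject", s),
        source = which(subj == s & sess %in% ses[1:2]),
        target = which(subj == s & sess == ses[3]))
    }
  } else {
    stopifnot("dataset" %in% names(data))
    ds <- sort(unique(data$dataset))
    if (length(ds) != 2)
      stop("CDCV needs exactly two datasets.", call. = FALSE)
    for (j in 1:2) {
      folds[[length(folds) + 1]] <- list(
        name = paste0(ds[j], "_to_", ds[3 - j]),
        source = which(data$dataset == ds[j]),
        target = which(data$dataset == ds[3 - j]))
    }
  }
  folds
}

#' Run a validation protocol
#'
#' Trains one model per fold on the fold's labeled source rows, predicts the
#' held-back target rows, and aggregates accuracy (percent, mean and standard
#' deviation over folds, the Pacc convention) together with a pooled K x K
#' confusion matrix.
#'
#' @param data Tibble with `subject`, `session`, the label column, and
#'   numeric feature columns (`dataset` column for CDCV).
#' @param protocol Protocol name, see [protocol_folds()].
#' @param config A [dadpc_config()].
#' @param label_col Label column name.
#' @param per_session_folds CUCE granularity switch.
#' @param fit_fn Model routine: `function(source, target, config, label_col)`
#'   returning predicted target labels (original coding). The default trains
#'   [dadpc_fit()] and predicts with [predict.dadpc()]; injecting a trivial
#'   model (e.g. constant majority-class) reproduces chance accuracy.
#' @return Object of class `protocol_result`: `folds` tibble (per-fold
#'   accuracy), `mean_acc`, `sd_acc` (percent), `confusion`, `protocol`.
#' @export
run_protocol <- function(data, protocol, config = dadpc_config(),
                         label_col = "class", per_session_folds = FALSE,
                         fit_fn = NULL) {
  folds <- protocol_folds(data, protocol, per_session_folds)
  if (length(folds) == 0) stop("no usable folds.", call. = FALSE)
  if (is.null(fit_fn)) {
    fit_fn <- function(source, target, config, label_col) {
      fit <- dadpc_fit(source, target, config, label_col)
      predict(fit, target)$.pred_class
    }
  }
  levels <- sort(unique(data[[label_col]]))
  K <- length(levels)
  conf <- matrix(0L, K, K, dimnames = list(true = levels, pred = levels))
  rows <- purrr::map(folds, function(f) {
    src <- data[f$source, , drop = FALSE]
    tgt <- data[f$target, , drop = FALSE]
    truth <- tgt[[label_col]]
    pred <- fit_fn(src, dplyr::select(tgt, -dplyr::all_of(label_col)),
                   config, label_col)
    conf <<- conf + confusion(match(truth, levels), match(pred, levels), K)
    tibble::tibble(fold = f$name, n_target = nrow(tgt),
                   accuracy = 100 * mean(pred == truth))
  })
  folds_tbl <- dplyr::bind_rows(rows)
  structure(list(folds = folds_tbl,
                 mean_acc = mean(folds_tbl$accuracy),
                 sd_acc = stats::sd(folds_tbl$accuracy),
                 confusion = conf, protocol = protocol,
                 levels = levels), class = "protocol_result")
}

#' @export
print.protocol_result <- function(x, ...) {
  cat("<protocol_result> ", x$protocol, ": ",
      sprintf("%.2f +/- %.2f%%", x$mean_acc, x$sd_acc),
      " over ", nrow(x$folds), " folds\n", sep = "")
  invisible(x)
}

#' @export
tidy.protocol_result <- function(x, ...) x$folds

#' @export
glance.protocol_result <- function(x, ...) {
  tibble::tibble(protocol = x$protocol, n_folds = nrow(x$folds),
                 mean_acc = x$mean_acc, sd_acc = x$sd_acc)
}

#' @export
autoplot.protocol_result <- function(object, ...) {
  ggplot2::ggplot(object$folds,
                  ggplot2::aes(x = .data$fold, y = .data$accuracy)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = object$mean_acc, linetype = 2) +
    ggplot2::labs(x = NULL, y = "accuracy (%)",
                  title = paste(object$protocol, "per-fold accuracy")) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Source-label noise sweep
#'
#' Corrupts eta% of the source labels (target labels are never touched),
#' refits the model at each level, and reports target accuracy per level.
#' The eta = 0 entry equals an uncorrupted run with the same configuration.
#'
#' @param source,target Source (labeled) and target (unlabeled) data frames.
#' @param target_truth True target labels for scoring.
#' @param etas Noise percentages (default `c(0, 5, 10, 15, 20, 25)`).
#' @param config A [dadpc_config()].
#' @param label_col Label column in `source`.
#' @param seed Seed for the label-corruption draws.
#' @return Tibble with `eta` and `accuracy` (percent).
#' @export
noise_sweep <- function(source, target, target_truth,
                        etas = c(0, 5, 10, 15, 20, 25),
                        config = dadpc_config(), label_col = "class",
                        seed = 1) {
  levels <- sort(unique(source[[label_col]]))
  K <- length(levels)
  purrr::map_dfr(etas, function(eta) {
    src <- source
    y <- match(src[[label_col]], levels)
    src[[label_col]] <- levels[corrupt_labels(y, eta, K, seed = seed)]
    fit <- dadpc_fit(src, target, config, label_col)
    pred <- predict(fit, target)$.pred_class
    tibble::tibble(eta = eta, accuracy = 100 * mean(pred == target_truth))
  })
}

#' Confusion matrix of true versus predicted labels
#'
#' @param labels_true,labels_pred Integer labels in `1..K`, equal length.
#' @param K Number of classes.
#' @return K x K integer matrix; entry (i, j) counts true class i predicted
#'   as class j. Row sums conserve the per-class counts.
#' @export
confusion <- function(labels_true, labels_pred, K) {
  stopifnot(length(labels_true) == length(labels_pred))
  lt <- as.integer(labels_true); lp <- as.integer(labels_pred)
  if (any(lt < 1 | lt > K | lp < 1 | lp > K, na.rm = FALSE) || anyNA(c(lt, lp)))
    stop("labels must lie in 1..K.", call. = FALSE)
  m <- matrix(0L, K, K)
  for (i in seq_along(lt)) m[lt[i], lp[i]] <- m[lt[i], lp[i]] + 1L
  m
}

#' Mutual-information map between features and predicted classes
#'
#' Estimates the mutual information between every feature column and every
#' class's prediction (predictions hardened to labels, then one class versus
#' the rest), giving a K x d matrix that is min-max scaled to [0, 1]. The
#' default estimator is the k-nearest-neighbour mixed continuous-discrete
#' estimator (k = 3); a quantile-histogram plug-in estimator is available as
#' a fallback. A constant feature column has mutual information 0 by
#' definition.
#'
#' @param X_t Target feature matrix or data frame (rows aligned with
#'   `P_hat`).
#' @param P_hat N x K matrix of predicted class probabilities (or an integer
#'   label vector).
#' @param method `"knn"` or `"histogram"`.
#' @param k Neighbour count for the knn estimator.
#' @param n_bins Bin count for the histogram estimator.
#' @return Object of class `mutual_info_map`: `I` (scaled to [0, 1]), `I_raw`
#'   (nats), `method`.
#' @export
mutual_info_map <- function(X_t, P_hat, method = c("knn", "histogram"),
                            k = 3, n_bins = 8) {
  method <- match.arg(method)
  X <- as.matrix(X_t)
  lab <- if (is.matrix(P_hat)) max.col(P_hat, ties.method = "first")
         else as.integer(P_hat)
  stopifnot(nrow(X) == length(lab))
  K <- max(lab)
  I <- matrix(0, K, ncol(X))
  for (kk in seq_len(K)) {
    y <- as.integer(lab == kk)
    for (j in seq_len(ncol(X))) {
      x <- X[, j]
      I[kk, j] <- if (stats::sd(x) == 0) 0
        else if (method == "knn") mi_knn_discrete(x, y, k)
        else mi_hist_discrete(x, y, n_bins)
    }
  }
  rng <- range(I)
  I_scaled <- if (diff(rng) == 0) I * 0 else (I - rng[1]) / diff(rng)
  structure(list(I = I_scaled, I_raw = I, method = method),
            class = "mutual_info_map")
}

# mixed continuous-discrete kNN mutual-information estimator
mi_knn_discrete <- function(x, y, k = 3) {
  n <- length(x)
  counts <- table(y)
  psi_ny <- digamma(as.numeric(counts[as.character(y)]))
  psi_k <- numeric(n); psi_m <- numeric(n); use <- logical(n)
  for (i in seq_len(n)) {
    same <- which(y == y[i]); same <- same[same != i]
    if (length(same) == 0) next
    ki <- min(k, length(same))
    d <- sort(abs(x[same] - x[i]), partial = ki)[ki]
    m <- sum(abs(x - x[i]) <= d) - 1L
    psi_k[i] <- digamma(ki); psi_m[i] <- digamma(max(m, ki))
    use[i] <- TRUE
  }
  if (!any(use)) return(0)
  val <- digamma(n) - mean(psi_ny[use]) + mean(psi_k[use]) - mean(psi_m[use])
  max(val, 0)
}

# quantile-histogram plug-in estimator (fallback)
mi_hist_discrete <- function(x, y, n_bins = 8) {
  br <- unique(stats::quantile(x, probs = seq(0, 1, length.out = n_bins + 1)))
  if (length(br) < 2) return(0)
  bx <- cut(x, breaks = br, include.lowest = TRUE)
  tab <- table(bx, y)
  p <- tab / sum(tab)
  px <- rowSums(p); py <- colSums(p)
  e <- outer(px, py)
  nz <- p > 0
  max(sum(p[nz] * log(p[nz] / e[nz])), 0)
}

#' @export
print.mutual_info_map <- function(x, ...) {
  cat("<mutual_info_map> ", nrow(x$I), " classes x ", ncol(x$I),
      " features (", x$method, " estimator), scaled to [0, 1]\n", sep = "")
  invisible(x)
}
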