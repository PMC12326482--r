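#' Memory bank of unit-normalized features and centroids
#'
#' The bank stores one L2-normalized row per sample (source rows first is not
#' required; a domain mask records origin) followed by K normalized class
#' centroids. Source labels are fixed at construction; target labels are
#' pseudo-labels and may change at every refresh. Features are stored
#' directly, with no momentum blending.
#'
#' @param H_all Latent features for all N samples, samples in rows.
#' @param C0 A `centroid_set` (from [init_centroids()]) giving the initial
#'   source-derived centroids.
#' @param labels Length-N integer labels in `1..K`: true labels for source
#'   rows, `NA` allowed for target rows (filled by
#'   [assign_pseudo_labels()]).
#' @param is_source Length-N logical domain mask.
#' @return Object of class `memory_bank` with fields `B` ((N+K) x dim, unit
#'   rows), `labels`, `is_source`, `n`, `K`.
#' @export
init_bank <- function(H_all, C0, labels, is_source) {
  stopifnot(inherits(C0, "centroid_set"))
  n <- nrow(H_all)
  K <- nrow(C0$C)
  stopifnot(length(labels) == n, length(is_source) == n)
  B <- rbind(l2_normalize_rows(H_all), l2_normalize_rows(C0$C))
  structure(list(B = B, labels = as.integer(labels),
                 is_source = as.logical(is_source), n = n, K = K),
            class = "memory_bank")
}

l2_normalize_rows <- function(X) {
  nrm <- sqrt(rowSums(X^2))
  if (any(nrm == 0))
    stop("zero-norm feature row: cannot normalize a degenerate feature.",
         call. = FALSE)
  X / nrm
}

#' Replace bank rows with fresh (normalized) features
#'
#' Exactly the rows in `batch_indices` are overwritten by the normalized new
#' features; all other rows (and the centroid block) are untouched. No
#' momentum: re-updating with identical features is idempotent.
#'
#' @param bank A [init_bank()] object.
#' @param batch_features Matrix of new features, one row per index.
#' @param batch_indices Sample indices in `1..N`.
#' @return The updated `memory_bank`.
#' @export
update_bank <- function(bank, batch_features, batch_indices) {
  stopifnot(inherits(bank, "memory_bank"))
  if (length(batch_indices) == 0) return(bank)
  batch_indices <- as.integer(batch_indices)
  if (any(batch_indices < 1) || any(batch_indices > bank$n))
    stop("batch index out of range 1..", bank$n, ".", call. = FALSE)
  bank$B[batch_indices, ] <- l2_normalize_rows(
    matrix(batch_features, nrow = length(batch_indices)))
  bank
}

bank_centroids <- function(bank) {
  bank$B[bank$n + seq_len(bank$K), , drop = FALSE]
}

#' Cosine nearest-centroid pseudo-labels for target rows
#'
#' Assigns each target sample the class of the centroid minimizing
#' \eqn{1 - \cos(h, c_k)}; ties break to the lowest class index. Assignments
#' are deterministic, order-independent, and invariant to positive rescaling
#' of the features.
#'
#' @param bank A `memory_bank`.
#' @return The bank with target entries of `labels` replaced by fresh
#'   pseudo-labels; the labels vector itself is in attribute-free integer
#'   form.
#' @export
assign_pseudo_labels <- function(bank) {
  stopifnot(inherits(bank, "memory_bank"))
  Cn <- bank_centroids(bank)
  feats <- bank$B[seq_len(bank$n), , drop = FALSE]
  sim <- feats %*% t(Cn)        # rows unit norm, so this is cosine similarity
  lab <- max.col(sim, ties.method = "first")
  bank$labels[!bank$is_source] <- lab[!bank$is_source]
  bank
}

#' Refresh centroids from pooled true and pseudo labels
#'
#' Each centroid becomes the mean of the bank features currently carrying its
#' label (source true labels and target pseudo-labels pooled), re-normalized
#' to unit length before being written back into the centroid block. A class
#' with no members keeps its previous centroid and a warning is emitted
#' (`empty_policy = "keep"`, the default); `"reseed"` instead re-seeds the
#' centroid from the sample farthest from its assigned centroid.
#'
#' @param bank A `memory_bank` whose labels are all assigned.
#' @param empty_policy `"keep"` or `"reseed"`.
#' @return List with the updated `bank`, a `centroid_set` (`C` = normalized
#'   centroids, `counts` per class), invisibly consistent with the bank
#'   block.
#' @export
refresh_centroids <- function(bank, empty_policy = c("keep", "reseed")) {
  empty_policy <- match.arg(empty_policy)
  stopifnot(inherits(bank, "memory_bank"), !anyNA(bank$labels))
  feats <- bank$B[seq_len(bank$n), , drop = FALSE]
  counts <- tabulate(bank$labels, nbins = bank$K)
  Cn <- bank_centroids(bank)
  for (k in seq_len(bank$K)) {
    if (counts[k] > 0) {
      mk <- colMeans(feats[bank$labels == k, , drop = FALSE])
      Cn[k, ] <- mk / sqrt(sum(mk^2))
    } else if (empty_policy == "keep") {
      warning("class ", k, " has no members; keeping previous centroid.",
              call. = FALSE)
    } else {
      sim <- feats %*% t(bank_centroids(bank))
      far <- which.min(apply(sim, 1, max))
      Cn[k, ] <- feats[far, ]
      warning("class ", k, " empty; re-seeded from farthest sample.",
              call. = FALSE)
    }
  }
  bank$B[bank$n + seq_len(bank$K), ] <- Cn
  list(bank = bank,
       centroids = structure(list(C = Cn, counts = counts),
                             class = "centroid_set"))
}
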