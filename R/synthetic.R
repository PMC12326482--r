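#' Recipe for multi-subject synthetic feature data
#'
#' Describes a multi-subject, multi-session labeled feature dataset with the
#' statistical structure the domain-adaptation model assumes: per-class
#' Gaussian clusters (unit within-class standard deviation) around
#' simplex-spread class means, a subject-specific affine domain shift (random
#' rotation of a stated principal angle plus a random translation of stated
#' norm), an optional milder session shift, a fraction of far-field outlier
#' samples, and eta% source-label noise applied downstream by
#' [corrupt_labels()].
#'
#' The defaults are the package's reference study conditions: 3 classes in 20
#' dimensions, 150 samples per class per domain, a 15-degree rotation with a
#' translation of 1 noise-standard-deviation, and 5% outliers. The subject
#' rotation turns the feature baseline toward a random class-contrast
#' direction, so the induced mean shift lands on discriminative axes (the
#' inter-subject baseline drift that motivates robust alignment). The
#' class-mean separation (4.5) and baseline norm (9) are chosen once so that
#' a source-trained nearest-class-mean classifier lands mid-way between
#' chance and ceiling on the shifted target domain, leaving measurable
#' headroom for adaptation while keeping the target clusters recoverable.
#'
#' @param n_subjects,n_sessions Grid of recording units to simulate.
#' @param K,d,n_per_class Classes, feature dimension, samples per class per
#'   (subject, session).
#' @param separation Pairwise Euclidean distance between class means.
#' @param baseline Norm of a common offset added to every class mean
#'   (band-power-like features have a nonzero baseline; a domain rotation
#'   then induces a genuine mean shift between domains).
#' @param rotation_deg,translation Subject-shift magnitudes: principal angle
#'   in degrees of a random rotation, and norm of a random translation
#'   (units of the within-class standard deviation).
#' @param session_rotation_deg,session_translation Session-shift magnitudes
#'   (applied to sessions after the first).
#' @param outlier_fraction,outlier_scale Fraction of samples replaced by
#'   isotropic far-field draws of the given standard deviation.
#' @param label_noise_eta Source-label noise percentage (0-100); stored for
#'   the manifest, applied by [corrupt_labels()].
#' @param seed Integer seed; the generator is a pure function of
#'   (recipe, seed).
#' @param dataset_name Dataset tag carried into the output (for
#'   cross-database protocols).
#' @return Object of class `synth_recipe`.
#' @export
synth_recipe <- function(n_subjects = 2, n_sessions = 1, K = 3, d = 20,
                         n_per_class = 150, separation = 4.5, baseline = 9,
                         rotation_deg = 15, translation = 1.0,
                         session_rotation_deg = 5, session_translation = 0.3,
                         outlier_fraction = 0.05, outlier_scale = 8,
                         label_noise_eta = 0, seed = 7,
                         dataset_name = "A") {
  stopifnot(n_subjects >= 1, n_sessions >= 1, K >= 2, d >= K,
            n_per_class >= 1, separation > 0,
            outlier_fraction >= 0, outlier_fraction < 1,
            label_noise_eta >= 0, label_noise_eta <= 100)
  if (separation < 2)
    warning("class-mean separation below twice the noise scale; ",
            "classes will overlap heavily.", call. = FALSE)
  structure(as.list(environment()), class = "synth_recipe")
}

# rotation with every principal angle equal to theta; the first rotation
# plane can be pinned to given orthonormal directions (u1, u2), the rest of
# the frame is random
random_rotation <- function(d, theta, u1 = NULL, u2 = NULL) {
  B <- matrix(stats::rnorm(d * d), d)
  if (!is.null(u1)) B <- cbind(u1, u2, B[, seq_len(d - 2), drop = FALSE])
  Q <- qr.Q(qr(B))
  if (!is.null(u1)) {
    # keep the pinned directions' signs (QR may flip them)
    if (sum(Q[, 1] * u1) < 0) Q[, 1] <- -Q[, 1]
    if (sum(Q[, 2] * u2) < 0) Q[, 2] <- -Q[, 2]
  }
  G <- diag(d)
  for (j in seq_len(floor(d / 2))) {
    i1 <- 2 * j - 1; i2 <- 2 * j
    G[i1, i1] <- cos(theta); G[i2, i2] <- cos(theta)
    G[i1, i2] <- -sin(theta); G[i2, i1] <- sin(theta)
  }
  Q %*% G %*% t(Q)
}

random_translation <- function(d, norm) {
  v <- stats::rnorm(d)
  v / sqrt(sum(v^2)) * norm
}

# K simplex-spread class means with pairwise distance `separation` in R^d,
# displaced from the origin by a common baseline along the all-ones
# direction of the simplex coordinates (band-power-like features have a
# nonzero baseline living in the same subspace as the class contrasts)
class_means <- function(K, d, separation, baseline = 0) {
  E <- diag(K) * separation / sqrt(2)
  E <- sweep(E, 2, colMeans(E))
  E <- cbind(E, matrix(0, K, d - K))
  bdir <- c(rep(1, K), rep(0, d - K)) / sqrt(K)
  sweep(E, 2, baseline * bdir, "+")
}

#' Generate a synthetic multi-subject dataset
#'
#' Draws the dataset described by a [synth_recipe()]: for every (subject,
#' session), `n_per_class` Gaussian samples per class around the shifted
#' class means, with `outlier_fraction` of samples replaced by far-field
#' draws. Subject 1 / session 1 is the unshifted reference frame; every other
#' subject (session) receives its own random shift of the stated magnitude.
#' Identical recipe and seed reproduce identical bytes.
#'
#' @param recipe A [synth_recipe()].
#' @return A tibble with columns `dataset`, `subject`, `session`, `class`
#'   (integer 1..K), `is_outlier`, and features `x1..xd`; attribute
#'   `"manifest"` records the applied shifts.
#' @export
synth_generate <- function(recipe) {
  stopifnot(inherits(recipe, "synth_recipe"))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(recipe$seed)
  r <- recipe
  mu <- class_means(r$K, r$d, r$separation, r$baseline)
  blocks <- list(); manifest <- list()
  bi <- 0
  # baseline direction (common to all classes) and the class-contrast span:
  # the subject rotation's first plane turns the baseline toward a random
  # contrast direction, so the induced mean shift lands on discriminative
  # axes -- the inter-subject baseline drift the method is built to absorb
  bdir <- c(rep(1, r$K), rep(0, r$d - r$K)) / sqrt(r$K)
  for (su in seq_len(r$n_subjects)) {
    if (su == 1) {
      Rs <- diag(r$d); ts <- rep(0, r$d)
    } else {
      co <- stats::rnorm(r$K); co <- co - mean(co)
      w <- c(co, rep(0, r$d - r$K)); w <- w / sqrt(sum(w^2))
      Rs <- random_rotation(r$d, r$rotation_deg * pi / 180, bdir, w)
      ts <- random_translation(r$d, r$translation)
    }
    for (se in seq_len(r$n_sessions)) {
      if (se == 1) {
        Rse <- diag(r$d); tse <- rep(0, r$d)
      } else {
        Rse <- random_rotation(r$d, r$session_rotation_deg * pi / 180)
        tse <- random_translation(r$d, r$session_translation)
      }
      n <- r$K * r$n_per_class
      y <- rep(seq_len(r$K), each = r$n_per_class)
      X <- mu[y, , drop = FALSE] + matrix(stats::rnorm(n * r$d), n)
      X <- X %*% t(Rse %*% Rs)
      X <- sweep(X, 2, Rse %*% ts + tse, "+")
      is_out <- rep(FALSE, n)
      n_out <- round(r$outlier_fraction * n)
      if (n_out > 0) {
        idx <- sample.int(n, n_out)
        X[idx, ] <- matrix(stats::rnorm(n_out * r$d, sd = r$outlier_scale),
                           n_out)
        is_out[idx] <- TRUE
      }
      colnames(X) <- paste0("x", seq_len(r$d))
      bi <- bi + 1
      blocks[[bi]] <- tibble::tibble(dataset = r$dataset_name, subject = su,
                                     session = se, class = y,
                                     is_outlier = is_out,
                                     tibble::as_tibble(X))
      manifest[[bi]] <- tibble::tibble(dataset = r$dataset_name, subject = su,
                                       session = se,
                                       rotation_deg = if (su == 1) 0 else r$rotation_deg,
                                       translation = if (su == 1) 0 else r$translation,
                                       session_rotation_deg = if (se == 1) 0 else r$session_rotation_deg,
                                       session_translation = if (se == 1) 0 else r$session_translation)
    }
  }
  out <- dplyr::bind_rows(blocks)
  attr(out, "manifest") <- dplyr::bind_rows(manifest)
  attr(out, "recipe") <- recipe
  out
}

#' Source/target domain pair from the default two-subject recipe
#'
#' Convenience split of a two-subject [synth_generate()] draw: subject 1 is
#' the labeled source, subject 2 the unlabeled target; the target's true
#' labels are returned separately for evaluation only.
#'
#' @param recipe A [synth_recipe()] with `n_subjects >= 2`.
#' @return List with `source` (tibble incl. `class`), `target` (features
#'   only), `target_truth` (integer vector).
#' @export
synth_domain_pair <- function(recipe = synth_recipe()) {
  dat <- synth_generate(recipe)
  src <- dplyr::filter(dat, .data$subject == 1, .data$session == 1)
  tgt <- dplyr::filter(dat, .data$subject == 2, .data$session == 1)
  feats <- grep("^x\\d+$", names(dat), value = TRUE)
  list(source = dplyr::select(src, dplyr::all_of(c("class", feats))),
       target = dplyr::select(tgt, dplyr::all_of(feats)),
       target_truth = tgt$class)
}

#' Training configuration of the reference synthetic study
#'
#' The settings used throughout the package's bundled synthetic experiments:
#' a d-64-16-64-d tanh network (compact enough for the 20-dimensional
#' reference recipe), balanced minibatches of 64, 20 warm-up epochs, 120
#' epochs total, learning rate 1e-3, `lambda1 = lambda2 = 0.01`,
#' `lambda3 = 0.5`, and Euclidean nearest-centroid assignment (the natural
#' metric for low-dimensional standardized features; cosine, the default
#' elsewhere, is suited to unit-normalized high-dimensional deep features).
#'
#' @param seed Integer seed for initialization and batch order.
#' @param ... Overrides forwarded to [dadpc_config()].
#' @return A [dadpc_config()].
#' @export
synth_study_config <- function(seed = 1, ...) {
  args <- list(hidden_dims = c(64, 16, 64), batch_size = 64,
               max_epochs = 120, warmup_epochs = 20,
               lambda1 = 0.01, lambda2 = 0.01, lambda3 = 0.5,
               lr = 1e-3, seed = seed, distance = "euclidean")
  over <- list(...)
  args[names(over)] <- over
  do.call(dadpc_config, args)
}

#' Replace eta% of labels with random wrong labels
#'
#' Exactly `round(eta_percent/100 * n)` entries, chosen uniformly, are
#' replaced by a uniform draw over the *other* K-1 classes, so every
#' corrupted label is actually wrong and `eta_percent` is an effective noise
#' rate. Intended for source labels only; target labels are never touched by
#' the training pipeline.
#'
#' @param labels Integer labels in `1..K`.
#' @param eta_percent Noise percentage, 0-100.
#' @param K Number of classes (default `max(labels)`).
#' @param seed Integer seed.
#' @return Corrupted label vector.
#' @export
corrupt_labels <- function(labels, eta_percent, K = max(labels), seed = 1) {
  stopifnot(eta_percent >= 0, eta_percent <= 100, K >= 2)
  labels <- as.integer(labels)
  n_flip <- round(eta_percent / 100 * length(labels))
  if (n_flip == 0) return(labels)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  idx <- sample.int(length(labels), n_flip)
  labels[idx] <- vapply(labels[idx], function(y) {
    others <- setdiff(seq_len(K), y)
    others[sample.int(length(others), 1L)]
  }, integer(1))
  labels
}

#' Synthesize multichannel band-limited EEG-like noise
#'
#' Each channel is an independent sum of brick-wall band-limited Gaussian
#' noise components (frequency-domain synthesis) with exactly the requested
#' per-band sample variances, plus an optional broadband floor. Useful for
#' exercising the differential-entropy pipeline end to end with a known
#' ground truth: a band of variance v should recover
#' \eqn{\mathrm{DE} = \tfrac12\ln(2\pi e v)}.
#'
#' @param channels Number of channels.
#' @param fs Sampling rate in Hz.
#' @param duration_s Duration in seconds.
#' @param band_powers Named numeric vector/list of per-band variances, keyed
#'   by the names of `bands`.
#' @param seed Integer seed.
#' @param floor_power Variance of an added white-noise floor (default 0).
#' @param bands Band definitions, default [eeg_bands()].
#' @return Channels x time numeric matrix.
#' @export
synth_eeg <- function(channels, fs, duration_s, band_powers, seed = 1,
                      floor_power = 0, bands = eeg_bands()) {
  stopifnot(all(names(band_powers) %in% names(bands)))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  n <- floor(fs * duration_s)
  freqs <- (seq_len(n) - 1) * fs / n
  sym <- pmin(freqs, fs - freqs)      # two-sided frequency magnitude
  out <- matrix(0, channels, n)
  for (ch in seq_len(channels)) {
    sig <- rep(0, n)
    for (bn in names(band_powers)) {
      v <- band_powers[[bn]]
      if (v <= 0) next
      b <- bands[[bn]]
      keep <- sym >= b[1] & sym <= b[2]
      spec <- stats::fft(stats::rnorm(n))
      spec[!keep] <- 0
      comp <- Re(stats::fft(spec, inverse = TRUE)) / n
      comp <- comp * sqrt(v / stats::var(comp))
      sig <- sig + comp
    }
    if (floor_power > 0)
      sig <- sig + stats::rnorm(n, sd = sqrt(floor_power))
    out[ch, ] <- sig
  }
  out
}
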