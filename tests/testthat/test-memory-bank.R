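make_bank <- function() {
  H <- matrix(c(3, 4,
                0, 5,
                1, 0), ncol = 2, byrow = TRUE)
  C0 <- init_centroids(H[1:2, ], c(1, 2))
  init_bank(H, C0, labels = c(1, 2, NA), is_source = c(TRUE, TRUE, FALSE))
}

test_that("bank construction normalizes rows and is deterministic", {
  b <- make_bank()
  expect_equal(nrow(b$B), 3 + 2)
  expect_equal(sqrt(rowSums(b$B^2)), rep(1, 5))
  expect_equal(b$B[1, ], c(0.6, 0.8))
  expect_identical(make_bank(), b)
  H0 <- matrix(c(0, 0, 1, 1), 2, byrow = TRUE)
  expect_error(init_bank(H0, init_centroids(H0[2, , drop = FALSE], 1),
                         c(1, NA), c(TRUE, FALSE)), "zero-norm")
})

test_that("bank updates touch exactly the given rows, without momentum", {
  b <- make_bank()
  expect_identical(update_bank(b, matrix(0, 0, 2), integer(0)), b)
  b1 <- update_bank(b, matrix(c(0, 5), 1), 1)
  expect_equal(b1$B[1, ], c(0, 1))
  expect_equal(b1$B[2, ], b$B[2, ])
  expect_equal(update_bank(b1, matrix(c(0, 5), 1), 1), b1)
  expect_error(update_bank(b, matrix(1, 1, 2), 9), "out of range")
})

test_that("pseudo-labels are cosine nearest-centroid with scale invariance", {
  b <- make_bank()
  # centroid block is rows 4-5: classes at (0.6,0.8) and (0,1)
  b$B[4, ] <- c(1, 0); b$B[5, ] <- c(0, 1)
  b$B[3, ] <- c(0.9, 0.1) / sqrt(0.82)
  b <- assign_pseudo_labels(b)
  expect_equal(b$labels[3], 1L)
  expect_equal(b$labels[1:2], c(1L, 2L))  # source labels untouched
  b2 <- b; b2$B[3, ] <- b$B[3, ]          # positive rescale is a no-op after
  expect_equal(assign_pseudo_labels(b2)$labels, b$labels)
})

test_that("centroid refresh averages labeled features and conserves counts", {
  H <- matrix(c(1, 0,
                0, 1,
                0, 1), ncol = 2, byrow = TRUE)
  C0 <- init_centroids(H[c(1, 3), ], c(1, 2))
  b <- init_bank(H, C0, labels = c(1, 1, 2), is_source = c(TRUE, TRUE, FALSE))
  out <- refresh_centroids(b)
  expect_equal(out$centroids$C[1, ], c(sqrt(2) / 2, sqrt(2) / 2))
  expect_equal(out$centroids$C[2, ], c(0, 1))
  expect_equal(sum(out$centroids$counts), b$n)
  # empty class keeps previous centroid, with a warning
  b$labels <- c(1, 1, 1)
  expect_warning(out2 <- refresh_centroids(b), "no members")
  expect_equal(out2$centroids$C[2, ], dadpc:::bank_centroids(b)[2, ])
})

test_that("refresh/assign alternation settles on separated clusters", {
  set.seed(41)
  # three clusters with distinct directions (assignment is by cosine)
  mu <- matrix(c(10, 1, 1, 10, 7, 7), 3, byrow = TRUE)
  y <- rep(1:3, each = 30)
  H <- mu[y, ] + matrix(rnorm(180, sd = 0.4), 90)
  src <- y <= 0 # all target except a seed sample per class
  keep <- c(1, 31, 61)
  is_source <- seq_len(90) %in% keep
  C0 <- init_centroids(H[keep, , drop = FALSE], y[keep])
  b <- init_bank(H, C0, labels = ifelse(is_source, y, NA), is_source)
  b <- assign_pseudo_labels(b)
  changes <- integer(20)
  for (r in 1:20) {
    prev <- b$labels
    b <- refresh_centroids(b)$bank
    b <- assign_pseudo_labels(b)
    changes[r] <- sum(b$labels != prev)
  }
  expect_equal(changes[20], 0L)
  expect_true(all(diff(changes) <= 0) || sum(changes[10:20]) == 0)
  expect_equal(b$labels, y)
})
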