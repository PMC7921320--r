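cfg_fine <- decoding_config(window_ms = 200, sample_step_ms = 0.1)

test_that("exponential convolution has unit area and the right shape", {
  cfg <- decoding_config(window_ms = 100, sample_step_ms = 2)
  expect_equal(convolve_response(numeric(0), cfg), rep(0, 50))
  v <- convolve_response(0, cfg)
  expect_equal(which.max(v), 1L)
  grid <- seq(0, 98, by = 2)
  expect_equal(v, exp(-grid / 5) / 5, tolerance = 1e-12)
  # quadrature: integral ~ spike count on a fine grid
  v2 <- convolve_response(c(10, 50, 90.5), cfg_fine)
  expect_equal(sum(v2) * 0.1, 3, tolerance = 0.02)
  expect_warning(convolve_response(c(10, 250), cfg_fine), "Dropping")
})

test_that("train/test split is a stratified half/half partition", {
  labels <- rep(paste0("p", 1:8), each = 100)
  set.seed(1)
  sp <- split_train_test(labels)
  expect_equal(sort(c(sp$train, sp$test)), seq_along(labels))
  expect_equal(unname(table(labels[sp$train])), rep(50L, 8L),
               ignore_attr = TRUE)
  expect_equal(unname(table(labels[sp$test])), rep(50L, 8L),
               ignore_attr = TRUE)
  sp2 <- split_train_test(labels)
  expect_false(identical(sp, sp2))  # fresh randomness
  # odd counts differ by at most one
  set.seed(2)
  sp3 <- split_train_test(rep(c("a", "b"), each = 7))
  expect_equal(abs(length(sp3$train) - length(sp3$test)), 2L)
  expect_error(split_train_test(c("a", "a", "b")), "at least 2")
})

test_that("bootstrap sums have the right count, labels and expectation", {
  resp <- matrix(1:20, nrow = 10, ncol = 2)
  labels <- rep(c("a", "b"), each = 5)
  set.seed(1)
  bt <- bootstrap_responses(resp, labels, n_bootstrap = 50)
  expect_equal(nrow(bt$responses), 100L)
  expect_equal(bt$labels, rep(c("a", "b"), each = 50))
  # degenerate one-member group: every bootstrapped response equals it
  set.seed(2)
  one <- bootstrap_responses(resp[1, , drop = FALSE], "a", 10)
  expect_true(all(t(one$responses) == resp[1, ]))
  # expectation = N x group mean (Monte-Carlo over many resamples)
  set.seed(3)
  many <- bootstrap_responses(resp[1:5, , drop = FALSE], rep("a", 5), 4000)
  expect_equal(colMeans(many$responses), 5 * colMeans(resp[1:5, ]),
               tolerance = 0.02)
})

test_that("PCA retains the fewest components reaching the variance target", {
  set.seed(1)
  # data on a line plus tiny noise -> one component
  line <- outer(rnorm(100), c(1, 2, 3)) +
    matrix(rnorm(300, sd = 1e-4), 100)
  expect_equal(fit_response_pca(line, 0.95)$n_components, 1L)
  # isotropic Gaussian: components needed ~ 0.95 * d
  iso <- matrix(rnorm(4000 * 40), 4000)
  n_iso <- fit_response_pca(iso, 0.95)$n_components
  expect_gt(n_iso, 33)
  expect_lte(n_iso, 39)
  # retained fraction reaches the target by construction
  p <- fit_response_pca(iso, 0.95)
  expect_gte(sum(p$variance_fraction), 0.95)
  # zero-variance data are flagged
  z <- fit_response_pca(matrix(1, 10, 5), 0.95)
  expect_true(z$zero_variance)
  expect_equal(z$n_components, 1L)
})

test_that("projection equals generic least squares on the component basis", {
  set.seed(2)
  X <- matrix(rnorm(50 * 20), 50)
  pca <- fit_response_pca(X, 0.9)
  # projecting the stored mean gives the zero vector
  expect_equal(as.numeric(project_responses(rbind(pca$center), pca)),
               rep(0, pca$n_components), tolerance = 1e-10)
  # projecting a basis vector (offset by the mean) gives a unit coordinate
  e1 <- pca$center + pca$rotation[, 1]
  coord <- as.numeric(project_responses(rbind(e1), pca))
  expect_equal(coord, c(1, rep(0, pca$n_components - 1)), tolerance = 1e-10)
  # generic least-squares oracle: lm.fit on the basis columns
  y <- rnorm(20)
  ls <- stats::lm.fit(pca$rotation, y - pca$center)$coefficients
  expect_equal(as.numeric(project_responses(rbind(y), pca)),
               unname(ls), tolerance = 1e-10)
  expect_error(project_responses(matrix(0, 1, 3), pca), "length")
})

test_that("kNN majority vote and tie-breaks match hand enumeration", {
  # all nine neighbours of class A
  train <- cbind(c(rep(0, 9), rep(10, 9)), 0)
  lab <- rep(c("A", "B"), each = 9)
  expect_equal(knn_classify(cbind(0.1, 0), train, lab, k = 9), "A")
  # constructed 4-4-1 tie at k = 9: A nearer in summed distance
  tr <- rbind(cbind(1 + 0.1 * (0:3), 0),     # four A at x ~ 1
              cbind(2 + 0.1 * (0:3), 0),     # four B at x ~ 2
              c(5, 0))                       # one C far away
  lb <- c(rep("A", 4), rep("B", 4), "C")
  expect_equal(knn_classify(cbind(0, 0), tr, lb, k = 9), "A")
  # mirrored: B nearer
  expect_equal(knn_classify(cbind(3.3, 0), tr, lb, k = 9), "B")
  # permuting training order does not change predictions
  set.seed(4)
  trn <- matrix(rnorm(40), 20)
  lbl <- rep(c("A", "B"), 10)
  tst <- matrix(rnorm(10), 5)
  p1 <- knn_classify(tst, trn, lbl, k = 5)
  ord <- sample(20)
  p2 <- knn_classify(tst, trn[ord, ], lbl[ord], k = 5)
  expect_equal(p1, p2)
  expect_error(knn_classify(tst, trn, lbl, k = 21), "smaller")
})

test_that("precision, recall and F1 follow the confusion-matrix definitions", {
  expect_equal(f1_from_confusion(diag(8))$f1_score, 1)
  u <- f1_from_confusion(matrix(1, 8, 8))
  expect_equal(u$f1_score, 0.125)
  expect_equal(unname(u$precision), rep(0.125, 8))
  # diag 6, off-diagonal 2 (row sum 20): precision = recall = F1 = 0.3
  m <- matrix(2, 8, 8); diag(m) <- 6
  r <- f1_from_confusion(m)
  expect_equal(unname(r$precision), rep(0.3, 8))
  expect_equal(unname(r$recall), rep(0.3, 8))
  expect_equal(r$f1_score, 0.3)
  # a class never predicted gets precision 0 by convention
  m2 <- matrix(0, 3, 3); m2[1, 2] <- 5; m2[2, 2] <- 5; m2[3, 3] <- 5
  r2 <- f1_from_confusion(m2)
  expect_equal(unname(r2$precision[1]), 0)
  expect_error(f1_from_confusion(matrix(0, 8, 8)), "zero")
  # macro F1 is invariant under simultaneous row/column permutation
  set.seed(5)
  cm <- matrix(rpois(64, 4), 8)
  perm <- sample(8)
  expect_equal(f1_from_confusion(cm[perm, perm])$f1_score,
               f1_from_confusion(cm)$f1_score)
})

test_that("the decoder threshold is the shuffled mean plus two SDs", {
  pop <- c(0.1157, 0.1242, 0.1327)   # mean 0.1242, sd 0.0085
  expect_equal(decoder_threshold(pop), 0.1412, tolerance = 1e-4)
  expect_equal(decoder_threshold(rep(0.2, 5)), 0.2)
  base <- decoder_threshold(c(0.12, 0.125, 0.13))
  expect_gt(decoder_threshold(c(0.12, 0.125, 0.13, 0.2)), base)
  expect_error(decoder_threshold(0.125), "at least 2")
})
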