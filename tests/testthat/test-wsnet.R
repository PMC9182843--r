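test_that("global average pooling is the per-channel location mean", {
  expect_equal(global_average_pool(matrix(3, 7, 4)), rep(3, 4))
  expect_equal(global_average_pool(matrix(c(1, 5, 3, 7), 2)), c(3, 5))
  set.seed(13)
  fm <- matrix(rnorm(21 * 128), 21)
  loop <- vapply(seq_len(128), function(k) {
    s <- 0
    for (i in 1:21) s <- s + fm[i, k]
    s / 21
  }, numeric(1))
  expect_equal(global_average_pool(fm), loop, tolerance = 1e-12)
  expect_error(global_average_pool(matrix(0, 0, 4)),
               class = "wsgait_shape_error")
})

test_that("localized scores are per-location classifier dot products", {
  set.seed(14)
  fm <- matrix(rnorm(5 * 4), 5)
  expect_equal(localized_scores(fm, matrix(1, 4, 1))[, 1], rowSums(fm))
  expect_equal(localized_scores(matrix(0, 5, 4), matrix(rnorm(12), 4)),
               matrix(0, 5, 3))
  Wc <- matrix(rnorm(4 * 3), 4)
  loop <- matrix(0, 5, 3)
  for (i in 1:5) for (cl in 1:3) loop[i, cl] <- sum(fm[i, ] * Wc[, cl])
  expect_equal(localized_scores(fm, Wc), loop)
  expect_error(localized_scores(fm, matrix(0, 5, 3)),
               class = "wsgait_shape_error")
})

test_that("coincident class means give zero Fisher weights", {
  set.seed(15)
  base <- matrix(rnorm(40 * 3), 40)
  scores <- rbind(base, base)  # class 2 is an exact copy: identical means
  labels <- rep(1:2, each = 40)
  fw <- fisher_weights(scores, labels)
  expect_equal(fw$lambda, numeric(1), tolerance = 1e-10)
})

test_that("zero within-class variance falls back to the documented ridge", {
  scores <- matrix(c(0, 0, 2, 2), ncol = 1)
  labels <- c(1, 1, 2, 2)
  expect_warning(fw <- fisher_weights(scores, labels, n_prime = 1),
                 class = "wsgait_ridge_applied")
  # scalar brute force: Sb = (0-1)^2 + (2-1)^2 = 2, Sw = 0 ridged to 1e-6
  expect_equal(fw$lambda, 2 / 1e-6, tolerance = 1e-8)
})

test_that("Fisher weights match an independent whitened eigensolve", {
  set.seed(16)
  for (rep_ in 1:25) {
    K <- sample(2:5, 1)
    d <- sample(2:6, 1)
    prob <- random_fisher_problem(K, d, n_per_class = 30)
    np <- min(K - 1, d)  # rank bound of the between-class scatter
    fw <- fisher_weights(prob$scores, prob$labels, n_prime = np)
    st <- naive_scatter(prob$scores, prob$labels)
    want <- whitened_fisher_eigenvalues(st$Sw, st$Sb)[seq_len(np)]
    expect_equal(fw$lambda, pmax(want, 0), tolerance = 1e-8)
    # eigenvector property: Sb v = lambda Sw v for the leading pair
    v <- fw$projection[, 1]
    expect_equal(st$Sb %*% v, fw$lambda[1] * st$Sw %*% v, tolerance = 1e-6)
  }
})

test_that("Fisher weights are invariant under invertible reparameterization", {
  set.seed(17)
  for (rep_ in 1:10) {
    prob <- random_fisher_problem(2, 4, n_per_class = 40)
    A <- matrix(rnorm(16), 4)
    while (abs(det(A)) < 0.1) A <- matrix(rnorm(16), 4)
    f1 <- fisher_weights(prob$scores, prob$labels, n_prime = 1)
    f2 <- fisher_weights(prob$scores %*% A, prob$labels, n_prime = 1)
    expect_equal(f1$lambda, f2$lambda, tolerance = 1e-6)
  }
})

test_that("pushing class means apart never decreases the top weight", {
  set.seed(18)
  noise <- matrix(rnorm(60 * 3), 60)
  labels <- rep(1:2, each = 30)
  lam <- vapply(c(0.5, 1.5, 3), function(sep) {
    scores <- noise
    scores[labels == 2, 1] <- scores[labels == 2, 1] + sep
    fisher_weights(scores, labels, n_prime = 1)$lambda[1]
  }, numeric(1))
  expect_true(all(diff(lam) > 0))
})

test_that("single-class input warns and returns zero weights", {
  set.seed(19)
  expect_warning(
    fw <- fisher_weights(matrix(rnorm(20), 10), rep(1, 10), n_prime = 1),
    class = "wsgait_degenerate_input")
  expect_equal(fw$lambda, 0)
})

test_that("reweighting scales projected components by normalized weights", {
  V <- diag(3)[, 1:2]
  gap <- c(1, 2, 3)
  unit <- wsgait:::new_fisher_weights(c(1, 1), V)
  expect_equal(reweight_features(gap, unit), c(1, 2))
  kill <- wsgait:::new_fisher_weights(c(1, 0), V)
  expect_equal(reweight_features(gap, kill), c(1, 0))
  set.seed(20)
  lam <- sort(abs(rnorm(2)), decreasing = TRUE)
  fw <- wsgait:::new_fisher_weights(lam, V)
  out <- reweight_features(gap, fw)
  plain <- drop(crossprod(V, gap))
  expect_lte(sqrt(sum(out^2)), sqrt(sum(plain^2)) + 1e-12)
  zero <- wsgait:::new_fisher_weights(c(0, 0), V)
  expect_warning(z <- reweight_features(gap, zero),
                 class = "wsgait_degenerate_input")
  expect_equal(z, c(0, 0))
})

test_that("fusion is the sum of per-scale linear maps", {
  v <- c(1, 2, 3)
  expect_equal(fuse_features(list(v), list(diag(3))), v)
  expect_equal(fuse_features(list(v, v), list(diag(3), diag(3))), 2 * v)
  expect_equal(fuse_features(list(v, v), list(matrix(0, 3, 3),
                                              matrix(0, 3, 3))),
               rep(0, 3))
  expect_error(fuse_features(list(v), list(matrix(0, 2, 4))),
               class = "wsgait_shape_error")
})

test_that("softmax classification is stable and exact", {
  K <- 4
  expect_equal(classify(numeric(3), matrix(0, 3, K), numeric(K)),
               rep(1 / K, K))
  big <- classify(c(1), matrix(c(1000, 0, 0), 1), numeric(3))
  expect_equal(big, c(1, 0, 0), tolerance = 1e-12)
  set.seed(21)
  W <- matrix(rnorm(12), 3); b <- rnorm(4); v <- rnorm(3)
  z <- drop(crossprod(W, v)) + b
  expect_equal(classify(v, W, b), exp(z) / sum(exp(z)), tolerance = 1e-12)
  expect_equal(sum(classify(v, W, b)), 1, tolerance = 1e-9)
})
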