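test_that("rank-k identification handles exact and exhaustive cases", {
  scores <- diag(4)[c(1, 2, 3, 4), ]
  expect_equal(rank_k_identification(scores, 1:4, k = 1), 100)
  set.seed(25)
  rand <- matrix(rnorm(40), 10, 4)
  expect_equal(rank_k_identification(rand, sample(4, 10, TRUE), k = 4), 100)
  expect_error(rank_k_identification(rand, sample(4, 10, TRUE), k = 5),
               class = "wsgait_invalid_argument")
})

test_that("rank-1 on uniform random scores sits at the chance level", {
  set.seed(26)
  n <- 1e5
  scores <- matrix(runif(n * 10), n, 10)
  labels <- sample(10, n, replace = TRUE)
  ir <- rank_k_identification(scores, labels, k = 1)
  expect_equal(ir, 10, tolerance = 0.05)  # 10% +/- 0.5 points
})

test_that("identification rate is non-decreasing in the rank depth", {
  set.seed(27)
  scores <- matrix(rnorm(200 * 8), 200)
  labels <- sample(8, 200, TRUE)
  ir <- vapply(1:8, function(k) rank_k_identification(scores, labels, k),
               numeric(1))
  expect_true(all(diff(ir) >= 0))
  expect_equal(ir[8], 100)
})

test_that("ties in scores resolve toward the lowest class index", {
  scores <- matrix(1, 2, 3)
  # probe 1: class 1 wins its tie; probe 2: class 2 loses the tie to class 1
  expect_equal(rank_k_identification(scores, c(1, 2), k = 1), 50)
})

test_that("cosine verification scores hit their geometric anchors", {
  a <- c(1, 0, 0)
  expect_equal(verification_scores(a, a), 1)
  expect_equal(verification_scores(a, c(0, 1, 0)), 0)
  expect_equal(verification_scores(a, -a), -1)
  expect_warning(z <- verification_scores(a, c(0, 0, 0)),
                 class = "wsgait_degenerate_input")
  expect_equal(z, 0)
})

test_that("ROC endpoints and monotonicity hold", {
  set.seed(28)
  genuine <- runif(50, 0.8, 1)
  impostor <- runif(50, 0, 0.2)
  roc <- roc_curve(genuine, impostor)
  expect_true(any(roc$far == 0 & roc$tar == 1))  # perfect separation
  expect_equal(roc$far[nrow(roc)], 1)
  expect_equal(roc$tar[nrow(roc)], 1)            # accept-all endpoint
  expect_true(all(diff(roc$far) >= 0))
  expect_true(all(diff(roc$tar) >= 0))
})

test_that("identical score distributions trace the chance diagonal", {
  set.seed(29)
  genuine <- rnorm(5000)
  impostor <- rnorm(5000)
  roc <- roc_curve(genuine, impostor)
  mid <- dplyr::filter(roc, .data$far > 0.05, .data$far < 0.95)
  expect_lt(max(abs(mid$tar - mid$far)), 0.02)
})

test_that("ROC operating points agree with an independent implementation", {
  set.seed(30)
  genuine <- rnorm(300, mean = 1)
  impostor <- rnorm(300)
  roc <- roc_curve(genuine, impostor)
  pr <- pROC::roc(response = c(rep(1, 300), rep(0, 300)),
                  predictor = c(genuine, impostor), quiet = TRUE,
                  direction = "<")
  co <- pROC::coords(pr, x = "all", ret = c("specificity", "sensitivity"))
  want <- tibble::tibble(far = 1 - co$specificity, tar = co$sensitivity)
  want <- dplyr::arrange(want, .data$far, .data$tar)
  got <- dplyr::arrange(dplyr::distinct(roc[, c("far", "tar")]),
                        .data$far, .data$tar)
  # pROC sweeps midpoints between scores; the operating points coincide
  expect_equal(nrow(got), nrow(want))
  expect_equal(got$far, want$far, tolerance = 1e-12)
  expect_equal(got$tar, want$tar, tolerance = 1e-12)
})

test_that("the precision TAR variant is available", {
  genuine <- c(0.9, 0.8)
  impostor <- c(0.1, 0.85)
  roc_pr <- roc_curve(genuine, impostor, tar = "precision")
  # at threshold 0.85: TP = 1, FP = 1 -> precision 0.5
  row <- roc_pr[roc_pr$threshold == 0.85, ]
  expect_equal(row$tar, 0.5)
})

test_that("VR at a FAR target interpolates and handles degenerate curves", {
  set.seed(31)
  genuine <- runif(100, 0.8, 1)
  impostor <- runif(100, 0, 0.2)
  roc <- roc_curve(genuine, impostor)
  expect_equal(vr_at_far(roc, 1e-3), 1)
  degenerate <- tibble::tibble(threshold = -Inf, far = 1, tar = 1)
  expect_warning(v <- vr_at_far(degenerate, 1e-3),
                 class = "wsgait_degenerate_input")
  expect_equal(v, 1)
})

test_that("chance-level scores give VR approximately equal to the FAR", {
  set.seed(32)
  genuine <- runif(20000)
  impostor <- runif(20000)
  roc <- roc_curve(genuine, impostor)
  expect_equal(vr_at_far(roc, 1e-3), 1e-3, tolerance = 2)  # within 3e-3
  expect_equal(vr_at_far(roc, 0.1), 0.1, tolerance = 0.05)
})
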