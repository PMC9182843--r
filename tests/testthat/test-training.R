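test_that("cross-entropy matches its closed forms and a loop oracle", {
  expect_lt(cross_entropy(c(1, 0, 0), c(1, 0, 0)), 1e-6)
  expect_equal(cross_entropy(c(0.5, 0.5), c(1, 0)), log(2))
  set.seed(22)
  o <- matrix(runif(8 * 5, 0.05, 1), 8)
  o <- o / rowSums(o)
  y <- matrix(0, 8, 5)
  y[cbind(1:8, sample(5, 8, TRUE))] <- 1
  loop <- 0
  for (i in 1:8) {
    for (k in 1:5) loop <- loop - y[i, k] * log(o[i, k])
  }
  expect_equal(cross_entropy(o, y), loop / 8, tolerance = 1e-10)
  expect_error(cross_entropy(c(0.5, 0.5), c(1, 0, 0)),
               class = "wsgait_shape_error")
})

test_that("local loss is the weighted sum of per-scale losses", {
  y <- c(1, 0, 0)
  perfect <- list(c(1, 0, 0), c(1, 0, 0))
  expect_lt(local_loss(perfect, y), 1e-6)
  preds <- list(c(0.5, 0.25, 0.25), c(0.2, 0.4, 0.4))
  expect_equal(local_loss(preds, y, alpha_i = c(1, 0)),
               cross_entropy(preds[[1]], y))
  set.seed(23)
  a <- runif(2)
  expect_equal(local_loss(preds, y, alpha_i = a),
               a[1] * cross_entropy(preds[[1]], y) +
                 a[2] * cross_entropy(preds[[2]], y), tolerance = 1e-12)
  expect_error(local_loss(preds, y, alpha_i = c(1, 1, 1)),
               class = "wsgait_invalid_argument")
})

test_that("the composite loss combines components with alpha and beta", {
  expect_equal(overall_loss(1, 1, 0.99, 0.87), 1.86)
  expect_equal(overall_loss(0, 0, 0.5, 0.5), 0)
  expect_equal(overall_loss(2, 3, 0.5, 0.5), 2.5)
  expect_error(overall_loss(-1, 0), class = "wsgait_invalid_argument")
})

test_that("backprop gradients match finite differences on a tiny model", {
  ws <- asNamespace("wsgait")
  ds <- tiny_dataset(3, 4, length = 128, noise_sd = 0.05, seed = 5)
  spec <- ws$resolve_spec(
    wmscnn_spec(scales = c(2, 3), input_length = 128, fused_dim = 8,
                backbone = backbone_config(dropout_rate = 0, l2 = 0),
                fusion_dropout = 0), n_classes = 3)
  init <- ws$wmscnn_init(spec, seed = 7)
  params <- init$params
  sig <- lapply(ds$signals, l2_normalize)
  stacks <- ws$stack_scales(sig, spec$scales)
  lens <- stats::setNames(as.list(128 %/% spec$scales),
                          ws$scale_key(spec$scales))
  idx <- seq_along(sig)
  fisher <- ws$wmscnn_forward(spec, params, init$fisher, stacks, lens, idx,
                              ds$labels, training = TRUE,
                              update_fisher = TRUE)$fisher
  lossfn <- function(p) {
    ws$wmscnn_forward(spec, p, fisher, stacks, lens, idx, ds$labels,
                      training = FALSE)$overall_loss
  }
  fwd <- ws$wmscnn_forward(spec, params, fisher, stacks, lens, idx,
                           ds$labels, training = TRUE, update_fisher = FALSE)
  grads <- ws$wmscnn_backward(spec, params, fwd)
  set.seed(24)
  for (nm in c("tau2.fuse.W", "fc.W", "tau3.head.W", "tau2.Conv1_1.W",
               "tau3.Conv2_2.W")) {
    i <- sample(length(params[[nm]]), 1)
    eps <- 1e-5
    p_up <- params; p_up[[nm]][i] <- p_up[[nm]][i] + eps
    p_dn <- params; p_dn[[nm]][i] <- p_dn[[nm]][i] - eps
    numeric_grad <- (lossfn(p_up) - lossfn(p_dn)) / (2 * eps)
    expect_equal(grads[[nm]][i], numeric_grad, tolerance = 1e-4)
  }
})

test_that("training separable data drives the local loss down and fits", {
  ds <- simulate_gait(5, 40, length = 200, noise_sd = 0, seed = 31)
  fit <- fit_wmscnn(ds, wmscnn_spec(scales = 2:5),
                    train_config(max_epochs = 150, patience = 150,
                                 seed = 31))
  # eval-mode local loss on the training windows (dropout off)
  ws <- asNamespace("wsgait")
  sig <- lapply(ds$signals, l2_normalize)
  stacks <- ws$stack_scales(sig, fit$spec$scales)
  lens <- stats::setNames(as.list(fit$spec$input_length %/% fit$spec$scales),
                          ws$scale_key(fit$spec$scales))
  fwd <- ws$wmscnn_forward(fit$spec, fit$params, fit$fisher, stacks, lens,
                           seq_along(sig), ds$labels, training = FALSE)
  expect_lt(fwd$local_loss, 0.1)
  scores <- predict(fit, ds, type = "prob")
  expect_equal(rank_k_identification(scores, ds$labels, k = 1), 100)
})

test_that("training is deterministic under a fixed seed", {
  ds <- tiny_dataset(3, 6, length = 128, seed = 9)
  run <- function() {
    fit <- fit_wmscnn(ds, wmscnn_spec(scales = c(2, 3), fused_dim = 16),
                      train_config(max_epochs = 3, patience = 3,
                                   batch_size = 8, seed = 2))
    fit$history$overall_loss
  }
  expect_equal(run(), run(), tolerance = 1e-6)
})

test_that("history bookkeeping and early-stopping state are consistent", {
  ds <- tiny_dataset(3, 6, length = 128, seed = 9)
  fit <- fit_wmscnn(ds, wmscnn_spec(scales = c(2, 3), fused_dim = 16),
                    train_config(max_epochs = 1, patience = 5, seed = 2))
  expect_equal(nrow(fit$history), 1L)
  fit5 <- fit_wmscnn(ds, wmscnn_spec(scales = c(2, 3), fused_dim = 16),
                     train_config(max_epochs = 5, patience = 5, seed = 2))
  # the checkpointed epoch attains the running-minimum validation loss
  expect_equal(fit5$history$val_loss[fit5$best_epoch],
               min(fit5$history$val_loss))
  expect_true(all(cummin(fit5$history$val_loss)[fit5$best_epoch] ==
                    min(fit5$history$val_loss)))
})

test_that("the Fisher-ablated variant trains with identical shapes", {
  ds <- tiny_dataset(3, 6, length = 128, seed = 9)
  full <- fit_wmscnn(ds, wmscnn_spec(scales = c(2, 3), fused_dim = 16),
                     train_config(max_epochs = 2, patience = 2, seed = 2))
  ablated <- fit_wmscnn(ds, wmscnn_spec(scales = c(2, 3), fused_dim = 16,
                                        ws = FALSE),
                        train_config(max_epochs = 2, patience = 2, seed = 2))
  pf <- predict(full, ds, type = "prob")
  pa <- predict(ablated, ds, type = "prob")
  expect_equal(dim(pf), dim(pa))
  ef <- predict(full, ds, type = "embedding")
  ea <- predict(ablated, ds, type = "embedding")
  expect_equal(dim(ef), dim(ea))
})

test_that("a class missing from the training data is reported upfront", {
  ds <- tiny_dataset(3, 6, length = 128, seed = 9)
  ds$labels[ds$labels == 2L] <- 3L
  expect_error(fit_wmscnn(ds, wmscnn_spec(scales = c(2, 3))),
               class = "wsgait_invalid_argument")
})
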