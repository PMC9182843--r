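# Losses and the end-to-end training loop.

#' Categorical cross-entropy
#'
#' `-sum(o_hat * log(o))`, averaged over the batch when matrices (one sample
#' per row) are given. Probabilities are clipped to `[1e-7, 1]` before the
#' logarithm.
#'
#' @param o Predicted probability vector, or matrix with one sample per row.
#' @param o_hat True (one-hot) vector or matrix of matching shape.
#' @return Non-negative scalar loss.
#' @export
#' @examples
#' cross_entropy(c(0.5, 0.5), c(1, 0))  # log(2)
cross_entropy <- function(o, o_hat) {
  if (is.matrix(o) != is.matrix(o_hat) ||
      (is.matrix(o) && !all(dim(o) == dim(o_hat))) ||
      (!is.matrix(o) && length(o) != length(o_hat))) {
    stop_shape("`o` and `o_hat` must have identical shapes")
  }
  oc <- pmax(o, 1e-7)
  if (is.matrix(o)) mean(-rowSums(o_hat * log(oc)))
  else -sum(o_hat * log(oc))
}

#' Weighted sum of per-scale classification losses
#'
#' @param per_scale_preds List of per-scale probability vectors (or matrices,
#'   one sample per row).
#' @param labels One-hot vector/matrix of true labels shared by all scales.
#' @param alpha_i Per-scale weights, one per prediction (default uniform
#'   `1/s`).
#' @return Scalar weighted loss.
#' @export
local_loss <- function(per_scale_preds, labels, alpha_i = NULL) {
  s <- length(per_scale_preds)
  if (is.null(alpha_i)) alpha_i <- rep(1 / s, s)
  if (length(alpha_i) != s) {
    stop_invalid("%d scale weights supplied for %d predictions",
                 length(alpha_i), s)
  }
  sum(vapply(seq_len(s), function(i) {
    alpha_i[i] * cross_entropy(per_scale_preds[[i]], labels)
  }, numeric(1)))
}

#' Composite training loss
#'
#' `alpha * local + beta * global` with the tuned weighting factors
#' `alpha = 0.99`, `beta = 0.87` as defaults.
#'
#' @param local Local (per-scale) loss component.
#' @param global_ Global classifier loss component.
#' @param alpha,beta Non-negative weighting factors.
#' @return Scalar overall loss.
#' @export
#' @examples
#' overall_loss(1, 1)  # 1.86
overall_loss <- function(local, global_, alpha = 0.99, beta = 0.87) {
  if (local < 0 || global_ < 0) stop_invalid("losses must be >= 0")
  alpha * local + beta * global_
}

#' Training control parameters
#'
#' Defaults follow the reference training recipe: Adam at learning rate
#' 0.001, batch size 32, up to 200 epochs with early stopping after 50 epochs
#' without validation improvement, loss weights `alpha = 0.99`,
#' `beta = 0.87`.
#'
#' @param learning_rate Adam learning rate.
#' @param batch_size Windows per batch.
#' @param max_epochs Epoch cap.
#' @param patience Early-stopping patience in epochs (on validation loss).
#' @param alpha,beta Overall-loss weighting factors.
#' @param alpha_i Per-scale local-loss weights (default uniform).
#' @param val_fraction Fraction of the training data held out (stratified)
#'   for the early-stopping monitor.
#' @param fisher_momentum Exponential-average momentum for the per-batch
#'   Fisher scatter statistics.
#' @param seed Integer seed controlling the split, shuffling, initialization
#'   and dropout.
#' @return A `train_config` list.
#' @export
train_config <- function(learning_rate = 0.001, batch_size = 32,
                         max_epochs = 200, patience = 50, alpha = 0.99,
                         beta = 0.87, alpha_i = NULL, val_fraction = 0.1,
                         fisher_momentum = 0.9, seed = 1) {
  stopifnot(learning_rate > 0, alpha > 0, alpha <= 1, beta > 0, beta <= 1,
            val_fraction >= 0, val_fraction < 1)
  structure(list(learning_rate = learning_rate,
                 batch_size = assert_count(batch_size, "batch_size"),
                 max_epochs = assert_count(max_epochs, "max_epochs"),
                 patience = assert_count(patience, "patience"),
                 alpha = alpha, beta = beta, alpha_i = alpha_i,
                 val_fraction = val_fraction,
                 fisher_momentum = fisher_momentum,
                 seed = assert_count(seed, "seed", min = 0L)),
            class = "train_config")
}

# Stratified validation split: per class, ceil(val_fraction * n) windows
# (never all of them) go to validation.
stratified_split <- function(labels, val_fraction) {
  val <- integer(0)
  for (cl in sort(unique(labels))) {
    ids <- which(labels == cl)
    n_val <- min(length(ids) - 1L, ceiling(val_fraction * length(ids)))
    if (n_val > 0L) val <- c(val, sample(ids, n_val))
  }
  sort(val)
}

#' Fit the weighted multi-scale gait network
#'
#' End-to-end training: windows are L2-normalized per sensor triple,
#' block-averaged at each configured scale, and all per-scale backbones,
#' heads, the fusion layer and the global classifier are optimized jointly by
#' Adam on shuffled batches under the composite loss. Fisher scatter
#' statistics are refreshed every batch (exponential average) and the
#' resulting eigenweights modulate the per-scale features; they are not
#' trained by backprop. Early stopping monitors a stratified validation
#' split; the best-validation weights are returned.
#'
#' @param data A `gait_dataset` (or list with `signals` and `labels`).
#' @param model A [wmscnn_spec()].
#' @param control A [train_config()].
#' @param normalize L2-normalize windows before training (default `TRUE`).
#' @param verbose Print per-epoch progress.
#' @return A `wmscnn_fit` with elements `spec`, `params`, `fisher`,
#'   `history` (tibble), `control`.
#' @export
fit_wmscnn <- function(data, model = wmscnn_spec(), control = train_config(),
                       normalize = TRUE, verbose = FALSE) {
  signals <- data$signals
  labels <- as.integer(data$labels)
  n <- length(signals)
  stopifnot(n == length(labels), n > 0)
  classes <- sort(unique(labels))
  spec <- resolve_spec(model, n_classes = max(labels),
                       input_length = nrow(signals[[1L]]))
  if (length(classes) < 2L) stop_invalid("need at least 2 classes to train")
  if (!setequal(classes, seq_len(spec$n_classes))) {
    stop_invalid("labels must cover 1..n_classes; classes %s are absent",
                 paste(setdiff(seq_len(spec$n_classes), classes),
                       collapse = ","))
  }
  if (normalize) signals <- lapply(signals, l2_normalize)

  set.seed(control$seed)
  val_idx <- stratified_split(labels, control$val_fraction)
  tr_idx <- setdiff(seq_len(n), val_idx)
  missing_cl <- setdiff(classes, unique(labels[tr_idx]))
  if (length(missing_cl)) {
    stop_invalid("classes %s absent from the training split",
                 paste(missing_cl, collapse = ","))
  }

  stacks <- stack_scales(signals, spec$scales)
  lengths <- lapply(spec$scales, function(tau) spec$input_length %/% tau)
  names(lengths) <- scale_key(spec$scales)

  init <- wmscnn_init(spec, seed = control$seed)
  params <- init$params
  fisher <- init$fisher
  opt <- adam_init(params)
  s <- length(spec$scales)
  alpha_i <- control$alpha_i %||% rep(1 / s, s)

  best <- list(val = Inf, params = params, fisher = fisher, epoch = 0L)
  hist <- vector("list", control$max_epochs)
  stall <- 0L
  for (epoch in seq_len(control$max_epochs)) {
    order_ <- sample(tr_idx)
    n_batches <- ceiling(length(order_) / control$batch_size)
    ep_local <- ep_global <- ep_overall <- 0
    for (bi in seq_len(n_batches)) {
      from <- (bi - 1L) * control$batch_size + 1L
      idx <- order_[from:min(bi * control$batch_size, length(order_))]
      fwd <- wmscnn_forward(spec, params, fisher, stacks, lengths, idx,
                            labels = labels[idx], training = TRUE,
                            alpha = control$alpha, beta = control$beta,
                            alpha_i = alpha_i, update_fisher = TRUE,
                            fisher_momentum = control$fisher_momentum)
      fisher <- fwd$fisher
      grads <- wmscnn_backward(spec, params, fwd)
      st <- adam_step(params, grads, opt, lr = control$learning_rate)
      params <- st$params
      opt <- st$state
      w <- length(idx) / length(order_)
      ep_local <- ep_local + w * fwd$local_loss
      ep_global <- ep_global + w * fwd$global_loss
      ep_overall <- ep_overall + w * fwd$overall_loss
    }
    if (length(val_idx)) {
      vfwd <- wmscnn_forward(spec, params, fisher, stacks, lengths, val_idx,
                             labels = labels[val_idx], training = FALSE,
                             alpha = control$alpha, beta = control$beta,
                             alpha_i = alpha_i)
      val_loss <- vfwd$overall_loss
      val_acc <- mean(max.col(vfwd$probs, ties.method = "first") ==
                        labels[val_idx])
    } else {
      val_loss <- ep_overall
      val_acc <- NA_real_
    }
    hist[[epoch]] <- tibble::tibble(epoch = epoch, local_loss = ep_local,
                                    global_loss = ep_global,
                                    overall_loss = ep_overall,
                                    val_loss = val_loss,
                                    val_accuracy = val_acc)
    if (verbose) {
      message(sprintf("epoch %3d  overall %.4f  val %.4f  val acc %.3f",
                      epoch, ep_overall, val_loss, val_acc))
    }
    if (val_loss < best$val - 1e-8) {
      best <- list(val = val_loss, params = params, fisher = fisher,
                   epoch = epoch)
      stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= control$patience) break
    }
  }
  structure(list(spec = spec, params = best$params, fisher = best$fisher,
                 history = dplyr::bind_rows(hist), control = control,
                 best_epoch = best$epoch, normalize = normalize,
                 classes = classes),
            class = "wmscnn_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.wmscnn_fit <- function(x, ...) {
  h <- x$history
  cat(sprintf(
    "<wmscnn_fit> %d classes, scales {%s}; %d epochs (best %d), val loss %.4f\n",
    x$spec$n_classes, paste(x$spec$scales, collapse = ","), nrow(h),
    x$best_epoch, min(h$val_loss)))
  invisible(x)
}

#' Predict from a fitted weighted multi-scale network
#'
#' @param object A `wmscnn_fit`.
#' @param newdata A `gait_dataset` or list of L x 6 window matrices.
#' @param type `"prob"` (class probabilities), `"class"` (label index), or
#'   `"embedding"` (fused global feature).
#' @param ... Unused.
#' @return A matrix (probabilities/embeddings) or integer vector of labels.
#' @export
predict.wmscnn_fit <- function(object, newdata,
                               type = c("prob", "class", "embedding"), ...) {
  type <- match.arg(type)
  signals <- if (inherits(newdata, "gait_dataset")) newdata$signals
             else if (is.list(newdata) && !is.null(newdata$signals)) newdata$signals
             else newdata
  if (object$normalize) signals <- lapply(signals, l2_normalize)
  spec <- object$spec
  if (nrow(signals[[1L]]) != spec$input_length) {
    stop_shape("model expects windows of length %d but newdata has %d",
               spec$input_length, nrow(signals[[1L]]))
  }
  stacks <- stack_scales(signals, spec$scales)
  lengths <- lapply(spec$scales, function(tau) spec$input_length %/% tau)
  names(lengths) <- scale_key(spec$scales)
  fwd <- wmscnn_forward(spec, object$params, object$fisher, stacks, lengths,
                        seq_along(signals), training = FALSE)
  switch(type,
         prob = fwd$probs,
         class = max.col(fwd$probs, ties.method = "first"),
         embedding = fwd$embedding)
}

#' @export
tidy.wmscnn_fit <- function(x, ...) x$history

#' @export
glance.wmscnn_fit <- function(x, ...) {
  h <- x$history
  tibble::tibble(n_classes = x$spec$n_classes,
                 n_scales = length(x$spec$scales),
                 epochs = nrow(h), best_epoch = x$best_epoch,
                 final_overall_loss = h$overall_loss[nrow(h)],
                 best_val_loss = min(h$val_loss),
                 final_val_accuracy = h$val_accuracy[nrow(h)])
}

#' Plot training trajectories
#'
#' @param object A `wmscnn_fit`.
#' @param ... Unused.
#' @return A ggplot of the loss components and validation loss per epoch.
#' @export
autoplot.wmscnn_fit <- function(object, ...) {
  long <- tidyr::pivot_longer(object$history,
                              c("local_loss", "global_loss", "overall_loss",
                                "val_loss"),
                              names_to = "component", values_to = "loss")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$loss,
                                     colour = .data$component)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "loss", colour = NULL) +
    ggplot2::theme_minimal()
}
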