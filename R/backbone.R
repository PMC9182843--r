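# Per-scale 1-D convolutional backbone.
#
# The default layer plan (for a 200 x 6 input): Conv1_1 9x1/32 -> MaxPool 2 ->
# Conv2_1 5x1/64 -> Conv2_2 5x1/128 stride 2 (same) -> MaxPool 2 ->
# Conv3_1 3x1/128, ReLU after every convolution, dropout after the stack.
# Conv2_2 halves the length, so it runs at stride 2 with same padding; its
# parameter count is unaffected by that choice.

#' Default backbone layer plan
#'
#' @param dropout_rate Dropout applied after the convolutional stack during
#'   training (default 0.5).
#' @param l2 L2 penalty coefficient on convolution kernels (default 1e-4).
#' @return A `backbone_config`: ordered layer specs plus activation/dropout
#'   settings. The first convolution accepts 6 input channels.
#' @export
#' @examples
#' count_parameters(backbone_config())
backbone_config <- function(dropout_rate = 0.5, l2 = 1e-4) {
  layers <- list(
    list(name = "Conv1_1", kind = "conv", kernel = 9L, n_kernels = 32L,
         stride = 1L, padding = "valid"),
    list(name = "MaxPool1", kind = "maxpool", kernel = 2L, stride = 2L),
    list(name = "Conv2_1", kind = "conv", kernel = 5L, n_kernels = 64L,
         stride = 1L, padding = "valid"),
    list(name = "Conv2_2", kind = "conv", kernel = 5L, n_kernels = 128L,
         stride = 2L, padding = "same"),
    list(name = "MaxPool2", kind = "maxpool", kernel = 2L, stride = 2L),
    list(name = "Conv3_1", kind = "conv", kernel = 3L, n_kernels = 128L,
         stride = 1L, padding = "valid")
  )
  structure(list(layers = layers, in_channels = 6L, activation = "relu",
                 dropout_rate = dropout_rate, l2 = l2),
            class = "backbone_config")
}

#' @export
print.backbone_config <- function(x, ...) {
  cat("<backbone_config>\n")
  print(backbone_shapes(x, input_length = 200L))
  invisible(x)
}

#' Per-layer trainable parameter counts
#'
#' Each convolution contributes `kernel * in_channels * out_channels +
#' out_channels`; pooling layers contribute none.
#'
#' @param config A [backbone_config()].
#' @return A tibble with `layer`, `kind`, and `parameters`.
#' @export
count_parameters <- function(config) {
  stopifnot(inherits(config, "backbone_config"))
  ch <- config$in_channels
  rows <- purrr::map_dfr(config$layers, function(ly) {
    n <- 0L
    if (ly$kind == "conv") {
      n <- ly$kernel * ch * ly$n_kernels + ly$n_kernels
      ch <<- ly$n_kernels
    }
    tibble::tibble(layer = ly$name, kind = ly$kind, parameters = n)
  })
  rows
}

#' Trace feature-map shapes through the backbone
#'
#' @param config A [backbone_config()].
#' @param input_length Input signal length in samples.
#' @return A tibble with one row per layer: output `length` and `channels`.
#'   Errors (naming the layer) if any layer's output would be empty.
#' @export
backbone_shapes <- function(config, input_length) {
  stopifnot(inherits(config, "backbone_config"))
  L <- assert_count(input_length, "input_length")
  ch <- config$in_channels
  purrr::map_dfr(config$layers, function(ly) {
    if (ly$kind == "conv") {
      if (ly$padding == "valid" && L < ly$kernel) {
        stop_shape("layer %s: input length %d shorter than kernel %d",
                   ly$name, L, ly$kernel)
      }
      L <<- conv_out_length(L, ly$kernel, ly$stride, ly$padding)
      ch <<- ly$n_kernels
    } else {
      L <<- L %/% 2L
    }
    if (L < 1L) stop_shape("layer %s produces an empty feature map", ly$name)
    tibble::tibble(layer = ly$name, kind = ly$kind, length = L, channels = ch)
  })
}

#' Initialize backbone weights
#'
#' Kaiming-normal kernels, zero biases. Per-scale backbones share the layer
#' plan but never the weights; call once per scale.
#'
#' @param config A [backbone_config()].
#' @param seed Integer seed.
#' @return Named list of `W`/`b` arrays, one pair per convolution layer.
#' @export
backbone_init <- function(config, seed = 1) {
  stopifnot(inherits(config, "backbone_config"))
  with_seed(seed, {
    ch <- config$in_channels
    weights <- list()
    for (ly in config$layers) {
      if (ly$kind != "conv") next
      weights[[paste0(ly$name, ".W")]] <- kaiming_init(ly$kernel * ch,
                                                       ly$n_kernels)
      weights[[paste0(ly$name, ".b")]] <- numeric(ly$n_kernels)
      ch <- ly$n_kernels
    }
    weights
  })
}

# Batched forward through the backbone. X: (B*L) x C matrix. Returns the final
# feature map (B*P) x C_out, its location count P, and caches for backprop.
backbone_forward_batch <- function(X, B, L, config, weights,
                                   training = FALSE) {
  caches <- list()
  for (li in seq_along(config$layers)) {
    ly <- config$layers[[li]]
    if (ly$kind == "conv") {
      if (ly$padding == "valid" && L < ly$kernel) {
        stop_shape("layer %s: input length %d shorter than kernel %d",
                   ly$name, L, ly$kernel)
      }
      cf <- conv1d_forward(X, B, L,
                           W = weights[[paste0(ly$name, ".W")]],
                           b = weights[[paste0(ly$name, ".b")]],
                           kernel = ly$kernel, stride = ly$stride,
                           padding = ly$padding)
      rf <- relu_forward(cf$out)
      X <- rf$out
      L <- cf$P
      caches[[li]] <- list(kind = "conv", name = ly$name, conv = cf$cache,
                           relu = rf$cache)
    } else {
      pf <- maxpool2_forward(X, B, L)
      X <- pf$out
      L <- pf$P
      caches[[li]] <- list(kind = "maxpool", pool = pf$cache)
    }
    if (L < 1L) stop_shape("layer %s produces an empty feature map", ly$name)
  }
  df <- dropout_forward(X, config$dropout_rate, training)
  list(fmap = df$out, P = L, caches = caches, dropout = df$cache)
}

# Backward through the backbone; returns conv weight gradients (named like the
# weights) and optionally the input gradient.
backbone_backward_batch <- function(dFmap, fwd, config, weights,
                                    want_dx = FALSE) {
  dX <- dropout_backward(dFmap, fwd$dropout)
  grads <- list()
  for (li in rev(seq_along(config$layers))) {
    cc <- fwd$caches[[li]]
    if (cc$kind == "conv") {
      dX <- relu_backward(dX, cc$relu)
      bk <- conv1d_backward(dX, cc$conv)
      wn <- paste0(cc$name, ".W")
      grads[[wn]] <- bk$dW + 2 * config$l2 * weights[[wn]]
      grads[[paste0(cc$name, ".b")]] <- bk$db
      dX <- bk$dX
    } else {
      dX <- maxpool2_backward(dX, cc$pool)
    }
  }
  if (want_dx) grads$.dX <- dX
  grads
}

#' Run a signal through the backbone
#'
#' Applies the configured convolution (cross-correlation convention), ReLU and
#' max-pooling layers to a single signal; dropout is inactive outside
#' training.
#'
#' @param signal An L x C numeric matrix (C must match the config's input
#'   channels).
#' @param config A [backbone_config()].
#' @param weights Output of [backbone_init()].
#' @return A locations x channels feature-map matrix (all entries >= 0).
#' @export
backbone_forward <- function(signal, config, weights) {
  stopifnot(is.matrix(signal), inherits(config, "backbone_config"))
  if (ncol(signal) != config$in_channels) {
    stop_shape("signal has %d channels; config expects %d", ncol(signal),
               config$in_channels)
  }
  out <- backbone_forward_batch(signal, B = 1L, L = nrow(signal), config,
                                weights, training = FALSE)
  out$fmap
}
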