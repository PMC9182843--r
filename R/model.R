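# Full weighted multi-scale network: independent per-scale backbones, a
# classifier head per scale (whose pooled logits feed both the local loss and
# the Fisher-weighted feature), a learned fusion layer, and a global softmax
# classifier. Parameters live in one flat named list so the optimizer is a
# loop over arrays; Fisher statistics are non-trainable state refreshed from
# batch localized scores.

#' Model specification for the weighted multi-scale network
#'
#' @param n_classes Number of identities. May be `NULL` and inferred at fit
#'   time.
#' @param scales Block-averaging scale factors, one CNN branch per scale
#'   (default `2:5`, the four-branch ensemble).
#' @param input_length Window length in samples; `NULL` (default) resolves it
#'   from the data at fit time. The reference configuration uses 200.
#' @param fused_dim Dimension of the fused global feature (default 64).
#' @param n_prime Number of Fisher discriminant directions; default
#'   `min(n_classes - 1, feature channels)`.
#' @param backbone A [backbone_config()].
#' @param fusion_dropout Dropout rate after the fusion layer during training
#'   (default 0.8).
#' @param ws If `FALSE`, the Fisher weighting is ablated: the projection is a
#'   fixed identity truncation with unit weights, leaving all shapes intact.
#' @return A `wmscnn_spec` object.
#' @export
wmscnn_spec <- function(n_classes = NULL, scales = 2:5, input_length = NULL,
                        fused_dim = 64, n_prime = NULL,
                        backbone = backbone_config(), fusion_dropout = 0.8,
                        ws = TRUE) {
  scales <- sort(vapply(scales, assert_count, 1L, name = "scales"))
  if (anyDuplicated(scales)) stop_invalid("duplicate scales")
  if (!is.null(input_length)) {
    input_length <- assert_count(input_length, "input_length")
  }
  structure(list(n_classes = n_classes, scales = scales,
                 input_length = input_length,
                 fused_dim = assert_count(fused_dim, "fused_dim"),
                 n_prime = n_prime, backbone = backbone,
                 fusion_dropout = fusion_dropout, ws = isTRUE(ws)),
            class = "wmscnn_spec")
}

#' @export
print.wmscnn_spec <- function(x, ...) {
  cat(sprintf("<wmscnn_spec> scales {%s}, input %s, fused dim %d, ws %s\n",
              paste(x$scales, collapse = ","),
              x$input_length %||% "<from data>", x$fused_dim,
              if (x$ws) "on" else "off (ablated)"))
  invisible(x)
}

# Resolve open fields once the class count and window length are known.
resolve_spec <- function(spec, n_classes, input_length = NULL) {
  if (is.null(spec$n_classes)) spec$n_classes <- n_classes
  if (is.null(spec$input_length)) {
    if (is.null(input_length)) stop_invalid("window length is unresolved")
    spec$input_length <- input_length
  } else if (!is.null(input_length) && spec$input_length != input_length) {
    stop_invalid("spec expects windows of length %d but the data has %d",
                 spec$input_length, input_length)
  }
  K <- spec$n_classes
  if (K < 2L) stop_invalid("need at least 2 classes")
  ch <- utils::tail(backbone_shapes(spec$backbone, spec$input_length)$channels, 1L)
  if (is.null(spec$n_prime)) spec$n_prime <- min(K - 1L, ch)
  spec$n_prime <- min(spec$n_prime, K - 1L)
  # every branch must produce a non-empty final feature map
  for (tau in spec$scales) {
    backbone_shapes(spec$backbone, spec$input_length %/% tau)
  }
  spec
}

scale_key <- function(tau) paste0("tau", tau)

# Initialize all trainable parameters (Kaiming kernels and dense weights,
# zero biases) and the per-scale Fisher state.
wmscnn_init <- function(spec, seed = 1) {
  K <- spec$n_classes
  np <- spec$n_prime
  params <- list()
  ch <- utils::tail(backbone_shapes(spec$backbone, spec$input_length)$channels, 1L)
  for (i in seq_along(spec$scales)) {
    tau <- spec$scales[i]
    key <- scale_key(tau)
    bw <- backbone_init(spec$backbone, seed = child_seed(seed, 100L + i))
    names(bw) <- paste0(key, ".", names(bw))
    params <- c(params, bw)
    params[[paste0(key, ".head.W")]] <-
      with_seed(child_seed(seed, 200L + i), kaiming_init(ch, K))
    params[[paste0(key, ".head.b")]] <- numeric(K)
    params[[paste0(key, ".fuse.W")]] <-
      with_seed(child_seed(seed, 300L + i),
                t(kaiming_init(np, spec$fused_dim)))
  }
  params[["fc.W"]] <- with_seed(child_seed(seed, 400L),
                                kaiming_init(spec$fused_dim, K))
  params[["fc.b"]] <- numeric(K)
  fisher <- lapply(spec$scales, function(tau) {
    list(Sw = NULL, Sb = NULL,
         projection = diag(K)[, seq_len(np), drop = FALSE],
         lambda = rep(1, np), initialized = FALSE)
  })
  names(fisher) <- scale_key(spec$scales)
  list(params = params, fisher = fisher)
}

# Stack per-scale block-averaged signals for a whole dataset:
# result[[key]] is an (n * L_tau) x 6 matrix, window rows contiguous.
stack_scales <- function(signals, scales) {
  out <- lapply(scales, function(tau) {
    do.call(rbind, lapply(signals, function(s) downsample(s, tau)))
  })
  names(out) <- scale_key(scales)
  out
}

batch_rows <- function(idx, L) {
  rep((idx - 1L) * L, each = L) + rep(seq_len(L), times = length(idx))
}

# Forward pass over a batch. `stacks` holds the full per-scale stacked
# matrices; `idx` selects windows. Returns losses, probabilities, the fused
# embedding, and (if `training`) caches for the backward pass.
wmscnn_forward <- function(spec, params, fisher, stacks, lengths, idx,
                          labels = NULL, training = FALSE,
                          alpha = 0.99, beta = 0.87, alpha_i = NULL,
                          update_fisher = FALSE, fisher_momentum = 0.9) {
  B <- length(idx)
  K <- spec$n_classes
  np <- spec$n_prime
  s <- length(spec$scales)
  if (is.null(alpha_i)) alpha_i <- rep(1 / s, s)
  Y <- NULL
  if (!is.null(labels)) {
    Y <- matrix(0, B, K)
    Y[cbind(seq_len(B), labels)] <- 1
  }
  per_scale <- vector("list", s)
  Fg <- matrix(0, B, spec$fused_dim)
  local_ce <- numeric(s)
  for (i in seq_len(s)) {
    tau <- spec$scales[i]
    key <- scale_key(tau)
    L <- lengths[[key]]
    X <- stacks[[key]][batch_rows(idx, L), , drop = FALSE]
    bb <- backbone_forward_batch(X, B, L, spec$backbone, sub_params(params, key),
                                 training = training)
    P <- bb$P
    group <- rep(seq_len(B), each = P)
    G <- rowsum(bb$fmap, group, reorder = TRUE) / P
    headW <- params[[paste0(key, ".head.W")]]
    headb <- params[[paste0(key, ".head.b")]]
    logits <- G %*% headW + rep(headb, each = B)
    probs_local <- softmax_rows(logits)
    fs <- fisher[[key]]
    if (update_fisher && spec$ws && !is.null(labels)) {
      S <- bb$fmap %*% headW + rep(headb, each = nrow(bb$fmap))
      st <- scatter_matrices(S, rep(labels, each = P))
      if (!fs$initialized) {
        fs$Sw <- st$Sw; fs$Sb <- st$Sb; fs$initialized <- TRUE
      } else {
        fs$Sw <- fisher_momentum * fs$Sw + (1 - fisher_momentum) * st$Sw
        fs$Sb <- fisher_momentum * fs$Sb + (1 - fisher_momentum) * st$Sb
      }
      fw <- fisher_eig(fs$Sw, fs$Sb, np)
      fs$projection <- fw$projection
      fs$lambda <- fw$lambda
      fisher[[key]] <- fs
    }
    if (spec$ws) {
      lam_max <- max(fs$lambda)
      lam_n <- if (lam_max > 0) fs$lambda / lam_max else rep(1, np)
      Fhat <- (logits %*% fs$projection) * rep(lam_n, each = B)
    } else {
      lam_n <- rep(1, np)
      Fhat <- logits[, seq_len(np), drop = FALSE]
    }
    Wf <- params[[paste0(key, ".fuse.W")]]  # fused_dim x n_prime
    Fg <- Fg + Fhat %*% t(Wf)
    if (!is.null(Y)) local_ce[i] <- cross_entropy(probs_local, Y)
    per_scale[[i]] <- list(key = key, bb = bb, P = P, group = group, G = G,
                           logits = logits, probs_local = probs_local,
                           Fhat = Fhat, lam_n = lam_n,
                           projection = fisher[[key]]$projection)
  }
  fd <- dropout_forward(Fg, spec$fusion_dropout, training)
  Zg <- fd$out %*% params[["fc.W"]] + rep(params[["fc.b"]], each = B)
  probs_g <- softmax_rows(Zg)
  out <- list(probs = probs_g, embedding = Fg, per_scale = per_scale,
              fisher = fisher)
  if (!is.null(Y)) {
    out$local_loss <- sum(alpha_i * local_ce)
    out$global_loss <- cross_entropy(probs_g, Y)
    out$overall_loss <- overall_loss(out$local_loss, out$global_loss,
                                     alpha, beta)
    out$Y <- Y
  }
  if (training) {
    out$cache <- list(Fg_dropped = fd$out, drop_mask = fd$cache, B = B,
                      alpha = alpha, beta = beta, alpha_i = alpha_i, idx = idx)
  }
  out
}

sub_params <- function(params, key) {
  pre <- paste0(key, ".")
  keep <- startsWith(names(params), pre)
  out <- params[keep]
  names(out) <- substring(names(out), nchar(pre) + 1L)
  out
}

# Backward pass; returns gradients named like `params`.
wmscnn_backward <- function(spec, params, fwd) {
  cc <- fwd$cache
  B <- cc$B
  K <- spec$n_classes
  np <- spec$n_prime
  grads <- list()
  dZg <- cc$beta * (fwd$probs - fwd$Y) / B
  grads[["fc.W"]] <- crossprod(cc$Fg_dropped, dZg)
  grads[["fc.b"]] <- colSums(dZg)
  dFg <- dropout_backward(dZg %*% t(params[["fc.W"]]), cc$drop_mask)
  for (i in seq_along(spec$scales)) {
    ps <- fwd$per_scale[[i]]
    key <- ps$key
    Wf <- params[[paste0(key, ".fuse.W")]]
    grads[[paste0(key, ".fuse.W")]] <- crossprod(dFg, ps$Fhat)
    dFhat <- dFg %*% Wf
    if (spec$ws) {
      dlogits_g <- (dFhat * rep(ps$lam_n, each = B)) %*% t(ps$projection)
    } else {
      dlogits_g <- matrix(0, B, K)
      dlogits_g[, seq_len(np)] <- dFhat
    }
    dlogits <- dlogits_g +
      cc$alpha * cc$alpha_i[i] * (ps$probs_local - fwd$Y) / B
    headW <- params[[paste0(key, ".head.W")]]
    grads[[paste0(key, ".head.W")]] <- crossprod(ps$G, dlogits)
    grads[[paste0(key, ".head.b")]] <- colSums(dlogits)
    dG <- dlogits %*% t(headW)
    dfmap <- dG[ps$group, , drop = FALSE] / ps$P
    bg <- backbone_backward_batch(dfmap, ps$bb, spec$backbone,
                                  sub_params(params, key))
    names(bg) <- paste0(key, ".", names(bg))
    grads <- c(grads, bg)
  }
  grads
}
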