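# Weight-update branch: global average pooling, localized classification,
# Fisher-criterion weighting, fusion, and the softmax classifier.
#
# The Fisher branch treats the per-location class scores of a feature map as
# samples: their within- and between-class scatter define a generalized
# eigenproblem whose leading eigenvalues weight the discriminative directions
# of score space.

#' Global average pooling of a feature map
#'
#' @param fmap A locations x channels numeric matrix.
#' @return Numeric vector of per-channel means.
#' @export
global_average_pool <- function(fmap) {
  if (!is.matrix(fmap) || nrow(fmap) < 1L) {
    stop_shape("feature map must be a matrix with at least one location")
  }
  colMeans(fmap)
}

#' Localized class scores of a feature map
#'
#' Row `i` holds the per-class dot products of location `i`'s feature vector
#' with the classifier weight columns (plus bias): the classifier applied at
#' every temporal location rather than to the pooled vector.
#'
#' @param fmap A locations x channels matrix.
#' @param class_weights A channels x n_classes matrix.
#' @param bias Optional per-class bias vector.
#' @return A locations x n_classes score matrix.
#' @export
localized_scores <- function(fmap, class_weights, bias = NULL) {
  if (!is.matrix(fmap) || !is.matrix(class_weights)) {
    stop_shape("`fmap` and `class_weights` must be matrices")
  }
  if (ncol(fmap) != nrow(class_weights)) {
    stop_shape("channel mismatch: fmap has %d, class_weights expects %d",
               ncol(fmap), nrow(class_weights))
  }
  out <- fmap %*% class_weights
  if (!is.null(bias)) out <- out + rep(bias, each = nrow(out))
  out
}

# Scatter matrices of labelled score vectors. Between-class scatter is the
# unweighted sum of (m_i - m)(m_i - m)' over class means.
scatter_matrices <- function(scores, labels) {
  classes <- sort(unique(labels))
  d <- ncol(scores)
  m <- colMeans(scores)
  Sw <- matrix(0, d, d)
  Sb <- matrix(0, d, d)
  for (cl in classes) {
    sc <- scores[labels == cl, , drop = FALSE]
    mi <- colMeans(sc)
    centered <- sweep(sc, 2L, mi, "-")
    Sw <- Sw + crossprod(centered)
    Sb <- Sb + tcrossprod(mi - m)
  }
  list(Sw = Sw, Sb = Sb, class_means = NULL, grand_mean = m,
       n_classes = length(classes))
}

#' Fisher-discriminant weights of localized scores
#'
#' Forms the within-class scatter (sum of centered outer products per class)
#' and between-class scatter (sum of `(m_i - m)(m_i - m)'` over class means)
#' of the score vectors, then solves the generalized eigenproblem of
#' `Sw^-1 Sb`. The leading `n_prime` eigenvalues are the feature weights; the
#' associated eigenvectors define the discriminant projection.
#'
#' If `Sw` is singular a ridge `eps * I` with `eps = 1e-6 * trace(Sw)/d`
#' (floored at `1e-6` when the trace vanishes) is added with a warning. With a
#' single class the between-class scatter is zero and zero weights are
#' returned with a warning.
#'
#' @param scores An n x d matrix of localized score vectors (pooled over a
#'   batch).
#' @param labels Integer class labels, one per row.
#' @param n_prime Number of discriminant directions, at most `n_classes - 1`.
#' @return A `fisher_weights` object: `lambda` (length `n_prime`, descending,
#'   clipped at 0) and `projection` (d x n_prime, unit-norm columns).
#' @export
fisher_weights <- function(scores, labels, n_prime = NULL) {
  if (!is.matrix(scores)) scores <- as.matrix(scores)
  if (nrow(scores) != length(labels)) {
    stop_shape("one label per score row required (%d rows, %d labels)",
               nrow(scores), length(labels))
  }
  st <- scatter_matrices(scores, labels)
  d <- ncol(scores)
  if (is.null(n_prime)) n_prime <- max(1L, min(st$n_classes - 1L, d))
  n_prime <- assert_count(n_prime, "n_prime")
  if (st$n_classes < 2L) {
    rlang::warn("single class: between-class scatter is zero, returning zero weights",
                class = "wsgait_degenerate_input")
    return(new_fisher_weights(numeric(n_prime),
                              diag(d)[, seq_len(n_prime), drop = FALSE]))
  }
  if (n_prime > st$n_classes - 1L) {
    stop_invalid("n_prime = %d exceeds n_classes - 1 = %d", n_prime,
                 st$n_classes - 1L)
  }
  fisher_eig(st$Sw, st$Sb, n_prime)
}

# Solve Sw^-1 Sb for the top eigenpairs, ridging Sw if it is singular.
fisher_eig <- function(Sw, Sb, n_prime) {
  d <- ncol(Sw)
  Swr <- Sw
  rc <- tryCatch(rcond(Swr), error = function(e) 0)
  if (!is.finite(rc) || rc < 1e-12) {
    eps <- 1e-6 * sum(diag(Sw)) / d
    if (eps <= 0) eps <- 1e-6
    Swr <- Sw + diag(eps, d)
    rlang::warn(sprintf("singular within-class scatter: ridge %.3g added", eps),
                class = "wsgait_ridge_applied")
  }
  A <- solve(Swr, Sb)
  ev <- eigen(A)
  lam <- Re(ev$values)
  ord <- order(lam, decreasing = TRUE)
  lam <- lam[ord]
  vec <- Re(ev$vectors[, ord, drop = FALSE])
  lam <- pmax(lam, 0)
  take <- seq_len(min(n_prime, length(lam)))
  lam <- lam[take]
  vec <- vec[, take, drop = FALSE]
  # deterministic orientation and unit norm per column
  for (j in seq_len(ncol(vec))) {
    v <- vec[, j]
    nv <- sqrt(sum(v^2))
    if (nv > 0) v <- v / nv
    piv <- which.max(abs(v))
    if (v[piv] < 0) v <- -v
    vec[, j] <- v
  }
  if (length(lam) < n_prime) {
    pad <- n_prime - length(lam)
    lam <- c(lam, numeric(pad))
    vec <- cbind(vec, matrix(0, d, pad))
  }
  new_fisher_weights(lam, vec)
}

new_fisher_weights <- function(lambda, projection) {
  structure(list(lambda = lambda, projection = projection),
            class = "fisher_weights")
}

#' @export
print.fisher_weights <- function(x, ...) {
  cat(sprintf("<fisher_weights> n_prime = %d, lambda = %s\n",
              length(x$lambda),
              paste(signif(x$lambda, 4), collapse = ", ")))
  invisible(x)
}

#' Reweight a pooled feature by Fisher weights
#'
#' Projects the vector onto the Fisher eigenvectors and scales component `j`
#' by `lambda_j / max(lambda)`, so the most discriminative direction keeps
#' weight 1 and the rest shrink proportionally.
#'
#' @param gap Numeric vector living in the space the projection was computed
#'   in (length `d`).
#' @param fw A [fisher_weights()] result.
#' @return Numeric vector of length `n_prime`. All-zero `lambda` yields a zero
#'   vector with a warning.
#' @export
reweight_features <- function(gap, fw) {
  stopifnot(inherits(fw, "fisher_weights"))
  gap <- as.numeric(gap)
  if (length(gap) != nrow(fw$projection)) {
    stop_shape("vector length %d does not match projection dimension %d",
               length(gap), nrow(fw$projection))
  }
  lam_max <- max(fw$lambda)
  if (lam_max <= 0) {
    rlang::warn("all Fisher weights are zero; returning zero vector",
                class = "wsgait_degenerate_input")
    return(numeric(length(fw$lambda)))
  }
  drop(crossprod(fw$projection, gap)) * (fw$lambda / lam_max)
}

#' Fuse per-scale features into a global feature
#'
#' `F_global = W_1 f_1 + ... + W_s f_s`: a learned linear map per scale,
#' summed. During training a dropout layer follows the fusion; this function
#' is the deterministic (inference) form.
#'
#' @param weighted List of per-scale feature vectors.
#' @param fusion_weights List of matrices, `fusion_weights[[s]]` mapping scale
#'   `s`'s feature dimension to the common fused dimension (dim fused x dim_s).
#' @return Numeric fused feature vector.
#' @export
fuse_features <- function(weighted, fusion_weights) {
  if (length(weighted) != length(fusion_weights)) {
    stop_shape("%d feature vectors but %d fusion matrices", length(weighted),
               length(fusion_weights))
  }
  out <- NULL
  for (s in seq_along(weighted)) {
    W <- fusion_weights[[s]]
    v <- as.numeric(weighted[[s]])
    if (ncol(W) != length(v)) {
      stop_shape("fusion matrix %d is %dx%d but feature has length %d", s,
                 nrow(W), ncol(W), length(v))
    }
    term <- drop(W %*% v)
    out <- if (is.null(out)) term else out + term
  }
  out
}

#' Softmax classification of a global feature
#'
#' @param global_feat Numeric fused feature vector.
#' @param fc_weights A dim x n_classes weight matrix.
#' @param fc_bias Per-class bias vector.
#' @return Class probability vector (non-negative, sums to 1).
#' @export
classify <- function(global_feat, fc_weights, fc_bias) {
  v <- as.numeric(global_feat)
  if (length(v) != nrow(fc_weights)) {
    stop_shape("feature length %d does not match weight rows %d", length(v),
               nrow(fc_weights))
  }
  z <- drop(crossprod(fc_weights, v)) + fc_bias
  drop(softmax_rows(matrix(z, nrow = 1L)))
}
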