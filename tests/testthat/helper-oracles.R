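# Independent brute-force oracles used to freeze expected values. These stay
# deliberately naive (explicit loops, no shared code with the implementation).

# Block averaging by explicit double loop.
naive_downsample <- function(x, tau) {
  p <- nrow(x) %/% tau
  out <- matrix(0, p, ncol(x))
  for (t in seq_len(p)) {
    for (ch in seq_len(ncol(x))) {
      acc <- 0
      for (k in ((t - 1) * tau + 1):(t * tau)) acc <- acc + x[k, ch]
      out[t, ch] <- acc / tau
    }
  }
  out
}

# Valid cross-correlation 1-D convolution by explicit triple loop.
# W: (kernel * C_in) x C_out, offset-major rows; returns P x C_out.
naive_conv1d <- function(x, W, b, kernel, stride = 1) {
  P <- (nrow(x) - kernel) %/% stride + 1
  C_in <- ncol(x)
  C_out <- ncol(W)
  out <- matrix(0, P, C_out)
  for (p in seq_len(P)) {
    for (co in seq_len(C_out)) {
      acc <- b[co]
      for (j in seq_len(kernel)) {
        for (ci in seq_len(C_in)) {
          acc <- acc + x[(p - 1) * stride + j, ci] * W[(j - 1) * C_in + ci, co]
        }
      }
      out[p, co] <- acc
    }
  }
  out
}

# Leave-one-out nearest-centroid accuracy on flattened raw windows.
nearest_centroid_loo <- function(signals, labels) {
  X <- t(vapply(signals, as.vector, numeric(length(signals[[1]]))))
  classes <- sort(unique(labels))
  correct <- 0
  for (i in seq_len(nrow(X))) {
    d <- vapply(classes, function(cl) {
      ids <- setdiff(which(labels == cl), i)
      if (!length(ids)) return(Inf)
      cen <- colMeans(X[ids, , drop = FALSE])
      sum((X[i, ] - cen)^2)
    }, numeric(1))
    if (classes[which.min(d)] == labels[i]) correct <- correct + 1
  }
  correct / nrow(X)
}

# Scatter matrices by explicit loops (independent of the implementation).
naive_scatter <- function(scores, labels) {
  classes <- sort(unique(labels))
  d <- ncol(scores)
  m <- colMeans(scores)
  Sw <- matrix(0, d, d)
  Sb <- matrix(0, d, d)
  for (cl in classes) {
    rows <- which(labels == cl)
    mi <- colMeans(scores[rows, , drop = FALSE])
    for (r in rows) {
      v <- scores[r, ] - mi
      Sw <- Sw + outer(v, v)
    }
    Sb <- Sb + outer(mi - m, mi - m)
  }
  list(Sw = Sw, Sb = Sb)
}

# Generalized eigenvalues of (Sb, Sw) via Cholesky whitening — a dense
# symmetric-eigenproblem route entirely different from solve() + eigen().
whitened_fisher_eigenvalues <- function(Sw, Sb) {
  R <- chol(Sw)
  Rinv <- backsolve(R, diag(nrow(Sw)))
  A <- t(Rinv) %*% Sb %*% Rinv
  sort(eigen((A + t(A)) / 2, symmetric = TRUE, only.values = TRUE)$values,
       decreasing = TRUE)
}

# Random labelled score clouds for Fisher tests.
random_fisher_problem <- function(n_classes, d, n_per_class, spread = 2) {
  labels <- rep(seq_len(n_classes), each = n_per_class)
  centers <- matrix(rnorm(n_classes * d, sd = spread), n_classes, d)
  scores <- centers[labels, , drop = FALSE] +
    matrix(rnorm(length(labels) * d), ncol = d)
  list(scores = scores, labels = labels)
}

# Small gait dataset shared by the heavier tests.
tiny_dataset <- function(n_subjects = 3, windows = 4, length = 128,
                         noise_sd = 0.05, seed = 11) {
  simulate_gait(n_subjects, windows, length = length, noise_sd = noise_sd,
                seed = seed)
}
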