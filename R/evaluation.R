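# Gallery/probe identification and verification metrics.

#' Rank-k identification rate
#'
#' Percentage of probes whose true class is among the `k` highest-scoring
#' classes. Ties are broken toward the lowest class index.
#'
#' @param probe_scores An n_probe x n_classes score matrix (higher = better).
#' @param labels True class indices (1-based), one per probe.
#' @param k Rank depth, `k <= n_classes`.
#' @return Identification rate as a percentage in `[0, 100]`.
#' @export
rank_k_identification <- function(probe_scores, labels, k = 1) {
  if (!is.matrix(probe_scores)) probe_scores <- as.matrix(probe_scores)
  k <- assert_count(k, "k")
  if (k > ncol(probe_scores)) {
    stop_invalid("k = %d exceeds the number of classes %d", k,
                 ncol(probe_scores))
  }
  if (nrow(probe_scores) != length(labels)) {
    stop_shape("one label per probe required")
  }
  hits <- vapply(seq_len(nrow(probe_scores)), function(i) {
    sc <- probe_scores[i, ]
    truth <- labels[i]
    # position of the true class after sorting, lowest index first on ties
    pos <- sum(sc > sc[truth]) + sum(sc == sc[truth] & seq_along(sc) < truth) + 1L
    pos <= k
  }, logical(1))
  100 * mean(hits)
}

#' Cosine similarity scores for verification pairs
#'
#' Row-wise cosine similarity between two embedding matrices; rows are paired
#' samples. Zero-norm embeddings score 0 with a warning.
#'
#' @param embeddings_a,embeddings_b Matrices of equal shape, one embedding per
#'   row (vectors are treated as a single pair).
#' @return Numeric similarity vector in `[-1, 1]`.
#' @export
verification_scores <- function(embeddings_a, embeddings_b) {
  if (!is.matrix(embeddings_a)) embeddings_a <- matrix(embeddings_a, nrow = 1L)
  if (!is.matrix(embeddings_b)) embeddings_b <- matrix(embeddings_b, nrow = 1L)
  if (!all(dim(embeddings_a) == dim(embeddings_b))) {
    stop_shape("embedding matrices must have equal dimensions")
  }
  na <- sqrt(rowSums(embeddings_a^2))
  nb <- sqrt(rowSums(embeddings_b^2))
  dot <- rowSums(embeddings_a * embeddings_b)
  bad <- na < 1e-12 | nb < 1e-12
  if (any(bad)) {
    rlang::warn(sprintf("%d zero-norm embedding pair(s) scored 0", sum(bad)),
                class = "wsgait_degenerate_input")
  }
  out <- numeric(length(dot))
  out[!bad] <- dot[!bad] / (na[!bad] * nb[!bad])
  out
}

#' ROC curve of a verification score distribution
#'
#' Sweeps an acceptance threshold over all distinct scores (accept when
#' `score >= threshold`). By default TAR is the true-positive rate
#' `TP / (TP + FN)`; `tar = "precision"` instead reports `TP / (TP + FP)`.
#' FAR is `FP / (FP + TN)`. The accept-none `(0, 0)` and accept-all `(1, 1)`
#' endpoints are always included.
#'
#' @param genuine_scores Scores of same-identity pairs.
#' @param impostor_scores Scores of different-identity pairs.
#' @param tar `"tpr"` (default) or `"precision"`.
#' @return A tibble with columns `threshold`, `far`, `tar`, ordered by
#'   increasing `far`.
#' @export
roc_curve <- function(genuine_scores, impostor_scores,
                      tar = c("tpr", "precision")) {
  tar <- match.arg(tar)
  if (!length(genuine_scores) || !length(impostor_scores)) {
    stop_invalid("both score sets must be non-empty")
  }
  all_scores <- c(genuine_scores, impostor_scores)
  is_gen <- c(rep(1, length(genuine_scores)), rep(0, length(impostor_scores)))
  ord <- order(all_scores, decreasing = TRUE)
  s_sorted <- all_scores[ord]
  tp_cum <- cumsum(is_gen[ord])
  fp_cum <- cumsum(1 - is_gen[ord])
  # last index of each distinct score = the ">= threshold" operating point
  last <- which(c(s_sorted[-1] != s_sorted[-length(s_sorted)], TRUE))
  thr <- c(s_sorted[last], -Inf)
  tp <- c(tp_cum[last], length(genuine_scores))
  fp <- c(fp_cum[last], length(impostor_scores))
  fn <- length(genuine_scores) - tp
  tn <- length(impostor_scores) - fp
  tar_v <- if (tar == "tpr") tp / (tp + fn)
           else ifelse(tp + fp > 0, tp / (tp + fp), 1)
  far_v <- fp / (fp + tn)
  out <- tibble::tibble(threshold = c(Inf, thr),
                        far = c(0, far_v), tar = c(0, tar_v))
  dplyr::arrange(out, .data$far, .data$tar)
}

#' Verification rate at a target false-acceptance rate
#'
#' TAR linearly interpolated at the target FAR. If the target lies below the
#' smallest achievable non-zero operating point, the TAR of the smallest FAR
#' is returned with a warning.
#'
#' @param roc Output of [roc_curve()].
#' @param far_target Target FAR (default `1e-3`, the standard biometric
#'   operating point).
#' @return Verification rate in `[0, 1]`.
#' @export
vr_at_far <- function(roc, far_target = 1e-3) {
  stopifnot(is.data.frame(roc), all(c("far", "tar") %in% names(roc)))
  agg <- dplyr::summarise(dplyr::group_by(roc, .data$far),
                          tar = max(.data$tar), .groups = "drop")
  agg <- dplyr::arrange(agg, .data$far)
  if (far_target < min(agg$far)) {
    rlang::warn(sprintf(
      "far_target %.3g below smallest achievable FAR %.3g; returning its TAR",
      far_target, min(agg$far)), class = "wsgait_degenerate_input")
    return(agg$tar[1L])
  }
  if (nrow(agg) == 1L) return(agg$tar[1L])
  approx(agg$far, agg$tar, xout = min(far_target, max(agg$far)),
         ties = "ordered")$y
}

#' Gallery/probe evaluation of a fitted model
#'
#' Identification uses the global classifier's softmax scores on the probe
#' windows (rank-1 and rank-5 rates). Verification scores every probe
#' embedding against every gallery embedding by cosine similarity; pairs
#' sharing an identity are genuine, the rest impostor.
#'
#' @param fit A `wmscnn_fit`.
#' @param probe A `gait_dataset` of probe windows.
#' @param gallery A `gait_dataset` of enrolled windows (for verification);
#'   defaults to `NULL`, skipping verification.
#' @param far_targets FAR operating points reported by `vr_at_far`.
#' @return A `gait_eval`: tibble-backed report with `rank1_ir`, `rank5_ir`
#'   (percentages), the ROC tibble, and `vr_at_far` per target.
#' @export
evaluate_gait <- function(fit, probe, gallery = NULL,
                          far_targets = c(1e-3, 1e-2)) {
  stopifnot(inherits(fit, "wmscnn_fit"))
  scores <- predict(fit, probe, type = "prob")
  k5 <- min(5L, ncol(scores))
  rank1 <- rank_k_identification(scores, probe$labels, k = 1)
  rank5 <- rank_k_identification(scores, probe$labels, k = k5)
  roc <- NULL
  vr <- NULL
  if (!is.null(gallery)) {
    ep <- predict(fit, probe, type = "embedding")
    eg <- predict(fit, gallery, type = "embedding")
    np_ <- nrow(ep); ng <- nrow(eg)
    pair_p <- rep(seq_len(np_), times = ng)
    pair_g <- rep(seq_len(ng), each = np_)
    sims <- verification_scores(ep[pair_p, , drop = FALSE],
                                eg[pair_g, , drop = FALSE])
    genuine <- probe$labels[pair_p] == gallery$labels[pair_g]
    roc <- roc_curve(sims[genuine], sims[!genuine])
    vr <- vapply(far_targets, function(ft) vr_at_far(roc, ft), numeric(1))
    names(vr) <- paste0("far_", format(far_targets, scientific = TRUE))
  }
  structure(list(rank1_ir = rank1, rank5_ir = rank5, rank5_k = k5,
                 roc = roc, vr_at_far = vr, n_probe = length(probe$labels)),
            class = "gait_eval")
}

#' @export
print.gait_eval <- function(x, ...) {
  cat(sprintf("<gait_eval> %d probes: rank-1 IR %.2f%%, rank-%d IR %.2f%%\n",
              x$n_probe, x$rank1_ir, x$rank5_k, x$rank5_ir))
  if (!is.null(x$vr_at_far)) {
    for (nm in names(x$vr_at_far)) {
      cat(sprintf("  VR @ %s = %.3f\n", sub("far_", "FAR ", nm),
                  x$vr_at_far[[nm]]))
    }
  }
  invisible(x)
}

#' @export
tidy.gait_eval <- function(x, ...) {
  out <- tibble::tibble(metric = c("rank1_ir", "rank5_ir"),
                        value = c(x$rank1_ir, x$rank5_ir))
  if (!is.null(x$vr_at_far)) {
    out <- dplyr::bind_rows(out, tibble::tibble(
      metric = paste0("vr_", names(x$vr_at_far)),
      value = unname(x$vr_at_far)))
  }
  out
}

#' Plot the verification ROC curve
#'
#' @param object A `gait_eval` with a ROC component.
#' @param ... Unused.
#' @return A ggplot of TAR against FAR (log-scaled FAR axis).
#' @export
autoplot.gait_eval <- function(object, ...) {
  if (is.null(object$roc)) stop_invalid("no ROC in this report")
  dd <- dplyr::filter(object$roc, .data$far > 0)
  ggplot2::ggplot(dd, ggplot2::aes(x = .data$far, y = .data$tar)) +
    ggplot2::geom_step() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "false acceptance rate",
                  y = "true acceptance rate") +
    ggplot2::theme_minimal()
}
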