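# Multi-scale signal reconstruction by non-overlapping block averaging.

#' Coarse-grain a window at one time scale
#'
#' Output row `t` is the per-channel mean of input rows
#' `(t-1)*tau + 1 ... t*tau`; the trailing `N mod tau` rows are discarded, so
#' the result has `floor(N / tau)` rows. `tau = 1` is the identity.
#'
#' @param window An N x 6 numeric matrix.
#' @param tau Positive integer scale factor, `tau <= N`.
#' @return A `floor(N/tau)` x 6 matrix.
#' @export
#' @examples
#' w <- matrix(rep(1:4, 6), ncol = 6)
#' downsample(w, 2)[, 1]  # 1.5 3.5
downsample <- function(window, tau) {
  x <- assert_window_matrix(window)
  tau <- assert_count(tau, "tau")
  n <- nrow(x)
  if (tau > n) stop_invalid("tau = %d exceeds window length %d", tau, n)
  if (tau == 1L) return(x)
  p <- n %/% tau
  grp <- rep(seq_len(p), each = tau)
  out <- rowsum(x[seq_len(p * tau), , drop = FALSE], grp, reorder = TRUE) / tau
  dimnames(out) <- list(NULL, colnames(x))
  out
}

#' Build the multi-scale bundle of a window
#'
#' One block-averaged signal per requested scale, scales sorted ascending.
#'
#' @param window An N x 6 numeric matrix.
#' @param scales Distinct positive integer scale factors, all `<= N`. The
#'   default `2:5` is the four-branch ensemble used throughout.
#' @return A `multiscale_bundle`: list with `scales` and `signals` (named
#'   `tau<k>`).
#' @export
#' @examples
#' b <- build_bundle(matrix(rnorm(1200), ncol = 6), scales = c(2, 3, 4, 5))
#' vapply(b$signals, nrow, 1L)  # 100 66 50 40
build_bundle <- function(window, scales = 2:5) {
  x <- assert_window_matrix(window)
  scales <- vapply(scales, assert_count, 1L, name = "scales")
  if (anyDuplicated(scales)) stop_invalid("duplicate scales: %s",
                                          paste(scales, collapse = ","))
  if (any(scales > nrow(x))) {
    stop_invalid("scales %s exceed window length %d",
                 paste(scales[scales > nrow(x)], collapse = ","), nrow(x))
  }
  scales <- sort(scales)
  signals <- lapply(scales, function(tau) downsample(x, tau))
  names(signals) <- paste0("tau", scales)
  structure(list(scales = scales, signals = signals),
            class = "multiscale_bundle")
}

#' @export
print.multiscale_bundle <- function(x, ...) {
  cat(sprintf("<multiscale_bundle> scales {%s}, lengths {%s}\n",
              paste(x$scales, collapse = ","),
              paste(vapply(x$signals, nrow, 1L), collapse = ",")))
  invisible(x)
}
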