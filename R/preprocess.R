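# Normalization and fixed-length windowing of 6-channel inertial streams.

#' Per-step L2 normalization of sensor triples
#'
#' At every time step the accelerometer triple (Ax,Ay,Az) and the gyroscope
#' triple (Gx,Gy,Gz) are each divided by their Euclidean norm, so only the
#' instantaneous sensor direction is kept. This cancels multiplicative gain
#' and device-orientation magnitude effects ("phone shifting" artifacts).
#' Steps where a triple's norm falls below `1e-12` are left as zeros.
#'
#' @param window An L x 6 numeric matrix (columns Ax,Ay,Az,Gx,Gy,Gz) or a
#'   `gait_dataset` (normalized window-wise).
#' @return Object of the same shape with unit-norm triples.
#' @export
#' @examples
#' w <- matrix(rep(c(3, 4, 0, 1, 0, 0), each = 4), nrow = 4)
#' l2_normalize(w)[1, ]  # 0.6 0.8 0 1 0 0
l2_normalize <- function(window) {
  if (inherits(window, "gait_dataset")) {
    window$signals <- lapply(window$signals, l2_normalize)
    return(window)
  }
  x <- assert_window_matrix(window)
  if (all(x == 0)) {
    rlang::warn("all-zero window passed to l2_normalize; returned unchanged",
                class = "wsgait_degenerate_input")
    return(x)
  }
  out <- x
  for (g in list(1:3, 4:6)) {
    nrm <- sqrt(rowSums(x[, g, drop = FALSE]^2))
    keep <- nrm >= 1e-12
    out[keep, g] <- x[keep, g, drop = FALSE] / nrm[keep]
    out[!keep, g] <- 0
  }
  out
}

#' Cut a continuous stream into fixed-length windows
#'
#' Contiguous slices of `length` rows taken every `stride` rows, no padding:
#' `floor((T - length) / stride) + 1` windows for a T-row stream.
#'
#' @param stream A T x 6 numeric matrix.
#' @param length Window length in samples.
#' @param stride Step between window starts.
#' @return A list of L x 6 matrices (empty, with a warning, if `T < length`).
#' @export
window_stream <- function(stream, length, stride = length) {
  x <- assert_window_matrix(stream, "stream")
  length <- assert_count(length, "length")
  stride <- assert_count(stride, "stride")
  T_ <- nrow(x)
  if (T_ < length) {
    rlang::warn(sprintf("stream of %d rows is shorter than window length %d",
                        T_, length),
                class = "wsgait_degenerate_input")
    return(list())
  }
  starts <- seq(1L, T_ - length + 1L, by = stride)
  lapply(starts, function(s) x[s:(s + length - 1L), , drop = FALSE])
}
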