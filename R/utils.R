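# Internal helpers shared across modules.

channel_names <- function() c("Ax", "Ay", "Az", "Gx", "Gy", "Gz")

stop_invalid <- function(msg, ...) {
  rlang::abort(sprintf(msg, ...), class = "wsgait_invalid_argument")
}

stop_shape <- function(msg, ...) {
  rlang::abort(sprintf(msg, ...), class = "wsgait_shape_error")
}

assert_count <- function(x, name, min = 1L) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x < min || x != floor(x)) {
    stop_invalid("`%s` must be a single integer >= %d (got %s)", name, min,
                 paste(format(x), collapse = ","))
  }
  as.integer(x)
}

assert_window_matrix <- function(x, name = "window") {
  if (inherits(x, "inertial_window")) x <- x$values
  if (!is.matrix(x) || !is.numeric(x)) {
    stop_shape("`%s` must be a numeric matrix with 6 channel columns", name)
  }
  if (ncol(x) != 6L) {
    stop_shape("`%s` must have 6 columns (Ax,Ay,Az,Gx,Gy,Gz); got %d", name, ncol(x))
  }
  if (!all(is.finite(x))) stop_invalid("`%s` contains non-finite values", name)
  x
}

# Run expr under a fixed RNG state without disturbing the caller's stream.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  expr
}

# Derive a well-spread child seed from (seed, stream index); stays < 2^31.
child_seed <- function(seed, index) {
  x <- (as.double(seed) %% 2147483647) + 0
  x <- (x * 48271 + as.double(index) * 16807 + 12345) %% 2147483647
  as.integer(x)
}
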