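# Dataset readers and writers.
#
# Interchange formats: a long CSV (one row per time step, columns
# window_id, subject, t, Ax, Ay, Az, Gx, Gy, Gz) and an RDS array container
# holding `signals` (list of L x 6 matrices) and `labels`.

#' Write a gait dataset to CSV
#'
#' @param data A `gait_dataset`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gait_csv <- function(data, path) {
  stopifnot(inherits(data, "gait_dataset"))
  readr::write_csv(tibble::as_tibble(data), path, progress = FALSE)
  invisible(path)
}

#' Read a gait dataset from CSV
#'
#' Validates the schema (all of `window_id, subject, t, Ax..Gz` present and
#' numeric) and that every window has the same length; violations are
#' reported with the offending columns or window ids.
#'
#' @param path CSV file path.
#' @return A `gait_dataset`.
#' @export
read_gait_csv <- function(path) {
  if (!file.exists(path)) stop_invalid("file not found: %s", path)
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  required <- c("window_id", "subject", "t", channel_names())
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop_invalid("CSV is missing required column(s): %s",
                 paste(missing, collapse = ", "))
  }
  non_num <- required[!vapply(df[required], is.numeric, logical(1))]
  if (length(non_num)) {
    stop_invalid("non-numeric values in column(s): %s",
                 paste(non_num, collapse = ", "))
  }
  df <- dplyr::arrange(df, .data$window_id, .data$t)
  lens <- dplyr::count(df, .data$window_id)
  if (length(unique(lens$n)) > 1L) {
    common <- as.integer(names(sort(table(lens$n), decreasing = TRUE))[1L])
    bad <- lens$window_id[lens$n != common]
    stop_invalid("inconsistent window lengths; offending window_id(s): %s",
                 paste(bad, collapse = ", "))
  }
  split_df <- split(df, df$window_id)
  ids <- as.integer(names(split_df))
  ord <- order(ids)
  signals <- lapply(split_df[ord], function(d) {
    m <- as.matrix(d[, channel_names()])
    dimnames(m) <- list(NULL, channel_names())
    m
  })
  labels <- vapply(split_df[ord], function(d) as.integer(d$subject[1L]), 1L)
  new_gait_dataset(unname(signals), unname(labels))
}

#' Write a gait dataset to an RDS array container
#'
#' @param data A `gait_dataset`.
#' @param path Output `.rds` path.
#' @return `path`, invisibly.
#' @export
write_gait_rds <- function(data, path) {
  stopifnot(inherits(data, "gait_dataset"))
  saveRDS(list(signals = data$signals, labels = data$labels,
               sample_rate = data$sample_rate), path)
  invisible(path)
}

#' Read a gait dataset from an RDS array container
#'
#' @param path `.rds` path written by [write_gait_rds()].
#' @return A `gait_dataset`.
#' @export
read_gait_rds <- function(path) {
  if (!file.exists(path)) stop_invalid("file not found: %s", path)
  obj <- readRDS(path)
  if (!all(c("signals", "labels") %in% names(obj))) {
    stop_invalid("container must hold `signals` and `labels`")
  }
  lens <- vapply(obj$signals, nrow, 1L)
  if (length(unique(lens)) > 1L) {
    stop_invalid("inconsistent window lengths; offending window_id(s): %s",
                 paste(which(lens != lens[1L]), collapse = ", "))
  }
  new_gait_dataset(obj$signals, obj$labels,
                   sample_rate = obj$sample_rate %||% 100)
}

#' Load a gait dataset, dispatching on format
#'
#' @param path File path.
#' @param format `"csv"` or `"rds"`; inferred from the extension by default.
#' @return A `gait_dataset`.
#' @export
load_gait_dataset <- function(path, format = c("auto", "csv", "rds")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.rds$", path, ignore.case = TRUE)) "rds" else "csv"
  }
  switch(format, csv = read_gait_csv(path), rds = read_gait_rds(path))
}
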