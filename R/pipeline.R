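# End-to-end pipeline: simulate (optional) -> preprocess -> train -> evaluate,
# with every artifact written under one run directory.

#' Assemble a pipeline run configuration
#'
#' A single nested list mirrors the YAML config consumed by the command-line
#' interface; every field has a default so partial configs are valid.
#'
#' @param simulate List of [simulate_gait()] arguments (used when no `data`
#'   path is given): `n_subjects`, `windows_per_subject`, `length`,
#'   `covariate`, `magnitude`, `noise_sd`.
#' @param data Optional path to an existing dataset (CSV or RDS); overrides
#'   simulation.
#' @param scales Scale factors for the model.
#' @param probe_fraction Fraction of windows (stratified per subject) held
#'   out as the probe set.
#' @param train Named overrides for [train_config()].
#' @param model Named overrides for [wmscnn_spec()] (`fused_dim`,
#'   `fusion_dropout`, `ws`).
#' @param seed Master seed for the run.
#' @param out Output directory (created); `NULL` keeps artifacts in memory.
#' @return A `run_config` list.
#' @export
run_config <- function(simulate = list(), data = NULL, scales = 2:5,
                       probe_fraction = 0.25, train = list(), model = list(),
                       seed = 1, out = NULL) {
  sim_defaults <- list(n_subjects = 10, windows_per_subject = 40,
                       length = 200, covariate = "none", magnitude = 0,
                       noise_sd = 0.1)
  sim <- utils::modifyList(sim_defaults, simulate)
  structure(list(simulate = sim, data = data, scales = scales,
                 probe_fraction = probe_fraction, train = train,
                 model = model, seed = assert_count(seed, "seed", min = 0L),
                 out = out),
            class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose top-level keys match [run_config()] arguments.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop_invalid("config file not found: %s", path)
  do.call(run_config, yaml::read_yaml(path))
}

#' Stratified gallery/probe split
#'
#' Holds out a fraction of each subject's windows (at least one, never all)
#' as the probe set; the rest form the enrolled gallery.
#'
#' @param data A `gait_dataset`.
#' @param probe_fraction Fraction of each subject's windows assigned to the
#'   probe set.
#' @param seed Integer seed for the draw.
#' @return A list with `gallery` and `probe` datasets.
#' @export
split_gallery_probe <- function(data, probe_fraction = 0.25, seed = 1) {
  probe_idx <- with_seed(seed, {
    idx <- integer(0)
    for (cl in sort(unique(data$labels))) {
      ids <- which(data$labels == cl)
      n_probe <- max(1L, round(probe_fraction * length(ids)))
      n_probe <- min(n_probe, length(ids) - 1L)
      idx <- c(idx, sample(ids, n_probe))
    }
    sort(idx)
  })
  gal_idx <- setdiff(seq_along(data$labels), probe_idx)
  list(
    gallery = new_gait_dataset(data$signals[gal_idx], data$labels[gal_idx],
                               sample_rate = data$sample_rate,
                               split = "gallery"),
    probe = new_gait_dataset(data$signals[probe_idx], data$labels[probe_idx],
                             sample_rate = data$sample_rate, split = "probe")
  )
}

#' Run the full gait-recognition pipeline
#'
#' Simulates (or loads) a dataset, splits it into gallery and probe sets,
#' L2-normalizes, trains the weighted multi-scale network on the gallery, and
#' evaluates identification and verification on the probe set. When
#' `config$out` is set, the resolved config, seed, per-epoch training log,
#' model checkpoint and JSON report are all written there, which is
#' sufficient to reproduce the run.
#'
#' @param config A [run_config()].
#' @param verbose Print training progress.
#' @return A list with `fit` (`wmscnn_fit`), `eval` (`gait_eval`), `gallery`
#'   and `probe` datasets.
#' @export
run_gait_pipeline <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "run_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      rlang::abort(sprintf("pipeline stage '%s' failed: %s", name,
                           conditionMessage(e)), parent = e)
    })
  }
  data <- stage("data", {
    if (!is.null(config$data)) {
      load_gait_dataset(config$data)
    } else {
      sim <- config$simulate
      simulate_gait(sim$n_subjects, sim$windows_per_subject,
                    length = sim$length,
                    covariate = covariate_spec(sim$covariate, sim$magnitude),
                    noise_sd = sim$noise_sd, seed = config$seed)
    }
  })
  for (tau in config$scales) {
    if (tau > data$length) {
      stop_invalid("scale tau = %d exceeds window length %d", tau,
                   data$length)
    }
  }
  sets <- stage("split",
                split_gallery_probe(data, config$probe_fraction, config$seed))
  fit <- stage("train", {
    ctrl <- do.call(train_config,
                    utils::modifyList(list(seed = config$seed), config$train))
    spec <- do.call(wmscnn_spec,
                    utils::modifyList(list(scales = config$scales,
                                           input_length = data$length),
                                      config$model))
    fit_wmscnn(sets$gallery, model = spec, control = ctrl, verbose = verbose)
  })
  report <- stage("evaluate", evaluate_gait(fit, sets$probe, sets$gallery))
  if (!is.null(config$out)) {
    stage("write", {
      dir.create(config$out, recursive = TRUE, showWarnings = FALSE)
      cfg <- config
      cfg$out <- NULL
      yaml::write_yaml(unclass(cfg), file.path(config$out, "config.yaml"))
      readr::write_csv(fit$history, file.path(config$out, "training_log.csv"),
                       progress = FALSE)
      saveRDS(fit, file.path(config$out, "checkpoint.rds"))
      jsonlite::write_json(
        list(seed = config$seed, rank1_ir = report$rank1_ir,
             rank5_ir = report$rank5_ir,
             vr_at_far = as.list(report$vr_at_far)),
        file.path(config$out, "report.json"), auto_unbox = TRUE, digits = NA)
      if (!is.null(report$roc)) {
        readr::write_csv(report$roc, file.path(config$out, "roc.csv"),
                         progress = FALSE)
      }
    })
  }
  list(fit = fit, eval = report, gallery = sets$gallery, probe = sets$probe)
}
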