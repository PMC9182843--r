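# Synthetic quasi-periodic gait-signal generator.
#
# Each subject is a fixed harmonic signature: 3-5 harmonics of a base cadence
# per channel, with subject-specific amplitudes and phases. Windows of the same
# subject differ by additive Gaussian noise plus small cadence/phase jitter, so
# inter-subject separability is controlled in closed form.

#' Covariate perturbation specification
#'
#' Describes a nuisance condition applied to a gait window, emulating the
#' conditions under which smartphone gait data are collected: walking faster,
#' carrying a load on one side, or a hand in the pocket damping arm swing.
#'
#' @param kind One of `"none"`, `"fast_walk"`, `"load_left"`, `"load_right"`,
#'   `"pocket_hand"`, `"mixed"`. `"mixed"` picks one of the other perturbations
#'   at random per window.
#' @param magnitude Perturbation strength in `[0, 1]`.
#' @return A `covariate_spec` object.
#' @export
#' @examples
#' covariate_spec("pocket_hand", magnitude = 0.5)
covariate_spec <- function(kind = c("none", "fast_walk", "load_left",
                                    "load_right", "pocket_hand", "mixed"),
                           magnitude = 0) {
  kind <- match.arg(kind)
  if (!is.numeric(magnitude) || length(magnitude) != 1L ||
      is.na(magnitude) || magnitude < 0 || magnitude > 1) {
    stop_invalid("`magnitude` must be a single number in [0, 1]")
  }
  structure(list(kind = kind, magnitude = as.numeric(magnitude)),
            class = "covariate_spec")
}

#' @export
print.covariate_spec <- function(x, ...) {
  cat(sprintf("<covariate_spec> kind = %s, magnitude = %.3g\n",
              x$kind, x$magnitude))
  invisible(x)
}

# Per-channel fundamental amplitude template; vertical acceleration dominates
# and Az carries a gravity offset of 1 (unitless, pre-normalization).
gait_amplitude_template <- function() {
  list(base_amp = c(0.40, 0.40, 0.60, 0.50, 0.50, 0.45),
       dc = c(0, 0, 1, 0, 0, 0))
}

#' Draw reproducible per-subject gait signatures
#'
#' Each subject gets an independent seeded draw, so subject `i` is identical
#' across calls regardless of `n_subjects`.
#'
#' @param n_subjects Number of subjects (>= 2).
#' @param noise_sd Standard deviation of the additive window noise (unitless).
#' @param signature_scale Spread of per-subject deviations from the common
#'   amplitude template; larger values give more separable subjects.
#' @param seed Integer seed.
#' @return A list of `subject_profile` objects.
#' @export
gait_profiles <- function(n_subjects, noise_sd = 0.1, signature_scale = 1,
                          seed = 1) {
  n_subjects <- assert_count(n_subjects, "n_subjects", min = 2L)
  if (noise_sd < 0) stop_invalid("`noise_sd` must be >= 0")
  tmpl <- gait_amplitude_template()
  lapply(seq_len(n_subjects), function(i) {
    with_seed(child_seed(seed, i), {
      n_harm <- sample(3:5, 1L)
      amp <- matrix(0, nrow = 6L, ncol = n_harm)
      for (h in seq_len(n_harm)) {
        amp[, h] <- pmax(0, tmpl$base_amp / h +
                           signature_scale * 0.3 * rnorm(6L))
      }
      structure(list(
        subject_id = i,
        harmonic_amplitudes = amp,
        harmonic_phases = matrix(runif(6L * n_harm, 0, 2 * pi), nrow = 6L),
        base_cadence = runif(1L, 1.6, 2.2),
        noise_sd = noise_sd,
        dc = tmpl$dc
      ), class = "subject_profile")
    })
  })
}

# Render one noiseless window for a profile at a given cadence multiplier and
# fundamental phase offset; t in seconds at `sample_rate` Hz.
render_window <- function(profile, length, sample_rate = 100,
                          cadence_factor = 1, phase_offset = 0) {
  t <- (seq_len(length) - 1L) / sample_rate
  f0 <- profile$base_cadence * cadence_factor
  n_harm <- ncol(profile$harmonic_amplitudes)
  x <- matrix(rep(profile$dc, each = length), nrow = length)
  for (h in seq_len(n_harm)) {
    arg <- outer(2 * pi * f0 * h * t, rep(1, 6L)) + h * phase_offset
    arg <- sweep(arg, 2L, profile$harmonic_phases[, h], "+")
    x <- x + sweep(sin(arg), 2L, profile$harmonic_amplitudes[, h], "*")
  }
  colnames(x) <- channel_names()
  x
}

#' Generate a labeled synthetic gait dataset
#'
#' Produces `n_subjects * windows_per_subject` fixed-length 6-channel windows
#' (accelerometer Ax,Ay,Az then gyroscope Gx,Gy,Gz). Windows of one subject
#' share the subject's harmonic signature and differ by seeded Gaussian noise
#' and small cadence/phase jitter; an optional covariate perturbation is
#' applied to every window.
#'
#' @inheritParams gait_profiles
#' @param windows_per_subject Windows generated per subject.
#' @param length Samples per window (>= 32); 200 by default, i.e. 2 s at
#'   100 Hz.
#' @param covariate A [covariate_spec()].
#' @param sample_rate Sampling rate in Hz used for the time axis.
#' @param cadence_jitter Per-window relative cadence perturbation (uniform in
#'   `[-cadence_jitter, cadence_jitter]`).
#' @param phase_jitter Per-window fundamental phase perturbation in radians.
#' @return A `gait_dataset`: list of window matrices, integer subject labels
#'   (1-based), and the generating profiles.
#' @export
#' @examples
#' ds <- simulate_gait(3, 4, length = 200, seed = 7)
#' ds
simulate_gait <- function(n_subjects, windows_per_subject, length = 200,
                          covariate = covariate_spec("none"),
                          noise_sd = 0.1, signature_scale = 1, seed = 1,
                          sample_rate = 100, cadence_jitter = 0.02,
                          phase_jitter = 0.15) {
  n_subjects <- assert_count(n_subjects, "n_subjects", min = 2L)
  windows_per_subject <- assert_count(windows_per_subject,
                                      "windows_per_subject", min = 1L)
  length <- assert_count(length, "length", min = 32L)
  stopifnot(inherits(covariate, "covariate_spec"))

  profiles <- gait_profiles(n_subjects, noise_sd = noise_sd,
                            signature_scale = signature_scale, seed = seed)
  n_total <- n_subjects * windows_per_subject
  labels <- rep(seq_len(n_subjects), each = windows_per_subject)
  signals <- vector("list", n_total)
  for (w in seq_len(n_total)) {
    p <- profiles[[labels[w]]]
    sig <- with_seed(child_seed(seed, n_subjects + w), {
      cf <- 1 + runif(1L, -cadence_jitter, cadence_jitter)
      ph <- runif(1L, -phase_jitter, phase_jitter)
      x <- render_window(p, length, sample_rate, cf, ph)
      x + matrix(rnorm(length * 6L, sd = p$noise_sd), nrow = length)
    })
    if (covariate$kind != "none") {
      sig <- apply_covariate(sig, covariate,
                             seed = child_seed(seed, 2L * n_total + w))
    }
    signals[[w]] <- sig
  }
  new_gait_dataset(signals, labels,
                   profiles = profiles, sample_rate = sample_rate)
}

new_gait_dataset <- function(signals, labels, profiles = NULL,
                             sample_rate = 100, split = NULL) {
  stopifnot(length(signals) == length(labels))
  structure(list(
    signals = signals,
    labels = as.integer(labels),
    n_subjects = if (length(labels)) max(labels) else 0L,
    length = if (length(signals)) nrow(signals[[1L]]) else 0L,
    sample_rate = sample_rate,
    profiles = profiles,
    split = split
  ), class = "gait_dataset")
}

#' @export
print.gait_dataset <- function(x, ...) {
  cat(sprintf(
    "<gait_dataset> %d windows x %d steps x 6 channels, %d subjects%s\n",
    length(x$signals), x$length, x$n_subjects,
    if (!is.null(x$split)) paste0(" [", x$split, "]") else ""))
  invisible(x)
}

#' @export
length.gait_dataset <- function(x) length(x$signals)

#' Coerce a gait dataset to a tibble
#'
#' One row per time step per window, with the CSV interchange schema
#' `window_id, subject, t, Ax..Gz`.
#'
#' @param x A `gait_dataset`.
#' @param ... Unused.
#' @export
as_tibble.gait_dataset <- function(x, ...) {
  purrr::map2_dfr(x$signals, seq_along(x$signals), function(sig, id) {
    out <- tibble::as_tibble(as.data.frame(sig))
    out$window_id <- id
    out$subject <- x$labels[id]
    out$t <- seq_len(nrow(sig)) - 1L
    dplyr::select(out, "window_id", "subject", "t", dplyr::all_of(channel_names()))
  })
}

#' Apply a covariate perturbation to a window
#'
#' Physical mappings: `fast_walk` compresses the waveform period by a factor
#' `1 + magnitude / 2` via linear resampling (periodic extension);
#' `load_left` / `load_right` add a constant accelerometer bias and scale the
#' accelerometer fluctuation amplitude asymmetrically; `pocket_hand` attenuates
#' the gyroscope channels by `1 - magnitude / 2`; `none` is the identity.
#'
#' @param window An L x 6 numeric matrix (or `inertial_window`).
#' @param spec A [covariate_spec()].
#' @param seed Seed used only by `kind = "mixed"` to pick the perturbation.
#' @return A perturbed window matrix of the same shape.
#' @export
apply_covariate <- function(window, spec, seed = 1) {
  x <- assert_window_matrix(window)
  stopifnot(inherits(spec, "covariate_spec"))
  m <- spec$magnitude
  kind <- spec$kind
  if (kind == "mixed") {
    kind <- with_seed(seed, sample(c("fast_walk", "load_left", "load_right",
                                     "pocket_hand"), 1L))
  }
  out <- switch(kind,
    none = x,
    fast_walk = {
      factor <- 1 + 0.5 * m
      L <- nrow(x)
      xe <- rbind(x, x)  # periodic extension for indices past the window end
      idx <- 1 + (seq_len(L) - 1L) * factor
      apply(xe, 2L, function(col) approx(seq_len(2L * L), col, xout = idx)$y)
    },
    load_left = load_bias(x, m, side = -1),
    load_right = load_bias(x, m, side = +1),
    pocket_hand = {
      x[, 4:6] <- x[, 4:6] * (1 - 0.5 * m)
      x
    },
    stop_invalid("unknown covariate kind '%s'", kind)
  )
  colnames(out) <- channel_names()
  out
}

# Constant bias plus asymmetric amplitude scaling on accelerometer channels.
load_bias <- function(x, m, side) {
  acc <- x[, 1:3, drop = FALSE]
  mu <- colMeans(acc)
  acc <- sweep(sweep(acc, 2L, mu, "-") * (1 + side * 0.2 * m), 2L, mu, "+")
  acc <- acc + side * 0.3 * m
  x[, 1:3] <- acc
  x
}
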