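# Synthetic labeled ECG generator.
#
# Beats are sums of gaussian bumps for the P, Q, R, S and T waves. The three
# classes reproduce the morphological contrasts the classifier exploits:
#   N - normal sinus beat: all five waves, narrow QRS, upright T;
#   V - premature ventricular contraction: no P wave, QRS widened 2.5x,
#       inverted T;
#   L - left bundle branch block: QRS widened 1.8x with a notched R wave and
#       discordant (inverted) T.
# No claim of physiological fidelity is made; see the methods vignette.

BEAT_CLASSES <- c("N", "V", "L")

#' Morphology parameters for a synthetic beat class
#'
#' @param class_label one of `"N"`, `"V"`, `"L"`.
#' @return an object of class `morphology_params`: per-wave amplitudes (mV),
#'   centers (seconds relative to the R peak), widths (gaussian sigma,
#'   seconds), QRS width scale, P-wave presence flag, T polarity and a
#'   notched-R flag.
#' @examples
#' p <- morphology_params("V")
#' p$p_present  # FALSE: PVCs carry no P wave
#' @export
morphology_params <- function(class_label = "N") {
  if (length(class_label) != 1L || !class_label %in% BEAT_CLASSES) {
    abort("invalid class label '%s': must be one of %s",
          as.character(class_label)[1], paste(BEAT_CLASSES, collapse = ", "))
  }
  base <- list(
    class_label = class_label,
    wave_amplitudes = c(P = 0.12, Q = -0.10, R = 1.00, S = -0.20, T = 0.30),
    wave_centers    = c(P = -0.150, Q = -0.025, R = 0.000, S = 0.030, T = 0.220),
    wave_widths     = c(P = 0.020, Q = 0.008, R = 0.011, S = 0.009, T = 0.045),
    qrs_width_scale = 1,
    p_present = TRUE,
    t_polarity = +1,
    notch_r = FALSE
  )
  if (class_label == "V") {
    base$p_present <- FALSE
    base$qrs_width_scale <- 2.5
    base$t_polarity <- -1
    base$wave_amplitudes[["R"]] <- 1.10
    base$wave_amplitudes[["T"]] <- 0.40
  } else if (class_label == "L") {
    base$qrs_width_scale <- 1.8
    base$t_polarity <- -1
    base$notch_r <- TRUE
  }
  validate_morphology(base)
  structure(base, class = "morphology_params")
}

validate_morphology <- function(p) {
  if (!is.character(p$class_label) || !(p$class_label %in% BEAT_CLASSES)) {
    abort("invalid class label '%s': must be one of %s",
          as.character(p$class_label)[1], paste(BEAT_CLASSES, collapse = ", "))
  }
  if (any(p$wave_widths <= 0)) abort("wave_widths must all be positive")
  if (p$class_label %in% c("V", "L") && p$qrs_width_scale < 1) {
    abort("qrs_width_scale must be >= 1 for wide-QRS classes V and L")
  }
  if (p$class_label == "V" && isTRUE(p$p_present)) {
    abort("class V beats must have p_present = FALSE")
  }
  invisible(p)
}

# continuous-time beat morphology evaluated at times t (seconds from R peak);
# jitter: named list of per-wave amplitude and width multipliers (or NULL)
beat_waveform <- function(t, params, jitter = NULL) {
  amp <- params$wave_amplitudes
  cen <- params$wave_centers
  wid <- params$wave_widths
  qrs <- c("Q", "R", "S")
  wid[qrs] <- wid[qrs] * params$qrs_width_scale
  # Q/S move outward with the widening, but less than proportionally, so the
  # whole complex stays clear of the P search window
  cen[qrs] <- cen[qrs] * (1 + (params$qrs_width_scale - 1) / 2)
  amp[["T"]] <- abs(amp[["T"]]) * params$t_polarity
  if (!params$p_present) amp[["P"]] <- 0
  if (!is.null(jitter)) {
    amp <- amp * jitter$amp
    wid <- wid * jitter$width
  }
  y <- numeric(length(t))
  for (wv in names(amp)) {
    if (amp[[wv]] != 0) y <- y + amp[[wv]] * exp(-(t - cen[[wv]])^2 / (2 * wid[[wv]]^2))
  }
  if (isTRUE(params$notch_r)) {
    # notch: narrow dip on the right shoulder of the widened R wave
    wr <- params$wave_widths[["R"]] * params$qrs_width_scale
    ar <- amp[["R"]]
    y <- y - 0.25 * abs(ar) * exp(-(t - 0.9 * wr)^2 / (2 * (0.35 * wr)^2))
  }
  y
}

# per-beat morphological jitter (~5% amplitude, ~3% width), seeded
beat_jitter <- function(n_waves = 5L) {
  list(amp = exp(stats::rnorm(n_waves, 0, 0.05)),
       width = exp(stats::rnorm(n_waves, 0, 0.03)))
}

#' Generate one synthetic beat window
#'
#' Returns a window of exactly `d` samples with the R peak at the center
#' index `(d + 1) / 2`, built as a sum of gaussian waves plus small seeded
#' beat-to-beat amplitude/width jitter. Deterministic given `seed`.
#'
#' @param params a [morphology_params()] object (or a class label string).
#' @param fs sampling rate in Hz (>= 120).
#' @param seed integer seed driving the morphological jitter.
#' @param d window length in samples (odd; default 201, i.e. the R sample
#'   plus 100 samples on each side at 360 Hz).
#' @return numeric vector of length `d` (mV), with attributes `label` and
#'   `r_center` (the 1-based center index).
#' @examples
#' b <- generate_beat(morphology_params("N"), fs = 360, seed = 1)
#' which.max(b) == 101
#' @export
generate_beat <- function(params, fs = 360, seed = 1L, d = 201L) {
  if (is.character(params)) params <- morphology_params(params)
  validate_morphology(params)
  if (fs < 120) abort("fs must be >= 120 Hz (got %g)", fs)
  if (d %% 2L == 0L) abort("window length d must be odd (got %d)", d)
  half <- (d - 1L) %/% 2L
  t <- (seq_len(d) - (half + 1L)) / fs
  jit <- with_seed(seed, beat_jitter())
  names(jit$amp) <- names(jit$width) <- names(params$wave_amplitudes)
  y <- beat_waveform(t, params, jit)
  structure(y, label = params$class_label, r_center = half + 1L)
}

#' Specification of a synthetic ECG record
#'
#' @param n_beats number of beats (>= 1).
#' @param class_mix named probabilities over N, V, L (sum to 1). Default:
#'   the MIT-BIH census proportions of the three classes.
#' @param fs sampling rate (Hz).
#' @param rr_mean,rr_jitter mean and standard deviation of the RR interval
#'   (seconds).
#' @param noise_rms additive white gaussian noise level (mV RMS).
#' @param baseline_amp,baseline_freq sinusoidal baseline wander amplitude
#'   (mV) and frequency (Hz).
#' @param seed integer seed; the full record is deterministic given the spec.
#' @param d beat window length in samples.
#' @return an object of class `record_spec`.
#' @export
record_spec <- function(n_beats = 3000L,
                        class_mix = c(N = 74064, V = 6608, L = 8032) / 88704,
                        fs = 360, rr_mean = 0.8, rr_jitter = 0.05,
                        noise_rms = 0.03, baseline_amp = 0.05,
                        baseline_freq = 0.3, seed = 1L, d = 201L) {
  if (fs <= 0) abort("fs must be positive")
  if (n_beats < 1) abort("n_beats must be >= 1")
  if (any(class_mix < 0) || abs(sum(class_mix) - 1) > 1e-9) {
    abort("class_mix entries must be nonnegative and sum to 1")
  }
  if (is.null(names(class_mix))) names(class_mix) <- BEAT_CLASSES
  structure(list(n_beats = as.integer(n_beats), class_mix = class_mix,
                 fs = fs, rr_mean = rr_mean, rr_jitter = rr_jitter,
                 noise_rms = noise_rms, baseline_amp = baseline_amp,
                 baseline_freq = baseline_freq, seed = as.integer(seed),
                 d = as.integer(d)),
            class = "record_spec")
}

#' Generate a synthetic annotated ECG record
#'
#' Beats are placed sequentially with jittered RR intervals (clipped so that
#' consecutive beat windows never overlap), then white noise and a sinusoidal
#' baseline wander are added. Annotations give the true R sample of each
#' beat and its class.
#'
#' @param spec a [record_spec()].
#' @return list of class `ecg_record` with elements `signal` (mV), `fs`,
#'   `annotations` (data.frame: `r_index`, `label`) and `source_id`.
#' @export
generate_record <- function(spec = record_spec()) {
  stopifnot(inherits(spec, "record_spec"))
  d <- spec$d
  half <- (d - 1L) %/% 2L
  min_rr <- (d + 1L) / spec$fs
  if (spec$rr_mean < min_rr) {
    abort("rr_mean (%.3f s) shorter than the beat window (%.3f s at fs=%g)",
          spec$rr_mean, min_rr, spec$fs)
  }
  with_seed(spec$seed, {
    labels <- sample(BEAT_CLASSES, spec$n_beats, replace = TRUE,
                     prob = spec$class_mix)
    rr <- stats::rnorm(spec$n_beats, spec$rr_mean, spec$rr_jitter)
    rr <- pmax(rr, min_rr)
    r_idx <- half + 1L + cumsum(c(0, round(rr[-spec$n_beats] * spec$fs)))
    r_idx <- as.integer(r_idx)
    n <- r_idx[spec$n_beats] + half + as.integer(round(0.2 * spec$fs))
    sig <- numeric(n)
    beat_seeds <- sample.int(.Machine$integer.max, spec$n_beats)
    for (i in seq_len(spec$n_beats)) {
      w <- generate_beat(labels[i], fs = spec$fs, seed = beat_seeds[i], d = d)
      sig[(r_idx[i] - half):(r_idx[i] + half)] <- as.numeric(w)
    }
    if (spec$noise_rms > 0) sig <- sig + stats::rnorm(n, 0, spec$noise_rms)
    if (spec$baseline_amp > 0) {
      ph <- stats::runif(1, 0, 2 * pi)
      sig <- sig + spec$baseline_amp *
        sin(2 * pi * spec$baseline_freq * seq_len(n) / spec$fs + ph)
    }
    structure(list(signal = sig, fs = spec$fs,
                   annotations = data.frame(r_index = r_idx, label = labels,
                                            stringsAsFactors = FALSE),
                   source_id = sprintf("synthetic-seed%d", spec$seed)),
              class = "ecg_record")
  })
}

#' Stratified fold assignment
#'
#' Assigns each item a fold id such that, per class, fold counts differ by at
#' most one; remainder items go to the lowest-numbered folds. The per-class
#' permutation is random (seeded by the caller's RNG state).
#'
#' @param labels class label vector.
#' @param folds number of folds (>= 2).
#' @return integer fold ids in `1:folds`.
#' @export
stratify_folds <- function(labels, folds = 4L) {
  if (folds < 2) abort("folds must be >= 2")
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    if (length(idx) < folds) {
      abort("class '%s' has %d beats, fewer than %d folds", cl, length(idx), folds)
    }
    base <- length(idx) %/% folds
    rem <- length(idx) %% folds
    sizes <- base + as.integer(seq_len(folds) <= rem)
    fold[sample(idx)] <- rep(seq_len(folds), times = sizes)
  }
  fold
}

#' Generate a labeled beat dataset with stratified folds
#'
#' Generates `spec$n_beats` beat windows directly (noise and a random-phase
#' baseline-wander segment added per window) and assigns stratified fold ids.
#'
#' @param spec a [record_spec()].
#' @param folds number of cross-validation folds (default 4).
#' @return object of class `beat_set`: list with `windows` (n x d matrix),
#'   `labels` (character), `fold` (integer), `fs`, `d`.
#' @export
generate_dataset <- function(spec = record_spec(), folds = 4L) {
  stopifnot(inherits(spec, "record_spec"))
  d <- spec$d
  half <- (d - 1L) %/% 2L
  with_seed(spec$seed, {
    labels <- sample(BEAT_CLASSES, spec$n_beats, replace = TRUE,
                     prob = spec$class_mix)
    beat_seeds <- sample.int(.Machine$integer.max, spec$n_beats)
    X <- matrix(0, nrow = spec$n_beats, ncol = d)
    tt <- seq_len(d) / spec$fs
    for (i in seq_len(spec$n_beats)) {
      w <- as.numeric(generate_beat(labels[i], fs = spec$fs,
                                    seed = beat_seeds[i], d = d))
      if (spec$noise_rms > 0) w <- w + stats::rnorm(d, 0, spec$noise_rms)
      if (spec$baseline_amp > 0) {
        ph <- stats::runif(1, 0, 2 * pi)
        w <- w + spec$baseline_amp * sin(2 * pi * spec$baseline_freq * tt + ph)
      }
      X[i, ] <- w
    }
    fold <- stratify_folds(labels, folds)
    structure(list(windows = X, labels = labels, fold = fold,
                   fs = spec$fs, d = d),
              class = "beat_set")
  })
}

#' @export
print.beat_set <- function(x, ...) {
  cat(sprintf("<beat_set> %d beats x %d samples, classes: %s\n",
              nrow(x$windows), x$d,
              paste(sprintf("%s=%d", names(table(x$labels)),
                            as.integer(table(x$labels))), collapse = " ")))
  invisible(x)
}

#' @export
print.ecg_record <- function(x, ...) {
  cat(sprintf("<ecg_record> %d samples at %g Hz, %d annotated beats (%s)\n",
              length(x$signal), x$fs, nrow(x$annotations), x$source_id))
  invisible(x)
}
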