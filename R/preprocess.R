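# Signal conditioning ahead of feature extraction: morphological baseline
# removal, wavelet R-peak detection, fixed-length beat segmentation.

#' Construct an ECG record container
#'
#' @param samples numeric voltage series (mV).
#' @param fs sampling rate (Hz).
#' @param source_id free-text provenance tag.
#' @param annotations optional data.frame with columns `r_index`, `label`.
#' @return object of class `ecg_record`.
#' @export
ecg_record <- function(samples, fs, source_id = "", annotations = NULL) {
  if (fs <= 0) abort("fs must be positive")
  if (!all(is.finite(samples))) abort("samples must be finite")
  structure(list(signal = as.numeric(samples), fs = fs,
                 annotations = annotations, source_id = source_id),
            class = "ecg_record")
}

#' Remove baseline wander with morphological operators
#'
#' Estimates the baseline by a morphological opening (flat structuring
#' element of 0.2 s, suppressing peaks) followed by a closing (0.28 s,
#' filling valleys) and subtracts it. The element widths bracket the QRS and
#' T-wave durations, so heartbeat morphology passes through while sub-1-Hz
#' drift is absorbed into the baseline estimate.
#'
#' @param record an `ecg_record`.
#' @param open_sec,close_sec structuring element widths (seconds).
#' @return the filtered `ecg_record`.
#' @export
baseline_filter <- function(record, open_sec = 0.2, close_sec = 0.28) {
  stopifnot(inherits(record, "ecg_record"))
  w1 <- odd_window(open_sec, record$fs)
  w2 <- odd_window(close_sec, record$fs)
  if (length(record$signal) < max(w1, w2)) {
    abort("record (%d samples) shorter than the largest structuring element (%d)",
          length(record$signal), max(w1, w2))
  }
  baseline <- morph_close(morph_open(record$signal, w1), w2)
  out <- record
  out$signal <- record$signal - baseline
  out
}

#' Detect R peaks with a dyadic-wavelet modulus-maxima detector
#'
#' Candidate beats are regions where the scale-2^3 detail coefficients exceed
#' an adaptive threshold (`threshold_factor` times the trailing RMS of those
#' coefficients over `rms_window` seconds). Each candidate must show a
#' modulus-maxima pair of opposite sign at scale 2^2; the R peak is placed at
#' the dominant local extremum of the signal between/around the pair. A
#' refractory period suppresses the smaller of two detections closer than
#' `refractory` seconds.
#'
#' @param record an `ecg_record` (expected baseline-filtered).
#' @param threshold_factor multiplier on the trailing RMS (default 0.6, which
#'   keeps a >5x margin to the smallest QRS modulus while rejecting
#'   broadband noise bursts).
#' @param refractory refractory period in seconds (default 0.2).
#' @param rms_window trailing RMS window in seconds (default 2).
#' @return integer vector of strictly increasing R sample indices.
#' @export
detect_r_peaks <- function(record, threshold_factor = 0.6, refractory = 0.2,
                           rms_window = 2) {
  stopifnot(inherits(record, "ecg_record"))
  x <- record$signal
  fs <- record$fs
  n <- length(x)
  if (n < 16L || all(x == x[1])) return(integer(0))
  dec <- atrous_dwt(x, scales = 3L)
  w3 <- dec$w[[3]]
  w2 <- dec$w[[2]]

  # causal trailing RMS (cumulative sums; window clipped at the start)
  wlen <- max(8L, as.integer(round(rms_window * fs)))
  trailing_rms <- function(w) {
    cs <- cumsum(w^2)
    lead <- c(rep(0, wlen), cs[1:(n - wlen)])
    cnt <- pmin(seq_len(n), wlen)
    sqrt(pmax(cs - lead, 0) / cnt)
  }
  thr <- pmax(threshold_factor * trailing_rms(w3), 1e-3 * max(abs(w3)))
  thr2 <- pmax(threshold_factor * trailing_rms(w2), 1e-3 * max(abs(w2)))

  above <- abs(w3) > thr
  if (!any(above)) return(integer(0))
  # merge candidate runs separated by < 60 ms
  gap <- as.integer(round(0.06 * fs))
  idx <- which(above)
  brk <- c(TRUE, diff(idx) > gap)
  grp <- cumsum(brk)
  half_srch <- as.integer(round(0.05 * fs))
  peaks <- integer(0)
  mods <- numeric(0)
  for (g in unique(grp)) {
    seg <- idx[grp == g]
    a <- max(1L, min(seg) - half_srch)
    b <- min(n, max(seg) + half_srch)
    # require an opposite-signed modulus-maxima pair at scale 2^2, both
    # significant against the adaptive scale-2^2 background
    mm <- local_modmax(w2, a, b,
                       thr = max(0.1 * max(abs(w2[a:b])), thr2[min(b, n)]))
    if (length(mm) < 2L || length(unique(sign(w2[mm]))) < 2L) next
    r <- (a:b)[which.max(abs(x[a:b]))]
    peaks <- c(peaks, r)
    mods <- c(mods, max(abs(w3[a:b])))
  }
  if (!length(peaks)) return(integer(0))
  # T-wave rejection: a candidate within 360 ms of the previous accepted peak
  # whose scale-2^3 modulus is below half the previous one's is a T wave
  ord <- order(peaks)
  peaks <- peaks[ord]
  mods <- mods[ord]
  twin <- as.integer(round(0.36 * fs))
  keepT <- rep(TRUE, length(peaks))
  last <- NA_integer_
  for (i in seq_along(peaks)) {
    if (!is.na(last) && peaks[i] - peaks[last] < twin && mods[i] < 0.5 * mods[last]) {
      keepT[i] <- FALSE
    } else {
      last <- i
    }
  }
  peaks <- peaks[keepT]
  # refractory: keep the larger-amplitude of detections closer than refractory
  peaks <- sort(unique(peaks))
  ref <- as.integer(round(refractory * fs))
  keep <- rep(TRUE, length(peaks))
  i <- 1L
  while (i < length(peaks)) {
    j <- i + 1L
    while (j <= length(peaks) && keep[i] && peaks[j] - peaks[i] < ref) {
      if (abs(x[peaks[j]]) > abs(x[peaks[i]])) keep[i] <- FALSE else keep[j] <- FALSE
      j <- j + 1L
    }
    i <- if (keep[i]) j else i + 1L
  }
  peaks[keep]
}

#' Cut fixed-length beat windows around detected R peaks
#'
#' Each window spans `(d-1)/2` samples on either side of its R peak. Peaks
#' whose window would cross a record boundary are skipped; their count is
#' reported in the `skipped` attribute.
#'
#' @param record an `ecg_record`.
#' @param peaks integer R sample indices.
#' @param d window length (odd, default 201).
#' @param labels optional per-peak class labels.
#' @return a `beat_set` whose `r_index` maps each window center back to the
#'   source record; attribute `skipped` counts dropped edge beats.
#' @export
segment_beats <- function(record, peaks, d = 201L, labels = NULL) {
  stopifnot(inherits(record, "ecg_record"))
  if (d %% 2L == 0L) abort("d must be odd")
  n <- length(record$signal)
  half <- (d - 1L) %/% 2L
  peaks <- as.integer(peaks)
  ok <- peaks - half >= 1L & peaks + half <= n
  kept <- peaks[ok]
  X <- matrix(0, nrow = length(kept), ncol = d)
  for (i in seq_along(kept)) {
    X[i, ] <- record$signal[(kept[i] - half):(kept[i] + half)]
  }
  out <- structure(list(windows = X,
                        labels = if (!is.null(labels)) labels[ok] else NULL,
                        fold = NULL, r_index = kept,
                        fs = record$fs, d = d),
                   class = "beat_set")
  attr(out, "skipped") <- sum(!ok)
  out
}

# match detected peaks to truth within tol samples; returns sensitivity, ppv
match_peaks <- function(detected, truth, tol) {
  used <- rep(FALSE, length(detected))
  tp <- 0L
  for (r in truth) {
    dists <- abs(detected - r)
    dists[used] <- Inf
    j <- which.min(dists)
    if (length(j) && is.finite(dists[j]) && dists[j] <= tol) {
      tp <- tp + 1L
      used[j] <- TRUE
    }
  }
  c(sensitivity = if (length(truth)) tp / length(truth) else NA_real_,
    ppv = if (length(detected)) tp / length(detected) else NA_real_)
}
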