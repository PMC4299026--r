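# Fiducial-point delineation of a single beat window via the dyadic wavelet
# decomposition: the QRS complex dominates the low scales (2^1, 2^2) while
# the smoother P and T waves emerge at scale 2^4. A wave peak maps to a zero
# crossing between a modulus-maxima pair of opposite sign.

FPD_NAMES <- c("P_on", "P_peak", "P_end", "QRS_on", "QRS_end",
               "T_on", "T_peak", "T_end")

# find the strongest opposite-signed modulus-maxima pair of w inside
# [from, to] and return list(on, peak, end) as indices, or NULL.
# Peak = zero crossing between the pair; on/end = outermost samples where
# |w| falls below frac * pair modulus, searched outward from the pair.
wave_bounds <- function(w, from, to, thr, frac = 0.1) {
  mm <- local_modmax(w, from, to, thr = thr)
  if (length(mm) < 2L) return(NULL)
  pos <- mm[w[mm] > 0]
  neg <- mm[w[mm] < 0]
  if (!length(pos) || !length(neg)) return(NULL)
  # best pair: maximize combined modulus over adjacent opposite-sign maxima
  best <- NULL
  best_mag <- -Inf
  for (p in pos) for (q in neg) {
    if (abs(p - q) < 2L) next
    mag <- abs(w[p]) + abs(w[q])
    if (mag > best_mag) {
      best_mag <- mag
      best <- sort(c(p, q))
    }
  }
  if (is.null(best)) return(NULL)
  a <- best[1]
  b <- best[2]
  # zero crossing between the pair
  seg <- a:b
  zc <- seg[which.min(abs(w[seg]))]
  sw <- w[a:b]
  flip <- which(sw[-1] * sw[-length(sw)] <= 0)
  if (length(flip)) zc <- a + flip[1] - 1L
  lev <- frac * max(abs(w[a]), abs(w[b]))
  on <- a
  while (on > from && abs(w[on - 1L]) > lev) on <- on - 1L
  end <- b
  while (end < to && abs(w[end + 1L]) > lev) end <- end + 1L
  list(on = on, peak = zc, end = end, modulus = max(abs(w[a]), abs(w[b])))
}

#' Delineate the fiducial points of a beat window
#'
#' Locates the onset, peak and end of the P and T waves and the onset and end
#' of the QRS complex, as signed sample offsets relative to the R peak at the
#' window center. Search regions: QRS within +/-60 ms at scale 2^2; P wave in
#' [-200, -60] ms and T wave in [+80, +400] ms (clipped to the window) at
#' scale 2^4. A wave is declared undetected when its modulus maximum is below
#' 0.1 times the QRS modulus maximum at the same scale, or when no
#' opposite-signed maxima pair with an interior zero crossing exists; an
#' undetected point takes the position of the detected neighbor fiducial
#' point closer to the R peak (falling back to the R peak itself).
#'
#' @param beat numeric beat window (odd length, R at the center) or a one-row
#'   `beat_set`.
#' @param fs sampling rate (Hz).
#' @return object of class `fiducial_set`: `offsets` (named integer, signed
#'   samples relative to R) and `detected_mask` (named logical).
#' @export
delineate_fpd <- function(beat, fs = 360) {
  v <- as.numeric(beat)
  d <- length(v)
  if (d %% 2L == 0L) abort("beat window must have odd length")
  ctr <- (d + 1L) %/% 2L
  ms <- function(x) as.integer(round(x * fs / 1000))
  dec <- atrous_dwt(v, scales = 4L)
  w2 <- dec$w[[2]]
  w4 <- dec$w[[4]]

  off <- stats::setNames(rep(NA_integer_, 8L), FPD_NAMES)
  mask <- stats::setNames(rep(FALSE, 8L), FPD_NAMES)

  # QRS at scale 2^2 within +/-60 ms
  qfrom <- max(2L, ctr - ms(60))
  qto <- min(d - 1L, ctr + ms(60))
  qrs_mod2 <- max(abs(w2[qfrom:qto]))
  qrs <- wave_bounds(w2, qfrom, qto, thr = 0.1 * qrs_mod2, frac = 0.1)
  if (!is.null(qrs) && qrs_mod2 > 1e-12) {
    off["QRS_on"] <- min(qrs$on, ctr) - ctr
    off["QRS_end"] <- max(qrs$end, ctr) - ctr
    mask[c("QRS_on", "QRS_end")] <- TRUE
  }

  # reference modulus at scale 2^4 for the detection threshold
  qrs_mod4 <- max(abs(w4[qfrom:qto]))

  # P wave at scale 2^4 in [-200, -60] ms
  pfrom <- max(2L, ctr - ms(200))
  pto <- max(pfrom + 2L, ctr - ms(60))
  pw <- wave_bounds(w4, pfrom, pto, thr = 0.1 * qrs_mod4, frac = 0.25)
  if (!is.null(pw) && pw$modulus >= 0.1 * qrs_mod4) {
    off["P_on"] <- pw$on - ctr
    off["P_peak"] <- pw$peak - ctr
    off["P_end"] <- pw$end - ctr
    mask[c("P_on", "P_peak", "P_end")] <- TRUE
  }

  # T wave at scale 2^4 in [+80, +400] ms (clipped to the window)
  tfrom <- min(d - 2L, ctr + ms(80))
  tto <- min(d - 1L, ctr + ms(400))
  tw <- if (tto - tfrom >= 3L) {
    wave_bounds(w4, tfrom, tto, thr = 0.1 * qrs_mod4, frac = 0.25)
  }
  if (!is.null(tw) && tw$modulus >= 0.1 * qrs_mod4) {
    off["T_on"] <- tw$on - ctr
    off["T_peak"] <- tw$peak - ctr
    off["T_end"] <- tw$end - ctr
    mask[c("T_on", "T_peak", "T_end")] <- TRUE
  }

  fiducial_set(off, mask, d)
}

# substitution + ordering enforcement shared by delineate_fpd and tests
fiducial_set <- function(off, mask, d) {
  half <- (d - 1L) %/% 2L
  # substitute undetected points with the detected neighbor closer to R
  # left chain, inner to outer: QRS_on, P_end, P_peak, P_on
  left <- c("QRS_on", "P_end", "P_peak", "P_on")
  inner <- 0L
  for (nm in left) {
    if (is.na(off[nm])) off[nm] <- inner else inner <- off[nm]
  }
  right <- c("QRS_end", "T_on", "T_peak", "T_end")
  inner <- 0L
  for (nm in right) {
    if (is.na(off[nm])) off[nm] <- inner else inner <- off[nm]
  }
  # enforce ordering P_on <= P_peak <= P_end <= QRS_on <= 0 <= QRS_end <=
  # T_on <= T_peak <= T_end and the window range
  off["QRS_on"] <- min(off["QRS_on"], 0L)
  off["P_end"] <- min(off["P_end"], off["QRS_on"])
  off["P_peak"] <- min(off["P_peak"], off["P_end"])
  off["P_on"] <- min(off["P_on"], off["P_peak"])
  off["QRS_end"] <- max(off["QRS_end"], 0L)
  off["T_on"] <- max(off["T_on"], off["QRS_end"])
  off["T_peak"] <- max(off["T_peak"], off["T_on"])
  off["T_end"] <- max(off["T_end"], off["T_peak"])
  off <- pmax(pmin(as.integer(off), half), -half)
  names(off) <- FPD_NAMES
  structure(list(offsets = off, detected_mask = mask),
            class = "fiducial_set")
}

#' @export
print.fiducial_set <- function(x, ...) {
  cat("<fiducial_set> offsets (samples from R):\n")
  print(x$offsets)
  cat("detected:", paste(names(x$detected_mask)[x$detected_mask], collapse = " "), "\n")
  invisible(x)
}

# batch delineation: beat_set -> n x 8 matrix of offsets
delineate_fpd_batch <- function(beats, fs = NULL) {
  stopifnot(inherits(beats, "beat_set"))
  fs <- fs %||% beats$fs
  t(apply(beats$windows, 1, function(v) delineate_fpd(v, fs)$offsets))
}
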