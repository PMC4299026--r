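# A trous (undecimated) dyadic wavelet decomposition used by both the R-peak
# detector and the fiducial-point delineator.
#
# Smoothing filter: the quadratic-spline lowpass [1, 3, 3, 1]/8 applied with
# holes of 2^(j-1) samples at scale j. Detail filter: a zero-phase central
# difference at the dyadic spacing, w_j[n] = a_{j-1}[n + 2^(j-1)] -
# a_{j-1}[n - 2^(j-1)]. The zero-phase detail keeps modulus-maxima
# zero-crossings aligned with wave extrema, so no group-delay compensation is
# needed downstream. Boundaries are handled by edge replication.

# shift a vector by k samples with edge replication
shift_replicate <- function(x, k) {
  n <- length(x)
  if (k == 0L) return(x)
  if (k > 0L) c(x[(k + 1L):n], rep(x[n], k)) else c(rep(x[1L], -k), x[1L:(n + k)])
}

# one smoothing step at hole spacing h: symmetric (zero-phase) placement of
# the [1,3,3,1]/8 kernel, taps at offsets (-2h, -h, +h, +2h)
atrous_smooth <- function(x, h) {
  (shift_replicate(x, -2L * h) + 3 * shift_replicate(x, -h) +
     3 * shift_replicate(x, h) + shift_replicate(x, 2L * h)) / 8
}

#' Undecimated dyadic wavelet decomposition
#'
#' Computes detail coefficients of a signal at scales 2^1 .. 2^J with a
#' quadratic-spline smoothing cascade and zero-phase difference details.
#' Detail coefficients behave like a smoothed derivative: an ECG wave peak
#' maps to a zero crossing flanked by a modulus-maxima pair of opposite sign.
#'
#' @param x numeric signal.
#' @param scales number of dyadic scales J (default 4).
#' @return list with `w` (list of J detail vectors, same length as `x`) and
#'   `a` (list of J smoothed approximations).
#' @keywords internal
atrous_dwt <- function(x, scales = 4L) {
  n <- length(x)
  stopifnot(n >= 4L, scales >= 1L)
  a <- x
  w <- vector("list", scales)
  as <- vector("list", scales)
  for (j in seq_len(scales)) {
    h <- 2L^(j - 1L)
    w[[j]] <- shift_replicate(a, h) - shift_replicate(a, -h)
    a <- atrous_smooth(a, h)
    as[[j]] <- a
  }
  list(w = w, a = as)
}

# locate modulus-maxima (local extrema of |w| above thr) indices within a
# detail vector restricted to idx range
local_modmax <- function(w, from, to, thr = 0) {
  from <- max(2L, from)
  to <- min(length(w) - 1L, to)
  if (to < from) return(integer(0))
  seg <- from:to
  v <- abs(w[seg])
  keep <- v > thr & v >= abs(w[seg - 1L]) & v >= abs(w[seg + 1L])
  seg[keep]
}
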