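# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores the global RNG state so that seeded package operations
#' do not perturb the caller's random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# stop() with call. = FALSE and sprintf-style formatting
abort <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# Centered running minimum with a flat structuring element of odd width w,
# van Herk / Gil-Werman: O(n) via per-block prefix/suffix extrema.
# Out-of-range positions act as +Inf (erosion identity).
running_min <- function(x, w) {
  stopifnot(w >= 1L, w %% 2L == 1L)
  n <- length(x)
  if (n < w) abort("signal (%d samples) shorter than structuring element (%d)", n, w)
  r <- (w - 1L) %/% 2L
  xe <- c(rep(Inf, r), x, rep(Inf, r))
  ne <- length(xe)
  pad <- (w - ne %% w) %% w
  xp <- c(xe, rep(Inf, pad))
  m <- matrix(xp, nrow = w)
  pre <- m
  for (j in 2:w) pre[j, ] <- pmin(pre[j, ], pre[j - 1L, ])
  suf <- m
  for (j in (w - 1L):1L) suf[j, ] <- pmin(suf[j, ], suf[j + 1L, ])
  pre <- as.vector(pre)
  suf <- as.vector(suf)
  idx <- seq_len(n)                # window [idx, idx + w - 1] in padded coords
  pmin(suf[idx], pre[idx + w - 1L])
}

running_max <- function(x, w) -running_min(-x, w)

# morphological opening / closing with flat SE of width w (odd)
morph_open  <- function(x, w) running_max(running_min(x, w), w)
morph_close <- function(x, w) running_min(running_max(x, w), w)

# odd window length >= 3 covering `seconds` at rate fs
odd_window <- function(seconds, fs) {
  w <- max(3L, as.integer(round(seconds * fs)))
  if (w %% 2L == 0L) w <- w + 1L
  w
}

# number of bits needed to represent nonnegative integer-valued doubles
bit_length <- function(x) {
  b <- ifelse(x >= 1, floor(log2(x)) + 1, 0)
  # guard against floating log2 landing exactly on an integer boundary
  b <- ifelse(x >= 2^b, b + 1, b)
  ifelse(x < 2^(b - 1) & b > 0, b - 1, b)
}
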