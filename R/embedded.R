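# Integer-domain mirror of the classifier for microcontroller-class targets:
# gaussian membership functions become two-chord piecewise-linear functions
# on a 16-bit feature grid, fuzzification keeps precision by overflow-driven
# left shifts followed by 16-bit truncation, and defuzzification compares
# (M1 - M2) << 16 against alpha_q16 * S without any division.
#
# All integer arithmetic is carried in doubles; every intermediate fits well
# below 2^53, so the operations are bit-exact images of 32/48-bit integer
# hardware.

INT_MAX16 <- 65535
G_S_INT <- function() round(INT_MAX16 * exp(-2.35^2 / 2))   # gaussian at |c-x| = S

#' Build a 16-bit feature quantizer from a model's normalization
#'
#' Maps each normalized coefficient affinely from [-span, span] onto
#' [0, 65535] (clipping outside). The default span of 4.7 normalized units
#' covers the full support 4S = 4 * 2.35 sigma of a unit-width membership
#' function.
#'
#' @param model a trained `nfc_model`.
#' @param span half-range in normalized units (default 4.7).
#' @return list with `lo`, `hi`, `step` per coefficient.
#' @keywords internal
feature_quantizer <- function(model, span = 4.7) {
  lo <- rep(-span, model$k)
  hi <- rep(span, model$k)
  step <- (hi - lo) / INT_MAX16
  if (any(step <= 0)) abort("degenerate quantizer")
  list(lo = lo, hi = hi, step = step, span = span)
}

quantize_features <- function(model, quantizer, X) {
  Z <- nfc_scale(model, X)
  Q <- sweep(Z, 2, quantizer$lo)
  Q <- sweep(Q, 2, quantizer$step, "/")
  matrix(pmin(pmax(round(Q), 0), INT_MAX16), nrow = nrow(Z))
}

#' Linearize a gaussian membership function onto the 16-bit grid
#'
#' The scaled gaussian (peak mapped to 65535) is replaced by:
#' 65535 at the center; the chord from (0, 65535) to (S, G_S) for offsets
#' below S; the chord from (S, G_S) to (2S, 1) on [S, 2S); the plateau 1 on
#' [2S, 4S); and 0 beyond 4S, where S = 2.35 sigma on the quantized axis and
#' G_S = round(65535 * exp(-2.35^2 / 2)) = 4143 is the scaled gaussian value
#' at S. Chord slopes are stored as Q16 fixed point so evaluation needs only
#' integer multiply and shift.
#'
#' @param mf a [membership_function()] on the normalized feature scale.
#' @param quantizer a quantizer for the coefficient (list with `lo`, `step`).
#' @param coef which coefficient's quantizer column to use (default 1).
#' @return object of class `linearized_mf` with integer fields `center_int`,
#'   `s_int`, `seg1_slope_q16`, `seg2_slope_q16`.
#' @export
linearize_mf <- function(mf, quantizer, coef = 1L) {
  stopifnot(inherits(mf, "membership_function"))
  lo <- quantizer$lo[coef]
  step <- quantizer$step[coef]
  if (!is.finite(step) || step <= 0) abort("degenerate quantizer")
  c_int <- min(max(round((mf$center - lo) / step), 0), INT_MAX16)
  s_int <- max(1, round(2.35 * mf$sigma / step))
  gs <- G_S_INT()
  structure(list(center_int = c_int, s_int = s_int,
                 seg2_slope_q16 = round((INT_MAX16 - gs) * 65536 / s_int),
                 seg1_slope_q16 = round((gs - 1) * 65536 / s_int),
                 g_s = gs),
            class = "linearized_mf")
}

#' Evaluate a linearized membership function at 16-bit inputs
#'
#' Piecewise evaluation with integer add/multiply/shift only; symmetric in
#' |c - x| and non-increasing as the offset grows.
#'
#' @param lmf a `linearized_mf`.
#' @param x_int integer input(s) in 0..65535.
#' @return integer grade(s) in 0..65535.
#' @export
eval_linearized <- function(lmf, x_int) {
  delta <- abs(lmf$center_int - x_int)
  s <- lmf$s_int
  out <- numeric(length(delta))
  r4 <- delta >= 4 * s
  r2 <- !r4 & delta >= 2 * s
  r1 <- !r4 & !r2 & delta >= s
  r0 <- !r4 & !r2 & !r1
  out[r4] <- 0
  out[r2] <- 1
  out[r1] <- pmax(1, lmf$g_s - floor((delta[r1] - s) * lmf$seg1_slope_q16 / 65536))
  out[r0] <- pmin(INT_MAX16,
                  pmax(lmf$g_s,
                       INT_MAX16 - floor(delta[r0] * lmf$seg2_slope_q16 / 65536)))
  out
}

#' Quantize a trained neuro-fuzzy model for integer inference
#'
#' Linearizes every membership function, converts alpha to unsigned Q0.16
#' fixed point (round(alpha * 2^16), clipped to 65535) and attaches the
#' 16-bit feature quantizer.
#'
#' @param model a trained `nfc_model` (alpha tuned, or supply `alpha`).
#' @param alpha optional override of the model's tuned alpha.
#' @param span quantizer half-range in normalized units (default 4.7).
#' @return object of class `quantized_nfc`.
#' @export
quantize_model <- function(model, alpha = NULL, span = 4.7) {
  stopifnot(inherits(model, "nfc_model"))
  if (!isTRUE(model$trained)) abort("model must be trained before quantization")
  alpha <- alpha %||% model$alpha
  if (is.na(alpha)) abort("alpha not tuned; pass alpha explicitly")
  qz <- feature_quantizer(model, span)
  lmfs <- vector("list", model$k)
  for (kk in seq_len(model$k)) {
    lmfs[[kk]] <- lapply(BEAT_CLASSES, function(cl) {
      linearize_mf(membership_function(model$centers[kk, cl],
                                       model$sigmas[kk, cl]),
                   qz, coef = kk)
    })
    names(lmfs[[kk]]) <- BEAT_CLASSES
  }
  structure(list(lmfs = lmfs,
                 alpha_q16 = min(max(round(alpha * 65536), 0), INT_MAX16),
                 quantizer = qz, k = model$k,
                 scaling = model$scaling),
            class = "quantized_nfc")
}

#' Integer fuzzification with shift-truncate accumulators
#'
#' Processes coefficients in feature order. The grades of the first
#' coefficient seed three accumulators; after each subsequent multiply the
#' three 32-bit accumulators are left-shifted by the largest common amount
#' that overflows none of them, then the low 16 bits are discarded. Zero
#' accumulators propagate as zeros.
#'
#' @param qmodel a `quantized_nfc`.
#' @param u_int integer feature vector (length k) on the 16-bit grid.
#' @return object of class `int_fuzzy_state`: `accumulators` (3 named
#'   integers) and `applied_shift_log` (total left shifts).
#' @export
int_fuzzify <- function(qmodel, u_int) {
  stopifnot(inherits(qmodel, "quantized_nfc"))
  if (length(u_int) != qmodel$k) {
    abort("feature vector length %d, model expects k=%d", length(u_int), qmodel$k)
  }
  res <- int_fuzzify_batch(qmodel, matrix(u_int, nrow = 1))
  structure(list(accumulators = stats::setNames(res$acc[1, ], BEAT_CLASSES),
                 applied_shift_log = res$shifts[1]),
            class = "int_fuzzy_state")
}

# vectorized across beats: U (n x k integer grid) -> list(acc n x 3, shifts n)
int_fuzzify_batch <- function(qmodel, U) {
  n <- nrow(U)
  grade <- function(j) {
    vapply(1:3, function(l) eval_linearized(qmodel$lmfs[[j]][[l]], U[, j]),
           numeric(n))
  }
  acc <- matrix(grade(1L), nrow = n)
  shifts <- numeric(n)
  if (qmodel$k >= 2L) {
    for (j in 2:qmodel$k) {
      acc <- acc * matrix(grade(j), nrow = n)      # < 2^32: 16-bit x 16-bit
      mx <- pmax(acc[, 1], acc[, 2], acc[, 3])
      s <- ifelse(mx > 0, 32 - bit_length(mx), 0)
      shifts <- shifts + s
      acc <- floor(acc * 2^s / 65536)              # common shift, drop 16 LSBs
    }
  }
  list(acc = acc, shifts = shifts)
}

#' Division-free integer defuzzification
#'
#' Computes M1, M2 and S on the integer accumulators and applies the decision
#' (M1 - M2) * 2^16 >= alpha_q16 * S in widened integer arithmetic. Label
#' semantics match [defuzzify()]: ties and all-zero accumulators give U.
#'
#' @param state an `int_fuzzy_state` (or a length-3 accumulator vector).
#' @param alpha_q16 alpha as unsigned Q0.16 (0..65535).
#' @return a `classification_result`.
#' @export
int_defuzzify <- function(state, alpha_q16) {
  acc <- if (inherits(state, "int_fuzzy_state")) state$accumulators else state
  acc <- as.numeric(acc)
  if (length(acc) != 3L || any(acc < 0)) abort("need 3 nonnegative accumulators")
  if (alpha_q16 < 0 || alpha_q16 > INT_MAX16) abort("alpha_q16 out of range")
  srt <- sort(acc, decreasing = TRUE)
  m1 <- srt[1]
  m2 <- srt[2]
  s <- sum(acc)
  label <- if (s == 0 || m1 == m2 || (m1 - m2) * 65536 < alpha_q16 * s) {
    "U"
  } else {
    BEAT_CLASSES[which.max(acc)]
  }
  structure(list(fuzzy_values = stats::setNames(acc, BEAT_CLASSES),
                 label = label, is_pathological = label != "N",
                 m1 = m1, m2 = m2, s = s),
            class = "classification_result")
}

# batch integer classification: raw features -> labels
int_classify_batch <- function(model, qmodel, features) {
  U <- quantize_features(model, qmodel$quantizer, as.matrix(features))
  fz <- int_fuzzify_batch(qmodel, U)
  acc <- fz$acc
  m1i <- max.col(acc, ties.method = "first")
  m1 <- acc[cbind(seq_len(nrow(acc)), m1i)]
  a2 <- acc
  a2[cbind(seq_len(nrow(acc)), m1i)] <- -Inf
  m2 <- apply(a2, 1, max)
  s <- rowSums(acc)
  ok <- s > 0 & m1 > m2 & (m1 - m2) * 65536 >= qmodel$alpha_q16 * s
  ifelse(ok, BEAT_CLASSES[m1i], "U")
}

#' Audit float vs integer classification parity
#'
#' Classifies the same beats through the floating-point model and its
#' quantized mirror and reports the label agreement rate plus NDR/ARR deltas
#' when true labels are supplied.
#'
#' @param model a trained, alpha-tuned `nfc_model`.
#' @param qmodel the matching `quantized_nfc`.
#' @param features n x k raw feature matrix.
#' @param labels optional true labels for NDR/ARR deltas.
#' @param alpha_test optional float-side alpha override (the integer side
#'   always uses `qmodel$alpha_q16`).
#' @return list: `agreement`, `n`, `n_agree`, `float_labels`, `int_labels`,
#'   and when labels are given `ndr_float`, `ndr_int`, `arr_float`,
#'   `arr_int`, `ndr_delta`, `arr_delta`.
#' @export
parity_audit <- function(model, qmodel, features, labels = NULL,
                         alpha_test = NULL) {
  alpha <- alpha_test %||% model$alpha
  fl <- nfc_predict(model, features, alpha)
  il <- int_classify_batch(model, qmodel, features)
  out <- list(agreement = mean(fl == il), n = length(fl),
              n_agree = sum(fl == il), float_labels = fl, int_labels = il)
  if (!is.null(labels)) {
    rf <- compute_ndr_arr(fl, labels)
    ri <- compute_ndr_arr(il, labels)
    out$ndr_float <- rf$ndr
    out$ndr_int <- ri$ndr
    out$arr_float <- rf$arr
    out$arr_int <- ri$arr
    out$ndr_delta <- ri$ndr - rf$ndr
    out$arr_delta <- ri$arr - rf$arr
  }
  out
}
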