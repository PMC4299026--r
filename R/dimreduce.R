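# Dimensionality reduction: sparse ternary random projections (with 2-bit
# packing), PCA by power iteration with deflation, and feature concatenation.

#' Sample a sparse ternary (Achlioptas) projection matrix
#'
#' Entries are i.i.d. +1 with probability 1/6, -1 with probability 1/6 and 0
#' with probability 2/3, so each of the k output coefficients is a signed sum
#' of roughly d/3 input samples and the projection needs no multiplications.
#'
#' @param k number of output coefficients (1 <= k < d).
#' @param d input window length.
#' @param seed integer seed.
#' @return object of class `achlioptas_matrix`: integer k x d matrix with
#'   attributes `k`, `d`, `seed`.
#' @export
sample_achlioptas <- function(k, d, seed = 1L) {
  if (k < 1 || k >= d) abort("need 1 <= k < d (got k=%d, d=%d)", k, d)
  P <- with_seed(seed, {
    matrix(sample(c(-1L, 0L, 1L), k * d, replace = TRUE,
                  prob = c(1 / 6, 2 / 3, 1 / 6)),
           nrow = k, ncol = d)
  })
  structure(P, class = "achlioptas_matrix", k = as.integer(k),
            d = as.integer(d), seed = as.integer(seed))
}

validate_achlioptas <- function(P) {
  if (!all(P %in% c(-1L, 0L, 1L))) abort("matrix entries must be in {-1, 0, +1}")
  invisible(P)
}

#' Project a beat window with a ternary matrix by signed accumulation
#'
#' Computes u = P v using only additions and subtractions: for each row, the
#' +1 columns of v are accumulated and the -1 columns subtracted. Exactly
#' equal to the dense matrix-vector product.
#'
#' @param P an `achlioptas_matrix` (or any ternary k x d matrix).
#' @param v numeric beat window of length d.
#' @return feature vector of length k with attribute `reducer_id = "rp"`.
#' @export
project_rp <- function(P, v) {
  if (ncol(P) != length(v)) {
    abort("window length %d does not match matrix d=%d", length(v), ncol(P))
  }
  u <- numeric(nrow(P))
  for (i in seq_len(nrow(P))) {
    row <- P[i, ]
    u[i] <- sum(v[row == 1L]) - sum(v[row == -1L])
  }
  structure(u, reducer_id = "rp")
}

# batch variant: n x d windows -> n x k features (signed accumulation is
# equivalent to the dense product; the dense product is used for speed)
project_rp_batch <- function(P, X) {
  if (ncol(P) != ncol(X)) abort("window length mismatch")
  X %*% t(unclass(P) * 1)
}

#' Pack a ternary matrix into 2 bits per entry
#'
#' Encoding map: 0 -> 00, +1 -> 01, -1 -> 10. Entries are laid out row-major;
#' entry 4i+j (0-based) occupies bits 2j..2j+1 (LSB first) of byte i. Packed
#' size is ceiling(k d / 4) bytes, one quarter of an 8-bit encoding.
#'
#' @param P an `achlioptas_matrix`.
#' @return raw vector of length `ceiling(k * d / 4)`.
#' @export
pack_achlioptas <- function(P) {
  validate_achlioptas(P)
  codes <- t(unclass(P))          # column-major of transpose = row-major of P
  codes <- as.integer(codes)
  codes[codes == 1L] <- 1L
  codes[codes == -1L] <- 2L
  nb <- ceiling(length(codes) / 4)
  codes <- c(codes, integer(nb * 4L - length(codes)))
  m <- matrix(codes, nrow = 4L)
  as.raw(m[1, ] + 4L * m[2, ] + 16L * m[3, ] + 64L * m[4, ])
}

#' Unpack a 2-bit-packed ternary matrix
#'
#' @param buffer raw vector from [pack_achlioptas()].
#' @param k,d matrix dimensions.
#' @return the reconstructed `achlioptas_matrix`.
#' @export
unpack_achlioptas <- function(buffer, k, d) {
  nb <- ceiling(k * d / 4)
  if (length(buffer) != nb) {
    abort("buffer has %d bytes, expected %d for a %dx%d matrix",
          length(buffer), nb, k, d)
  }
  b <- as.integer(buffer)
  codes <- rbind(b %% 4L, (b %/% 4L) %% 4L, (b %/% 16L) %% 4L, (b %/% 64L) %% 4L)
  codes <- as.integer(codes)[seq_len(k * d)]
  vals <- integer(length(codes))
  vals[codes == 1L] <- 1L
  vals[codes == 2L] <- -1L
  if (any(codes == 3L)) abort("invalid 2-bit code 11 in buffer")
  P <- matrix(vals, nrow = k, ncol = d, byrow = TRUE)
  structure(P, class = "achlioptas_matrix", k = as.integer(k),
            d = as.integer(d), seed = NA_integer_)
}

#' Fit a PCA projection by power iteration with deflation
#'
#' Computes the k leading eigenvectors of the sample covariance
#' (1/N) sum_i (v_i - mean)(v_i - mean)^T by power iteration (tolerance 1e-9,
#' at most 1000 iterations per component) with deflation. The sign of each
#' component is fixed so that its largest-magnitude element is positive; rows
#' are returned in descending eigenvalue order.
#'
#' @param X N x d matrix of beat windows (N >= k + 1).
#' @param k number of components.
#' @param tol,max_iter power-iteration stopping parameters.
#' @return object of class `pca_matrix`: list with `components` (k x d),
#'   `mean_vector`, `eigenvalues`, `k`, `d`.
#' @export
fit_pca <- function(X, k, tol = 1e-9, max_iter = 1000L) {
  X <- as.matrix(X)
  if (nrow(X) < k + 1) abort("need at least k+1 = %d beats (got %d)", k + 1, nrow(X))
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  if (max(abs(Xc)) < 1e-12) abort("degenerate input: all windows identical")
  N <- nrow(X)
  d <- ncol(X)
  S <- crossprod(Xc) / N
  comps <- matrix(0, nrow = k, ncol = d)
  evals <- numeric(k)
  for (j in seq_len(k)) {
    v <- S[, which.max(diag(S))]
    if (sqrt(sum(v^2)) < 1e-300) v <- rep(1 / sqrt(d), d)
    v <- v / sqrt(sum(v^2))
    lambda <- 0
    for (it in seq_len(max_iter)) {
      w <- S %*% v
      lambda_new <- sqrt(sum(w^2))
      if (lambda_new < 1e-300) break
      w <- w / lambda_new
      delta <- min(sqrt(sum((w - v)^2)), sqrt(sum((w + v)^2)))
      v <- as.numeric(w)
      lambda <- lambda_new
      if (delta < tol) break
    }
    if (v[which.max(abs(v))] < 0) v <- -v
    comps[j, ] <- v
    evals[j] <- lambda
    S <- S - lambda * tcrossprod(v)
  }
  structure(list(components = comps, mean_vector = mu, eigenvalues = evals,
                 k = as.integer(k), d = as.integer(d)),
            class = "pca_matrix")
}

#' Project a beat window onto fitted principal components
#'
#' Computes u = T (v - mean_vector).
#'
#' @param T_mat a `pca_matrix` from [fit_pca()].
#' @param v beat window of length d.
#' @return feature vector of length k with attribute `reducer_id = "pca"`.
#' @export
project_pca <- function(T_mat, v) {
  stopifnot(inherits(T_mat, "pca_matrix"))
  if (length(v) != T_mat$d) {
    abort("window length %d does not match d=%d", length(v), T_mat$d)
  }
  u <- as.numeric(T_mat$components %*% (v - T_mat$mean_vector))
  structure(u, reducer_id = "pca")
}

project_pca_batch <- function(T_mat, X) {
  sweep(X, 2, T_mat$mean_vector) %*% t(T_mat$components)
}

#' Concatenate projection coefficients with fiducial-point offsets
#'
#' @param u8 length-8 projection feature vector.
#' @param fpd a `fiducial_set` from [delineate_fpd()].
#' @return length-16 feature vector: projection coefficients first, then the
#'   8 signed sample offsets.
#' @export
combine_features <- function(u8, fpd) {
  if (length(u8) != 8L) abort("u8 must have 8 coefficients (got %d)", length(u8))
  stopifnot(inherits(fpd, "fiducial_set"))
  structure(c(as.numeric(u8), as.numeric(fpd$offsets)),
            reducer_id = paste0(attr(u8, "reducer_id") %||% "proj", "+fpd"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
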