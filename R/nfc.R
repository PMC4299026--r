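# Three-layer neuro-fuzzy classifier: gaussian membership layer, product
# fuzzification, alpha-thresholded defuzzification. Training by batch
# gradient descent on the mean squared error between the normalized fuzzy
# vector and the one-hot class target (conjugate-gradient optimization of
# the same objective available as an option).

#' Gaussian membership function
#'
#' @param center real center c.
#' @param sigma positive width sigma.
#' @return object of class `membership_function`.
#' @export
membership_function <- function(center, sigma) {
  if (!is.finite(sigma) || sigma <= 0) abort("sigma must be positive")
  structure(list(center = center, sigma = sigma), class = "membership_function")
}

#' Evaluate a gaussian membership grade
#'
#' mu(u) = exp(-(u - c)^2 / (2 sigma^2)), in (0, 1], maximal at the center.
#'
#' @param mf a [membership_function()].
#' @param u_k coefficient value(s).
#' @return membership grade(s) in (0, 1].
#' @export
membership_grade <- function(mf, u_k) {
  stopifnot(inherits(mf, "membership_function"))
  exp(-(u_k - mf$center)^2 / (2 * mf$sigma^2))
}

SIGMA_FLOOR <- 1e-3

#' Initialize a neuro-fuzzy model from labeled features
#'
#' Fits per-coefficient affine normalization (zero mean, unit variance) on
#' the training features, then sets each class's membership centers to the
#' per-class sample means and the widths to the per-class sample standard
#' deviations of the normalized coefficients (floored at 1e-3).
#'
#' @param features n x k numeric feature matrix.
#' @param labels length-n class labels in N, V, L.
#' @return object of class `nfc_model` with `centers` and `sigmas` (k x 3
#'   matrices, columns N/V/L), `alpha` (NA until tuned), `scaling`, `k`.
#' @export
init_model <- function(features, labels) {
  X <- as.matrix(features)
  labels <- as.character(labels)
  missing_cl <- setdiff(BEAT_CLASSES, unique(labels))
  if (length(missing_cl)) {
    abort("class(es) %s absent from training features", paste(missing_cl, collapse = ", "))
  }
  if (any(table(labels) < 2L)) abort("need at least 2 samples per class")
  k <- ncol(X)
  mu <- colMeans(X)
  sd0 <- apply(X, 2, stats::sd)
  sd0[!is.finite(sd0) | sd0 < 1e-8] <- 1
  Z <- sweep(sweep(X, 2, mu), 2, sd0, "/")
  centers <- sigmas <- matrix(0, nrow = k, ncol = 3,
                              dimnames = list(NULL, BEAT_CLASSES))
  for (cl in BEAT_CLASSES) {
    zi <- Z[labels == cl, , drop = FALSE]
    centers[, cl] <- colMeans(zi)
    sigmas[, cl] <- pmax(apply(zi, 2, stats::sd), SIGMA_FLOOR)
  }
  structure(list(centers = centers, sigmas = sigmas, alpha = NA_real_,
                 scaling = list(mu = mu, sd = sd0), k = as.integer(k),
                 classes = BEAT_CLASSES, trained = FALSE,
                 loss_history = numeric(0), reducer_id = NULL),
            class = "nfc_model")
}

# normalize raw features with the model's stored affine map
nfc_scale <- function(model, X) {
  X <- matrix(as.numeric(X), ncol = model$k)
  sweep(sweep(X, 2, model$scaling$mu), 2, model$scaling$sd, "/")
}

# per-class log fuzzy values for normalized features Z (n x k) -> n x 3
nfc_logf <- function(model, Z) {
  out <- matrix(0, nrow = nrow(Z), ncol = 3, dimnames = list(NULL, BEAT_CLASSES))
  for (j in 1:3) {
    Dev <- sweep(Z, 2, model$centers[, j])
    Dev <- sweep(Dev, 2, model$sigmas[, j], "/")
    out[, j] <- -0.5 * rowSums(Dev^2)
  }
  out
}

# normalized fuzzy vector p (rows sum to 1), computed stably in log domain
nfc_posterior <- function(logf) {
  m <- apply(logf, 1, max)
  f <- exp(logf - m)
  f / rowSums(f)
}

#' Fuzzification: product of membership grades per class
#'
#' f_l = prod_k mu_{k,l}(u_k) for l in N, V, L. `u` is taken on the model's
#' normalized feature scale if `normalized = TRUE`, otherwise raw features
#' are normalized first.
#'
#' @param model an `nfc_model`.
#' @param u feature vector of length k.
#' @param normalized whether `u` is already on the normalized scale.
#' @return named numeric vector of 3 fuzzy values.
#' @export
fuzzify <- function(model, u, normalized = FALSE) {
  stopifnot(inherits(model, "nfc_model"))
  if (length(u) != model$k) {
    abort("feature vector has length %d, model expects k=%d", length(u), model$k)
  }
  Z <- if (normalized) matrix(as.numeric(u), nrow = 1) else nfc_scale(model, u)
  exp(nfc_logf(model, Z)[1, ])
}

#' Defuzzification: margin-vs-sum decision rule
#'
#' Let M1 >= M2 be the two largest fuzzy values and S their sum over classes.
#' If M1 - M2 >= alpha * S the beat takes the argmax class (N, V or L),
#' otherwise it is marked unknown (U). Ties (M1 == M2) and all-zero fuzzy
#' vectors yield U. V, L and U are flagged pathological.
#'
#' @param fuzzy_values 3 nonnegative fuzzy values (named or in N, V, L order).
#' @param alpha defuzzification coefficient in 0..1.
#' @return object of class `classification_result`: `fuzzy_values`, `label`,
#'   `is_pathological`, `m1`, `m2`, `s`.
#' @export
defuzzify <- function(fuzzy_values, alpha) {
  f <- as.numeric(fuzzy_values)
  if (length(f) != 3L || any(!is.finite(f)) || any(f < 0)) {
    abort("fuzzy_values must be 3 nonnegative finite numbers")
  }
  if (alpha < 0 || alpha > 1) abort("alpha must be in [0, 1]")
  srt <- sort(f, decreasing = TRUE)
  m1 <- srt[1]
  m2 <- srt[2]
  s <- sum(f)
  label <- if (s == 0 || m1 == m2 || (m1 - m2) < alpha * s) {
    "U"
  } else {
    BEAT_CLASSES[which.max(f)]
  }
  structure(list(fuzzy_values = stats::setNames(f, BEAT_CLASSES),
                 label = label, is_pathological = label != "N",
                 m1 = m1, m2 = m2, s = s),
            class = "classification_result")
}

#' @export
print.classification_result <- function(x, ...) {
  cat(sprintf("<classification_result> label=%s (%s)  f = [%s]\n",
              x$label, if (x$is_pathological) "pathological" else "normal",
              paste(signif(x$fuzzy_values, 4), collapse = ", ")))
  invisible(x)
}

# MSE loss between normalized fuzzy vector and one-hot target, plus analytic
# gradients wrt centers and sigmas (on normalized features Z)
nfc_loss_grad <- function(centers, sigmas, Z, Y) {
  n <- nrow(Z)
  logf <- matrix(0, nrow = n, ncol = 3)
  for (j in 1:3) {
    Dev <- sweep(Z, 2, centers[, j])
    Dev <- sweep(Dev, 2, sigmas[, j], "/")
    logf[, j] <- -0.5 * rowSums(Dev^2)
  }
  p <- nfc_posterior(logf)
  q <- 2 * (p - Y)
  loss <- sum((p - Y)^2) / n
  # dL/dlogf_im = (p_im / n) * (q_im - sum_l q_il p_il)
  g <- p * (q - rowSums(q * p)) / n
  gc <- gs <- matrix(0, nrow = nrow(centers), ncol = 3)
  for (j in 1:3) {
    Dev <- sweep(Z, 2, centers[, j])
    s2 <- sigmas[, j]^2
    gc[, j] <- colSums(Dev * g[, j]) / s2
    gs[, j] <- colSums(Dev^2 * g[, j]) / (s2 * sigmas[, j])
  }
  list(loss = loss, grad_centers = gc, grad_sigmas = gs)
}

#' Train the membership functions by gradient descent
#'
#' Minimizes the mean squared error between the normalized fuzzy vector
#' f_l / sum(f) and the one-hot class target over the training set, updating
#' all gaussian centers and widths. Widths are floored at 1e-3 after every
#' step. `method = "cg"` optimizes the identical objective with conjugate
#' gradients (stats::optim) instead of fixed-step descent.
#'
#' @param model an initialized `nfc_model`.
#' @param features n x k raw feature matrix.
#' @param labels length-n class labels.
#' @param epochs gradient steps (default 200).
#' @param learning_rate step size on normalized features (default 0.05).
#' @param method `"gd"` (default) or `"cg"`.
#' @return the trained model, with `loss_history` recording the objective.
#' @export
train_model <- function(model, features, labels, epochs = 200L,
                        learning_rate = 0.05, method = c("gd", "cg")) {
  stopifnot(inherits(model, "nfc_model"))
  method <- match.arg(method)
  X <- as.matrix(features)
  labels <- as.character(labels)
  Z <- nfc_scale(model, X)
  Y <- outer(labels, BEAT_CLASSES, "==") * 1
  centers <- model$centers
  sigmas <- model$sigmas
  hist <- numeric(0)
  if (epochs > 0L) {
    if (method == "gd") {
      for (e in seq_len(epochs)) {
        lg <- nfc_loss_grad(centers, sigmas, Z, Y)
        if (!all(is.finite(lg$grad_centers)) || !all(is.finite(lg$grad_sigmas))) {
          abort("non-finite gradients at epoch %d; reduce learning_rate", e)
        }
        hist <- c(hist, lg$loss)
        centers <- centers - learning_rate * lg$grad_centers
        sigmas <- pmax(sigmas - learning_rate * lg$grad_sigmas, SIGMA_FLOOR)
      }
    } else {
      k <- model$k
      unflat <- function(par) {
        list(centers = matrix(par[1:(3 * k)], nrow = k),
             sigmas = matrix(pmax(par[(3 * k + 1):(6 * k)], SIGMA_FLOOR), nrow = k))
      }
      fn <- function(par) {
        pp <- unflat(par)
        nfc_loss_grad(pp$centers, pp$sigmas, Z, Y)$loss
      }
      gr <- function(par) {
        pp <- unflat(par)
        lg <- nfc_loss_grad(pp$centers, pp$sigmas, Z, Y)
        c(as.numeric(lg$grad_centers), as.numeric(lg$grad_sigmas))
      }
      opt <- stats::optim(c(as.numeric(centers), as.numeric(sigmas)), fn, gr,
                          method = "CG", control = list(maxit = epochs))
      pp <- unflat(opt$par)
      centers <- pp$centers
      sigmas <- pp$sigmas
      hist <- opt$value
    }
  }
  dimnames(centers) <- dimnames(sigmas) <- list(NULL, BEAT_CLASSES)
  model$centers <- centers
  model$sigmas <- sigmas
  model$trained <- TRUE
  model$loss_history <- hist
  model
}

# batch decision statistics: argmax class, margin (M1-M2)/S on normalized
# fuzzy values (scale-invariant, so the decision matches raw fuzzy values)
nfc_margins <- function(model, features, raw = FALSE) {
  X <- as.matrix(features)
  Z <- if (raw) X else nfc_scale(model, X)
  p <- nfc_posterior(nfc_logf(model, Z))
  ord1 <- max.col(p, ties.method = "first")
  m1 <- p[cbind(seq_len(nrow(p)), ord1)]
  p2 <- p
  p2[cbind(seq_len(nrow(p)), ord1)] <- -Inf
  m2 <- apply(p2, 1, max)
  tie <- m1 == m2
  list(argmax = BEAT_CLASSES[ord1], margin = m1 - m2, tie = tie)
}

# vector of predicted labels at a given alpha
nfc_predict <- function(model, features, alpha) {
  st <- nfc_margins(model, features)
  lab <- ifelse(!st$tie & st$margin >= alpha, st$argmax, "U")
  lab
}

#' Tune the defuzzification coefficient to meet an ARR bound
#'
#' Searches the grid alpha = 0, 0.001, ..., 1 for the smallest value whose
#' Abnormal Recognition Rate on the tuning set is at least `arr_min`
#' (raising alpha turns more beats into U, which counts as pathological, so
#' ARR is non-decreasing in alpha). If even alpha = 1 misses the bound, 1 is
#' returned with attribute `warning_flag = TRUE`.
#'
#' @param model a trained `nfc_model`.
#' @param features n x k tuning feature matrix.
#' @param labels true class labels (must include abnormal beats).
#' @param arr_min required minimum ARR (default 0.95).
#' @param step grid resolution (default 0.001).
#' @return the selected alpha (also stored if you assign it to
#'   `model$alpha`), with attributes `arr` and `warning_flag`.
#' @export
tune_alpha <- function(model, features, labels, arr_min = 0.95, step = 0.001) {
  labels <- as.character(labels)
  abn <- labels != "N"
  if (!any(abn)) abort("tuning set contains no abnormal beats")
  st <- nfc_margins(model, features)
  n_abn <- sum(abn)
  # an abnormal beat is missed only when it wins class N with margin >= alpha
  mm <- st$margin[abn & st$argmax == "N" & !st$tie]
  alphas <- seq(0, 1, by = step)
  miss <- vapply(alphas, function(a) sum(mm >= a), integer(1))
  arr <- 1 - miss / n_abn
  ok <- which(arr >= arr_min)
  if (length(ok)) {
    a <- alphas[ok[1]]
    structure(a, arr = arr[ok[1]], warning_flag = FALSE)
  } else {
    warning("ARR bound unreachable on the tuning set; returning alpha = 1")
    structure(1, arr = arr[length(arr)], warning_flag = TRUE)
  }
}

#' Classify one feature vector
#'
#' Fuzzifies then defuzzifies at `alpha_test` (defaulting to the model's
#' tuned alpha). The run-time alpha may differ from the trained one to trade
#' NDR against ARR without retraining.
#'
#' @param model a trained `nfc_model`.
#' @param u feature vector of length k.
#' @param alpha_test defuzzification coefficient (default: `model$alpha`).
#' @return a `classification_result`.
#' @export
classify <- function(model, u, alpha_test = NULL) {
  stopifnot(inherits(model, "nfc_model"))
  alpha <- alpha_test %||% model$alpha
  if (is.na(alpha)) abort("model alpha not tuned; pass alpha_test")
  Z <- nfc_scale(model, u)
  logf <- nfc_logf(model, Z)[1, ]
  # scale-invariant decision: exp(logf - max) has the same defuzzification
  f <- exp(logf - max(logf))
  defuzzify(f, alpha)
}

#' @export
print.nfc_model <- function(x, ...) {
  cat(sprintf("<nfc_model> k=%d coefficients, %d gaussian MFs (%s), alpha=%s\n",
              x$k, 3L * x$k, if (x$trained) "trained" else "initialized",
              if (is.na(x$alpha)) "untuned" else format(x$alpha)))
  invisible(x)
}
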