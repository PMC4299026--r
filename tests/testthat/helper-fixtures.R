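# Shared fixtures, built once per test run and memoized.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixtures)) assign(name, build(), envir = .fixtures)
  get(name, envir = .fixtures)
}

# 600-beat labeled dataset at default study conditions
small_dataset <- function() {
  fixture("small_ds", function() generate_dataset(record_spec(n_beats = 600, seed = 101)))
}

# RP(16) features for the small dataset plus a trained, alpha-tuned model
rp16_fit <- function() {
  fixture("rp16_fit", function() {
    ds <- small_dataset()
    P <- sample_achlioptas(16L, ds$d, seed = 77)
    feats <- ecgtriage:::project_rp_batch(P, ds$windows)
    tr <- ds$fold != 4L
    model <- train_model(init_model(feats[tr, ], ds$labels[tr]),
                         feats[tr, ], ds$labels[tr])
    model$alpha <- as.numeric(tune_alpha(model, feats[tr, ], ds$labels[tr]))
    list(ds = ds, P = P, feats = feats, train = tr, model = model)
  })
}

# well-separated 3-class gaussian features with known parameters
gaussian_features <- function(n_per_class = 200L, k = 4L, seed = 5L,
                              spread = 6, sd = 1) {
  set.seed(seed)
  # abnormal classes share a positive first coordinate, so the binary
  # normal-vs-abnormal relabeling stays linearly separable
  centers <- list(N = rep(0, k), V = rep(spread, k),
                  L = c(spread, rep(-spread, k - 1)))
  X <- do.call(rbind, lapply(names(centers), function(cl) {
    sweep(matrix(rnorm(n_per_class * k, sd = sd), ncol = k), 2,
          centers[[cl]], "+")
  }))
  list(X = X, labels = rep(names(centers), each = n_per_class),
       centers = centers)
}

# drop class/seed bookkeeping so ternary matrices compare by value + shape
strip_m <- function(P) {
  a <- unclass(P)
  attributes(a) <- list(dim = dim(a))
  a
}
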