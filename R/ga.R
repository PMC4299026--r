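# Genetic optimization of the sparse ternary projection matrix, trained
# jointly with the neuro-fuzzy classifier: each candidate matrix is scored by
# the NDR its tuned classifier reaches on train_set_2 under the ARR bound.

#' Genetic algorithm configuration
#'
#' Defaults are desk-scale (population 10, 10 generations) to keep runs
#' short; the reference configuration is 20 matrices over 30 generations.
#'
#' @param population_size number of candidate matrices (>= 2).
#' @param generations number of generations.
#' @param arr_min ARR bound enforced during alpha tuning (default 0.95).
#' @param mutation_rate per-entry resampling probability (default 0.02).
#' @param crossover_rate probability a child is produced by crossover
#'   (default 0.9; otherwise a parent is copied).
#' @param elitism number of elites carried over unchanged (default 2).
#' @param tournament tournament size for parent selection (default 3).
#' @param epochs,learning_rate NFC training parameters used inside fitness.
#' @param seed integer seed.
#' @return object of class `ga_config`.
#' @export
ga_config <- function(population_size = 10L, generations = 10L,
                      arr_min = 0.95, mutation_rate = 0.02,
                      crossover_rate = 0.9, elitism = 2L, tournament = 3L,
                      epochs = 200L, learning_rate = 0.05, seed = 1L) {
  if (population_size < 2L) abort("population_size must be >= 2")
  if (elitism >= population_size) abort("elitism must be < population_size")
  structure(list(population_size = as.integer(population_size),
                 generations = as.integer(generations), arr_min = arr_min,
                 mutation_rate = mutation_rate, crossover_rate = crossover_rate,
                 elitism = as.integer(elitism), tournament = as.integer(tournament),
                 epochs = as.integer(epochs), learning_rate = learning_rate,
                 seed = as.integer(seed)),
            class = "ga_config")
}

#' Fitness of a candidate projection matrix
#'
#' Projects train_set_1 and train_set_2 with `P`, initializes and trains the
#' classifier on train_set_1, tunes alpha on train_set_2 to meet `arr_min`,
#' and returns the NDR on train_set_2 at the tuned alpha. Candidates whose
#' alpha tuning cannot reach `arr_min` even at alpha = 1 are penalized below
#' every feasible candidate (fitness = NDR - 1).
#'
#' @param P an `achlioptas_matrix`.
#' @param train1_windows,train1_labels class-balanced training beats.
#' @param train2_windows,train2_labels larger tuning/scoring set.
#' @param arr_min ARR bound.
#' @param epochs,learning_rate NFC training parameters.
#' @param extra_features optional function (windows -> matrix) whose output
#'   is concatenated to the projection (used for the RP+FPD reducer).
#' @return list: `fitness`, `ndr`, `arr`, `alpha`, `feasible`, `model`.
#' @export
fitness <- function(P, train1_windows, train1_labels,
                    train2_windows, train2_labels, arr_min = 0.95,
                    epochs = 200L, learning_rate = 0.05,
                    extra_features = NULL) {
  if (!nrow(train1_windows) || !nrow(train2_windows)) abort("empty training set")
  feats <- function(X) {
    u <- project_rp_batch(P, X)
    if (!is.null(extra_features)) u <- cbind(u, extra_features(X))
    u
  }
  F1 <- feats(train1_windows)
  F2 <- feats(train2_windows)
  model <- train_model(init_model(F1, train1_labels), F1, train1_labels,
                       epochs = epochs, learning_rate = learning_rate)
  alpha <- suppressWarnings(
    tune_alpha(model, F2, train2_labels, arr_min = arr_min))
  feasible <- !isTRUE(attr(alpha, "warning_flag"))
  pred <- nfc_predict(model, F2, as.numeric(alpha))
  r <- compute_ndr_arr(pred, train2_labels)
  list(fitness = if (feasible) r$ndr else r$ndr - 1,
       ndr = r$ndr, arr = r$arr, alpha = as.numeric(alpha),
       feasible = feasible, model = model)
}

#' Row-wise uniform crossover of two ternary matrices
#'
#' Each row of the child is copied from one of the two parents with a fair
#' coin flip. Uses the caller's RNG stream when `seed` is NULL.
#'
#' @param parent_a,parent_b shape-compatible `achlioptas_matrix` objects.
#' @param seed optional integer seed.
#' @return the child `achlioptas_matrix`.
#' @export
crossover <- function(parent_a, parent_b, seed = NULL) {
  if (!identical(dim(parent_a), dim(parent_b))) abort("parent shape mismatch")
  draw <- function() {
    pick <- stats::runif(nrow(parent_a)) < 0.5
    child <- unclass(parent_a)
    child[!pick, ] <- unclass(parent_b)[!pick, ]
    structure(child, class = "achlioptas_matrix",
              k = nrow(child), d = ncol(child), seed = NA_integer_)
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

#' Per-entry mutation by Achlioptas resampling
#'
#' Each entry is independently replaced, with probability `rate`, by a fresh
#' draw from the ternary law (+1 w.p. 1/6, -1 w.p. 1/6, 0 w.p. 2/3).
#'
#' @param P an `achlioptas_matrix`.
#' @param rate per-entry mutation probability.
#' @param seed optional integer seed.
#' @return the mutated `achlioptas_matrix`.
#' @export
mutate <- function(P, rate, seed = NULL) {
  draw <- function() {
    n <- length(P)
    hit <- stats::runif(n) < rate
    out <- unclass(P)
    out[hit] <- sample(c(-1L, 0L, 1L), sum(hit), replace = TRUE,
                       prob = c(1 / 6, 2 / 3, 1 / 6))
    structure(out, class = "achlioptas_matrix",
              k = nrow(P), d = ncol(P), seed = NA_integer_)
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

#' Evolve a projection matrix jointly with the classifier
#'
#' Tournament selection, row-wise crossover, per-entry mutation and elitism
#' over a population of ternary matrices scored by [fitness()]. The best
#' individual ever seen is returned; with elitism >= 1 the best fitness per
#' generation is non-decreasing.
#'
#' @param cfg a [ga_config()].
#' @param train1_windows,train1_labels balanced training beats.
#' @param train2_windows,train2_labels tuning/scoring beats.
#' @param k,d projection shape.
#' @param extra_features optional feature-augmentation function (see
#'   [fitness()]).
#' @return object of class `ga_result`: `best_matrix`, `best_model`, `alpha`,
#'   `fitness_history` (per-generation best NDR), `final_ndr`, `final_arr`,
#'   `feasible`, `log` (per-generation data.frame).
#' @export
evolve <- function(cfg, train1_windows, train1_labels,
                   train2_windows, train2_labels, k, d,
                   extra_features = NULL) {
  stopifnot(inherits(cfg, "ga_config"))
  with_seed(cfg$seed, {
    seeds <- sample.int(.Machine$integer.max, cfg$population_size)
    pop <- lapply(seeds, function(s) sample_achlioptas(k, d, seed = s))
    evaluate_pop <- function(pop) {
      lapply(pop, fitness,
             train1_windows = train1_windows, train1_labels = train1_labels,
             train2_windows = train2_windows, train2_labels = train2_labels,
             arr_min = cfg$arr_min, epochs = cfg$epochs,
             learning_rate = cfg$learning_rate, extra_features = extra_features)
    }
    scores <- evaluate_pop(pop)
    fit <- vapply(scores, `[[`, 0, "fitness")
    best_i <- which.max(fit)
    best <- list(P = pop[[best_i]], score = scores[[best_i]], fit = fit[best_i])
    hist <- best$score$ndr
    log <- data.frame(generation = 0L, best_ndr = best$score$ndr,
                      best_arr = best$score$arr,
                      mean_ndr = mean(vapply(scores, `[[`, 0, "ndr")))
    gen <- 0L
    while (gen < cfg$generations) {
      gen <- gen + 1L
      ord <- order(fit, decreasing = TRUE)
      nextpop <- pop[ord[seq_len(cfg$elitism)]]
      pick_parent <- function() {
        cand <- sample.int(cfg$population_size, cfg$tournament)
        pop[[cand[which.max(fit[cand])]]]
      }
      while (length(nextpop) < cfg$population_size) {
        child <- if (stats::runif(1) < cfg$crossover_rate) {
          crossover(pick_parent(), pick_parent())
        } else {
          pick_parent()
        }
        nextpop[[length(nextpop) + 1L]] <- mutate(child, cfg$mutation_rate)
      }
      pop <- nextpop
      scores <- evaluate_pop(pop)
      fit <- vapply(scores, `[[`, 0, "fitness")
      gi <- which.max(fit)
      if (fit[gi] > best$fit) {
        best <- list(P = pop[[gi]], score = scores[[gi]], fit = fit[gi])
      }
      hist <- c(hist, best$score$ndr)
      log <- rbind(log, data.frame(generation = gen, best_ndr = best$score$ndr,
                                   best_arr = best$score$arr,
                                   mean_ndr = mean(vapply(scores, `[[`, 0, "ndr"))))
    }
    structure(list(best_matrix = best$P, best_model = best$score$model,
                   alpha = best$score$alpha,
                   fitness_history = hist,
                   final_ndr = best$score$ndr, final_arr = best$score$arr,
                   feasible = best$score$feasible, log = log),
              class = "ga_result")
  })
}

#' @export
print.ga_result <- function(x, ...) {
  cat(sprintf("<ga_result> best NDR=%.4f ARR=%.4f (alpha=%.3f%s) over %d generations\n",
              x$final_ndr, x$final_arr, x$alpha,
              if (x$feasible) "" else ", ARR bound not met", length(x$fitness_history) - 1L))
  invisible(x)
}
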