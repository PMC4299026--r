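# End-to-end pipeline orchestration behind the command-line entry point
# (inst/cli/ecgtriage). Every run writes a manifest (config + seeds +
# package version) next to its artifacts so results are reproducible.

#' Pipeline configuration
#'
#' @param reducer one of `"rp8"`, `"rp16"`, `"pca8"`, `"pca16"`, `"fpd"`,
#'   `"rp8+fpd"`, `"pca8+fpd"`.
#' @param d beat window length (odd; default 201).
#' @param fs sampling rate (Hz).
#' @param arr_min ARR bound for alpha tuning.
#' @param alpha_test optional run-time alpha override.
#' @param n_beats,folds synthetic dataset size and fold count.
#' @param train1_per_class balanced train_set_1 size per class.
#' @param ga a [ga_config()] (used by the rp reducers).
#' @param seed master seed.
#' @param out_dir artifact directory.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(reducer = "rp16", d = 201L, fs = 360,
                            arr_min = 0.95, alpha_test = NULL,
                            n_beats = 3000L, folds = 4L,
                            train1_per_class = 150L,
                            ga = ga_config(seed = seed), seed = 1L,
                            out_dir = tempfile("ecgtriage-run-")) {
  choices <- c("rp8", "rp16", "pca8", "pca16", "fpd", "rp8+fpd", "pca8+fpd")
  if (!reducer %in% choices) {
    abort("unknown reducer '%s' (choices: %s)", reducer, paste(choices, collapse = ", "))
  }
  if (arr_min <= 0 || arr_min > 1) abort("arr_min must be in (0, 1]")
  structure(list(reducer = reducer, d = as.integer(d), fs = fs,
                 arr_min = arr_min, alpha_test = alpha_test,
                 n_beats = as.integer(n_beats), folds = as.integer(folds),
                 train1_per_class = as.integer(train1_per_class),
                 ga = ga, seed = as.integer(seed), out_dir = out_dir),
            class = "pipeline_config")
}

# map the user-facing reducer names to cross_validate arguments
reducer_parts <- function(reducer) {
  switch(reducer,
         rp8 = list(name = "rp", k = 8L),
         rp16 = list(name = "rp", k = 16L),
         pca8 = list(name = "pca", k = 8L),
         pca16 = list(name = "pca", k = 16L),
         fpd = list(name = "fpd", k = 8L),
         `rp8+fpd` = list(name = "rp+fpd", k = 16L),
         `pca8+fpd` = list(name = "pca+fpd", k = 16L))
}

write_manifest <- function(cfg, command, path) {
  obj <- list(command = command,
              config = cfg[setdiff(names(cfg), "ga")],
              ga = unclass(cfg$ga),
              package_version = as.character(utils::packageVersion("ecgtriage")),
              timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Run a pipeline command
#'
#' Subcommands: `"synth"` writes a synthetic annotated record;
#' `"train"` fits the configured reducer + classifier on a synthetic dataset
#' and writes the model (JSON) and, for RP reducers, the packed matrix;
#' `"quantize"` converts a trained model to its integer mirror (JSON);
#' `"classify"` streams beat labels for a record CSV using a trained model;
#' `"evaluate"` runs the cross-validation and writes per-fold and mean
#' NDR/ARR reports (CSV + JSON); `"sweep"` writes an alpha_test Pareto curve
#' CSV; `"compare"` writes the baseline-classifier table. Every command
#' writes `manifest-<command>.json`.
#'
#' @param config a [pipeline_config()].
#' @param command one of the subcommands above.
#' @param model_path,record_path inputs for `classify`/`quantize`.
#' @return the artifact paths, invisibly (commands also return their main
#'   result object).
#' @export
run_pipeline <- function(config, command = c("synth", "train", "quantize",
                                             "classify", "evaluate", "sweep",
                                             "compare"),
                         model_path = NULL, record_path = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  command <- match.arg(command)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(...) file.path(config$out_dir, sprintf(...))
  write_manifest(config, command, out("manifest-%s.json", command))
  rp <- reducer_parts(config$reducer)
  spec <- record_spec(n_beats = config$n_beats, fs = config$fs,
                      seed = config$seed, d = config$d)

  if (command == "synth") {
    rec <- generate_record(spec)
    write_record(rec, out("record.csv"))
    return(invisible(list(record = out("record.csv"))))
  }

  if (command == "train") {
    ds <- generate_dataset(spec, folds = config$folds)
    tr <- fit_triage(ds, reducer = config$reducer,
                     arr_min = config$arr_min,
                     train1_per_class = config$train1_per_class,
                     ga_cfg = config$ga, seed = config$seed)
    write_nfc_model(tr$model, out("model.json"))
    if (!is.null(tr$matrix)) write_achlioptas(tr$matrix, out("matrix.bin"))
    if (!is.null(tr$pca)) {
      jsonlite::write_json(list(components = tr$pca$components,
                                mean_vector = tr$pca$mean_vector),
                           out("pca.json"), digits = NA)
    }
    return(invisible(list(model = out("model.json"), fit = tr)))
  }

  if (command == "quantize") {
    model <- read_nfc_model(model_path %||% out("model.json"))
    qm <- quantize_model(model)
    obj <- list(format = "ecgtriage-qnfc", version = 1L, k = qm$k,
                alpha_q16 = qm$alpha_q16, quantizer = qm$quantizer,
                lmfs = lapply(qm$lmfs, lapply, unclass))
    jsonlite::write_json(obj, out("model-quantized.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    return(invisible(list(quantized = out("model-quantized.json"))))
  }

  if (command == "evaluate") {
    ds <- generate_dataset(spec, folds = config$folds)
    cv <- cross_validate(ds, reducer = rp$name, k = rp$k,
                         arr_min = config$arr_min,
                         train1_per_class = config$train1_per_class,
                         ga_cfg = config$ga, seed = config$seed)
    fold_df <- do.call(rbind, lapply(seq_along(cv$fold_reports), function(i) {
      r <- cv$fold_reports[[i]]
      data.frame(fold = i, ndr = r$ndr, arr = r$arr, alpha = r$alpha_used, n = r$n)
    }))
    utils::write.csv(fold_df, out("cv-folds.csv"), row.names = FALSE)
    jsonlite::write_json(list(reducer = config$reducer, mean_ndr = cv$mean_ndr,
                              mean_arr = cv$mean_arr),
                         out("cv-mean.json"), auto_unbox = TRUE, digits = NA)
    return(invisible(list(cv = cv, folds = out("cv-folds.csv"))))
  }

  stop_if_no_model <- function() {
    if (is.null(model_path) && !file.exists(out("model.json"))) {
      abort("command '%s' needs a trained model (run 'train' or pass model_path)",
            command)
    }
  }

  if (command == "classify") {
    stop_if_no_model()
    model <- read_nfc_model(model_path %||% out("model.json"))
    rec <- read_record(record_path %||% out("record.csv"), fs = config$fs)
    filt <- baseline_filter(rec)
    peaks <- detect_r_peaks(filt)
    beats <- segment_beats(filt, peaks, d = config$d)
    feats <- extract_features_for(model, beats, config, out)
    alpha <- config$alpha_test %||% model$alpha
    lab <- nfc_predict(model, feats, alpha)
    res <- data.frame(r_index = beats$r_index - 1L, label = lab)
    utils::write.csv(res, out("beat-labels.csv"), row.names = FALSE)
    return(invisible(list(labels = out("beat-labels.csv"), n = nrow(res))))
  }

  if (command == "sweep") {
    ds <- generate_dataset(spec, folds = config$folds)
    tr <- fit_triage(ds, reducer = config$reducer, arr_min = config$arr_min,
                     train1_per_class = config$train1_per_class,
                     ga_cfg = config$ga, seed = config$seed)
    test_idx <- which(ds$fold == config$folds)
    curve <- pareto_sweep(tr$model, tr$extract(ds$windows[test_idx, , drop = FALSE]),
                          ds$labels[test_idx])
    utils::write.csv(curve, out("pareto.csv"), row.names = FALSE)
    return(invisible(list(curve = curve, path = out("pareto.csv"))))
  }

  if (command == "compare") {
    ds <- generate_dataset(spec, folds = config$folds)
    P <- sample_achlioptas(8L, config$d, seed = config$seed)
    feats <- cbind(project_rp_batch(P, ds$windows), delineate_fpd_batch(ds))
    tab <- baseline_compare(feats, ds$labels, ds$fold,
                            arr_min = config$arr_min, seed = config$seed)
    utils::write.csv(tab, out("baselines.csv"), row.names = FALSE)
    return(invisible(list(table = tab, path = out("baselines.csv"))))
  }
}

# fit reducer + NFC on folds 1..(folds-1) of a dataset, tune alpha; returns
# model, extractor, and reducer artifacts
fit_triage <- function(dataset, reducer, arr_min = 0.95,
                       train1_per_class = 150L, ga_cfg = NULL, seed = 1L) {
  rp <- reducer_parts(reducer)
  test_fold <- max(dataset$fold)
  train_idx <- which(dataset$fold != test_fold)
  with_seed(seed, {
    t1 <- balanced_subset(dataset$labels, train_idx, train1_per_class)
    red <- build_reducer(rp$name, dataset$windows[t1, , drop = FALSE],
                         dataset$labels[t1], dataset$fs, dataset$d, rp$k,
                         seed = seed, ga_cfg = ga_cfg %||% ga_config(seed = seed),
                         train2_windows = dataset$windows[train_idx, , drop = FALSE],
                         train2_labels = dataset$labels[train_idx])
    if (!is.null(red$ga)) {
      model <- red$ga$best_model
      model$alpha <- red$ga$alpha
    } else {
      F1 <- red$extract(dataset$windows[t1, , drop = FALSE])
      model <- train_model(init_model(F1, dataset$labels[t1]), F1, dataset$labels[t1])
      F2 <- red$extract(dataset$windows[train_idx, , drop = FALSE])
      model$alpha <- as.numeric(tune_alpha(model, F2, dataset$labels[train_idx],
                                           arr_min = arr_min))
    }
    model$reducer_id <- reducer
    list(model = model, extract = red$extract,
         matrix = if (!is.null(red$ga)) red$ga$best_matrix,
         pca = red$pca)
  })
}

# feature extraction for `classify` given a stored model's reducer_id
extract_features_for <- function(model, beats, config, out) {
  rp <- reducer_parts(model$reducer_id %||% config$reducer)
  X <- beats$windows
  proj <- switch(rp$name,
    rp = , `rp+fpd` = {
      P <- read_achlioptas(out("matrix.bin"))
      project_rp_batch(P, X)
    },
    pca = , `pca+fpd` = {
      obj <- jsonlite::read_json(out("pca.json"), simplifyVector = TRUE)
      Tm <- structure(list(components = obj$components,
                           mean_vector = as.numeric(obj$mean_vector),
                           k = nrow(obj$components), d = ncol(obj$components)),
                      class = "pca_matrix")
      project_pca_batch(Tm, X)
    },
    fpd = NULL)
  fpd <- if (grepl("fpd", rp$name)) delineate_fpd_batch(beats)
  if (is.null(proj)) fpd else if (is.null(fpd)) proj else cbind(proj, fpd)
}
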