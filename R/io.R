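# File formats and readers/writers.
#
# Signal CSV dialect: single column `mv` (header), one sample per row.
# Annotation CSV dialect: columns `sample_index` (0-based), `label`.
# WFDB-digest dialect: a text export in the style of rdsamp/rdann -c -- a
# multi-column CSV whose header names the leads (sample index first column),
# paired with an annotation CSV. Binary WFDB .dat files are not parsed.
#
# Achlioptas matrix file: 8-byte header (magic "AC", k and d as little-endian
# uint16, 2 reserved bytes) followed by the row-major 2-bit packed payload.
# PCA matrix file: one-line JSON header, then little-endian doubles row-major.
# Model files: versioned JSON.

uint16_le <- function(x) as.raw(c(x %% 256L, x %/% 256L))

#' Write / read an Achlioptas matrix in packed binary form
#'
#' @param P an `achlioptas_matrix`.
#' @param path file path.
#' @return `read_achlioptas` returns the matrix; `write_achlioptas` its path,
#'   invisibly.
#' @export
write_achlioptas <- function(P, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(as.raw(c(0x41, 0x43)), uint16_le(nrow(P)), uint16_le(ncol(P)),
             as.raw(c(0, 0))), con)
  writeBin(pack_achlioptas(P), con)
  invisible(path)
}

#' @rdname write_achlioptas
#' @export
read_achlioptas <- function(path) {
  raw <- readBin(path, "raw", file.size(path))
  if (length(raw) < 8L || raw[1] != 0x41 || raw[2] != 0x43) {
    abort("not an Achlioptas matrix file: %s", path)
  }
  k <- as.integer(raw[3]) + 256L * as.integer(raw[4])
  d <- as.integer(raw[5]) + 256L * as.integer(raw[6])
  unpack_achlioptas(raw[-(1:8)], k, d)
}

#' Write / read a trained neuro-fuzzy model as versioned JSON
#'
#' @param model an `nfc_model`.
#' @param path file path.
#' @export
write_nfc_model <- function(model, path) {
  obj <- list(format = "ecgtriage-nfc", version = 1L,
              k = model$k, classes = model$classes,
              centers = model$centers, sigmas = model$sigmas,
              alpha_train = model$alpha,
              scaling = model$scaling, trained = model$trained,
              reducer_id = model$reducer_id)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_nfc_model
#' @export
read_nfc_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "ecgtriage-nfc")) abort("not an nfc model file: %s", path)
  structure(list(centers = matrix(obj$centers, ncol = 3,
                                  dimnames = list(NULL, BEAT_CLASSES)),
                 sigmas = matrix(obj$sigmas, ncol = 3,
                                 dimnames = list(NULL, BEAT_CLASSES)),
                 alpha = obj$alpha_train %||% NA_real_,
                 scaling = list(mu = as.numeric(obj$scaling$mu),
                                sd = as.numeric(obj$scaling$sd)),
                 k = as.integer(obj$k), classes = BEAT_CLASSES,
                 trained = isTRUE(obj$trained), loss_history = numeric(0),
                 reducer_id = obj$reducer_id),
            class = "nfc_model")
}

#' Write an ECG record (and annotations) in the package CSV dialect
#'
#' @param record an `ecg_record`.
#' @param path signal CSV path; annotations go to `<path>.ann.csv` when
#'   present.
#' @export
write_record <- function(record, path) {
  utils::write.csv(data.frame(mv = record$signal), path, row.names = FALSE)
  if (!is.null(record$annotations)) {
    ann <- data.frame(sample_index = record$annotations$r_index - 1L,
                      label = record$annotations$label)
    utils::write.csv(ann, paste0(path, ".ann.csv"), row.names = FALSE)
  }
  invisible(path)
}

#' Read an ECG record from CSV or a WFDB-digest export
#'
#' `dialect = "csv"` reads the single-column signal dialect written by
#' [write_record()]; annotations are looked up at `<path>.ann.csv` (or
#' `ann_path`). `dialect = "wfdb-csv"` reads a multi-lead rdsamp-style CSV
#' and selects one lead by name (default MLII). Annotation labels outside
#' N, V, L are dropped; the dropped count is reported via the
#' `dropped_annotations` attribute.
#'
#' @param path signal file path.
#' @param fs sampling rate of the stored signal (Hz; default 360).
#' @param dialect `"csv"` or `"wfdb-csv"`.
#' @param lead lead name for multi-lead files (default `"MLII"`).
#' @param ann_path optional annotation CSV path.
#' @return an `ecg_record` (annotations attached when found).
#' @export
read_record <- function(path, fs = 360, dialect = c("csv", "wfdb-csv"),
                        lead = "MLII", ann_path = NULL) {
  dialect <- match.arg(dialect)
  df <- utils::read.csv(path, check.names = FALSE)
  sig <- if (dialect == "csv") {
    if (!"mv" %in% names(df)) abort("CSV dialect requires an 'mv' column")
    df$mv
  } else {
    leads <- setdiff(names(df), names(df)[1])   # first column = sample index
    if (!lead %in% leads) {
      abort("lead '%s' not present; available leads: %s", lead,
            paste(leads, collapse = ", "))
    }
    df[[lead]]
  }
  ann_path <- ann_path %||% paste0(path, ".ann.csv")
  ann <- NULL
  dropped <- 0L
  if (file.exists(ann_path)) {
    adf <- utils::read.csv(ann_path)
    keep <- adf$label %in% BEAT_CLASSES
    dropped <- sum(!keep)
    if (dropped) {
      message(sprintf("dropped %d annotations with labels outside N/V/L", dropped))
    }
    adf <- adf[keep, , drop = FALSE]
    ann <- data.frame(r_index = as.integer(adf$sample_index) + 1L,
                      label = as.character(adf$label))
  }
  rec <- ecg_record(sig, fs, source_id = path, annotations = ann)
  attr(rec, "dropped_annotations") <- dropped
  rec
}
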