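# Plain-text persistence: UTF-8 dictionaries, JSON-lines recordings, CSV
# feature tables, model files. Replaces the original system's embedded
# SQLite store with an equally inspectable directory layout:
#   dictionary.json   recordings.jsonl   features.csv

#' Import a dictionary from a text file
#'
#' One word per line, UTF-8 (Turkish characters welcome); blank lines are
#' skipped and duplicates are rejected with their line numbers. Importing a
#' dictionary replaces the active one — when `dataset` already holds
#' records, the call refuses unless `confirm = TRUE`, in which case the
#' records and feature table are cleared.
#'
#' @param path text file, one word per line
#' @param dataset optional existing `sign_dataset` to replace the dictionary
#'   of
#' @param confirm explicit consent to drop existing records
#' @return a character vector of class `sign_dictionary` (or, when `dataset`
#'   is given, the dataset with the new dictionary and cleared records)
#' @export
import_dictionary_txt <- function(path, dataset = NULL, confirm = FALSE) {
  if (!file.exists(path)) stop_invalid("dictionary file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  words <- trimws(lines)
  keep <- nzchar(words)
  words <- words[keep]
  if (!length(words)) stop_invalid("dictionary file contains no words")
  if (anyDuplicated(words)) {
    ln <- which(keep)[duplicated(words)]
    stop_invalid("duplicate word(s) at line(s) ", paste(ln, collapse = ", "))
  }
  dict <- structure(words, class = "sign_dictionary")
  if (is.null(dataset)) return(dict)
  stopifnot(inherits(dataset, "sign_dataset"))
  if (length(dataset$recordings) && !isTRUE(confirm))
    stop_invalid("replacing the dictionary deletes all existing records; ",
                 "pass confirm = TRUE to proceed")
  sign_dataset(dictionary = words)
}

num_json <- function(x) jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA)

recording_to_json <- function(rec) {
  obj <- list(label = rec$label, rep = rec$rep %||% NA_integer_,
              duration = rec$duration)
  for (arm in c("left", "right")) {
    s <- rec[[arm]]
    obj[[arm]] <- list(emg = unclass(s$emg$values),
                       accel = unclass(s$imu$accel),
                       gyro = unclass(s$imu$gyro),
                       orientation = unclass(s$imu$orientation))
  }
  num_json(obj)
}

json_to_recording <- function(line) {
  obj <- jsonlite::fromJSON(line)
  arms <- lapply(c("left", "right"), function(arm) {
    a <- obj[[arm]]
    emg <- matrix(as.integer(a$emg), ncol = 8L)
    n_imu <- nrow(a$accel)
    armband_stream(arm, (seq_len(nrow(emg)) - 1L) / EMG_FS, emg,
                   (seq_len(n_imu) - 1L) / IMU_FS,
                   matrix(as.numeric(a$accel), ncol = 3L),
                   matrix(as.numeric(a$gyro), ncol = 3L),
                   matrix(as.numeric(a$orientation), ncol = 4L))
  })
  rec <- structure(list(left = arms[[1L]], right = arms[[2L]],
                        label = obj$label, duration = obj$duration),
                   class = "two_arm_recording")
  if (!is.na(obj$rep)) rec$rep <- as.integer(obj$rep)
  rec
}

#' Save a dataset to a directory
#'
#' Layout: `dictionary.json` (word list), `recordings.jsonl` (one recording
#' per line: metadata plus channel arrays) and, when features are present,
#' `features.csv` (registry-named columns plus a final `label` column). All
#' writers are deterministic.
#'
#' @param dataset a `sign_dataset`
#' @param directory output directory (created if missing)
#' @return `directory`, invisibly
#' @export
save_dataset <- function(dataset, directory) {
  stopifnot(inherits(dataset, "sign_dataset"))
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  writeLines(num_json(dataset$dictionary),
             file.path(directory, "dictionary.json"), useBytes = TRUE)
  con <- file(file.path(directory, "recordings.jsonl"), "w", encoding = "UTF-8")
  on.exit(close(con))
  for (rec in dataset$recordings) writeLines(recording_to_json(rec), con)
  if (!is.null(dataset$features)) {
    df <- data.frame(dataset$features, check.names = FALSE,
                     stringsAsFactors = FALSE)
    df$label <- dataset$labels
    data.table::fwrite(df, file.path(directory, "features.csv"))
  }
  invisible(directory)
}

#' Load a dataset saved by [save_dataset()]
#'
#' @param directory dataset directory
#' @return a `sign_dataset`
#' @export
load_dataset <- function(directory) {
  dict_f <- file.path(directory, "dictionary.json")
  rec_f <- file.path(directory, "recordings.jsonl")
  if (!file.exists(dict_f))
    stop_invalid("corrupt dataset directory: missing dictionary.json")
  if (!file.exists(rec_f))
    stop_invalid("corrupt dataset directory: missing recordings.jsonl")
  dict <- jsonlite::fromJSON(dict_f)
  lines <- readLines(rec_f, encoding = "UTF-8", warn = FALSE)
  recordings <- lapply(lines, json_to_recording)
  ds <- sign_dataset(dictionary = dict, recordings = recordings)
  feat_f <- file.path(directory, "features.csv")
  if (file.exists(feat_f)) {
    df <- data.table::fread(feat_f, encoding = "UTF-8", data.table = FALSE)
    labs <- df$label
    m <- as.matrix(df[, setdiff(names(df), "label"), drop = FALSE])
    if (ncol(m) != 1044L)
      stop_invalid("corrupt dataset directory: features.csv has ", ncol(m),
                   " feature columns (expected 1044)")
    ds$features <- m
    ds$labels <- as.character(labs)
  }
  ds
}

#' Remove one (sign, repetition) record
#'
#' Deletes the matching recording and, if present, its feature row.
#'
#' @param dataset a `sign_dataset`
#' @param word sign word
#' @param rep repetition index
#' @return the updated dataset
#' @export
delete_record <- function(dataset, word, rep) {
  stopifnot(inherits(dataset, "sign_dataset"))
  hit <- vapply(dataset$recordings, function(r)
    identical(r$label, word) && identical(r$rep %||% NA_integer_,
                                          as.integer(rep)), logical(1L))
  if (!any(hit)) stop_invalid("no record for '", word, "' repetition ", rep)
  i <- which(hit)[1L]
  dataset$recordings <- dataset$recordings[-i]
  if (!is.null(dataset$features)) {
    dataset$features <- dataset$features[-i, , drop = FALSE]
    dataset$labels <- dataset$labels[-i]
  }
  dataset
}

#' Save a trained model
#'
#' The file embeds the algorithm name and parameters, the training seed, the
#' standardization statistics and the feature-registry hash, so a reloaded
#' model reproduces predictions exactly and refuses feature tables whose
#' registry does not match.
#'
#' @param model a `sign_model`
#' @param path output file
#' @return `path`, invisibly
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "sign_model"))
  saveRDS(list(format = "signstream-model", version = 1L,
               algorithm = model$spec$algorithm,
               parameters = model$spec$params, model = model), path)
  invisible(path)
}

#' Load a model saved by [save_model()]
#'
#' @param path model file
#' @return a `sign_model`
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stop_invalid("model file not found: ", path)
  obj <- readRDS(path)
  if (!identical(obj$format, "signstream-model") ||
      !inherits(obj$model, "sign_model"))
    stop_invalid("not a signstream model file: ", path)
  obj$model
}

check_registry <- function(model, registry) {
  h <- fnv1a_hash(registry)
  if (!identical(model$registry_hash, h))
    stop_invalid("feature-registry hash mismatch: model was trained on ",
                 model$registry_hash, ", current registry is ", h)
  invisible(TRUE)
}
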