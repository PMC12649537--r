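#' Write / read a recording with a JSON sidecar
#'
#' The on-disk container is a data file (`.csv`: channels x samples with no
#' header, or `.rds`) plus a JSON sidecar `<stem>.json` carrying `fs`,
#' `channel_labels`, `subject_id`, `trial_id` and `ratings`. CSV keeps the
#' container plain-text and language-neutral; RDS is lossless and compact.
#'
#' @param recording a [raw_recording()].
#' @param stem output path without extension.
#' @param format `"csv"` or `"rds"`.
#' @return `write_recording` returns the data-file path invisibly;
#'   `read_recording` returns a [raw_recording()].
#' @export
write_recording <- function(recording, stem, format = c("csv", "rds")) {
  format <- match.arg(format)
  data_path <- paste0(stem, ".", format)
  if (format == "csv") {
    utils::write.table(recording$data, data_path, sep = ",",
                       row.names = FALSE, col.names = FALSE)
  } else {
    saveRDS(recording$data, data_path)
  }
  sidecar <- list(fs = recording$fs, channel_labels = recording$channel_labels,
                  subject_id = recording$subject_id, trial_id = recording$trial_id,
                  ratings = recording$ratings)
  jsonlite::write_json(sidecar, paste0(stem, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(data_path)
}

#' @param path data-file path (`.csv` or `.rds`); the sidecar is looked up at
#'   the same stem.
#' @rdname write_recording
#' @export
read_recording <- function(path) {
  stem <- sub("\\.(csv|rds)$", "", path)
  sidecar_path <- paste0(stem, ".json")
  if (!file.exists(path)) stop("no such recording file: ", path)
  if (!file.exists(sidecar_path)) stop("missing sidecar: ", sidecar_path)
  side <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  missing <- setdiff(c("fs", "channel_labels", "subject_id", "trial_id"), names(side))
  if (length(missing)) {
    stop("sidecar is missing required field(s): ", paste(missing, collapse = ", "))
  }
  data <- if (grepl("\\.rds$", path)) {
    readRDS(path)
  } else {
    as.matrix(utils::read.table(path, sep = ",", header = FALSE))
  }
  dimnames(data) <- NULL
  raw_recording(data, side$fs, side$channel_labels, side$subject_id,
                side$trial_id, as.list(side$ratings))
}

#' Write / read a generated dataset directory
#'
#' One recording per file (`r0001` ...) plus `manifest.csv`.
#'
#' @param dataset result of [generate_dataset()].
#' @param dir output directory (created if needed).
#' @param format recording container format.
#' @return `write_dataset` returns `dir` invisibly; `read_dataset` returns a
#'   list with `recordings` and `manifest`.
#' @export
write_dataset <- function(dataset, dir, format = "csv") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(dataset$recordings)) {
    write_recording(dataset$recordings[[i]],
                    file.path(dir, sprintf("r%04d", i)), format)
  }
  utils::write.csv(dataset$manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(dir) {
  files <- sort(list.files(dir, pattern = "^r[0-9]+\\.(csv|rds)$", full.names = TRUE))
  if (!length(files)) stop("no recordings found in ", dir)
  manifest_path <- file.path(dir, "manifest.csv")
  manifest <- if (file.exists(manifest_path)) utils::read.csv(manifest_path) else NULL
  list(recordings = lapply(files, read_recording), manifest = manifest)
}

#' Save / load a trained model
#'
#' @param model a [c2g_model()].
#' @param path `.rds` file path.
#' @return `load_model` returns the model; `save_model` the path, invisibly.
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  m <- readRDS(path)
  if (!inherits(m, "c2g_model")) stop("not a saved c2g_model: ", path)
  m
}

## ---- experiment configuration --------------------------------------------

config_known_keys <- c("seed", "scheme", "protocol", "variant", "montage_name",
                       "preprocess", "deformer", "bca", "tcn", "train",
                       "mlp_hidden", "rnn_hidden", "dropout", "k")

#' Read and validate an experiment configuration file
#'
#' YAML or JSON; unknown top-level keys are rejected and the parsed list
#' round-trips to an equivalent file through [write_experiment_config()].
#'
#' @param path config file path.
#' @return Named list of configuration values (class `experiment_config`).
#' @export
read_experiment_config <- function(path) {
  x <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  unknown <- setdiff(names(x), config_known_keys)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  structure(x, class = "experiment_config")
}

#' @param config an `experiment_config` (or plain named list).
#' @rdname read_experiment_config
#' @export
write_experiment_config <- function(config, path) {
  x <- unclass(config)
  unknown <- setdiff(names(x), config_known_keys)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else {
    yaml::write_yaml(x, path)
  }
  invisible(path)
}

# Build the model/training sub-configurations named in a config list,
# falling back to defaults; fs comes from the data.
configs_from_list <- function(cfg, fs) {
  mk <- function(fun, args) do.call(fun, args %||% list())
  defo_args <- as.list(cfg$deformer)
  defo_args$fs <- fs
  list(deformer = do.call(deformer_config, defo_args),
       bca = mk(bca_config, as.list(cfg$bca)),
       tcn = mk(tcn_config, as.list(cfg$tcn)),
       train = mk(train_config, as.list(cfg$train)))
}
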