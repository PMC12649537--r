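#' Multichannel EEG recording container
#'
#' The canonical in-memory representation of one trial: a channels x samples
#' matrix of microvolt values plus the metadata needed downstream (sampling
#' rate, channel labels, subject/trial identifiers, self-assessment ratings).
#'
#' @param data numeric matrix, channels x samples (microvolts).
#' @param fs sampling rate in Hz (> 0).
#' @param channel_labels character vector, one label per row of `data`.
#' @param subject_id,trial_id identifiers (coerced to character).
#' @param ratings named list or vector of rating values, e.g.
#'   `list(valence = 7, arousal = 8, dominance = 5)`.
#' @return An object of class `raw_recording`.
#' @export
raw_recording <- function(data, fs, channel_labels,
                          subject_id = "s01", trial_id = "t01",
                          ratings = list()) {
  data <- as.matrix(data)
  if (!is.numeric(data)) stop("recording data must be numeric")
  if (nrow(data) != length(channel_labels)) {
    stop(sprintf("data has %d rows but %d channel labels were given",
                 nrow(data), length(channel_labels)))
  }
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) {
    stop("fs must be a single positive number")
  }
  if (anyDuplicated(channel_labels)) stop("duplicated channel labels")
  if (any(!is.finite(data))) stop("recording contains non-finite samples")
  rownames(data) <- channel_labels
  structure(
    list(data = data, fs = as.numeric(fs),
         channel_labels = as.character(channel_labels),
         subject_id = as.character(subject_id),
         trial_id = as.character(trial_id),
         ratings = as.list(ratings)),
    class = "raw_recording")
}

#' @export
print.raw_recording <- function(x, ...) {
  cat(sprintf("<raw_recording> subject %s, trial %s: %d channels x %d samples @ %g Hz (%.1f s)\n",
              x$subject_id, x$trial_id, nrow(x$data), ncol(x$data), x$fs,
              ncol(x$data) / x$fs))
  if (length(x$ratings)) {
    cat("  ratings:", paste(names(x$ratings), unlist(x$ratings),
                            sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
dim.raw_recording <- function(x) dim(x$data)

#' Set of fixed-length analysis windows cut from one recording
#'
#' @param windows numeric array `n_windows x channels x window_samples`.
#' @param fs sampling rate in Hz.
#' @param window_seconds window length in seconds.
#' @param channel_labels channel labels (second array axis).
#' @param subject_id,trial_id provenance identifiers.
#' @param start_times numeric vector of window start times in seconds.
#' @param normalized logical; TRUE once windows are per-channel z-scored.
#' @return An object of class `window_set`.
#' @export
window_set <- function(windows, fs, window_seconds, channel_labels,
                       subject_id = "s01", trial_id = "t01",
                       start_times = NULL, normalized = FALSE) {
  if (length(dim(windows)) != 3L) stop("windows must be a 3-d array")
  ws <- round(window_seconds * fs)
  if (dim(windows)[3] != ws) {
    stop(sprintf("window axis has %d samples, expected round(%g * %g) = %d",
                 dim(windows)[3], window_seconds, fs, ws))
  }
  if (is.null(start_times)) start_times <- rep(NA_real_, dim(windows)[1])
  structure(
    list(windows = windows, fs = fs, window_seconds = window_seconds,
         channel_labels = as.character(channel_labels),
         subject_id = as.character(subject_id),
         trial_id = as.character(trial_id),
         start_times = start_times, normalized = isTRUE(normalized)),
    class = "window_set")
}

#' @export
print.window_set <- function(x, ...) {
  d <- dim(x$windows)
  cat(sprintf("<window_set> %d windows x %d channels x %d samples (%g s @ %g Hz)%s\n",
              d[1], d[2], d[3], x$window_seconds, x$fs,
              if (x$normalized) ", z-scored" else ""))
  invisible(x)
}

n_windows <- function(x) dim(x$windows)[1]
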