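#' Construct a multi-channel sEMG recording
#'
#' An `emg_recording` holds one continuous multi-channel surface-EMG trial:
#' a channels-by-samples signal matrix, its sampling rate, the identity of
#' the subject and trial, and an optional per-sample activity label stream.
#'
#' @param data numeric matrix, `n_channels` x `n_samples`, arbitrary units.
#' @param fs sampling rate in Hz (positive scalar).
#' @param subject_id subject identifier (scalar character).
#' @param labels optional integer vector of length `n_samples` holding the
#'   active class id (`0 .. C-1`) per sample; `NA` marks unlabeled samples.
#' @param channel_names optional character vector of channel (muscle) names;
#'   defaults to `ch1 .. chN`.
#' @param trial_id trial identifier (scalar character).
#'
#' @return An object of class `emg_recording`: a list with fields `data`,
#'   `fs`, `subject_id`, `channel_names`, `labels`, `trial_id`.
#' @examples
#' rec <- emg_recording(matrix(rnorm(2000), 2), fs = 1000, subject_id = "S1")
#' rec
#' @export
emg_recording <- function(data, fs, subject_id, labels = NULL,
                          channel_names = NULL, trial_id = "t1") {
  if (!is.matrix(data) || !is.numeric(data))
    stop_("`data` must be a numeric matrix (channels x samples)")
  if (nrow(data) < 1L || ncol(data) < 1L)
    stop_("`data` must have at least one channel and one sample")
  assert_finite(data, "`data`")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop_("`fs` must be a positive scalar (Hz)")
  if (!is.character(subject_id) || length(subject_id) != 1L)
    stop_("`subject_id` must be a scalar character")
  if (is.null(channel_names))
    channel_names <- paste0("ch", seq_len(nrow(data)))
  if (length(channel_names) != nrow(data))
    stop_("`channel_names` length (%d) != number of channels (%d)",
          length(channel_names), nrow(data))
  if (!is.null(labels)) {
    if (length(labels) != ncol(data))
      stop_("`labels` length (%d) != number of samples (%d)",
            length(labels), ncol(data))
    labels <- as.integer(labels)
    if (any(labels < 0L, na.rm = TRUE))
      stop_("`labels` must be class ids >= 0 (NA for unlabeled)")
  }
  structure(
    list(data = data, fs = as.numeric(fs), subject_id = subject_id,
         channel_names = as.character(channel_names),
         labels = labels, trial_id = as.character(trial_id)),
    class = "emg_recording")
}

#' @export
print.emg_recording <- function(x, ...) {
  cat(sprintf("<emg_recording> subject %s, trial %s: %d channels x %d samples @ %g Hz\n",
              x$subject_id, x$trial_id, nrow(x$data), ncol(x$data), x$fs))
  if (!is.null(x$labels)) {
    tab <- table(x$labels, useNA = "no")
    cat("  labels:", paste(sprintf("%s:%d", names(tab), tab), collapse = " "), "\n")
  } else cat("  labels: none\n")
  invisible(x)
}

n_channels <- function(rec) nrow(rec$data)
n_samples <- function(rec) ncol(rec$data)
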