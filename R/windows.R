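#' Construct a window set
#'
#' A `window_set` is the unit the relation network consumes: `n` segmented,
#' preprocessed windows, each logically a `1 x n_channels x L` matrix.
#' Windows are stored as an `n_channels x L x n` array (column-major
#' friendly); labels use class ids `0 .. C-1` with `NA` for unlabeled.
#'
#' @param windows numeric array, `n_channels x L x n`.
#' @param labels integer vector length `n` (`NA` allowed).
#' @param subject_ids character vector length `n`.
#' @param starts integer vector length `n`: 0-based sample index of each
#'   window's first sample in its source recording (half-open span
#'   `[start, start + L)`).
#' @param fs sampling rate in Hz.
#' @return An object of class `window_set`.
#' @export
window_set <- function(windows, labels, subject_ids, starts, fs) {
  if (!is.array(windows) || length(dim(windows)) != 3L)
    stop_("`windows` must be a 3-d array (channels x L x n)")
  n <- dim(windows)[3]
  if (length(labels) != n || length(subject_ids) != n || length(starts) != n)
    stop_("labels/subject_ids/starts must each have length n = %d", n)
  structure(
    list(windows = windows, labels = as.integer(labels),
         subject_ids = as.character(subject_ids),
         starts = as.integer(starts), fs = as.numeric(fs)),
    class = "window_set")
}

#' @export
print.window_set <- function(x, ...) {
  d <- dim(x$windows)
  cat(sprintf("<window_set> %d windows of shape 1 x %d x %d @ %g Hz (%d subject(s))\n",
              d[3], d[1], d[2], x$fs, length(unique(x$subject_ids))))
  invisible(x)
}

#' Number of windows in a window set
#' @param ws a [window_set()].
#' @return integer count.
#' @export
n_windows <- function(ws) dim(ws$windows)[3]

#' Subset a window set by window index
#' @param ws a [window_set()].
#' @param idx integer indices (1-based) of the windows to keep.
#' @return a [window_set()] with the selected windows, order preserved.
#' @export
ws_subset <- function(ws, idx) {
  n <- n_windows(ws)
  if (length(idx) && (min(idx) < 1L || max(idx) > n))
    stop_("window index out of range 1..%d", n)
  window_set(ws$windows[, , idx, drop = FALSE], ws$labels[idx],
             ws$subject_ids[idx], ws$starts[idx], ws$fs)
}

#' Concatenate window sets
#' @param ... [window_set()] objects with identical window shape and fs.
#' @return a single combined [window_set()].
#' @export
ws_bind <- function(...) {
  sets <- list(...)
  if (length(sets) == 1L && is.list(sets[[1]]) && !inherits(sets[[1]], "window_set"))
    sets <- sets[[1]]
  stopifnot(length(sets) >= 1L)
  d1 <- dim(sets[[1]]$windows)[1:2]
  for (s in sets)
    if (!identical(dim(s$windows)[1:2], d1) || s$fs != sets[[1]]$fs)
      stop_("window sets have incompatible shapes or sampling rates")
  arr <- array(unlist(lapply(sets, function(s) s$windows), use.names = FALSE),
               dim = c(d1, sum(vapply(sets, n_windows, 0L))))
  window_set(arr,
             unlist(lapply(sets, `[[`, "labels")),
             unlist(lapply(sets, `[[`, "subject_ids")),
             unlist(lapply(sets, `[[`, "starts")),
             sets[[1]]$fs)
}

#' Segment a recording into overlapping sliding windows
#'
#' Applies the standard sliding-window segmentation: windows of
#' `window_ms` milliseconds advanced by `increment_ms`, i.e.
#' `L = round(window_ms * fs / 1000)` samples per window and a hop of
#' `round(increment_ms * fs / 1000)` samples, yielding
#' `floor((n_samples - L) / hop) + 1` windows. Each window spans the
#' half-open sample range `[start, start + L)` (0-based) and carries the
#' majority per-sample label inside its span; windows whose majority class
#' covers 50% of the span or less (label transitions) are flagged but kept.
#'
#' @param rec an [emg_recording()] (labels optional).
#' @param window_ms window length in milliseconds (default 200).
#' @param increment_ms hop between consecutive windows in ms (default 25).
#' @return A [window_set()]; attribute `transition` is a logical vector
#'   marking windows without a strict (> 50%) majority label.
#' @examples
#' rec <- emg_recording(matrix(rnorm(14 * 1000), 14), fs = 1000,
#'                      subject_id = "S1")
#' ws <- segment_windows(rec)
#' dim(ws$windows) # 14 x 200 x 33
#' @export
segment_windows <- function(rec, window_ms = 200, increment_ms = 25) {
  stopifnot(inherits(rec, "emg_recording"))
  L <- as.integer(round(window_ms * rec$fs / 1000))
  hop <- as.integer(round(increment_ms * rec$fs / 1000))
  if (L < 1L || hop < 1L)
    stop_("window/increment too short for fs = %g Hz", rec$fs)
  ns <- n_samples(rec)
  if (ns < L)
    stop_("recording (%d samples) is shorter than one %g ms window (%d samples)",
          ns, window_ms, L)
  n <- (ns - L) %/% hop + 1L
  starts <- (seq_len(n) - 1L) * hop            # 0-based
  nc <- n_channels(rec)
  arr <- array(0, dim = c(nc, L, n))
  for (i in seq_len(n))
    arr[, , i] <- rec$data[, (starts[i] + 1L):(starts[i] + L), drop = FALSE]
  transition <- logical(n)
  labels <- rep(NA_integer_, n)
  if (!is.null(rec$labels)) {
    for (i in seq_len(n)) {
      span <- rec$labels[(starts[i] + 1L):(starts[i] + L)]
      span <- span[!is.na(span)]
      if (length(span)) {
        tab <- tabulate(span + 1L)
        best <- which.max(tab)                  # ties: lowest class id
        labels[i] <- best - 1L
        transition[i] <- tab[best] <= L / 2
      }
    }
  }
  ws <- window_set(arr, labels, rep(rec$subject_id, n), starts, rec$fs)
  attr(ws, "transition") <- transition
  ws
}
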