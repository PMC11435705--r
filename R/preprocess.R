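#' Band-limit an sEMG recording
#'
#' Removes motion artifact and high-frequency noise with cascaded zero-phase
#' Butterworth filters: a high-pass at `hp_hz` followed by a low-pass at
#' `lp_hz`, each of the given order, applied forward-backward
#' ([signal::filtfilt()]) so no group delay is introduced and window/label
#' alignment downstream is preserved.
#'
#' @param rec an [emg_recording()].
#' @param hp_hz high-pass corner frequency in Hz (default 20: below the
#'   usable sEMG band, where motion artifact lives).
#' @param lp_hz low-pass corner frequency in Hz (default 450: above the
#'   usable sEMG band). Must be below the Nyquist frequency `fs/2`.
#' @param order Butterworth order for each cascade stage (default 3).
#'
#' @return A new `emg_recording` with filtered `data`; labels and metadata
#'   unchanged.
#' @examples
#' rec <- emg_recording(matrix(rnorm(4000), 2), fs = 1000, subject_id = "S1")
#' filt <- bandlimit_filter(rec)
#' @export
bandlimit_filter <- function(rec, hp_hz = 20, lp_hz = 450, order = 3) {
  stopifnot(inherits(rec, "emg_recording"))
  nyq <- rec$fs / 2
  if (lp_hz >= nyq)
    stop_("low-pass corner %g Hz must be below Nyquist (%g Hz at fs = %g Hz)",
          lp_hz, nyq, rec$fs)
  if (hp_hz >= lp_hz)
    stop_("high-pass corner (%g Hz) must be below the low-pass corner (%g Hz)",
          hp_hz, lp_hz)
  assert_finite(rec$data, "recording data")
  hp <- signal::butter(order, hp_hz / nyq, type = "high")
  lp <- signal::butter(order, lp_hz / nyq, type = "low")
  out <- rec$data
  for (c in seq_len(nrow(out))) {
    x <- signal::filtfilt(hp, out[c, ])
    out[c, ] <- signal::filtfilt(lp, x)
  }
  assert_finite(out, "filtered data")
  rec$data <- out
  rec
}

#' Normalize each channel by a reference peak amplitude
#'
#' Divides every channel by a per-channel reference peak (in practice the
#' peak activation of the corresponding muscle during normal walking), so
#' channels become dimensionless and comparable across subjects.
#'
#' @param rec an [emg_recording()].
#' @param peaks positive numeric vector, one reference peak per channel.
#'   Defaults to each channel's own maximum absolute value.
#' @return A new `emg_recording` with scaled `data`.
#' @export
normalize_by_peak <- function(rec, peaks = apply(abs(rec$data), 1, max)) {
  stopifnot(inherits(rec, "emg_recording"))
  if (length(peaks) != n_channels(rec))
    stop_("`peaks` length (%d) != number of channels (%d)",
          length(peaks), n_channels(rec))
  bad <- which(!is.finite(peaks) | peaks <= 0)
  if (length(bad))
    stop_("non-positive reference peak for channel(s): %s",
          paste(rec$channel_names[bad], collapse = ", "))
  rec$data <- rec$data / peaks
  rec
}
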