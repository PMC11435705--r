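# Cohort files on disk: a directory holding `manifest.json` plus one CSV per
# recording (wide format: one column per channel, optional `label` column).
# Signal values are written as C "%.17g" literals so doubles round-trip
# exactly; everything is plain text.

#' Write a cohort of recordings to disk
#'
#' @param recs a list of [emg_recording()] objects (may be empty).
#' @param path directory to create/overwrite; becomes a cohort directory
#'   with a JSON manifest and one CSV file per recording.
#' @return `path`, invisibly.
#' @seealso [read_cohort()]
#' @export
write_cohort <- function(recs, path) {
  if (inherits(recs, "emg_recording")) recs <- list(recs)
  if (!all(vapply(recs, inherits, TRUE, "emg_recording")))
    stop_("`recs` must be a list of emg_recording objects")
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  entries <- vector("list", length(recs))
  for (i in seq_along(recs)) {
    r <- recs[[i]]
    file <- sprintf("rec_%03d.csv", i)
    dt <- data.table::as.data.table(
      lapply(seq_len(n_channels(r)), function(c) sprintf("%.17g", r$data[c, ])))
    data.table::setnames(dt, r$channel_names)
    if (!is.null(r$labels)) dt[["label"]] <- r$labels
    data.table::fwrite(dt, file.path(path, file))
    entries[[i]] <- list(
      file = file, subject_id = r$subject_id, trial_id = r$trial_id,
      fs = r$fs, channel_names = as.list(r$channel_names),
      n_channels = n_channels(r), n_samples = n_samples(r),
      labeled = !is.null(r$labels))
  }
  manifest <- list(format = "emgadapt-cohort", version = 1L,
                   n_recordings = length(recs), recordings = entries)
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}

#' Read a cohort of recordings from disk
#'
#' @param path a cohort directory written by [write_cohort()].
#' @return a list of [emg_recording()] objects in manifest order.
#' @export
read_cohort <- function(path) {
  mf <- file.path(path, "manifest.json")
  if (!file.exists(mf))
    stop_("no cohort manifest found at %s", mf)
  manifest <- jsonlite::read_json(mf)
  if (!identical(manifest$format, "emgadapt-cohort"))
    stop_("%s is not an emgadapt cohort manifest", mf)
  lapply(manifest$recordings, function(e) {
    required <- c("file", "subject_id", "fs")
    missing <- required[!vapply(required, function(f) !is.null(e[[f]]), TRUE)]
    if (length(missing))
      stop_("cohort manifest entry is missing required field(s): %s",
            paste(missing, collapse = ", "))
    dt <- data.table::fread(file.path(path, e$file), colClasses = "numeric")
    chn <- unlist(e$channel_names)
    labels <- if (isTRUE(e$labeled)) as.integer(dt[["label"]]) else NULL
    data <- t(as.matrix(dt[, chn, with = FALSE]))
    dimnames(data) <- NULL
    emg_recording(data, fs = e$fs, subject_id = e$subject_id,
                  labels = labels, channel_names = chn,
                  trial_id = e$trial_id %||% "t1")
  })
}
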