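#' Multi-channel MEA recording
#'
#' Raw extracellular voltage of one well: a channels-by-samples matrix in
#' microvolts plus the sampling rate and channel identities.
#'
#' @param well_id well identifier.
#' @param signal numeric matrix, channels x samples, microvolts.
#' @param sampling_rate_hz sampling rate (Hz), typically 10000.
#' @param channel_ids character vector naming the rows of `signal`;
#'   defaults to `"ch01"`, `"ch02"`, ...
#' @param t0_s time of the first sample (s).
#' @return An object of class `mea_recording`.
#' @export
mea_recording <- function(well_id, signal, sampling_rate_hz = 10000,
                          channel_ids = NULL, t0_s = 0) {
  signal <- as.matrix(signal)
  storage.mode(signal) <- "double"
  if (is.null(channel_ids))
    channel_ids <- sprintf("ch%02d", seq_len(nrow(signal)))
  stopifnot(length(channel_ids) == nrow(signal), sampling_rate_hz > 0)
  if (any(!is.finite(signal))) {
    bad <- which(!is.finite(signal), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-finite sample in channel %s at index %d",
                 channel_ids[bad[1L]], bad[2L]))
  }
  structure(list(well_id = as.character(well_id),
                 channel_ids = as.character(channel_ids),
                 signal = signal,
                 sampling_rate_hz = as.numeric(sampling_rate_hz),
                 t0_s = as.numeric(t0_s)),
            class = "mea_recording")
}

#' @export
print.mea_recording <- function(x, ...) {
  cat(sprintf("MEA recording, well %s: %d channels x %d samples (%.1f s at %g Hz)\n",
              x$well_id, nrow(x$signal), ncol(x$signal),
              ncol(x$signal) / x$sampling_rate_hz, x$sampling_rate_hz))
  invisible(x)
}

#' Duration of a recording in seconds
#' @param recording a [mea_recording()].
#' @export
recording_duration <- function(recording) {
  ncol(recording$signal) / recording$sampling_rate_hz
}

#' Per-channel spike trains of one well
#'
#' @param well_id well identifier.
#' @param trains named list of numeric vectors, spike times in seconds,
#'   strictly increasing within each channel.
#' @param duration_s recording duration (s), if known; used for firing
#'   rates and activity thresholds.
#' @return An object of class `spike_train_set`.
#' @export
spike_train_set <- function(well_id, trains, duration_s = NA_real_) {
  stopifnot(is.list(trains))
  if (length(trains) &&
      (is.null(names(trains)) || anyDuplicated(names(trains))))
    stop("trains must be a named list with unique channel ids")
  for (ch in names(trains)) {
    t <- trains[[ch]]
    if (length(t) && (anyNA(t) || any(t < 0)))
      stop(sprintf("channel %s has negative or missing spike times", ch))
    if (length(t) > 1L && is.unsorted(t, strictly = TRUE))
      stop(sprintf("channel %s spike times are not strictly increasing", ch))
    trains[[ch]] <- as.numeric(t)
  }
  structure(list(well_id = as.character(well_id), trains = trains,
                 duration_s = as.numeric(duration_s)),
            class = "spike_train_set")
}

#' @export
print.spike_train_set <- function(x, ...) {
  cat(sprintf("Spike trains, well %s: %d channels, %d spikes%s\n",
              x$well_id, length(x$trains), sum(lengths(x$trains)),
              if (is.na(x$duration_s)) ""
              else sprintf(" over %.1f s", x$duration_s)))
  invisible(x)
}
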