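#' Spike detection configuration
#'
#' @param threshold_sd detection threshold as a multiple of the baseline
#'   standard deviation (default 5, i.e. spikes cross +/-5 SD).
#' @param refractory_ms dead time after an accepted threshold crossing
#'   during which further crossings are ignored (ms).
#' @param alignment `"extremum"` places the spike time at the local
#'   extremum of the deviation within 2 ms after the crossing;
#'   `"crossing"` uses the crossing sample itself.
#' @param search_span_s portion of the recording searched for quiet
#'   baseline segments (default the first 10 s).
#' @param apply_bandpass apply a 2nd-order 100 Hz high-pass and 4th-order
#'   3.5 kHz low-pass Butterworth filter before detection, mirroring a
#'   typical MEA acquisition chain.  Off by default: real recordings
#'   normally arrive already filtered.
#' @param exclude_noisy_uv if non-`NULL`, channels whose quiet-segment RMS
#'   exceeds this many microvolts are reported as excluded by
#'   [detect_spikes_recording()].
#' @return A list of class `spike_detect_config`.
#' @export
spike_detect_config <- function(threshold_sd = 5, refractory_ms = 1,
                                alignment = c("extremum", "crossing"),
                                search_span_s = 10, apply_bandpass = FALSE,
                                exclude_noisy_uv = NULL) {
  stopifnot(threshold_sd > 0, refractory_ms > 0, search_span_s > 0)
  structure(list(threshold_sd = threshold_sd, refractory_ms = refractory_ms,
                 alignment = match.arg(alignment),
                 search_span_s = search_span_s,
                 apply_bandpass = isTRUE(apply_bandpass),
                 exclude_noisy_uv = exclude_noisy_uv),
            class = "spike_detect_config")
}

#' Estimate baseline noise from quiet segments
#'
#' Finds the two non-overlapping 200-ms windows with the lowest
#' root-mean-square amplitude inside the first `search_span_s` seconds of
#' the channel and takes them as activity-free baseline; the baseline mean
#' and standard deviation are computed over their concatenation.
#'
#' @param channel_signal numeric vector, one channel's voltage trace (uV).
#' @param sampling_rate_hz sampling rate in Hz.
#' @param config a [spike_detect_config()].
#' @return A list of class `baseline_estimate` with `mean_uv`, `sd_uv`,
#'   `segment_starts_s` (the two chosen window starts) and `rms_uv`.
#' @export
estimate_baseline <- function(channel_signal, sampling_rate_hz,
                              config = spike_detect_config()) {
  win <- round(0.2 * sampling_rate_hz)
  n <- length(channel_signal)
  if (n < 2L * win)
    stop("signal shorter than 2 x 200 ms; cannot estimate baseline")
  span <- min(n, round(config$search_span_s * sampling_rate_hz))
  x <- channel_signal[seq_len(span)]
  # candidate windows on a 50-ms grid (finer than the window, coarse
  # enough to stay cheap on long spans)
  step <- max(1L, round(0.05 * sampling_rate_hz))
  starts <- seq(1L, span - win + 1L, by = step)
  cum2 <- cumsum(c(0, x^2))
  rms <- sqrt((cum2[starts + win] - cum2[starts]) / win)
  ord <- order(rms)
  first <- ord[1L]
  # lowest-RMS window not overlapping the first
  second <- ord[which(abs(starts[ord] - starts[first]) >= win)[1L]]
  if (is.na(second))
    stop("could not find two non-overlapping quiet segments")
  seg <- c(channel_signal[starts[first] + seq_len(win) - 1L],
           channel_signal[starts[second] + seq_len(win) - 1L])
  est <- list(mean_uv = mean(seg), sd_uv = stats::sd(seg),
              rms_uv = sqrt(mean(seg^2)),
              segment_starts_s = sort((starts[c(first, second)] - 1L) /
                                        sampling_rate_hz))
  if (est$sd_uv <= 0)
    stop("degenerate baseline: quiet segments have zero variance (flat signal)")
  structure(est, class = "baseline_estimate")
}

#' Detect spikes by threshold crossing
#'
#' A spike is emitted wherever the absolute deviation of the signal from
#' the baseline mean first exceeds `threshold_sd * sd_uv` (so positive-
#' and negative-going deflections are treated symmetrically).  With
#' `alignment = "extremum"` the spike time is the local extremum of the
#' deviation within 2 ms after the crossing.  Crossings within
#' `refractory_ms` of the previous accepted crossing are suppressed.
#'
#' @inheritParams estimate_baseline
#' @param baseline a [estimate_baseline()] result for this channel.
#' @return Strictly increasing numeric vector of spike times (s).
#' @export
detect_spikes <- function(channel_signal, sampling_rate_hz, baseline,
                          config = spike_detect_config()) {
  stopifnot(inherits(baseline, "baseline_estimate"))
  if (baseline$sd_uv <= 0) stop("degenerate baseline (sd 0)")
  if (config$apply_bandpass)
    channel_signal <- mea_bandpass(channel_signal, sampling_rate_hz)
  dev <- abs(channel_signal - baseline$mean_uv)
  thr <- config$threshold_sd * baseline$sd_uv
  above <- dev > thr
  # rising edges: first sample of each excursion above threshold
  edges <- which(above & !c(FALSE, above[-length(above)]))
  if (length(edges) == 0L) return(numeric(0))
  dead <- config$refractory_ms / 1000 * sampling_rate_hz
  keep <- logical(length(edges))
  last <- -Inf
  for (k in seq_along(edges)) {
    if (edges[k] - last >= dead) {
      keep[k] <- TRUE
      last <- edges[k]
    }
  }
  edges <- edges[keep]
  if (config$alignment == "extremum") {
    look <- round(0.002 * sampling_rate_hz)
    n <- length(dev)
    idx <- vapply(edges, function(e) {
      w <- e:min(n, e + look)
      w[which.max(dev[w])]
    }, 0L)
  } else {
    idx <- edges
  }
  t <- sort(unique((idx - 1L) / sampling_rate_hz))
  t
}

#' Run baseline estimation and spike detection on a whole recording
#'
#' @param recording a [mea_recording()].
#' @param config a [spike_detect_config()].
#' @return A [spike_train_set()]; channels whose baseline is degenerate
#'   yield empty trains with a warning, and channels excluded by the
#'   `exclude_noisy_uv` pre-filter are reported in the
#'   `excluded_channels` attribute.
#' @export
detect_spikes_recording <- function(recording, config = spike_detect_config()) {
  stopifnot(inherits(recording, "mea_recording"))
  fs <- recording$sampling_rate_hz
  trains <- stats::setNames(vector("list", length(recording$channel_ids)),
                            recording$channel_ids)
  excluded <- character(0)
  for (i in seq_along(recording$channel_ids)) {
    ch <- recording$channel_ids[i]
    sig <- recording$signal[i, ]
    bl <- tryCatch(estimate_baseline(sig, fs, config), error = function(e) e)
    if (inherits(bl, "error")) {
      warning(sprintf("channel %s: %s; emitting no spikes", ch,
                      conditionMessage(bl)))
      trains[[ch]] <- numeric(0)
      next
    }
    if (!is.null(config$exclude_noisy_uv) &&
        bl$rms_uv > config$exclude_noisy_uv) {
      excluded <- c(excluded, ch)
      trains[[ch]] <- numeric(0)
      next
    }
    trains[[ch]] <- detect_spikes(sig, fs, bl, config) + recording$t0_s
  }
  out <- spike_train_set(recording$well_id, trains,
                         duration_s = ncol(recording$signal) / fs)
  attr(out, "excluded_channels") <- excluded
  out
}

# Acquisition-chain style filter: 2nd-order high-pass at 100 Hz followed
# by a 4th-order low-pass at 3.5 kHz (Butterworth, zero-phase not needed
# for threshold detection).
mea_bandpass <- function(x, fs) {
  ny <- fs / 2
  hp <- signal::butter(2, 100 / ny, type = "high")
  x <- signal::filter(hp, x)
  if (3500 < ny) {
    lp <- signal::butter(4, 3500 / ny, type = "low")
    x <- signal::filter(lp, x)
  }
  as.numeric(x)
}
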