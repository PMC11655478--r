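#' MaxInterval detector parameters
#'
#' Bundle of the five parameters of the MaxInterval burst detector.  The
#' first three (maximum inter-spike interval to start a burst, maximum
#' interval to end it, and minimum interval between bursts) are the
#' data-dependent ones that the regression model of [predict_params()]
#' learns; the last two (minimum duration, minimum number of spikes) are
#' conventionally held fixed.
#'
#' All intervals are in milliseconds, matching how these parameters are
#' quoted in the MEA literature and in acquisition software.
#'
#' @param max_start_ms maximum inter-spike interval (ms) that opens a
#'   candidate reverberation.
#' @param max_end_ms maximum inter-spike interval (ms) that extends a
#'   candidate once open.
#' @param min_between_ms candidates closer together than this gap (ms) are
#'   merged into one.
#' @param min_duration_ms candidates shorter than this (ms) are discarded.
#' @param min_spikes candidates with fewer spikes than this are discarded.
#' @return An object of class `maxinterval_params` (a named list).
#' @examples
#' maxinterval_params()                    # hippocampal defaults 15/20/25/20/5
#' maxinterval_preset("cortical_isi100")   # 100/100/200/20/5
#' @export
maxinterval_params <- function(max_start_ms = 15, max_end_ms = 20,
                               min_between_ms = 25, min_duration_ms = 20,
                               min_spikes = 5L) {
  p <- list(max_start_ms = as.numeric(max_start_ms),
            max_end_ms = as.numeric(max_end_ms),
            min_between_ms = as.numeric(min_between_ms),
            min_duration_ms = as.numeric(min_duration_ms),
            min_spikes = as.integer(min_spikes))
  vals <- unlist(p[1:4])
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all MaxInterval intervals must be positive and finite")
  if (is.na(p$min_spikes) || p$min_spikes < 1L)
    stop("min_spikes must be an integer >= 1")
  structure(p, class = "maxinterval_params")
}

#' Named MaxInterval parameter presets
#'
#' `"hippocampal_default"` (15/20/25/20/5) suits reverberating hippocampal
#' cultures; `"cortical_isi100"` (100/100/200/20/5) widens the inter-spike
#' interval thresholds for the slower, non-reverberating bursts of cortical
#' cultures.
#'
#' @param name preset name.
#' @return A [maxinterval_params()] object.
#' @export
maxinterval_preset <- function(name = c("hippocampal_default", "cortical_isi100")) {
  switch(match.arg(name),
         hippocampal_default = maxinterval_params(15, 20, 25, 20, 5L),
         cortical_isi100 = maxinterval_params(100, 100, 200, 20, 5L))
}

#' @export
print.maxinterval_params <- function(x, ...) {
  cat(sprintf(paste0("MaxInterval parameters: start<=%g ms, end<=%g ms, ",
                     "between>=%g ms, duration>=%g ms, spikes>=%d\n"),
              x$max_start_ms, x$max_end_ms, x$min_between_ms,
              x$min_duration_ms, x$min_spikes))
  invisible(x)
}
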