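#' Detect reverberations on one channel with the MaxInterval method
#'
#' Three-phase MaxInterval detector.  Phase 1 scans the inter-spike
#' intervals (ISIs): a candidate opens at spike *i* when
#' `ISI(i, i+1) <= max_start_ms` and extends while successive ISIs stay
#' `<= max_end_ms` (the opening pair is part of the candidate).  Phase 2
#' merges adjacent candidates whose gap (next first spike minus previous
#' last spike) is strictly below `min_between_ms`.  Phase 3 discards
#' candidates shorter than `min_duration_ms` or with fewer than
#' `min_spikes` spikes.  An event spans its first to its last spike.
#'
#' The default phase order is merge-then-filter, the convention of the
#' widely used MaxInterval implementations; `phase_order = "filter_merge"`
#' applies the duration/count filter before merging instead.
#'
#' @param spike_times numeric vector of spike times in seconds, strictly
#'   increasing.
#' @param params a [maxinterval_params()] object.
#' @param phase_order `"merge_filter"` (default) or `"filter_merge"`.
#' @return A data frame with one row per reverberation and columns
#'   `start_s`, `end_s`, `n_spikes`.
#' @examples
#' detect_reverberations(c(0, 10, 20, 30, 40) / 1000, maxinterval_params())
#' @export
detect_reverberations <- function(spike_times, params = maxinterval_params(),
                                  phase_order = c("merge_filter", "filter_merge")) {
  phase_order <- match.arg(phase_order)
  stopifnot(inherits(params, "maxinterval_params"))
  if (length(spike_times) == 0L) return(empty_events())
  if (anyNA(spike_times) || any(!is.finite(spike_times)))
    stop("spike_times must be finite")
  if (is.unsorted(spike_times, strictly = TRUE))
    stop("spike_times must be strictly increasing")

  cand <- mi_candidates(spike_times, params$max_start_ms / 1000,
                        params$max_end_ms / 1000)
  if (phase_order == "merge_filter") {
    cand <- mi_merge(cand, params$min_between_ms / 1000)
    cand <- mi_filter(cand, params$min_duration_ms / 1000, params$min_spikes)
  } else {
    cand <- mi_filter(cand, params$min_duration_ms / 1000, params$min_spikes)
    cand <- mi_merge(cand, params$min_between_ms / 1000)
  }
  cand
}

empty_events <- function() {
  data.frame(start_s = numeric(0), end_s = numeric(0), n_spikes = integer(0))
}

# Phase 1: single left-to-right scan over ISIs.  A spike consumed by a
# candidate cannot open the next one.
mi_candidates <- function(t, max_start_s, max_end_s) {
  n <- length(t)
  if (n < 2L) return(empty_events())
  isi <- diff(t)
  starts <- integer(0); ends <- integer(0)
  i <- 1L
  while (i < n) {
    if (isi[i] <= max_start_s) {
      j <- i + 1L
      while (j < n && isi[j] <= max_end_s) j <- j + 1L
      starts <- c(starts, i); ends <- c(ends, j)
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  data.frame(start_s = t[starts], end_s = t[ends],
             n_spikes = ends - starts + 1L)
}

# Phase 2: merge runs of candidates with strict gap < min_between.
mi_merge <- function(ev, min_between_s) {
  if (nrow(ev) < 2L) return(ev)
  gaps <- ev$start_s[-1L] - ev$end_s[-nrow(ev)]
  grp <- cumsum(c(0, as.integer(!(gaps < min_between_s))))
  data.frame(
    start_s = tapply(ev$start_s, grp, min),
    end_s = tapply(ev$end_s, grp, max),
    n_spikes = as.integer(tapply(ev$n_spikes, grp, sum)),
    row.names = NULL)
}

# Phase 3: drop short or sparse candidates (strict <).
mi_filter <- function(ev, min_duration_s, min_spikes) {
  keep <- (ev$end_s - ev$start_s) >= min_duration_s - 1e-12 &
    ev$n_spikes >= min_spikes
  ev[keep, , drop = FALSE]
}

#' Merge timed events separated by short gaps
#'
#' Maximal runs of non-overlapping, ordered events whose successive gaps
#' (next start minus previous end) are strictly below `max_gap_ms` become
#' one parent event spanning the run; spike counts are summed and the
#' member events are kept as children.  With the default 300 ms gap this
#' is the rule that combines reverberations into bursts and network
#' reverberations into network bursts.
#'
#' @param events data frame with columns `start_s`, `end_s`, `n_spikes`
#'   (extra columns are carried into the children), ordered by `start_s`
#'   and non-overlapping.
#' @param max_gap_ms merge gap in milliseconds; a gap exactly equal to it
#'   does **not** merge (strict `<`).
#' @return A data frame of parents with columns `start_s`, `end_s`,
#'   `n_spikes`, `n_children` and a list-column `children` holding the
#'   member events of each parent.
#' @export
merge_events <- function(events, max_gap_ms = 300) {
  stopifnot(is.data.frame(events), max_gap_ms > 0)
  n <- nrow(events)
  if (n == 0L)
    return(cbind(empty_events(),
                 data.frame(n_children = integer(0)),
                 data.frame(children = I(list()))))
  if (is.unsorted(events$start_s)) stop("events must be ordered by start_s")
  if (n > 1L && any(events$start_s[-1L] < events$end_s[-n] - 1e-12))
    stop("events must be non-overlapping")
  gaps <- if (n > 1L) events$start_s[-1L] - events$end_s[-n] else numeric(0)
  grp <- cumsum(c(0L, as.integer(!(gaps < max_gap_ms / 1000))))
  idx <- split(seq_len(n), grp)
  out <- data.frame(
    start_s = vapply(idx, function(i) events$start_s[i[1L]], 0),
    end_s = vapply(idx, function(i) events$end_s[i[length(i)]], 0),
    n_spikes = vapply(idx, function(i) sum(events$n_spikes[i]), 0L),
    n_children = lengths(idx),
    row.names = NULL)
  out$children <- I(lapply(idx, function(i) events[i, , drop = FALSE]))
  out
}
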