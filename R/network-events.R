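#' Network-level detection criteria
#'
#' A well-level (network) reverberation requires that at least
#' `participation_fraction` of the well's active channels contribute a
#' reverberation to a group of temporally overlapping reverberations, of
#' which at least `simultaneity_fraction` are open at the same instant.
#'
#' @param participation_fraction fraction of active channels that must
#'   participate (default 2/3).
#' @param simultaneity_fraction fraction that must be simultaneously
#'   active (default 1/2).
#' @param simultaneity_base `"required"` reads the simultaneity fraction
#'   against the required participation count
#'   (`ceil(simultaneity_fraction * ceil(participation_fraction * n_active))`);
#'   `"actual"` reads it against the number of channels actually
#'   participating in the candidate.
#' @param active_mfr_hz minimum firing rate (Hz) for a channel to count as
#'   active (default 0.1).
#' @param merge_gap_ms gap below which network reverberations merge into
#'   network bursts (default 300 ms, strict `<`).
#' @return A list of class `network_criteria`.
#' @export
network_criteria <- function(participation_fraction = 2 / 3,
                             simultaneity_fraction = 1 / 2,
                             simultaneity_base = c("required", "actual"),
                             active_mfr_hz = 0.1,
                             merge_gap_ms = 300) {
  stopifnot(participation_fraction > 0, participation_fraction <= 1,
            simultaneity_fraction > 0, simultaneity_fraction <= 1,
            active_mfr_hz >= 0, merge_gap_ms > 0)
  structure(list(participation_fraction = participation_fraction,
                 simultaneity_fraction = simultaneity_fraction,
                 simultaneity_base = match.arg(simultaneity_base),
                 active_mfr_hz = active_mfr_hz,
                 merge_gap_ms = merge_gap_ms),
            class = "network_criteria")
}

#' Channels active enough to enter the network criteria
#'
#' @param spike_trains a [spike_train_set()].
#' @param duration_s recording duration (s); defaults to the set's own.
#' @param criteria a [network_criteria()].
#' @return Character vector of channel ids with firing rate
#'   `>= active_mfr_hz`.
#' @export
active_channels <- function(spike_trains, duration_s = spike_trains$duration_s,
                            criteria = network_criteria()) {
  stopifnot(inherits(spike_trains, "spike_train_set"), duration_s > 0)
  rate <- lengths(spike_trains$trains) / duration_s
  if (criteria$active_mfr_hz == 0)
    return(names(spike_trains$trains)[lengths(spike_trains$trains) >= 1L])
  names(spike_trains$trains)[rate >= criteria$active_mfr_hz]
}

#' Detect well-level network reverberations
#'
#' Candidate events are connected components of temporal overlap among
#' all active channels' reverberation intervals (intervals are chained
#' while their half-open spans intersect).  A candidate is accepted when
#' (a) it involves at least `ceil(participation_fraction * n_active)`
#' distinct channels, and (b) at some instant at least
#' `ceil(simultaneity_fraction * participation_threshold)` of its
#' reverberations are simultaneously open (sweep-line maximum).  The
#' accepted event spans its earliest child start to its latest child end.
#'
#' @param reverberations named list (by channel id) of reverberation data
#'   frames as returned by [detect_reverberations()].
#' @param active character vector of active channel ids (see
#'   [active_channels()]); reverberations on other channels are an error.
#' @param criteria a [network_criteria()].
#' @return A data frame with one row per network reverberation: `start_s`,
#'   `end_s`, `n_spikes`, `n_channels`, `max_simultaneous` and a
#'   list-column `children` of the member reverberations (with a
#'   `channel` column).
#' @export
detect_network_reverberations <- function(reverberations, active,
                                          criteria = network_criteria()) {
  stopifnot(is.list(reverberations))
  if (length(active) == 0L) stop("no active channels")
  extra <- setdiff(names(reverberations)[vapply(reverberations, nrow, 0L) > 0L],
                   active)
  if (length(extra))
    stop("reverberations on channels not in the active set: ",
         paste(extra, collapse = ", "))

  empty <- data.frame(start_s = numeric(0), end_s = numeric(0),
                      n_spikes = integer(0), n_channels = integer(0),
                      max_simultaneous = integer(0))
  empty$children <- I(list())

  ev <- do.call(rbind, lapply(names(reverberations), function(ch) {
    r <- reverberations[[ch]]
    if (is.null(r) || nrow(r) == 0L) return(NULL)
    cbind(channel = ch, r[, c("start_s", "end_s", "n_spikes")])
  }))
  if (is.null(ev) || nrow(ev) == 0L) return(empty)
  ev <- ev[order(ev$start_s, ev$end_s), , drop = FALSE]

  need_part <- ceiling(criteria$participation_fraction * length(active))

  # connected components of interval overlap: a new component starts when
  # an interval begins at/after the running maximum end (half-open spans)
  run_end <- cummax_end(ev$end_s)
  comp <- cumsum(c(1L, as.integer(ev$start_s[-1L] >= run_end[-nrow(ev)])))
  idx <- split(seq_len(nrow(ev)), comp)

  rows <- lapply(idx, function(i) {
    sub <- ev[i, , drop = FALSE]
    n_ch <- length(unique(sub$channel))
    conc <- max_concurrency(sub$start_s, sub$end_s)
    base <- if (criteria$simultaneity_base == "required") need_part else n_ch
    need_sim <- ceiling(criteria$simultaneity_fraction * base)
    if (n_ch >= need_part && conc >= need_sim) {
      out <- data.frame(start_s = min(sub$start_s), end_s = max(sub$end_s),
                        n_spikes = sum(sub$n_spikes), n_channels = n_ch,
                        max_simultaneous = conc)
      out$children <- I(list(sub))
      out
    } else NULL
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (length(rows) == 0L) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

cummax_end <- function(end_s) cummax(end_s)

# sweep-line maximum number of simultaneously open intervals; zero-width
# intervals are treated as momentarily open at their start
max_concurrency <- function(start_s, end_s) {
  end_s <- pmax(end_s, start_s + 1e-12)
  times <- c(start_s, end_s)
  delta <- c(rep(1L, length(start_s)), rep(-1L, length(end_s)))
  ord <- order(times, delta)  # ends (-1) before starts (+1) at ties
  max(cumsum(delta[ord]))
}

#' Detect network bursts from network reverberations
#'
#' Network reverberations separated by a gap strictly below
#' `criteria$merge_gap_ms` (default 300 ms) are combined into network
#' bursts; this is [merge_events()] applied at the well level.
#'
#' @param network_reverberations output of
#'   [detect_network_reverberations()].
#' @param criteria a [network_criteria()].
#' @return Parent/children data frame as from [merge_events()].
#' @export
detect_network_bursts <- function(network_reverberations,
                                  criteria = network_criteria()) {
  merge_events(network_reverberations, criteria$merge_gap_ms)
}
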