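#' Compute the eight per-well network-dynamics outcome measures
#'
#' The measures fall into four categories.  Spiking activity: `mfr_hz`,
#' the mean firing rate over active channels.  Network synchronicity:
#' `pct_random_spikes`, the percentage of all spikes falling outside every
#' network-burst span, and `nbr_per_min`, network bursts per minute.
#' Network rhythmicity: `nibi_s`, the mean quiescent interval between
#' consecutive network bursts (previous end to next start), and
#' `cov_nibi`, its coefficient of variation (sample SD over mean).
#' Network burst characteristics: `nbd_s`, mean network-burst duration;
#' `net_reverb_dur_s`, mean network-reverberation duration; and `nbc`,
#' mean number of network reverberations per network burst.
#'
#' Measures whose defining sample is empty are `NA` (never coerced to 0):
#' `nibi_s` needs at least two network bursts and `cov_nibi` at least
#' three; `nbd_s`, `nbc` and `net_reverb_dur_s` need at least one event.
#'
#' @param spike_trains a [spike_train_set()].
#' @param network_reverberations data frame from
#'   [detect_network_reverberations()].
#' @param network_bursts data frame from [detect_network_bursts()].
#' @param duration_s analysis duration (s).
#' @param active character vector of active channel ids.
#' @param mfr_over `"active"` (default) averages the firing rate over
#'   active channels only; `"all"` over every recorded channel.
#' @param nibi_mode `"end_to_start"` (default) measures the quiescence
#'   between bursts; `"start_to_start"` measures burst-onset periods.
#' @return A one-row data frame with columns `well`, `mfr_hz`,
#'   `pct_random_spikes`, `nbr_per_min`, `nibi_s`, `cov_nibi`, `nbd_s`,
#'   `net_reverb_dur_s`, `nbc`.
#' @export
compute_well_metrics <- function(spike_trains, network_reverberations,
                                 network_bursts, duration_s,
                                 active = names(spike_trains$trains),
                                 mfr_over = c("active", "all"),
                                 nibi_mode = c("end_to_start", "start_to_start")) {
  stopifnot(inherits(spike_trains, "spike_train_set"), duration_s > 0)
  mfr_over <- match.arg(mfr_over)
  nibi_mode <- match.arg(nibi_mode)

  counts <- lengths(spike_trains$trains)
  mfr_chans <- if (mfr_over == "active") active else names(spike_trains$trains)
  mfr <- if (length(mfr_chans) == 0L) 0
         else mean(counts[mfr_chans] / duration_s)

  all_spikes <- unlist(spike_trains$trains, use.names = FALSE)
  nb <- network_bursts
  n_nb <- if (is.null(nb)) 0L else nrow(nb)

  pct_rs <- NA_real_
  if (length(all_spikes) > 0L) {
    inside <- rep(FALSE, length(all_spikes))
    if (n_nb > 0L)
      for (i in seq_len(n_nb))
        inside <- inside | (all_spikes >= nb$start_s[i] &
                              all_spikes <= nb$end_s[i])
    pct_rs <- 100 * sum(!inside) / length(all_spikes)
  }

  nbr <- n_nb / duration_s * 60

  nibi <- cov_nibi <- nbd <- nbc <- nr_dur <- NA_real_
  if (n_nb >= 1L) {
    nbd <- mean(nb$end_s - nb$start_s)
    nbc <- mean(nb$n_children)
  }
  if (n_nb >= 2L) {
    gaps <- switch(nibi_mode,
                   end_to_start = nb$start_s[-1L] - nb$end_s[-n_nb],
                   start_to_start = diff(nb$start_s))
    nibi <- mean(gaps)
    if (length(gaps) >= 2L) cov_nibi <- stats::sd(gaps) / mean(gaps)
  }
  if (!is.null(network_reverberations) && nrow(network_reverberations) > 0L)
    nr_dur <- mean(network_reverberations$end_s -
                     network_reverberations$start_s)

  data.frame(well = spike_trains$well_id, mfr_hz = mfr,
             pct_random_spikes = pct_rs, nbr_per_min = nbr,
             nibi_s = nibi, cov_nibi = cov_nibi, nbd_s = nbd,
             net_reverb_dur_s = nr_dur, nbc = nbc,
             stringsAsFactors = FALSE)
}
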