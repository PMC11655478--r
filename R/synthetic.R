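#' Configuration of the synthetic MEA well generator
#'
#' The generator emulates a 12-electrode well of a reverberating
#' (hippocampal-type) culture: network bursts recur with Gamma-distributed
#' quiescent intervals; each burst consists of one or more reverberations
#' (short high-frequency spike clusters) realized on each participating
#' channel with a jittered onset; isolated background and intra-burst
#' noise spikes are added.  Spike placement respects guard zones sized
#' from the generating MaxInterval parameters, so that running the
#' detector with those parameters reproduces the ground-truth
#' reverberations exactly — the synthetic analogue of an expert's optimal
#' parameter choice.
#'
#' @param n_channels electrodes per well (default 12).
#' @param duration_s recording length (s).
#' @param sampling_rate_hz sampling rate (Hz).
#' @param background_rate_hz rate of isolated background spikes per
#'   channel (Hz).
#' @param nibi_mean_s,nibi_shape mean and shape of the Gamma distribution
#'   of network inter-burst (quiescent) intervals.
#' @param reverb_lambda reverberations per burst are `1 + Poisson(reverb_lambda)`.
#' @param intra_isi_ms mean of the (truncated) exponential intra-
#'   reverberation inter-spike interval (ms).
#' @param reverb_spikes_mean mean spike count per reverberation (Poisson,
#'   floored at the detector's `min_spikes`).
#' @param gap_range_ms range of gaps between consecutive reverberations
#'   of a burst (ms); the lower end is raised to stay above the
#'   generating `max_start`/`max_end`/`min_between` guard.
#' @param participation probability that a channel takes part in a given
#'   network burst.
#' @param jitter_sd_ms SD of the per-channel onset jitter (ms).
#' @param amp_mean_uv,amp_sd_uv spike amplitude distribution (uV);
#'   amplitudes are truncated below at `8 * noise_sd_uv` so threshold
#'   detection can recover them.
#' @param noise_sd_uv Gaussian noise SD of the rendered signal (uV).
#' @param noise_spike_rate_hz rate of isolated noise spikes in the gaps
#'   between reverberations of a burst (Hz).
#' @param params generating [maxinterval_params()] — the ground-truth
#'   "optimal" detector parameters.
#' @param seed RNG seed; every draw of the generator flows from it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_channels = 12, duration_s = 600,
                       sampling_rate_hz = 10000,
                       background_rate_hz = 0.2,
                       nibi_mean_s = 6, nibi_shape = 4,
                       reverb_lambda = 2,
                       intra_isi_ms = 6, reverb_spikes_mean = 10,
                       gap_range_ms = c(60, 280),
                       participation = 0.85, jitter_sd_ms = 5,
                       amp_mean_uv = 40, amp_sd_uv = 8,
                       noise_sd_uv = 3, noise_spike_rate_hz = 2,
                       params = maxinterval_params(), seed = 1L) {
  stopifnot(n_channels >= 1, duration_s > 0, sampling_rate_hz > 0,
            background_rate_hz >= 0, nibi_mean_s > 0, nibi_shape > 0,
            reverb_lambda >= 0, intra_isi_ms > 0, reverb_spikes_mean >= 1,
            length(gap_range_ms) == 2L, participation >= 0,
            participation <= 1, jitter_sd_ms >= 0, noise_sd_uv >= 0,
            inherits(params, "maxinterval_params"))
  structure(as.list(environment()), class = "sim_config")
}

# guard distance (s): closer than this to an existing spike, an isolated
# spike could extend or open a detector candidate
sim_guard_s <- function(params) {
  1.05 * max(params$max_start_ms, params$max_end_ms) / 1000
}

# effective inter-reverberation gap range (s); errors when infeasible
sim_gap_range_s <- function(config) {
  p <- config$params
  lo <- max(config$gap_range_ms[1L],
            1.05 * max(p$max_start_ms, p$max_end_ms, p$min_between_ms)) / 1000
  hi <- config$gap_range_ms[2L] / 1000
  if (lo >= hi)
    stop("infeasible config: inter-reverberation gap range (",
         config$gap_range_ms[1L], "-", config$gap_range_ms[2L],
         " ms) lies below the MaxInterval guard scale")
  c(lo, hi)
}

# one reverberation's spike times starting at t0: ISIs from an
# exponential truncated well inside the start/end thresholds, redrawn
# until the span satisfies the duration criterion
sim_reverb <- function(t0, config) {
  p <- config$params
  bound <- 0.8 * min(p$max_start_ms, p$max_end_ms) / 1000
  mean_isi <- min(config$intra_isi_ms / 1000, 0.9 * bound)
  n <- max(p$min_spikes, stats::rpois(1L, config$reverb_spikes_mean))
  for (try in 1:200) {
    isi <- stats::rexp(n - 1L, rate = 1 / mean_isi)
    isi <- pmin(pmax(isi, 1e-3), bound)
    if (sum(isi) >= p$min_duration_ms / 1000) break
  }
  if (sum(isi) < p$min_duration_ms / 1000)  # stretch as a last resort
    isi <- isi * (p$min_duration_ms / 1000 * 1.05) / sum(isi)
  t0 + c(0, cumsum(isi))
}

#' Generate one synthetic well with full ground truth
#'
#' @param config a [sim_config()].
#' @return A list with `spike_trains` (a [spike_train_set()]) and `truth`:
#'   per-channel spike times and reverberation/burst intervals, the
#'   network reverberations and network bursts implied by the standard
#'   network rules, the generating parameters and the config.
#' @export
generate_well <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  p <- config$params
  gap_rng <- sim_gap_range_s(config)
  guard <- sim_guard_s(p)
  chans <- sprintf("ch%02d", seq_len(config$n_channels))
  rate <- config$nibi_shape / config$nibi_mean_s

  reverbs <- stats::setNames(
    lapply(chans, function(.) list()), chans)
  spikes <- stats::setNames(lapply(chans, function(.) numeric(0)), chans)
  burst_windows <- list()  # per network burst: list of per-channel reverb intervals

  t_cursor <- 0
  repeat {
    t_cursor <- t_cursor + stats::rgamma(1L, shape = config$nibi_shape,
                                         rate = rate)
    if (t_cursor > config$duration_s - 1) break
    n_rev <- 1L + stats::rpois(1L, config$reverb_lambda)
    gaps <- stats::runif(max(0L, n_rev - 1L), gap_rng[1L], gap_rng[2L])
    member <- stats::runif(config$n_channels) < config$participation
    burst_end <- t_cursor
    for (ci in which(member)) {
      ch <- chans[ci]
      t <- t_cursor + abs(stats::rnorm(1L, 0, config$jitter_sd_ms / 1000))
      for (r in seq_len(n_rev)) {
        st <- sim_reverb(t, config)
        reverbs[[ch]][[length(reverbs[[ch]]) + 1L]] <-
          c(start_s = st[1L], end_s = st[length(st)], n_spikes = length(st))
        spikes[[ch]] <- c(spikes[[ch]], st)
        burst_end <- max(burst_end, st[length(st)])
        if (r < n_rev) {
          # guarded noise spikes in the inter-reverberation gap
          g0 <- st[length(st)] + guard
          g1 <- st[length(st)] + gaps[r] - guard
          if (g1 > g0 && config$noise_spike_rate_hz > 0) {
            k <- stats::rpois(1L, config$noise_spike_rate_hz * (g1 - g0))
            if (k > 0L) {
              cand <- sort(stats::runif(k, g0, g1))
              keep <- cand[c(TRUE, diff(cand) > guard)]
              spikes[[ch]] <- c(spikes[[ch]], keep)
            }
          }
          t <- st[length(st)] + gaps[r]
        }
      }
    }
    t_cursor <- burst_end
  }

  # guarded background spikes over the whole record
  for (ch in chans) {
    k <- stats::rpois(1L, config$background_rate_hz * config$duration_s)
    if (k > 0L) {
      cand <- sort(stats::runif(k, 0, config$duration_s))
      existing <- sort(spikes[[ch]])
      ok <- logical(length(cand))
      last_kept <- -Inf
      for (i in seq_along(cand)) {
        x <- cand[i]
        j <- findInterval(x, existing)
        near <- min(if (j >= 1L) x - existing[j] else Inf,
                    if (j < length(existing)) existing[j + 1L] - x else Inf,
                    x - last_kept)
        if (near > guard) {
          ok[i] <- TRUE
          last_kept <- x
        }
      }
      spikes[[ch]] <- c(spikes[[ch]], cand[ok])
    }
    spikes[[ch]] <- sort(spikes[[ch]])
  }

  rev_df <- lapply(chans, function(ch) {
    if (length(reverbs[[ch]]) == 0L) return(empty_events())
    m <- do.call(rbind, reverbs[[ch]])
    df <- data.frame(start_s = m[, "start_s"], end_s = m[, "end_s"],
                     n_spikes = as.integer(m[, "n_spikes"]))
    df[order(df$start_s), , drop = FALSE]
  })
  names(rev_df) <- chans

  sts <- spike_train_set("sim_well", spikes, duration_s = config$duration_s)
  crit <- network_criteria()
  act <- active_channels(sts, criteria = crit)
  rev_act <- rev_df[act]
  net_rev <- detect_network_reverberations(rev_act, act, crit)
  net_burst <- detect_network_bursts(net_rev, crit)
  bursts <- lapply(rev_df, merge_events, max_gap_ms = crit$merge_gap_ms)

  list(spike_trains = sts,
       truth = list(reverberations = rev_df, bursts = bursts,
                    network_reverberations = net_rev,
                    network_bursts = net_burst,
                    active = act, params = p, config = config))
}

#' Render a voltage signal from spike trains
#'
#' Each spike becomes a biphasic extracellular waveform (dominant
#' negative phase, ~1 ms) whose extremum sits at the spike time, scaled
#' by a per-spike amplitude draw and superposed on Gaussian noise.
#'
#' @param spike_trains a [spike_train_set()].
#' @param config a [sim_config()] (uses amplitude and noise fields).
#' @param duration_s rendered length (s); defaults to the train set's.
#' @return A [mea_recording()].
#' @export
render_signal <- function(spike_trains, config = sim_config(),
                          duration_s = spike_trains$duration_s) {
  stopifnot(inherits(spike_trains, "spike_train_set"), duration_s > 0)
  fs <- config$sampling_rate_hz
  n <- round(duration_s * fs)
  w <- spike_waveform(fs)
  peak <- which.max(abs(w))
  chans <- names(spike_trains$trains)
  sig <- matrix(0, nrow = length(chans), ncol = n)
  for (i in seq_along(chans)) {
    x <- if (config$noise_sd_uv > 0) stats::rnorm(n, 0, config$noise_sd_uv)
         else numeric(n)
    for (t in spike_trains$trains[[i]]) {
      amp <- max(8 * config$noise_sd_uv,
                 stats::rnorm(1L, config$amp_mean_uv, config$amp_sd_uv))
      at <- round(t * fs) + 1L
      lo <- at - peak + 1L
      idx <- seq_along(w) + lo - 1L
      ok <- idx >= 1L & idx <= n
      x[idx[ok]] <- x[idx[ok]] + amp * w[ok]
    }
    sig[i, ] <- x
  }
  mea_recording(spike_trains$well_id, sig, fs, chans)
}

# biphasic unit waveform: sharp negative trough followed by a slower
# positive rebound, |trough| normalized to 1
spike_waveform <- function(fs) {
  t <- seq(0, 0.0012, by = 1 / fs)
  w <- -exp(-((t - 3e-4) / 1.2e-4)^2) + 0.35 * exp(-((t - 7e-4) / 2.5e-4)^2)
  w / max(abs(w))
}

#' Generate labelled 5-s training windows
#'
#' Each window is a single-channel 5-s realization (50,000 samples at
#' 10 kHz) containing one or more reverberating burst clusters whose
#' structure realizes window-specific MaxInterval parameters drawn from
#' `param_ranges`; the stored blocks are the rendered signal, the binary
#' spike raster, the binary occupancy of the ground-truth reverberations,
#' and the three generating parameters (max-start, max-end, min-between,
#' ms).  By construction, running [detect_reverberations()] on the spike
#' block with the stored parameters reproduces the burst block exactly.
#'
#' @param n number of windows.
#' @param param_ranges list with elements `max_start_ms`, `max_end_ms`,
#'   `min_between_ms`, each a `c(lo, hi)` range the window parameters are
#'   drawn from (uniformly).
#' @param config a [sim_config()] supplying waveform/noise/ISI settings;
#'   its `params` fix `min_duration_ms`/`min_spikes`.
#' @param seed RNG seed.
#' @param clusters_mean mean number of burst clusters per window
#'   (`1 + Poisson(clusters_mean - 1)`).
#' @return A list of `n` training samples (`signal`, `spikes`, `bursts`,
#'   `params_ms`).
#' @export
generate_training_dataset <- function(n,
                                      param_ranges = list(
                                        max_start_ms = c(8, 30),
                                        max_end_ms = c(10, 40),
                                        min_between_ms = c(15, 60)),
                                      config = sim_config(),
                                      seed = 1L, clusters_mean = 2) {
  stopifnot(n >= 1L)
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    par <- maxinterval_params(
      stats::runif(1L, param_ranges$max_start_ms[1L], param_ranges$max_start_ms[2L]),
      stats::runif(1L, param_ranges$max_end_ms[1L], param_ranges$max_end_ms[2L]),
      stats::runif(1L, param_ranges$min_between_ms[1L], param_ranges$min_between_ms[2L]),
      config$params$min_duration_ms, config$params$min_spikes)
    # every stored window must contain burst activity (the overlap-error
    # normalization is undefined on an all-zero target)
    for (try in 1:50) {
      w <- generate_training_window(par, config, clusters_mean)
      if (sum(w$bursts) > 0L) break
    }
    w
  })
}

# one 5-s single-channel window realizing `par`
generate_training_window <- function(par, config, clusters_mean) {
  wcfg <- config
  wcfg$params <- par
  fs <- config$sampling_rate_hz
  len <- 5 * fs
  gap_rng <- sim_gap_range_s(wcfg)
  guard <- sim_guard_s(par)

  k <- 1L + stats::rpois(1L, max(0, clusters_mean - 1))
  onsets <- sort(stats::runif(k, 0.2, 4.0))
  spikes <- numeric(0)
  rev_int <- list()
  for (on in onsets) {
    if (length(spikes) && on - max(spikes) < 0.35) next  # keep clusters apart
    n_rev <- 1L + stats::rpois(1L, config$reverb_lambda)
    t <- on
    for (r in seq_len(n_rev)) {
      if (t > 4.8) break
      st <- sim_reverb(t, wcfg)
      st <- st[st < 4.99]
      if (length(st) < par$min_spikes ||
          st[length(st)] - st[1L] < par$min_duration_ms / 1000) break
      rev_int[[length(rev_int) + 1L]] <- c(st[1L], st[length(st)])
      spikes <- c(spikes, st)
      gap <- stats::runif(1L, gap_rng[1L], gap_rng[2L])
      # guarded noise spike in the gap, occasionally
      g0 <- st[length(st)] + guard
      g1 <- st[length(st)] + gap - guard
      if (g1 > g0 && config$noise_spike_rate_hz > 0 &&
          stats::runif(1L) < config$noise_spike_rate_hz * (g1 - g0))
        spikes <- c(spikes, stats::runif(1L, g0, g1))
      t <- st[length(st)] + gap
    }
  }
  spikes <- sort(spikes)

  # quantize to the sample grid; blocks and ground truth share the grid
  idx <- unique(round(spikes * fs) + 1L)
  idx <- idx[idx >= 1L & idx <= len]
  spk_block <- integer(len)
  spk_block[idx] <- 1L
  qt <- (idx - 1L) / fs
  bst_block <- integer(len)
  for (iv in rev_int) {
    a <- round(iv[1L] * fs) + 1L
    b <- round(iv[2L] * fs) + 1L
    bst_block[a:b] <- 1L
  }
  sts <- spike_train_set("win", list(ch01 = qt), duration_s = 5)
  rec <- render_signal(sts, wcfg, duration_s = 5)
  list(signal = as.numeric(rec$signal[1L, ]),
       spikes = spk_block, bursts = bst_block,
       params_ms = c(par$max_start_ms, par$max_end_ms, par$min_between_ms))
}
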