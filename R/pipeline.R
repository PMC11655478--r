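#' Full default-parameter analysis of one well's spike trains
#'
#' Runs the event hierarchy bottom-up: per-channel reverberations
#' (MaxInterval), bursts (<300 ms merge), active-channel set, network
#' reverberations (participation/simultaneity criteria), network bursts,
#' and the eight outcome measures.
#'
#' @param spike_trains a [spike_train_set()] with known duration (or pass
#'   `duration_s`).
#' @param params a [maxinterval_params()].
#' @param criteria a [network_criteria()].
#' @param duration_s analysis duration; defaults to the set's own.
#' @param phase_order passed to [detect_reverberations()].
#' @return A list with `events` (`reverberations`, `bursts`,
#'   `network_reverberations`, `network_bursts`), `active`, `metrics`
#'   (one-row data frame) and `duration_s`.
#' @export
analyze_spike_trains <- function(spike_trains, params = maxinterval_params(),
                                 criteria = network_criteria(),
                                 duration_s = spike_trains$duration_s,
                                 phase_order = "merge_filter") {
  stopifnot(inherits(spike_trains, "spike_train_set"))
  if (is.na(duration_s)) stop("duration_s is required")
  rev_df <- lapply(spike_trains$trains, detect_reverberations, params = params,
                   phase_order = phase_order)
  finish_analysis(spike_trains, rev_df, criteria, duration_s)
}

# shared downstream stages: bursts, network events, metrics
finish_analysis <- function(spike_trains, rev_df, criteria, duration_s) {
  act <- active_channels(spike_trains, duration_s, criteria)
  rev_act <- rev_df[intersect(names(rev_df), act)]
  net_rev <- if (length(act))
    detect_network_reverberations(rev_act, act, criteria)
  else data.frame(start_s = numeric(0), end_s = numeric(0),
                  n_spikes = integer(0), n_channels = integer(0),
                  max_simultaneous = integer(0))
  net_burst <- detect_network_bursts(net_rev, criteria)
  bursts <- lapply(rev_df, merge_events, max_gap_ms = criteria$merge_gap_ms)
  metrics <- compute_well_metrics(spike_trains, net_rev, net_burst,
                                  duration_s, act)
  list(events = list(reverberations = rev_df, bursts = bursts,
                     network_reverberations = net_rev,
                     network_bursts = net_burst),
       active = act, metrics = metrics, duration_s = duration_s)
}

#' Analyze one or more input files end to end
#'
#' Accepts recordings (HDF5 or delimited voltage dumps, which go through
#' spike detection first) and/or spike tables.  Each well is analyzed
#' independently with either fixed default parameters or parameters
#' predicted per window by a model checkpoint; failures in one well are
#' reported and do not stop the others.
#'
#' @param inputs character vector of input paths.
#' @param mode `"default"` or `"model"`.
#' @param out_dir output directory for the per-run event CSV, metric CSV
#'   and JSON run manifest.
#' @param params a [maxinterval_params()] (default mode).
#' @param checkpoint model checkpoint directory (model mode).
#' @param criteria a [network_criteria()].
#' @param spike_config a [spike_detect_config()] for recording inputs.
#' @param seed run seed recorded in the manifest.
#' @return Invisibly, a list with `metrics` (stacked rows), `wells`
#'   (per-well results), `failures` (named error messages) and
#'   `manifest`.
#' @export
run_analysis <- function(inputs, mode = c("default", "model"),
                         out_dir = ".", params = maxinterval_params(),
                         checkpoint = NULL, criteria = network_criteria(),
                         spike_config = spike_detect_config(), seed = 1L) {
  mode <- match.arg(mode)
  model <- NULL
  if (mode == "model") {
    if (is.null(checkpoint)) stop("model mode requires a checkpoint")
    model <- load_model(checkpoint)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wells <- list(); failures <- character(0)
  metrics <- NULL

  for (path in inputs) {
    res <- tryCatch({
      is_rec <- grepl("\\.(h5|hdf5|tsv|txt)$", path, ignore.case = TRUE)
      if (is_rec) {
        rec <- read_recording(path)
        sts <- detect_spikes_recording(rec, spike_config)
        one <- if (mode == "default")
          analyze_spike_trains(sts, params, criteria)
        else analyze_with_model(sts, model, recording = rec,
                                criteria = criteria)
        list(well = sts$well_id, result = one, sts = sts)
      } else {
        tabs <- read_spike_table(path)
        if (inherits(tabs, "spike_train_set")) tabs <- list(tabs)
        lapply(tabs, function(sts) {
          if (is.na(sts$duration_s))
            sts$duration_s <- if (sum(lengths(sts$trains)))
              max(unlist(sts$trains)) else 1
          one <- if (mode == "default")
            analyze_spike_trains(sts, params, criteria)
          else analyze_with_model(sts, model, criteria = criteria)
          list(well = sts$well_id, result = one, sts = sts)
        })
      }
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures[path] <- conditionMessage(res)
      message("well analysis failed for ", path, ": ", conditionMessage(res))
      next
    }
    if (!is.null(res$well)) res <- list(res)
    for (r in res) {
      wells[[r$well]] <- r$result
      metrics <- rbind(metrics, r$result$metrics)
      write_event_table(r$result$events,
                        file.path(out_dir, paste0("events_", r$well, ".csv")),
                        well = r$well)
    }
  }
  if (!is.null(metrics))
    write_metric_table(metrics, file.path(out_dir, "metrics.csv"))

  manifest <- list(
    version = as.character(utils::packageVersion("meaburst")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed, mode = mode,
    inputs = lapply(stats::setNames(inputs, inputs), function(p)
      list(size = file.info(p)$size, digest = file_digest(p))),
    params = if (mode == "default") unclass(params) else NULL,
    checkpoint = checkpoint,
    criteria = unclass(criteria),
    wells = lapply(wells, function(w) list(
      n_network_bursts = nrow(w$events$network_bursts),
      n_network_reverberations = nrow(w$events$network_reverberations),
      n_active_channels = length(w$active))),
    failures = as.list(failures))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null")
  invisible(list(metrics = metrics, wells = wells, failures = failures,
                 manifest = manifest))
}

# cheap content digest (sum-based; avoids external digest packages)
file_digest <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  raw <- readBin(con, "raw", n = file.info(path)$size)
  v <- as.integer(raw)
  sprintf("%d-%d", length(v), sum(v * (seq_along(v) %% 997)) %% 2147483647)
}

#' Read an analysis configuration file
#'
#' A single YAML file with sections `spikes`, `maxinterval`, `network`,
#' `model` and `simulate`; every section is optional and unknown keys are
#' rejected.  `maxinterval` may name a `preset`
#' (`"hippocampal_default"` or `"cortical_isi100"`) and then override
#' individual parameters.
#'
#' @param path YAML file.
#' @return A list with `params`, `criteria`, `spike_config` and the raw
#'   `model`/`simulate` sections.
#' @export
read_analysis_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- c("spikes", "maxinterval", "network", "model", "simulate")
  bad <- setdiff(names(cfg), known)
  if (length(bad)) stop("unknown config sections: ", paste(bad, collapse = ", "))

  mi <- cfg$maxinterval
  params <- if (is.null(mi)) maxinterval_params() else {
    base <- if (!is.null(mi$preset)) maxinterval_preset(mi$preset)
            else maxinterval_params()
    mi$preset <- NULL
    for (k in names(mi)) base[[k]] <- mi[[k]]
    do.call(maxinterval_params, unclass(base))
  }
  criteria <- do.call(network_criteria, cfg$network %||% list())
  spike_config <- do.call(spike_detect_config, cfg$spikes %||% list())
  list(params = params, criteria = criteria, spike_config = spike_config,
       model = cfg$model, simulate = cfg$simulate)
}
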