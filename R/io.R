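#' @title Reading and writing MEA data
#' @description
#' All on-disk timestamps are in seconds and all MaxInterval parameters in
#' milliseconds; conversion happens only at these boundaries.  Two
#' recording layouts are supported:
#'
#' * **hdf5** (requires the `rhdf5` package): dataset `/signal`
#'   (channels x samples, microvolts), dataset `/channel_ids` (strings),
#'   root attributes `sampling_rate_hz` and `well_id`.
#' * **delimited**: a tab-separated text dump whose first two lines are
#'   `# well_id <id>` and `# sampling_rate_hz <rate>`, followed by a
#'   header of channel ids and one row per sample.
#'
#' Spike tables are CSV with header `well,channel,time_s`; event tables
#' `well,level,event_id,parent_id,channel,start_s,end_s,n_spikes`; metric
#' tables one row per well with the eight outcome measures.
#' @name mea_io
NULL

need_rhdf5 <- function() {
  if (!requireNamespace("rhdf5", quietly = TRUE))
    stop("the 'rhdf5' package is required for the HDF5 layout; ",
         "use layout = \"delimited\" otherwise")
}

guess_layout <- function(path) {
  if (grepl("\\.(h5|hdf5)$", path, ignore.case = TRUE)) "hdf5" else "delimited"
}

#' Write a recording
#'
#' @param recording a [mea_recording()].
#' @param path output file.
#' @param layout `"hdf5"` or `"delimited"`; guessed from the extension by
#'   default.
#' @return `path`, invisibly.
#' @export
write_recording <- function(recording, path, layout = guess_layout(path)) {
  stopifnot(inherits(recording, "mea_recording"))
  layout <- match.arg(layout, c("hdf5", "delimited"))
  if (layout == "hdf5") {
    need_rhdf5()
    if (file.exists(path)) unlink(path)
    rhdf5::h5createFile(path)
    rhdf5::h5write(recording$signal, path, "signal")
    rhdf5::h5write(recording$channel_ids, path, "channel_ids")
    fid <- rhdf5::H5Fopen(path)
    rhdf5::h5writeAttribute(recording$sampling_rate_hz, fid, "sampling_rate_hz")
    rhdf5::h5writeAttribute(recording$well_id, fid, "well_id")
    rhdf5::h5writeAttribute(recording$t0_s, fid, "t0_s")
    rhdf5::H5Fclose(fid)
    rhdf5::h5closeAll()
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c(sprintf("# well_id %s", recording$well_id),
                 sprintf("# sampling_rate_hz %.10g", recording$sampling_rate_hz),
                 sprintf("# t0_s %.10g", recording$t0_s),
                 paste(recording$channel_ids, collapse = "\t")), con)
    utils::write.table(format(t(recording$signal), digits = 17, trim = TRUE,
                              scientific = TRUE),
                       con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Read a recording
#'
#' @param path input file.
#' @param layout `"hdf5"` or `"delimited"`; guessed from the extension.
#' @return A [mea_recording()]; malformed files (missing sampling rate,
#'   ragged channels, non-finite samples) raise errors.
#' @export
read_recording <- function(path, layout = guess_layout(path)) {
  if (!file.exists(path)) stop("no such file: ", path)
  layout <- match.arg(layout, c("hdf5", "delimited"))
  if (layout == "hdf5") {
    need_rhdf5()
    att <- rhdf5::h5readAttributes(path, "/")
    if (is.null(att$sampling_rate_hz))
      stop("format error: missing sampling_rate_hz attribute")
    sig <- rhdf5::h5read(path, "signal")
    ids <- as.character(rhdf5::h5read(path, "channel_ids"))
    rhdf5::h5closeAll()
    mea_recording(as.character(att$well_id), sig,
                  as.numeric(att$sampling_rate_hz), ids,
                  t0_s = if (is.null(att$t0_s)) 0 else as.numeric(att$t0_s))
  } else {
    lines <- readLines(path)
    hdr <- grep("^# ", lines, value = TRUE)
    get_meta <- function(key) {
      m <- grep(paste0("^# ", key, " "), hdr, value = TRUE)
      if (length(m) == 0L) return(NULL)
      sub(paste0("^# ", key, " "), "", m[1L])
    }
    rate <- get_meta("sampling_rate_hz")
    if (is.null(rate)) stop("format error: missing sampling_rate_hz metadata")
    well <- get_meta("well_id")
    t0 <- get_meta("t0_s")
    body <- lines[!grepl("^# ", lines)]
    ids <- strsplit(body[1L], "\t", fixed = TRUE)[[1L]]
    rows <- strsplit(body[-1L], "\t", fixed = TRUE)
    if (length(rows) && any(lengths(rows) != length(ids)))
      stop("format error: ragged channels (unequal row lengths)")
    m <- matrix(as.numeric(unlist(rows, use.names = FALSE)),
                ncol = length(ids), byrow = TRUE)
    mea_recording(if (is.null(well)) "well" else well, t(m),
                  as.numeric(rate), ids,
                  t0_s = if (is.null(t0)) 0 else as.numeric(t0))
  }
}

#' Write a spike table
#'
#' @param spike_trains a [spike_train_set()].
#' @param path output CSV (`well,channel,time_s`).
#' @export
write_spike_table <- function(spike_trains, path) {
  stopifnot(inherits(spike_trains, "spike_train_set"))
  rows <- do.call(rbind, lapply(names(spike_trains$trains), function(ch) {
    t <- spike_trains$trains[[ch]]
    if (length(t) == 0L) return(NULL)
    data.frame(well = spike_trains$well_id, channel = ch, time_s = t)
  }))
  if (is.null(rows))
    rows <- data.frame(well = character(0), channel = character(0),
                       time_s = numeric(0))
  utils::write.csv(format_num_df(rows, "time_s"), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

format_num_df <- function(df, cols) {
  for (cc in intersect(cols, names(df)))
    df[[cc]] <- formatC(df[[cc]], digits = 12, format = "f", drop0trailing = TRUE)
  df
}

#' Read a spike table
#'
#' Rows are grouped per well; within each channel the times are sorted
#' and exact duplicate `(channel, time)` rows are collapsed with a
#' warning.  Unknown columns are ignored with a warning; negative times
#' are an error.
#'
#' @param path CSV with header `well,channel,time_s`.
#' @return A [spike_train_set()] if the file holds a single well,
#'   otherwise a named list of them.
#' @export
read_spike_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("well", "channel", "time_s")
  if (!all(need %in% names(df)))
    stop("spike table must have columns well,channel,time_s")
  extra <- setdiff(names(df), need)
  if (length(extra))
    warning("ignoring unknown columns: ", paste(extra, collapse = ", "))
  if (nrow(df) && any(df$time_s < 0)) stop("negative spike times")
  make_one <- function(sub) {
    trains <- lapply(split(sub$time_s, sub$channel), function(t) {
      st <- sort(t)
      if (anyDuplicated(st)) {
        warning("duplicate (channel,time) rows collapsed")
        st <- unique(st)
      }
      st
    })
    spike_train_set(sub$well[1L], trains)
  }
  if (nrow(df) == 0L) return(spike_train_set("well", list()))
  wells <- split(df, df$well)
  out <- lapply(wells, make_one)
  if (length(out) == 1L) out[[1L]] else out
}

#' Write an event table
#'
#' Flattens an event hierarchy (reverberations within bursts, network
#' reverberations within network bursts) into one CSV with parent
#' linkage ids.  `channel` is empty for network-level rows.
#'
#' @param events named list with any of `bursts` (per-channel list of
#'   [merge_events()] outputs), `network_bursts` ([merge_events()] output)
#'   and `network_reverberations`; the convenient source is
#'   [analyze_spike_trains()]`$events`.
#' @param path output CSV.
#' @param well well id written in the first column.
#' @export
write_event_table <- function(events, path, well = "well") {
  rows <- list()
  next_id <- 1L
  add <- function(level, parent_id, channel, start_s, end_s, n_spikes) {
    id <- next_id
    next_id <<- next_id + 1L
    rows[[length(rows) + 1L]] <<- data.frame(
      well = well, level = level, event_id = id,
      parent_id = ifelse(is.na(parent_id), "", as.character(parent_id)),
      channel = channel, start_s = start_s, end_s = end_s,
      n_spikes = n_spikes)
    id
  }
  if (!is.null(events$bursts)) {
    for (ch in names(events$bursts)) {
      b <- events$bursts[[ch]]
      for (i in seq_len(nrow(b))) {
        pid <- add("burst", NA, ch, b$start_s[i], b$end_s[i], b$n_spikes[i])
        kids <- b$children[[i]]
        for (j in seq_len(nrow(kids)))
          add("reverberation", pid, ch, kids$start_s[j], kids$end_s[j],
              kids$n_spikes[j])
      }
    }
  }
  if (!is.null(events$network_bursts)) {
    nb <- events$network_bursts
    for (i in seq_len(nrow(nb))) {
      pid <- add("network_burst", NA, "", nb$start_s[i], nb$end_s[i],
                 nb$n_spikes[i])
      kids <- nb$children[[i]]
      for (j in seq_len(nrow(kids)))
        add("network_reverberation", pid, "", kids$start_s[j], kids$end_s[j],
            kids$n_spikes[j])
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(well = character(0), level = character(0),
               event_id = integer(0), parent_id = character(0),
               channel = character(0), start_s = numeric(0),
               end_s = numeric(0), n_spikes = integer(0))
  utils::write.csv(format_num_df(out, c("start_s", "end_s")), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an event table back into a data frame
#' @param path event CSV written by [write_event_table()].
#' @export
read_event_table <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(parent_id = "character",
                                 channel = "character"))
}

#' Write / read a metric table
#'
#' One row per well with the eight outcome measures; `NA` marks measures
#' undefined for that well (never encoded as 0).
#'
#' @param metrics data frame as from [compute_well_metrics()] (rows may
#'   be stacked across wells).
#' @param path CSV path.
#' @export
write_metric_table <- function(metrics, path) {
  utils::write.csv(metrics, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @rdname write_metric_table
#' @export
read_metric_table <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Save / load a training dataset
#'
#' The container is HDF5 with datasets `signal`, `spikes` and `bursts`
#' (`n x 50000`), `params_ms` (`n x 3`, stored rounded to integer
#' milliseconds) and a root attribute `count`.
#'
#' @param samples list of training samples as produced by
#'   [generate_training_dataset()]: each has `signal`, `spikes`, `bursts`
#'   (length-50000 vectors) and `params_ms` (3 values, ms).
#' @param path container path.
#' @export
save_training_dataset <- function(samples, path) {
  need_rhdf5()
  stopifnot(length(samples) >= 1L)
  for (s in samples) validate_training_sample(s)
  n <- length(samples)
  sig <- t(vapply(samples, function(s) s$signal, numeric(50000L)))
  spk <- t(vapply(samples, function(s) as.integer(s$spikes), integer(50000L)))
  bst <- t(vapply(samples, function(s) as.integer(s$bursts), integer(50000L)))
  par <- t(vapply(samples, function(s) as.integer(round(s$params_ms)),
                  integer(3L)))
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  rhdf5::h5write(sig, path, "signal")
  rhdf5::h5write(spk, path, "spikes")
  rhdf5::h5write(bst, path, "bursts")
  rhdf5::h5write(par, path, "params_ms")
  fid <- rhdf5::H5Fopen(path)
  rhdf5::h5writeAttribute(n, fid, "count")
  rhdf5::H5Fclose(fid)
  rhdf5::h5closeAll()
  invisible(path)
}

#' @rdname save_training_dataset
#' @export
load_training_dataset <- function(path) {
  need_rhdf5()
  blocks <- c("signal", "spikes", "bursts", "params_ms")
  present <- rhdf5::h5ls(path)$name
  if (!all(blocks %in% present))
    stop("format error: container missing blocks ",
         paste(setdiff(blocks, present), collapse = ", "))
  sig <- rhdf5::h5read(path, "signal")
  spk <- rhdf5::h5read(path, "spikes")
  bst <- rhdf5::h5read(path, "bursts")
  par <- rhdf5::h5read(path, "params_ms")
  rhdf5::h5closeAll()
  if (ncol(sig) != 50000L || ncol(par) != 3L ||
      !all(dim(spk) == dim(sig)) || !all(dim(bst) == dim(sig)))
    stop("format error: block shape mismatch")
  lapply(seq_len(nrow(sig)), function(i) {
    s <- list(signal = as.numeric(sig[i, ]), spikes = as.integer(spk[i, ]),
              bursts = as.integer(bst[i, ]), params_ms = as.numeric(par[i, ]))
    validate_training_sample(s)
    s
  })
}

validate_training_sample <- function(s) {
  stopifnot(length(s$signal) == 50000L, length(s$spikes) == 50000L,
            length(s$bursts) == 50000L, length(s$params_ms) == 3L)
  if (!all(s$spikes %in% c(0L, 1L)) || !all(s$bursts %in% c(0L, 1L)))
    stop("spikes/bursts blocks must be binary")
  if (any(s$params_ms <= 0)) stop("params_ms must be positive")
  invisible(s)
}
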