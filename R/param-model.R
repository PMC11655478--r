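#' Preprocess a 5-s window into a model input
#'
#' A 5-s window at 10 kHz has 50,000 timestamps.  Signal windows are
#' min-max normalized to `[0, 1]` per window and then averaged within
#' consecutive bins of 30 timestamps (1667 bins; the final bin averages
#' the remaining 20 samples) or 100 timestamps (500 bins).  Spike rasters
#' are binned by an any-spike-in-bin indicator by default (`"binary"`),
#' or by the bin mean (`"mean"`).  Windows shorter than 50,000 samples
#' are right-padded with zeros before binning.
#'
#' @param window either a training sample (list with `signal` and
#'   `spikes` blocks) or a numeric vector (taken as the block matching
#'   the variant).
#' @param variant `"spikes30"`, `"signal30"` or `"signal100"`.
#' @param spike_binning `"binary"` or `"mean"` (spikes30 only).
#' @return Numeric vector of length 1667 (factor 30) or 500 (factor 100).
#' @export
preprocess_window <- function(window, variant = c("signal30", "spikes30", "signal100"),
                              spike_binning = c("binary", "mean")) {
  variant <- match.arg(variant)
  spike_binning <- match.arg(spike_binning)
  x <- if (is.list(window)) {
    if (variant == "spikes30") window$spikes else window$signal
  } else as.numeric(window)
  if (length(x) > 50000L) stop("window longer than 50000 samples")
  if (length(x) < 50000L) x <- c(x, numeric(50000L - length(x)))
  factor <- if (variant == "signal100") 100L else 30L
  if (variant != "spikes30") {
    rng <- range(x)
    if (diff(rng) == 0) {
      warning("window has zero dynamic range; returning all-zeros input")
      x <- numeric(50000L)
    } else {
      x <- (x - rng[1L]) / diff(rng)
    }
  }
  bins <- ceiling(50000L / factor)
  grp <- rep(seq_len(bins), each = factor, length.out = 50000L)
  out <- as.numeric(rowsum(x, grp) / tabulate(grp, bins))
  if (variant == "spikes30" && spike_binning == "binary")
    out <- as.numeric(out > 0)
  out
}

#' Burst-overlap error and custom accuracy
#'
#' The normalized timestamp-wise discrepancy between two binary burst
#' arrays, `A = sum(|b_p - b_t|) / sum(b_t)`: 0 when the predicted bursts
#' match the target exactly, 1 when the prediction is all zeros.  The
#' normalization by the target's active timestamps prevents trivially
#' good scores from empty predictions, so an all-zero **target** is an
#' error.  `custom_accuracy()` is the learning-curve companion,
#' `max(0, 1 - A)`.
#'
#' @param predicted_bursts,target_bursts equal-length binary vectors.
#' @return A non-negative scalar.
#' @export
burst_overlap_error <- function(predicted_bursts, target_bursts) {
  if (length(predicted_bursts) != length(target_bursts))
    stop("burst arrays must have equal length")
  denom <- sum(target_bursts)
  if (denom == 0)
    stop("target burst array is all-zero; overlap error is undefined")
  sum(abs(predicted_bursts - target_bursts)) / denom
}

#' @rdname burst_overlap_error
#' @export
custom_accuracy <- function(predicted_bursts, target_bursts) {
  max(0, 1 - burst_overlap_error(predicted_bursts, target_bursts))
}

#' Training configuration for the parameter-regression model
#'
#' @param variant input variant (see [preprocess_window()]).
#' @param architecture a [cnn_architecture()].
#' @param epochs,batch_size,learning_rate optimizer settings.
#' @param seed seed for initialization and shuffling.
#' @param split named fractions `train`/`validation`/`test`, summing to 1.
#' @param eval_accuracy also evaluate the burst-level custom accuracy on
#'   the validation split at each epoch (slower; off by default).
#' @param clip_bounds list of `c(lo, hi)` bounds (ms) applied to the
#'   predicted max-start, max-end and min-between.
#' @param min_duration_ms,min_spikes the two fixed MaxInterval parameters
#'   appended to every prediction.
#' @param spike_binning passed to [preprocess_window()].
#' @param standardize_targets regress z-scored targets (scaling fitted on
#'   the training split and inverted at prediction time) instead of raw
#'   milliseconds.  The three targets share a scale, so raw regression is
#'   the default; z-scoring helps when target magnitudes differ strongly.
#' @export
train_config <- function(variant = "signal30",
                         architecture = cnn_architecture(),
                         epochs = 30L, batch_size = 32L,
                         learning_rate = 1e-3, seed = 1L,
                         split = c(train = 0.7, validation = 0.15, test = 0.15),
                         eval_accuracy = FALSE,
                         clip_bounds = list(max_start_ms = c(2, 200),
                                            max_end_ms = c(2, 200),
                                            min_between_ms = c(2, 500)),
                         min_duration_ms = 20, min_spikes = 5L,
                         spike_binning = "binary",
                         standardize_targets = FALSE) {
  stopifnot(abs(sum(split) - 1) < 1e-8, epochs >= 0, batch_size >= 1)
  structure(list(variant = variant, architecture = architecture,
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, seed = as.integer(seed),
                 split = split, eval_accuracy = isTRUE(eval_accuracy),
                 clip_bounds = clip_bounds,
                 min_duration_ms = min_duration_ms,
                 min_spikes = as.integer(min_spikes),
                 spike_binning = spike_binning,
                 standardize_targets = isTRUE(standardize_targets)),
            class = "train_config")
}

#' Deterministic train/validation/test assignment
#' @keywords internal
split_dataset <- function(n, split, seed) {
  set.seed(seed + 1L)
  idx <- sample.int(n)
  n_tr <- round(split[["train"]] * n)
  n_va <- round(split[["validation"]] * n)
  list(train = idx[seq_len(n_tr)],
       validation = idx[n_tr + seq_len(min(n_va, n - n_tr))],
       test = idx[setdiff(seq_len(n), seq_len(n_tr + n_va))])
}

#' Train the parameter-regression CNN
#'
#' Mini-batch Adam on the mean-squared error between predicted and target
#' MaxInterval parameters (milliseconds).  Weights are updated from the
#' training split only; the learning curves record per-epoch train and
#' validation MSE (and, when `eval_accuracy` is on, the validation-split
#' mean custom accuracy of the bursts detected with the predicted
#' parameters).  Fully deterministic given the config seed.
#'
#' @param samples list of training samples (from
#'   [generate_training_dataset()] or [load_training_dataset()]).
#' @param config a [train_config()].
#' @param model optionally, a [build_model()] handle to continue training.
#' @return A list with `model` (trained handle), `curves` (one row per
#'   epoch) and `split` (the index assignment).
#' @export
train_model <- function(samples, config = train_config(), model = NULL) {
  stopifnot(length(samples) >= 10L)
  X <- t(vapply(samples,
                function(s) preprocess_window(s, config$variant,
                                              config$spike_binning),
                numeric(variant_length(config$variant))))
  Y <- t(vapply(samples, function(s) as.numeric(s$params_ms), numeric(3L)))
  sp <- split_dataset(length(samples), config$split, config$seed)
  if (length(sp$train) == 0L || length(sp$validation) == 0L)
    stop("train and validation splits must be non-empty")
  if (is.null(model)) model <- build_model(config)
  if (config$standardize_targets) {
    mu <- colMeans(Y[sp$train, , drop = FALSE])
    sdv <- apply(Y[sp$train, , drop = FALSE], 2L, stats::sd)
    sdv[!is.finite(sdv) | sdv == 0] <- 1
    model$target_scale <- list(mu = mu, sd = sdv)
    Y <- sweep(sweep(Y, 2L, mu), 2L, sdv, "/")
  }
  unscale <- function(p) {
    if (is.null(model$target_scale)) return(p)
    sweep(sweep(p, 2L, model$target_scale$sd, "*"), 2L,
          model$target_scale$mu, "+")
  }
  Y_ms <- t(vapply(samples, function(s) as.numeric(s$params_ms), numeric(3L)))
  opt <- adam_init(model$weights)

  curves <- data.frame(epoch = integer(0), train_mse = numeric(0),
                       val_mse = numeric(0), val_accuracy = numeric(0))
  set.seed(config$seed + 2L)
  for (ep in seq_len(config$epochs)) {
    ord <- sample(sp$train)
    batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
    tr_loss <- 0
    for (bt in batches) {
      fwd <- cnn_forward(model, X[bt, , drop = FALSE], keep_cache = TRUE)
      err <- fwd$out - Y[bt, , drop = FALSE]
      loss <- mean(err^2)
      if (!is.finite(loss))
        stop("training aborted: non-finite loss at epoch ", ep,
             " (learning rate too high?)")
      tr_loss <- tr_loss + loss * length(bt)
      grads <- cnn_backward(model, fwd$cache, 2 * err / length(err))
      st <- adam_step(model$weights, grads, opt, config$learning_rate)
      model$weights <- st$weights
      opt <- st$opt
    }
    # validation MSE always reported in milliseconds for comparability
    val_pred <- unscale(cnn_forward(model, X[sp$validation, , drop = FALSE]))
    val_mse <- mean((val_pred - Y_ms[sp$validation, , drop = FALSE])^2)
    val_acc <- NA_real_
    if (config$eval_accuracy)
      val_acc <- evaluate_model(model, samples, sp$validation)$mean_accuracy
    curves <- rbind(curves, data.frame(
      epoch = ep, train_mse = tr_loss / length(sp$train),
      val_mse = val_mse, val_accuracy = val_acc))
  }
  list(model = model, curves = curves, split = sp)
}

clip_params <- function(raw, bounds) {
  c(max(bounds$max_start_ms[1L], min(bounds$max_start_ms[2L], raw[1L])),
    max(bounds$max_end_ms[1L], min(bounds$max_end_ms[2L], raw[2L])),
    max(bounds$min_between_ms[1L], min(bounds$min_between_ms[2L], raw[3L])))
}

#' Predict MaxInterval parameters for a window
#'
#' Runs the model on one preprocessed window and returns the three
#' predicted parameters clipped to the configured bounds, with the two
#' fixed parameters appended from the config.
#'
#' @param model a trained `mea_cnn` handle.
#' @param window raw window or training sample (see
#'   [preprocess_window()]), or an already-preprocessed vector of the
#'   model's input length.
#' @return A [maxinterval_params()] object.
#' @export
predict_params <- function(model, window) {
  stopifnot(inherits(model, "mea_cnn"))
  cfg <- model$config
  x <- if (is.numeric(window) && length(window) == model$input_len)
    as.numeric(window)
  else preprocess_window(window, model$variant, cfg$spike_binning)
  if (length(x) != model$input_len)
    stop("window incompatible with model variant ", model$variant)
  raw <- as.numeric(cnn_forward(model, matrix(x, nrow = 1L)))
  if (!is.null(model$target_scale))
    raw <- raw * model$target_scale$sd + model$target_scale$mu
  p <- clip_params(raw, cfg$clip_bounds)
  maxinterval_params(p[1L], p[2L], p[3L], cfg$min_duration_ms, cfg$min_spikes)
}

#' Burst-level evaluation of a model on stored windows
#'
#' For each sample, the model's predicted parameters drive
#' [detect_reverberations()] on the sample's spike raster; the resulting
#' burst occupancy is compared with the stored target bursts through the
#' overlap error.
#'
#' @param model a trained `mea_cnn`.
#' @param samples list of training samples.
#' @param idx indices of `samples` to evaluate (default all).
#' @param sampling_rate_hz raster sampling rate.
#' @return List with `mean_overlap_error`, `mean_accuracy` and the
#'   per-sample values.
#' @export
evaluate_model <- function(model, samples, idx = seq_along(samples),
                           sampling_rate_hz = 10000) {
  errs <- vapply(idx, function(i) {
    s <- samples[[i]]
    par <- predict_params(model, s)
    burst_overlap_error(bursts_to_raster(s$spikes, par, sampling_rate_hz),
                        s$bursts)
  }, 0)
  list(mean_overlap_error = mean(errs),
       mean_accuracy = mean(pmax(0, 1 - errs)),
       overlap_error = errs, accuracy = pmax(0, 1 - errs))
}

# detect reverberations on a binary spike raster and return their binary
# occupancy at the same resolution
bursts_to_raster <- function(spike_raster, params, sampling_rate_hz = 10000) {
  idx <- which(spike_raster == 1L)
  out <- integer(length(spike_raster))
  if (length(idx) == 0L) return(out)
  ev <- detect_reverberations((idx - 1L) / sampling_rate_hz, params)
  for (i in seq_len(nrow(ev))) {
    a <- round(ev$start_s[i] * sampling_rate_hz) + 1L
    b <- round(ev$end_s[i] * sampling_rate_hz) + 1L
    out[a:b] <- 1L
  }
  out
}

#' Save / load a model checkpoint
#'
#' A checkpoint is a directory holding `model.json` (architecture,
#' variant, training config and a digest of the weights) plus
#' `weights.rds` (the weight tensors).  Loading refuses a checkpoint
#' whose variant does not match `expect_variant`.
#'
#' @param model a `mea_cnn` handle.
#' @param dir checkpoint directory (created if needed).
#' @export
save_model <- function(model, dir) {
  stopifnot(inherits(model, "mea_cnn"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- unclass(model$config)
  cfg$architecture <- NULL
  meta <- list(variant = model$variant, input_len = model$input_len,
               n_parameters = model$n_parameters,
               architecture = unclass(model$architecture),
               config = cfg,
               target_scale = model$target_scale,
               weights_digest = weights_digest(model$weights))
  jsonlite::write_json(meta, file.path(dir, "model.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  saveRDS(model$weights, file.path(dir, "weights.rds"))
  invisible(dir)
}

#' @rdname save_model
#' @param dir checkpoint directory.
#' @param expect_variant if non-`NULL`, error unless the checkpoint's
#'   variant matches.
#' @export
load_model <- function(dir, expect_variant = NULL) {
  meta <- jsonlite::read_json(file.path(dir, "model.json"),
                              simplifyVector = TRUE)
  if (!is.null(expect_variant) && !identical(meta$variant, expect_variant))
    stop("checkpoint variant ", meta$variant, " does not match expected ",
         expect_variant)
  weights <- readRDS(file.path(dir, "weights.rds"))
  arch <- meta$architecture
  arch$conv <- lapply(seq_len(nrow(arch$conv)), function(i) as.list(arch$conv[i, ]))
  cfg <- meta$config
  cfg$architecture <- do.call(cnn_architecture, arch)
  cfg$split <- unlist(cfg$split)
  cfg <- structure(cfg, class = "train_config")
  ts <- meta$target_scale
  ts <- if (length(ts$mu) == 3L)
    list(mu = as.numeric(ts$mu), sd = as.numeric(ts$sd))
  else NULL
  structure(list(architecture = cfg$architecture, variant = meta$variant,
                 input_len = meta$input_len, weights = weights,
                 n_parameters = meta$n_parameters, config = cfg,
                 target_scale = ts),
            class = "mea_cnn")
}

weights_digest <- function(w) {
  v <- unlist(w, use.names = FALSE)
  sprintf("%.8e", sum(v) + sum(v^2))
}

#' Analyze spike trains with model-predicted parameters
#'
#' Each channel's data is cut into consecutive non-overlapping windows
#' (default 5 s).  For every window containing spikes, the model predicts
#' that window's MaxInterval parameters, which drive
#' [detect_reverberations()] within the window.  Reverberations abutting
#' a window boundary are merged across it when their gap is below the
#' mean of the two windows' predicted `min_between`.  The downstream
#' burst, network and metric stages are identical to the default path.
#'
#' @param spike_trains a [spike_train_set()] with a known duration.
#' @param model a trained `mea_cnn`.
#' @param recording the matching [mea_recording()]; required for the
#'   signal variants, ignored for `spikes30`.
#' @param window_s analysis window length (s).
#' @param criteria a [network_criteria()].
#' @param sampling_rate_hz raster rate used for the spikes30 raster when
#'   no recording is given.
#' @return The same structure as [analyze_spike_trains()].
#' @export
analyze_with_model <- function(spike_trains, model, recording = NULL,
                               window_s = 5, criteria = network_criteria(),
                               sampling_rate_hz = 10000) {
  stopifnot(inherits(spike_trains, "spike_train_set"),
            inherits(model, "mea_cnn"))
  dur <- spike_trains$duration_s
  if (is.na(dur)) stop("spike_trains must carry duration_s")
  if (model$variant != "spikes30" && is.null(recording))
    stop("variant ", model$variant, " needs the raw recording")
  if (!is.null(recording)) sampling_rate_hz <- recording$sampling_rate_hz
  n_win <- max(1L, ceiling(dur / window_s))
  if (dur < window_s)
    warning("recording shorter than one window; processed as a single padded window")
  wlen <- round(window_s * sampling_rate_hz)

  rev_df <- stats::setNames(vector("list", length(spike_trains$trains)),
                            names(spike_trains$trains))
  for (ch in names(spike_trains$trains)) {
    t <- spike_trains$trains[[ch]]
    per_win <- vector("list", n_win)
    win_between <- rep(NA_real_, n_win)
    for (w in seq_len(n_win)) {
      w0 <- (w - 1L) * window_s
      tw <- t[t >= w0 & t < w0 + window_s] - w0
      if (length(tw) == 0L) next
      x <- if (model$variant == "spikes30") {
        r <- integer(wlen)
        r[pmin(wlen, round(tw * sampling_rate_hz) + 1L)] <- 1L
        list(spikes = r, signal = NULL)
      } else {
        ci <- match(ch, recording$channel_ids)
        a <- round(w0 * sampling_rate_hz) + 1L
        seg <- recording$signal[ci, a:min(ncol(recording$signal), a + wlen - 1L)]
        list(signal = seg, spikes = NULL)
      }
      par <- predict_params(model, x)
      win_between[w] <- par$min_between_ms
      ev <- detect_reverberations(tw, par)
      if (nrow(ev)) {
        ev$start_s <- ev$start_s + w0
        ev$end_s <- ev$end_s + w0
        per_win[[w]] <- ev
      }
    }
    ev <- do.call(rbind, c(per_win, list(empty_events())))
    # merge across window boundaries using the mean predicted min_between
    if (nrow(ev) > 1L) {
      merged <- ev[1L, , drop = FALSE]
      for (i in 2:nrow(ev)) {
        gap <- ev$start_s[i] - merged$end_s[nrow(merged)]
        wa <- floor(merged$end_s[nrow(merged)] / window_s) + 1L
        wb <- floor(ev$start_s[i] / window_s) + 1L
        thr <- mean(c(win_between[wa], win_between[wb]), na.rm = TRUE) / 1000
        if (wa != wb && gap < thr) {
          merged$end_s[nrow(merged)] <- ev$end_s[i]
          merged$n_spikes[nrow(merged)] <- merged$n_spikes[nrow(merged)] +
            ev$n_spikes[i]
        } else {
          merged <- rbind(merged, ev[i, , drop = FALSE])
        }
      }
      ev <- merged
    }
    rownames(ev) <- NULL
    rev_df[[ch]] <- ev
  }
  finish_analysis(spike_trains, rev_df, criteria, dur)
}
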