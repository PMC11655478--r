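test_that("window preprocessing produces the documented shapes and values", {
  x <- list(signal = seq_len(50000) / 50000, spikes = integer(50000))
  expect_length(preprocess_window(x, "signal30"), 1667L)
  expect_length(preprocess_window(x, "signal100"), 500L)
  expect_length(preprocess_window(x, "spikes30"), 1667L)

  s30 <- preprocess_window(x, "signal30")
  expect_true(all(s30 >= 0 & s30 <= 1))
  # the last factor-30 bin averages the remaining 20 samples
  expect_equal(s30[1667], mean((49981:50000 - 1) / 49999))

  x$spikes[6 * 30 + 1] <- 1L        # one spike in bin 7
  sp <- preprocess_window(x, "spikes30")
  expect_equal(which(sp == 1), 7L)
  expect_equal(sum(sp), 1)
  spm <- preprocess_window(x, "spikes30", spike_binning = "mean")
  expect_equal(spm[7], 1 / 30)

  expect_warning(flat <- preprocess_window(rep(2, 50000), "signal30"),
                 "zero dynamic range")
  expect_true(all(flat == 0))

  # short windows are right-padded with zeros before binning
  short <- preprocess_window(rep(1, 25000), "signal100")
  expect_length(short, 500L)
  expect_equal(short[255], 0)
})

test_that("burst-overlap error obeys its closed-form identities", {
  b <- c(0, 1, 1, 0, 1, 1, 0, 0)
  expect_equal(burst_overlap_error(b, b), 0)
  expect_equal(custom_accuracy(b, b), 1)
  expect_equal(burst_overlap_error(numeric(8), b), 1)
  expect_equal(custom_accuracy(numeric(8), b), 0)

  bt <- c(1, 1, 1, 1, 0, 0, 0, 0)
  bp <- c(1, 1, 0, 0, 0, 0, 0, 0)   # 2 mismatched positions, 4 target ones
  expect_equal(burst_overlap_error(bp, bt), 0.5)

  expect_error(burst_overlap_error(b, numeric(8)), "all-zero")
  expect_error(burst_overlap_error(b, b[-1]), "equal length")

  # asymmetric unless both arrays have the same number of active stamps
  bt2 <- c(1, 1, 0, 0)
  bp2 <- c(1, 1, 1, 0)
  expect_false(burst_overlap_error(bp2, bt2) == burst_overlap_error(bt2, bp2))
  bp3 <- c(0, 1, 1, 0)              # same mass: symmetric
  expect_equal(burst_overlap_error(bp3, bt2), burst_overlap_error(bt2, bp3))
})

test_that("model construction is seeded and validates its architecture", {
  cfg <- train_config(variant = "signal100", seed = 11)
  m1 <- build_model(cfg)
  m2 <- build_model(cfg)
  expect_identical(m1$weights, m2$weights)
  set.seed(1)
  out <- meaburst:::cnn_forward(m1, matrix(runif(500), 1))
  expect_equal(dim(out), c(1L, 3L))
  expect_error(build_model(train_config(architecture = cnn_architecture(output = 4))),
               "exactly 3 outputs")
  expect_error(build_model(train_config(
    variant = "signal100",
    architecture = cnn_architecture(conv = list(list(filters = 4, kernel = 7,
                                                     pool = 600))))),
    "no temporal positions")
})

test_that("backpropagated gradients match numerical differentiation", {
  cfg <- train_config(
    variant = "signal100", seed = 4,
    architecture = cnn_architecture(conv = list(list(filters = 2, kernel = 3,
                                                     pool = 2)), dense = 4))
  m <- build_model(cfg)
  set.seed(9)
  X <- matrix(runif(2 * 500), 2, 500)
  Y <- matrix(rnorm(6), 2, 3)
  fwd <- meaburst:::cnn_forward(m, X, keep_cache = TRUE)
  g <- meaburst:::cnn_backward(m, fwd$cache, 2 * (fwd$out - Y) / length(Y))
  eps <- 1e-6
  for (nm in names(m$weights)) {
    for (i in sample(length(m$weights[[nm]]), min(5, length(m$weights[[nm]])))) {
      m2 <- m
      m2$weights[[nm]][i] <- m$weights[[nm]][i] + eps
      lp <- mean((meaburst:::cnn_forward(m2, X) - Y)^2)
      m2$weights[[nm]][i] <- m$weights[[nm]][i] - eps
      lm <- mean((meaburst:::cnn_forward(m2, X) - Y)^2)
      num <- (lp - lm) / (2 * eps)
      expect_lt(abs(num - g[[nm]][i]) / max(1e-6, abs(num)), 1e-4)
    }
  }
})

test_that("training overfits identical samples to their shared target", {
  ds <- generate_training_dataset(1, seed = 3)
  samples <- rep(ds, 20)
  for (i in seq_along(samples)) samples[[i]]$params_ms <- c(15, 20, 25)
  cfg <- train_config(variant = "signal30", epochs = 40, batch_size = 8,
                      split = c(train = 0.8, validation = 0.2, test = 0),
                      seed = 2)
  fit <- train_model(samples, cfg)
  expect_equal(nrow(fit$curves), 40L)
  p <- predict_params(fit$model, samples[[1]])
  expect_lt(abs(p$max_start_ms - 15), 1)
  expect_lt(abs(p$max_end_ms - 20), 1)
  expect_lt(abs(p$min_between_ms - 25), 1)
  # the fixed parameters ride along from the config
  expect_equal(p$min_duration_ms, 20)
  expect_equal(p$min_spikes, 5L)
  # training loss decreases overall on this separable problem
  expect_lt(fit$curves$train_mse[40], fit$curves$train_mse[1])
})

test_that("zero epochs yields the initialization and empty curves", {
  ds <- generate_training_dataset(12, seed = 6)
  cfg <- train_config(variant = "signal30", epochs = 0, seed = 5,
                      split = c(train = 0.8, validation = 0.2, test = 0))
  fit <- train_model(ds, cfg)
  expect_equal(nrow(fit$curves), 0L)
  expect_identical(fit$model$weights, build_model(cfg)$weights)
})

test_that("true labels beat shuffled labels on a separable contrast", {
  # two window populations whose burst structure (dense fast vs sparse
  # slow reverberations) matches their parameter labels
  A <- generate_training_dataset(30, param_ranges = list(
    max_start_ms = c(9, 11), max_end_ms = c(11, 13),
    min_between_ms = c(18, 22)), config = sim_config(intra_isi_ms = 3),
    seed = 8)
  B <- generate_training_dataset(30, param_ranges = list(
    max_start_ms = c(95, 105), max_end_ms = c(105, 115),
    min_between_ms = c(115, 125)),
    config = sim_config(intra_isi_ms = 60, reverb_spikes_mean = 12),
    seed = 9)
  samples <- c(A, B)
  shuffled <- samples
  set.seed(14)
  perm <- sample(length(samples))
  for (i in seq_along(samples)) shuffled[[i]]$params_ms <- samples[[perm[i]]]$params_ms
  cfg <- train_config(variant = "spikes30", epochs = 40, batch_size = 16,
                      learning_rate = 3e-3,
                      split = c(train = 0.7, validation = 0.3, test = 0),
                      seed = 9)
  fit_true <- train_model(samples, cfg)
  fit_shuf <- train_model(shuffled, cfg)
  expect_lt(tail(fit_true$curves$val_mse, 1),
            0.75 * tail(fit_shuf$curves$val_mse, 1))
})

test_that("predictions are clipped to the configured bounds", {
  m <- constant_model(c(-5, 500, 0.1), variant = "spikes30")
  ds <- generate_training_dataset(1, seed = 10)
  p <- predict_params(m, ds[[1]])
  expect_equal(p$max_start_ms, 2)      # lower bound
  expect_equal(p$max_end_ms, 200)      # upper bound
  expect_equal(p$min_between_ms, 2)
})

test_that("checkpoints round-trip and refuse a variant mismatch", {
  cfg <- train_config(variant = "signal100", epochs = 0, seed = 12)
  m <- build_model(cfg)
  dir <- withr::local_tempdir()
  save_model(m, dir)
  back <- load_model(dir, expect_variant = "signal100")
  expect_equal(back$weights, m$weights)
  ds <- generate_training_dataset(1, seed = 13)
  expect_equal(unclass(predict_params(back, ds[[1]])),
               unclass(predict_params(m, ds[[1]])))
  expect_error(load_model(dir, expect_variant = "spikes30"), "variant")
})

test_that("model-driven analysis with a constant predictor equals the default path", {
  w <- generate_well(sim_config(duration_s = 60, seed = 13))
  a1 <- analyze_spike_trains(w$spike_trains, maxinterval_params())
  a2 <- analyze_with_model(w$spike_trains, constant_model())
  expect_equal(a2$metrics, a1$metrics)
  expect_equal(a2$events$network_bursts$start_s,
               a1$events$network_bursts$start_s)

  # signal variants require the raw recording
  expect_error(analyze_with_model(w$spike_trains,
                                  constant_model(variant = "signal30")),
               "needs the raw recording")
})

test_that("an empty channel triggers no prediction and no events", {
  sts <- spike_train_set("w", list(a = c(1.0, 1.01, 1.02, 1.03, 1.05),
                                   b = numeric(0)), duration_s = 10)
  a <- analyze_with_model(sts, constant_model())
  expect_equal(nrow(a$events$reverberations$b), 0L)
})

test_that("a recording shorter than one window is processed with a warning", {
  sts <- spike_train_set("w", list(a = c(0.5, 0.51, 0.52, 0.53, 0.54)),
                         duration_s = 2)
  expect_warning(a <- analyze_with_model(sts, constant_model()),
                 "shorter than one window")
  expect_equal(nrow(a$events$reverberations$a), 1L)
})
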