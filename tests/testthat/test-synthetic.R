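test_that("the generator is reproducible from its seed", {
  w1 <- generate_well(sim_config(duration_s = 45, seed = 17))
  w2 <- generate_well(sim_config(duration_s = 45, seed = 17))
  expect_identical(w1$spike_trains$trains, w2$spike_trains$trains)
  expect_identical(w1$truth$network_bursts$start_s,
                   w2$truth$network_bursts$start_s)
  w3 <- generate_well(sim_config(duration_s = 45, seed = 18))
  expect_false(identical(w1$spike_trains$trains, w3$spike_trains$trains))
})

test_that("without network bursts only background spikes remain", {
  cfg <- sim_config(duration_s = 60, nibi_mean_s = 1e9, background_rate_hz = 1,
                    seed = 19)
  w <- generate_well(cfg)
  expect_true(all(vapply(w$truth$reverberations, nrow, 0L) == 0L))
  expect_equal(nrow(w$truth$network_bursts), 0L)
  expect_gt(sum(lengths(w$spike_trains$trains)), 0L)
})

test_that("background spike counts behave like the configured Poisson rate", {
  cfg <- sim_config(duration_s = 300, n_channels = 12, nibi_mean_s = 1e9,
                    background_rate_hz = 0.5, seed = 23)
  w <- generate_well(cfg)
  lambda <- 0.5 * 300
  counts <- lengths(w$spike_trains$trains)
  # mean count within 3 SD of the Poisson expectation across channels
  expect_lt(abs(mean(counts) - lambda), 3 * sqrt(lambda / 12))
})

test_that("detection with the generating parameters reproduces ground truth", {
  w <- generate_well(sim_config(duration_s = 120, seed = 29))
  for (ch in names(w$truth$reverberations)) {
    det <- detect_reverberations(w$spike_trains$trains[[ch]], w$truth$params)
    expect_true(events_equal(det, w$truth$reverberations[[ch]]),
                label = paste("channel", ch))
  }
  a <- analyze_spike_trains(w$spike_trains, w$truth$params)
  expect_equal(nrow(a$events$network_bursts), nrow(w$truth$network_bursts))
  expect_equal(a$events$network_bursts$start_s,
               w$truth$network_bursts$start_s)
})

test_that("full participation with small jitter gives exact network counts", {
  cfg <- sim_config(duration_s = 300, participation = 1, jitter_sd_ms = 5,
                    seed = 37)
  w <- generate_well(cfg)
  a <- analyze_spike_trains(w$spike_trains, w$truth$params)
  expect_gt(nrow(w$truth$network_bursts), 10L)
  expect_equal(nrow(a$events$network_bursts), nrow(w$truth$network_bursts))
})

test_that("rendered signal has the configured noise floor and spike shape", {
  cfg <- sim_config(noise_sd_uv = 3, seed = 41)
  quiet <- spike_train_set("w", list(ch01 = numeric(0)), duration_s = 10)
  rec <- render_signal(quiet, cfg)
  expect_lt(abs(sd(rec$signal[1, ]) - 3) / 3, 0.10)

  one <- spike_train_set("w", list(ch01 = 1.0), duration_s = 2)
  cfg0 <- sim_config(noise_sd_uv = 0, amp_mean_uv = 40, amp_sd_uv = 0, seed = 43)
  rec1 <- render_signal(one, cfg0)
  x <- rec1$signal[1, ]
  peak <- which.max(abs(x))
  expect_lt(abs((peak - 1) / 10000 - 1.0), 0.001)
  expect_lt(abs(abs(x[peak]) - 40) / 40, 0.20)

  none <- render_signal(quiet, cfg0, duration_s = 1)
  expect_true(all(none$signal == 0))
})

test_that("an infeasible reverberation gap range is rejected", {
  cfg <- sim_config(gap_range_ms = c(10, 24),
                    params = maxinterval_params(15, 20, 25, 20, 5))
  expect_error(generate_well(cfg), "infeasible")
})

test_that("training windows are self-consistent under their own parameters", {
  ds <- generate_training_dataset(40, seed = 47)
  expect_length(ds, 40L)
  for (s in ds) {
    expect_length(s$signal, 50000L)
    expect_true(all(s$spikes %in% c(0L, 1L)))
    expect_gt(sum(s$bursts), 0L)
    p <- maxinterval_params(s$params_ms[1], s$params_ms[2], s$params_ms[3],
                            20, 5)
    raster <- meaburst:::bursts_to_raster(s$spikes, p)
    expect_equal(burst_overlap_error(raster, s$bursts), 0)
  }
})

test_that("fixed parameters pass through to the stored params block", {
  ds <- generate_training_dataset(1, param_ranges = list(
    max_start_ms = c(15, 15), max_end_ms = c(20, 20),
    min_between_ms = c(25, 25)), seed = 53)
  expect_equal(ds[[1]]$params_ms, c(15, 20, 25))
})
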