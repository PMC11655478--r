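make_revs <- function(chans, start = 1.00, end = 1.10) {
  out <- lapply(chans, function(ch) data.frame(start_s = start, end_s = end,
                                               n_spikes = 6L))
  names(out) <- chans
  out
}

test_that("active channel set follows the firing-rate threshold", {
  sts <- spike_train_set("w", list(a = seq(0, 590, by = 10),  # 60 spikes/600 s
                                   b = c(1, 2), c = numeric(0)),
                         duration_s = 600)
  crit <- network_criteria(active_mfr_hz = 0.1)
  expect_equal(active_channels(sts, criteria = crit), "a")   # exactly 0.1 Hz: in
  expect_setequal(active_channels(sts, criteria = network_criteria(active_mfr_hz = 0)),
                  c("a", "b"))                                # any spike counts
  silent <- spike_train_set("w", list(a = numeric(0)), duration_s = 10)
  expect_equal(length(active_channels(silent, criteria = crit)), 0L)
})

test_that("12-channel worked cases meet the two-thirds / one-half criteria", {
  active <- sprintf("ch%02d", 1:12)   # participation threshold ceil(8) = 8

  nine <- detect_network_reverberations(make_revs(active[1:9]), active)
  expect_equal(nrow(nine), 1L)        # 9 >= 8 and concurrency 9 >= ceil(8/2)=4
  expect_equal(nine$n_channels, 9L)
  expect_equal(nine$start_s, 1.00)
  expect_equal(nine$end_s, 1.10)

  five <- detect_network_reverberations(make_revs(active[1:5]), active)
  expect_equal(nrow(five), 0L)        # 5 < 8

  eight <- detect_network_reverberations(make_revs(active[1:8]), active)
  expect_equal(nrow(eight), 1L)       # ties at exact equality are accepted
})

test_that("a single-channel well degenerates gracefully", {
  one <- detect_network_reverberations(make_revs("ch01"), "ch01")
  expect_equal(nrow(one), 1L)
  expect_equal(one$n_channels, 1L)
  expect_equal(one$start_s, 1.00)
  expect_equal(one$end_s, 1.10)
})

test_that("simultaneity is judged by the sweep-line maximum", {
  active <- sprintf("ch%02d", 1:12)
  # 8 channels participate but only 3 overlap at any instant (< ceil(8/2) = 4)
  revs <- lapply(1:8, function(i) {
    s <- 1.0 + (i - 1) * 0.04
    data.frame(start_s = s, end_s = s + 0.1, n_spikes = 6L)
  })
  names(revs) <- active[1:8]
  got <- detect_network_reverberations(revs, active)
  expect_equal(nrow(got), 0L)
  # with the staggering halved, 4+ are concurrently open: accepted
  revs2 <- lapply(1:8, function(i) {
    s <- 1.0 + (i - 1) * 0.02
    data.frame(start_s = s, end_s = s + 0.1, n_spikes = 6L)
  })
  names(revs2) <- active[1:8]
  expect_equal(nrow(detect_network_reverberations(revs2, active)), 1L)
})

test_that("raising the participation fraction never adds events", {
  set.seed(55)
  w <- generate_well(sim_config(duration_s = 90, seed = 55,
                                participation = 0.6))
  act <- active_channels(w$spike_trains)
  revs <- w$truth$reverberations[act]
  counts <- vapply(c(0.25, 0.5, 2 / 3, 0.85, 1), function(pf) {
    nrow(detect_network_reverberations(revs, act,
                                       network_criteria(participation_fraction = pf)))
  }, 0L)
  expect_true(all(diff(counts) <= 0L))
})

test_that("network reverberations satisfy their own participation post-condition", {
  set.seed(66)
  w <- generate_well(sim_config(duration_s = 120, seed = 66))
  act <- w$truth$active
  need <- ceiling(2 / 3 * length(act))
  nr <- w$truth$network_reverberations
  expect_gt(nrow(nr), 0L)
  expect_true(all(nr$n_channels >= need))
  expect_true(all(nr$max_simultaneous >= ceiling(need / 2)))
})

test_that("reverberations on unknown channels are rejected", {
  expect_error(detect_network_reverberations(make_revs("chXX"), "ch01"),
               "not in the active set")
})

test_that("network bursts merge network reverberations across sub-300-ms gaps", {
  nr <- data.frame(start_s = c(1.0, 1.3, 2.0), end_s = c(1.1, 1.5, 2.1),
                   n_spikes = c(50L, 60L, 40L))
  nb <- detect_network_bursts(nr)
  expect_equal(nrow(nb), 2L)     # gap 0.2 merges, gap 0.5 does not
  expect_equal(nb$n_children, c(2L, 1L))
  expect_equal(nb$end_s, c(1.5, 2.1))
})
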