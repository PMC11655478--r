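test_that("hand-traced MaxInterval cases come out as expected", {
  p <- maxinterval_params()  # 15/20/25/20/5

  expect_equal(nrow(detect_reverberations(numeric(0), p)), 0L)

  one <- detect_reverberations(c(0, 10, 20, 30, 40) / 1000, p)
  expect_equal(one, data.frame(start_s = 0, end_s = 0.04, n_spikes = 5L))

  # 30 ms gap: too long to extend (> max_end 20) and not merged (>= 25)
  two <- detect_reverberations(c(0, 10, 20, 30, 40, 70, 80, 90, 100, 110) / 1000, p)
  expect_equal(two$start_s, c(0, 0.07))
  expect_equal(two$end_s, c(0.04, 0.11))
  expect_equal(two$n_spikes, c(5L, 5L))

  # fewer than min_spikes
  expect_equal(nrow(detect_reverberations(c(0, 10, 20) / 1000, p)), 0L)

  expect_error(detect_reverberations(c(0.2, 0.1), p), "increasing")
})

test_that("candidate opening pair counts toward the burst and gaps split it", {
  p <- maxinterval_params(15, 20, 20, 1, 2L)
  # opening ISI 12 ms is inside; the 22 ms ISI (> max_end) closes the
  # burst and, being >= min_between, keeps the two candidates separate
  ev <- detect_reverberations(c(0, 12, 18, 40, 48, 56) / 1000, p)
  expect_equal(ev$n_spikes, c(3L, 3L))
  expect_equal(ev$start_s, c(0, 0.040))
})

test_that("naive reference and scan implementation agree on random trains", {
  set.seed(20240915)
  for (i in 1:300) {
    t <- random_train()
    p <- random_params()
    expect_true(events_equal(detect_reverberations(t, p),
                             naive_maxinterval(t, p)),
                label = sprintf("train %d (n=%d)", i, length(t)))
  }
})

test_that("filter-then-merge phase order matches the naive reference too", {
  set.seed(77)
  for (i in 1:100) {
    t <- random_train()
    p <- random_params()
    expect_true(events_equal(
      detect_reverberations(t, p, phase_order = "filter_merge"),
      naive_maxinterval(t, p, phase_order = "filter_merge")))
  }
})

test_that("reverberation count is non-increasing in min_spikes", {
  set.seed(31)
  for (i in 1:25) {
    t <- random_train()
    counts <- vapply(1:8, function(ms) {
      nrow(detect_reverberations(t, maxinterval_params(15, 20, 25, 5, ms)))
    }, 0L)
    expect_true(all(diff(counts) <= 0L))
  }
})

test_that("cortical ISI100 intervals contain the hippocampal-default intervals", {
  set.seed(5150)
  hip <- maxinterval_preset("hippocampal_default")
  cor <- maxinterval_preset("cortical_isi100")
  for (i in 1:40) {
    t <- random_train()
    a <- detect_reverberations(t, hip)
    b <- detect_reverberations(t, cor)
    if (nrow(a) == 0L) next
    contained <- vapply(seq_len(nrow(a)), function(k) {
      any(b$start_s <= a$start_s[k] + 1e-12 & b$end_s >= a$end_s[k] - 1e-12)
    }, TRUE)
    expect_true(all(contained))
  }
})

test_that("merge_events applies the strict sub-gap rule and is idempotent", {
  ev <- data.frame(start_s = c(0, 0.20), end_s = c(0.10, 0.30),
                   n_spikes = c(5L, 7L))
  m <- merge_events(ev, 300)
  expect_equal(nrow(m), 1L)
  expect_equal(m$start_s, 0)
  expect_equal(m$end_s, 0.30)
  expect_equal(m$n_spikes, 12L)
  expect_equal(m$n_children, 2L)
  expect_equal(nrow(m$children[[1L]]), 2L)

  # merging the parents again changes nothing
  m2 <- merge_events(m[, c("start_s", "end_s", "n_spikes")], 300)
  expect_equal(m2$start_s, m$start_s)
  expect_equal(m2$end_s, m$end_s)
  expect_equal(m2$n_children, 1L)

  single <- merge_events(ev[1L, ], 300)
  expect_equal(single$start_s, 0)
  expect_equal(single$end_s, 0.10)

  expect_error(merge_events(data.frame(start_s = c(0, 0.05),
                                       end_s = c(0.10, 0.2),
                                       n_spikes = c(1L, 1L)), 300),
               "non-overlapping")
})

test_that("gap of exactly the merge threshold keeps events separate", {
  ev <- data.frame(start_s = c(0, 0.4), end_s = c(0.1, 0.5),
                   n_spikes = c(5L, 5L))
  expect_equal(nrow(merge_events(ev, 300)), 2L)          # gap 300 ms: no merge
  ev$start_s[2L] <- 0.1 + 0.299999
  expect_equal(nrow(merge_events(ev, 300)), 1L)          # gap 299.999 ms: merge
})
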