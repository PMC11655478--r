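# Deliberately naive reference MaxInterval detector, written as a plain
# spike-by-spike walk with repeated pairwise merging.  Kept independent of
# the package implementation so the two can be compared on random trains.
naive_maxinterval <- function(t_s, params, phase_order = "merge_filter") {
  ms <- params$max_start_ms / 1000
  me <- params$max_end_ms / 1000
  mb <- params$min_between_ms / 1000
  md <- params$min_duration_ms / 1000
  n <- length(t_s)
  cand <- list()
  i <- 1L
  while (i < n) {
    if (t_s[i + 1L] - t_s[i] <= ms) {
      j <- i + 1L
      while (j < n && t_s[j + 1L] - t_s[j] <= me) j <- j + 1L
      cand[[length(cand) + 1L]] <- list(start = t_s[i], end = t_s[j],
                                        count = j - i + 1L)
      i <- j + 1L
    } else i <- i + 1L
  }
  merge_pass <- function(cand) {
    repeat {
      merged <- FALSE
      if (length(cand) >= 2L) {
        for (k in seq_len(length(cand) - 1L)) {
          if (cand[[k + 1L]]$start - cand[[k]]$end < mb) {
            cand[[k]] <- list(start = cand[[k]]$start, end = cand[[k + 1L]]$end,
                              count = cand[[k]]$count + cand[[k + 1L]]$count)
            cand[[k + 1L]] <- NULL
            merged <- TRUE
            break
          }
        }
      }
      if (!merged) return(cand)
    }
  }
  filter_pass <- function(cand)
    Filter(function(cc) cc$end - cc$start >= md && cc$count >= params$min_spikes,
           cand)
  cand <- if (phase_order == "merge_filter") filter_pass(merge_pass(cand))
          else merge_pass(filter_pass(cand))
  if (length(cand) == 0L)
    return(data.frame(start_s = numeric(0), end_s = numeric(0),
                      n_spikes = integer(0)))
  data.frame(start_s = vapply(cand, `[[`, 0, "start"),
             end_s = vapply(cand, `[[`, 0, "end"),
             n_spikes = vapply(cand, `[[`, 0L, "count"))
}

# random spike train with bursty clumps so all three phases get exercised
random_train <- function(n_max = 60L) {
  n <- sample.int(n_max, 1L)
  t <- cumsum(stats::rexp(n, rate = sample(c(20, 60, 200), 1L)))
  sort(stats::runif(1L) + t)
}

random_params <- function() {
  maxinterval_params(stats::runif(1, 2, 50), stats::runif(1, 2, 50),
                     stats::runif(1, 5, 100), stats::runif(1, 1, 30),
                     sample(1:8, 1L))
}

events_equal <- function(a, b, tol = 1e-9) {
  nrow(a) == nrow(b) &&
    (nrow(a) == 0L ||
       (max(abs(a$start_s - b$start_s)) < tol &&
          max(abs(a$end_s - b$end_s)) < tol &&
          all(a$n_spikes == b$n_spikes)))
}

# constant-output model handle used in pipeline equivalence tests
constant_model <- function(params_ms = c(15, 20, 25), variant = "spikes30") {
  m <- build_model(train_config(variant = variant, epochs = 0L, seed = 1L))
  for (nm in names(m$weights)) m$weights[[nm]][] <- 0
  m$weights$bo[] <- params_ms
  m
}
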