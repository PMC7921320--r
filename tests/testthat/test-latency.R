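make_psth <- function(counts, bin = 2) {
  structure(list(counts = counts, bin_width_ms = bin,
                 duration_ms = bin * length(counts), n_trials = 1L,
                 bin_left_ms = (seq_along(counts) - 1) * bin),
            class = "psth")
}

test_that("the peristimulus histogram is trial-normalised", {
  p <- build_psth(list(numeric(0), numeric(0)), 2, 20)
  expect_equal(p$counts, rep(0, 10))
  # one spike per trial in the third bin
  p2 <- build_psth(list(c(4.5), c(5.9), c(4.1)), 2, 20)
  expect_equal(p2$counts[3], 1)
  expect_equal(sum(p2$counts), 1)
  # homogeneous 10 Hz: each 2 ms bin ~ 0.02 spikes/trial
  set.seed(1)
  trains <- replicate(2000, sort(runif(rpois(1, 5), 0, 500)),
                      simplify = FALSE)
  p3 <- build_psth(trains, 2, 500)
  expect_equal(mean(p3$counts), 0.02, tolerance = 0.05)
  expect_lt(max(abs(p3$counts - 0.02)), 0.02)
  expect_error(build_psth(trains, 3, 500), "divide")
})

test_that("baseline statistics follow the spontaneous histogram moments", {
  # empty spontaneous activity -> zero mean and SD
  empty <- replicate(10, numeric(0), simplify = FALSE)
  b <- baseline_stats(empty, 1800, 2, 500)
  expect_equal(b$mean, 0)
  expect_equal(b$sd, 0)
  # Poisson spontaneous firing: per-bin mean ~ rate x bin width
  set.seed(2)
  segs <- replicate(100, sort(runif(rpois(1, 18), 0, 1800)),
                    simplify = FALSE)
  b2 <- baseline_stats(segs, 1800, 2, 500)
  expect_equal(b2$mean, 0.02, tolerance = 0.1)
  # per-bin SD across bins ~ sqrt(mean / n_trials) for Poisson counts
  expect_equal(b2$sd, sqrt(0.02 / b2$n_pseudo_trials), tolerance = 0.15)
  expect_error(baseline_stats(list(), 1800, 2, 500), "Insufficient")
})

test_that("latency is the first of two consecutive supra-threshold bins", {
  counts <- rep(0.02, 250)
  counts[26:250] <- 0.2
  res <- detect_latency(make_psth(counts),
                        list(mean = 0.02, sd = 0.005))
  expect_true(res$identified)
  expect_equal(res$latency_ms, 50)
  expect_equal(res$threshold, 0.03)
  # flat histogram at baseline: not identified
  flat <- detect_latency(make_psth(rep(0.02, 250)),
                         list(mean = 0.02, sd = 0.005))
  expect_false(flat$identified)
  expect_true(is.na(flat$latency_ms))
  # a single isolated supra-threshold bin is not a response
  iso <- rep(0.02, 250); iso[40] <- 1
  expect_false(detect_latency(make_psth(iso),
                              list(mean = 0.02, sd = 0.005))$identified)
})

test_that("the threshold is strict so a zero-SD baseline needs a real increase", {
  counts <- rep(0.02, 100)
  res <- detect_latency(make_psth(counts), list(mean = 0.02, sd = 0))
  expect_false(res$identified)
})

test_that("raising the baseline SD never shortens the detected latency", {
  set.seed(3)
  counts <- 0.02 + 0.01 * runif(250)
  counts[50:250] <- counts[50:250] + 0.2 * exp(-(0:200) / 30)
  lats <- sapply(c(0.001, 0.01, 0.05, 0.3), function(s) {
    r <- detect_latency(make_psth(counts), list(mean = 0.02, sd = s))
    if (r$identified) r$latency_ms else Inf
  })
  expect_true(all(diff(lats) >= 0))
})

test_that("short latencies are flagged as presumed direct input", {
  counts <- rep(0, 150); counts[4:10] <- 1
  r <- detect_latency(make_psth(counts), list(mean = 0.001, sd = 0.001))
  expect_equal(r$latency_ms, 6)
  expect_true(r$direct_input)
  counts2 <- rep(0, 150); counts2[31:40] <- 1
  r2 <- detect_latency(make_psth(counts2), list(mean = 0.001, sd = 0.001))
  expect_false(r2$direct_input)
})

test_that("injected response latency is recovered from simulated trials", {
  p <- single_pulse_protocol(n_channels = 1, repetitions = 400)
  m <- neuron_model(baseline_rate_hz = 10, separability = 4,
                    response_gain = 2, response_latency_ms = 20,
                    response_decay_ms = 15)
  ts <- simulate_neuron(p, m, seed = 11, window_ms = 300,
                        spontaneous_s = 60)
  r <- estimate_latency(ts, "single_pulse")
  expect_true(r$identified)
  expect_gte(r$latency_ms, 18)
  expect_lte(r$latency_ms, 22)
  expect_equal(r$stim_type, "single_pulse")
})

test_that("a weak brief response is found at 2 ms but lost at 10 ms bins", {
  # a short burst (~4 ms) clears two consecutive 2 ms bins, but dilutes into
  # a single 10 ms bin, failing the two-consecutive-bin requirement there
  p <- single_pulse_protocol(n_channels = 1, repetitions = 400)
  m <- neuron_model(baseline_rate_hz = 10, separability = 1,
                    response_gain = 0.6, response_latency_ms = 20,
                    response_decay_ms = 2)
  ts <- simulate_neuron(p, m, seed = 14, window_ms = 300,
                        spontaneous_s = 60)
  tab <- latency_bin_sensitivity(ts, c(2, 10), duration_ms = 300)
  expect_true(tab$identified[tab$bin_width_ms == 2])
  expect_false(tab$identified[tab$bin_width_ms == 10])
})

test_that("bin-width sensitivity reports one row per width", {
  p <- stim_protocol(seed = 4)
  m <- neuron_model(baseline_rate_hz = 10, separability = 3,
                    response_gain = 1.5, response_latency_ms = 12)
  ts <- simulate_neuron(p, m, seed = 12, spontaneous_s = 60)
  tab <- latency_bin_sensitivity(ts, c(2, 5, 10))
  expect_equal(nrow(tab), 3L)
  expect_equal(tab$bin_width_ms, c(2, 5, 10))
  expect_true(all(tab$identified))
  # latencies agree within one coarse bin
  expect_lt(max(tab$latency_ms) - min(tab$latency_ms), 10)
  # no-response neuron: not identified at any width
  ts0 <- simulate_neuron(p, neuron_model(baseline_rate_hz = 10,
                                         separability = 0),
                         seed = 13, spontaneous_s = 60)
  tab0 <- latency_bin_sensitivity(ts0, c(2, 5, 10))
  expect_false(any(tab0$identified))
})
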