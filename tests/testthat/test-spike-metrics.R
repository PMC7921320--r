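test_that("moving average filter matches hand-computed windows", {
  expect_equal(moving_average_filter(rep(2, 10), 5), rep(2, 10))
  x <- c(3, 1, 4, 1, 5)
  expect_identical(moving_average_filter(x, 1), x)
  # centered window over an impulse, shrunken at the edges
  y <- moving_average_filter(c(0, 0, 5, 0, 0), 5)
  expect_equal(y[3], 1)
  expect_equal(y[1], 5 / 3)  # window covers samples 1..3
  expect_error(moving_average_filter(x, 4), "odd")
  expect_error(moving_average_filter(x, 7), "length")
})

test_that("mean waveform is the pointwise mean", {
  m <- rbind(c(1, 2, 3), c(3, 2, 1))
  expect_equal(mean_waveform(m), c(2, 2, 2))
  wf <- simulate_waveforms(10, noise_sd_mv = 0, seed = 1)
  expect_equal(mean_waveform(wf), wf$template)
  a <- c(0, 1, 0)
  expect_equal(mean_waveform(rbind(a, -a)), c(0, 0, 0))
})

test_that("mean of noisy copies converges to the template", {
  few <- simulate_waveforms(5, noise_sd_mv = 0.5, seed = 1)
  many <- simulate_waveforms(500, noise_sd_mv = 0.5, seed = 1)
  err_few <- max(abs(mean_waveform(few) - few$template))
  err_many <- max(abs(mean_waveform(many) - many$template))
  expect_lt(err_many, err_few)
  expect_lt(err_many, 0.12)
})

test_that("shape metrics are exact on a symmetric triangular spike", {
  # base 0, peak 4 mV, rise 0.2 ms, fall 0.2 ms, sampled at 100 kHz
  dt <- 0.01
  t <- seq(0, 2, by = dt)
  v <- pmax(0, 4 * (1 - abs(t - 1) / 0.2))
  m <- spike_shape_metrics(v, 1e5)
  expect_true(m$measurable)
  expect_equal(m$spike_amplitude_mv, 4, tolerance = 1e-6)
  expect_equal(m$half_height_amplitude_mv, 2, tolerance = 1e-6)
  expect_equal(m$rise_time_ms, 0.18, tolerance = 0.02)
  expect_equal(m$half_height_duration_ms, 0.2, tolerance = 0.02)
})

test_that("flat or degenerate traces are flagged unmeasurable, not errors", {
  expect_false(spike_shape_metrics(rep(0, 100))$measurable)
  expect_false(spike_shape_metrics(seq(0, 1, length.out = 50))$measurable)
  expect_false(spike_shape_metrics(c(0, 1))$measurable)
})

test_that("shape metrics recover the generator ground truth at zero noise", {
  wf <- simulate_waveforms(3, amplitude_mv = 3, rise_time_ms = 0.27,
                           half_width_ms = 0.35, noise_sd_mv = 0, seed = 1)
  m <- spike_shape_metrics(mean_waveform(wf), wf$sampling_rate_hz)
  one_sample <- 1000 / wf$sampling_rate_hz
  expect_true(m$measurable)
  expect_lt(abs(m$spike_amplitude_mv - 3), 0.05)
  expect_lt(abs(m$rise_time_ms - 0.27), 2 * one_sample)
  expect_lt(abs(m$half_height_duration_ms - 0.35), 2 * one_sample)
})

test_that("interval CV and CV2 match hand calculations and bounds", {
  expect_equal(isi_cv(c(2, 2, 2, 2)), 0)
  expect_equal(isi_cv(c(1, 3)), sqrt(2) / 2)
  expect_equal(isi_cv2(c(5, 5, 5)), 0)
  expect_equal(isi_cv2(c(1, 3)), 1)
  expect_true(is.na(isi_cv(3)))
  expect_true(is.na(isi_cv2(numeric(0))))
  set.seed(1)
  for (i in 1:5) {
    isis <- rgamma(200, shape = runif(1, 0.5, 5), rate = 1)
    expect_lte(isi_cv2(isis), 2)
    # scale invariance
    expect_equal(isi_cv(isis * 10), isi_cv(isis))
    expect_equal(isi_cv2(isis * 10), isi_cv2(isis))
  }
})

test_that("exponential intervals give CV ~ 1, CV2 ~ 1 and regularity ~ 0", {
  set.seed(42)
  isis <- stats::rexp(10000, rate = 1 / 50)
  expect_lt(abs(isi_cv(isis) - 1), 0.05)
  expect_lt(abs(isi_cv2(isis) - 1), 0.05)
  expect_lt(abs(firing_regularity(isis)), 0.05)
})

test_that("gamma shape MLE recovers the shape and is scale-free", {
  set.seed(7)
  isis <- rgamma(10000, shape = 4, rate = 0.2)
  expect_lt(abs(firing_regularity(isis) - log(4)), 0.1)
  expect_equal(firing_regularity(isis * 10), firing_regularity(isis),
               tolerance = 1e-8)
  expect_warning(reg <- firing_regularity(rep(3, 100)), "Degenerate")
  expect_identical(reg, Inf)
  expect_error(firing_regularity(1:5), "10")
})

test_that("gamma shape MLE agrees with an independent generic optimiser", {
  set.seed(11)
  isis <- rgamma(2000, shape = 2.5, rate = 0.1)
  fit <- suppressWarnings(MASS::fitdistr(isis, "gamma"))
  expect_equal(firing_regularity(isis),
               log(unname(fit$estimate["shape"])), tolerance = 1e-2)
})

test_that("firing frequency is count over duration", {
  expect_equal(firing_frequency(0, 10), 0)
  expect_equal(firing_frequency(961, 100), 9.61)
  expect_equal(firing_frequency(100, 10), 10)
  expect_error(firing_frequency(10, 0), "duration_s")
})

test_that("regularity_metrics summarises a simulated neuron sensibly", {
  ts <- simulate_neuron(tiny_protocol(),
                        neuron_model(baseline_rate_hz = 20, isi_shape = 1),
                        seed = 9, spontaneous_s = 100)
  m <- regularity_metrics(ts)
  expect_equal(nrow(m), 1L)
  expect_lt(abs(m$cv - 1), 0.1)
  expect_lt(abs(m$cv2_mean - 1), 0.1)
  expect_lt(abs(m$firing_regularity), 0.15)
  expect_lt(abs(m$firing_frequency_hz - 20), 1)
})
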