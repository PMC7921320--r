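#' Specify a synthetic thalamic-like neuron
#'
#' Parameters of the generative model used to emulate a recorded neuron. The
#' instantaneous firing rate during a trial is
#' \deqn{\lambda(t) = r_0 + s \sum_j g_{c(j)} \, \frac{1}{\tau_d}
#'       e^{-(t - t_j - L)/\tau_d} \; [t > t_j + L],}
#' a baseline rate \eqn{r_0} plus, for every stimulation pulse \eqn{j} on
#' channel \eqn{c(j)} at time \eqn{t_j}, a causal exponential rate bump of
#' area \eqn{s \, g_{c(j)}} (expected evoked spikes per pulse) starting after
#' the response latency \eqn{L} and decaying with time constant \eqn{\tau_d}.
#' Spikes are drawn from this profile by time-rescaling a gamma renewal
#' process of shape `isi_shape`, so rate profile and interspike-interval
#' regularity are controlled independently: `isi_shape = 1` gives Poisson
#' firing, larger values more regular firing.
#'
#' With `separability = 0` the evoked term vanishes and all patterns evoke
#' statistically identical (pure baseline) responses; increasing
#' `separability` scales the pattern-specific rate modulation and therefore
#' the decodability of the patterns.
#'
#' @param baseline_rate_hz Spontaneous firing rate, spikes/s (> 0).
#' @param isi_shape Gamma shape of the interspike-interval distribution
#'   (> 0; 1 = Poisson).
#' @param response_latency_ms Conduction/processing delay between a pulse and
#'   the onset of the evoked rate increase, ms. Either one value or one per
#'   channel.
#' @param response_gain Evoked spikes per pulse per unit separability; one
#'   value or one per channel.
#' @param response_decay_ms Decay time constant of the evoked rate bump, ms.
#' @param separability Dimensionless scaling (>= 0) of the evoked response.
#' @return A `neuron_model` list.
#' @examples
#' neuron_model(baseline_rate_hz = 10, separability = 0)
#' @export
neuron_model <- function(baseline_rate_hz = 10,
                         isi_shape = 1,
                         response_latency_ms = 12,
                         response_gain = 1,
                         response_decay_ms = 15,
                         separability = 1) {
  check_scalar(baseline_rate_hz, "baseline_rate_hz")
  check_scalar(isi_shape, "isi_shape")
  check_scalar(response_decay_ms, "response_decay_ms")
  check_scalar(separability, "separability", positive = FALSE)
  if (separability < 0) abort("`separability` must be >= 0.")
  if (any(response_latency_ms < 0)) abort("latencies must be >= 0.")
  if (any(response_gain < 0)) abort("gains must be >= 0.")
  structure(
    list(baseline_rate_hz = baseline_rate_hz,
         isi_shape = isi_shape,
         response_latency_ms = response_latency_ms,
         response_gain = response_gain,
         response_decay_ms = response_decay_ms,
         separability = separability),
    class = "neuron_model")
}

# Cumulative evoked intensity of one pattern at times t (ms): closed form of
# the integral of the unit-area causal exponential bumps, scaled by
# separability * per-channel gain. Baseline handled separately.
evoked_cumulative <- function(t, pulse_times, pulse_channels, model) {
  gains <- rep_len(model$response_gain, max(c(pulse_channels, 1L)))
  lats <- rep_len(model$response_latency_ms, max(c(pulse_channels, 1L)))
  out <- numeric(length(t))
  for (j in seq_along(pulse_times)) {
    onset <- pulse_times[j] + lats[pulse_channels[j]]
    g <- model$separability * gains[pulse_channels[j]]
    if (g == 0) next
    dt <- t - onset
    out <- out + g * ifelse(dt > 0, 1 - exp(-dt / model$response_decay_ms), 0)
  }
  out
}

# Draw one spike train on [0, window_ms) for a cumulative intensity given on
# a fine grid, by time-rescaling a unit-rate gamma renewal process
# (shape kappa, rate kappa) into operational time.
draw_rescaled_train <- function(grid_ms, Lambda, kappa) {
  total <- Lambda[length(Lambda)]
  if (total <= 0) return(numeric(0))
  # tiny ramp keeps Lambda strictly increasing where the intensity is zero
  Lambda <- Lambda + seq_along(Lambda) * 1e-12
  n_max <- ceiling(total + 10 * sqrt(total / kappa) + 10)
  s <- cumsum(rgamma(n_max, shape = kappa, rate = kappa))
  while (s[length(s)] < total) {
    s <- c(s, s[length(s)] +
             cumsum(rgamma(n_max, shape = kappa, rate = kappa)))
  }
  s <- s[s < total]
  if (!length(s)) return(numeric(0))
  approx(Lambda, grid_ms, xout = s, ties = "ordered")$y
}

#' Simulate trial-structured spike responses for one neuron
#'
#' Runs the generative model of [neuron_model()] over every (pattern, trial)
#' of a stimulation protocol, producing spike times aligned to trial onset in
#' a fixed analysis window, together with spontaneous-activity segments drawn
#' from the same renewal process at baseline rate (standing in for the
#' inter-trial relaxation phases).
#'
#' @param protocol A [stim_protocol()] or [single_pulse_protocol()].
#' @param model A [neuron_model()].
#' @param seed Integer seed; the result is deterministic given
#'   (protocol, model, seed).
#' @param window_ms Analysis window after trial onset, ms.
#' @param neuron_id Label stored with the spikes.
#' @param spontaneous_s Total simulated spontaneous time, s, stored as
#'   segments of one inter-trial interval each.
#' @param grid_step_ms Resolution of the intensity grid used to invert the
#'   time-rescaling transform.
#' @return A `trial_set` object; see [trial_set()].
#' @examples
#' ts <- simulate_neuron(stim_protocol(seed = 1),
#'                       neuron_model(separability = 0),
#'                       seed = 1, spontaneous_s = 10)
#' ts
#' @export
simulate_neuron <- function(protocol, model, seed = 1L,
                            window_ms = 1000, neuron_id = "sim1",
                            spontaneous_s = 180,
                            grid_step_ms = 0.1) {
  stopifnot(inherits(protocol, "stim_protocol"),
            inherits(model, "neuron_model"))
  check_scalar(window_ms, "window_ms")
  seeds <- derive_seeds(seed, 2L)

  rate_ms <- model$baseline_rate_hz / 1000
  kappa <- model$isi_shape
  grid <- seq(0, window_ms, by = grid_step_ms)

  # per-pattern cumulative intensity on the grid (baseline + evoked)
  Lambdas <- lapply(protocol$pattern_names, function(nm) {
    p <- protocol$pulses[protocol$pulses$pattern == nm, ]
    rate_ms * grid + evoked_cumulative(grid, p$time_ms, p$channel, model)
  })
  names(Lambdas) <- protocol$pattern_names

  set.seed(seeds[1])
  reps <- protocol$repetitions
  spikes <- purrr::map_dfr(protocol$pattern_names, function(nm) {
    trains <- lapply(seq_len(reps), function(i) {
      st <- draw_rescaled_train(grid, Lambdas[[nm]], kappa)
      st[st >= 0 & st < window_ms]
    })
    tibble(neuron_id = neuron_id,
           pattern = nm,
           trial = rep(seq_len(reps), lengths(trains)),
           spike_time_ms = unlist(trains))
  })

  set.seed(seeds[2])
  seg_ms <- protocol$inter_trial_interval_ms
  n_seg <- max(0L, floor(spontaneous_s * 1000 / seg_ms))
  spont <- vector("list", n_seg)
  if (n_seg > 0 && rate_ms > 0) {
    # one long stationary train chopped into inter-trial-interval segments
    total_ms <- n_seg * seg_ms
    n_max <- ceiling(rate_ms * total_ms + 10 * sqrt(rate_ms * total_ms) + 10)
    t_all <- cumsum(rgamma(n_max, shape = kappa, rate = kappa * rate_ms))
    while (t_all[length(t_all)] < total_ms) {
      t_all <- c(t_all, t_all[length(t_all)] +
                   cumsum(rgamma(n_max, shape = kappa, rate = kappa * rate_ms)))
    }
    t_all <- t_all[t_all < total_ms]
    idx <- findInterval(t_all, seq(0, total_ms, by = seg_ms),
                        rightmost.closed = FALSE)
    for (i in seq_len(n_seg))
      spont[[i]] <- t_all[idx == i] - (i - 1) * seg_ms
  } else {
    spont <- replicate(n_seg, numeric(0), simplify = FALSE)
  }

  trial_set(spikes,
            analysis_window_ms = window_ms,
            spontaneous = spont,
            spontaneous_segment_ms = seg_ms,
            n_trials = reps,
            pattern_names = protocol$pattern_names)
}

#' Simulate spike waveforms with known shape parameters
#'
#' Generates noisy copies of a continuous unimodal spike template with exact
#' ground-truth shape metrics, as a fixture for validating
#' [spike_shape_metrics()]. The template is an asymmetric triangular bump on
#' a flat baseline: amplitude `amplitude_mv`, linear rise lasting
#' `rise_time_ms / 0.9` (so that the 10%-to-peak rise time is exactly
#' `rise_time_ms`), and a linear fall whose duration is set so that the full
#' width at half maximum is `half_width_ms`.
#'
#' @param n Number of traces.
#' @param amplitude_mv Peak amplitude above baseline, mV.
#' @param rise_time_ms Time from 10% of amplitude to peak, ms.
#' @param half_width_ms Full width at half maximum, ms.
#' @param noise_sd_mv Gaussian noise SD added independently to every sample.
#' @param sampling_rate_hz Sampling rate (100 kHz by default).
#' @param duration_ms Trace length, ms.
#' @param seed Integer seed.
#' @return A `waveform_set`: list with `traces` (n x samples matrix, mV),
#'   `sampling_rate_hz` and `ground_truth`.
#' @examples
#' wf <- simulate_waveforms(5, amplitude_mv = 3, noise_sd_mv = 0)
#' spike_shape_metrics(mean_waveform(wf), wf$sampling_rate_hz)
#' @export
simulate_waveforms <- function(n = 10L,
                               amplitude_mv = 3,
                               rise_time_ms = 0.27,
                               half_width_ms = 0.35,
                               noise_sd_mv = 0.1,
                               sampling_rate_hz = 1e5,
                               duration_ms = 4,
                               seed = 1L) {
  check_scalar(n, "n", integerish = TRUE)
  check_scalar(amplitude_mv, "amplitude_mv")
  check_scalar(rise_time_ms, "rise_time_ms")
  check_scalar(half_width_ms, "half_width_ms")
  if (noise_sd_mv < 0) abort("`noise_sd_mv` must be >= 0.")
  rise_full <- rise_time_ms / 0.9
  fall_full <- 2 * half_width_ms - rise_full
  if (fall_full <= 0)
    abort("`half_width_ms` too small for the requested rise time.")

  dt <- 1000 / sampling_rate_hz
  t <- seq(0, duration_ms, by = dt)
  peak_t <- duration_ms / 2
  template <- numeric(length(t))
  rising <- t >= (peak_t - rise_full) & t <= peak_t
  falling <- t > peak_t & t <= (peak_t + fall_full)
  template[rising] <- amplitude_mv * (t[rising] - (peak_t - rise_full)) / rise_full
  template[falling] <- amplitude_mv * (1 - (t[falling] - peak_t) / fall_full)

  set.seed(derive_seeds(seed, 1L))
  traces <- matrix(rep(template, each = n), nrow = n)
  if (noise_sd_mv > 0)
    traces <- traces + matrix(stats::rnorm(n * length(t), 0, noise_sd_mv),
                              nrow = n)
  structure(
    list(traces = traces,
         sampling_rate_hz = sampling_rate_hz,
         template = template,
         ground_truth = list(amplitude_mv = amplitude_mv,
                             rise_time_ms = rise_time_ms,
                             half_width_ms = half_width_ms)),
    class = "waveform_set")
}

#' Read and write waveform sets as delimited text
#'
#' One trace per row in a headerless CSV matrix (mV), with a JSON sidecar
#' `<path>.json` holding the sampling rate and, for synthetic sets, the
#' ground-truth shape parameters.
#'
#' @param wf A `waveform_set`.
#' @param path CSV path.
#' @return `write_waveforms()` returns `path` invisibly; `read_waveforms()`
#'   a `waveform_set`.
#' @export
write_waveforms <- function(wf, path) {
  stopifnot(inherits(wf, "waveform_set"))
  utils::write.table(wf$traces, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  jsonlite::write_json(
    list(sampling_rate_hz = wf$sampling_rate_hz,
         ground_truth = wf$ground_truth),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_waveforms
#' @export
read_waveforms <- function(path) {
  if (!file.exists(path)) abort(sprintf("No such file: %s", path))
  traces <- as.matrix(utils::read.csv(path, header = FALSE))
  dimnames(traces) <- NULL
  sidecar <- paste0(path, ".json")
  meta <- if (file.exists(sidecar)) {
    jsonlite::read_json(sidecar, simplifyVector = TRUE)
  } else {
    list(sampling_rate_hz = 1e5, ground_truth = NULL)
  }
  structure(list(traces = traces,
                 sampling_rate_hz = meta$sampling_rate_hz,
                 ground_truth = meta$ground_truth),
            class = "waveform_set")
}

#' @export
print.waveform_set <- function(x, ...) {
  cat(sprintf("<waveform_set> %d traces x %d samples at %g kHz\n",
              nrow(x$traces), ncol(x$traces), x$sampling_rate_hz / 1000))
  invisible(x)
}
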