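#' Centered moving-average filter
#'
#' Low-pass filters a voltage trace with a centered moving average. At
#' 100 kHz sampling, the default width of 5 samples corresponds to a 50 µs
#' window. Edges are averaged over the shrunken window that fits.
#'
#' @param trace Numeric voltage vector.
#' @param width_samples Odd window width in samples.
#' @return Filtered vector of the same length.
#' @examples
#' moving_average_filter(c(0, 0, 5, 0, 0), 5)
#' @export
moving_average_filter <- function(trace, width_samples = 5L) {
  check_scalar(width_samples, "width_samples", integerish = TRUE)
  if (width_samples %% 2 == 0)
    abort("`width_samples` must be odd (centered window).")
  if (width_samples > length(trace))
    abort("`width_samples` exceeds the trace length.")
  if (width_samples == 1L) return(trace)
  h <- (width_samples - 1L) %/% 2L
  cs <- cumsum(c(0, trace))
  n <- length(trace)
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Mean spike waveform
#'
#' Pointwise mean of all traces in a waveform set (the overlaid-and-averaged
#' spike shape from which shape metrics are measured).
#'
#' @param waveforms A `waveform_set` (see [simulate_waveforms()]) or a
#'   numeric matrix with one trace per row.
#' @return Numeric vector, the mean trace.
#' @export
mean_waveform <- function(waveforms) {
  m <- if (inherits(waveforms, "waveform_set")) waveforms$traces else waveforms
  if (!is.matrix(m) || nrow(m) < 1L)
    abort("`waveforms` must contain at least one trace.")
  colMeans(m)
}

#' Spike-shape metrics from a mean waveform
#'
#' Measures the standard extracellular spike-shape quantities on a mean
#' spike trace:
#' * **spike amplitude** — voltage difference between the maximum peak and
#'   the take-off inflection point on the rising flank (located as the point
#'   of greatest positive curvature, i.e. the maximum of the second
#'   difference, before the peak);
#' * **rise time** — time from the crossing of 10% of the spike amplitude to
#'   the peak;
#' * **half-height amplitude** — half of the spike amplitude;
#' * **half-height duration** — time between the rising-phase and
#'   falling-phase crossings of the half-height level.
#'
#' Threshold crossings are located with linear interpolation between
#' samples. If the trace has no usable peak or a required crossing cannot be
#' found, the metrics are returned as `NA` with `measurable = FALSE` rather
#' than raising an error.
#'
#' @param mean_trace Numeric voltage vector (mV), typically from
#'   [mean_waveform()] after [moving_average_filter()].
#' @param sampling_rate_hz Sampling rate of the trace.
#' @return A one-row tibble: `spike_amplitude_mv`, `half_height_amplitude_mv`,
#'   `half_height_duration_ms`, `rise_time_ms`, `measurable`.
#' @export
spike_shape_metrics <- function(mean_trace, sampling_rate_hz = 1e5) {
  check_scalar(sampling_rate_hz, "sampling_rate_hz")
  dt <- 1000 / sampling_rate_hz
  unmeasurable <- tibble(spike_amplitude_mv = NA_real_,
                         half_height_amplitude_mv = NA_real_,
                         half_height_duration_ms = NA_real_,
                         rise_time_ms = NA_real_,
                         measurable = FALSE)
  n <- length(mean_trace)
  if (n < 5L) return(unmeasurable)
  peak <- which.max(mean_trace)
  if (peak <= 2L || peak >= n - 1L) return(unmeasurable)
  if (diff(range(mean_trace)) == 0) return(unmeasurable)

  # take-off point: maximum of the second difference on the rising flank
  rising <- mean_trace[1:peak]
  d2 <- diff(rising, differences = 2L)
  if (!length(d2) || all(d2 <= 0)) return(unmeasurable)
  infl <- which.max(d2) + 1L        # index into `rising`
  v0 <- rising[infl]
  amplitude <- mean_trace[peak] - v0
  if (amplitude <= 0) return(unmeasurable)

  cross_up <- function(level, from, to) {
    # last upward crossing of `level` before `to`, linearly interpolated
    seg <- mean_trace[from:to]
    below <- which(seg[-length(seg)] < level & seg[-1] >= level)
    if (!length(below)) return(NA_real_)
    i <- max(below)
    frac <- (level - seg[i]) / (seg[i + 1] - seg[i])
    (from - 1 + i - 1 + frac) * dt
  }
  cross_down <- function(level, from, to) {
    seg <- mean_trace[from:to]
    above <- which(seg[-length(seg)] >= level & seg[-1] < level)
    if (!length(above)) return(NA_real_)
    i <- min(above)
    frac <- (seg[i] - level) / (seg[i] - seg[i + 1])
    (from - 1 + i - 1 + frac) * dt
  }

  t_peak <- (peak - 1) * dt
  t10 <- cross_up(v0 + 0.1 * amplitude, infl, peak)
  half_level <- v0 + amplitude / 2
  t_half_up <- cross_up(half_level, infl, peak)
  t_half_down <- cross_down(half_level, peak, n)
  if (any(is.na(c(t10, t_half_up, t_half_down)))) return(unmeasurable)

  tibble(spike_amplitude_mv = amplitude,
         half_height_amplitude_mv = amplitude / 2,
         half_height_duration_ms = t_half_down - t_half_up,
         rise_time_ms = t_peak - t10,
         measurable = TRUE)
}

#' Interspike-interval coefficient of variation
#'
#' `isi_cv()` is the global coefficient of variation of the interspike
#' intervals, \eqn{\sigma_{ISI} / \mu_{ISI}} (sample SD, `n - 1`
#' denominator). `isi_cv2()` is the local pairwise variant, the mean over
#' adjacent interval pairs of
#' \eqn{2 |ISI_{i+1} - ISI_i| / (ISI_{i+1} + ISI_i)}, which is bounded in
#' [0, 2] and insensitive to slow rate drift. Both equal ~1 for Poisson
#' firing and 0 for a perfectly regular train, and are invariant under
#' uniform time rescaling.
#'
#' @param isis Numeric vector of interspike intervals (ms), all > 0.
#' @return A single number, or `NA` if fewer than 2 intervals are supplied.
#' @examples
#' isi_cv(c(1, 3))   # sqrt(2)/2
#' isi_cv2(c(1, 3))  # 1
#' @export
isi_cv <- function(isis) {
  if (length(isis) < 2L) return(NA_real_)
  if (any(isis <= 0)) abort("All interspike intervals must be > 0.")
  sd(isis) / mean(isis)
}

#' @rdname isi_cv
#' @export
isi_cv2 <- function(isis) {
  if (length(isis) < 2L) return(NA_real_)
  if (any(isis <= 0)) abort("All interspike intervals must be > 0.")
  a <- isis[-length(isis)]
  b <- isis[-1]
  mean(2 * abs(b - a) / (b + a))
}

#' Firing regularity from a gamma fit to the interspike intervals
#'
#' Fits a gamma distribution to the interspike intervals by maximum
#' likelihood and returns the natural logarithm of the fitted shape
#' parameter. Poisson firing (exponential intervals) gives 0; regular firing
#' gives positive values; bursty firing negative values. The measure is
#' invariant under uniform time rescaling of the intervals.
#'
#' The shape MLE solves the profile likelihood equation
#' \eqn{\log\kappa - \psi(\kappa) = \log \bar{x} - \overline{\log x}}
#' by Newton iteration from the standard closed-form starting value.
#'
#' @param isis Numeric vector of interspike intervals (ms), all > 0; at
#'   least 10 required.
#' @return `log(kappa_hat)`. Degenerate input (all intervals equal, where the
#'   MLE diverges) returns `Inf` with a warning rather than failing.
#' @examples
#' set.seed(1)
#' firing_regularity(rgamma(10000, shape = 4, rate = 4))  # ~ log(4)
#' @export
firing_regularity <- function(isis) {
  if (length(isis) < 10L)
    abort("At least 10 interspike intervals are required.")
  if (any(isis <= 0)) abort("All interspike intervals must be > 0.")
  s <- log(mean(isis)) - mean(log(isis))
  if (s < 1e-12) {
    warn("Degenerate (near-constant) intervals: gamma shape MLE diverges.")
    return(Inf)
  }
  kappa <- (3 - s + sqrt((s - 3)^2 + 24 * s)) / (12 * s)
  for (i in 1:25) {
    delta <- (log(kappa) - digamma(kappa) - s) /
      (1 / kappa - trigamma(kappa))
    kappa_new <- kappa - delta
    if (kappa_new <= 0) kappa_new <- kappa / 2
    if (abs(kappa_new - kappa) < 1e-10 * kappa) {
      kappa <- kappa_new
      break
    }
    kappa <- kappa_new
  }
  log(kappa)
}

#' Mean firing frequency
#'
#' Number of spikes divided by the recording duration.
#'
#' @param spike_count Number of spikes.
#' @param duration_s Recording duration in seconds (> 0).
#' @return Firing frequency in Hz.
#' @examples
#' firing_frequency(961, 100)  # 9.61 Hz
#' @export
firing_frequency <- function(spike_count, duration_s) {
  check_scalar(duration_s, "duration_s")
  check_scalar(spike_count, "spike_count", positive = FALSE)
  if (spike_count < 0) abort("`spike_count` must be >= 0.")
  spike_count / duration_s
}

#' Firing-regularity summary of a neuron's spontaneous activity
#'
#' Convenience wrapper computing all interspike-interval statistics from the
#' spontaneous segments of a [trial_set()]: CV, mean CV2, firing regularity
#' (log gamma shape) and mean firing frequency.
#'
#' @param ts A [trial_set()] with spontaneous segments.
#' @return One-row tibble: `neuron_id`, `n_isis`, `cv`, `cv2_mean`,
#'   `firing_regularity`, `firing_frequency_hz`.
#' @export
regularity_metrics <- function(ts) {
  stopifnot(inherits(ts, "trial_set"))
  if (!length(ts$spontaneous))
    abort("`ts` carries no spontaneous segments.")
  isis <- unlist(lapply(ts$spontaneous, function(v) diff(sort(v))))
  isis <- isis[isis > 0]
  n_spikes <- sum(lengths(ts$spontaneous))
  dur_s <- length(ts$spontaneous) * ts$spontaneous_segment_ms / 1000
  tibble(
    neuron_id = ts$spikes$neuron_id[1] %||% NA_character_,
    n_isis = length(isis),
    cv = isi_cv(isis),
    cv2_mean = isi_cv2(isis),
    firing_regularity = if (length(isis) >= 10L) firing_regularity(isis)
                        else NA_real_,
    firing_frequency_hz = firing_frequency(n_spikes, dur_s)
  )
}
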