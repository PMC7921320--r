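# Small fixtures shared across test files; everything is generated in code.

withr_tempfile <- function(ext = ".json") tempfile(fileext = ext)

tiny_protocol <- function(seed = 1L) {
  stim_protocol(seed = seed, pulses_per_pattern = c(2L, 4L), repetitions = 10L)
}

# a minimal hand-built trial set: `n_trials` per pattern, Poisson-ish spikes
tiny_trial_set <- function(n_patterns = 8L, n_trials = 10L, rate_hz = 10,
                           window_ms = 200, seed = 1L) {
  set.seed(seed)
  patterns <- paste0("p", seq_len(n_patterns))
  rows <- list()
  for (p in patterns) {
    for (tr in seq_len(n_trials)) {
      n <- stats::rpois(1, rate_hz * window_ms / 1000)
      if (n > 0)
        rows[[length(rows) + 1L]] <- tibble::tibble(
          neuron_id = "toy", pattern = p, trial = tr,
          spike_time_ms = sort(stats::runif(n, 0, window_ms)))
    }
  }
  trial_set(dplyr::bind_rows(rows), analysis_window_ms = window_ms,
            n_trials = n_trials, pattern_names = patterns)
}

# deterministic spike trains: one pattern-specific burst so decoding is easy
separable_trial_set <- function(n_trials = 12L, window_ms = 400) {
  patterns <- paste0("p", 1:8)
  rows <- purrr::map_dfr(seq_along(patterns), function(i) {
    purrr::map_dfr(seq_len(n_trials), function(tr) {
      base <- 40 * i
      tibble::tibble(neuron_id = "sep", pattern = patterns[i], trial = tr,
                     spike_time_ms = base + c(0, 2, 4, 6) + 0.1 * tr)
    })
  })
  trial_set(rows, analysis_window_ms = window_ms, n_trials = n_trials,
            pattern_names = patterns)
}
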