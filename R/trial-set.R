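#' Trial-structured spike responses of one neuron
#'
#' The unit of analysis for decoding and latency estimation: spike times per
#' (pattern, trial), aligned to stimulus onset within a fixed analysis
#' window, plus spontaneous-activity segments recorded (or simulated) between
#' trials.
#'
#' @param spikes A data frame with columns `neuron_id`, `pattern`, `trial`
#'   and `spike_time_ms`. Trials with no spikes need no rows; the trial grid
#'   is defined by `pattern_names` x `n_trials`.
#' @param analysis_window_ms Length of the per-trial analysis window, ms.
#' @param spontaneous List of numeric vectors of spike times (ms, each
#'   relative to its segment start) from inter-trial relaxation periods.
#' @param spontaneous_segment_ms Duration of each spontaneous segment, ms.
#' @param n_trials Number of trials per pattern.
#' @param pattern_names Pattern labels, in presentation order.
#' @return A `trial_set` object.
#' @export
trial_set <- function(spikes, analysis_window_ms = 1000,
                      spontaneous = list(),
                      spontaneous_segment_ms = 1800,
                      n_trials = NULL,
                      pattern_names = NULL) {
  spikes <- as_tibble(spikes)
  need <- c("neuron_id", "pattern", "trial", "spike_time_ms")
  missing <- setdiff(need, names(spikes))
  if (length(missing))
    abort(paste0("`spikes` is missing column(s): ",
                 paste(missing, collapse = ", ")))
  if (is.null(pattern_names)) pattern_names <- unique(spikes$pattern)
  if (is.null(n_trials)) n_trials <- max(spikes$trial, 0L)
  out <- structure(
    list(spikes = spikes,
         analysis_window_ms = analysis_window_ms,
         spontaneous = spontaneous,
         spontaneous_segment_ms = spontaneous_segment_ms,
         n_trials = as.integer(n_trials),
         pattern_names = pattern_names),
    class = "trial_set")
  validate_trial_set(out)
}

validate_trial_set <- function(x) {
  s <- x$spikes
  if (any(s$spike_time_ms < 0) || any(s$spike_time_ms >= x$analysis_window_ms))
    abort("Spike times must lie in [0, analysis_window_ms).")
  bad <- s |>
    dplyr::group_by(.data$pattern, .data$trial) |>
    dplyr::summarise(sorted = !is.unsorted(.data$spike_time_ms),
                     .groups = "drop") |>
    dplyr::filter(!.data$sorted)
  if (nrow(bad))
    abort(sprintf("Spike times are unsorted in %d trial(s), e.g. pattern '%s' trial %d.",
                  nrow(bad), bad$pattern[1], bad$trial[1]))
  if (!all(s$pattern %in% x$pattern_names))
    abort("Spikes reference patterns absent from `pattern_names`.")
  x
}

#' @export
print.trial_set <- function(x, ...) {
  cat(sprintf("<trial_set> neuron '%s': %d patterns x %d trials, %d spikes\n",
              x$spikes$neuron_id[1] %||% "?", length(x$pattern_names),
              x$n_trials, nrow(x$spikes)))
  cat(sprintf("  analysis window %g ms; %d spontaneous segments (%g ms each)\n",
              x$analysis_window_ms, length(x$spontaneous),
              x$spontaneous_segment_ms))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a) || !length(a)) b else a

#' @export
as_tibble.trial_set <- function(x, ...) x$spikes

# spike times of every (pattern, trial), as a list of numeric vectors in
# pattern-major order, including empty trials
spike_trains <- function(ts, patterns = ts$pattern_names) {
  key <- paste(ts$spikes$pattern, ts$spikes$trial, sep = "\r")
  split_spk <- split(ts$spikes$spike_time_ms, key)
  grid <- expand.grid(trial = seq_len(ts$n_trials), pattern = patterns,
                      stringsAsFactors = FALSE)
  keys <- paste(grid$pattern, grid$trial, sep = "\r")
  trains <- split_spk[keys]
  trains[vapply(trains, is.null, logical(1))] <- list(numeric(0))
  names(trains) <- keys
  list(trains = trains, pattern = grid$pattern, trial = grid$trial)
}

#' Read and write trial-structured spike tables
#'
#' The on-disk format is a delimited text table with header
#' `neuron_id,pattern,trial,spike_time_ms` (one row per spike), accompanied
#' by a JSON sidecar `<path>.json` holding the analysis window, trial counts,
#' pattern names and spontaneous segments.
#'
#' @param ts A [trial_set()].
#' @param path Path of the CSV table; the sidecar is written next to it.
#' @return `write_trials()` returns `path` invisibly. `read_trials()` returns
#'   a validated `trial_set`; malformed rows (duplicate spikes times within a
#'   trial are permitted, unsorted or out-of-window times are not) raise an
#'   error naming the offending rows.
#' @export
write_trials <- function(ts, path) {
  stopifnot(inherits(ts, "trial_set"))
  write.csv(ts$spikes, path, row.names = FALSE, quote = TRUE)
  meta <- list(analysis_window_ms = ts$analysis_window_ms,
               n_trials = ts$n_trials,
               pattern_names = ts$pattern_names,
               spontaneous_segment_ms = ts$spontaneous_segment_ms,
               spontaneous = ts$spontaneous)
  jsonlite::write_json(meta, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  if (!file.exists(path)) abort(sprintf("No such file: %s", path))
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("neuron_id", "pattern", "trial", "spike_time_ms")
  missing <- setdiff(need, names(tab))
  if (length(missing))
    abort(paste0("Input table is missing column(s): ",
                 paste(missing, collapse = ", ")))
  dup <- which(duplicated(tab))
  if (length(dup))
    abort(sprintf("Duplicated spike row(s) at line(s) %s of %s (header = line 1).",
                  paste(head(dup + 1L, 5L), collapse = ", "), path))
  sidecar <- paste0(path, ".json")
  meta <- if (file.exists(sidecar)) {
    m <- jsonlite::read_json(sidecar, simplifyVector = FALSE)
    m$pattern_names <- unlist(m$pattern_names)
    m$analysis_window_ms <- as.numeric(m$analysis_window_ms)
    m$n_trials <- as.integer(m$n_trials)
    m$spontaneous_segment_ms <- as.numeric(m$spontaneous_segment_ms)
    m
  } else {
    list(analysis_window_ms = 1000, n_trials = max(tab$trial),
         pattern_names = unique(tab$pattern),
         spontaneous_segment_ms = 1800, spontaneous = list())
  }
  spont <- lapply(meta$spontaneous %||% list(),
                  function(v) as.numeric(unlist(v)))
  trial_set(tab,
            analysis_window_ms = meta$analysis_window_ms,
            spontaneous = spont,
            spontaneous_segment_ms = meta$spontaneous_segment_ms,
            n_trials = meta$n_trials,
            pattern_names = meta$pattern_names)
}
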