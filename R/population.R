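#' Summarise decoding and response metrics across a neuron population
#'
#' Takes a per-neuron results table (one row per neuron with at least
#' `f1_score` and `shuffled_f1` as fractions), derives the above-chance
#' decoder threshold (mean + 2 SD of the shuffled scores), flags decoders,
#' and reports population aggregates in the mean-plus-minus-SD convention.
#'
#' @param per_neuron A data frame with columns `neuron_id`, `f1_score`,
#'   `shuffled_f1`; any further numeric columns (latencies, spike-shape or
#'   regularity metrics) are aggregated too.
#' @param threshold Decoder threshold as a fraction; by default computed
#'   from the `shuffled_f1` column via [decoder_threshold()] (at least 2
#'   neurons required in that case).
#' @return A `population_summary`: list with `per_neuron` (input plus
#'   `is_decoder`), `aggregates` (tibble of mean, sd, n per numeric
#'   column), `threshold`, `n_decoders` and `decoder_fraction`.
#' @export
summarise_population <- function(per_neuron, threshold = NULL) {
  per_neuron <- as_tibble(per_neuron)
  if (nrow(per_neuron) < 1L) abort("Need at least one neuron.")
  need <- c("neuron_id", "f1_score", "shuffled_f1")
  missing <- setdiff(need, names(per_neuron))
  if (length(missing))
    abort(paste0("`per_neuron` is missing column(s): ",
                 paste(missing, collapse = ", ")))
  if (is.null(threshold)) {
    if (nrow(per_neuron) < 2L)
      abort("Computing the threshold needs >= 2 neurons; pass `threshold`.")
    threshold <- decoder_threshold(per_neuron$shuffled_f1)
  }
  per_neuron$is_decoder <- per_neuron$f1_score > threshold

  num_cols <- names(per_neuron)[vapply(per_neuron, is.numeric, logical(1))]
  aggregates <- purrr::map_dfr(num_cols, function(cl) {
    v <- per_neuron[[cl]]
    tibble(metric = cl,
           mean = mean(v, na.rm = TRUE),
           sd = if (sum(!is.na(v)) > 1L) sd(v, na.rm = TRUE) else NA_real_,
           n = sum(!is.na(v)))
  })

  structure(
    list(per_neuron = per_neuron,
         aggregates = aggregates,
         threshold = threshold,
         n_decoders = sum(per_neuron$is_decoder),
         decoder_fraction = mean(per_neuron$is_decoder)),
    class = "population_summary")
}

#' @export
print.population_summary <- function(x, ...) {
  cat(sprintf("<population_summary> %d neurons; decoder threshold %.2f%%\n",
              nrow(x$per_neuron), 100 * x$threshold))
  cat(sprintf("  %d of %d (%.1f%%) decode above chance\n",
              x$n_decoders, nrow(x$per_neuron), 100 * x$decoder_fraction))
  print(x$aggregates)
  invisible(x)
}

#' @export
#' @method tidy population_summary
tidy.population_summary <- function(x, ...) x$per_neuron

#' @rdname summarise_population
#' @param x A `population_summary`.
#' @param ... Unused.
#' @method glance population_summary
#' @export
glance.population_summary <- function(x, ...) {
  tibble(n_neurons = nrow(x$per_neuron),
         threshold = x$threshold,
         n_decoders = x$n_decoders,
         decoder_fraction = x$decoder_fraction,
         mean_f1 = mean(x$per_neuron$f1_score),
         mean_shuffled_f1 = mean(x$per_neuron$shuffled_f1))
}
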