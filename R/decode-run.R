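#' Decode stimulation patterns from single-neuron spike responses
#'
#' Runs the complete single-neuron decoding analysis on a trial-structured
#' spike response set:
#'
#' 1. each trial's spike train is convolved with a causal exponential kernel
#'    into a continuous response function;
#' 2. responses are split at random, per pattern, half into a training and
#'    half into a test set;
#' 3. each set is bootstrap-resampled per pattern (each bootstrapped
#'    response the sum of N resampled responses) and principal components
#'    explaining `variance_explained` of the training-set variance are
#'    extracted;
#' 4. all bootstrapped responses are projected onto the components by least
#'    squares;
#' 5. each bootstrapped test response is classified by relative majority
#'    among its `k_neighbors` nearest training responses;
#' 6. steps 2--5 are repeated `n_iterations` times with fresh random splits
#'    and the confusion matrices are averaged.
#'
#' The decoding performance is the macro F1 score of the averaged confusion
#' matrix. Shuffling the pattern labels before the splits yields the
#' neuron's shuffled-label (chance) score; for eight patterns chance is 1/8
#' = 12.5%. With `shuffle = "per_iteration"` a fresh permutation is drawn
#' before every split, which averages away the spurious decodability that a
#' single fixed permutation inherits from finite-trial pattern means and
#' concentrates the null tightly around chance; `"once"` keeps one
#' permutation for all iterations.
#'
#' @param ts A [trial_set()] (or a spikes data frame coercible to one) with
#'   every pattern represented by at least 2 trials.
#' @param config A [decoding_config()].
#' @param shuffle `"none"` (or `FALSE`), `"per_iteration"` (or `TRUE`), or
#'   `"once"`: whether and how to permute pattern labels for the null
#'   analysis.
#' @param engine `"cpp"` (fast compiled core, the default) or `"r"` (pure-R
#'   reference path). Both consume identical random draws and give identical
#'   results up to floating-point tie handling.
#' @param expected_patterns Optional vector of pattern names that must all be
#'   present; an informative error lists any that are missing.
#' @return A `decoding_result`: averaged `confusion` matrix (rows = true,
#'   columns = decoded pattern), per-class `precision`, `recall` and
#'   `f1_per_class`, macro `f1_score` (fraction), mean retained
#'   `n_components`, the `config`, and the `shuffled` flag. See
#'   [tidy.decoding_result()], [glance.decoding_result()],
#'   [autoplot.decoding_result()].
#' @examples
#' \donttest{
#' ts <- simulate_neuron(stim_protocol(seed = 1),
#'                       neuron_model(separability = 0),
#'                       seed = 1, spontaneous_s = 0)
#' cfg <- decoding_config(n_bootstrap_per_pattern = 20, n_iterations = 2)
#' decode_patterns(ts, cfg)
#' }
#' @export
decode_patterns <- function(ts, config = decoding_config(),
                            shuffle = "none",
                            engine = c("cpp", "r"),
                            expected_patterns = NULL) {
  engine <- match.arg(engine)
  if (is.logical(shuffle))
    shuffle <- if (shuffle) "per_iteration" else "none"
  shuffle <- match.arg(shuffle, c("none", "per_iteration", "once"))
  if (is.data.frame(ts)) ts <- trial_set(ts)
  stopifnot(inherits(ts, "trial_set"))
  patterns <- ts$pattern_names
  if (!is.null(expected_patterns)) {
    absent <- setdiff(expected_patterns, patterns)
    if (length(absent))
      abort(paste0("Missing stimulation pattern(s): ",
                   paste(absent, collapse = ", ")))
  }
  if (length(patterns) < 2L)
    abort("Decoding needs at least 2 stimulation patterns.")
  if (ts$n_trials < 2L)
    abort("Decoding needs at least 2 trials per pattern.")
  present <- unique(ts$spikes$pattern)
  silent <- setdiff(patterns, present)
  if (length(silent))
    warn(paste0("Pattern(s) with no spikes in any trial: ",
                paste(silent, collapse = ", ")))

  conv <- convolve_trials(ts, config)
  resp <- conv$responses
  labels <- conv$pattern

  seeds <- derive_seeds(config$seed, config$n_iterations + 1L)
  if (shuffle == "once") {
    set.seed(seeds[1])
    labels <- sample(labels)
  }

  n_pat <- length(patterns)
  conf_sum <- matrix(0, n_pat, n_pat,
                     dimnames = list(true = patterns, decoded = patterns))
  n_comp_sum <- 0
  for (i in seq_len(config$n_iterations)) {
    set.seed(seeds[i + 1L])
    if (shuffle == "per_iteration") labels <- sample(labels)
    sp <- split_train_test(labels)
    rows_tr <- lapply(patterns, function(p) sp$train[labels[sp$train] == p])
    rows_te <- lapply(patterns, function(p) sp$test[labels[sp$test] == p])
    bi_tr <- bootstrap_indices(rows_tr, config$n_bootstrap_per_pattern)
    bi_te <- bootstrap_indices(rows_te, config$n_bootstrap_per_pattern)
    if (engine == "cpp") {
      it <- decode_iteration_cpp(resp, bi_tr, bi_te,
                                 config$variance_explained,
                                 config$k_neighbors, n_pat)
      conf_sum <- conf_sum + it$confusion
      n_comp_sum <- n_comp_sum + it$n_components
    } else {
      it <- decode_iteration_r(resp, bi_tr, bi_te, patterns, config)
      conf_sum <- conf_sum + it$confusion
      n_comp_sum <- n_comp_sum + it$n_components
    }
  }
  confusion <- conf_sum / config$n_iterations
  scores <- f1_from_confusion(confusion)

  structure(
    list(confusion = confusion,
         precision = scores$precision,
         recall = scores$recall,
         f1_per_class = scores$f1_per_class,
         f1_score = scores$f1_score,
         n_components_mean = n_comp_sum / config$n_iterations,
         pattern_names = patterns,
         shuffled = shuffle != "none",
         shuffle_mode = shuffle,
         config = config),
    class = "decoding_result")
}

# pure-R reference iteration consuming precomputed bootstrap index matrices
decode_iteration_r <- function(resp, bi_tr, bi_te, patterns, config) {
  boot_from_idx <- function(idx_list) {
    mats <- lapply(idx_list, function(idx) {
      boot <- matrix(0, nrow(idx), ncol(resp))
      for (j in seq_len(ncol(idx)))
        boot <- boot + resp[idx[, j], , drop = FALSE]
      boot
    })
    list(responses = do.call(rbind, mats),
         labels = rep(patterns, vapply(mats, nrow, integer(1))))
  }
  tr <- boot_from_idx(bi_tr)
  te <- boot_from_idx(bi_te)
  pca <- fit_response_pca(tr$responses, config$variance_explained)
  S <- project_responses(tr$responses, pca)
  T_ <- project_responses(te$responses, pca)
  pred <- knn_classify(T_, S, tr$labels, config$k_neighbors)
  confusion <- table(factor(te$labels, levels = patterns),
                     factor(pred, levels = patterns))
  list(confusion = unclass(confusion), n_components = pca$n_components)
}

#' Shuffled-label null decoding score
#'
#' Reruns the full decoding pipeline with pattern labels randomly permuted
#' across all responses before the train/test splits, giving the neuron's
#' chance-level F1 score. By default a fresh permutation is drawn before
#' every split; `reshuffle_each_iteration = FALSE` uses one permutation for
#' the whole run (which retains the spurious finite-trial structure of that
#' particular relabelling and therefore gives a much more variable null).
#'
#' @inheritParams decode_patterns
#' @param reshuffle_each_iteration Draw a fresh label permutation before
#'   every train/test split.
#' @return A `decoding_result` with `shuffled = TRUE`.
#' @export
shuffled_null <- function(ts, config = decoding_config(),
                          engine = c("cpp", "r"),
                          reshuffle_each_iteration = TRUE) {
  decode_patterns(ts, config,
                  shuffle = if (reshuffle_each_iteration) "per_iteration"
                            else "once",
                  engine = match.arg(engine))
}

#' @export
print.decoding_result <- function(x, ...) {
  cat(sprintf("<decoding_result>%s macro F1 = %.1f%% (%d patterns, %d iterations)\n",
              if (x$shuffled) " [shuffled labels]" else "",
              100 * x$f1_score, length(x$pattern_names),
              x$config$n_iterations))
  cat(sprintf("  mean retained components: %.1f\n", x$n_components_mean))
  invisible(x)
}

#' Tidy a decoding result
#'
#' @param x A `decoding_result`.
#' @param ... Unused.
#' @return `tidy()`: one row per pattern with `precision`, `recall` and
#'   `f1`; `glance()`: a one-row tibble with the macro `f1_score`, the mean
#'   number of retained components, and the configuration scalars.
#' @method tidy decoding_result
#' @export
tidy.decoding_result <- function(x, ...) {
  tibble(pattern = x$pattern_names,
         precision = unname(x$precision),
         recall = unname(x$recall),
         f1 = unname(x$f1_per_class))
}

#' @rdname tidy.decoding_result
#' @method glance decoding_result
#' @export
glance.decoding_result <- function(x, ...) {
  tibble(f1_score = x$f1_score,
         shuffled = x$shuffled,
         n_components_mean = x$n_components_mean,
         kernel_tau_ms = x$config$kernel_tau_ms,
         n_bootstrap_per_pattern = x$config$n_bootstrap_per_pattern,
         k_neighbors = x$config$k_neighbors,
         n_iterations = x$config$n_iterations,
         seed = x$config$seed)
}

#' Plot an averaged confusion matrix
#'
#' Heatmap of the iteration-averaged confusion matrix of a decoding run,
#' rows = presented pattern, columns = decoded pattern, fill = mean count of
#' bootstrapped test responses.
#'
#' @param object A `decoding_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot decoding_result
#' @export
autoplot.decoding_result <- function(object, ...) {
  df <- as.data.frame.table(object$confusion, responseName = "count")
  names(df)[1:2] <- c("true", "decoded")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$decoded, y = .data$true,
                                   fill = .data$count)) +
    ggplot2::geom_tile() +
    ggplot2::scale_y_discrete(limits = rev(levels(factor(df$true)))) +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "decoded pattern", y = "presented pattern",
                  fill = "mean count",
                  title = sprintf("macro F1 = %.1f%%%s",
                                  100 * object$f1_score,
                                  if (object$shuffled) " (shuffled)" else "")) +
    ggplot2::theme_minimal()
}
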