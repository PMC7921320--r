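#' Configuration of the decoding pipeline
#'
#' Bundles the tunable parameters of the bootstrap--PCA--kNN decoding
#' analysis. The defaults are the standard operating point of the method: an exponential
#' convolution kernel with a 5 ms characteristic time over a 1,000 ms
#' response window, 200 bootstrapped responses per pattern per set,
#' principal components retained to 95% explained variance, nine nearest
#' neighbours, and 50 random train/test splits.
#'
#' @param kernel_tau_ms Characteristic time of the causal exponential kernel.
#' @param window_ms Response window after stimulus onset, ms.
#' @param sample_step_ms Sampling grid of the convolved response, ms.
#' @param n_bootstrap_per_pattern Bootstrapped responses per pattern, per
#'   (train/test) set.
#' @param variance_explained Fraction of variance the retained principal
#'   components must explain.
#' @param k_neighbors Neighbours used by the kNN classifier (odd
#'   recommended).
#' @param n_iterations Number of independent train/test splits averaged into
#'   the confusion matrix.
#' @param seed Master RNG seed; every split and bootstrap draw derives from
#'   it, so results are fully reproducible.
#' @return A `decoding_config` list.
#' @export
decoding_config <- function(kernel_tau_ms = 5,
                            window_ms = 1000,
                            sample_step_ms = 2,
                            n_bootstrap_per_pattern = 200L,
                            variance_explained = 0.95,
                            k_neighbors = 9L,
                            n_iterations = 50L,
                            seed = 1L) {
  check_scalar(kernel_tau_ms, "kernel_tau_ms")
  check_scalar(window_ms, "window_ms")
  check_scalar(sample_step_ms, "sample_step_ms")
  check_scalar(n_bootstrap_per_pattern, "n_bootstrap_per_pattern",
               integerish = TRUE)
  check_scalar(k_neighbors, "k_neighbors", integerish = TRUE)
  check_scalar(n_iterations, "n_iterations", integerish = TRUE)
  check_scalar(seed, "seed", positive = FALSE, integerish = TRUE)
  if (variance_explained <= 0 || variance_explained > 1)
    abort("`variance_explained` must be in (0, 1].")
  structure(
    list(kernel_tau_ms = kernel_tau_ms,
         window_ms = window_ms,
         sample_step_ms = sample_step_ms,
         n_bootstrap_per_pattern = as.integer(n_bootstrap_per_pattern),
         variance_explained = variance_explained,
         k_neighbors = as.integer(k_neighbors),
         n_iterations = as.integer(n_iterations),
         seed = as.integer(seed)),
    class = "decoding_config")
}

#' Convolve a spike train with a causal exponential kernel
#'
#' Turns a spike train into a continuous response function by summing a
#' unit-area causal exponential kernel
#' \eqn{k(t) = \tau^{-1} e^{-t/\tau}, t \ge 0} placed at every spike,
#' evaluated on a regular sampling grid over the response window. Because
#' the kernel has unit area, the integral of the convolved response equals
#' the number of in-window spikes. Spikes outside `[0, window_ms)` are
#' dropped with a warning.
#'
#' @param spike_times_ms Numeric spike times, ms from stimulus onset.
#' @param config A [decoding_config()].
#' @return Numeric vector of length `window_ms / sample_step_ms`, the
#'   response sampled at grid points `0, step, 2*step, ...` (units 1/ms).
#' @examples
#' r <- convolve_response(c(0, 10), decoding_config())
#' sum(r) * 2  # ~ 2 spikes
#' @export
convolve_response <- function(spike_times_ms, config = decoding_config()) {
  grid <- seq(0, config$window_ms - config$sample_step_ms,
              by = config$sample_step_ms)
  out_of_window <- spike_times_ms < 0 | spike_times_ms >= config$window_ms
  if (any(out_of_window)) {
    warn(sprintf("Dropping %d spike(s) outside [0, %g) ms.",
                 sum(out_of_window), config$window_ms))
    spike_times_ms <- spike_times_ms[!out_of_window]
  }
  v <- numeric(length(grid))
  if (length(spike_times_ms)) {
    tau <- config$kernel_tau_ms
    for (s in spike_times_ms) {
      dt <- grid - s
      keep <- dt >= 0
      v[keep] <- v[keep] + exp(-dt[keep] / tau) / tau
    }
  }
  v
}

# all trials of a trial_set as a (n_trials_total x n_grid) response matrix
# plus labels; pattern-major row order
convolve_trials <- function(ts, config) {
  st <- spike_trains(ts)
  tau <- config$kernel_tau_ms
  grid <- seq(0, config$window_ms - config$sample_step_ms,
              by = config$sample_step_ms)
  mat <- matrix(0, nrow = length(st$trains), ncol = length(grid))
  for (i in seq_along(st$trains)) {
    s <- st$trains[[i]]
    s <- s[s >= 0 & s < config$window_ms]
    if (length(s)) {
      # exp(-(g - s)/tau) summed over spikes with g >= s, via a single
      # outer product on the in-window spikes
      e <- exp(outer(grid, -s, "+") / -tau)
      e[outer(grid, s, "<")] <- 0
      mat[i, ] <- rowSums(e) / tau
    }
  }
  list(responses = mat, pattern = st$pattern, trial = st$trial)
}

#' Stratified random train/test split
#'
#' Assigns the responses of every pattern half to a training set and half to
#' a test set (sizes differing by at most one for odd counts), so that every
#' pattern is present in both sets.
#'
#' @param labels Vector of pattern labels, one per response.
#' @return A list with integer index vectors `train` and `test`, a disjoint
#'   partition of `seq_along(labels)`. Uses the current RNG state.
#' @export
split_train_test <- function(labels) {
  idx <- split(seq_along(labels), labels)
  if (any(lengths(idx) < 2L))
    abort("Every pattern needs at least 2 responses to split.")
  picks <- lapply(idx, function(v) {
    n_tr <- floor(length(v) / 2)
    tr <- sample(v, n_tr)
    list(train = tr, test = setdiff(v, tr))
  })
  list(train = sort(unlist(lapply(picks, `[[`, "train"), use.names = FALSE)),
       test = sort(unlist(lapply(picks, `[[`, "test"), use.names = FALSE)))
}

#' Bootstrap-resample convolved responses
#'
#' For every pattern group, draws `n_bootstrap` samples of N responses with
#' replacement (N = group size) and stores each sample's elementwise sum as
#' one bootstrapped response. The expected value of a bootstrapped response
#' is therefore N times the group mean, and its label is the group's
#' pattern.
#'
#' @param responses Numeric matrix, one convolved response per row.
#' @param labels Pattern label of each row.
#' @param n_bootstrap Bootstrapped responses per pattern.
#' @return List with `responses` (matrix of bootstrapped sums, pattern-major)
#'   and `labels`. Uses the current RNG state.
#' @export
bootstrap_responses <- function(responses, labels, n_bootstrap = 200L) {
  groups <- split(seq_along(labels), labels)
  if (any(lengths(groups) == 0L)) abort("Empty pattern group.")
  out <- lapply(groups, function(rows) {
    m <- length(rows)
    idx <- matrix(sample(rows, n_bootstrap * m, replace = TRUE),
                  nrow = n_bootstrap)
    boot <- matrix(0, n_bootstrap, ncol(responses))
    for (j in seq_len(m)) boot <- boot + responses[idx[, j], , drop = FALSE]
    boot
  })
  list(responses = do.call(rbind, out),
       labels = rep(names(groups), each = n_bootstrap))
}

# bootstrap index matrices only (consumed by the C++ core); one
# (n_bootstrap x group size) matrix of global row indices per pattern
bootstrap_indices <- function(rows_by_pattern, n_bootstrap) {
  lapply(rows_by_pattern, function(rows) {
    matrix(sample(rows, n_bootstrap * length(rows), replace = TRUE),
           nrow = n_bootstrap)
  })
}

#' Principal-component basis of a response set
#'
#' Centers the responses on their mean and computes the ordered orthonormal
#' principal components, retaining the smallest number whose cumulative
#' explained-variance fraction reaches `variance_explained`.
#'
#' @param responses Numeric matrix, one response per row (>= 2 rows).
#' @param variance_explained Fraction in (0, 1].
#' @return A `response_pca` list: `rotation` (columns = retained
#'   components), `center`, `n_components`, `variance_fraction` (per
#'   retained component), `zero_variance` flag.
#' @export
fit_response_pca <- function(responses, variance_explained = 0.95) {
  if (nrow(responses) < 2L) abort("Need at least 2 responses for PCA.")
  ctr <- colMeans(responses)
  X <- sweep(responses, 2, ctr)
  G <- crossprod(X)
  e <- eigen(G, symmetric = TRUE)
  vals <- pmax(e$values, 0)
  total <- sum(vals)
  if (total <= 0) {
    return(structure(list(rotation = e$vectors[, 1, drop = FALSE],
                          center = ctr, n_components = 1L,
                          variance_fraction = NA_real_,
                          zero_variance = TRUE),
                     class = "response_pca"))
  }
  frac <- vals / total
  n_comp <- which(cumsum(frac) >= variance_explained)[1]
  structure(list(rotation = e$vectors[, seq_len(n_comp), drop = FALSE],
                 center = ctr,
                 n_components = as.integer(n_comp),
                 variance_fraction = frac[seq_len(n_comp)],
                 zero_variance = FALSE),
            class = "response_pca")
}

#' Project responses onto a principal-component basis
#'
#' Least-squares coefficients of each centered response on the component
#' basis; for an orthonormal basis these equal the inner products, so each
#' response is placed as a point in the N-dimensional component space.
#'
#' @param responses Numeric matrix, one response per row, same width as the
#'   basis vectors.
#' @param pca A `response_pca` from [fit_response_pca()].
#' @return Numeric matrix of coordinates (rows = responses, cols =
#'   components).
#' @export
project_responses <- function(responses, pca) {
  if (ncol(responses) != nrow(pca$rotation))
    abort("Response length does not match the component basis.")
  sweep(responses, 2, pca$center) %*% pca$rotation
}

#' k-nearest-neighbour classification in component space
#'
#' Classifies each test point by the relative majority label among its `k`
#' nearest training points (Euclidean distance). A tie between labels is
#' broken in favour of the label with the smaller summed distance over its
#' tied neighbours, then by the label of the single nearest tied neighbour,
#' making predictions deterministic and invariant to training-set order.
#'
#' @param test_coords,train_coords Coordinate matrices (rows = points).
#' @param train_labels Label of each training point.
#' @param k Number of neighbours; must not exceed the training-set size.
#' @return Character vector of predicted labels.
#' @export
knn_classify <- function(test_coords, train_coords, train_labels, k = 9L) {
  if (nrow(train_coords) < k)
    abort("Training set smaller than `k`.")
  train_labels <- as.character(train_labels)
  preds <- character(nrow(test_coords))
  for (i in seq_len(nrow(test_coords))) {
    d <- sqrt(colSums((t(train_coords) - test_coords[i, ])^2))
    nn <- order(d)[seq_len(k)]
    nn_lab <- train_labels[nn]
    counts <- table(nn_lab)
    tied <- names(counts)[counts == max(counts)]
    if (length(tied) > 1L) {
      sums <- vapply(tied, function(lb) sum(d[nn][nn_lab == lb]), numeric(1))
      tied <- tied[abs(sums - min(sums)) <= 1e-12]
      if (length(tied) > 1L) tied <- nn_lab[nn_lab %in% tied][1]
    }
    preds[i] <- tied[1]
  }
  preds
}

#' Precision, recall and macro F1 from a confusion matrix
#'
#' For each class c with rows = true and columns = predicted labels:
#' TP = `cm[c, c]`, FP = column sum - TP, FN = row sum - TP;
#' precision = TP / (TP + FP) (0 by convention when nothing was predicted as
#' c), recall = TP / (TP + FN), and the per-class F1 score is their harmonic
#' mean. The reported score is the unweighted (macro) mean of the per-class
#' F1 values; with a balanced design this coincides closely with the
#' micro-averaged score.
#'
#' @param cm Square non-negative matrix (may be averaged, i.e. non-integer).
#' @return List with `precision`, `recall`, `f1_per_class` (named vectors)
#'   and `f1_score` (macro mean, a fraction in [0, 1]).
#' @examples
#' f1_from_confusion(diag(8))$f1_score            # 1
#' f1_from_confusion(matrix(1, 8, 8))$f1_score    # 0.125
#' @export
f1_from_confusion <- function(cm) {
  cm <- as.matrix(cm)
  if (nrow(cm) != ncol(cm) || any(cm < 0))
    abort("`cm` must be a square non-negative matrix.")
  if (sum(cm) == 0) abort("`cm` is all zero.")
  tp <- diag(cm)
  fp <- colSums(cm) - tp
  fn <- rowSums(cm) - tp
  precision <- ifelse(tp + fp > 0, tp / (tp + fp), 0)
  recall <- ifelse(tp + fn > 0, tp / (tp + fn), 0)
  f1 <- ifelse(precision + recall > 0,
               2 * precision * recall / (precision + recall), 0)
  nm <- rownames(cm) %||% as.character(seq_len(nrow(cm)))
  list(precision = setNames(precision, nm),
       recall = setNames(recall, nm),
       f1_per_class = setNames(f1, nm),
       f1_score = mean(f1))
}

#' Threshold for counting a neuron as an above-chance decoder
#'
#' Mean plus two standard deviations of a population of shuffled-label F1
#' scores: a neuron whose unshuffled F1 exceeds this limit is counted as
#' decoding the stimulation patterns above chance.
#'
#' @param shuffled_f1 Numeric vector (length >= 2) of shuffled-label F1
#'   scores (fractions).
#' @return The threshold as a fraction.
#' @examples
#' decoder_threshold(c(0.1157, 0.1242, 0.1327))
#' @export
decoder_threshold <- function(shuffled_f1) {
  if (length(shuffled_f1) < 2L)
    abort("Need at least 2 shuffled F1 scores.")
  mean(shuffled_f1) + 2 * sd(shuffled_f1)
}
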