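#' Label output neurons by class-response probability
#'
#' With the weights frozen, the whole training set is presented once under
#' the labeling regime (same 200 Hz / 50 ms machinery as training) and the
#' cumulative output-spike counts `N_kj` per neuron k and class j are
#' recorded. Each neuron's response probabilities are
#' `Z_kj = N_kj / sum_j N_kj` and its label is `argmax_j Z_kj`. Neurons whose
#' maximum response probability falls below `removal_threshold`, and neurons
#' that never spiked, are flagged removed and take no part in testing.
#'
#' @param state a trained `snn_network` (plasticity is not applied).
#' @param train the training [snn_dataset] (filtered, bias appended).
#' @param cfg labeling [encoding_config] (defaults match training timing).
#' @param removal_threshold minimum acceptable max-class response
#'   probability, or `NULL` to keep all spiking neurons. Default 0.75.
#' @param seed optional integer; when given, seeds the labeling pass.
#' @return an object of class `evaluation_tables`: `N` (m x J spike counts),
#'   `Z` (response probabilities), `label` (0-based class per neuron, `NA`
#'   for spikeless neurons), `removed` (logical), `n_classes`.
#' @export
label_neurons <- function(state, train, cfg = encoding_config(),
                          removal_threshold = 0.75, seed = NULL) {
  if (nrow(train$images) == 0) stop("empty training set")
  if (!is.null(seed)) set.seed(as.integer(seed))
  m <- nrow(state$W); J <- train$n_classes
  N <- matrix(0, m, J)
  for (s in seq_len(nrow(train$images))) {
    spikes <- encode_sample(train$images[s, ], cfg)
    res <- run_presentation(state, spikes, out_rate_hz = cfg$out_rate_hz,
                            presentation_ms = cfg$presentation_ms,
                            plasticity = NULL)
    state <- res$state
    if (nrow(res$events)) {
      counts <- tabulate(res$events$neuron, nbins = m)
      N[, train$labels[s] + 1L] <- N[, train$labels[s] + 1L] + counts
    }
  }
  response_tables(N, removal_threshold)
}

#' Response probabilities, labels and removal flags from spike counts
#'
#' The arithmetic half of [label_neurons]: given the labeling-phase spike
#' counts `N_kj`, computes `Z_kj = N_kj / sum_j N_kj`, assigns each neuron
#' the class of its highest response probability, and flags for removal any
#' neuron whose maximum response probability is below `removal_threshold` or
#' that produced no spikes at all (such neurons get no label).
#'
#' @param N spike-count matrix, neurons x classes.
#' @param removal_threshold minimum acceptable max-class response
#'   probability, or `NULL` to keep all spiking neurons.
#' @return an `evaluation_tables` object (see [label_neurons]).
#' @export
response_tables <- function(N, removal_threshold = 0.75) {
  tot <- rowSums(N)
  Z <- N / ifelse(tot > 0, tot, 1)
  label <- ifelse(tot > 0, max.col(Z, ties.method = "first") - 1L, NA_integer_)
  removed <- tot == 0
  if (!is.null(removal_threshold)) {
    removed <- removed | apply(Z, 1, max) < removal_threshold
  }
  structure(list(N = N, Z = Z, label = as.integer(label), removed = removed,
                 n_classes = ncol(N)),
            class = "evaluation_tables")
}

#' @export
print.evaluation_tables <- function(x, ...) {
  cat("evaluation_tables:", nrow(x$N), "neurons,", x$n_classes, "classes\n")
  cat("  removed neurons:", sum(x$removed), "| labeled per class:",
      paste(tabulate(x$label[!x$removed] + 1L, nbins = x$n_classes),
            collapse = " "), "\n")
  invisible(x)
}

#' Predict the class of one sample by population mean firing
#'
#' Runs one test presentation (by default 600 Hz output gating over 200 ms),
#' counts the spikes of every retained neuron, and predicts
#' `J = argmax_j mean(S_k : label_k = j)` — the class whose neuron
#' population fired most on average. Ties break toward the lowest class
#' index; classes with no retained neurons are excluded.
#'
#' @param state a trained `snn_network`.
#' @param tables [label_neurons] output.
#' @param sample intensity vector (filtered, bias appended).
#' @param cfg test-phase [encoding_config]; default [test_encoding_config()].
#' @return 0-based predicted class index.
#' @export
predict_class <- function(state, tables, sample, cfg = test_encoding_config()) {
  keep <- !tables$removed
  if (!any(keep)) stop("no retained neurons to predict with")
  spikes <- encode_sample(sample, cfg)
  res <- run_presentation(state, spikes, out_rate_hz = cfg$out_rate_hz,
                          presentation_ms = cfg$presentation_ms,
                          plasticity = NULL)
  counts <- tabulate(res$events$neuron, nbins = nrow(state$W))
  means <- rep(-Inf, tables$n_classes)
  for (j in seq_len(tables$n_classes)) {
    pop <- which(keep & tables$label == j - 1L)
    if (length(pop)) means[j] <- sum(counts[pop]) / length(pop)
  }
  which.max(means) - 1L   # which.max takes the first (lowest) index on ties
}

#' Classification accuracy over a test set
#'
#' @param state a trained `snn_network`.
#' @param tables [label_neurons] output.
#' @param test the test [snn_dataset] (same filter and bias as training).
#' @param cfg test-phase [encoding_config].
#' @param seed optional integer; when given, seeds the test pass.
#' @return list with `accuracy` (proportion correct), `confusion`
#'   (true class x predicted class count matrix) and `predicted` (0-based
#'   vector).
#' @export
evaluate_accuracy <- function(state, tables, test, cfg = test_encoding_config(),
                              seed = NULL) {
  if (nrow(test$images) == 0) stop("empty test set")
  if (!is.null(seed)) set.seed(as.integer(seed))
  J <- test$n_classes
  pred <- integer(nrow(test$images))
  for (s in seq_len(nrow(test$images))) {
    pred[s] <- predict_class(state, tables, test$images[s, ], cfg)
  }
  confusion <- matrix(0L, J, J,
                      dimnames = list(true = 0:(J - 1), predicted = 0:(J - 1)))
  for (s in seq_along(pred)) {
    confusion[test$labels[s] + 1L, pred[s] + 1L] <-
      confusion[test$labels[s] + 1L, pred[s] + 1L] + 1L
  }
  list(accuracy = mean(pred == test$labels), confusion = confusion,
       predicted = pred)
}
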