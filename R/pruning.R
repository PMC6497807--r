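#' Pruning configuration
#'
#' Activity-triggered pruning: a neuron that produces a maximal run of at
#' least `run_length` consecutive output spikes inside the input window of
#' one presentation earns one consistent-firing count; once its count reaches
#' the prune parameter `r`, a user-set percentage of its weights is pruned —
#' exactly once per neuron per training run.
#'
#' @param run_length consecutive-spike threshold (default 8).
#' @param r consistent-firing counts required to trigger pruning (default 10).
#' @param percentage fraction of a neuron's weights to prune, in \[0, 1\].
#' @param mode `"prune"` (smallest-magnitude weights set to 0), `"soft"`
#'   (lowest-valued weights frozen at the lower bound -1) or `"off"`.
#' @param timing `"during"` (activity-triggered, while training) or
#'   `"after"` (every neuron pruned once training has finished).
#' @return a list of class `prune_config`.
#' @export
prune_config <- function(run_length = 8, r = 10, percentage = 0,
                         mode = c("off", "prune", "soft"),
                         timing = c("during", "after")) {
  stopifnot(run_length >= 1, r >= 1, percentage >= 0, percentage <= 1)
  structure(list(run_length = as.integer(run_length), r = as.integer(r),
                 percentage = percentage, mode = match.arg(mode),
                 timing = match.arg(timing)),
            class = "prune_config")
}

#' Count consistent-firing occurrences in one presentation
#'
#' Scans the firing-neuron sequence of the events that fall inside the input
#' window (step < `input_window_ms`); each maximal run of at least
#' `run_length` identical neuron ids contributes one occurrence for that
#' neuron. Runs never span presentation boundaries.
#'
#' @param events event data frame from [run_presentation] (one presentation).
#' @param input_window_ms the presentation's input window, in ms.
#' @param cfg a [prune_config].
#' @return named integer vector of per-neuron occurrence increments (empty
#'   when no run reaches the threshold).
#' @export
count_consecutive_runs <- function(events, input_window_ms, cfg) {
  ids <- events$neuron[events$step < input_window_ms]
  if (length(ids) == 0) return(integer(0))
  runs <- rle(ids)
  hit <- runs$lengths >= cfg$run_length
  if (!any(hit)) return(integer(0))
  tab <- table(runs$values[hit])
  out <- as.integer(tab)
  names(out) <- names(tab)
  out
}

#' Update consistent-firing counters and trigger one-shot pruning
#'
#' Adds the per-neuron increments to the counters; any neuron whose counter
#' reaches `r` and has not been pruned yet has [prune_weights] applied to its
#' row, once and never again. With `mode = "off"` (or `timing = "after"`)
#' counters are still tracked but no prune is applied.
#'
#' @param state an `snn_network`.
#' @param increments named vector from [count_consecutive_runs].
#' @param cfg a [prune_config].
#' @return the updated `snn_network`.
#' @export
maybe_trigger_prune <- function(state, increments, cfg) {
  if (length(increments)) {
    idx <- as.integer(names(increments))
    state$prune_counter[idx] <- state$prune_counter[idx] + increments
  }
  if (cfg$mode == "off" || cfg$timing != "during") return(state)
  ready <- which(state$prune_counter >= cfg$r & !state$pruned)
  for (k in ready) {
    pr <- prune_weights(state$W[k, ], cfg$percentage, cfg$mode)
    state$W[k, ] <- pr$weights
    state$prune_mask[k, pr$frozen_index] <- TRUE
    state$pruned[k] <- TRUE
    state$prune_log[[length(state$prune_log) + 1L]] <-
      list(neuron = k, time_ms = state$global_time_ms, mode = cfg$mode,
           percentage = cfg$percentage, n_frozen = length(pr$frozen_index))
  }
  state
}

round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Prune one neuron's weight vector
#'
#' Selects `k = round(percentage * length(weights))` synapses
#' (round-half-away-from-zero; ties in the selection criterion broken by
#' lower synapse index):
#' * `mode = "prune"` — the k weights of smallest magnitude ("centered about
#'   0") are set to 0, the conventional magnitude criterion;
#' * `mode = "soft"` — the k lowest-valued weights are set to the lower
#'   bound -1, matching a representation where background inputs share one
#'   saturated value while foreground weights stay free.
#'
#' Selected synapses are frozen: they take no further STDP updates.
#'
#' @param weights one neuron's weight vector.
#' @param percentage fraction of weights to prune, in \[0, 1\].
#' @param mode `"prune"` or `"soft"`.
#' @return list with `weights` (modified vector) and `frozen_index`.
#' @export
prune_weights <- function(weights, percentage, mode = c("prune", "soft")) {
  mode <- match.arg(mode)
  stopifnot(percentage >= 0, percentage <= 1)
  k <- as.integer(round_half_away(percentage * length(weights)))
  if (k == 0) return(list(weights = weights, frozen_index = integer(0)))
  key <- if (mode == "prune") abs(weights) else weights
  sel <- order(key, seq_along(weights))[seq_len(k)]
  weights[sel] <- if (mode == "prune") 0 else -1
  list(weights = weights, frozen_index = sort(sel))
}

#' Prune every output neuron of a trained network
#'
#' Baseline for comparing prune-during-training against pruning applied to an
#' already-trained network: [prune_weights] is applied to every neuron's row
#' at the given percentage and mode.
#'
#' @param state a trained `snn_network`.
#' @param percentage fraction of each neuron's weights to prune.
#' @param mode `"prune"` or `"soft"`.
#' @return the pruned `snn_network`.
#' @export
prune_after_training <- function(state, percentage, mode = c("prune", "soft")) {
  mode <- match.arg(mode)
  for (k in seq_len(nrow(state$W))) {
    pr <- prune_weights(state$W[k, ], percentage, mode)
    state$W[k, ] <- pr$weights
    state$prune_mask[k, pr$frozen_index] <- TRUE
    if (length(pr$frozen_index)) state$pruned[k] <- TRUE
  }
  state
}

#' Per-neuron prune report
#'
#' @param state an `snn_network` after training.
#' @param path optional CSV path.
#' @return data frame with one row per prune event: neuron, global time (ms),
#'   mode, percentage and frozen-synapse count.
#' @export
prune_report <- function(state, path = NULL) {
  if (length(state$prune_log) == 0) {
    out <- data.frame(neuron = integer(0), time_ms = integer(0),
                      mode = character(0), percentage = numeric(0),
                      n_frozen = integer(0))
  } else {
    out <- do.call(rbind, lapply(state$prune_log, as.data.frame))
  }
  if (!is.null(path)) utils::write.csv(out, path, row.names = FALSE)
  out
}
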