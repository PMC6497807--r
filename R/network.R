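#' Initialize network state with uniform random weights
#'
#' Weights are drawn i.i.d. uniform on \[-1, 1\] for an `m` (output) x `n`
#' (input) fully connected single layer. Prune masks, counters and the
#' global clock start at zero; no input has spiked yet.
#'
#' @param m number of output neurons.
#' @param n number of input neurons (including the bias input, if used).
#' @return an object of class `snn_network` with fields `W` (m x n weight
#'   matrix), `prune_mask` (logical m x n, `TRUE` = frozen), `prune_counter`
#'   (per-neuron consistent-firing count), `pruned` (per-neuron one-shot
#'   flag), `last_input_spike_ms` (global time of each input's most recent
#'   spike, `-Inf` if none), `global_time_ms`, and `update_count` (running
#'   tally of synapse modifications).
#' @export
init_weights <- function(m, n) {
  if (m < 1 || n < 1) stop("m and n must be positive")
  structure(
    list(W = matrix(stats::runif(m * n, -1, 1), nrow = m, ncol = n),
         prune_mask = matrix(FALSE, m, n),
         prune_counter = integer(m),
         pruned = logical(m),
         prune_log = list(),
         last_input_spike_ms = rep(-Inf, n),
         global_time_ms = 0L,
         update_count = 0),
    class = "snn_network")
}

#' @export
print.snn_network <- function(x, ...) {
  cat("snn_network:", nrow(x$W), "output x", ncol(x$W), "input neurons\n")
  cat("  weights in [", sprintf("%.3f", min(x$W)), ",",
      sprintf("%.3f", max(x$W)), "] | pruned neurons:", sum(x$pruned),
      "| frozen synapses:", sum(x$prune_mask), "\n")
  cat("  clock:", x$global_time_ms, "ms | synapse updates:",
      format(x$update_count, big.mark = ","), "\n")
  invisible(x)
}

#' Membrane potentials at one time step
#'
#' The instantaneous potential of output neuron k is the inner product of its
#' weight row with the binary input-spike vector at the current step,
#' `u_k = sum_i W_ki x_i`; the bias term enters through the bias input's
#' weight column. Potentials are evaluated only at output firing steps and
#' never integrated over time.
#'
#' @param state an `snn_network`.
#' @param x binary input-spike vector of length `n`.
#' @return numeric vector of length `m`.
#' @export
membrane_potentials <- function(state, x) {
  if (length(x) != ncol(state$W)) {
    stop("input vector length ", length(x), " does not match n = ", ncol(state$W))
  }
  drop(state$W %*% x)
}

#' Sample the firing neuron from the softmax of membrane potentials
#'
#' Returns index k with probability `exp(u_k) / sum_i exp(u_i)`, computed
#' stably by shifting by `max(u)`. Consumes exactly one uniform draw.
#'
#' @param u finite numeric vector of membrane potentials.
#' @return integer index of the winning output neuron.
#' @export
softmax_fire <- function(u) {
  if (length(u) == 0) stop("empty potential vector")
  if (any(!is.finite(u))) stop("membrane potentials must be finite")
  p <- exp(u - max(u))
  cdf <- cumsum(p)
  draw <- stats::runif(1) * cdf[length(cdf)]
  findInterval(draw, cdf, left.open = TRUE) + 1L
}

#' Softmax probabilities of a potential vector
#'
#' @param u finite numeric vector.
#' @return probability vector summing to 1.
#' @export
softmax_probs <- function(u) {
  p <- exp(u - max(u))
  p / sum(p)
}

#' Run one presentation of a sample through the network
#'
#' For each 1-ms step `t` in `[0, presentation_ms)`: input spikes at `t`
#' update the per-input last-spike clock, then an output firing event occurs
#' with probability `out_rate_hz / 1000` (one global Poisson process gates
#' all output firing; at most one event per step). At an event the membrane
#' potentials are computed from the input-spike snapshot of that step and the
#' firing neuron is drawn from their softmax. When a plasticity hook is
#' supplied it is applied after each event; with `plasticity = NULL` the
#' weights are untouched (labeling/testing mode). The global clock advances
#' by `presentation_ms`.
#'
#' Random draws occur in a fixed order — the per-step event gate for the whole
#' presentation first, then one draw per event in time order — so runs that
#' share a seed and inputs consume the stream identically whether or not
#' plasticity or pruning is active.
#'
#' @param state an `snn_network`.
#' @param spikes a `spike_train_block` from [encode_sample] with `n` columns.
#' @param out_rate_hz rate of the output-gating Poisson process (Hz).
#' @param presentation_ms duration of the presentation; defaults to the
#'   number of rows in `spikes`.
#' @param plasticity `NULL`, or a hook `function(state, event)` returning the
#'   updated state (see [stdp_hook]).
#' @return list with `state` (updated network) and `events`, a data frame
#'   with one row per firing event: `time_ms` (global), `step` (0-based step
#'   within the presentation) and `neuron`. Input snapshots for events are in
#'   `attr(events, "snapshots")` (list of binary vectors) when any event
#'   occurred.
#' @export
run_presentation <- function(state, spikes, out_rate_hz = 200,
                             presentation_ms = nrow(spikes),
                             plasticity = NULL) {
  p_out <- out_rate_hz / 1000
  if (p_out > 1) stop("out_rate_hz/1000 must be a valid per-ms probability")
  n <- ncol(state$W)
  if (ncol(spikes) != n) stop("spike block has ", ncol(spikes), " inputs; network expects ", n)
  t0 <- state$global_time_ms
  sp <- unclass(spikes)
  gate <- stats::runif(presentation_ms) < p_out
  ev_step <- integer(0); ev_neuron <- integer(0); snapshots <- list()
  zero_x <- numeric(n)
  for (t in seq_len(presentation_ms) - 1L) {
    x <- if (t < nrow(sp)) sp[t + 1L, ] else zero_x
    spiked <- which(x == 1L)
    if (length(spiked)) state$last_input_spike_ms[spiked] <- t0 + t
    if (gate[t + 1L]) {
      u <- drop(state$W %*% x)
      k <- softmax_fire(u)
      event <- list(time_ms = t0 + t, step = t, neuron = k, input_snapshot = x)
      if (!is.null(plasticity)) state <- plasticity(state, event)
      ev_step <- c(ev_step, t); ev_neuron <- c(ev_neuron, k)
      snapshots[[length(snapshots) + 1L]] <- x
    }
  }
  state$global_time_ms <- t0 + as.integer(presentation_ms)
  events <- data.frame(time_ms = t0 + ev_step, step = ev_step, neuron = ev_neuron)
  attr(events, "snapshots") <- snapshots
  list(state = state, events = events)
}

#' Save a model checkpoint
#'
#' Serializes the network together with the retained-pixel index, the run
#' configuration and the seeds in force, so that reloading reproduces
#' subsequent training bit for bit.
#'
#' @param state an `snn_network`.
#' @param path output file path (RDS).
#' @param retained_pixel_index pixel filter index used for this model.
#' @param config optional run configuration list.
#' @param seed optional master seed recorded with the model.
#' @return `invisible(path)`.
#' @export
save_checkpoint <- function(state, path, retained_pixel_index = NULL,
                            config = NULL, seed = NULL) {
  saveRDS(list(state = state, retained_pixel_index = retained_pixel_index,
               config = config, seed = seed,
               package_version = as.character(utils::packageVersion("spikeprune"))),
          path)
  invisible(path)
}

#' Load a model checkpoint written by [save_checkpoint]
#' @param path checkpoint file path.
#' @return the checkpoint list.
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) stop("checkpoint not found: ", path)
  readRDS(path)
}
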