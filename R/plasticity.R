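#' STDP configuration
#'
#' Parameters of the simplified spike-timing-dependent plasticity rule:
#' exponential long-term potentiation `dw = a * exp(-b (w + 1))`, constant
#' long-term depression `dw = -c`, and a `sigma_ms` coincidence window. The
#' defaults are the cross-validated values used throughout
#' (a = 0.0667, b = 2.5, c = 0.0167, sigma = 10 ms, bounds \[-1, 1\]).
#'
#' @param a LTP scale, in (0, 1).
#' @param b_exp LTP exponential decay rate, positive.
#' @param c_ltd LTD magnitude, in (0, 1); the LTD step is `-c_ltd`.
#' @param sigma_ms coincidence window: a synapse is potentiated when
#'   `0 <= t_out - t_in < sigma_ms` (strict upper bound).
#' @param w_min,w_max hard weight bounds.
#' @param ltp_form `"exponential"` (default) or `"constant"`; the constant
#'   form uses magnitude `c_ltd` and exists to expose the exact LTP/LTD
#'   balance of the scaled update in tests.
#' @param scale_n `"unpruned"` (default) or `"total"`: whether the scaling
#'   denominator n counts only a neuron's unpruned synapses or all of them.
#' @return a list of class `stdp_config`.
#' @export
stdp_config <- function(a = 0.0667, b_exp = 2.5, c_ltd = 0.0167,
                        sigma_ms = 10, w_min = -1, w_max = 1,
                        ltp_form = c("exponential", "constant"),
                        scale_n = c("unpruned", "total")) {
  stopifnot(a > 0, a < 1, b_exp > 0, c_ltd >= 0, c_ltd < 1, sigma_ms > 0,
            w_min < w_max)
  structure(list(a = a, b_exp = b_exp, c_ltd = c_ltd, sigma_ms = sigma_ms,
                 w_min = w_min, w_max = w_max,
                 ltp_form = match.arg(ltp_form),
                 scale_n = match.arg(scale_n)),
            class = "stdp_config")
}

#' LTP weight increment
#'
#' `a * exp(-b_exp * (w + 1))`: strictly positive, strictly decreasing in w,
#' equal to `a` at the lower bound and decaying toward 0 as w approaches the
#' upper bound, which is what keeps potentiated weights inside \[-1, 1\].
#' With `ltp_form = "constant"` the increment is `c_ltd` regardless of w.
#'
#' @param w current weight value(s).
#' @param cfg an [stdp_config].
#' @return weight increment(s), same length as `w`.
#' @export
ltp_delta <- function(w, cfg) {
  if (cfg$ltp_form == "constant") rep(cfg$c_ltd, length(w))
  else cfg$a * exp(-cfg$b_exp * (w + 1))
}

#' LTD weight increment
#'
#' Constant `-c_ltd` regardless of the current weight; depressed weights are
#' clipped at the lower bound.
#'
#' @param cfg an [stdp_config].
#' @return the (negative) LTD increment.
#' @export
ltd_delta <- function(cfg) -cfg$c_ltd

#' Classify the firing neuron's synapses into LTP and LTD sets
#'
#' For every unpruned synapse of the neuron that fired: LTP when its input's
#' most recent spike is within the coincidence window
#' (`0 <= t_out - t_in < sigma_ms`), otherwise LTD — including inputs that
#' have never spiked. Frozen (pruned) synapses belong to neither set.
#'
#' @param event a firing event (list with `time_ms` and `neuron`).
#' @param last_input_spike_ms per-input global time of most recent spike.
#' @param cfg an [stdp_config].
#' @param prune_mask_row logical vector, `TRUE` where the synapse is frozen.
#' @return list with `ltp_index`, `ltd_index` (integer index vectors),
#'   `p` (LTP count) and `d` (LTD count).
#' @export
classify_synapses <- function(event, last_input_spike_ms, cfg,
                              prune_mask_row = logical(length(last_input_spike_ms))) {
  dt <- event$time_ms - last_input_spike_ms
  if (any(dt < 0)) stop("event precedes a recorded input spike")
  in_window <- is.finite(dt) & dt < cfg$sigma_ms
  ltp <- which(in_window & !prune_mask_row)
  ltd <- which(!in_window & !prune_mask_row)
  list(ltp_index = ltp, ltd_index = ltd, p = length(ltp), d = length(ltd))
}

#' Apply one scaled STDP update to the firing neuron's weights
#'
#' LTP synapses move by `(d/n) * ltp_delta(w)` and LTD synapses by
#' `(p/n) * (-c_ltd)`, where `p` and `d` are the LTP/LTD counts and `n` is
#' the scaling denominator (the neuron's unpruned synapse count by default,
#' see [stdp_config]). The opposing scale factors keep the net weight change
#' of the two branches proportional, which equalizes the weight
#' distributions across output neurons without explicit mean/variance
#' normalization. Touched weights are clipped to `[w_min, w_max]`; frozen
#' synapses never move. The network's `update_count` grows by `p + d`, the
#' number of synapses modified by the event.
#'
#' @param state an `snn_network`.
#' @param event the firing event the breakdown was computed for.
#' @param breakdown output of [classify_synapses] for this event.
#' @param cfg an [stdp_config].
#' @return the updated `snn_network`.
#' @export
apply_scaled_update <- function(state, event, breakdown, cfg) {
  k <- event$neuron
  if (length(breakdown$ltp_index) && any(state$prune_mask[k, breakdown$ltp_index])) {
    stop("breakdown includes frozen synapses for neuron ", k)
  }
  n_scale <- if (cfg$scale_n == "total") ncol(state$W) else breakdown$p + breakdown$d
  if (n_scale == 0) return(state)
  w <- state$W[k, ]
  if (breakdown$p > 0) {
    i <- breakdown$ltp_index
    w[i] <- w[i] + (breakdown$d / n_scale) * ltp_delta(w[i], cfg)
  }
  if (breakdown$d > 0) {
    i <- breakdown$ltd_index
    w[i] <- w[i] + (breakdown$p / n_scale) * ltd_delta(cfg)
  }
  touched <- c(breakdown$ltp_index, breakdown$ltd_index)
  w[touched] <- pmin(pmax(w[touched], cfg$w_min), cfg$w_max)
  state$W[k, ] <- w
  state$update_count <- state$update_count + breakdown$p + breakdown$d
  state
}

#' Build a plasticity hook for [run_presentation]
#'
#' Returns `function(state, event)` that classifies the firing neuron's
#' synapses against the per-input last-spike clock and applies the scaled
#' STDP update.
#'
#' @param cfg an [stdp_config].
#' @return a plasticity hook closure.
#' @export
stdp_hook <- function(cfg) {
  force(cfg)
  function(state, event) {
    bd <- classify_synapses(event, state$last_input_spike_ms, cfg,
                            state$prune_mask[event$neuron, ])
    apply_scaled_update(state, event, bd, cfg)
  }
}
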