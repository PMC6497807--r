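#' Poisson rate-coding configuration
#'
#' Defaults follow the training/labeling regime: inputs fire at up to 200 Hz
#' (intensity x 200), each sample is presented for 50 ms, and input spikes are
#' confined to the first 40 ms so the final 10 ms are silent. For testing use
#' [test_encoding_config].
#'
#' @param max_rate_hz peak input firing rate at intensity 1, in Hz.
#' @param presentation_ms presentation period per sample, in ms.
#' @param input_window_ms portion of the presentation during which the input
#'   is displayed; no input spikes occur at or after this time.
#' @param out_rate_hz rate of the global output-firing Poisson process, in Hz.
#' @return a list of class `encoding_config`.
#' @export
encoding_config <- function(max_rate_hz = 200, presentation_ms = 50,
                            input_window_ms = 40, out_rate_hz = 200) {
  if (input_window_ms > presentation_ms) {
    stop("input_window_ms must not exceed presentation_ms")
  }
  if (max_rate_hz / 1000 > 1) stop("max_rate_hz/1000 must be a valid per-ms probability")
  if (out_rate_hz / 1000 > 1) stop("out_rate_hz/1000 must be a valid per-ms probability")
  structure(list(max_rate_hz = max_rate_hz,
                 presentation_ms = as.integer(presentation_ms),
                 input_window_ms = as.integer(input_window_ms),
                 out_rate_hz = out_rate_hz),
            class = "encoding_config")
}

#' Test-phase encoding configuration
#'
#' During testing the output process runs at 600 Hz over a 200 ms
#' presentation, and the input is displayed for the full presentation (the
#' silent tail only matters when plasticity is active).
#'
#' @inheritParams encoding_config
#' @return an [encoding_config].
#' @export
test_encoding_config <- function(max_rate_hz = 200, presentation_ms = 200,
                                 out_rate_hz = 600) {
  encoding_config(max_rate_hz = max_rate_hz, presentation_ms = presentation_ms,
                  input_window_ms = presentation_ms, out_rate_hz = out_rate_hz)
}

#' Encode one sample as a block of millisecond-binned Poisson spike trains
#'
#' Each input neuron fires independently at every 1-ms step inside the input
#' window with probability `intensity * max_rate_hz / 1000` — the
#' Bernoulli-per-bin realization of a Poisson process whose event times are
#' rounded to the millisecond grid (at most one spike per input per ms).
#' Steps at or beyond the input window carry no spikes.
#'
#' Randomness comes from R's global RNG stream; seed it at the phase level
#' for reproducibility.
#'
#' @param pixels intensity vector with values in \[0, 1\].
#' @param cfg an [encoding_config].
#' @return binary matrix of class `spike_train_block`,
#'   `presentation_ms` x `length(pixels)`; row `t` holds the spikes of step
#'   `t - 1` ms.
#' @export
encode_sample <- function(pixels, cfg) {
  if (any(pixels < 0 | pixels > 1)) stop("intensities must lie in [0, 1]")
  n <- length(pixels)
  win <- cfg$input_window_ms
  p <- pixels * cfg$max_rate_hz / 1000
  spikes <- matrix(0L, nrow = cfg$presentation_ms, ncol = n)
  if (win > 0 && n > 0) {
    u <- matrix(stats::runif(win * n), nrow = win, ncol = n)
    spikes[seq_len(win), ] <- (u < rep(p, each = win)) + 0L
  }
  structure(spikes, class = c("spike_train_block", "matrix", "array"),
            input_window_ms = win)
}

#' Export a spike block as a (time_ms, input) raster table
#'
#' @param spikes a `spike_train_block` from [encode_sample].
#' @param path optional CSV path; when given, the table is written there.
#' @return data frame with columns `time_ms` (0-based) and `input` (1-based),
#'   ordered by time then input.
#' @export
spike_raster <- function(spikes, path = NULL) {
  idx <- which(unclass(spikes) == 1L, arr.ind = TRUE)
  out <- data.frame(time_ms = idx[, 1] - 1L, input = idx[, 2])
  out <- out[order(out$time_ms, out$input), , drop = FALSE]
  rownames(out) <- NULL
  if (!is.null(path)) utils::write.csv(out, path, row.names = FALSE)
  out
}
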