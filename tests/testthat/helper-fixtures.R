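# Small in-code fixtures shared across tests.

# A tiny 2x2-image dataset with known bytes, for IDX round trips.
tiny_dataset <- function() {
  snn_dataset(
    images = matrix(c(0, 51, 102, 255,
                      255, 0, 0, 204) / 255, nrow = 2, byrow = TRUE),
    labels = c(3L, 7L), pixel_shape = c(2, 2), n_classes = 10)
}

write_tiny_idx <- function(dir = withr::local_tempdir(.local_envir = parent.frame())) {
  ds <- tiny_dataset()
  paths <- list(images = file.path(dir, "imgs.idx"),
                labels = file.path(dir, "labs.idx"))
  write_idx(ds, paths$images, paths$labels)
  paths
}

# Deterministic network with hand-set weights.
manual_network <- function(W) {
  st <- init_weights(nrow(W), ncol(W))
  st$W <- W
  st
}

# Scalar-loop oracle for the scaled STDP update: one synapse at a time,
# no vectorization, same arithmetic contract as the vectorized path.
scalar_update_oracle <- function(w, ltp_index, ltd_index, cfg) {
  p <- length(ltp_index); d <- length(ltd_index); n <- p + d
  out <- w
  for (i in ltp_index) {
    out[i] <- out[i] + (d / n) * (cfg$a * exp(-cfg$b_exp * (out[i] + 1)))
  }
  for (i in ltd_index) {
    out[i] <- out[i] + (p / n) * (-cfg$c_ltd)
  }
  for (i in c(ltp_index, ltd_index)) {
    out[i] <- min(max(out[i], cfg$w_min), cfg$w_max)
  }
  out
}

# Small trained-ish run used by several tests; cached per session.
small_run_config <- function(seed = 42) {
  cfg <- default_run_config(seed = seed)
  cfg$dataset$samples_per_class <- 40
  cfg$dataset$test_samples_per_class <- 8
  cfg$m <- 20
  cfg$epochs <- 1
  cfg
}
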