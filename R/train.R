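#' Derive an independent phase seed from a master seed
#'
#' Each pipeline phase (weight init, training, labeling, testing, data
#' generation) gets its own stream seed so phases are independently
#' reproducible and two runs that share a master seed consume identical
#' streams phase by phase.
#'
#' @param master integer master seed.
#' @param phase one of `"data"`, `"testdata"`, `"init"`, `"train"`,
#'   `"label"`, `"test"`, or an integer phase id.
#' @return an integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(master, phase) {
  phases <- c(data = 1, testdata = 2, init = 3, train = 4, label = 5, test = 6)
  id <- if (is.character(phase)) {
    if (!phase %in% names(phases)) stop("unknown phase: ", phase)
    phases[[phase]]
  } else as.numeric(phase)
  as.integer((as.numeric(master) %% 2147483647 * 131 + id * 524287) %% 2147483647)
}

#' Train the spiking network on a dataset
#'
#' Presents the dataset sequentially (in dataset order unless `shuffle`) for
#' `epochs` epochs with the STDP plasticity hook active, tracking
#' consistent-firing counts and applying activity-triggered pruning per
#' `prune_cfg`. With `timing = "after"` the network is pruned once at the
#' end instead.
#'
#' @param ds training [snn_dataset] (filtered, bias appended).
#' @param m number of output neurons.
#' @param epochs training epochs (default 3).
#' @param enc_cfg training [encoding_config].
#' @param stdp_cfg an [stdp_config].
#' @param prune_cfg a [prune_config].
#' @param seed master seed; phase seeds are derived with [derive_seed].
#' @param shuffle randomize sample order each epoch (default `FALSE`:
#'   sequential presentation).
#' @param record_events keep the full firing-event log (time, neuron) —
#'   needed for event-level run comparisons; off by default to save memory.
#' @return list of class `snn_fit`: `state` (trained network), `log`
#'   (per-epoch data frame with cumulative update counts and prunes),
#'   `events` (data frame or `NULL`), `first_prune_ms` (global time of the
#'   first prune trigger, `NA` if none), `seed`.
#' @export
train_snn <- function(ds, m, epochs = 3, enc_cfg = encoding_config(),
                      stdp_cfg = stdp_config(), prune_cfg = prune_config(),
                      seed = 1, shuffle = FALSE, record_events = FALSE) {
  set.seed(derive_seed(seed, "init"))
  state <- init_weights(m, n_inputs(ds))
  hook <- stdp_hook(stdp_cfg)
  set.seed(derive_seed(seed, "train"))
  n_samp <- nrow(ds$images)
  log <- data.frame(epoch = integer(0), updates = numeric(0),
                    pruned_neurons = integer(0))
  ev_list <- if (record_events) vector("list", epochs * n_samp) else NULL
  first_prune_ms <- NA_real_
  for (ep in seq_len(epochs)) {
    order_s <- if (shuffle) sample.int(n_samp) else seq_len(n_samp)
    for (s in order_s) {
      spikes <- encode_sample(ds$images[s, ], enc_cfg)
      res <- run_presentation(state, spikes, out_rate_hz = enc_cfg$out_rate_hz,
                              presentation_ms = enc_cfg$presentation_ms,
                              plasticity = hook)
      state <- res$state
      incr <- count_consecutive_runs(res$events, enc_cfg$input_window_ms,
                                     prune_cfg)
      n_pruned_before <- sum(state$pruned)
      state <- maybe_trigger_prune(state, incr, prune_cfg)
      if (is.na(first_prune_ms) && sum(state$pruned) > n_pruned_before) {
        first_prune_ms <- state$global_time_ms
      }
      if (record_events) {
        ev_list[[(ep - 1L) * n_samp + s]] <- res$events[c("time_ms", "neuron")]
      }
    }
    log <- rbind(log, data.frame(epoch = ep, updates = state$update_count,
                                 pruned_neurons = sum(state$pruned)))
  }
  if (prune_cfg$timing == "after" && prune_cfg$mode != "off") {
    state <- prune_after_training(state, prune_cfg$percentage, prune_cfg$mode)
  }
  events <- if (record_events) do.call(rbind, ev_list) else NULL
  structure(list(state = state, log = log, events = events,
                 first_prune_ms = first_prune_ms, seed = seed),
            class = "snn_fit")
}

#' @export
print.snn_fit <- function(x, ...) {
  cat("snn_fit: trained over", max(x$log$epoch), "epoch(s)\n")
  print(x$state)
  invisible(x)
}

#' Default run configuration
#'
#' A complete, serializable description of one experiment: dataset source,
#' network size, encoding/STDP/pruning parameters and the master seed. A run
#' is a pure function of this configuration.
#'
#' @param seed master seed.
#' @return nested list of class `run_config`.
#' @export
default_run_config <- function(seed = 1) {
  structure(list(
    dataset = list(type = "synthetic", n_classes = 4, samples_per_class = 200,
                   test_samples_per_class = 50, grid = c(28, 28),
                   fg_jitter = c(0.5, 1), salt_prob = 0.02,
                   images = NULL, labels = NULL,
                   test_images = NULL, test_labels = NULL),
    zero_fraction_threshold = 0.95,
    m = 100, epochs = 2, shuffle = FALSE,
    encoding = list(max_rate_hz = 200, presentation_ms = 50,
                    input_window_ms = 40, out_rate_hz = 200),
    testing = list(max_rate_hz = 200, presentation_ms = 200, out_rate_hz = 600),
    stdp = list(a = 0.0667, b_exp = 2.5, c_ltd = 0.0167, sigma_ms = 10),
    prune = list(run_length = 8, r = 10, percentage = 0, mode = "off",
                 timing = "during"),
    removal_threshold = 0.75,
    seed = as.integer(seed)), class = "run_config")
}

#' Load a run configuration from a YAML file
#'
#' Fields present in the file override [default_run_config]; everything else
#' keeps its default.
#'
#' @param path YAML file path.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- yaml::read_yaml(path)
  cfg <- default_run_config()
  merge_in <- function(base, over) {
    for (nm in names(over)) {
      base[[nm]] <- if (is.list(base[[nm]]) && is.list(over[[nm]])) {
        merge_in(base[[nm]], over[[nm]])
      } else over[[nm]]
    }
    base
  }
  structure(merge_in(unclass(cfg), user), class = "run_config")
}

load_config_datasets <- function(config) {
  d <- config$dataset
  if (identical(d$type, "synthetic")) {
    train <- generate_synthetic(d$n_classes, d$samples_per_class,
                                grid = d$grid, fg_jitter = d$fg_jitter,
                                salt_prob = d$salt_prob,
                                seed = derive_seed(config$seed, "data"))
    test <- generate_synthetic(d$n_classes, d$test_samples_per_class,
                               grid = d$grid, fg_jitter = d$fg_jitter,
                               salt_prob = d$salt_prob,
                               seed = derive_seed(config$seed, "testdata"))
  } else if (identical(d$type, "idx")) {
    train <- read_idx(d$images, d$labels)
    test <- if (!is.null(d$test_images)) read_idx(d$test_images, d$test_labels)
            else NULL
  } else stop("unknown dataset type: ", d$type)
  list(train = train, test = test)
}

prepare_inputs <- function(train, test, zero_fraction_threshold) {
  train_f <- remove_background_pixels(train, zero_fraction_threshold)
  idx <- match(train_f$retained_pixel_index, train$retained_pixel_index)
  test_f <- if (!is.null(test)) append_bias(apply_pixel_filter(test, idx)) else NULL
  list(train = append_bias(train_f), test = test_f,
       retained_pixel_index = train_f$retained_pixel_index)
}

#' Run a complete experiment from a configuration
#'
#' Generates or reads the datasets, computes the background-pixel filter on
#' the training split and applies it to both splits, appends the bias input,
#' trains the network, labels the output neurons, and measures test
#' accuracy. Every stochastic phase is seeded from `config$seed` via
#' [derive_seed], so the result is a pure function of the configuration.
#'
#' @param config a `run_config` (see [default_run_config]).
#' @param record_events keep the training firing-event log.
#' @return list of class `snn_run`: `fit`, `tables`, `result`
#'   (accuracy/confusion), `retained_pixel_index`, `config`.
#' @export
run_experiment <- function(config, record_events = FALSE) {
  ds <- load_config_datasets(config)
  prep <- prepare_inputs(ds$train, ds$test, config$zero_fraction_threshold)
  enc <- do.call(encoding_config, config$encoding)
  stdp <- do.call(stdp_config, config$stdp)
  prune <- do.call(prune_config, config$prune)
  fit <- train_snn(prep$train, m = config$m, epochs = config$epochs,
                   enc_cfg = enc, stdp_cfg = stdp, prune_cfg = prune,
                   seed = config$seed, shuffle = isTRUE(config$shuffle),
                   record_events = record_events)
  tables <- label_neurons(fit$state, prep$train, cfg = enc,
                          removal_threshold = config$removal_threshold,
                          seed = derive_seed(config$seed, "label"))
  result <- if (!is.null(prep$test)) {
    evaluate_accuracy(fit$state, tables, prep$test,
                      cfg = do.call(test_encoding_config, config$testing),
                      seed = derive_seed(config$seed, "test"))
  } else NULL
  structure(list(fit = fit, tables = tables, result = result,
                 retained_pixel_index = prep$retained_pixel_index,
                 config = config),
            class = "snn_run")
}

#' @export
print.snn_run <- function(x, ...) {
  print(x$fit)
  print(x$tables)
  if (!is.null(x$result)) {
    cat("  test accuracy:", sprintf("%.3f", x$result$accuracy), "\n")
  }
  invisible(x)
}
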