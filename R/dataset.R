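#' Construct a spiking-network dataset
#'
#' A `snn_dataset` holds pixel-intensity vectors (one row per sample, values
#' in \[0, 1\]), integer class labels, and bookkeeping for background-pixel
#' filtering and the always-on bias input.
#'
#' @param images numeric matrix, samples x pixels, values in \[0, 1\].
#' @param labels integer vector of 0-based class labels, one per sample.
#' @param pixel_shape integer vector `c(rows, cols)` of the original image grid.
#' @param n_classes number of classes; defaults to `max(labels) + 1`.
#' @param retained_pixel_index 1-based positions (in the original flattened
#'   grid) of the pixel columns currently present, strictly increasing.
#' @param has_bias logical; `TRUE` once a constant-1 bias column has been
#'   appended as the last input.
#'
#' @return an object of class `snn_dataset`.
#' @export
snn_dataset <- function(images, labels, pixel_shape,
                        n_classes = if (length(labels)) max(labels) + 1L else 0L,
                        retained_pixel_index = seq_len(ncol(images)),
                        has_bias = FALSE) {
  images <- as.matrix(images)
  labels <- as.integer(labels)
  if (nrow(images) != length(labels)) {
    stop("number of images (", nrow(images), ") does not match number of labels (",
         length(labels), ")")
  }
  if (any(images < 0 | images > 1)) {
    stop("pixel intensities must lie in [0, 1]")
  }
  if (is.unsorted(retained_pixel_index, strictly = TRUE)) {
    stop("retained_pixel_index must be strictly increasing")
  }
  n_pix <- ncol(images) - as.integer(has_bias)
  if (length(retained_pixel_index) != n_pix) {
    stop("retained_pixel_index length (", length(retained_pixel_index),
         ") does not match pixel column count (", n_pix, ")")
  }
  if (has_bias && nrow(images) > 0 && any(images[, ncol(images)] != 1)) {
    stop("bias column must be exactly 1 for every sample")
  }
  structure(
    list(images = images, labels = labels,
         n_classes = as.integer(n_classes),
         pixel_shape = as.integer(pixel_shape),
         retained_pixel_index = as.integer(retained_pixel_index),
         has_bias = isTRUE(has_bias)),
    class = "snn_dataset")
}

#' @export
print.snn_dataset <- function(x, ...) {
  cat("snn_dataset:", nrow(x$images), "samples,", ncol(x$images), "inputs",
      if (x$has_bias) "(incl. bias)" else "", "\n")
  cat("  classes:", x$n_classes,
      "| original grid:", paste(x$pixel_shape, collapse = "x"),
      "| retained pixels:", length(x$retained_pixel_index), "\n")
  invisible(x)
}

#' Number of input neurons a dataset presents to the network
#' @param ds an `snn_dataset`.
#' @return integer column count of the sample matrix.
#' @export
n_inputs <- function(ds) ncol(ds$images)

idx_magic_images <- 2051L # 0x00000803
idx_magic_labels <- 2049L # 0x00000801

read_idx_header <- function(con) {
  magic <- readBin(con, "integer", n = 1L, size = 4L, endian = "big")
  n_dim <- bitwAnd(magic, 0xFFL)
  dims <- readBin(con, "integer", n = n_dim, size = 4L, endian = "big")
  list(magic = magic, dims = dims)
}

#' Read an IDX image/label file pair
#'
#' Reads the big-endian IDX container used by MNIST: a magic number
#' (0x00000803 for uint8 image tensors, 0x00000801 for uint8 label vectors),
#' 32-bit dimension sizes, then raw uint8 data. Pixel bytes are scaled to
#' \[0, 1\] by division by 255. No pixel filtering is applied.
#'
#' @param images_path path to the IDX image file.
#' @param labels_path path to the IDX label file.
#' @return an [snn_dataset].
#' @export
read_idx <- function(images_path, labels_path) {
  for (p in c(images_path, labels_path)) {
    if (!file.exists(p)) stop("file not found: ", p)
  }
  icon <- file(images_path, "rb"); on.exit(close(icon), add = TRUE)
  ih <- read_idx_header(icon)
  if (ih$magic != idx_magic_images) {
    stop(sprintf("bad image magic number 0x%08x (expected 0x%08x)",
                 ih$magic, idx_magic_images))
  }
  n <- ih$dims[1]; rows <- ih$dims[2]; cols <- ih$dims[3]
  px <- readBin(icon, "integer", n = n * rows * cols, size = 1L, signed = FALSE)
  if (length(px) != n * rows * cols) stop("truncated image data in ", images_path)

  lcon <- file(labels_path, "rb"); on.exit(close(lcon), add = TRUE)
  lh <- read_idx_header(lcon)
  if (lh$magic != idx_magic_labels) {
    stop(sprintf("bad label magic number 0x%08x (expected 0x%08x)",
                 lh$magic, idx_magic_labels))
  }
  labels <- readBin(lcon, "integer", n = lh$dims[1], size = 1L, signed = FALSE)
  if (length(labels) != lh$dims[1]) stop("truncated label data in ", labels_path)
  if (lh$dims[1] != n) {
    stop("image count (", n, ") does not match label count (", lh$dims[1], ")")
  }
  # row-major pixel order within each image, one sample per matrix row
  images <- matrix(px / 255, nrow = n, ncol = rows * cols, byrow = TRUE)
  snn_dataset(images, labels, pixel_shape = c(rows, cols))
}

#' Write a dataset back to IDX image and label files
#'
#' Inverse of [read_idx] for unfiltered, bias-free datasets: intensities are
#' rescaled to uint8 (`round(x * 255)`) and written with big-endian headers,
#' so `write_idx(read_idx(...))` reproduces the original byte streams.
#'
#' @param ds an [snn_dataset] with neither filtering nor bias applied.
#' @param images_path,labels_path output paths.
#' @return `invisible(NULL)`.
#' @export
write_idx <- function(ds, images_path, labels_path) {
  if (ds$has_bias) stop("cannot write a bias-augmented dataset to IDX")
  if (ncol(ds$images) != prod(ds$pixel_shape)) {
    stop("cannot write a pixel-filtered dataset to IDX")
  }
  n <- nrow(ds$images)
  icon <- file(images_path, "wb"); on.exit(close(icon), add = TRUE)
  writeBin(c(idx_magic_images, n, ds$pixel_shape[1], ds$pixel_shape[2]),
           icon, size = 4L, endian = "big")
  bytes <- as.integer(round(t(ds$images) * 255))
  writeBin(as.raw(bytes), icon)
  lcon <- file(labels_path, "wb"); on.exit(close(lcon), add = TRUE)
  writeBin(c(idx_magic_labels, n), lcon, size = 4L, endian = "big")
  writeBin(as.raw(ds$labels), lcon)
  invisible(NULL)
}

#' Remove background pixels that are zero in most training samples
#'
#' Drops every pixel position whose value is exactly 0 in at least
#' `zero_fraction_threshold` of the samples (default 95%). The retained index
#' must be computed on the training split only and then re-applied to any
#' other split with [apply_pixel_filter] so input dimensions agree.
#'
#' @param ds an [snn_dataset] without bias.
#' @param zero_fraction_threshold proportion in (0, 1\]; a pixel is background
#'   when its zero fraction is `>=` this value.
#' @return the filtered dataset; its `retained_pixel_index` records the kept
#'   original pixel positions for reuse on other splits.
#' @export
remove_background_pixels <- function(ds, zero_fraction_threshold = 0.95) {
  if (ds$has_bias) stop("filter pixels before appending the bias input")
  if (zero_fraction_threshold <= 0 || zero_fraction_threshold > 1) {
    stop("zero_fraction_threshold must lie in (0, 1]")
  }
  zero_frac <- colMeans(ds$images == 0)
  keep <- which(zero_frac < zero_fraction_threshold)
  if (length(keep) == 0) stop("all pixels classified as background; degenerate dataset")
  snn_dataset(ds$images[, keep, drop = FALSE], ds$labels, ds$pixel_shape,
              n_classes = ds$n_classes,
              retained_pixel_index = ds$retained_pixel_index[keep])
}

#' Apply a previously computed pixel filter to another split
#'
#' @param ds an unfiltered, bias-free [snn_dataset] (e.g. a test split).
#' @param retained_pixel_index the index returned on the training split.
#' @return the dataset restricted to the retained pixels.
#' @export
apply_pixel_filter <- function(ds, retained_pixel_index) {
  if (ds$has_bias) stop("filter pixels before appending the bias input")
  if (any(retained_pixel_index < 1 | retained_pixel_index > ncol(ds$images))) {
    stop("retained_pixel_index out of range for this dataset")
  }
  snn_dataset(ds$images[, retained_pixel_index, drop = FALSE], ds$labels,
              ds$pixel_shape, n_classes = ds$n_classes,
              retained_pixel_index = ds$retained_pixel_index[retained_pixel_index])
}

#' Append the constant-1 bias input
#'
#' Adds a trailing input with value 1 to every sample. The bias behaves like
#' any other input neuron: it is Poisson-encoded at the maximum rate and its
#' weight column plays the role of the per-neuron bias term in the membrane
#' potential.
#'
#' @param ds an [snn_dataset] without bias.
#' @return the augmented dataset with `has_bias = TRUE`.
#' @export
append_bias <- function(ds) {
  if (ds$has_bias) stop("bias input already appended")
  if (ncol(ds$images) == 0) stop("dataset has no pixel columns")
  snn_dataset(cbind(ds$images, 1), ds$labels, ds$pixel_shape,
              n_classes = ds$n_classes,
              retained_pixel_index = ds$retained_pixel_index,
              has_bias = TRUE)
}

#' Deterministic class-prototype masks on a pixel grid
#'
#' Class `c` occupies a horizontal band of rows (disjoint supports across
#' classes), inset by one column on each side so every class leaves clear
#' background.
#'
#' @param n_classes number of classes.
#' @param grid `c(rows, cols)`.
#' @return logical matrix, `n_classes` x `prod(grid)`, `TRUE` on foreground.
#' @keywords internal
prototype_masks <- function(n_classes, grid) {
  rows <- grid[1]; cols <- grid[2]
  band <- rows %/% n_classes
  if (band < 1 || cols < 3) {
    stop("grid ", rows, "x", cols, " too small for ", n_classes, " prototypes")
  }
  masks <- matrix(FALSE, n_classes, rows * cols)
  for (cl in seq_len(n_classes)) {
    r0 <- (cl - 1L) * band + 1L
    # leave the last row of each band blank so neighbouring bands never touch
    band_rows <- r0:(r0 + max(band - 2L, 0L))
    # row-major flattening: pixel (r, c) -> (r - 1) * cols + c
    for (r in band_rows) {
      masks[cl, (r - 1L) * cols + 2:(cols - 1L)] <- TRUE
    }
  }
  masks
}

#' Generate a synthetic class-prototype image dataset
#'
#' Emulates sparse-foreground / zero-background grayscale digits: each class
#' has a fixed prototype mask (horizontal bands with disjoint supports); each
#' sample multiplies the mask by i.i.d. per-pixel intensities drawn uniformly
#' from `fg_jitter`, then flips isolated background pixels to a random
#' intensity with probability `salt_prob`. With the default salt probability,
#' background pixels remain exactly 0 in well over 95% of samples, so
#' [remove_background_pixels] is exercised end to end.
#'
#' @param n_classes number of classes (default 4).
#' @param samples_per_class samples generated per class (default 200).
#' @param grid image grid `c(rows, cols)`; the 28 x 28 default matches the
#'   size of real handwritten-digit images, so each sample has a foreground
#'   of roughly 150 pixels and drives the network at realistic input rates.
#' @param fg_jitter interval within (0, 1\] for foreground intensities.
#' @param salt_prob per-background-pixel noise probability (default 0.02).
#' @param seed integer seed; the same seed reproduces the dataset exactly.
#' @return an [snn_dataset] with samples in class-interleaved order.
#' @export
generate_synthetic <- function(n_classes = 4, samples_per_class = 200,
                               grid = c(28, 28), fg_jitter = c(0.5, 1),
                               salt_prob = 0.02, seed = 1) {
  stopifnot(length(fg_jitter) == 2, fg_jitter[1] > 0, fg_jitter[2] <= 1,
            fg_jitter[1] <= fg_jitter[2], salt_prob >= 0, salt_prob < 1)
  masks <- prototype_masks(n_classes, grid)
  n <- n_classes * samples_per_class
  n_pix <- prod(grid)
  labels <- rep(seq_len(n_classes) - 1L, times = samples_per_class)
  images <- matrix(0, n, n_pix)
  old_seed <- get_rng_state()
  on.exit(restore_rng_state(old_seed), add = TRUE)
  set.seed(as.integer(seed))
  for (s in seq_len(n)) {
    m <- masks[labels[s] + 1L, ]
    row <- numeric(n_pix)
    row[m] <- stats::runif(sum(m), fg_jitter[1], fg_jitter[2])
    if (salt_prob > 0) {
      bg <- which(!m)
      salt <- bg[stats::runif(length(bg)) < salt_prob]
      row[salt] <- stats::runif(length(salt))
    }
    images[s, ] <- pmin(row, 1)
  }
  snn_dataset(images, labels, pixel_shape = grid, n_classes = n_classes)
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
}
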