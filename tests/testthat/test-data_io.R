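test_that("IDX files round-trip byte-for-byte and decode correctly", {
  dir <- withr::local_tempdir()
  paths <- write_tiny_idx(dir)
  ds <- read_idx(paths$images, paths$labels)
  expect_equal(nrow(ds$images), 2)
  expect_equal(ds$pixel_shape, c(2L, 2L))
  expect_equal(ds$labels, c(3L, 7L))
  expect_equal(ds$images[1, ], c(0, 51, 102, 255) / 255)

  # writer(reader(x)) reproduces the original byte streams
  out <- file.path(dir, c("imgs2.idx", "labs2.idx"))
  write_idx(ds, out[1], out[2])
  expect_identical(readBin(out[1], "raw", 1e4), readBin(paths$images, "raw", 1e4))
  expect_identical(readBin(out[2], "raw", 1e4), readBin(paths$labels, "raw", 1e4))
})

test_that("malformed IDX input is rejected", {
  dir <- withr::local_tempdir()
  paths <- write_tiny_idx(dir)

  # wrong image magic (0x00000802)
  bad <- file.path(dir, "bad.idx")
  bytes <- readBin(paths$images, "raw", 1e4)
  bytes[4] <- as.raw(2)
  writeBin(bytes, bad)
  expect_error(read_idx(bad, paths$labels), "magic")

  # label/image count mismatch
  lab3 <- file.path(dir, "lab3.idx")
  con <- file(lab3, "wb")
  writeBin(c(2049L, 3L), con, size = 4L, endian = "big")
  writeBin(as.raw(c(1, 2, 3)), con)
  close(con)
  expect_error(read_idx(paths$images, lab3), "match")

  expect_error(read_idx(file.path(dir, "nope.idx"), paths$labels), "not found")
})

test_that("background filter removes exactly the >=95%-zero pixels", {
  # pixel 1: zero in 3/3 samples (removed); pixel 2: zero in 2/3 (retained);
  # pixel 3: never zero (retained)
  ds <- snn_dataset(matrix(c(0, 0.5, 0.2,
                             0, 0.0, 0.4,
                             0, 0.0, 0.6), nrow = 3, byrow = TRUE),
                    labels = c(0L, 0L, 1L), pixel_shape = c(1, 3))
  f <- remove_background_pixels(ds)
  expect_equal(f$retained_pixel_index, c(2L, 3L))

  # inclusive threshold: zero fraction exactly at the threshold is removed
  ds20 <- snn_dataset(matrix(c(rep(0, 19), 0.5), ncol = 1),
                      labels = rep(0L, 20), pixel_shape = c(1, 1))
  expect_error(remove_background_pixels(ds20, 0.95), "degenerate")
  # one zero fewer than the threshold keeps the pixel
  ds19 <- snn_dataset(matrix(c(rep(0, 18), 0.5, 0.5), ncol = 1),
                      labels = rep(0L, 20), pixel_shape = c(1, 1))
  expect_equal(remove_background_pixels(ds19, 0.95)$retained_pixel_index, 1L)
})

test_that("filter index computed on train applies consistently to test", {
  train <- generate_synthetic(samples_per_class = 20, salt_prob = 0, seed = 1)
  test <- generate_synthetic(samples_per_class = 5, salt_prob = 0, seed = 2)
  tf <- remove_background_pixels(train)
  sf <- apply_pixel_filter(test, tf$retained_pixel_index)
  expect_equal(ncol(sf$images), ncol(tf$images))
  expect_equal(sf$retained_pixel_index, tf$retained_pixel_index)

  # idempotence on a noise-free set: re-filtering removes nothing
  tf2 <- remove_background_pixels(tf)
  expect_identical(tf2$retained_pixel_index, tf$retained_pixel_index)
})

test_that("bias append adds a trailing constant-1 input exactly once", {
  ds <- snn_dataset(matrix(c(0.5, 0), nrow = 1), labels = 0L,
                    pixel_shape = c(1, 2))
  b <- append_bias(ds)
  expect_equal(b$images[1, ], c(0.5, 0, 1))
  expect_true(b$has_bias)
  expect_equal(n_inputs(b), 3)
  expect_error(append_bias(b), "already")
})

test_that("synthetic generator is deterministic with clean backgrounds", {
  a <- generate_synthetic(n_classes = 2, samples_per_class = 10,
                          salt_prob = 0, seed = 99)
  b <- generate_synthetic(n_classes = 2, samples_per_class = 10,
                          salt_prob = 0, seed = 99)
  expect_identical(a, b)

  # with salt_prob = 0 every background pixel is exactly 0 in all samples
  masks <- spikeprune:::prototype_masks(2, c(28, 28))
  bg <- !(masks[1, ] | masks[2, ])
  expect_true(all(a$images[, bg] == 0))
  # and the generated backgrounds satisfy the 95% filter by construction
  f <- remove_background_pixels(generate_synthetic(samples_per_class = 50,
                                                   seed = 3))
  expect_true(all(colMeans(f$images == 0) < 0.95))

  expect_error(generate_synthetic(n_classes = 5, grid = c(4, 4)), "too small")
})

test_that("classes are more similar within than between", {
  ds <- generate_synthetic(n_classes = 4, samples_per_class = 50, seed = 5)
  cos <- function(x, y) sum(x * y) / sqrt(sum(x^2) * sum(y^2))
  # class prototype estimate: mean image per class
  protos <- lapply(0:3, function(cl) colMeans(ds$images[ds$labels == cl, ]))
  between <- combn(4, 2, function(ij) cos(protos[[ij[1]]], protos[[ij[2]]]))
  within <- sapply(0:3, function(cl) {
    rows <- which(ds$labels == cl)[1:10]
    mean(combn(rows, 2, function(ij) cos(ds$images[ij[1], ], ds$images[ij[2], ])))
  })
  expect_lt(mean(between), mean(within))
})
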