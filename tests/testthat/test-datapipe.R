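test_that("normalization maps the channel means to zero and inverts exactly", {
  px <- array(c(0.485, 0.456, 0.406), dim = c(1, 1, 3, 1))
  expect_equal(as.vector(normalize_images(px)), c(0, 0, 0), tolerance = 1e-12)
  one <- array(1, dim = c(1, 1, 3, 1))
  expect_equal(as.vector(normalize_images(one)),
               c((1 - 0.485) / 0.229, (1 - 0.456) / 0.224, (1 - 0.406) / 0.225),
               tolerance = 1e-12)
  set.seed(30)
  x <- array(runif(8 * 8 * 3 * 2), dim = c(8, 8, 3, 2))
  expect_equal(denormalize_images(normalize_images(x)), x, tolerance = 1e-12)
  # byte input is scaled to [0, 1] first
  b <- array(255L, dim = c(2, 2, 3, 1))
  expect_equal(normalize_images(b), normalize_images(array(1, dim(b))))
  expect_error(normalize_images(array(0, c(2, 2, 4, 1))), "3 channels")
})

test_that("bilinear resize honors identity, shape, constancy", {
  set.seed(31)
  x <- array(runif(28 * 28 * 3 * 2), dim = c(28, 28, 3, 2))
  expect_identical(resize_images(x, 28), x)
  expect_equal(dim(resize_images(x, 224)), c(224, 224, 3, 2))
  k <- array(0.37, dim = c(28, 28, 3, 1))
  expect_equal(resize_images(k, 64), array(0.37, c(64, 64, 3, 1)),
               tolerance = 1e-12)
})

test_that("archives round-trip through the MedMNIST-style reader", {
  set.seed(32)
  ds <- synth_generate(synthetic_spec(num_classes = 3, samples_per_class = 4,
                                      image_size = 8, seed = 7))
  path <- tempfile(fileext = ".npz")
  write_medmnist(list(train = ds, test = ds), path)
  back <- read_medmnist(path, "train")
  expect_identical(dim(back$images), dim(ds$images))
  expect_true(all(back$images == ds$images))
  expect_identical(back$labels, ds$labels)
  # split with its own size
  expect_equal(length(read_medmnist(path, "test")$labels), 12)
  expect_error(read_medmnist(path, "val"), "val_images")
  expect_error(read_medmnist(path, "train", num_classes = 2), "class count")
})

test_that("grayscale arrays are replicated to three channels", {
  ns <- asNamespace("medspectralnet")
  set.seed(33)
  gray <- array(sample(0:255, 5 * 6 * 6, TRUE), dim = c(5, 6, 6))
  labs <- matrix(0:4, ncol = 1)           # stored as an N x 1 column
  path <- tempfile(fileext = ".npz")
  ns$write_zip(list("train_images.npy" = ns$npy_bytes(gray, "|u1"),
                    "train_labels.npy" = ns$npy_bytes(labs, "<i4")),
               path)
  got <- read_medmnist(path, "train")
  expect_equal(dim(got$images), c(5, 6, 6, 3))
  expect_true(all(got$images[, , , 1] == gray))
  expect_true(all(got$images[, , , 2] == got$images[, , , 3]))
  expect_identical(got$labels, 0:4)       # flattened to length N
})

test_that("the image-folder reader assigns classes by sorted folder order", {
  root <- file.path(tempfile("imgdir"))
  for (cl in c("benign", "malignant")) {
    dir.create(file.path(root, cl), recursive = TRUE)
  }
  set.seed(34)
  img <- array(runif(8 * 8 * 3), dim = c(8, 8, 3))
  png::writePNG(img, file.path(root, "benign", "a.png"))
  png::writePNG(img, file.path(root, "malignant", "b.png"))
  png::writePNG(img[, , 1], file.path(root, "malignant", "c.png"))  # gray
  ds <- read_image_folder(root)
  expect_identical(ds$class_names, c("benign", "malignant"))
  expect_identical(ds$labels, c(0L, 1L, 1L))
  expect_equal(dim(ds$images), c(3, 8, 8, 3))
  writeLines("x", file.path(root, "benign", "d.jpg"))
  expect_error(read_image_folder(root), "JPEG")
})

test_that("the synthetic generator is deterministic, balanced, distinct", {
  sp <- synthetic_spec(num_classes = 4, samples_per_class = 50,
                       image_size = 32, seed = 5)
  a <- synth_generate(sp); b <- synth_generate(sp)
  expect_identical(a$images, b$images)
  expect_identical(a$labels, b$labels)
  expect_equal(dim(a$images), c(200, 32, 32, 3))
  expect_equal(as.vector(table(a$labels)), rep(50, 4))
  lf <- data.frame(cx = c(0.5, 0.5), cy = c(0.5, 0.5), radius = c(0.1, 0.1))
  hf <- data.frame(freq = c(4, 4), theta = c(0, 0))
  expect_error(synthetic_spec(2, low_freq = lf, high_freq = hf), "distinct")
})

test_that("frequency content separates classes that differ only in grating", {
  lf <- data.frame(cx = c(0.5, 0.5), cy = c(0.5, 0.5), radius = c(0.15, 0.15))
  hf <- data.frame(freq = c(4, 10), theta = c(pi / 4, pi / 4))
  sp <- synthetic_spec(num_classes = 2, samples_per_class = 10,
                       image_size = 32, low_freq = lf, high_freq = hf,
                       noise_sigma = 0, seed = 9)
  ds <- synth_generate(sp)
  feat <- vapply(seq_len(20), function(i) {
    g <- ds$images[i, , , 1] / 255
    oracle_band_power(g, 10) - oracle_band_power(g, 4)
  }, numeric(1))
  # band-power feature separates the two gratings perfectly
  expect_true(max(feat[ds$labels == 0]) < min(feat[ds$labels == 1]))
})
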