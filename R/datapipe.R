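# ---- dataset readers, normalization, synthetic generator --------------------

#' ImageNet channel statistics used for normalization
#' @format numeric length-3 vectors (R, G, B).
#' @name imagenet_stats
NULL
IMAGENET_MEAN <- c(0.485, 0.456, 0.406)
IMAGENET_STD <- c(0.229, 0.224, 0.225)

#' Channel-wise normalization to ImageNet statistics
#'
#' Raw byte values are first scaled to [0, 1], then each channel c is mapped
#' to (v - mean_c) / std_c with mean (0.485, 0.456, 0.406) and standard
#' deviation (0.229, 0.224, 0.225).
#'
#' @param images array (H, W, 3, N) or (H, W, 3); uint8 in 0..255 or floats
#'   already in [0, 1].
#' @return normalized array of the same shape.
#' @export
normalize_images <- function(images) {
  single <- length(dim(images)) == 3L
  if (single) dim(images) <- c(dim(images), 1L)
  d <- dim(images)
  if (d[3] != 3L) stop("normalize: expected 3 channels, got ", d[3])
  x <- images
  if (is.integer(x) || max(x) > 1.5) x <- x / 255
  for (c in 1:3) {
    x[, , c, ] <- (x[, , c, ] - IMAGENET_MEAN[c]) / IMAGENET_STD[c]
  }
  if (single) dim(x) <- d[1:3]
  x
}

#' Invert [normalize_images()]
#'
#' @param images normalized array (H, W, 3, N) or (H, W, 3).
#' @return array of [0, 1] intensities.
#' @export
denormalize_images <- function(images) {
  single <- length(dim(images)) == 3L
  if (single) dim(images) <- c(dim(images), 1L)
  d <- dim(images)
  if (d[3] != 3L) stop("denormalize: expected 3 channels, got ", d[3])
  x <- images
  for (c in 1:3) {
    x[, , c, ] <- x[, , c, ] * IMAGENET_STD[c] + IMAGENET_MEAN[c]
  }
  if (single) dim(x) <- d[1:3]
  x
}

# bilinear resampling with half-pixel centers; exact identity when sizes match
resize_bilinear <- function(x, th, tw) {
  d <- dim(x)
  H <- d[1]; W <- d[2]
  if (H == th && W == tw) return(x)
  src_h <- (seq_len(th) - 0.5) * (H / th) - 0.5
  src_w <- (seq_len(tw) - 0.5) * (W / tw) - 0.5
  i0 <- pmax(pmin(floor(src_h), H - 1), 0)
  fh <- pmax(pmin(src_h - i0, 1), 0)
  i1 <- pmin(i0 + 1, H - 1)
  j0 <- pmax(pmin(floor(src_w), W - 1), 0)
  fw <- pmax(pmin(src_w - j0, 1), 0)
  j1 <- pmin(j0 + 1, W - 1)
  xa <- x[i0 + 1, , , , drop = FALSE] * (1 - fh) +
    x[i1 + 1, , , , drop = FALSE] * fh
  fw_e <- rep(fw, each = th)
  xa[, j0 + 1, , , drop = FALSE] * (1 - fw_e) +
    xa[, j1 + 1, , , drop = FALSE] * fw_e
}

#' Bilinear resize of an image batch
#'
#' @param images array (H, W, C, N) or (H, W, C).
#' @param target_size target square extent (or length-2 `c(H, W)`).
#' @return resized array.
#' @export
resize_images <- function(images, target_size) {
  single <- length(dim(images)) == 3L
  if (single) dim(images) <- c(dim(images), 1L)
  ts <- rep(as.integer(target_size), length.out = 2L)
  out <- resize_bilinear(images, ts[1], ts[2])
  if (single) dim(out) <- dim(out)[1:3]
  out
}

#' Read a MedMNIST-style compressed array archive
#'
#' The archive is a zip of numpy arrays with keys `<split>_images` (N x H x W
#' or N x H x W x 3, uint8) and `<split>_labels` (N or N x 1 integers).
#' Grayscale images are replicated to three channels.
#'
#' @param path archive path (.npz).
#' @param split one of `"train"`, `"val"`, `"test"`.
#' @param num_classes optional declared class count; labels outside
#'   `[0, num_classes)` raise an error.
#' @return list with `images` (N x H x W x 3 integer array, 0..255) and
#'   `labels` (integer vector, 0-based).
#' @export
read_medmnist <- function(path, split = c("train", "val", "test"),
                          num_classes = NULL) {
  split <- match.arg(split)
  if (!file.exists(path)) stop("archive not found: ", path)
  tmp <- tempfile("npz")
  dir.create(tmp)
  on.exit(unlink(tmp, recursive = TRUE))
  files <- utils::unzip(path, exdir = tmp)
  want <- paste0(split, c("_images", "_labels"))
  got <- sub("\\.npy$", "", basename(files))
  for (k in want) {
    if (!k %in% got) stop("archive is missing key '", k, "'")
  }
  images <- read_npy(files[match(paste0(want[1], ".npy"), basename(files))])
  labels <- read_npy(files[match(paste0(want[2], ".npy"), basename(files))])
  labels <- as.integer(round(as.vector(labels)))
  d <- dim(images)
  if (length(d) == 3L) {
    images <- array(rep(images, 3L), dim = c(d, 3L))
  } else if (length(d) != 4L || d[4] != 3L) {
    stop("unsupported image array shape: ", paste(d, collapse = "x"))
  }
  if (length(labels) != dim(images)[1]) stop("label/image count mismatch")
  if (!is.null(num_classes) && any(labels < 0L | labels >= num_classes)) {
    stop("label outside declared class count [0, ", num_classes, ")")
  }
  list(images = images, labels = labels)
}

#' Write datasets to a MedMNIST-style archive
#'
#' @param splits named list; each of `train`, `val`, `test` (any subset) is a
#'   list with `images` (N x H x W x 3 or N x H x W, 0..255) and `labels`.
#' @param path output .npz path.
#' @return the path, invisibly.
#' @export
write_medmnist <- function(splits, path) {
  entries <- list()
  for (nm in names(splits)) {
    s <- splits[[nm]]
    entries[[paste0(nm, "_images.npy")]] <- npy_bytes(s$images, "|u1")
    entries[[paste0(nm, "_labels.npy")]] <-
      npy_bytes(matrix(as.integer(s$labels), ncol = 1L), "<i4")
  }
  write_zip(entries, path)
  invisible(path)
}

#' Read an image-folder dataset
#'
#' Layout: `root/<class_name>/*.png`; the class index is the 0-based position
#' of the class folder in sorted order. Only PNG images are supported.
#'
#' @param root dataset root directory.
#' @return list with `images` (N x H x W x 3, 0..255), `labels`,
#'   `class_names`.
#' @export
read_image_folder <- function(root) {
  if (!dir.exists(root)) stop("dataset root not found: ", root)
  classes <- sort(list.dirs(root, recursive = FALSE, full.names = FALSE))
  if (length(classes) == 0L) stop("no class subdirectories under ", root)
  imgs <- list(); labels <- integer(0)
  for (ci in seq_along(classes)) {
    fs <- sort(list.files(file.path(root, classes[ci]), full.names = TRUE))
    for (f in fs) {
      if (grepl("\\.(jpe?g)$", f, ignore.case = TRUE)) {
        stop("JPEG is not supported by this reader; convert to PNG: ", f)
      }
      if (!grepl("\\.png$", f, ignore.case = TRUE)) next
      p <- png::readPNG(f)
      if (length(dim(p)) == 2L) p <- array(rep(p, 3L), dim = c(dim(p), 3L))
      p <- p[, , 1:3, drop = FALSE]
      imgs[[length(imgs) + 1L]] <- round(p * 255)
      labels <- c(labels, ci - 1L)
    }
  }
  if (length(imgs) == 0L) stop("no PNG images found under ", root)
  d <- dim(imgs[[1]])
  images <- array(0L, dim = c(length(imgs), d[1], d[2], 3L))
  for (i in seq_along(imgs)) images[i, , , ] <- imgs[[i]]
  list(images = images, labels = labels, class_names = classes)
}

#' Convert a reader dataset to the internal batch layout
#'
#' Reorders N x H x W x 3 images to (H, W, 3, N), scales bytes to [0, 1], and
#' optionally resizes. Normalization is left to the trainer (augmentation
#' operates on raw intensities).
#'
#' @param dataset list with `images` (N x H x W x 3) and `labels`.
#' @param input_size optional target extent.
#' @return list with `x` (H, W, 3, N array in [0, 1]) and `y` (labels).
#' @export
as_image_batch <- function(dataset, input_size = NULL) {
  x <- aperm(dataset$images, c(2, 3, 4, 1)) / 255
  if (!is.null(input_size)) x <- resize_images(x, input_size)
  list(x = x, y = as.integer(dataset$labels))
}

#' Specification of the synthetic two-frequency dataset
#'
#' Each class is defined by a low-frequency radial blob (class-specific
#' position and scale) plus a high-frequency sinusoidal grating
#' (class-specific spatial frequency and orientation), so that class evidence
#' is split across frequency bands and both SpectralFlow streams carry
#' signal.
#'
#' @param num_classes number of classes.
#' @param samples_per_class images per class.
#' @param image_size square image extent in pixels.
#' @param low_freq data frame with per-class columns `cx`, `cy` (relative
#'   blob center), `radius` (relative scale); defaults place the classes on a
#'   circle with increasing radii.
#' @param high_freq data frame with per-class columns `freq`
#'   (cycles/image) and `theta` (orientation, radians); defaults spread both.
#' @param noise_sigma additive Gaussian pixel noise sd (intensity units).
#' @param seed integer; fully determines the dataset.
#' @return object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(num_classes = 4L, samples_per_class = 50L,
                           image_size = 32L, low_freq = NULL,
                           high_freq = NULL, noise_sigma = 0.05, seed = 1L) {
  K <- as.integer(num_classes)
  if (is.null(low_freq)) {
    ang <- 2 * pi * (seq_len(K) - 1) / K + pi / 4
    low_freq <- data.frame(cx = 0.5 + 0.22 * cos(ang),
                           cy = 0.5 + 0.22 * sin(ang),
                           radius = 0.10 + 0.03 * (seq_len(K) - 1))
  }
  if (is.null(high_freq)) {
    high_freq <- data.frame(freq = 4 + 3 * (seq_len(K) - 1),
                            theta = pi * (seq_len(K) - 1) / K)
  }
  key <- paste(low_freq$cx, low_freq$cy, low_freq$radius,
               high_freq$freq, high_freq$theta)
  if (anyDuplicated(key)) stop("class-conditional parameters must be distinct")
  structure(list(num_classes = K,
                 samples_per_class = as.integer(samples_per_class),
                 image_size = as.integer(image_size),
                 low_freq = low_freq, high_freq = high_freq,
                 noise_sigma = noise_sigma, seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate the synthetic frequency-structured dataset
#'
#' @param spec a [synthetic_spec()].
#' @return list with `images` (N x H x W x 3 integer, 0..255), `labels`
#'   (0-based, balanced), and `spec`. Byte-identical across runs for equal
#'   seeds.
#' @export
synth_generate <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(spec$seed)
  S <- spec$image_size
  K <- spec$num_classes
  n <- spec$samples_per_class
  N <- K * n
  xg <- (seq_len(S) - 0.5) / S
  gx <- matrix(xg, S, S); gy <- matrix(xg, S, S, byrow = TRUE)
  images <- array(0L, dim = c(N, S, S, 3L))
  labels <- integer(N)
  idx <- 1L
  for (k in seq_len(K)) {
    lf <- spec$low_freq[k, ]; hf <- spec$high_freq[k, ]
    for (s in seq_len(n)) {
      jx <- rnorm(1, sd = 0.02); jy <- rnorm(1, sd = 0.02)
      phase <- runif(1, 0, 2 * pi)
      d2 <- (gx - (lf$cx + jx))^2 + (gy - (lf$cy + jy))^2
      blob <- 0.35 * exp(-d2 / (2 * lf$radius^2))
      grat <- 0.15 * sin(2 * pi * hf$freq * (gx * cos(hf$theta) +
                                               gy * sin(hf$theta)) + phase)
      img <- 0.4 + blob + grat
      if (spec$noise_sigma > 0) {
        img <- img + rnorm(S * S, sd = spec$noise_sigma)
      }
      byte <- as.integer(round(pmin(pmax(img, 0), 1) * 255))
      images[idx, , , ] <- rep(byte, 3L)
      labels[idx] <- k - 1L
      idx <- idx + 1L
    }
  }
  perm <- sample.int(N)
  list(images = images[perm, , , , drop = FALSE], labels = labels[perm],
       spec = spec)
}
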