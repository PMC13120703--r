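# ---- training-time augmentation --------------------------------------------
# Applied to single raw-intensity images ([0, 1], shape H x W x 3) on the
# training split only; evaluation uses deterministic resize + normalize.

#' Augmentation configuration
#'
#' Two presets match the ablation arms: `mode = "normal"` enables only random
#' horizontal flipping; `mode = "cutmix"` enables the full stack (flip,
#' affine with translation up to 10 percent, perspective distortion, color
#' jitter, Gaussian blur, random erasing) plus batch-level CutMix with
#' probability 0.5. Any field can be overridden.
#'
#' @param mode `"normal"` or `"cutmix"`.
#' @param hflip_prob horizontal flip probability.
#' @param translate_frac maximum translation as a fraction of the extent.
#' @param rotate_deg maximum absolute rotation (degrees) of the random affine.
#' @param scale_range multiplicative scale range of the random affine.
#' @param perspective_prob probability of applying perspective distortion.
#' @param distortion_scale perspective corner displacement fraction.
#' @param jitter list with `brightness`, `contrast`, `saturation`, `hue`
#'   half-ranges.
#' @param blur_kernel Gaussian blur kernel size (odd).
#' @param blur_sigma range the blur sigma is drawn from.
#' @param blur_prob probability of applying the blur.
#' @param erase_prob probability of random erasing.
#' @param erase_area erased-area fraction range.
#' @param erase_aspect erased-box aspect-ratio range.
#' @param cutmix_prob probability of CutMix per batch (cutmix mode).
#' @param cutmix_alpha Beta(alpha, alpha) parameter for the mixing weight.
#' @return object of class `augmentation_config`.
#' @export
augmentation_config <- function(mode = c("normal", "cutmix"),
                                hflip_prob = 0.5, translate_frac = 0.10,
                                rotate_deg = 10, scale_range = c(0.9, 1.1),
                                perspective_prob = 0.5, distortion_scale = 0.1,
                                jitter = list(brightness = 0.2, contrast = 0.2,
                                              saturation = 0.2, hue = 0.02),
                                blur_kernel = 3L, blur_sigma = c(0.1, 1.0),
                                blur_prob = 0.5,
                                erase_prob = 0.5, erase_area = c(0.02, 0.2),
                                erase_aspect = c(0.3, 3.3),
                                cutmix_prob = 0.5, cutmix_alpha = 1.0) {
  mode <- match.arg(mode)
  cfg <- list(mode = mode, hflip_prob = hflip_prob,
              translate_frac = translate_frac, rotate_deg = rotate_deg,
              scale_range = scale_range, perspective_prob = perspective_prob,
              distortion_scale = distortion_scale, jitter = jitter,
              blur_kernel = as.integer(blur_kernel), blur_sigma = blur_sigma,
              blur_prob = blur_prob,
              erase_prob = erase_prob, erase_area = erase_area,
              erase_aspect = erase_aspect, cutmix_prob = cutmix_prob,
              cutmix_alpha = cutmix_alpha)
  if (mode == "normal") {
    cfg$translate_frac <- 0; cfg$rotate_deg <- 0; cfg$scale_range <- c(1, 1)
    cfg$perspective_prob <- 0
    cfg$jitter <- list(brightness = 0, contrast = 0, saturation = 0, hue = 0)
    cfg$blur_prob <- 0; cfg$erase_prob <- 0; cfg$cutmix_prob <- 0
  }
  probs <- c(cfg$hflip_prob, cfg$perspective_prob, cfg$blur_prob,
             cfg$erase_prob, cfg$cutmix_prob)
  if (any(probs < 0 | probs > 1)) stop("probabilities must be in [0, 1]")
  if (cfg$translate_frac < 0 || cfg$translate_frac > 1) {
    stop("translate_frac must be in [0, 1]")
  }
  structure(cfg, class = "augmentation_config")
}

# inverse-warp bilinear sampling under a homography (output -> input coords),
# edge-clamped
warp_homography <- function(img, Hmat) {
  d <- dim(img)
  H <- d[1]; W <- d[2]
  ys <- matrix(seq_len(H), H, W)        # row coordinate
  xs <- matrix(seq_len(W), H, W, byrow = TRUE)
  den <- Hmat[3, 1] * xs + Hmat[3, 2] * ys + Hmat[3, 3]
  sx <- (Hmat[1, 1] * xs + Hmat[1, 2] * ys + Hmat[1, 3]) / den
  sy <- (Hmat[2, 1] * xs + Hmat[2, 2] * ys + Hmat[2, 3]) / den
  x0 <- pmax(pmin(floor(sx), W - 1), 1); fx <- pmax(pmin(sx - x0, 1), 0)
  y0 <- pmax(pmin(floor(sy), H - 1), 1); fy <- pmax(pmin(sy - y0, 1), 0)
  out <- img
  for (c in seq_len(d[3])) {
    ch <- img[, , c]
    v00 <- ch[cbind(c(y0), c(x0))]; v01 <- ch[cbind(c(y0), c(x0 + 1))]
    v10 <- ch[cbind(c(y0 + 1), c(x0))]; v11 <- ch[cbind(c(y0 + 1), c(x0 + 1))]
    v <- (1 - c(fy)) * ((1 - c(fx)) * v00 + c(fx) * v01) +
      c(fy) * ((1 - c(fx)) * v10 + c(fx) * v11)
    out[, , c] <- matrix(v, H, W)
  }
  out
}

# homography (3x3, output->input) from 4 point correspondences
homography_from_points <- function(src, dst) {
  A <- matrix(0, 8, 8); b <- numeric(8)
  for (i in 1:4) {
    x <- dst[i, 1]; y <- dst[i, 2]; u <- src[i, 1]; v <- src[i, 2]
    A[2 * i - 1, ] <- c(x, y, 1, 0, 0, 0, -x * u, -y * u); b[2 * i - 1] <- u
    A[2 * i, ] <- c(0, 0, 0, x, y, 1, -x * v, -y * v); b[2 * i] <- v
  }
  h <- solve(A, b)
  matrix(c(h, 1), 3, 3, byrow = TRUE)
}

gaussian_blur <- function(img, k, sigma) {
  half <- (k - 1L) %/% 2L
  kx <- exp(-((-half:half)^2) / (2 * sigma^2))
  kx <- kx / sum(kx)
  d <- dim(img)
  # replicate-pad then separable filter
  ih <- c(rep(1L, half), seq_len(d[1]), rep(d[1], half))
  iw <- c(rep(1L, half), seq_len(d[2]), rep(d[2], half))
  p <- img[ih, iw, , drop = FALSE]
  out <- array(0, dim = c(d[1], dim(p)[2], d[3]))
  for (o in seq_len(k)) out <- out + kx[o] * p[(o - 1) + seq_len(d[1]), , , drop = FALSE]
  out2 <- array(0, dim = d)
  for (o in seq_len(k)) out2 <- out2 + kx[o] * out[, (o - 1) + seq_len(d[2]), , drop = FALSE]
  out2
}

clip01 <- function(x) pmin(pmax(x, 0), 1)

#' Randomly augment a single training image
#'
#' Applies, in order: horizontal flip, random affine (translation up to the
#' configured fraction, small rotation/scale), random perspective, color
#' jitter, Gaussian blur, random erasing. Fully determined by the R RNG
#' state.
#'
#' @param image array (H, W, 3) of raw [0, 1] intensities.
#' @param cfg an [augmentation_config()].
#' @return augmented image, same shape and range.
#' @export
augment <- function(image, cfg) {
  stopifnot(inherits(cfg, "augmentation_config"))
  d <- dim(image)
  H <- d[1]; W <- d[2]
  img <- image
  if (runif(1) < cfg$hflip_prob) img <- img[, rev(seq_len(W)), , drop = FALSE]
  # affine: rotation/scale about the center plus translation (inverse map)
  ang <- runif(1, -cfg$rotate_deg, cfg$rotate_deg) * pi / 180
  sc <- runif(1, cfg$scale_range[1], cfg$scale_range[2])
  tx <- runif(1, -cfg$translate_frac, cfg$translate_frac) * W
  ty <- runif(1, -cfg$translate_frac, cfg$translate_frac) * H
  if (ang != 0 || sc != 1 || tx != 0 || ty != 0) {
    cxy <- c((W + 1) / 2, (H + 1) / 2)
    R <- matrix(c(cos(ang), -sin(ang), sin(ang), cos(ang)), 2, 2,
                byrow = TRUE) / sc
    Hm <- diag(3)
    Hm[1:2, 1:2] <- R
    Hm[1:2, 3] <- cxy - R %*% (cxy + c(tx, ty))
    img <- warp_homography(img, Hm)
  }
  if (runif(1) < cfg$perspective_prob && cfg$distortion_scale > 0) {
    ds <- cfg$distortion_scale
    corners <- matrix(c(1, 1, W, 1, W, H, 1, H), 4, 2, byrow = TRUE)
    jit <- cbind(runif(4, 0, ds * W / 2), runif(4, 0, ds * H / 2))
    sgn <- matrix(c(1, 1, -1, 1, -1, -1, 1, -1), 4, 2, byrow = TRUE)
    dst <- corners + sgn * jit
    Hm <- homography_from_points(corners, dst)
    img <- warp_homography(img, Hm)
  }
  j <- cfg$jitter
  if (j$brightness > 0) img <- clip01(img * runif(1, 1 - j$brightness, 1 + j$brightness))
  if (j$contrast > 0) {
    m <- mean(0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3])
    img <- clip01((img - m) * runif(1, 1 - j$contrast, 1 + j$contrast) + m)
  }
  if (j$saturation > 0) {
    gray <- 0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
    f <- runif(1, 1 - j$saturation, 1 + j$saturation)
    for (c in 1:3) img[, , c] <- clip01(gray + (img[, , c] - gray) * f)
  }
  if (j$hue > 0) {
    # rotation about the achromatic axis (small-angle hue shift)
    th <- runif(1, -j$hue, j$hue) * 2 * pi
    u <- cos(th); w <- sin(th)
    M <- matrix(c(
      0.299 + 0.701 * u + 0.168 * w, 0.587 - 0.587 * u + 0.330 * w, 0.114 - 0.114 * u - 0.497 * w,
      0.299 - 0.299 * u - 0.328 * w, 0.587 + 0.413 * u + 0.035 * w, 0.114 - 0.114 * u + 0.292 * w,
      0.299 - 0.300 * u + 1.250 * w, 0.587 - 0.588 * u - 1.050 * w, 0.114 + 0.886 * u - 0.203 * w
    ), 3, 3, byrow = TRUE)
    flat <- matrix(img, ncol = 3)
    img <- clip01(array(flat %*% t(M), dim = d))
  }
  if (runif(1) < cfg$blur_prob) {
    img <- gaussian_blur(img, cfg$blur_kernel,
                         runif(1, cfg$blur_sigma[1], cfg$blur_sigma[2]))
  }
  if (runif(1) < cfg$erase_prob) {
    area <- runif(1, cfg$erase_area[1], cfg$erase_area[2]) * H * W
    ar <- exp(runif(1, log(cfg$erase_aspect[1]), log(cfg$erase_aspect[2])))
    eh <- min(H, max(1L, as.integer(round(sqrt(area * ar)))))
    ew <- min(W, max(1L, as.integer(round(sqrt(area / ar)))))
    y0 <- sample.int(H - eh + 1L, 1L)
    x0 <- sample.int(W - ew + 1L, 1L)
    img[y0:(y0 + eh - 1L), x0:(x0 + ew - 1L), ] <-
      runif(eh * ew * d[3])
  }
  img
}

#' CutMix batch augmentation
#'
#' With probability `cutmix_prob` draws a mixing weight lam from
#' Beta(alpha, alpha), cuts a rectangle of area (1 - lam) * H * W centered
#' uniformly (clipped at the borders), pastes that region from a shuffled
#' partner image, and recomputes lam as one minus the clipped box-area
#' fraction. Otherwise (or for a batch of one) the batch is returned
#' unchanged with lam = 1.
#'
#' @param images array (H, W, C, N).
#' @param labels integer vector length N.
#' @param cfg an [augmentation_config()].
#' @param force_lam optional fixed lam (diagnostics); disables the
#'   probability gate.
#' @return list with `images`, `labels_a`, `labels_b`, `lam` (post-clip area
#'   fraction used for label mixing) and `lam_raw` (the pre-clip Beta draw,
#'   NA when the batch was returned unchanged).
#' @export
cutmix <- function(images, labels, cfg, force_lam = NULL) {
  d <- dim(images)
  N <- d[4]
  unchanged <- list(images = images, labels_a = labels, labels_b = labels,
                    lam = 1, lam_raw = NA_real_)
  if (N < 2L) return(unchanged)
  if (is.null(force_lam)) {
    if (runif(1) >= cfg$cutmix_prob) return(unchanged)
    lam <- rbeta(1, cfg$cutmix_alpha, cfg$cutmix_alpha)
  } else {
    lam <- force_lam
  }
  lam_raw <- lam
  H <- d[1]; W <- d[2]
  cut_h <- as.integer(round(H * sqrt(1 - lam)))
  cut_w <- as.integer(round(W * sqrt(1 - lam)))
  cy <- sample.int(H, 1L); cx <- sample.int(W, 1L)
  y1 <- max(1L, cy - cut_h %/% 2L); y2 <- min(H, y1 + cut_h - 1L)
  x1 <- max(1L, cx - cut_w %/% 2L); x2 <- min(W, x1 + cut_w - 1L)
  perm <- sample.int(N)
  if (cut_h > 0L && cut_w > 0L) {
    images[y1:y2, x1:x2, , ] <- images[y1:y2, x1:x2, , perm, drop = FALSE]
    lam <- 1 - (y2 - y1 + 1) * (x2 - x1 + 1) / (H * W)
  } else {
    lam <- 1
  }
  list(images = images, labels_a = labels, labels_b = labels[perm],
       lam = lam, lam_raw = lam_raw)
}
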