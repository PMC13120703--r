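# ---- Grad-CAM on registered internal sites ----------------------------------

GRADCAM_SITES <- c("contextgate.spatial", "spectralflow2.output")

# core routine over an arbitrary forward function:
#   forward(tape, record) -> logits variable (K x 1)
# The record environment must expose the requested activation variable.
gradcam_core <- function(forward, target_layer, class_index, out_hw) {
  tape <- new_tape()
  record <- new.env(parent = emptyenv())
  logits <- forward(tape, record)
  if (!exists(target_layer, envir = record, inherits = FALSE)) {
    stop("unknown layer '", target_layer, "'; registered sites: ",
         paste(ls(record), collapse = ", "))
  }
  act <- record[[target_layer]]
  K <- nrow(val(logits))
  if (class_index < 0L || class_index >= K) {
    stop("class_index must be in [0, ", K, ")")
  }
  seed <- matrix(0, K, ncol(val(logits)))
  seed[class_index + 1L, ] <- 1
  backward(tape, logits, seed = seed)
  A <- val(act)
  G <- act$g
  d <- dim(A)
  if (is.null(G)) G <- array(0, dim = d)
  hw <- d[1] * d[2]
  wts <- colMeans(matrix(G, hw, d[3]))          # spatial mean of gradients
  raw <- matrix(matrix(A, hw, d[3]) %*% wts, d[1], d[2])
  raw <- pmax(raw, 0)
  low <- max(raw) < 1e-8
  up <- resize_bilinear(array(raw, dim = c(d[1], d[2], 1, 1)),
                        out_hw[1], out_hw[2])[, , 1, 1]
  if (low) {
    vals <- matrix(0, out_hw[1], out_hw[2])
  } else {
    rng <- range(up)
    vals <- if (rng[2] > rng[1]) (up - rng[1]) / (rng[2] - rng[1]) else up / rng[2]
  }
  structure(list(values = vals, target_layer = target_layer,
                 class_index = as.integer(class_index),
                 low_evidence = low),
            class = "msn_heatmap")
}

#' Grad-CAM heatmap for a registered internal layer
#'
#' Captures the forward activation A at the named site and the gradient of
#' the chosen class logit with respect to A; channel weights are the spatial
#' means of the gradients, the map is ReLU(sum_c w_c A_c), bilinearly
#' upsampled to the input size and min-max normalized to [0, 1]. A raw map
#' that is identically (near) zero is returned as zeros with
#' `low_evidence = TRUE` — an uncertainty indicator rather than an error.
#'
#' @param model a [new_medspectralnet()] model (or [medspectralnet()] fit).
#' @param image single image, array (H, W, 3) of raw [0, 1] intensities
#'   (resized to the model's input size if needed).
#' @param target_layer `"contextgate.spatial"` (post-depthwise activation of
#'   the gated block) or `"spectralflow2.output"` (fused output of the second
#'   SpectralFlow).
#' @param class_index 0-based class whose logit is explained.
#' @param input_reference optional identifier stored in the result.
#' @return object of class `msn_heatmap` with `values` (H x W in [0, 1]),
#'   `target_layer`, `class_index`, `low_evidence`.
#' @export
gradcam <- function(model, image, target_layer = GRADCAM_SITES,
                    class_index = 0L, input_reference = NULL) {
  if (inherits(model, "medspectralnet")) model <- model$model
  target_layer <- match.arg(target_layer)
  d <- dim(image)
  if (length(d) != 3L || d[3] != 3L) stop("image must be (H, W, 3)")
  sz <- model$cfg$input_size
  x <- resize_images(array(image, dim = c(d, 1L)), sz)
  x <- normalize_images(x)
  hm <- gradcam_core(
    function(tape, record) msn_logits(tape, model, x, training = FALSE,
                                      record = record),
    target_layer, class_index, out_hw = c(sz, sz))
  hm$input_reference <- input_reference
  hm
}

#' @export
print.msn_heatmap <- function(x, ...) {
  cat("Grad-CAM heatmap at", x$target_layer, "for class", x$class_index, "\n")
  cat("  size:", paste(dim(x$values), collapse = " x "),
      " range: [", format(min(x$values), digits = 3), ",",
      format(max(x$values), digits = 3), "]\n")
  if (x$low_evidence) cat("  flagged: low evidence (raw map ~ 0)\n")
  invisible(x)
}

#' Save a heatmap (and optional overlay) as PNG
#'
#' @param heatmap an `msn_heatmap`.
#' @param path output PNG path.
#' @param image optional (H, W, 3) base image to blend under the map.
#' @param alpha overlay opacity.
#' @return the path, invisibly.
#' @export
write_heatmap_png <- function(heatmap, path, image = NULL, alpha = 0.5) {
  v <- heatmap$values
  # simple blue->red colormap
  col <- array(0, dim = c(dim(v), 3))
  col[, , 1] <- v
  col[, , 3] <- 1 - v
  col[, , 2] <- 1 - abs(2 * v - 1)
  out <- if (is.null(image)) col else clip01((1 - alpha) * image + alpha * col)
  png::writePNG(out, path)
  invisible(path)
}
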