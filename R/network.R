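# ---- full network assembly --------------------------------------------------
#
# image -> backbone -> f_b (512 x H/32 x W/32)
#       -> { SpectralFlow (USM), ContextGate (GM) } in parallel on f_b
#       -> fused = f_b + usm_out + gm_out
#       -> second SpectralFlow -> batch norm -> GAP -> linear head -> logits

#' Model configuration
#'
#' @param num_classes number of output classes (>= 2).
#' @param input_size working square input resolution (divisible by 32).
#' @param patch_size SpectralFlow patch size k for both instances.
#' @param stream_norm attention normalization for both SpectralFlow
#'   instances, see [spectralflow_config()].
#' @param gate_nonlinearity ContextGate gate nonlinearity.
#' @return object of class `msn_config`.
#' @export
model_config <- function(num_classes, input_size = 224L, patch_size = 3L,
                         stream_norm = "softmax_pair",
                         gate_nonlinearity = "gelu") {
  num_classes <- as.integer(num_classes)
  input_size <- as.integer(input_size)
  if (num_classes < 2L) stop("num_classes must be >= 2")
  if (input_size %% 32L != 0L) stop("input_size must be divisible by 32")
  C <- 512L
  structure(list(
    num_classes = num_classes, input_size = input_size,
    backbone = "resnet18", backbone_channels = C,
    usm = spectralflow_config(C, patch_size = patch_size,
                              stream_norm = stream_norm),
    gm = contextgate_config(C, gate_nonlinearity = gate_nonlinearity),
    second_usm = spectralflow_config(C, patch_size = patch_size,
                                     stream_norm = stream_norm)
  ), class = "msn_config")
}

#' Construct the full network with fresh (seeded) random parameters
#'
#' @param cfg a [model_config()].
#' @return model of class `msn_network`.
#' @export
new_medspectralnet <- function(cfg) {
  stopifnot(inherits(cfg, "msn_config"))
  C <- cfg$backbone_channels
  m <- list(
    cfg = cfg,
    backbone = new_resnet18(),
    usm = new_spectralflow(cfg$usm),
    gm = new_contextgate(cfg$gm),
    sf2 = new_spectralflow(cfg$second_usm),
    bn_final = make_bn(C),
    fc = make_linear(C, cfg$num_classes)
  )
  class(m) <- c("msn_network", "msn_module")
  m
}

#' Elementwise fusion of backbone and pathway outputs
#'
#' @param f_b backbone feature map.
#' @param usm_out SpectralFlow pathway output (same shape).
#' @param gm_out ContextGate pathway output (same shape).
#' @return `f_b + usm_out + gm_out`.
#' @export
fuse_pathways <- function(f_b, usm_out, gm_out) {
  if (!all(dim(f_b) == dim(usm_out)) || !all(dim(f_b) == dim(gm_out))) {
    stop("fuse_pathways: shape mismatch")
  }
  f_b + usm_out + gm_out
}

msn_logits <- function(tape, model, x, training = FALSE, record = NULL) {
  f_b <- resnet_features(tape, model$backbone, x, training)
  if (!is.null(record)) record[["backbone.output"]] <- f_b
  usm_out <- sf_forward(tape, model$usm, f_b)$x_f
  gm_out <- cg_forward(tape, model$gm, f_b, record = record)$x_final
  fused <- op_add(tape, op_add(tape, f_b, usm_out), gm_out)
  # second SpectralFlow refines the fused map; applied residually so the
  # whole head reduces to the identity under zeroed parameters
  sf2_out <- sf_forward(tape, model$sf2, fused,
                        record = record, record_prefix = "spectralflow2")$x_f
  refined <- op_add(tape, fused, sf2_out)
  h <- op_bn2d(tape, refined, model$bn_final, training)
  f_c <- op_squeeze_hw(tape, op_gap(tape, h))
  op_linear(tape, f_c, model$fc)
}

#' Network forward pass
#'
#' @param images normalized image batch, array (H, W, 3, N) with H, W
#'   divisible by 32.
#' @param model a [new_medspectralnet()] model.
#' @param training batch-norm mode.
#' @return logits matrix N x num_classes (one row per image).
#' @export
medspectralnet_forward <- function(images, model, training = FALSE) {
  check_fmap(images, "images")
  t(val(msn_logits(NULL, model, images, training = training)))
}

#' Class probabilities from logits
#'
#' Row-wise softmax; rows sum to one and the argmax is preserved.
#'
#' @param logits matrix N x num_classes of finite logits.
#' @return matrix N x num_classes of probabilities.
#' @export
predict_proba <- function(logits) {
  logits <- as.matrix(logits)
  if (any(!is.finite(logits))) stop("predict_proba: non-finite logits")
  z <- logits - apply(logits, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# forward in evaluation mode, batched to bound memory
msn_predict_logits <- function(model, images, batch_size = 64L) {
  n <- dim(images)[4]
  out <- matrix(0, n, model$cfg$num_classes)
  i <- 1L
  while (i <= n) {
    j <- min(i + batch_size - 1L, n)
    out[i:j, ] <- medspectralnet_forward(
      images[, , , i:j, drop = FALSE], model, training = FALSE)
    i <- j + 1L
  }
  out
}
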