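# ---- ContextGate: gated three-pathway fusion block --------------------------
#
# Three parallel pathways on the same input x (C channels):
#   spatial:  depthwise 3x3 -> SpectralFlow (C) -> 1x1 C -> m      (c_out)
#   gating:   1x1 C -> m -> GELU (or sigmoid)                      (g)
#   identity: 1x1 C -> m                                           (i)
# with m = floor(C/3). The gate is applied to the channel concatenation,
#   x_mod = g~ * Concat(c_out, i),     g~ = g repeated over both halves,
# a final 1x1 maps 2m -> C, and the input is added residually:
#   x_final = x_out + x.

#' ContextGate configuration
#'
#' @param channels number of input/output channels C (>= 3).
#' @param gate_nonlinearity `"gelu"` (default) or `"sigmoid"`; sigmoid
#'   guarantees gate values strictly inside (0, 1).
#' @param zero_init_bias initialize biases at zero.
#' @param inner_spectralflow optional [spectralflow_config()] for the
#'   SpectralFlow refinement inside the spatial pathway; defaults to the
#'   module's channel count with reduction 2 (1 if C is odd).
#' @return an object of class `contextgate_config`.
#' @export
contextgate_config <- function(channels, gate_nonlinearity = c("gelu", "sigmoid"),
                               zero_init_bias = TRUE, inner_spectralflow = NULL) {
  gate_nonlinearity <- match.arg(gate_nonlinearity)
  channels <- as.integer(channels)
  if (channels < 3L) stop("channels must be >= 3 (branch width floor(C/3) >= 1)")
  if (is.null(inner_spectralflow)) {
    inner_spectralflow <- spectralflow_config(
      channels, reduction = if (channels %% 2L == 0L) 2L else 1L,
      zero_init_bias = zero_init_bias)
  }
  if (inner_spectralflow$channels != channels) {
    stop("inner SpectralFlow must operate at the block's channel count")
  }
  structure(list(channels = channels, branch_width = channels %/% 3L,
                 gate_nonlinearity = gate_nonlinearity,
                 spatial_kernel = 3L, zero_init_bias = zero_init_bias,
                 inner_spectralflow = inner_spectralflow),
            class = "contextgate_config")
}

#' Construct a ContextGate module with fresh parameters
#'
#' @param cfg a [contextgate_config()].
#' @return a module of class `msn_contextgate`.
#' @export
new_contextgate <- function(cfg) {
  stopifnot(inherits(cfg, "contextgate_config"))
  C <- cfg$channels; m <- cfg$branch_width; zb <- cfg$zero_init_bias
  mod <- list(
    cfg = cfg,
    dw = make_conv(3L, C, C, pad = 1L, groups = C, zero_bias = zb, name = "dw"),
    inner_sf = new_spectralflow(cfg$inner_spectralflow),
    spatial_reduce = make_conv(1L, C, m, zero_bias = zb, name = "spatial_reduce"),
    gate = make_conv(1L, C, m, zero_bias = zb, name = "gate"),
    ident = make_conv(1L, C, m, zero_bias = zb, name = "ident"),
    out = make_conv(1L, 2L * m, C, zero_bias = zb, name = "out")
  )
  class(mod) <- c("msn_contextgate", "msn_module")
  mod
}

cg_spatial <- function(tape, mod, x, record = NULL) {
  d <- op_conv2d(tape, x, mod$dw)
  if (!is.null(record)) record[["contextgate.spatial"]] <- d
  refined <- sf_forward(tape, mod$inner_sf, d)$x_f
  op_conv2d(tape, refined, mod$spatial_reduce)
}

cg_gate <- function(tape, mod, x) {
  z <- op_conv2d(tape, x, mod$gate)
  if (mod$cfg$gate_nonlinearity == "gelu") op_gelu(tape, z) else op_sigmoid(tape, z)
}

cg_forward <- function(tape, mod, x, record = NULL) {
  if (dim(val(x))[3] != mod$cfg$channels) {
    stop("contextgate: input has ", dim(val(x))[3],
         " channels but the block is configured for ", mod$cfg$channels)
  }
  c_out <- cg_spatial(tape, mod, x, record)
  g <- cg_gate(tape, mod, x)
  i <- op_conv2d(tape, x, mod$ident)
  cat_ci <- op_concat_c(tape, c_out, i)
  g2 <- op_concat_c(tape, g, g)            # same gate weights both halves
  x_mod <- op_mul(tape, cat_ci, g2)
  x_out <- op_conv2d(tape, x_mod, mod$out)
  x_final <- op_add(tape, x_out, x)
  list(x_final = x_final, x_out = x_out, x_mod = x_mod,
       c_out = c_out, g = g, i = i)
}

# ---- public, value-level operations ----------------------------------------

#' ContextGate spatial pathway
#'
#' Depthwise 3x3 convolution, SpectralFlow refinement at full width, then a
#' 1x1 reduction to the branch width floor(C/3).
#'
#' @param x feature map (H, W, C, N).
#' @param module a [new_contextgate()] module.
#' @return array (H, W, floor(C/3), N).
#' @export
spatial_path <- function(x, module) {
  check_fmap(x)
  val(cg_spatial(NULL, module, x))
}

#' ContextGate gating pathway
#'
#' 1x1 convolution to the branch width followed by the configured
#' nonlinearity (GELU by default, sigmoid for a strictly (0,1) gate).
#'
#' @inheritParams spatial_path
#' @return gating tensor (H, W, floor(C/3), N).
#' @export
gating_path <- function(x, module) {
  check_fmap(x)
  val(cg_gate(NULL, module, x))
}

#' ContextGate identity pathway
#'
#' Plain 1x1 projection of the input to the branch width; no nonlinearity.
#'
#' @inheritParams spatial_path
#' @return array (H, W, floor(C/3), N).
#' @export
identity_path <- function(x, module) {
  check_fmap(x)
  val(op_conv2d(NULL, x, module$ident))
}

#' Elementwise gated fusion
#'
#' `x_mod = g~ * Concat(c_out, i)` where the gate is repeated channelwise so
#' the same weights modulate the spatial and identity halves.
#'
#' @param c_out spatial pathway output (H, W, m, N).
#' @param i identity pathway output (H, W, m, N).
#' @param g gating tensor (H, W, m, N).
#' @return array (H, W, 2m, N).
#' @export
gate_fuse <- function(c_out, i, g) {
  check_fmap(c_out, "c_out"); check_fmap(i, "i"); check_fmap(g, "g")
  if (!all(dim(c_out)[c(1, 2, 4)] == dim(i)[c(1, 2, 4)]) ||
      !all(dim(g)[c(1, 2, 4)] == dim(i)[c(1, 2, 4)])) {
    stop("gate_fuse: spatial/batch shape mismatch")
  }
  val(op_mul(NULL, op_concat_c(NULL, c_out, i), op_concat_c(NULL, g, g)))
}

#' ContextGate forward pass
#'
#' @param x feature map (H, W, C, N).
#' @param module a [new_contextgate()] module.
#' @param decomposition return all named intermediates?
#' @return the residual output (same shape as input), or a list of class
#'   `gate_decomposition` with `x_final`, `x_out`, `x_mod`, `c_out`, `g`, `i`.
#' @export
contextgate_forward <- function(x, module, decomposition = FALSE) {
  check_fmap(x)
  r <- cg_forward(NULL, module, x)
  if (!decomposition) return(val(r$x_final))
  out <- lapply(r, val)
  class(out) <- "gate_decomposition"
  out
}
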