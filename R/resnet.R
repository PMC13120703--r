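# ---- 18-layer residual backbone --------------------------------------------
#
# Standard basic-block residual network: 7x7/2 stem, 3x3/2 max pool, four
# stages of two basic blocks at widths 64/128/256/512 (first block of stages
# 2-4 strided with a 1x1 projection shortcut). Convolutions carry no bias
# (each is followed by batch normalization). With a 1000-class head this is
# the 11.7M-parameter reference configuration used for profiling.

make_basic_block <- function(cin, cout, stride) {
  b <- list(
    kind = "basic_block",
    conv1 = make_conv(3L, cin, cout, stride = stride, pad = 1L, bias = FALSE),
    bn1 = make_bn(cout),
    conv2 = make_conv(3L, cout, cout, pad = 1L, bias = FALSE),
    bn2 = make_bn(cout)
  )
  if (stride != 1L || cin != cout) {
    b$down_conv <- make_conv(1L, cin, cout, stride = stride, bias = FALSE)
    b$down_bn <- make_bn(cout)
  }
  b
}

#' Construct an 18-layer residual network
#'
#' @param num_classes if non-NULL, attach a global-average-pool + linear
#'   classification head of this many classes; if NULL the network is a
#'   feature extractor ending at the 512-channel map (spatial extent
#'   input/32).
#' @return a module of class `msn_resnet18`.
#' @export
new_resnet18 <- function(num_classes = NULL) {
  widths <- c(64L, 128L, 256L, 512L)
  m <- list(
    conv1 = make_conv(7L, 3L, 64L, stride = 2L, pad = 3L, bias = FALSE),
    bn1 = make_bn(64L),
    stages = lapply(seq_along(widths), function(s) {
      cin <- if (s == 1L) 64L else widths[s - 1L]
      stride <- if (s == 1L) 1L else 2L
      list(make_basic_block(cin, widths[s], stride),
           make_basic_block(widths[s], widths[s], 1L))
    })
  )
  if (!is.null(num_classes)) {
    m$fc <- make_linear(512L, as.integer(num_classes))
  }
  class(m) <- c("msn_resnet18", "msn_module")
  m
}

block_forward <- function(tape, b, x, training) {
  h <- op_conv2d(tape, x, b$conv1)
  h <- op_bn2d(tape, h, b$bn1, training)
  h <- op_relu(tape, h)
  h <- op_conv2d(tape, h, b$conv2)
  h <- op_bn2d(tape, h, b$bn2, training)
  sc <- x
  if (!is.null(b$down_conv)) {
    sc <- op_bn2d(tape, op_conv2d(tape, x, b$down_conv), b$down_bn, training)
  }
  op_relu(tape, op_add(tape, h, sc))
}

resnet_features <- function(tape, m, x, training) {
  d <- dim(val(x))
  if (d[1] %% 32L != 0L || d[2] %% 32L != 0L) {
    stop("backbone input extent (", d[1], "x", d[2],
         ") must be divisible by 32")
  }
  h <- op_relu(tape, op_bn2d(tape, op_conv2d(tape, x, m$conv1), m$bn1, training))
  h <- op_maxpool(tape, h, 3L, 2L, 1L)
  for (stage in m$stages) {
    for (b in stage) h <- block_forward(tape, b, h, training)
  }
  h
}

#' Backbone forward pass
#'
#' @param images array (H, W, 3, N), H and W divisible by 32.
#' @param backbone a [new_resnet18()] module (feature mode).
#' @param training use batch statistics (TRUE) or running statistics (FALSE)
#'   in batch normalization.
#' @return feature map (H/32, W/32, 512, N).
#' @export
backbone_forward <- function(images, backbone, training = FALSE) {
  check_fmap(images, "images")
  val(resnet_features(NULL, backbone, images, training))
}

resnet_logits <- function(tape, m, x, training) {
  f <- resnet_features(tape, m, x, training)
  fc <- op_squeeze_hw(tape, op_gap(tape, f))
  op_linear(tape, fc, m$fc)
}
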