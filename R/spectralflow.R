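# ---- SpectralFlow: global-context dynamic patch attention -------------------
#
# The module splits a feature map into a smoothed low-frequency stream and its
# exact high-frequency residue, then fuses the two with learned per-stream
# channel attention:
#   x_l      = Conv1x1(x), C -> C/r
#   weights  = softmax_k2(Conv1x1(GAP(x)))        (one k^2 kernel per reduced
#                                                  channel, shared spatially)
#   x_la     = patchwise weighted mean of x_l, broadcast per k x k patch
#   x_la~    = Conv1x1(x_la), C/r -> C
#   x_h      = x - x_la~                          (exact decomposition)
#   a_l, a_h = pairwise-softmax (or sigmoid) channel attention per stream
#   x_f      = Conv1x1(a_l * x_la~ + a_h * x_h)

#' SpectralFlow configuration
#'
#' @param channels number of input/output channels C.
#' @param patch_size patch extent k for the low-frequency aggregation
#'   (typically 3 or 5).
#' @param reduction channel reduction factor r; the low-frequency stream has
#'   C/r channels. C must be divisible by r.
#' @param stream_norm how the two per-stream attention vectors are
#'   normalized: `"softmax_pair"` (convex combination, a_l + a_h = 1 per
#'   channel) or `"sigmoid"` (independent gates).
#' @param zero_init_bias initialize all 1x1-convolution biases at zero, so a
#'   zero input maps to a zero output.
#' @return an object of class `spectralflow_config`.
#' @export
spectralflow_config <- function(channels, patch_size = 3L, reduction = 2L,
                                stream_norm = c("softmax_pair", "sigmoid"),
                                zero_init_bias = TRUE) {
  stream_norm <- match.arg(stream_norm)
  channels <- as.integer(channels); patch_size <- as.integer(patch_size)
  reduction <- as.integer(reduction)
  if (patch_size < 1L) stop("patch_size must be >= 1")
  if (channels < reduction) stop("channels must be >= reduction")
  if (channels %% reduction != 0L) stop("channels must be divisible by reduction")
  structure(list(channels = channels, patch_size = patch_size,
                 reduction = reduction, stream_norm = stream_norm,
                 zero_init_bias = zero_init_bias),
            class = "spectralflow_config")
}

#' Construct a SpectralFlow module with fresh parameters
#'
#' @param cfg a [spectralflow_config()].
#' @return a module (list of layers) of class `msn_spectralflow`.
#' @export
new_spectralflow <- function(cfg) {
  stopifnot(inherits(cfg, "spectralflow_config"))
  C <- cfg$channels; Cr <- C %/% cfg$reduction; k2 <- cfg$patch_size^2
  zb <- cfg$zero_init_bias
  m <- list(
    cfg = cfg,
    reduce = make_conv(1L, C, Cr, zero_bias = zb, name = "reduce"),
    filtergen = make_conv(1L, C, Cr * k2, zero_bias = zb, name = "filtergen"),
    proj = make_conv(1L, Cr, C, zero_bias = zb, name = "proj"),
    att_l = make_conv(1L, C, C, zero_bias = zb, name = "att_l"),
    att_h = make_conv(1L, C, C, zero_bias = zb, name = "att_h"),
    fuse = make_conv(1L, C, C, zero_bias = zb, name = "fuse")
  )
  class(m) <- c("msn_spectralflow", "msn_module")
  m
}

# symmetric (edge-inclusive mirror) index sequence of length n_out over 1..n
sym_index <- function(n_out, n) {
  p <- seq_len(n_out) - 1L
  t <- p %% (2L * n)
  ifelse(t < n, t + 1L, 2L * n - t)
}

# ---- patchwise weighted-mean smoothing op ----------------------------------
# x: (H, W, Cr, N); wts: (k2, Cr, N), normalized over k2 (h-fastest patch
# position order p = kh + k*(kw - 1)). Pads bottom/right symmetrically to the
# next multiple of k, replaces each k x k patch by its weighted mean, crops.
op_patch_smooth <- function(tape, x, wts, k) {
  xv <- val(x); wv <- val(wts)
  d <- dim(xv); H <- d[1]; W <- d[2]; Cr <- d[3]; N <- d[4]
  if (k == 1L) {
    # single-position patches with weight 1: identity
    out <- vr(xv)
    if (!is.null(tape)) {
      tape_push(tape, function() {
        acc_grad(x, out$g)
        acc_grad(wts, array(0, dim = dim_of(wv)))
      })
    }
    return(out)
  }
  nbh <- as.integer(ceiling(H / k)); nbw <- as.integer(ceiling(W / k))
  Hp <- nbh * k; Wp <- nbw * k
  ih <- sym_index(Hp, H); iw <- sym_index(Wp, W)
  xp <- xv[ih, iw, , , drop = FALSE]
  dim(xp) <- c(k, nbh, k, nbw, Cr, N)
  wm <- matrix(wv, nrow = k * k)            # k2 x (Cr*N)
  npatch <- nbh * nbw
  s <- matrix(0, npatch, Cr * N)            # per-patch weighted mean
  slices <- vector("list", k * k)
  for (kw in seq_len(k)) {
    for (kh in seq_len(k)) {
      p <- kh + k * (kw - 1L)
      sl <- matrix(xp[kh, , kw, , , ], npatch, Cr * N)
      slices[[p]] <- sl
      s <- s + sweep(sl, 2, wm[p, ], `*`)
    }
  }
  opad <- array(0, dim = c(k, nbh, k, nbw, Cr, N))
  sarr <- array(s, dim = c(nbh, nbw, Cr, N))
  for (kw in seq_len(k)) {
    for (kh in seq_len(k)) {
      opad[kh, , kw, , , ] <- sarr
    }
  }
  dim(opad) <- c(Hp, Wp, Cr, N)
  out <- vr(opad[seq_len(H), seq_len(W), , , drop = FALSE])
  if (!is.null(tape)) {
    tape_push(tape, function() {
      g <- out$g
      gp <- array(0, dim = c(Hp, Wp, Cr, N))
      gp[seq_len(H), seq_len(W), , ] <- g
      dim(gp) <- c(k, nbh, k, nbw, Cr, N)
      sg <- matrix(0, npatch, Cr * N)
      for (kw in seq_len(k)) {
        for (kh in seq_len(k)) {
          sg <- sg + matrix(gp[kh, , kw, , , ], npatch, Cr * N)
        }
      }
      gw <- matrix(0, k * k, Cr * N)
      gxp <- array(0, dim = c(k, nbh, k, nbw, Cr, N))
      for (kw in seq_len(k)) {
        for (kh in seq_len(k)) {
          p <- kh + k * (kw - 1L)
          gw[p, ] <- colSums(sg * slices[[p]])
          gxp[kh, , kw, , , ] <- array(sweep(sg, 2, wm[p, ], `*`),
                                       dim = c(nbh, nbw, Cr, N))
        }
      }
      acc_grad(wts, array(gw, dim = dim_of(wv)))
      dim(gxp) <- c(Hp, Wp, Cr, N)
      gx <- gxp[seq_len(H), seq_len(W), , , drop = FALSE]
      if (Hp > H) {
        for (j in seq(H + 1L, Hp)) {
          gx[ih[j], seq_len(W), , ] <- gx[ih[j], seq_len(W), , ] +
            gxp[j, seq_len(W), , ]
        }
      }
      if (Wp > W) {
        for (j in seq(W + 1L, Wp)) {
          gx[seq_len(H), iw[j], , ] <- gx[seq_len(H), iw[j], , ] +
            gxp[seq_len(H), j, , ]
        }
      }
      if (Hp > H && Wp > W) {
        for (jh in seq(H + 1L, Hp)) {
          for (jw in seq(W + 1L, Wp)) {
            gx[ih[jh], iw[jw], , ] <- gx[ih[jh], iw[jw], , ] + gxp[jh, jw, , ]
          }
        }
      }
      acc_grad(x, gx)
    })
  }
  out
}

# ---- tape-level forward -----------------------------------------------------

sf_patch_weights <- function(tape, mod, x) {
  cfg <- mod$cfg
  k2 <- cfg$patch_size^2; Cr <- cfg$channels %/% cfg$reduction
  g <- op_gap(tape, x)
  z <- op_conv2d(tape, g, mod$filtergen)              # (1,1,Cr*k2,N)
  N <- dim(val(z))[4]
  z <- op_reshape(tape, z, c(k2, Cr, N))
  op_softmax_dim1(tape, z)
}

sf_stream_fuse <- function(tape, mod, x_la_proj, x_h) {
  cfg <- mod$cfg
  zl <- op_conv2d(tape, op_gap(tape, x_la_proj), mod$att_l)
  zh <- op_conv2d(tape, op_gap(tape, x_h), mod$att_h)
  if (cfg$stream_norm == "softmax_pair") {
    a_l <- op_sigmoid(tape, op_sub(tape, zl, zh))
    a_h <- op_affine(tape, a_l, -1, 1)
  } else {
    a_l <- op_sigmoid(tape, zl)
    a_h <- op_sigmoid(tape, zh)
  }
  mix <- op_add(tape,
                op_scale_channels(tape, x_la_proj, a_l),
                op_scale_channels(tape, x_h, a_h))
  list(x_f = op_conv2d(tape, mix, mod$fuse), a_l = a_l, a_h = a_h)
}

sf_forward <- function(tape, mod, x, record = NULL, record_prefix = NULL) {
  cfg <- mod$cfg
  if (dim(val(x))[3] != cfg$channels) {
    stop("spectralflow: input has ", dim(val(x))[3],
         " channels but the module is configured for ", cfg$channels)
  }
  x_l <- op_conv2d(tape, x, mod$reduce)
  pw <- sf_patch_weights(tape, mod, x)
  x_la <- op_patch_smooth(tape, x_l, pw, cfg$patch_size)
  x_la_proj <- op_conv2d(tape, x_la, mod$proj)
  x_h <- op_sub(tape, x, x_la_proj)
  fused <- sf_stream_fuse(tape, mod, x_la_proj, x_h)
  if (!is.null(record) && !is.null(record_prefix)) {
    record[[paste0(record_prefix, ".output")]] <- fused$x_f
  }
  list(x_f = fused$x_f, patch_weights = pw, x_l = x_l, x_la = x_la,
       x_la_proj = x_la_proj, x_h = x_h, a_l = fused$a_l, a_h = fused$a_h)
}

# ---- public, value-level operations ----------------------------------------

check_fmap <- function(x, arg = "x") {
  if (!(is.array(x) && length(dim(x)) == 4L)) {
    stop(arg, " must be a 4-d array with dim (H, W, C, N)")
  }
  invisible(x)
}

#' Global-context patch filter weights
#'
#' Average-pools the input over its full spatial extent, maps the pooled
#' descriptor through a learned 1x1 convolution to one k^2-vector per reduced
#' channel, and softmax-normalizes over the k^2 patch positions. The weights
#' are shared by every spatial patch.
#'
#' @param x feature map, array (H, W, C, N).
#' @param module a [new_spectralflow()] module.
#' @return array (k^2, C/r, N) of nonnegative weights summing to 1 over the
#'   first axis.
#' @export
patch_filter_weights <- function(x, module) {
  check_fmap(x)
  if (dim(x)[3] != module$cfg$channels) {
    stop("channel mismatch: input has ", dim(x)[3], ", config expects ",
         module$cfg$channels)
  }
  val(sf_patch_weights(NULL, module, x))
}

#' Patchwise weighted-mean smoothing
#'
#' Partitions the map into non-overlapping k x k patches (after symmetric
#' bottom/right padding to the next multiple of k), replaces every patch by
#' its weighted mean under the given per-channel weights (broadcast to all
#' k^2 positions), and crops back — a piecewise-constant low-frequency map.
#'
#' @param x_l reduced feature map, array (H, W, C/r, N).
#' @param patch_weights array (k^2, C/r, N), normalized over the first axis.
#' @param k patch size.
#' @return smoothed map, same shape as `x_l`.
#' @export
smooth <- function(x_l, patch_weights, k) {
  check_fmap(x_l, "x_l")
  val(op_patch_smooth(NULL, x_l, patch_weights, as.integer(k)))
}

#' Low/high-frequency decomposition
#'
#' Projects the smoothed low-frequency map back to C channels and returns the
#' exact high-frequency residue `x_h = x - x_la_proj`. By construction
#' `x_la_proj + x_h` reproduces the input elementwise.
#'
#' @param x module input, array (H, W, C, N).
#' @param x_la smoothed low-frequency map, array (H, W, C/r, N).
#' @param module a [new_spectralflow()] module.
#' @return list with `x_la_proj` and `x_h`, both (H, W, C, N).
#' @export
decompose <- function(x, x_la, module) {
  check_fmap(x); check_fmap(x_la, "x_la")
  proj <- val(op_conv2d(NULL, x_la, module$proj))
  list(x_la_proj = proj, x_h = x - proj)
}

#' Attention-weighted fusion of the two frequency streams
#'
#' Each stream is average-pooled, passed through its own 1x1 convolution to
#' per-channel logits, and the pair is normalized (pairwise softmax by
#' default). The convex/gated combination is mixed by a final 1x1 convolution.
#'
#' @param x_la_proj projected low-frequency stream (H, W, C, N).
#' @param x_h high-frequency residue (H, W, C, N).
#' @param module a [new_spectralflow()] module.
#' @param parts also return the attention vectors?
#' @return fused map (H, W, C, N); if `parts`, a list with `x_f`, `a_l`, `a_h`.
#' @export
stream_fuse <- function(x_la_proj, x_h, module, parts = FALSE) {
  check_fmap(x_la_proj, "x_la_proj"); check_fmap(x_h, "x_h")
  if (!all(dim(x_la_proj) == dim(x_h))) stop("stream shape mismatch")
  r <- sf_stream_fuse(NULL, module, x_la_proj, x_h)
  if (parts) {
    list(x_f = val(r$x_f), a_l = val(r$a_l), a_h = val(r$a_h))
  } else {
    val(r$x_f)
  }
}

#' SpectralFlow forward pass
#'
#' @param x feature map, array (H, W, C, N), C matching the module config.
#' @param module a [new_spectralflow()] module.
#' @param decomposition return all named intermediates instead of just the
#'   fused output?
#' @return the fused map (same shape as the input), or a list of class
#'   `spectral_decomposition` with elements `x_f`, `patch_weights`, `x_l`,
#'   `x_la`, `x_la_proj`, `x_h`, `a_l`, `a_h`, `global_descriptor`.
#' @export
spectralflow_forward <- function(x, module, decomposition = FALSE) {
  check_fmap(x)
  r <- sf_forward(NULL, module, x)
  if (!decomposition) return(val(r$x_f))
  out <- lapply(r, val)
  out$global_descriptor <- val(op_gap(NULL, x))
  class(out) <- "spectral_decomposition"
  out
}
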