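#' @useDynLib medspectralnet, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats pnorm dnorm rnorm runif rbeta fft sd quantile
#' @importFrom utils unzip head tail
NULL

# ---- minimal tape-based reverse-mode autodiff -------------------------------
#
# A "variable" is an environment holding $v (value, an array) and $g (the
# accumulated gradient, same shape, or NULL). Ops compute values eagerly and,
# when a tape is supplied, push a closure that propagates the output gradient
# back to the input variables. backward() replays the tape in reverse.
# Passing tape = NULL runs every op in pure inference mode (no caches).

new_tape <- function() {
  e <- new.env(parent = emptyenv())
  e$nodes <- vector("list", 64L)
  e$n <- 0L
  e
}

tape_push <- function(tape, fn) {
  tape$n <- tape$n + 1L
  if (tape$n > length(tape$nodes)) {
    length(tape$nodes) <- 2L * tape$n
  }
  tape$nodes[[tape$n]] <- fn
  invisible(NULL)
}

#' Create an autodiff variable
#'
#' Wraps a numeric array in the mutable variable type used by the package's
#' reverse-mode autodiff tape. Model parameters are variables so optimizers
#' can update them in place.
#'
#' @param value numeric array (any shape).
#' @param requires_grad should gradients be accumulated for this variable?
#' @return an object of class `msn_var` with fields `v` (value) and `g`
#'   (gradient or NULL).
#' @export
vr <- function(value, requires_grad = TRUE) {
  e <- new.env(parent = emptyenv())
  e$v <- value
  e$g <- NULL
  e$requires_grad <- isTRUE(requires_grad)
  class(e) <- "msn_var"
  e
}

is_var <- function(x) inherits(x, "msn_var")

val <- function(x) if (is_var(x)) x$v else x

acc_grad <- function(x, g) {
  if (!is_var(x) || !x$requires_grad) return(invisible(NULL))
  if (is.null(x$g)) x$g <- g else x$g <- x$g + g
  invisible(NULL)
}

#' Run reverse-mode backpropagation over a tape
#'
#' @param tape a tape created by `new_tape()` that recorded the forward pass.
#' @param out the output variable the gradient is seeded at.
#' @param seed gradient seed; defaults to an array of ones shaped like `out`.
#' @export
backward <- function(tape, out, seed = NULL) {
  if (is.null(seed)) {
    seed <- array(1, dim = dim_of(out$v))
  }
  out$g <- seed
  if (tape$n > 0L) {
    for (i in seq(tape$n, 1L)) tape$nodes[[i]]()
  }
  invisible(NULL)
}

zero_grads <- function(params) {
  for (p in params) p$g <- NULL
  invisible(NULL)
}

dim_of <- function(x) {
  d <- dim(x)
  if (is.null(d)) length(x) else d
}

# ---- primitive ops ----------------------------------------------------------

op_add <- function(tape, a, b) {
  out <- vr(val(a) + val(b))
  if (!is.null(tape)) {
    tape_push(tape, function() {
      acc_grad(a, out$g)
      acc_grad(b, out$g)
    })
  }
  out
}

op_sub <- function(tape, a, b) {
  out <- vr(val(a) - val(b))
  if (!is.null(tape)) {
    tape_push(tape, function() {
      acc_grad(a, out$g)
      acc_grad(b, -out$g)
    })
  }
  out
}

op_mul <- function(tape, a, b) {
  av <- val(a); bv <- val(b)
  out <- vr(av * bv)
  if (!is.null(tape)) {
    tape_push(tape, function() {
      acc_grad(a, out$g * bv)
      acc_grad(b, out$g * av)
    })
  }
  out
}

# a*x + b with scalar a, b
op_affine <- function(tape, x, a, b) {
  out <- vr(a * val(x) + b)
  if (!is.null(tape)) {
    tape_push(tape, function() acc_grad(x, a * out$g))
  }
  out
}

op_relu <- function(tape, x) {
  xv <- val(x)
  mask <- xv > 0
  out <- vr(xv * mask)
  if (!is.null(tape)) {
    tape_push(tape, function() acc_grad(x, out$g * mask))
  }
  out
}

# exact GELU: x * Phi(x); derivative Phi(x) + x * phi(x)
op_gelu <- function(tape, x) {
  xv <- val(x)
  ph <- pnorm(xv)
  out <- vr(xv * ph)
  if (!is.null(tape)) {
    tape_push(tape, function() acc_grad(x, out$g * (ph + xv * dnorm(xv))))
  }
  out
}

op_sigmoid <- function(tape, x) {
  s <- 1 / (1 + exp(-val(x)))
  out <- vr(s)
  if (!is.null(tape)) {
    tape_push(tape, function() acc_grad(x, out$g * s * (1 - s)))
  }
  out
}

# global average pool over H, W: (H,W,C,N) -> (1,1,C,N)
op_gap <- function(tape, x) {
  xv <- val(x)
  d <- dim(xv)
  m <- colMeans(matrix(xv, d[1] * d[2], d[3] * d[4]))
  out <- vr(array(m, dim = c(1, 1, d[3], d[4])))
  if (!is.null(tape)) {
    tape_push(tape, function() {
      g <- array(rep(out$g / (d[1] * d[2]), each = d[1] * d[2]), dim = d)
      acc_grad(x, g)
    })
  }
  out
}

# broadcast-multiply per-channel attention a (1,1,C,N) over x (H,W,C,N)
op_scale_channels <- function(tape, x, a) {
  xv <- val(x); av <- val(a)
  d <- dim(xv)
  arep <- array(rep(av, each = d[1] * d[2]), dim = d)
  out <- vr(xv * arep)
  if (!is.null(tape)) {
    tape_push(tape, function() {
      acc_grad(x, out$g * arep)
      ga <- colSums(matrix(out$g * xv, d[1] * d[2], d[3] * d[4]))
      acc_grad(a, array(ga, dim = c(1, 1, d[3], d[4])))
    })
  }
  out
}

op_concat_c <- function(tape, a, b) {
  av <- val(a); bv <- val(b)
  da <- dim(av); db <- dim(bv)
  if (!all(da[c(1, 2, 4)] == db[c(1, 2, 4)])) {
    stop("concat: spatial/batch shape mismatch")
  }
  out <- vr(array(c(aperm_cat(av, bv)), dim = c(da[1], da[2], da[3] + db[3], da[4])))
  if (!is.null(tape)) {
    tape_push(tape, function() {
      g <- out$g
      acc_grad(a, g[, , seq_len(da[3]), , drop = FALSE])
      acc_grad(b, g[, , da[3] + seq_len(db[3]), , drop = FALSE])
    })
  }
  out
}

# channel-concat helper for (H,W,C,N) arrays sharing H,W,N
aperm_cat <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, dim = c(da[1], da[2], da[3] + db[3], da[4]))
  out[, , seq_len(da[3]), ] <- a
  out[, , da[3] + seq_len(db[3]), ] <- b
  out
}

op_conv2d <- function(tape, x, layer) {
  xv <- val(x)
  b <- if (!is.null(layer$b)) layer$b$v else NULL
  y <- cpp_conv2d_fwd(xv, layer$w$v, b, layer$stride, layer$pad, layer$groups)
  out <- vr(y)
  if (!is.null(tape)) {
    wv <- layer$w$v
    need_gx <- is_var(x) && x$requires_grad
    tape_push(tape, function() {
      gr <- cpp_conv2d_bwd(xv, wv, out$g, layer$stride, layer$pad,
                           layer$groups, !is.null(layer$b), need_gx)
      if (need_gx) acc_grad(x, gr$gx)
      acc_grad(layer$w, gr$gw)
      if (!is.null(layer$b)) acc_grad(layer$b, gr$gb)
    })
  }
  out
}

op_maxpool <- function(tape, x, k, stride, pad) {
  xv <- val(x)
  r <- cpp_maxpool_fwd(xv, k, stride, pad)
  out <- vr(r$y)
  if (!is.null(tape)) {
    xd <- dim(xv)
    tape_push(tape, function() {
      acc_grad(x, cpp_maxpool_bwd(out$g, r$arg, xd))
    })
  }
  out
}

# 2-D batch normalization over (H,W,C,N); per-channel statistics.
# Works on the (H*W) x (C*N) matrix view to avoid permutations; per-channel
# quantities are expanded with rep(v, N) (columns are ordered c fastest).
op_bn2d <- function(tape, x, layer, training) {
  xv <- val(x)
  d <- dim(xv)
  C <- d[3]; N <- d[4]
  m <- d[1] * d[2] * N      # reduction count per channel
  xm <- matrix(xv, d[1] * d[2], C * N)
  chan_mean <- function(v) rowMeans(matrix(v, C, N))
  if (training) {
    mu <- chan_mean(colMeans(xm))
    xc <- sweep(xm, 2, rep(mu, N))
    var <- chan_mean(colMeans(xc * xc))
    layer$running_mean <- (1 - layer$momentum) * layer$running_mean +
      layer$momentum * mu
    unb <- if (m > 1) var * m / (m - 1) else var
    layer$running_var <- (1 - layer$momentum) * layer$running_var +
      layer$momentum * unb
  } else {
    mu <- layer$running_mean
    var <- layer$running_var
    xc <- sweep(xm, 2, rep(mu, N))
  }
  istd <- 1 / sqrt(var + layer$eps)
  xhat <- sweep(xc, 2, rep(istd, N), `*`)
  ym <- sweep(sweep(xhat, 2, rep(layer$gamma$v, N), `*`), 2,
              rep(layer$beta$v, N), `+`)
  out <- vr(array(ym, dim = d))
  if (!is.null(tape)) {
    tape_push(tape, function() {
      gm <- matrix(out$g, d[1] * d[2], C * N)
      acc_grad(layer$gamma, rowSums(matrix(colSums(gm * xhat), C, N)))
      acc_grad(layer$beta, rowSums(matrix(colSums(gm), C, N)))
      gxhat <- sweep(gm, 2, rep(layer$gamma$v, N), `*`)
      if (training) {
        t1 <- chan_mean(colMeans(gxhat))
        t2 <- chan_mean(colMeans(gxhat * xhat))
        gx <- sweep(gxhat, 2, rep(t1, N)) - sweep(xhat, 2, rep(t2, N), `*`)
        gx <- sweep(gx, 2, rep(istd, N), `*`)
      } else {
        gx <- sweep(gxhat, 2, rep(istd, N), `*`)
      }
      acc_grad(x, array(gx, dim = d))
    })
  }
  out
}

# fully connected layer on pooled features: x is (C, N); w is (C, K); b is (K)
op_linear <- function(tape, x, layer) {
  xv <- val(x)
  y <- crossprod(layer$w$v, xv) + layer$b$v   # K x N
  out <- vr(y)
  if (!is.null(tape)) {
    tape_push(tape, function() {
      acc_grad(layer$w, xv %*% t(out$g))
      acc_grad(layer$b, rowSums(out$g))
      acc_grad(x, layer$w$v %*% out$g)
    })
  }
  out
}

# softmax over the first dimension of a (K, ...) array
op_softmax_dim1 <- function(tape, x) {
  xv <- val(x)
  d <- dim_of(xv)
  xm <- matrix(xv, d[1])
  xm <- sweep(xm, 2, apply(xm, 2, max))
  e <- exp(xm)
  p <- sweep(e, 2, colSums(e), `/`)
  out <- vr(array(p, dim = d))
  if (!is.null(tape)) {
    tape_push(tape, function() {
      gm <- matrix(out$g, d[1])
      dot <- colSums(gm * p)
      acc_grad(x, array(p * sweep(gm, 2, dot), dim = d))
    })
  }
  out
}

# reshape (values shared, gradient reshaped back)
op_reshape <- function(tape, x, new_dim) {
  xv <- val(x)
  old_dim <- dim_of(xv)
  out <- vr(array(xv, dim = new_dim))
  if (!is.null(tape)) {
    tape_push(tape, function() acc_grad(x, array(out$g, dim = old_dim)))
  }
  out
}

# drop H,W singleton dims: (1,1,C,N) -> (C,N)
op_squeeze_hw <- function(tape, x) {
  d <- dim(val(x))
  op_reshape(tape, x, c(d[3], d[4]))
}

# cross-entropy from logits (K x N); target is an integer vector (1-based) or
# a K x N matrix of label weights (used for the CutMix mixed loss).
op_softmax_xent <- function(tape, logits, target) {
  lv <- val(logits)
  K <- nrow(lv); N <- ncol(lv)
  if (is.matrix(target)) {
    y <- target
  } else {
    y <- matrix(0, K, N)
    y[cbind(target, seq_len(N))] <- 1
  }
  lm <- sweep(lv, 2, apply(lv, 2, max))
  lse <- log(colSums(exp(lm)))
  logp <- sweep(lm, 2, lse)
  loss <- -sum(y * logp) / N
  out <- vr(loss)
  if (!is.null(tape)) {
    p <- exp(logp)
    tape_push(tape, function() {
      g <- (sweep(p, 2, colSums(y), `*`) - y) / N
      acc_grad(logits, g * out$g)
    })
  }
  out
}
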