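# ---- layer constructors -----------------------------------------------------
#
# Layers are environments so batch-norm running statistics can be updated in
# place during training. Parameters are `vr()` variables (see autograd.R).
# Convolution weights: kh x kw x (Cin/groups) x Cout; feature maps: H x W x C x N.

make_conv <- function(k, cin, cout, stride = 1L, pad = 0L, groups = 1L,
                      bias = TRUE, zero_bias = TRUE, name = "conv") {
  if (cin %% groups != 0 || cout %% groups != 0) {
    stop("conv: channels not divisible by groups")
  }
  fan_in <- k * k * cin / groups
  w <- array(rnorm(k * k * (cin / groups) * cout, sd = sqrt(2 / fan_in)),
             dim = c(k, k, cin / groups, cout))
  e <- new.env(parent = emptyenv())
  e$kind <- "conv"; e$name <- name
  e$k <- k; e$cin <- cin; e$cout <- cout
  e$stride <- stride; e$pad <- pad; e$groups <- groups
  e$w <- vr(w)
  e$b <- if (bias) vr(if (zero_bias) numeric(cout) else rnorm(cout, sd = 0.01)) else NULL
  class(e) <- "msn_layer"
  e
}

make_bn <- function(c, eps = 1e-5, momentum = 0.1, name = "bn") {
  e <- new.env(parent = emptyenv())
  e$kind <- "bn"; e$name <- name
  e$c <- c; e$eps <- eps; e$momentum <- momentum
  e$gamma <- vr(rep(1, c))
  e$beta <- vr(numeric(c))
  e$running_mean <- numeric(c)
  e$running_var <- rep(1, c)
  class(e) <- "msn_layer"
  e
}

make_linear <- function(cin, cout, zero_bias = TRUE, name = "fc") {
  e <- new.env(parent = emptyenv())
  e$kind <- "linear"; e$name <- name
  e$cin <- cin; e$cout <- cout
  e$w <- vr(matrix(rnorm(cin * cout, sd = 1 / sqrt(cin)), cin, cout))
  e$b <- vr(if (zero_bias) numeric(cout) else rnorm(cout, sd = 0.01))
  class(e) <- "msn_layer"
  e
}

#' Collect trainable parameters of a module
#'
#' Recursively walks a module (nested lists of layers) and returns the flat
#' list of parameter variables, in a stable order.
#'
#' @param m a layer, module, or fitted model component.
#' @return list of `msn_var` parameter variables.
#' @export
collect_params <- function(m) {
  if (is_var(m)) return(if (m$requires_grad) list(m) else list())
  if (inherits(m, "msn_layer")) {
    out <- list()
    for (f in c("w", "b", "gamma", "beta")) {
      v <- m[[f]]
      if (is_var(v)) out <- c(out, list(v))
    }
    return(out)
  }
  if (is.list(m)) {
    out <- list()
    for (el in m) out <- c(out, collect_params(el))
    return(out)
  }
  list()
}

#' Count trainable parameters
#'
#' Sums the sizes of every trainable parameter array (convolution and linear
#' weights and biases, and batch-normalization affine terms).
#'
#' @param model a module or fitted model.
#' @return integer total parameter count.
#' @export
count_params <- function(model) {
  sum(vapply(collect_params(model), function(p) length(p$v), numeric(1)))
}

# flatten / restore parameter values (checkpointing, best-model tracking)
params_state <- function(m) lapply(collect_params(m), function(p) p$v)

params_restore <- function(m, state) {
  ps <- collect_params(m)
  stopifnot(length(ps) == length(state))
  for (i in seq_along(ps)) ps[[i]]$v <- state[[i]]
  invisible(NULL)
}

# buffers (batch-norm running stats) for checkpointing
walk_layers <- function(m, fn) {
  if (inherits(m, "msn_layer")) { fn(m); return(invisible(NULL)) }
  if (is.list(m)) for (el in m) walk_layers(el, fn)
  invisible(NULL)
}

buffers_state <- function(m) {
  out <- list()
  walk_layers(m, function(l) {
    if (l$kind == "bn") {
      out[[length(out) + 1L]] <<- list(mean = l$running_mean, var = l$running_var)
    }
  })
  out
}

buffers_restore <- function(m, state) {
  i <- 0L
  walk_layers(m, function(l) {
    if (l$kind == "bn") {
      i <<- i + 1L
      l$running_mean <- state[[i]]$mean
      l$running_var <- state[[i]]$var
    }
  })
  invisible(NULL)
}

#' Zero every trainable parameter of a module
#'
#' Diagnostic helper: with all learned parameters at zero the ContextGate
#' block reduces exactly to the identity map and SpectralFlow maps any input
#' to zero, which the residual-identity tests exploit.
#'
#' @param m a layer or module (modified in place).
#' @return NULL, invisibly.
#' @export
zero_params <- function(m) {
  for (p in collect_params(m)) p$v[] <- 0
  invisible(NULL)
}
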