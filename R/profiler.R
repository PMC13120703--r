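# ---- parameter / multiply-accumulate profiling ------------------------------
#
# Convention: one MAC per fused multiply-add of every convolution
# (Cout * Cin/groups * k^2 * Hout * Wout) and fully connected layer
# (Cin * Cout). Normalization, activations, pooling, elementwise arithmetic
# and the patch-smoothing aggregation count zero. Under this convention the
# 18-layer residual reference at 224 x 224 measures 1.81 G.

MAC_CONVENTION <- "conv+linear MACs; norm/act/pool/elementwise = 0"

prof_row <- function(name, params, macs) {
  data.frame(layer = name, params = params, macs = macs,
             stringsAsFactors = FALSE)
}

conv_out_hw <- function(l, h, w) {
  c(floor((h + 2 * l$pad - l$k) / l$stride) + 1,
    floor((w + 2 * l$pad - l$k) / l$stride) + 1)
}

prof_layer <- function(l, h, w, name) {
  if (l$kind == "conv") {
    o <- conv_out_hw(l, h, w)
    macs <- l$cout * (l$cin / l$groups) * l$k^2 * o[1] * o[2]
    rows <- prof_row(name, count_params(l), macs)
    list(rows = rows, h = o[1], w = o[2])
  } else if (l$kind == "bn") {
    list(rows = prof_row(name, count_params(l), 0), h = h, w = w)
  } else if (l$kind == "linear") {
    list(rows = prof_row(name, count_params(l), l$cin * l$cout), h = h, w = w)
  } else {
    stop("unknown layer kind: ", l$kind)
  }
}

prof_sf <- function(m, h, w, name) {
  rows <- rbind(
    prof_layer(m$reduce, h, w, paste0(name, ".reduce"))$rows,
    prof_layer(m$filtergen, 1, 1, paste0(name, ".filtergen"))$rows,
    prof_layer(m$proj, h, w, paste0(name, ".proj"))$rows,
    prof_layer(m$att_l, 1, 1, paste0(name, ".att_l"))$rows,
    prof_layer(m$att_h, 1, 1, paste0(name, ".att_h"))$rows,
    prof_layer(m$fuse, h, w, paste0(name, ".fuse"))$rows
  )
  list(rows = rows, h = h, w = w)
}

prof_cg <- function(m, h, w, name) {
  inner <- prof_sf(m$inner_sf, h, w, paste0(name, ".inner_sf"))
  rows <- rbind(
    prof_layer(m$dw, h, w, paste0(name, ".dw"))$rows,
    inner$rows,
    prof_layer(m$spatial_reduce, h, w, paste0(name, ".spatial_reduce"))$rows,
    prof_layer(m$gate, h, w, paste0(name, ".gate"))$rows,
    prof_layer(m$ident, h, w, paste0(name, ".ident"))$rows,
    prof_layer(m$out, h, w, paste0(name, ".out"))$rows
  )
  list(rows = rows, h = h, w = w)
}

prof_block <- function(b, h, w, name) {
  c1 <- prof_layer(b$conv1, h, w, paste0(name, ".conv1"))
  rows <- rbind(c1$rows,
                prof_layer(b$bn1, c1$h, c1$w, paste0(name, ".bn1"))$rows)
  c2 <- prof_layer(b$conv2, c1$h, c1$w, paste0(name, ".conv2"))
  rows <- rbind(rows, c2$rows,
                prof_layer(b$bn2, c2$h, c2$w, paste0(name, ".bn2"))$rows)
  if (!is.null(b$down_conv)) {
    dc <- prof_layer(b$down_conv, h, w, paste0(name, ".down_conv"))
    rows <- rbind(rows, dc$rows,
                  prof_layer(b$down_bn, dc$h, dc$w, paste0(name, ".down_bn"))$rows)
  }
  list(rows = rows, h = c2$h, w = c2$w)
}

prof_resnet <- function(m, h, w, name = "backbone") {
  c1 <- prof_layer(m$conv1, h, w, paste0(name, ".conv1"))
  rows <- rbind(c1$rows,
                prof_layer(m$bn1, c1$h, c1$w, paste0(name, ".bn1"))$rows)
  h <- floor((c1$h + 2 * 1 - 3) / 2) + 1   # 3x3/2 max pool, pad 1
  w <- floor((c1$w + 2 * 1 - 3) / 2) + 1
  for (s in seq_along(m$stages)) {
    for (b in seq_along(m$stages[[s]])) {
      r <- prof_block(m$stages[[s]][[b]], h, w,
                      sprintf("%s.stage%d.block%d", name, s, b))
      rows <- rbind(rows, r$rows)
      h <- r$h; w <- r$w
    }
  }
  if (!is.null(m$fc)) {
    rows <- rbind(rows, prof_layer(m$fc, 1, 1, paste0(name, ".fc"))$rows)
  }
  list(rows = rows, h = h, w = w)
}

prof_module <- function(m, h, w, name = "model") {
  if (inherits(m, "msn_resnet18")) return(prof_resnet(m, h, w, name))
  if (inherits(m, "msn_spectralflow")) return(prof_sf(m, h, w, name))
  if (inherits(m, "msn_contextgate")) return(prof_cg(m, h, w, name))
  if (inherits(m, "msn_network")) {
    bb <- prof_resnet(m$backbone, h, w, "backbone")
    rows <- bb$rows
    rows <- rbind(rows, prof_sf(m$usm, bb$h, bb$w, "usm")$rows)
    rows <- rbind(rows, prof_cg(m$gm, bb$h, bb$w, "gm")$rows)
    rows <- rbind(rows, prof_sf(m$sf2, bb$h, bb$w, "sf2")$rows)
    rows <- rbind(rows, prof_layer(m$bn_final, bb$h, bb$w, "bn_final")$rows)
    rows <- rbind(rows, prof_layer(m$fc, 1, 1, "fc")$rows)
    return(list(rows = rows, h = bb$h, w = bb$w))
  }
  if (inherits(m, "msn_layer")) return(prof_layer(m, h, w, name))
  stop("cannot profile object of class ", paste(class(m), collapse = "/"))
}

#' Multiply-accumulate count of one forward pass
#'
#' @param model a module or full network.
#' @param input_size input extent fed to the module (square if scalar, or
#'   `c(H, W)`); for the full network this is the image size, for a
#'   standalone module the feature-map extent.
#' @return total MAC count (numeric; one MAC = one fused multiply-add).
#' @export
count_macs <- function(model, input_size) {
  hw <- rep(as.numeric(input_size), length.out = 2L)
  sum(prof_module(model, hw[1], hw[2])$rows$macs)
}

#' Profile a model: per-layer parameters and MACs
#'
#' @param model a module or full network.
#' @param input_size square input extent.
#' @return object of class `msn_profile`: list with `total_params`,
#'   `total_macs`, `per_layer` (data frame), `input_size`, `convention`.
#' @export
profile_model <- function(model, input_size) {
  hw <- rep(as.numeric(input_size), length.out = 2L)
  r <- prof_module(model, hw[1], hw[2])
  structure(list(total_params = sum(r$rows$params),
                 total_macs = sum(r$rows$macs),
                 per_layer = r$rows,
                 input_size = as.integer(hw),
                 convention = MAC_CONVENTION),
            class = "msn_profile")
}

#' @export
print.msn_profile <- function(x, ...) {
  cat("Profile at input", paste(x$input_size, collapse = " x "), "\n")
  cat("  convention:", x$convention, "\n")
  cat(sprintf("  total params: %s (%.2f M)\n",
              format(x$total_params, big.mark = ","), x$total_params / 1e6))
  cat(sprintf("  total MACs:   %s (%.2f G)\n",
              format(x$total_macs, big.mark = ","), x$total_macs / 1e9))
  invisible(x)
}
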