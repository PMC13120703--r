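# ---- user-facing fitting interface ------------------------------------------

#' Fit a dual-stream frequency-decomposed image classifier
#'
#' Builds the full network (18-layer residual backbone, parallel SpectralFlow
#' and ContextGate pathways, residual fusion, second SpectralFlow, batch
#' normalization, global average pooling, linear head) with seeded random
#' initialization and trains it with cross-entropy.
#'
#' @param x training images: array (H, W, 3, N) of raw [0, 1] intensities,
#'   or a dataset list with `images` (N x H x W x 3, 0..255) and `labels`
#'   as returned by [synth_generate()] / [read_medmnist()].
#' @param y 0-based integer labels (ignored when `x` is a dataset list).
#' @param num_classes number of classes; inferred from the labels if NULL.
#' @param input_size working resolution (divisible by 32); images are
#'   bilinearly resized to it.
#' @param epochs,optimizer,learning_rate,batch_size,augmentation,weight_decay,momentum
#'   passed to [train_config()].
#' @param validation optional held-out data in either accepted form; used
#'   for the per-epoch test curve and best-model selection.
#' @param patch_size SpectralFlow patch size (3 or 5).
#' @param seed seed controlling initialization, shuffling and augmentation.
#' @param verbose print per-epoch progress?
#' @return object of class `medspectralnet` with elements `model`,
#'   `config`, `train_config`, `history`, `seed`, `levels`.
#' @export
medspectralnet <- function(x, y = NULL, num_classes = NULL, input_size = 32L,
                           epochs = 30L, optimizer = "adam",
                           learning_rate = 1e-3, batch_size = 32L,
                           augmentation = "normal", weight_decay = 0,
                           momentum = 0.9, validation = NULL,
                           patch_size = 3L, seed = 1L, verbose = FALSE) {
  tr <- coerce_data(x, y, input_size)
  if (is.null(num_classes)) num_classes <- max(tr$y) + 1L
  ev <- if (!is.null(validation)) coerce_data(validation, NULL, input_size)
  cfg <- model_config(num_classes, input_size = input_size,
                      patch_size = patch_size)
  set.seed(seed)
  model <- new_medspectralnet(cfg)
  tcfg <- train_config(optimizer = optimizer, learning_rate = learning_rate,
                       weight_decay = weight_decay, momentum = momentum,
                       epochs = epochs, batch_size = batch_size,
                       augmentation = augmentation, seed = seed)
  res <- train(model, tr, ev, tcfg, verbose = verbose)
  structure(list(model = res$model, config = cfg, train_config = tcfg,
                 history = res$history, seed = as.integer(seed),
                 n_train = length(tr$y)),
            class = "medspectralnet")
}

coerce_data <- function(x, y, input_size) {
  if (is.list(x) && !is.null(x$images)) {
    return(as_image_batch(x, input_size))
  }
  if (is.list(x) && !is.null(x$x)) {
    return(list(x = resize_images(x$x, input_size), y = as.integer(x$y)))
  }
  if (is.array(x) && length(dim(x)) == 4L) {
    if (is.null(y)) stop("labels y required when x is an array")
    xx <- if (max(x) > 1.5) x / 255 else x
    return(list(x = resize_images(xx, input_size), y = as.integer(y)))
  }
  stop("unsupported training data; pass (H,W,3,N) array + labels or a dataset list")
}

#' @export
print.medspectralnet <- function(x, ...) {
  cfg <- x$config
  cat("Dual-stream frequency-decomposed classifier (SpectralFlow + ContextGate)\n")
  cat(sprintf("  %d classes, input %dx%d, patch size k = %d\n",
              cfg$num_classes, cfg$input_size, cfg$input_size,
              cfg$usm$patch_size))
  cat(sprintf("  parameters: %.2f M\n", count_params(x$model) / 1e6))
  if (nrow(x$history) > 0) {
    last <- x$history[nrow(x$history), ]
    cat(sprintf("  trained %d epochs (%s); final train acc %.3f",
                nrow(x$history), x$train_config$optimizer,
                last$train_accuracy))
    if (!is.na(last$test_accuracy)) {
      cat(sprintf(", best test acc %.3f",
                  max(x$history$test_accuracy, na.rm = TRUE)))
    }
    cat("\n")
  }
  invisible(x)
}

#' @export
summary.medspectralnet <- function(object, ...) {
  print(object)
  prof <- profile_model(object$model, object$config$input_size)
  cat(sprintf("  MACs at %d px: %.3f G (%s)\n", prof$input_size,
              prof$total_macs / 1e9, prof$convention))
  if (nrow(object$history) > 0) {
    cat("  history (last 5 epochs):\n")
    print(tail(object$history, 5), row.names = FALSE)
  }
  invisible(object)
}

#' Predict from a fitted classifier
#'
#' @param object a [medspectralnet()] fit.
#' @param newdata images: (H, W, 3, N) raw [0, 1] array or a dataset list.
#' @param type `"prob"` (default), `"class"` (0-based labels), or
#'   `"logits"`.
#' @param ... unused.
#' @return matrix N x K, or integer vector for `type = "class"`.
#' @export
predict.medspectralnet <- function(object, newdata,
                                   type = c("prob", "class", "logits"), ...) {
  type <- match.arg(type)
  nd <- coerce_data(newdata, NULL, object$config$input_size)
  logits <- msn_predict_logits(object$model, normalize_images(nd$x))
  switch(type,
         logits = logits,
         prob = predict_proba(logits),
         class = max.col(logits, ties.method = "first") - 1L)
}

#' Plot training history
#'
#' Loss (left) and accuracy (right) curves over epochs for the training and
#' held-out splits.
#'
#' @param x a `medspectralnet` fit.
#' @param ... passed to `matplot`.
#' @importFrom graphics matplot legend par
#' @export
plot.medspectralnet <- function(x, ...) {
  h <- x$history
  if (nrow(h) == 0) stop("no history: model was trained for 0 epochs")
  op <- par(mfrow = c(1, 2))
  on.exit(par(op))
  matplot(h$epoch, cbind(h$train_loss, h$test_loss), type = "l", lty = 1,
          col = c("steelblue", "firebrick"), xlab = "epoch", ylab = "loss", ...)
  legend("topright", c("train", "test"), lty = 1,
         col = c("steelblue", "firebrick"), bty = "n")
  matplot(h$epoch, cbind(h$train_accuracy, h$test_accuracy), type = "l",
          lty = 1, col = c("steelblue", "firebrick"), xlab = "epoch",
          ylab = "accuracy", ...)
  legend("bottomright", c("train", "test"), lty = 1,
         col = c("steelblue", "firebrick"), bty = "n")
  invisible(x)
}

# ---- checkpointing ----------------------------------------------------------

#' Save model parameters with a JSON config sidecar
#'
#' Writes the parameter and batch-norm state to `path` (RDS) and a
#' `<path>.json` sidecar recording the model configuration and seed so the
#' run is reconstructible.
#'
#' @param fit a `medspectralnet` fit (or list with `model`, `config`, `seed`).
#' @param path checkpoint path.
#' @return the path, invisibly.
#' @export
save_checkpoint <- function(fit, path) {
  model <- if (inherits(fit, "medspectralnet")) fit$model else fit$model
  saveRDS(list(params = params_state(model), buffers = buffers_state(model)),
          path)
  cfg <- if (inherits(fit, "medspectralnet")) fit$config else fit$config
  side <- list(
    num_classes = cfg$num_classes, input_size = cfg$input_size,
    backbone = cfg$backbone, patch_size = cfg$usm$patch_size,
    stream_norm = cfg$usm$stream_norm,
    gate_nonlinearity = cfg$gm$gate_nonlinearity,
    seed = fit$seed,
    optimizer = if (!is.null(fit$train_config)) fit$train_config$optimizer,
    learning_rate = if (!is.null(fit$train_config)) fit$train_config$learning_rate
  )
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       null = "null")
  invisible(path)
}

#' Load a checkpoint saved by [save_checkpoint()]
#'
#' @param path checkpoint path (the sidecar `<path>.json` must exist).
#' @return list with `model` (reconstructed, parameters restored) and
#'   `config`.
#' @export
load_checkpoint <- function(path) {
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  cfg <- model_config(side$num_classes, input_size = side$input_size,
                      patch_size = side$patch_size,
                      stream_norm = side$stream_norm,
                      gate_nonlinearity = side$gate_nonlinearity)
  model <- new_medspectralnet(cfg)
  st <- readRDS(path)
  params_restore(model, st$params)
  buffers_restore(model, st$buffers)
  list(model = model, config = cfg, seed = side$seed)
}
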