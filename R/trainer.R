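# ---- seeded training / evaluation loops -------------------------------------

#' Training configuration
#'
#' @param optimizer `"adam"`, `"sgd"`, or `"rmsprop"`.
#' @param learning_rate step size (default 1e-3).
#' @param weight_decay L2 coefficient added to gradients (default 0).
#' @param momentum SGD momentum (default 0.9; ignored by the others).
#' @param epochs number of passes over the training data.
#' @param batch_size minibatch size.
#' @param augmentation `"normal"` (flip only) or `"cutmix"` (full stack plus
#'   CutMix), the two ablation arms; or an [augmentation_config()].
#' @param seed integer controlling shuffling, augmentation and
#'   initialization-independent randomness of the run.
#' @return object of class `train_config`.
#' @export
train_config <- function(optimizer = c("adam", "sgd", "rmsprop"),
                         learning_rate = 1e-3, weight_decay = 0,
                         momentum = 0.9, epochs = 200L, batch_size = 128L,
                         augmentation = "normal", seed = 1L) {
  optimizer <- match.arg(optimizer)
  if (learning_rate < 0) stop("learning_rate must be >= 0")
  if (epochs < 0) stop("epochs must be >= 0")
  if (is.character(augmentation)) {
    augmentation <- augmentation_config(mode = augmentation)
  }
  structure(list(optimizer = optimizer, learning_rate = learning_rate,
                 weight_decay = weight_decay, momentum = momentum,
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 augmentation = augmentation, seed = as.integer(seed)),
            class = "train_config")
}

#' Construct a first-order optimizer over a parameter list
#'
#' @param name one of `"adam"`, `"sgd"`, `"rmsprop"`.
#' @param params list of parameter variables (see [collect_params()]).
#' @param cfg a [train_config()] (supplies learning rate, momentum, decay).
#' @return an optimizer handle with a `$step()` method consuming the
#'   gradients accumulated in `params`.
#' @export
make_optimizer <- function(name, params, cfg) {
  valid <- c("adam", "sgd", "rmsprop")
  if (!name %in% valid) {
    stop("unknown optimizer '", name, "'; valid: ", paste(valid, collapse = ", "))
  }
  e <- new.env(parent = emptyenv())
  e$name <- name
  e$lr <- cfg$learning_rate
  e$wd <- cfg$weight_decay
  e$t <- 0L
  e$m <- vector("list", length(params))
  e$v <- vector("list", length(params))
  e$step <- function() {
    e$t <- e$t + 1L
    for (i in seq_along(params)) {
      p <- params[[i]]
      g <- p$g
      if (is.null(g)) next
      if (e$wd > 0) g <- g + e$wd * p$v
      if (name == "sgd") {
        if (is.null(e$m[[i]])) e$m[[i]] <- g * 0
        e$m[[i]] <- cfg$momentum * e$m[[i]] + g
        p$v <- p$v - e$lr * e$m[[i]]
      } else if (name == "rmsprop") {
        if (is.null(e$v[[i]])) e$v[[i]] <- g * 0
        e$v[[i]] <- 0.99 * e$v[[i]] + 0.01 * g * g
        p$v <- p$v - e$lr * g / (sqrt(e$v[[i]]) + 1e-8)
      } else {
        if (is.null(e$m[[i]])) { e$m[[i]] <- g * 0; e$v[[i]] <- g * 0 }
        e$m[[i]] <- 0.9 * e$m[[i]] + 0.1 * g
        e$v[[i]] <- 0.999 * e$v[[i]] + 0.001 * g * g
        mhat <- e$m[[i]] / (1 - 0.9^e$t)
        vhat <- e$v[[i]] / (1 - 0.999^e$t)
        p$v <- p$v - e$lr * mhat / (sqrt(vhat) + 1e-8)
      }
    }
    invisible(NULL)
  }
  class(e) <- "msn_optimizer"
  e
}

augment_batch <- function(xb, acfg) {
  full <- acfg$mode == "cutmix" || acfg$hflip_prob > 0 ||
    acfg$translate_frac > 0 || acfg$erase_prob > 0 || acfg$blur_prob > 0 ||
    acfg$perspective_prob > 0
  if (!full) return(xb)
  for (i in seq_len(dim(xb)[4])) {
    xb[, , , i] <- augment(xb[, , , i], acfg)
  }
  xb
}

#' Train a network
#'
#' Standard epoch loop with cross-entropy loss on logits; under CutMix the
#' loss is `lam * CE(labels_a) + (1 - lam) * CE(labels_b)`. Shuffling,
#' augmentation and CutMix draws are all derived from `cfg$seed`. The
#' parameter state with the best evaluation accuracy is restored at the end.
#'
#' @param model a [new_medspectralnet()] model (modified in place).
#' @param train_data list with `x` (H, W, 3, N raw [0, 1] intensities) and
#'   `y` (0-based integer labels), e.g. from [as_image_batch()].
#' @param eval_data held-out data in the same layout (may be NULL).
#' @param cfg a [train_config()].
#' @param verbose print per-epoch progress?
#' @return list with the trained `model` and `history` (a data frame with
#'   per-epoch `train_loss`, `train_accuracy`, `test_loss`, `test_accuracy`).
#' @export
train <- function(model, train_data, eval_data = NULL, cfg = train_config(),
                  verbose = FALSE) {
  stopifnot(inherits(cfg, "train_config"))
  set.seed(cfg$seed)
  x <- train_data$x; y <- as.integer(train_data$y)
  n <- dim(x)[4]
  params <- collect_params(model)
  opt <- make_optimizer(cfg$optimizer, params, cfg)
  hist <- data.frame(epoch = integer(0), train_loss = numeric(0),
                     train_accuracy = numeric(0), test_loss = numeric(0),
                     test_accuracy = numeric(0))
  best_acc <- -Inf; best_state <- NULL; best_buf <- NULL
  acfg <- cfg$augmentation
  for (ep in seq_len(cfg$epochs)) {
    ord <- sample.int(n)
    ep_loss <- 0; ep_correct <- 0; seen <- 0
    i <- 1L
    while (i <= n) {
      j <- min(i + cfg$batch_size - 1L, n)
      idx <- ord[i:j]
      xb <- x[, , , idx, drop = FALSE]
      yb <- y[idx]
      xb <- augment_batch(xb, acfg)
      xb <- normalize_images(xb)
      mixed <- NULL
      if (acfg$mode == "cutmix" && acfg$cutmix_prob > 0) {
        mixed <- cutmix(xb, yb, acfg)
        xb <- mixed$images
      }
      tape <- new_tape()
      logits <- msn_logits(tape, model, xb, training = TRUE)
      K <- model$cfg$num_classes
      if (!is.null(mixed) && mixed$lam < 1) {
        tgt <- matrix(0, K, length(yb))
        tgt[cbind(mixed$labels_a + 1L, seq_along(yb))] <-
          tgt[cbind(mixed$labels_a + 1L, seq_along(yb))] + mixed$lam
        tgt[cbind(mixed$labels_b + 1L, seq_along(yb))] <-
          tgt[cbind(mixed$labels_b + 1L, seq_along(yb))] + (1 - mixed$lam)
        loss <- op_softmax_xent(tape, logits, tgt)
      } else {
        loss <- op_softmax_xent(tape, logits, yb + 1L)
      }
      if (!is.finite(val(loss))) {
        stop("non-finite loss at epoch ", ep, ", batch starting at ", i)
      }
      zero_grads(params)
      backward(tape, loss, seed = 1)
      opt$step()
      nb <- length(idx)
      ep_loss <- ep_loss + val(loss) * nb
      pred <- apply(val(logits), 2, which.max) - 1L
      ep_correct <- ep_correct + sum(pred == yb)
      seen <- seen + nb
      i <- j + 1L
    }
    tr_loss <- ep_loss / seen
    tr_acc <- ep_correct / seen
    te_loss <- NA_real_; te_acc <- NA_real_
    if (!is.null(eval_data)) {
      ev <- evaluate(model, eval_data)
      te_loss <- ev$loss; te_acc <- ev$accuracy
      if (te_acc > best_acc) {
        best_acc <- te_acc
        best_state <- params_state(model)
        best_buf <- buffers_state(model)
      }
    }
    hist <- rbind(hist, data.frame(epoch = ep, train_loss = tr_loss,
                                   train_accuracy = tr_acc,
                                   test_loss = te_loss, test_accuracy = te_acc))
    if (verbose) {
      message(sprintf("epoch %3d  train loss %.4f acc %.3f  test loss %s acc %s",
                      ep, tr_loss, tr_acc,
                      ifelse(is.na(te_loss), "-", sprintf("%.4f", te_loss)),
                      ifelse(is.na(te_acc), "-", sprintf("%.3f", te_acc))))
    }
  }
  if (!is.null(best_state)) {
    params_restore(model, best_state)
    buffers_restore(model, best_buf)
  }
  list(model = model, history = hist)
}

#' Evaluate a network on held-out data
#'
#' Deterministic: resize/normalize only, batch-norm running statistics.
#'
#' @param model a trained model.
#' @param data list with `x` (H, W, 3, N raw [0, 1]) and `y` (0-based labels).
#' @param curves also compute one-vs-rest ROC/PR curves?
#' @return list with `loss`, `accuracy`, `confusion`, `probs`, `pred`, and
#'   (optionally) `roc`/`pr` per-class curves with macro-average areas.
#' @export
evaluate <- function(model, data, curves = FALSE) {
  n <- if (is.null(dim(data$x))) 0L else dim(data$x)[4]
  if (n == 0L) stop("evaluate: empty dataset")
  xb <- normalize_images(data$x)
  y <- as.integer(data$y)
  logits <- msn_predict_logits(model, xb)
  probs <- predict_proba(logits)
  K <- model$cfg$num_classes
  logp <- log(pmax(probs, 1e-12))
  loss <- -mean(logp[cbind(seq_len(n), y + 1L)])
  pred <- max.col(probs, ties.method = "first") - 1L
  conf <- confusion_matrix(y, pred, K)
  out <- list(loss = loss, accuracy = accuracy(conf), confusion = conf,
              probs = probs, pred = pred)
  if (curves) {
    out$ovr <- one_vs_rest(probs, y)
  }
  out
}
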