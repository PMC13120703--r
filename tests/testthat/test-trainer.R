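test_that("optimizers take the textbook first step", {
  cfg <- train_config(learning_rate = 0.1, momentum = 0.9)
  # scalar quadratic loss L = theta^2, gradient 2*theta
  p <- vr(3)
  p$g <- 2 * p$v
  opt <- make_optimizer("sgd", list(p), cfg)
  opt$step()
  expect_equal(p$v, 3 - 0.1 * 6, tolerance = 1e-12)    # theta - lr * grad

  p2 <- vr(3); p2$g <- 2 * p2$v
  make_optimizer("adam", list(p2), cfg)$step()
  expect_false(p2$v == 3)                               # a step was taken
  # adam first step is lr * sign(grad) up to epsilon
  expect_equal(p2$v, 3 - 0.1, tolerance = 1e-6)

  p3 <- vr(3); p3$g <- 2 * p3$v
  make_optimizer("rmsprop", list(p3), cfg)$step()
  expect_true(is.finite(p3$v) && p3$v < 3)

  zero <- train_config(learning_rate = 0)
  p4 <- vr(3); p4$g <- 2 * p4$v
  make_optimizer("adam", list(p4), zero)$step()
  expect_equal(p4$v, 3)                                 # lr 0: unchanged

  expect_error(make_optimizer("adagrad", list(p), cfg), "sgd")
})

test_that("zero epochs leave the model untouched with an empty history", {
  set.seed(50)
  model <- new_medspectralnet(model_config(4, input_size = 32))
  before <- lapply(collect_params(model), function(p) p$v)
  ds <- make_small_fit_data(n_per_class = 2)
  b <- as_image_batch(ds, 32)
  r <- train(model, b, NULL, train_config(epochs = 0, seed = 1))
  expect_equal(nrow(r$history), 0)
  after <- lapply(collect_params(model), function(p) p$v)
  expect_identical(before, after)
})

test_that("the mixed loss degenerates to plain cross-entropy at lam = 1", {
  ns <- asNamespace("medspectralnet")
  set.seed(51)
  logits <- vr(matrix(rnorm(12), 3, 4))
  y <- c(1L, 3L, 2L, 1L)
  plain <- ns$op_softmax_xent(NULL, logits, y)$v
  tgt <- matrix(0, 3, 4); tgt[cbind(y, 1:4)] <- 1      # lam = 1 mixture
  mixed <- ns$op_softmax_xent(NULL, logits, tgt)$v
  expect_equal(mixed, plain, tolerance = 1e-12)
})

test_that("evaluation is consistent with its own confusion matrix", {
  set.seed(52)
  model <- new_medspectralnet(model_config(4, input_size = 32))
  ds <- make_small_fit_data(n_per_class = 5)
  b <- as_image_batch(ds, 32)
  ev <- evaluate(model, b)
  expect_equal(ev$accuracy, sum(diag(ev$confusion)) / sum(ev$confusion))
  expect_equal(sum(ev$confusion), length(b$y))
  expect_equal(ev$accuracy, mean(ev$pred == b$y))
  expect_error(evaluate(model, list(x = NULL, y = integer(0))), "empty")
})

test_that("a fixed seed reproduces the training history exactly", {
  ds <- make_small_fit_data(n_per_class = 4, seed = 77)
  f1 <- medspectralnet(ds, input_size = 32, epochs = 2, batch_size = 8,
                       seed = 3)
  f2 <- medspectralnet(ds, input_size = 32, epochs = 2, batch_size = 8,
                       seed = 3)
  expect_identical(f1$history, f2$history)
})

test_that("an overparameterized network memorizes a single small batch", {
  set.seed(53)
  lf <- data.frame(cx = c(0.3, 0.7, 0.3, 0.7), cy = c(0.3, 0.3, 0.7, 0.7),
                   radius = c(0.1, 0.12, 0.14, 0.16))
  sp <- synthetic_spec(num_classes = 4, samples_per_class = 4,
                       image_size = 32, low_freq = lf, seed = 13)
  ds <- synth_generate(sp)
  b <- as_image_batch(ds, 32)
  model <- new_medspectralnet(model_config(4, input_size = 32))
  cfg <- train_config(epochs = 50, batch_size = 16, seed = 13,
                      augmentation = augmentation_config("normal",
                                                         hflip_prob = 0))
  r <- train(model, b, NULL, cfg)
  expect_gte(max(r$history$train_accuracy), 1.0)
  expect_true(all(is.finite(r$history$train_loss)))
})
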