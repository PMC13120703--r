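test_that("backbone maps input extent to extent/32 at 512 channels", {
  set.seed(20)
  bb <- new_resnet18()
  x <- rand_fmap(32, 32, 3, 2, sd = 0.5)
  f <- backbone_forward(x, bb)
  expect_equal(dim(f), c(1, 1, 512, 2))
  x64 <- rand_fmap(64, 32, 3, 1, sd = 0.5)
  expect_equal(dim(backbone_forward(x64, bb)), c(2, 1, 512, 1))
  expect_error(backbone_forward(rand_fmap(30, 32, 3, 1), bb), "divisible by 32")
})

test_that("pathway fusion is elementwise addition", {
  set.seed(21)
  f <- rand_fmap(2, 2, 4, 1); u <- rand_fmap(2, 2, 4, 1); g <- rand_fmap(2, 2, 4, 1)
  expect_equal(fuse_pathways(f, u, g), f + u + g)
  expect_equal(fuse_pathways(f, array(0, dim(f)), array(0, dim(f))), f)
  ones <- array(1, dim(f))
  expect_equal(fuse_pathways(ones, ones, ones), 3 * ones)
  expect_error(fuse_pathways(f, u, rand_fmap(3, 2, 4, 1)), "mismatch")
})

test_that("full forward yields one logit row per image and class", {
  set.seed(22)
  model <- new_medspectralnet(model_config(11, input_size = 32))
  x <- normalize_images(array(runif(32 * 32 * 3 * 2), c(32, 32, 3, 2)))
  lg <- medspectralnet_forward(x, model)
  expect_equal(dim(lg), c(2, 11))
  expect_true(all(is.finite(lg)))
  expect_error(model_config(1), "num_classes")
  expect_error(model_config(4, input_size = 100), "divisible by 32")
})

test_that("the two pathways are order-independent on the same features", {
  set.seed(23)
  model <- new_medspectralnet(model_config(4, input_size = 32))
  f_b <- rand_fmap(2, 2, 512, 1, sd = 0.1)
  u1 <- spectralflow_forward(f_b, model$usm)
  g1 <- contextgate_forward(f_b, model$gm)
  g2 <- contextgate_forward(f_b, model$gm)   # reversed evaluation order
  u2 <- spectralflow_forward(f_b, model$usm)
  expect_identical(u1, u2)
  expect_identical(g1, g2)
})

test_that("zeroed pathway parameters reduce to backbone + BN + GAP + FC", {
  set.seed(24)
  ns <- asNamespace("medspectralnet")
  model <- new_medspectralnet(model_config(4, input_size = 32))
  zero_params(model$usm); zero_params(model$gm); zero_params(model$sf2)
  x <- normalize_images(array(runif(32 * 32 * 3 * 4), c(32, 32, 3, 4)))
  lg <- t(ns$val(ns$msn_logits(NULL, model, x, training = TRUE)))
  # reduced graph: the ContextGate residual passes f_b through, so the head
  # sees 2*f_b, and batch-statistics normalization cancels the factor
  f_b <- ns$val(ns$resnet_features(NULL, model$backbone, vr(x, FALSE), TRUE))
  bnl <- ns$make_bn(512L)
  h <- ns$val(ns$op_bn2d(NULL, vr(f_b, FALSE), bnl, TRUE))
  fc <- apply(h, c(3, 4), mean)                  # GAP, 512 x 4
  ref <- t(crossprod(model$fc$w$v, fc) + model$fc$b$v)
  # agreement is limited by the batch-norm epsilon (the doubled activations
  # rescale the variance but not the 1e-5 stabilizer)
  expect_equal(lg, ref, tolerance = 1e-3)
})

test_that("probabilities are a proper, order-preserving softmax", {
  expect_equal(predict_proba(matrix(c(0, 0), 1)), matrix(0.5, 1, 2))
  lg <- matrix(rnorm(12), 3, 4)
  p <- predict_proba(lg)
  expect_equal(rowSums(p), rep(1, 3))
  expect_equal(predict_proba(lg + 5), p)                   # shift invariance
  expect_equal(apply(p, 1, which.max), apply(lg, 1, which.max))
  expect_equal(as.vector(predict_proba(matrix(log(1:3), 1))),
               c(1, 2, 3) / 6, tolerance = 1e-12)
  expect_error(predict_proba(matrix(c(1, Inf), 1)), "finite")
})

test_that("every trainable parameter receives a finite gradient", {
  set.seed(25)
  ns <- asNamespace("medspectralnet")
  model <- new_medspectralnet(model_config(4, input_size = 32))
  x <- normalize_images(array(runif(32 * 32 * 3 * 2), c(32, 32, 3, 2)))
  tape <- ns$new_tape()
  loss <- ns$op_softmax_xent(tape, ns$msn_logits(tape, model, x, TRUE),
                             c(1L, 3L))
  backward(tape, loss, seed = 1)
  for (p in collect_params(model)) {
    expect_false(is.null(p$g))
    expect_true(all(is.finite(p$g)))
  }
})

test_that("checkpoints round-trip parameters and configuration", {
  set.seed(26)
  model <- new_medspectralnet(model_config(4, input_size = 32))
  fit <- structure(list(model = model,
                        config = model$cfg, seed = 26L,
                        train_config = train_config(epochs = 0)),
                   class = "medspectralnet")
  path <- tempfile(fileext = ".rds")
  save_checkpoint(fit, path)
  expect_true(file.exists(paste0(path, ".json")))
  re <- load_checkpoint(path)
  x <- normalize_images(array(runif(32 * 32 * 3 * 2), c(32, 32, 3, 2)))
  expect_equal(medspectralnet_forward(x, re$model),
               medspectralnet_forward(x, model))
})
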