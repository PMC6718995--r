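test_that("forward pass matches the shape calculus and softmax normalizes", {
  spec <- tiny_spec(classes = 5L)
  model <- build_network(spec, n_classes = 5, seed = 3)
  imgs <- list(array(runif(16 * 16 * 3), dim = c(16, 16, 3)),
               array(0, dim = c(16, 16, 3)))
  preds <- predict(model, imgs)
  probs <- as.matrix(preds[, paste0("prob_", 0:4)])
  expect_equal(rowSums(probs), c(1, 1), tolerance = 1e-6)
  expect_true(all(probs >= 0))
  expect_true(all(is.finite(probs))) # all-zero input stays finite
  # runtime shapes agree with infer_shapes (audited inside training)
  act <- dualpathnet:::as_act_matrix(imgs)
  fwd <- dualpathnet:::net_forward(model, act$X, act$n, act$h, act$w)
  want <- infer_shapes(spec, check_channels = FALSE)
  expect_identical(fwd$shapes[, 1], want$width)
  expect_identical(fwd$shapes[, 2], want$height)
  expect_identical(fwd$shapes[, 3], want$channels)
})

test_that("the original architecture pools 336 features on a 64x64 input", {
  model <- build_network(builtin_specs()$original, n_classes = 5, seed = 1)
  img <- list(array(runif(64 * 64 * 3), dim = c(64, 64, 3)))
  feats <- dualpathnet:::pooled_features(model, img)
  expect_identical(ncol(feats), 336L)
  expect_true(all(feats >= 0))
})

test_that("building a network from a failing spec errors before allocation", {
  spec <- builtin_specs()$reductive
  spec$modules[[2]]$branches[[1]]$filters <- 33L
  expect_error(build_network(spec), "audit", class = "dualpathnet_spec_error")
})

test_that("training loss decreases on a fixed small batch", {
  set <- separable_image_set(n_per_class = 6)
  model <- build_network(tiny_spec(), n_classes = 2, seed = 2)
  cfg <- training_config(learning_rate = 0.005, epochs = 6, batch_size = 6,
                         seed = 2, weight_decay = 0)
  fit <- train_network(model, set, validation = NULL, config = cfg)
  h <- fit$history
  expect_identical(nrow(h), 6L)
  expect_lt(h$train_loss[6], h$train_loss[1])
})

test_that("a trivially separable two-class problem is learned to accuracy 1", {
  set <- separable_image_set(n_per_class = 12)
  parts <- split_dataset(set, ratio = 0.75, seed = 4)
  model <- build_network(tiny_spec(), n_classes = 2, seed = 4)
  # ten epochs: evaluation uses batch-norm running statistics, which need a
  # few dozen batches to track the batch statistics from their cold start
  cfg <- training_config(epochs = 10, batch_size = 6, seed = 4)
  fit <- train_network(model, parts$train, parts$validation, cfg)
  expect_equal(max(fit$history$val_accuracy), 1.0)
})

test_that("zero epochs returns the untrained model with empty history", {
  model <- build_network(tiny_spec(), n_classes = 2, seed = 1)
  fit <- train_network(model, separable_image_set(2),
                       config = training_config(epochs = 0, seed = 1))
  expect_identical(nrow(fit$history), 0L)
})

test_that("training is fully reproducible under a fixed seed", {
  set <- separable_image_set(n_per_class = 5)
  cfg <- training_config(epochs = 3, batch_size = 5, seed = 8)
  run <- function() {
    model <- build_network(tiny_spec(), n_classes = 2, seed = 8)
    train_network(model, set, set, cfg)
  }
  f1 <- run(); f2 <- run()
  expect_identical(f1$history, f2$history)
  expect_identical(f1$layers[[1]]$units[[1]]$W, f2$layers[[1]]$units[[1]]$W)
})

test_that("prediction ties break toward the lowest class and order is kept", {
  model <- build_network(tiny_spec(classes = 3L), n_classes = 3, seed = 1)
  # force uniform logits: zero FC weights and bias
  model$layers[[6]]$W[] <- 0
  model$layers[[6]]$b[] <- 0
  imgs <- lapply(1:4, function(i) array(runif(16 * 16 * 3), dim = c(16, 16, 3)))
  preds <- predict(model, imgs)
  expect_identical(nrow(preds), 4L)
  expect_true(all(preds$pred == 0L))
  expect_equal(as.numeric(as.matrix(preds[, paste0("prob_", 0:2)])),
               rep(1 / 3, 12), tolerance = 1e-9)
})

test_that("input shape and label mismatches raise argument errors", {
  model <- build_network(tiny_spec(), n_classes = 2, seed = 1)
  wrong <- list(array(0.5, dim = c(8, 8, 3)))
  expect_error(predict(model, wrong), "expects", class = "dualpathnet_spec_error")
  set <- separable_image_set(2)
  set$label <- set$label + 5L
  expect_error(train_network(model, set, config = training_config(epochs = 1)),
               class = "dualpathnet_spec_error")
  expect_error(train_network(model, set[0, ], config = training_config(epochs = 1)),
               "empty", class = "dualpathnet_spec_error")
})

test_that("checkpoints round-trip and broom accessors summarize the fit", {
  set <- separable_image_set(4)
  model <- build_network(tiny_spec(), n_classes = 2, seed = 6)
  fit <- train_network(model, set, set, training_config(epochs = 2, seed = 6))
  path <- withr::local_tempfile(fileext = ".rds")
  save_model(fit, path)
  back <- load_model(path)
  expect_identical(predict(back, set)$pred, predict(fit, set)$pred)
  expect_identical(tidy(fit), fit$history)
  g <- glance(fit)
  expect_identical(g$epochs_run, 2L)
  expect_identical(g$architecture, "tiny")
  expect_true(g$best_val_accuracy >= 0 && g$best_val_accuracy <= 1)
})
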