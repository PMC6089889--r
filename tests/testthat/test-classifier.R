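test_that("width multiplier sets the published channel progression", {
  m1 <- build_network(network_config(alpha = 1, input_size = 224), seed = 1)
  d1 <- network_summary(m1)
  expect_equal(d1$channels[1], 32)
  expect_equal(d1$channels[length(d1$channels)], 1024)

  m05 <- build_network(network_config(alpha = 0.5, input_size = 224),
                       seed = 1)
  d05 <- network_summary(m05)
  expect_equal(d05$channels[1], 16)
  expect_equal(d05$channels[length(d05$channels)], 512)

  # thinner network has strictly fewer parameters (overfitting control)
  expect_lt(d05$n_params, d1$n_params)

  # input 224 -> 7x7 pre-pooling map; strides at blocks 2, 4, 6, 12
  expect_equal(d05$feature_hw, 7)
  expect_equal(which(d05$block_strides == 2), c(2, 4, 6, 12))

  expect_warning(network_config(alpha = 0.3), "rounding")
})

test_that("predictions live on the simplex and ignore batch composition", {
  model <- build_network(network_config(alpha = 0.25, input_size = 64),
                         seed = 2)
  x <- array(runif(64 * 64 * 3 * 6), dim = c(64, 64, 3, 6))
  p <- predict_patch(model, x)
  expect_equal(dim(p), c(6, 4))
  expect_true(all(p >= 0))
  expect_equal(rowSums(p), rep(1, 6), tolerance = 1e-6)

  # alone vs in a batch
  p1 <- predict_patch(model, x[, , , 3])
  expect_equal(as.numeric(p1), unname(p[3, ]), tolerance = 1e-6)

  # zeroed output layer -> uniform distribution
  w <- model_weights(model)
  w$Wfc[] <- 0; w$bfc[] <- 0
  model <- set_model_weights(model, w)
  expect_equal(as.numeric(predict_patch(model, x[, , , 1])),
               rep(0.25, 4), tolerance = 1e-7)

  expect_error(predict_patch(model, array(0, dim = c(32, 32, 3))), "64")
})

test_that("training reduces the loss on separable textures and is seeded", {
  g <- patch_geometry("half", patch_size = 72L, step = 72L,
                      label_window = 24L, resize_to = 72L, crop_size = 64L)
  patches <- fake_patch_set(12, rs = 72L)
  run <- function() {
    model <- build_network(network_config(alpha = 0.25, input_size = 64,
                                          dropout_rate = 0.2), seed = 31)
    model <- train_classifier(
      model, patches,
      train_config("scratch", iterations = 300L, eval_every = 100L,
                   seed = 41),
      g, holdout = patches)
    model
  }
  m1 <- run()
  h <- tidy(m1)
  expect_equal(nrow(h), 3)
  expect_lt(h$loss[3], h$loss[1])          # end strictly below start
  expect_gt(h$holdout_macro_recall[3], 0.9) # separable problem is learned
  # identical seeds give identical loss trajectories
  m2 <- run()
  expect_identical(tidy(m1)$loss, tidy(m2)$loss)
})

test_that("analytic gradients match numeric differentiation at the head", {
  model <- build_network(network_config(alpha = 0.25, input_size = 64,
                                        dropout_rate = 0), seed = 5)
  x <- array(runif(64 * 64 * 3 * 8), dim = c(64, 64, 3, 8))
  y <- rep(1:4, each = 2L)
  lg <- gleasonet:::gn_loss_grads(model$ptr, x, y)
  w <- model_weights(model)
  # final-layer parameters sit above the batch-norm stack, where single
  # precision finite differences are well conditioned
  for (probe in list(c("Wfc", 1L), c("Wfc", 7L), c("bfc", 2L))) {
    nm <- probe[1]; i <- as.integer(probe[2])
    grads <- lg$grads[[if (nm == "Wfc") length(lg$grads) - 1L
                       else length(lg$grads)]]
    eps <- 1e-2
    w2 <- w; w2[[nm]][i] <- w2[[nm]][i] + eps
    gleasonet:::gn_set_weights(model$ptr, w2)
    lp <- gleasonet:::gn_loss_grads(model$ptr, x, y)$loss
    w2[[nm]][i] <- w2[[nm]][i] - 2 * eps
    gleasonet:::gn_set_weights(model$ptr, w2)
    lm <- gleasonet:::gn_loss_grads(model$ptr, x, y)$loss
    gleasonet:::gn_set_weights(model$ptr, w)
    expect_equal(as.numeric(grads)[i], (lp - lm) / (2 * eps),
                 tolerance = 0.05)
  }
})

test_that("divergent training aborts with a diagnostic", {
  g <- patch_geometry("half", patch_size = 72L, step = 72L,
                      label_window = 24L, resize_to = 72L, crop_size = 64L)
  patches <- fake_patch_set(4, rs = 72L)
  model <- build_network(network_config(alpha = 0.25, input_size = 64),
                         seed = 6)
  expect_error(
    train_classifier(model, patches,
                     train_config("scratch", iterations = 20L,
                                  learning_rate = 1e12, seed = 1),
                     g),
    "diverged")
})

test_that("checkpoints restore the exact model", {
  model <- build_network(network_config(alpha = 0.25, input_size = 64),
                         seed = 7)
  x <- array(runif(64 * 64 * 3), dim = c(64, 64, 3))
  dir <- withr::local_tempdir()
  save_model(model, dir)
  expect_true(file.exists(file.path(dir, "architecture.json")))
  back <- load_model(dir)
  expect_equal(predict_patch(back, x), predict_patch(model, x),
               tolerance = 1e-7)
})
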