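test_that("batch weights follow the inverse-frequency formula", {
  # one 4x4 tile with an even foreground/background split: both weights 2
  t1 <- matrix(0L, 4, 4); t1[1:2, ] <- 1L
  bw <- compute_batch_weights(t1)
  expect_equal(bw$r_fg, 2.0)
  expect_equal(bw$r_bg, 2.0)
  # 100 pixels, 25 foreground
  t2 <- matrix(0L, 10, 10); t2[1:5, 1:5] <- 1L
  bw2 <- compute_batch_weights(t2)
  expect_equal(bw2$r_fg, 4.0)
  expect_equal(bw2$r_bg, 100 / 75)
  # all-background batch: foreground weight 0 and the degenerate flag
  bw3 <- compute_batch_weights(matrix(0L, 5, 5))
  expect_equal(bw3$r_fg, 0)
  expect_true(bw3$degenerate)
  expect_error(compute_batch_weights(list()), "empty")
})

test_that("each present label contributes equal total weight to the batch", {
  set.seed(42)
  for (rep in 1:50) {
    tgts <- lapply(seq_len(sample(1:4, 1)), function(i)
      random_mask(8, 8, runif(1, 0.05, 0.95)))
    bw <- compute_batch_weights(tgts)
    if (!bw$degenerate) {
      expect_equal(bw$r_fg * bw$c_fg, bw$c_K)
      expect_equal(bw$r_bg * bw$c_bg, bw$c_K)
    }
    expect_equal(bw$c_fg + bw$c_bg, bw$c_K)
  }
})

test_that("the two-pixel toy loss evaluates to 4 ln 2", {
  # 1 foreground + 1 background pixel (both weights 2), uniform prediction
  scores <- array(0, dim = c(1, 2, 2))
  target <- matrix(c(1L, 0L), 1, 2)
  expect_equal(weighted_loss(scores, target), 4 * log(2), tolerance = 1e-6)
})

test_that("reference loss and compiled loss agree on random batches", {
  cfg <- network_config(depth = 2, base_filters = 4, input_size = 16)
  net <- build_network(cfg, seed = 31)
  set.seed(32)
  for (rep in 1:5) {
    x <- array(runif(16 * 16 * 3), dim = c(16, 16, 3))
    tg <- random_mask(16, 16, runif(1, 0.1, 0.9))
    bw <- compute_batch_weights(tg)
    res <- overlapseg:::unet_apply_cpp(net$weights, x, cfg$depth, tg,
                                       bw$r_fg, bw$r_bg, FALSE)
    expect_equal(res$loss,
                 weighted_loss(res$logits, tg, bw),
                 tolerance = 1e-8)
  }
})

test_that("unit weights reduce the loss to plain summed cross-entropy plus L2", {
  set.seed(33)
  scores <- array(rnorm(8 * 8 * 2), dim = c(8, 8, 2))
  tg <- random_mask(8, 8)
  w1 <- list(r_fg = 1, r_bg = 1)
  plain <- {
    a <- scores[, , 1]; b <- scores[, , 2]
    logZ <- log(exp(a) + exp(b))
    sum(ifelse(tg != 0, logZ - a, logZ - b))
  }
  expect_equal(weighted_loss(scores, tg, w1), plain, tolerance = 1e-10)
  net <- build_network(network_config(depth = 1, base_filters = 2,
                                      input_size = 8), seed = 1)
  l2 <- sum(vapply(net$weights, function(w) sum(w$W^2), 0))
  expect_equal(weighted_loss(scores, tg, w1, lambda_l2 = 0.001, params = net),
               plain + 0.001 * l2, tolerance = 1e-10)
  # zero weights contribute zero penalty
  z <- net; z$weights <- lapply(z$weights, function(w) list(W = w$W * 0, b = w$b))
  expect_equal(weighted_loss(scores, tg, w1, lambda_l2 = 1, params = z),
               plain, tolerance = 1e-10)
  expect_gte(weighted_loss(scores, tg), 0)
})

test_that("a confident correct prediction drives the loss toward zero", {
  tg <- random_mask(8, 8)
  scores <- array(0, dim = c(8, 8, 2))
  scores[, , 1] <- ifelse(tg != 0, 50, -50)
  scores[, , 2] <- -scores[, , 1]
  expect_lt(weighted_loss(scores, tg), 1e-10)
})

test_that("staircase schedule decays by floor(step / every)", {
  cfg <- train_config()
  expect_equal(staircase_lr(0, cfg), 1e-5)
  expect_equal(staircase_lr(9999, cfg), 1e-5)
  expect_equal(staircase_lr(10000, cfg), 9e-6)
  expect_equal(staircase_lr(20000, cfg), 8.1e-6, tolerance = 1e-12)
  steps <- seq(0, 50000, by = 500)
  lrs <- staircase_lr(steps, cfg)
  expect_true(all(diff(lrs) <= 0))
})

test_that("training reduces the loss and is seed-reproducible", {
  ds <- separable_tiles(n = 10, side = 16)
  cfg <- train_config(lr0 = 1e-3, decay_every = 1000, epochs = 30,
                      batch_size = 3, seed = 41)
  ncfg <- network_config(depth = 2, base_filters = 4, input_size = 16)
  fit <- train_class_network(ds, cfg, ncfg)
  h <- fit$history$epochs
  expect_equal(nrow(h), 30)
  expect_lt(h$train_loss[30], h$train_loss[1])
  fit2 <- train_class_network(ds, cfg, ncfg)
  expect_equal(fit$history$epochs$train_loss, fit2$history$epochs$train_loss,
               tolerance = 1e-10)
  expect_equal(fit$params$weights, fit2$params$weights, tolerance = 1e-10)
})

test_that("one epoch yields exactly one history record", {
  ds <- separable_tiles(n = 4, side = 16)
  cfg <- train_config(lr0 = 1e-3, epochs = 1, batch_size = 2, seed = 42)
  ncfg <- network_config(depth = 1, base_filters = 2, input_size = 16)
  fit <- train_class_network(ds, cfg, ncfg)
  expect_equal(nrow(fit$history$epochs), 1)
  expect_equal(nrow(fit$history$steps), 2)  # 4 tiles / batch 2
  expect_equal(fit$params$step, 2L)
})

test_that("a tiny network learns a separable tile set to high pixel accuracy", {
  ds <- separable_tiles(n = 10, side = 16, seed = 7)
  cfg <- train_config(lr0 = 2e-3, decay_every = 1000, epochs = 150,
                      batch_size = 3, seed = 43)
  ncfg <- network_config(depth = 2, base_filters = 4, input_size = 16)
  fit <- train_class_network(ds, cfg, ncfg)
  acc <- overlapseg:::monitor_eval(fit$params, ds, ncfg)$accuracy
  expect_gt(acc, 0.95)
})

test_that("the monitoring pass reports test loss and accuracy in the history", {
  ds <- separable_tiles(n = 6, side = 16)
  ev <- separable_tiles(n = 3, side = 16, seed = 123)
  cfg <- train_config(lr0 = 1e-3, epochs = 10, batch_size = 3, seed = 44)
  ncfg <- network_config(depth = 1, base_filters = 2, input_size = 16)
  fit <- train_class_network(ds, cfg, ncfg, eval_set = ev, eval_every = 5)
  h <- fit$history$epochs
  expect_false(is.na(h$test_loss[5]))
  expect_true(is.na(h$test_loss[4]))
  expect_true(h$test_accuracy[10] >= 0 && h$test_accuracy[10] <= 1)
})
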