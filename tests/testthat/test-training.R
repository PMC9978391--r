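test_that("AdaGrad matches a hand-rolled oracle on a scalar quadratic", {
  # minimize f(theta) = (theta - 3)^2 from theta = 0, lr = 0.1
  lr <- 0.1; eps <- 1e-8
  theta <- 0; acc <- 0
  theta_o <- 0; acc_o <- 0
  for (i in 1:10) {
    g <- 2 * (theta - 3)
    st <- adagrad_step(theta, g, acc, lr, eps)
    theta <- st$par; acc <- st$acc
    # independent arithmetic
    g_o <- 2 * (theta_o - 3)
    acc_o <- acc_o + g_o^2
    theta_o <- theta_o - lr * g_o / sqrt(acc_o + eps)
    expect_equal(theta, theta_o, tolerance = 1e-12)
    expect_equal(acc, acc_o, tolerance = 1e-12)
  }
  expect_gt(theta, 0)  # moved toward the minimum
  # array parameters update elementwise
  st <- adagrad_step(c(1, 2), c(0.5, -1), c(0, 0), 0.01)
  expect_equal(st$par, c(1, 2) - 0.01 * c(0.5, -1) / sqrt(c(0.25, 1) + 1e-8))
})

test_that("training pairs degrade, restore and renormalize each gradient", {
  vol <- generate_phantom(tiny_phantom(noise_sigma = 2))
  pairs <- build_pairs(vol)
  expect_length(pairs, n_gradients(vol))
  p <- pairs[[3]]
  expect_equal(dim(p$source), dim(p$target))
  expect_equal(dim(p$target), c(9, 9, 6))
  # rescaled intensities live in [0, 1] and spans match after renormalization
  expect_lte(max(p$target), 1)
  expect_equal(range(p$source), range(p$target))
  expect_equal(p$bval, vol$bvals[3])
  # non-divisible volumes are zero-padded up front
  odd <- dwi_volume(array(runif(5 * 7 * 4), c(5, 7, 4, 1)), 0,
                    matrix(0, 3, 1))
  expect_equal(dim(build_pairs(odd)[[1]]$target), c(6, 9, 6))
  # constant target survives the degrade/restore cycle: zero-loss pair
  cst <- dwi_volume(array(4, c(6, 6, 6, 1)), 0, matrix(0, 3, 1))
  pc <- build_pairs(cst)[[1]]
  expect_equal(pc$source, pc$target, tolerance = 1e-12)
})

test_that("pairs split into exactly three groups with b = 0 merged into b = 1000", {
  mk <- function(b) list(source = 0, target = 0, bval = b, subject = 1)
  pairs <- lapply(c(0, 1000, 1000, 1500, 2000, 2000), mk)
  gr <- group_by_bvalue(pairs)
  expect_named(gr, c("b0_b1000", "b1500", "b2000"))
  expect_length(gr$b0_b1000$pairs, 3)
  expect_length(gr$b1500$pairs, 1)
  expect_length(gr$b2000$pairs, 2)
  expect_equal(gr$b0_b1000$bvalues, c(0, 1000))
  # all pairs on one shell: one non-empty group, two empty
  gr2 <- group_by_bvalue(lapply(rep(1500, 4), mk))
  expect_length(gr2$b1500$pairs, 4)
  expect_length(gr2$b0_b1000$pairs, 0)
  expect_length(gr2$b2000$pairs, 0)
  # unknown shell errors, naming the value
  expect_error(group_by_bvalue(list(mk(700))), "700",
               class = "dwisr_config_error")
})

test_that("the AdaGrad/MSE loop learns, logs and checkpoints deterministically", {
  vol <- generate_phantom(tiny_phantom(seed = 3, noise_sigma = 2))
  pairs <- build_pairs(vol)[1:4]
  class(pairs) <- "dwi_pairs"
  ctrl <- training_control(epochs = 5, checkpoint_interval = 8, seed = 11)
  fit1 <- fit_srcnn(pairs, tiny_spec(seed = 2), ctrl)
  fit2 <- fit_srcnn(pairs, tiny_spec(seed = 2), ctrl)
  expect_identical(fit1$weights, fit2$weights)  # bit-identical reruns
  expect_equal(fit1$iterations, 20L)
  expect_equal(fit1$log$iteration, 1:20)
  expect_true(all(fit1$log$loss >= 0))
  # checkpoints at the interval plus a final snapshot
  expect_equal(vapply(fit1$checkpoints, `[[`, 0L, "iteration"),
               c(8L, 16L, 20L))
})

test_that("a single fixed pair is fit monotonically enough to reduce its loss", {
  set.seed(4)
  tgt <- rand_grid(c(6, 6, 6), 13)
  src <- interpolate_up(downsample(tgt, 3), 3)
  src <- normalize_range(src, tgt)
  pairs <- structure(list(list(source = src, target = tgt, bval = 1000,
                               subject = 1)), class = "dwi_pairs")
  fit <- fit_srcnn(pairs, tiny_spec(seed = 1),
                   training_control(epochs = 300, checkpoint_interval = 1e6))
  expect_lt(tail(fit$log$loss, 1), fit$log$loss[1])
})

test_that("identity task keeps its zero-loss optimum reachable", {
  g <- rand_grid(c(6, 6, 6), 31)
  pairs <- structure(list(list(source = g, target = g, bval = 1500,
                               subject = 1)), class = "dwi_pairs")
  fit <- fit_srcnn(pairs, tiny_spec(seed = 7, init_scale = 1e-3),
                   training_control(epochs = 200,
                                    checkpoint_interval = 1e6))
  expect_lte(tail(fit$log$loss, 1), fit$log$loss[1])
})

test_that("per-subject loss aggregates the member iteration losses", {
  log <- data.frame(iteration = 1:6, epoch = 1L,
                    subject = c(1, 1, 2, 2, 2, 3),
                    bval = 1000, loss = c(1, 3, 2, 4, 6, 5))
  sl <- subject_loss(log)
  expect_equal(sl$loss[sl$subject == 1], 2)
  expect_equal(sl$loss[sl$subject == 2], 4)
  expect_equal(sl$loss[sl$subject == 3], 5)
})

test_that("training on phantoms reduces held-out error versus the untrained model", {
  train_vol <- generate_phantom(tiny_phantom(seed = 21, noise_sigma = 2))
  test_vol <- generate_phantom(tiny_phantom(seed = 22, noise_sigma = 2))
  tr <- build_pairs(train_vol)
  te <- build_pairs(test_vol)
  spec <- tiny_spec(seed = 5)
  ctrl <- training_control(epochs = 8, checkpoint_interval = 1e6, seed = 5)
  fit <- fit_srcnn(tr, spec, ctrl)
  m0 <- init_srcnn(spec)
  held_mse <- function(model) mean(vapply(te, function(p)
    mse(srcnn_forward(model, p$source), p$target), 0))
  expect_lt(held_mse(fit), held_mse(m0))
})

test_that("divergence and empty groups raise informative errors", {
  g <- rand_grid(c(6, 6, 6))
  pairs <- structure(list(list(source = g, target = g * 10, bval = 0,
                               subject = 1)), class = "dwi_pairs")
  expect_error(fit_srcnn(pairs, tiny_spec(),
                         training_control(learning_rate = 1e80, epochs = 5,
                                          checkpoint_interval = 1e6)),
               class = "dwisr_divergence_error")
  expect_error(fit_srcnn(structure(list(), class = "dwi_pairs")),
               class = "dwisr_usage_error")
  expect_error(training_control(batch_size = 2),
               class = "dwisr_config_error")
})

test_that("model methods expose coefficients, summaries and predictions", {
  vol <- generate_phantom(tiny_phantom(seed = 6))
  pairs <- build_pairs(vol)[1:2]
  class(pairs) <- "dwi_pairs"
  fit <- fit_srcnn(pairs, tiny_spec(),
                   training_control(epochs = 2, checkpoint_interval = 3))
  expect_identical(coef(fit), fit$weights)
  s <- summary(fit)
  expect_s3_class(s, "summary.srcnn")
  expect_equal(s$iterations, 4L)
  expect_output(print(fit), "trained for 4 iterations")
  # prediction upsamples by the resampling factor
  lr <- downsample(dwi_grid(vol, 1), 3)
  pred <- predict(fit, lr)
  expect_equal(dim(pred), dim(lr) * 3)
  # the output is a nonnegative magnitude
  interp <- interpolate_up(lr, 3)
  expect_gte(min(pred), 0)
  # literal range mode takes exactly the interpolated input's range
  pred_r <- predict(fit, lr, renormalize = "range")
  expect_equal(range(pred_r), range(interp))
})
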