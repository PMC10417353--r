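test_that("network output has the right shape, range and parameter scaling", {
  m <- build_unet3d(unet_config(in_channels = 3, depth = 3, base_filters = 2),
                    seed = 1)
  x <- array(rnorm(16^3 * 3), c(16, 16, 16, 3))
  p <- gliotrack:::unet_forward(m, x)$prob
  expect_identical(dim(p), c(16L, 16L, 16L))
  expect_true(all(p >= 0 & p <= 1))
  # shape not divisible by 2^depth is rejected
  expect_error(gliotrack:::unet_forward(m, array(0, c(12, 16, 16, 3))),
               "divisible")
  # all-zero input with zeroed final bias gives sigmoid(0) = 0.5 everywhere
  m$params$final_b <- 0
  p0 <- gliotrack:::unet_forward(m, array(0, c(16, 16, 16, 3)))$prob
  expect_lt(max(abs(p0 - 0.5)), 1e-12)
  # parameter count strictly increases with base_filters
  n_by_base <- vapply(c(2L, 4L, 8L), function(b)
    n_parameters(build_unet3d(unet_config(base_filters = b))), integer(1))
  expect_true(all(diff(n_by_base) > 0))
})

test_that("soft Dice loss matches its closed forms and gradients check out", {
  d <- c(8, 8, 8)
  t <- array(0, d); t[1:4, , ] <- 1
  expect_lt(soft_dice_loss(t, t), 1e-4)            # perfect prediction
  expect_gt(soft_dice_loss(1 - t, t), 1 - 1e-4)    # complete miss
  # uniform 0.5 prediction on a half-full target: closed form 0.5
  expect_equal(soft_dice_loss(array(0.5, d), t), 0.5, tolerance = 1e-4)
  expect_error(soft_dice_loss(array(0.5, d), array(0, c(4, 4, 4))), "shape")
  expect_error(soft_dice_loss(array(2, d), t), "\\[0, 1\\]")
  # analytic gradients agree with central differences through the whole net
  set.seed(1)
  m <- build_unet3d(unet_config(in_channels = 2, depth = 1, base_filters = 2),
                    seed = 3)
  x <- array(rnorm(8^3 * 2), c(8, 8, 8, 2))
  tt <- array((runif(8^3) < 0.3) * 1, c(8, 8, 8))
  f <- gliotrack:::unet_forward(m, x, keep_cache = TRUE)
  gr <- gliotrack:::unet_backward(m, f, gliotrack:::soft_dice_grad(f$prob, tt))
  loss_at <- function(mm) soft_dice_loss(gliotrack:::unet_forward(mm, x)$prob, tt)
  eps <- 1e-6
  for (nm in c("enc1_w1", "enc1_g1", "bott_w2", "dec1_w1", "final_w",
               "final_b", "enc1_be2")) {
    j <- sample(length(m$params[[nm]]), 1)
    m2 <- m
    m2$params[[nm]][j] <- m$params[[nm]][j] + eps; lp <- loss_at(m2)
    m2$params[[nm]][j] <- m$params[[nm]][j] - eps; lm <- loss_at(m2)
    expect_equal(gr[[nm]][j], (lp - lm) / (2 * eps),
                 tolerance = 1e-3, label = paste("grad", nm))
  }
})

test_that("augmentation applies identical transforms to image and label", {
  set.seed(10)
  lab <- array((runif(6^3) < 0.4) * 1, c(6, 6, 6))
  stack <- array(0, c(6, 6, 6, 2))
  stack[, , , 1] <- lab  # channel mirrors the label
  stack[, , , 2] <- rnorm(6^3)
  # p = 0: identity
  a0 <- augment_sample(stack, lab, p = 0)
  expect_identical(a0$stack, stack)
  expect_identical(a0$label, lab)
  expect_false(a0$flipped)
  # p = 1: transforms always fire and keep the correspondence exact
  for (i in 1:20) {
    a1 <- augment_sample(stack, lab, p = 1)
    expect_true(a1$flipped)
    expect_identical(a1$stack[, , , 1], a1$label)
    expect_equal(dice(a1$label, a1$label), 1)
  }
  # double flip along one axis is an involution
  f1 <- gliotrack:::flip_axis(stack, 2)
  expect_identical(gliotrack:::flip_axis(f1, 2), stack)
  # four quarter-turns restore the input
  r <- lab
  for (i in 1:4) r <- gliotrack:::rot90_axial(r, 1)
  expect_identical(r, lab)
  # flip branch fires at the configured frequency
  set.seed(42)
  flips <- vapply(1:2000, function(i)
    augment_sample(stack, lab, p = 0.5)$flipped, logical(1))
  expect_lt(abs(mean(flips) - 0.5), 0.034)  # 3 binomial SDs at n = 2000
})

test_that("early stopping fires only after the full patience window", {
  # best at epoch 5, flat afterwards
  h <- c(0.1, 0.3, 0.5, 0.6, 0.7, rep(0.7, 20))
  expect_false(should_stop(h[1:14], patience = 10))
  expect_true(should_stop(h[1:15], patience = 10))
  expect_false(should_stop(cumsum(rep(0.01, 30)), patience = 10))
  expect_false(should_stop(rep(0.5, 10), patience = 10))  # length <= patience
  # ties do not reset: plateau counts from the first best
  expect_true(should_stop(c(0.8, rep(0.8, 10)), patience = 10))
})

test_that("plateau scheduler decays the rate by its factor after each plateau", {
  expect_equal(plateau_lr(c(0.5, 0.6, 0.7), lr = 1e-3, patience = 5), 1e-3)
  # plateau of 5 non-improving epochs triggers one decay
  expect_equal(plateau_lr(c(0.7, rep(0.7, 5)), lr = 1e-3, patience = 5,
                          factor = 0.5), 5e-4)
  # two full plateaus, two decays
  expect_equal(plateau_lr(c(0.7, rep(0.7, 10)), lr = 1e-3, patience = 5,
                          factor = 0.5), 2.5e-4)
  # improvement resets the wait counter
  expect_equal(plateau_lr(c(0.7, 0.6, 0.6, 0.6, 0.6, 0.8, 0.7, 0.7),
                          lr = 1e-3, patience = 5), 1e-3)
})

test_that("a tiny network overfits one phantom and stitched inference is consistent", {
  fx <- overfit_fixture()
  best <- max(fx$fit$history$val_dice)
  expect_gte(best, 0.9)
  # training history records loss, dice and lr per epoch
  expect_identical(names(fx$fit$history),
                   c("epoch", "train_loss", "val_dice", "lr"))
  # window = volume shape is exactly the single forward pass
  whole <- predict_volume(fx$fit$model, fx$stack)
  same <- predict_volume(fx$fit$model, fx$stack,
                         window = dim(fx$stack$channels)[1:3])
  expect_identical(whole$voxels, same$voxels)
  # overlapped sliding windows agree closely with the single pass; exact
  # agreement needs windows large against the receptive field, so at this
  # scale the check is overlap-level (instance-norm statistics and padding
  # halos differ per window)
  stitched <- predict_volume(fx$fit$model, fx$stack, window = c(24, 24, 24),
                             overlap = 0.5)
  expect_gte(dice(stitched, whole), 0.9)
  expect_gte(dice(whole, fx$case$gtv1_true), 0.9)
})

test_that("training is reproducible and honors the epoch cap", {
  case <- tiny_phantom(seed = 21, gs = 16, edema_radius_mm = 9,
                       cavity_radius_mm = 4, rim_thickness_mm = 2,
                       nodule_radius_mm = 0)
  stack <- preprocess_case(case$ce_t1w, case$flair, case$brain_mask, "gtv1")
  tc <- list(stack = stack, label = case$gtv1_true$voxels)
  cfg <- train_config(lr = 1e-3, max_epochs = 2, crop_shape = c(16, 16, 16),
                      seed = 9)
  m <- build_unet3d(unet_config(base_filters = 2), seed = 4)
  f1 <- train_unet3d(m, list(tc), list(tc), cfg)
  f2 <- train_unet3d(m, list(tc), list(tc), cfg)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$model$params, f2$model$params)
  # max_epochs = 0 returns the untrained model with empty history
  f0 <- train_unet3d(m, list(tc), list(tc),
                     train_config(max_epochs = 0))
  expect_identical(f0$model$params, m$params)
  expect_identical(nrow(f0$history), 0L)
  expect_error(train_unet3d(m, list(), list(tc), cfg), "at least one")
})

test_that("predict_volume handles stub models, thresholds and padding", {
  stub <- function(x) array(0.8, dim(x)[1:3])
  stack <- channel_stack(array(rnorm(10 * 10 * 10 * 3), c(10, 10, 10, 3)),
                         spacing_mm = c(2, 2, 2))
  full <- predict_volume(stub, stack, threshold = 0.5)
  expect_equal(sum(full$voxels), 1000)
  expect_equal(full$spacing_mm, c(2, 2, 2))
  none <- predict_volume(stub, stack, threshold = 0.9)
  expect_equal(sum(none$voxels), 0)
  # a real model pads non-divisible shapes and crops back
  m <- build_unet3d(unet_config(base_filters = 2), seed = 2)
  odd <- array(rnorm(12 * 20 * 10 * 3), c(12, 20, 10, 3))
  pred <- predict_volume(m, odd)
  expect_identical(dim(pred$voxels), c(12L, 20L, 10L))
})
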