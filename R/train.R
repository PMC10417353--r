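#' Soft Dice loss
#'
#' `1 - (2*sum(p*t) + smooth) / (sum(p) + sum(t) + smooth)`, the training
#' objective for binary segmentation; always in \[0, 1\].
#'
#' @param prob probability grid in \[0, 1\].
#' @param target binary grid of the same shape.
#' @param smooth smoothing constant protecting empty masks.
#' @return scalar loss.
#' @export
soft_dice_loss <- function(prob, target, smooth = 1e-5) {
  p <- as_volume_array(prob); t <- as_volume_array(target)
  stopifnot_same_shape(p, t, "probability and target")
  if (min(p) < 0 || max(p) > 1)
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  1 - (2 * sum(p * t) + smooth) / (sum(p) + sum(t) + smooth)
}

# Gradient of the soft Dice loss wrt prob.
soft_dice_grad <- function(prob, target, smooth = 1e-5) {
  S <- sum(prob * target); P <- sum(prob); Tt <- sum(target)
  den <- P + Tt + smooth
  -(2 * target * den - (2 * S + smooth)) / den^2
}

rot90_axial <- function(a, k) {
  k <- k %% 4L
  if (k == 0L) return(a)
  nd <- length(dim(a))
  for (i in seq_len(k)) {
    a <- if (nd == 4L) aperm(a, c(2, 1, 3, 4)) else aperm(a, c(2, 1, 3))
    idx <- rev(seq_len(dim(a)[1]))
    a <- if (nd == 4L) a[idx, , , , drop = FALSE] else a[idx, , , drop = FALSE]
  }
  a
}

flip_axis <- function(a, axis) {
  nd <- length(dim(a))
  idx <- rev(seq_len(dim(a)[axis]))
  switch(axis,
         if (nd == 4L) a[idx, , , , drop = FALSE] else a[idx, , , drop = FALSE],
         if (nd == 4L) a[, idx, , , drop = FALSE] else a[, idx, , drop = FALSE],
         if (nd == 4L) a[, , idx, , drop = FALSE] else a[, , idx, drop = FALSE])
}

#' On-the-fly training augmentation
#'
#' With probability `p` applies a random axis flip, and independently with
#' probability `p` a random multiple-of-90-degree in-plane (axial) rotation.
#' The image stack and the label receive identical transforms, so the
#' voxelwise correspondence is preserved exactly. Uses the current R RNG
#' stream.
#'
#' @param stack (D,H,W,C) array or `channel_stack`.
#' @param label 3D binary array matching the stack grid.
#' @param p probability of each transform family (default 0.5).
#' @return `list(stack, label, flipped, rotated)`; `flipped`/`rotated` report
#'   whether each branch fired.
#' @export
augment_sample <- function(stack, label, p = 0.5) {
  stopifnot(p >= 0, p <= 1)
  arr <- if (inherits(stack, "channel_stack")) stack$channels else stack
  lab <- as_volume_array(label)
  flipped <- runif(1) < p
  if (flipped) {
    ax <- sample.int(3L, 1L)
    arr <- flip_axis(arr, ax)
    lab <- flip_axis(lab, ax)
  }
  rotated <- runif(1) < p
  if (rotated) {
    k <- sample.int(3L, 1L)  # 90, 180 or 270 degrees
    if (dim(arr)[1] != dim(arr)[2]) {
      rotated <- FALSE  # non-square axial plane: rotation would change shape
    } else {
      arr <- rot90_axial(arr, k)
      lab <- rot90_axial(lab, k)
    }
  }
  if (inherits(stack, "channel_stack")) {
    stack$channels <- arr
    list(stack = stack, label = lab, flipped = flipped, rotated = rotated)
  } else {
    list(stack = arr, label = lab, flipped = flipped, rotated = rotated)
  }
}

#' Early-stopping decision
#'
#' TRUE when the best (maximal) validation value occurred at least `patience`
#' epochs before the most recent one. Ties do not reset the counter: the
#' first occurrence of the best value counts.
#'
#' @param val_history numeric vector of per-epoch validation scores (higher
#'   is better), oldest first.
#' @param patience non-improving epochs tolerated (default 10).
#' @return logical.
#' @export
should_stop <- function(val_history, patience = 10L) {
  stopifnot(length(val_history) >= 1, patience >= 1)
  best <- which.max(val_history)  # first occurrence on ties
  (length(val_history) - best) >= patience
}

#' Learning rate after applying reduce-on-plateau to a validation history
#'
#' Scans the history once: whenever the score fails to improve on the best
#' seen for `patience` consecutive epochs, the rate is multiplied by
#' `factor` and the wait counter resets.
#'
#' @param val_history numeric vector, oldest first.
#' @param lr initial learning rate.
#' @param patience epochs without improvement before each reduction.
#' @param factor multiplicative decay in (0, 1).
#' @return the learning rate in force after the last epoch.
#' @export
plateau_lr <- function(val_history, lr, patience = 5L, factor = 0.5) {
  stopifnot(factor > 0, factor < 1, patience >= 1)
  best <- -Inf; wait <- 0L
  for (v in val_history) {
    if (v > best) { best <- v; wait <- 0L }
    else {
      wait <- wait + 1L
      if (wait >= patience) { lr <- lr * factor; wait <- 0L }
    }
  }
  lr
}

#' Training configuration
#'
#' @param lr initial Adam learning rate.
#' @param scheduler_patience,scheduler_factor reduce-on-plateau settings.
#' @param early_stop_patience epochs without validation improvement before
#'   stopping (default 10).
#' @param max_epochs epoch cap.
#' @param batch_size crops per gradient step.
#' @param aug_probability augmentation probability (default 0.5).
#' @param crop_shape training crop (default 128^3).
#' @param seed RNG seed for sampling, augmentation and shuffling.
#' @return object of class `train_config`.
#' @export
train_config <- function(lr = 1e-4, scheduler_patience = 5L,
                         scheduler_factor = 0.5, early_stop_patience = 10L,
                         max_epochs = 100L, batch_size = 1L,
                         aug_probability = 0.5,
                         crop_shape = c(128L, 128L, 128L), seed = 1L) {
  stopifnot(lr > 0, early_stop_patience >= 1,
            aug_probability >= 0, aug_probability <= 1,
            scheduler_factor > 0, scheduler_factor < 1)
  structure(list(lr = lr, scheduler_patience = as.integer(scheduler_patience),
                 scheduler_factor = scheduler_factor,
                 early_stop_patience = as.integer(early_stop_patience),
                 max_epochs = as.integer(max_epochs),
                 batch_size = as.integer(batch_size),
                 aug_probability = aug_probability,
                 crop_shape = as.integer(crop_shape), seed = as.integer(seed)),
            class = "train_config")
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t; bc2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

as_training_case <- function(case) {
  stopifnot(is.list(case), !is.null(case$stack), !is.null(case$label))
  list(stack = if (inherits(case$stack, "channel_stack")) case$stack$channels
               else case$stack,
       label = as_volume_array(case$label))
}

#' Train a 3D U-Net with Dice loss
#'
#' Minimizes the soft Dice loss with Adam over random (optionally augmented)
#' crops, reduces the learning rate on validation plateaus, keeps the
#' checkpoint with the best validation Dice (threshold 0.5), and stops early
#' when validation Dice has not improved for `early_stop_patience` epochs.
#'
#' @param model a `unet3d` from [build_unet3d()].
#' @param train_cases,val_cases lists of `list(stack, label)` where `stack`
#'   is a `channel_stack`/4D array and `label` a binary 3D array.
#' @param cfg a [train_config()].
#' @param verbose print per-epoch progress.
#' @return `list(model, history)`; `model` carries the best-validation
#'   parameters and `history` is a data.frame with epoch, train_loss,
#'   val_dice and lr.
#' @export
train_unet3d <- function(model, train_cases, val_cases, cfg = train_config(),
                         verbose = FALSE) {
  stopifnot(inherits(model, "unet3d"), inherits(cfg, "train_config"))
  if (length(train_cases) < 1 || length(val_cases) < 1)
    stop("need at least one training and one validation case", call. = FALSE)
  train_cases <- lapply(train_cases, as_training_case)
  val_cases <- lapply(val_cases, as_training_case)
  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        val_dice = numeric(), lr = numeric())
  if (cfg$max_epochs == 0L) return(list(model = model, history = history))

  state <- adam_init(model$params)
  lr <- cfg$lr
  val_hist <- numeric(0)
  best_dice <- -Inf; best_params <- model$params
  wait_sched <- 0L
  with_seed(cfg$seed, {
    for (epoch in seq_len(cfg$max_epochs)) {
      ord <- sample(seq_along(train_cases))
      losses <- numeric(0)
      for (ci in ord) {
        tc <- train_cases[[ci]]
        d <- dim(tc$stack)[1:3]
        cs <- pmin(cfg$crop_shape, d)
        if (all(cs == d)) {
          smp <- list(stack = tc$stack, label = tc$label)
        } else {
          smp <- extract_training_crops(tc$stack, tc$label, cs, n = 1L,
                                        rng_seed = sample.int(2^30, 1L))[[1]]
        }
        if (cfg$aug_probability > 0)
          smp <- augment_sample(smp$stack, smp$label, cfg$aug_probability)
        fwd <- unet_forward(model, smp$stack, keep_cache = TRUE)
        losses <- c(losses, soft_dice_loss(fwd$prob, smp$label))
        gp <- soft_dice_grad(fwd$prob, smp$label)
        grads <- unet_backward(model, fwd, gp)
        upd <- adam_step(model$params, grads, state, lr)
        model$params <- upd$params; state <- upd$state
      }
      vd <- vapply(val_cases, function(vc) {
        pred <- unet_forward(model, vc$stack)$prob >= 0.5
        dice(pred * 1, vc$label)
      }, numeric(1))
      val_dice <- mean(vd)
      val_hist <- c(val_hist, val_dice)
      history <- rbind(history, data.frame(epoch = epoch,
                                           train_loss = mean(losses),
                                           val_dice = val_dice, lr = lr))
      if (verbose)
        message(sprintf("epoch %3d  loss %.4f  val_dice %.4f  lr %.2e",
                        epoch, mean(losses), val_dice, lr))
      if (val_dice > best_dice) {
        best_dice <- val_dice; best_params <- model$params; wait_sched <- 0L
      } else {
        wait_sched <- wait_sched + 1L
        if (wait_sched >= cfg$scheduler_patience) {
          lr <- lr * cfg$scheduler_factor; wait_sched <- 0L
        }
      }
      if (should_stop(val_hist, cfg$early_stop_patience)) break
    }
  })
  model$params <- best_params
  list(model = model, history = history)
}
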