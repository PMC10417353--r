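# Shared phantom fixtures, built in code at test time.

# Small default phantom (48^3 at 2 mm) used across modules.
tiny_phantom <- function(seed = 1L, gs = 48L, noise_sd = 0.02, ...) {
  generate_phantom(phantom_spec(grid_shape = rep(gs, 3L),
                                spacing_mm = c(2, 2, 2), seed = seed,
                                noise_sd = noise_sd, ...))
}

# A bank of phantoms with randomized (but valid) lesion geometry, packaged
# as training cases (GTV1 target).
phantom_bank <- function(n, seed0 = 100L, gs = 48L) {
  lapply(seq_len(n), function(i) {
    s <- seed0 + i
    set.seed(s)
    cav <- runif(1, 8, 11); rim <- runif(1, 3, 4.5); nod <- runif(1, 1.5, 2.5)
    # shrink the lesion if needed so the edema sphere fits inside the brain
    cap <- 0.75 * gs - 4
    need <- cav + rim + 2 * nod
    if (need > cap - 1) {
      s <- (cap - 1) / need
      cav <- cav * s; rim <- rim * s; nod <- nod * s
      need <- cap - 1
    }
    ede <- min(need + runif(1, 1, 6), cap)
    ctr <- (gs - 1) / 2 + runif(3, -1.5, 1.5)
    case <- generate_phantom(phantom_spec(
      grid_shape = rep(gs, 3L), spacing_mm = c(2, 2, 2), seed = s,
      cavity_radius_mm = cav, rim_thickness_mm = rim, edema_radius_mm = ede,
      nodule_radius_mm = nod, cavity_center = ctr))
    stack <- preprocess_case(case$ce_t1w, case$flair, case$brain_mask, "gtv1")
    list(stack = stack, label = case$gtv1_true$voxels, case = case)
  })
}

# Random binary mask pair on a small grid (for metric oracles).
random_mask_pair <- function(d = c(10, 10, 10), p = 0.08) {
  list(a = array(runif(prod(d)) < p, d), b = array(runif(prod(d)) < p, d))
}

# O(n^2) brute-force directed Hausdorff (gt -> pred), in mm.
brute_hausdorff <- function(gt, pred, spacing) {
  cg <- which(gt != 0, arr.ind = TRUE)
  cp <- which(pred != 0, arr.ind = TRUE)
  if (nrow(cg) == 0 || nrow(cp) == 0) return(Inf)
  worst <- 0
  for (i in seq_len(nrow(cg))) {
    d2 <- colSums((t(cp) * spacing - cg[i, ] * spacing)^2)
    worst <- max(worst, min(d2))
  }
  sqrt(worst)
}

# Train a small network once per test run and memoize it; reused by the
# overfit and stitching tests.
overfit_fixture <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    case <- tiny_phantom(seed = 11L, gs = 32L)
    stack <- preprocess_case(case$ce_t1w, case$flair, case$brain_mask, "gtv1")
    tc <- list(stack = stack, label = case$gtv1_true$voxels)
    model <- build_unet3d(unet_config(base_filters = 4L), seed = 2L)
    fit <- train_unet3d(model, list(tc), list(tc),
                        train_config(lr = 1e-2, max_epochs = 50L,
                                     crop_shape = c(32L, 32L, 32L),
                                     aug_probability = 0,
                                     early_stop_patience = 50L, seed = 5L))
    cache <<- list(fit = fit, case = case, stack = stack)
    cache
  }
})
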