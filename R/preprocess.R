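#' Resample a volume onto a new grid shape
#'
#' The physical field of view is preserved: the output spacing is the input
#' spacing scaled by the shape ratio, and sampling uses the voxel-center
#' convention (so resampling onto the input shape is the identity). Images
#' are interpolated trilinearly; masks use nearest neighbor and stay binary.
#'
#' @param v `volume_grid` (or 3D array with 1 mm spacing assumed).
#' @param target_shape positive integer triple.
#' @param kind "image" (trilinear) or "mask" (nearest neighbor; input must be
#'   binary).
#' @return resampled `volume_grid`.
#' @export
resample_to_grid <- function(v, target_shape, kind = c("image", "mask")) {
  kind <- match.arg(kind)
  a <- as_volume_array(v)
  sp <- vol_spacing(v)
  target_shape <- as.integer(target_shape)
  if (length(target_shape) != 3L || any(target_shape < 1L))
    stop("`target_shape` must be a positive integer triple", call. = FALSE)
  if (kind == "mask" && !is_binary_volume(a))
    stop("kind = \"mask\" requires a binary input volume", call. = FALSE)
  out <- .resample3(a, dim(a), target_shape, if (kind == "mask") 1L else 0L)
  volume_grid(out, sp * dim(a) / target_shape,
              if (is_volume_grid(v)) v$orientation else "RAS")
}

#' Zero-mean, unit-variance normalization over nonzero voxels
#'
#' Standardizes the nonzero voxel set to mean 0 and population variance 1
#' (n denominator); voxels that are exactly zero (background/air) remain
#' exactly zero.
#'
#' @param v `volume_grid` or 3D array.
#' @return normalized volume of the same class.
#' @export
normalize_nonzero <- function(v) {
  a <- as_volume_array(v)
  nz <- a != 0
  n <- sum(nz)
  if (n < 2)
    stop("degenerate input: need at least 2 nonzero voxels", call. = FALSE)
  x <- a[nz]
  mu <- mean(x)
  sd_pop <- sqrt(mean((x - mu)^2))
  if (sd_pop == 0)
    stop("degenerate input: nonzero voxels have zero variance", call. = FALSE)
  a[nz] <- (x - mu) / sd_pop
  if (is_volume_grid(v)) volume_grid(a, v$spacing_mm, v$orientation) else a
}

#' Apply a brain mask (skull stripping with a provided mask)
#'
#' @param v `volume_grid` or array.
#' @param brain_mask binary mask of the same shape.
#' @return volume with voxels outside the mask set to 0.
#' @export
apply_brain_mask <- function(v, brain_mask) {
  a <- as_volume_array(v)
  m <- as_volume_array(brain_mask)
  stopifnot_same_shape(a, m, "volume and brain mask")
  if (!is_binary_volume(m)) stop("brain mask must be binary", call. = FALSE)
  a <- a * m
  if (is_volume_grid(v)) volume_grid(a, v$spacing_mm, v$orientation) else a
}

#' Assemble the 3-channel model input for a segmentation target
#'
#' Channel order encodes the target: for GTV1 (T2w/FLAIR target) the channels
#' are (skull-stripped FLAIR, skull-stripped CE-T1w, with-skull FLAIR); for
#' GTV2 (CE-T1w target) they are (skull-stripped CE-T1w, skull-stripped
#' FLAIR, with-skull CE-T1w). The with-skull channel helps delineate
#' resection cavities that abut the skull. Assembly is a pure selection: no
#' voxel values are altered.
#'
#' @param flair_ss,t1ce_ss skull-stripped, normalized volumes.
#' @param flair_skull,t1ce_skull with-skull, normalized volumes.
#' @param target "gtv1" or "gtv2".
#' @return `channel_stack`: a (D,H,W,3) array plus spacing and target.
#' @export
assemble_channels <- function(flair_ss, t1ce_ss, flair_skull, t1ce_skull,
                              target = c("gtv1", "gtv2")) {
  target <- match.arg(tolower(target), c("gtv1", "gtv2"))
  vols <- list(flair_ss, t1ce_ss, flair_skull, t1ce_skull)
  for (i in 2:4) stopifnot_same_shape(vols[[1]], vols[[i]], "channel volumes")
  sps <- vapply(vols, vol_spacing, numeric(3))
  if (max(abs(sps - sps[, 1])) > 1e-6)
    stop("channel volumes must share one grid (spacing mismatch)", call. = FALSE)
  chans <- if (target == "gtv1") list(flair_ss, t1ce_ss, flair_skull)
           else list(t1ce_ss, flair_ss, t1ce_skull)
  d <- dim(as_volume_array(chans[[1]]))
  arr <- array(c(as_volume_array(chans[[1]]), as_volume_array(chans[[2]]),
                 as_volume_array(chans[[3]])), c(d, 3L))
  channel_stack(arr, spacing_mm = sps[, 1], target = target)
}

#' Construct a channel stack
#'
#' @param channels (D,H,W,C) numeric array.
#' @param spacing_mm voxel spacing.
#' @param target "gtv1" or "gtv2".
#' @return object of class `channel_stack`.
#' @export
channel_stack <- function(channels, spacing_mm = c(1, 1, 1), target = "gtv1") {
  stopifnot(length(dim(channels)) == 4L)
  structure(list(channels = channels, spacing_mm = as.numeric(spacing_mm),
                 target = target), class = "channel_stack")
}

#' @export
print.channel_stack <- function(x, ...) {
  d <- dim(x$channels)
  cat(sprintf("<channel_stack> %dx%dx%d voxels, %d channels, target %s\n",
              d[1], d[2], d[3], d[4], toupper(x$target)))
  invisible(x)
}

#' Preprocess one case into a model-ready channel stack
#'
#' Runs the standard chain: resample to the common grid, normalize the
#' with-skull volumes, skull-strip with the brain mask and normalize the
#' stripped volumes, then assemble the target-specific 3-channel input.
#' Normalization happens after resampling; the with-skull channel is
#' standardized over the whole head, the stripped channels over brain only.
#'
#' @param t1ce,flair `volume_grid`s including skull.
#' @param brain_mask binary `volume_grid`.
#' @param target "gtv1" or "gtv2".
#' @param grid_shape optional target grid, e.g. `c(256, 256, 160)`; NULL
#'   keeps the native grid.
#' @return `channel_stack`.
#' @export
preprocess_case <- function(t1ce, flair, brain_mask,
                            target = c("gtv1", "gtv2"), grid_shape = NULL) {
  target <- match.arg(tolower(target), c("gtv1", "gtv2"))
  if (!is.null(grid_shape)) {
    t1ce <- resample_to_grid(t1ce, grid_shape, "image")
    flair <- resample_to_grid(flair, grid_shape, "image")
    brain_mask <- resample_to_grid(brain_mask, grid_shape, "mask")
  }
  t1_sk <- normalize_nonzero(t1ce)
  fl_sk <- normalize_nonzero(flair)
  t1_ss <- normalize_nonzero(apply_brain_mask(t1ce, brain_mask))
  fl_ss <- normalize_nonzero(apply_brain_mask(flair, brain_mask))
  assemble_channels(fl_ss, t1_ss, fl_sk, t1_sk, target)
}

#' Extract training crops from a channel stack
#'
#' Draws `n` crops of exactly `crop_shape`. With probability 0.5 a crop is
#' centered on a uniformly chosen foreground voxel of the label (clamped so
#' the crop stays inside the volume), otherwise its origin is uniform.
#' Deterministic for a fixed seed.
#'
#' @param stack `channel_stack` (or 4D array).
#' @param label binary 3D array / `volume_grid` matching the stack grid.
#' @param crop_shape integer triple, each entry at most the stack shape.
#' @param n number of crops.
#' @param rng_seed integer seed.
#' @param fg_probability probability of centering a crop on the foreground.
#' @return list of `n` elements, each `list(stack = 4D array, label = 3D
#'   array)`.
#' @export
extract_training_crops <- function(stack, label, crop_shape, n = 1L,
                                   rng_seed = 1L, fg_probability = 0.5) {
  arr <- if (inherits(stack, "channel_stack")) stack$channels else stack
  lab <- as_volume_array(label)
  d <- dim(arr)[1:3]
  stopifnot_same_shape(arr[, , , 1, drop = TRUE], lab, "stack and label")
  crop_shape <- as.integer(crop_shape)
  if (any(crop_shape > d))
    stop("crop_shape exceeds the stack shape", call. = FALSE)
  fg <- which(lab != 0, arr.ind = TRUE)
  with_seed(rng_seed, {
    lapply(seq_len(n), function(i) {
      if (nrow(fg) > 0 && runif(1) < fg_probability) {
        ctr <- fg[sample.int(nrow(fg), 1L), ]
        org <- pmin(pmax(ctr - crop_shape %/% 2, 1L), d - crop_shape + 1L)
      } else {
        org <- vapply(seq_len(3), function(ax)
          sample.int(d[ax] - crop_shape[ax] + 1L, 1L), integer(1))
      }
      ix <- lapply(1:3, function(ax) seq.int(org[ax], length.out = crop_shape[ax]))
      list(stack = arr[ix[[1]], ix[[2]], ix[[3]], , drop = FALSE],
           label = lab[ix[[1]], ix[[2]], ix[[3]], drop = FALSE])
    })
  })
}
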