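#' Configuration of the 3D U-Net
#'
#' An encoder-decoder with `depth` max-pooling levels, two 3x3x3
#' convolution + instance-norm + ReLU layers per block, skip connections by
#' channel concatenation, nearest-neighbor upsampling, and a final 1x1x1
#' convolution with sigmoid output giving a per-voxel foreground
#' probability. Filter counts double per level (base_filters at the top,
#' base_filters * 2^depth at the bottleneck).
#'
#' @param in_channels number of input channels (default 3).
#' @param depth number of downsampling levels (default 3).
#' @param base_filters filters in the first encoder block (default 32).
#' @param norm "instance" or "none".
#' @return object of class `unet_config`.
#' @export
unet_config <- function(in_channels = 3L, depth = 3L, base_filters = 32L,
                        norm = c("instance", "none")) {
  norm <- match.arg(norm)
  stopifnot(depth >= 1, base_filters >= 1, in_channels >= 1)
  structure(list(in_channels = as.integer(in_channels),
                 depth = as.integer(depth),
                 base_filters = as.integer(base_filters), norm = norm),
            class = "unet_config")
}

# He-initialized 3x3x3 conv weight stored as a (27*cin, cout) matrix.
init_conv3 <- function(cin, cout) {
  matrix(rnorm(27 * cin * cout, sd = sqrt(2 / (27 * cin))), 27 * cin, cout)
}

block_channels <- function(cfg) {
  depth <- cfg$depth; base <- cfg$base_filters
  enc_out <- base * 2^(seq_len(depth) - 1)
  enc_in <- c(cfg$in_channels, enc_out[-depth])
  bott_out <- base * 2^depth
  # decoder l receives upsampled features from below plus the skip at level l
  dec_below <- c(enc_out[-1], bott_out)  # channels arriving from below at level l
  dec_in <- dec_below + enc_out
  list(enc_in = enc_in, enc_out = enc_out, bott_in = enc_out[depth],
       bott_out = bott_out, dec_in = dec_in, dec_out = enc_out)
}

#' Build a 3D U-Net
#'
#' @param cfg a [unet_config()].
#' @param seed integer seed for weight initialization.
#' @return object of class `unet3d` holding the configuration and a named
#'   parameter list. Accepts inputs whose spatial shape is divisible by
#'   `2^depth`.
#' @export
build_unet3d <- function(cfg = unet_config(), seed = 1L) {
  stopifnot(inherits(cfg, "unet_config"))
  ch <- block_channels(cfg)
  params <- list()
  with_seed(seed, {
    add_block <- function(nm, cin, cout) {
      params[[paste0(nm, "_w1")]] <<- init_conv3(cin, cout)
      params[[paste0(nm, "_b1")]] <<- numeric(cout)
      params[[paste0(nm, "_g1")]] <<- rep(1, cout)
      params[[paste0(nm, "_be1")]] <<- numeric(cout)
      params[[paste0(nm, "_w2")]] <<- init_conv3(cout, cout)
      params[[paste0(nm, "_b2")]] <<- numeric(cout)
      params[[paste0(nm, "_g2")]] <<- rep(1, cout)
      params[[paste0(nm, "_be2")]] <<- numeric(cout)
    }
    for (l in seq_len(cfg$depth))
      add_block(paste0("enc", l), ch$enc_in[l], ch$enc_out[l])
    add_block("bott", ch$bott_in, ch$bott_out)
    for (l in seq_len(cfg$depth))
      add_block(paste0("dec", l), ch$dec_in[l], ch$dec_out[l])
    params$final_w <- matrix(rnorm(ch$dec_out[1], sd = sqrt(1 / ch$dec_out[1])),
                             ch$dec_out[1], 1)
    params$final_b <- 0
  })
  structure(list(cfg = cfg, params = params), class = "unet3d")
}

#' Number of trainable parameters
#'
#' @param model a `unet3d`.
#' @return integer parameter count.
#' @export
n_parameters <- function(model) {
  sum(vapply(model$params, length, integer(1)))
}

#' @export
print.unet3d <- function(x, ...) {
  cat(sprintf("<unet3d> depth %d, base_filters %d, in_channels %d, %s norm, %d parameters\n",
              x$cfg$depth, x$cfg$base_filters, x$cfg$in_channels, x$cfg$norm,
              n_parameters(x)))
  invisible(x)
}

# ---- layer forward/backward -------------------------------------------------

# conv3 + instance norm + ReLU, fused in C++. light = TRUE keeps no cache
# (inference); the ReLU mask is recovered from y > 0 in the backward pass.
cbr_fwd <- function(x, w, b, g, be, norm, light = FALSE) {
  fw <- .cbr_forward_cpp(x, dim(x), w, b, g, be, norm == "instance")
  if (light) return(list(y = fw$y))
  list(y = fw$y, x = x, xhat = fw$xhat, istd = fw$istd)
}

cbr_bwd <- function(gy, cache, w, g, norm) {
  use_norm <- norm == "instance"
  bw <- .cbr_backward_cpp(cache$x, dim(cache$x), w, g, cache$y, cache$xhat,
                          cache$istd, gy, use_norm)
  list(gx = bw$gx, gw = bw$gw, gb = bw$gb,
       gg = if (use_norm) bw$gg else NULL,
       gbe = if (use_norm) bw$gbe else NULL)
}

block_fwd <- function(x, p, nm, norm, light = FALSE) {
  c1 <- cbr_fwd(x, p[[paste0(nm, "_w1")]], p[[paste0(nm, "_b1")]],
                p[[paste0(nm, "_g1")]], p[[paste0(nm, "_be1")]], norm, light)
  c2 <- cbr_fwd(c1$y, p[[paste0(nm, "_w2")]], p[[paste0(nm, "_b2")]],
                p[[paste0(nm, "_g2")]], p[[paste0(nm, "_be2")]], norm, light)
  if (light) list(y = c2$y) else list(y = c2$y, c1 = c1, c2 = c2)
}

block_bwd <- function(gy, cache, p, nm, norm, grads) {
  b2 <- cbr_bwd(gy, cache$c2, p[[paste0(nm, "_w2")]],
                p[[paste0(nm, "_g2")]], norm)
  b1 <- cbr_bwd(b2$gx, cache$c1, p[[paste0(nm, "_w1")]],
                p[[paste0(nm, "_g1")]], norm)
  grads[[paste0(nm, "_w2")]] <- b2$gw; grads[[paste0(nm, "_b2")]] <- b2$gb
  grads[[paste0(nm, "_w1")]] <- b1$gw; grads[[paste0(nm, "_b1")]] <- b1$gb
  if (norm == "instance") {
    grads[[paste0(nm, "_g2")]] <- b2$gg; grads[[paste0(nm, "_be2")]] <- b2$gbe
    grads[[paste0(nm, "_g1")]] <- b1$gg; grads[[paste0(nm, "_be1")]] <- b1$gbe
  }
  b1$gx
}

check_unet_input <- function(model, x) {
  d <- dim(x)
  if (length(d) != 4L || d[4] != model$cfg$in_channels)
    stop("input must be a (D,H,W,", model$cfg$in_channels, ") array",
         call. = FALSE)
  if (any(d[1:3] %% 2^model$cfg$depth != 0))
    stop("input spatial shape must be divisible by 2^depth = ",
         2^model$cfg$depth, call. = FALSE)
  invisible(d)
}

# Full forward pass. keep_cache = TRUE retains every intermediate needed by
# unet_backward (training); FALSE is the memory-lean inference path.
unet_forward <- function(model, x, keep_cache = FALSE) {
  check_unet_input(model, x)
  p <- model$params; depth <- model$cfg$depth; norm <- model$cfg$norm
  light <- !keep_cache
  enc <- vector("list", depth)
  pool_idx <- vector("list", depth)
  pool_dim <- vector("list", depth)
  cur <- x
  for (l in seq_len(depth)) {
    enc[[l]] <- block_fwd(cur, p, paste0("enc", l), norm, light)
    pl <- .maxpool3_forward(enc[[l]]$y, dim(enc[[l]]$y))
    pool_idx[[l]] <- pl$idx
    pool_dim[[l]] <- dim(enc[[l]]$y)
    cur <- pl$y
  }
  bott <- block_fwd(cur, p, "bott", norm, light)
  cur <- bott$y
  dec <- vector("list", depth)
  up_ch <- integer(depth)
  for (l in rev(seq_len(depth))) {
    up <- .upsample3_forward(cur, dim(cur))
    up_ch[l] <- dim(up)[4]
    sk <- enc[[l]]$y
    cat_in <- array(c(up, sk), c(dim(up)[1:3], dim(up)[4] + dim(sk)[4]))
    dec[[l]] <- block_fwd(cat_in, p, paste0("dec", l), norm, light)
    cur <- dec[[l]]$y
  }
  fm <- matrix(cur, ncol = dim(cur)[4])
  z <- drop(fm %*% p$final_w) + p$final_b
  prob <- 1 / (1 + exp(-z))
  dim(prob) <- dim(cur)[1:3]
  if (!keep_cache) return(list(prob = prob))
  list(prob = prob, enc = enc, bott = bott, dec = dec, fm = fm,
       pool_idx = pool_idx, pool_dim = pool_dim, up_ch = up_ch, x = x)
}

# Backward from dL/dprob; returns the named gradient list.
unet_backward <- function(model, fwd, gprob) {
  p <- model$params; depth <- model$cfg$depth; norm <- model$cfg$norm
  grads <- new.env(parent = emptyenv())
  prob <- fwd$prob
  gz <- as.numeric(gprob) * as.numeric(prob) * (1 - as.numeric(prob))
  grads$final_w <- crossprod(fwd$fm, gz)
  grads$final_b <- sum(gz)
  gcur <- array(matrix(gz, ncol = 1) %*% t(p$final_w), dim(fwd$dec[[1]]$y))
  gskip <- vector("list", depth)
  for (l in seq_len(depth)) {
    gcat <- block_bwd(gcur, fwd$dec[[l]], p, paste0("dec", l), norm, grads)
    nup <- fwd$up_ch[l]
    gup <- gcat[, , , seq_len(nup), drop = FALSE]
    gskip[[l]] <- gcat[, , , nup + seq_len(dim(gcat)[4] - nup), drop = FALSE]
    glower <- .upsample3_backward(gup, dim(gup) %/% c(2L, 2L, 2L, 1L))
    if (l < depth) {
      gcur <- glower  # gradient wrt dec[[l+1]]$y
    } else {
      gbott_in <- block_bwd(glower, fwd$bott, p, "bott", norm, grads)
    }
  }
  # encoder, from the bottom up
  g_from_below <- gbott_in
  for (l in rev(seq_len(depth))) {
    gy <- .maxpool3_backward(g_from_below, fwd$pool_idx[[l]], fwd$pool_dim[[l]]) +
      gskip[[l]]
    g_from_below <- block_bwd(gy, fwd$enc[[l]], p, paste0("enc", l), norm, grads)
  }
  as.list(grads)
}

#' Run the network on a full channel stack with sliding windows
#'
#' Window probabilities are blended over overlaps with a center-weighted
#' (Gaussian) importance map — voxels near a window face, where the
#' zero-padding halo distorts the receptive field, contribute less than
#' voxels a window predicts from its center — then thresholded. If the
#' window exceeds the volume (or the volume shape is not divisible by
#' `2^depth`), the volume is zero-padded to the next valid shape, predicted
#' in one pass, and cropped back.
#'
#' @param model a trained `unet3d`, or a function mapping a (D,H,W,C) array
#'   to a (D,H,W) probability array (useful for stubs and oracles).
#' @param stack `channel_stack` or 4D array.
#' @param window integer triple, each divisible by `2^depth`; NULL = whole
#'   volume.
#' @param overlap fraction of window overlap between neighboring positions.
#' @param threshold probability cutoff for the binary output.
#' @param sigma_scale width of the Gaussian importance map as a fraction of
#'   the window (nnU-Net-style 1/8 default).
#' @return binary `volume_grid` of the input spatial shape.
#' @export
predict_volume <- function(model, stack, window = NULL, overlap = 0.5,
                           threshold = 0.5, sigma_scale = 0.125) {
  arr <- if (inherits(stack, "channel_stack")) stack$channels else stack
  sp <- if (inherits(stack, "channel_stack")) stack$spacing_mm else c(1, 1, 1)
  d <- dim(arr)[1:3]
  mdl_fun <- if (is.function(model)) model
             else function(x) unet_forward(model, x)$prob
  mult <- if (is.function(model)) 1L else 2L^model$cfg$depth
  pd <- as.integer(ceiling(d / mult) * mult)
  if (is.null(window)) window <- pd
  window <- pmin(as.integer(window), pd)
  if (!is.function(model) && any(window %% mult != 0))
    stop("window must be divisible by 2^depth = ", mult, call. = FALSE)
  pd <- pmax(pd, window)
  padded <- array(0, c(pd, dim(arr)[4]))
  padded[seq_len(d[1]), seq_len(d[2]), seq_len(d[3]), ] <- arr
  acc <- array(0, pd)
  cnt <- array(0, pd)
  gauss1 <- function(w) {
    x <- seq_len(w) - (w + 1) / 2
    g <- exp(-x^2 / (2 * (sigma_scale * w)^2))
    pmax(g, 1e-8)
  }
  wmap <- outer(outer(gauss1(window[1]), gauss1(window[2])), gauss1(window[3]))
  starts <- function(n, w) {
    stride <- max(1L, as.integer(round(w * (1 - overlap))))
    unique(c(seq.int(1L, max(1L, n - w + 1L), by = stride), n - w + 1L))
  }
  for (i in starts(pd[1], window[1]))
    for (j in starts(pd[2], window[2]))
      for (k in starts(pd[3], window[3])) {
        ii <- seq.int(i, length.out = window[1])
        jj <- seq.int(j, length.out = window[2])
        kk <- seq.int(k, length.out = window[3])
        pr <- mdl_fun(padded[ii, jj, kk, , drop = FALSE])
        acc[ii, jj, kk] <- acc[ii, jj, kk] + pr * wmap
        cnt[ii, jj, kk] <- cnt[ii, jj, kk] + wmap
      }
  prob <- acc / cnt
  out <- (prob >= threshold) * 1
  volume_grid(array(out[seq_len(d[1]), seq_len(d[2]), seq_len(d[3])], d), sp)
}
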