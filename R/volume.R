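#' A 3D voxel grid with physical spacing
#'
#' `volume_grid` is the universal image carrier of the package: a 3D numeric
#' array plus voxel spacing in millimetres and an orientation label. All
#' coordinates in the package are 0-based voxel indices; physical positions
#' refer to voxel centers.
#'
#' @param voxels 3D numeric (or logical) array.
#' @param spacing_mm positive numeric triple, voxel edge lengths in mm.
#' @param orientation axis-order label carried through I/O (default "RAS").
#' @return An object of class `volume_grid`.
#' @export
volume_grid <- function(voxels, spacing_mm = c(1, 1, 1), orientation = "RAS") {
  if (length(dim(voxels)) != 3L)
    stop("`voxels` must be a 3D array", call. = FALSE)
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) != 3L || any(!is.finite(spacing_mm)) || any(spacing_mm <= 0))
    stop("`spacing_mm` must be a positive numeric triple", call. = FALSE)
  if (is.logical(voxels)) voxels <- array(as.numeric(voxels), dim(voxels))
  if (any(!is.finite(voxels)))
    stop("`voxels` must contain finite values only", call. = FALSE)
  structure(list(voxels = voxels, spacing_mm = spacing_mm,
                 orientation = orientation),
            class = "volume_grid")
}

#' @export
print.volume_grid <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<volume_grid> %d x %d x %d voxels, spacing %.3g x %.3g x %.3g mm [%s]\n",
              d[1], d[2], d[3], x$spacing_mm[1], x$spacing_mm[2], x$spacing_mm[3],
              x$orientation))
  cat(sprintf("  range [%.4g, %.4g]\n", min(x$voxels), max(x$voxels)))
  invisible(x)
}

#' @export
dim.volume_grid <- function(x) dim(x$voxels)

is_volume_grid <- function(x) inherits(x, "volume_grid")

as_volume_array <- function(v) {
  if (is_volume_grid(v)) v$voxels else v
}

vol_spacing <- function(v, default = c(1, 1, 1)) {
  if (is_volume_grid(v)) v$spacing_mm else default
}

#' Test whether a grid is binary
#'
#' @param v `volume_grid` or array.
#' @return TRUE if every voxel is 0 or 1.
#' @export
is_binary_volume <- function(v) {
  a <- as_volume_array(v)
  all(a == 0 | a == 1)
}

stopifnot_same_shape <- function(a, b, what = "volumes") {
  if (!identical(dim(as_volume_array(a)), dim(as_volume_array(b))))
    stop(sprintf("%s must share one grid (shape mismatch)", what), call. = FALSE)
  invisible(TRUE)
}

#' Volume of a binary mask in cubic centimetres
#'
#' Voxel count times the physical voxel volume. One cc = 1000 mm^3.
#'
#' @param mask binary `volume_grid` or array.
#' @param spacing_mm spacing override when `mask` is a bare array.
#' @return Volume in cc.
#' @export
mask_volume_cc <- function(mask, spacing_mm = NULL) {
  a <- as_volume_array(mask)
  sp <- if (is.null(spacing_mm)) vol_spacing(mask) else as.numeric(spacing_mm)
  if (any(sp <= 0)) stop("spacing must be positive", call. = FALSE)
  sum(a != 0) * prod(sp) / 1000
}
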