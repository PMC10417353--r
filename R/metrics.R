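#' Dice similarity coefficient
#'
#' `2|A n B| / (|A| + |B|)`. Two empty masks are in perfect agreement and
#' score 1 by convention.
#'
#' @param a,b binary grids of identical shape.
#' @return Dice in \[0, 1\].
#' @export
dice <- function(a, b) {
  x <- as_volume_array(a) != 0; y <- as_volume_array(b) != 0
  stopifnot_same_shape(x, y, "masks")
  denom <- sum(x) + sum(y)
  if (denom == 0) return(1)
  2 * sum(x & y) / denom
}

#' Jaccard coefficient
#'
#' `|A n B| / (A u B)`; related to Dice by J = D / (2 - D). Penalizes poor
#' overlap more strongly than Dice. Two empty masks score 1.
#'
#' @inheritParams dice
#' @return Jaccard in \[0, 1\].
#' @export
jaccard <- function(a, b) {
  x <- as_volume_array(a) != 0; y <- as_volume_array(b) != 0
  stopifnot_same_shape(x, y, "masks")
  u <- sum(x | y)
  if (u == 0) return(1)
  sum(x & y) / u
}

#' Directed Hausdorff distance, ground truth to prediction
#'
#' The largest, over ground-truth voxels, of the Euclidean distance (between
#' voxel centers, in mm) to the closest prediction voxel. Deliberately
#' directed and un-percentiled; it is zero whenever the ground truth is a
#' subset of the prediction. Computed with an exact Euclidean distance
#' transform of the prediction.
#'
#' @param gt,pred binary grids of identical shape.
#' @param spacing_mm voxel spacing (taken from `gt` if it is a
#'   `volume_grid`).
#' @param symmetric if TRUE, returns the max of both directed distances.
#' @return distance in mm; `Inf` (with a warning) if either mask is empty.
#' @export
hausdorff <- function(gt, pred, spacing_mm = NULL, symmetric = FALSE) {
  g <- as_volume_array(gt) != 0; p <- as_volume_array(pred) != 0
  stopifnot_same_shape(g, p, "masks")
  sp <- if (is.null(spacing_mm)) vol_spacing(gt) else as.numeric(spacing_mm)
  if (!any(g) || !any(p)) {
    warning("empty mask: Hausdorff distance undefined, returning Inf")
    return(Inf)
  }
  directed <- function(from, to) {
    d2 <- .edt3_sq(to, dim(to), sp)
    sqrt(max(d2[from]))
  }
  h <- directed(g, p)
  if (symmetric) h <- max(h, directed(p, g))
  h
}

#' Evaluate a predicted mask against ground truth
#'
#' @param pred,gt binary grids of identical shape.
#' @param spacing_mm voxel spacing in mm.
#' @return object of class `metrics_report`: list with `dice`, `jaccard`,
#'   `hausdorff_mm`.
#' @export
evaluate_case <- function(pred, gt, spacing_mm = NULL) {
  res <- list(dice = dice(gt, pred),
              jaccard = jaccard(gt, pred),
              hausdorff_mm = hausdorff(gt, pred, spacing_mm))
  structure(res, class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("Dice %.4f | Jaccard %.4f | Hausdorff %.2f mm\n",
              x$dice, x$jaccard, x$hausdorff_mm))
  invisible(x)
}

#' Evaluate a batch of mask pairs into a per-case table
#'
#' @param preds,gts lists of binary grids.
#' @param spacing_mm voxel spacing shared by all cases.
#' @param ids optional case identifiers.
#' @return data.frame with columns id, dice, jaccard, hausdorff_mm.
#' @export
evaluate_batch <- function(preds, gts, spacing_mm = NULL, ids = NULL) {
  stopifnot(length(preds) == length(gts))
  if (is.null(ids)) ids <- seq_along(preds)
  rows <- lapply(seq_along(preds), function(i) {
    r <- evaluate_case(preds[[i]], gts[[i]], spacing_mm)
    data.frame(id = ids[i], dice = r$dice, jaccard = r$jaccard,
               hausdorff_mm = r$hausdorff_mm)
  })
  do.call(rbind, rows)
}
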