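#' Multi-level Otsu thresholds
#'
#' Splits a set of intensities into `n_classes` groups by choosing
#' `n_classes - 1` thresholds on a binned histogram that maximize the
#' between-class variance (the multi-level generalization of Otsu's
#' criterion). The search is exact over the histogram: a dynamic program
#' equivalent to exhaustive enumeration of all threshold tuples.
#'
#' @param values numeric vector (at least `n_classes` distinct values).
#' @param n_classes number of intensity classes (default 4).
#' @param n_bins histogram bins (default 128).
#' @return object of class `otsu_result`: `thresholds` (ascending, length
#'   `n_classes - 1`), `n_classes`, `n_bins`, and `classify`, a function
#'   mapping intensities to class labels 1..n_classes.
#' @export
multi_otsu_thresholds <- function(values, n_classes = 4L, n_bins = 128L) {
  values <- as.numeric(values[is.finite(values)])
  n_classes <- as.integer(n_classes)
  if (length(unique(values)) < n_classes)
    stop("degenerate input: need at least n_classes distinct values",
         call. = FALSE)
  rng <- range(values)
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  centers <- (breaks[-1] + breaks[-length(breaks)]) / 2
  bin <- pmin(pmax(findInterval(values, breaks, rightmost.closed = TRUE), 1L),
              n_bins)
  counts <- tabulate(bin, nbins = n_bins)
  cuts <- .multiotsu_split(as.numeric(counts), centers, n_classes)
  thresholds <- vapply(cuts, function(b) {
    nxt <- b + which(counts[(b + 1):n_bins] > 0)[1]  # next occupied bin
    (centers[b] + centers[nxt]) / 2
  }, numeric(1))
  classify <- function(x) findInterval(x, thresholds) + 1L
  structure(list(thresholds = thresholds, n_classes = n_classes,
                 n_bins = n_bins, breaks = breaks, classify = classify),
            class = "otsu_result")
}

#' @export
print.otsu_result <- function(x, ...) {
  cat(sprintf("<otsu_result> %d classes, thresholds: %s\n", x$n_classes,
              paste(signif(x$thresholds, 5), collapse = ", ")))
  invisible(x)
}

#' Remove the resection cavity from a GTV2 segmentation
#'
#' Clusters the CE-T1w intensities inside the GTV2 mask into `n_classes`
#' groups by multi-level Otsu thresholding and removes the lowest-intensity
#' class — the dark resection cavity — leaving the residual enhancing
#' lesion. All higher classes are retained. The output is always a subset of
#' the input mask. If the intensities inside the mask are too uniform to
#' split, the mask is returned unchanged with a warning.
#'
#' @param t1ce CE-T1w `volume_grid` or array (raw or normalized; Otsu
#'   thresholds are invariant to affine intensity rescaling up to binning).
#' @param gtv2_mask nonempty binary grid.
#' @param n_classes Otsu classes (default 4).
#' @param n_bins histogram bins (default 128).
#' @param largest_component if TRUE, keep only the largest connected
#'   component of the result (off by default).
#' @return binary `volume_grid`: the enhancing-lesion (ENH) mask.
#' @export
remove_cavity <- function(t1ce, gtv2_mask, n_classes = 4L, n_bins = 128L,
                          largest_component = FALSE) {
  a <- as_volume_array(t1ce)
  m <- as_volume_array(gtv2_mask) != 0
  stopifnot_same_shape(a, m, "image and mask")
  if (!any(m)) stop("GTV2 mask is empty", call. = FALSE)
  sp <- vol_spacing(t1ce, vol_spacing(gtv2_mask))
  otsu <- tryCatch(multi_otsu_thresholds(a[m], n_classes, n_bins),
                   error = function(e) NULL)
  if (is.null(otsu)) {
    warning("degenerate intensities inside GTV2: cannot separate the cavity; ",
            "returning the mask unchanged")
    return(volume_grid(array(as.numeric(m), dim(a)), sp))
  }
  enh <- m & (a > otsu$thresholds[1])
  if (largest_component && any(enh)) enh <- largest_cc(enh)
  volume_grid(array(as.numeric(enh), dim(a)), sp)
}

# 6-connected largest component by flood fill.
largest_cc <- function(mask) {
  d <- dim(mask)
  labels <- array(0L, d)
  idx <- which(mask)
  lab <- 0L
  nb <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
              c(0, 0, 1), c(0, 0, -1))
  coord <- arrayInd(idx, d)
  pos <- array(0L, d); pos[idx] <- seq_along(idx)
  visited <- logical(length(idx))
  sizes <- integer(0)
  for (s in seq_along(idx)) {
    if (visited[s]) next
    lab <- lab + 1L
    queue <- s; visited[s] <- TRUE; size <- 0L
    while (length(queue)) {
      cur <- queue[length(queue)]; queue <- queue[-length(queue)]
      size <- size + 1L
      labels[idx[cur]] <- lab
      cc <- coord[cur, ]
      for (k in seq_len(6)) {
        q <- cc + nb[k, ]
        if (any(q < 1) || any(q > d)) next
        pj <- pos[q[1], q[2], q[3]]
        if (pj > 0L && !visited[pj]) { visited[pj] <- TRUE; queue <- c(queue, pj) }
      }
    }
    sizes[lab] <- size
  }
  labels == which.max(sizes)
}
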