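#' Write a phantom case as NIfTI files plus a JSON sidecar
#'
#' Writes `ce_t1w.nii.gz`, `flair.nii.gz`, `brain_mask.nii.gz`,
#' `gtv1.nii.gz`, `gtv2.nii.gz` (and `skull_mask.nii.gz`) plus `case.json`
#' recording the generating spec and analytic volumes.
#'
#' @param case a `phantom_case`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_phantom_case <- function(case, dir) {
  stopifnot(inherits(case, "phantom_case"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(v, name) {
    img <- RNifti::asNifti(v$voxels)
    RNifti::pixdim(img) <- v$spacing_mm
    RNifti::writeNifti(img, file.path(dir, paste0(name, ".nii.gz")))
  }
  wr(case$ce_t1w, "ce_t1w"); wr(case$flair, "flair")
  wr(case$brain_mask, "brain_mask"); wr(case$skull_mask, "skull_mask")
  wr(case$gtv1_true, "gtv1"); wr(case$gtv2_true, "gtv2")
  spec <- case$spec
  spec$tissue_means <- lapply(spec$tissue_means, as.list)
  jsonlite::write_json(
    list(spec = unclass(spec),
         analytic_gtv1_cc = case$analytic_gtv1_cc,
         analytic_gtv2_cc = case$analytic_gtv2_cc),
    file.path(dir, "case.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

read_nifti_grid <- function(path) {
  if (!file.exists(path)) stop("missing file: ", path, call. = FALSE)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e)
                    stop("cannot read NIfTI file ", path, ": ",
                         conditionMessage(e), call. = FALSE))
  volume_grid(array(as.numeric(img), dim(img)[1:3]),
              RNifti::pixdim(img)[1:3])
}

#' Load a case directory of NIfTI volumes
#'
#' Expects `ce_t1w.nii.gz`, `flair.nii.gz` and `brain_mask.nii.gz`; GTV
#' masks are loaded when present (otherwise the bundle is inference-only).
#' Masks are validated binary and all grids must agree in shape and spacing.
#'
#' @param dir directory written by [write_phantom_case()] or with the same
#'   layout.
#' @return list of `volume_grid`s (`ce_t1w`, `flair`, `brain_mask`, and
#'   optionally `gtv1`, `gtv2`, `skull_mask`) plus `meta` (parsed sidecar,
#'   if present).
#' @export
load_case <- function(dir) {
  p <- function(nm) file.path(dir, paste0(nm, ".nii.gz"))
  out <- list(ce_t1w = read_nifti_grid(p("ce_t1w")),
              flair = read_nifti_grid(p("flair")),
              brain_mask = read_nifti_grid(p("brain_mask")))
  for (nm in c("gtv1", "gtv2", "skull_mask"))
    if (file.exists(p(nm))) out[[nm]] <- read_nifti_grid(p(nm))
  for (nm in intersect(names(out), c("brain_mask", "gtv1", "gtv2", "skull_mask")))
    if (!is_binary_volume(out[[nm]]))
      stop("mask ", p(nm), " is not binary", call. = FALSE)
  ref <- out$ce_t1w
  for (nm in names(out)) {
    stopifnot_same_shape(ref, out[[nm]], paste0("volumes in ", dir))
    if (max(abs(out[[nm]]$spacing_mm - ref$spacing_mm)) > 1e-4)
      stop("spacing mismatch in ", dir, " for ", nm, call. = FALSE)
  }
  sidecar <- file.path(dir, "case.json")
  if (file.exists(sidecar)) out$meta <- jsonlite::read_json(sidecar)
  out
}

#' Write a longitudinal phantom series to disk
#'
#' One sub-directory per visit (`visit_01`, ...) plus `visits.csv` with the
#' ground-truth volumes.
#'
#' @param series output of [generate_series()].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_series <- function(series, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(series$cases))
    write_phantom_case(series$cases[[i]],
                       file.path(dir, sprintf("visit_%02d", i)))
  v <- series$visits
  write.csv(data.frame(visit_index = v$visit_index, date_days = v$date_days,
                       days_since_rt = v$days_since_rt,
                       gtv1_cc_true = v$gtv1_cc, enh_cc_true = v$enh_cc),
            file.path(dir, "visits.csv"), row.names = FALSE)
  invisible(dir)
}

#' Read a visit table for longitudinal scoring
#'
#' Accepts CSV with columns `date_days` (or `visit_date_days`), `flair_cc`,
#' `enh_cc` and optionally `days_since_rt`, `is_baseline`.
#'
#' @param path CSV file.
#' @return a [visit_series()].
#' @export
read_visits <- function(path) {
  df <- read.csv(path)
  if (is.null(df$date_days) && !is.null(df$visit_date_days))
    df$date_days <- df$visit_date_days
  need <- c("date_days", "flair_cc", "enh_cc")
  if (!all(need %in% names(df)))
    stop("visits file must contain columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  visit_series(df$date_days, df$flair_cc, df$enh_cc,
               if (!is.null(df$days_since_rt)) df$days_since_rt else NA,
               if (!is.null(df$is_baseline)) as.logical(df$is_baseline))
}

#' Write the longitudinal tracking report
#'
#' Emits `scores.json` (per-visit score, sub-grade, percent changes and rule
#' trace), `volumes.csv` (a plotting-ready table), and a static
#' volume-versus-time chart with score annotations (`volumes_plot.pdf`).
#'
#' @param visits a [visit_series()].
#' @param results output of [classify_series()].
#' @param dir output directory.
#' @param plot write the PDF chart (default TRUE).
#' @return the score table, invisibly.
#' @export
write_tracking_report <- function(visits, results, dir, plot = TRUE) {
  if (length(results) < 1) stop("empty results", call. = FALSE)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tab <- score_table(visits, results)
  write.csv(tab, file.path(dir, "volumes.csv"), row.names = FALSE)
  js <- lapply(seq_along(results), function(i) {
    r <- results[[i]]
    list(visit_index = i, date_days = visits$date_days[i],
         major = r$major, sub = if (r$sub == "none") NULL else r$sub,
         score = format_score(r),
         pct_flair = if (is.na(r$pct_flair)) NULL else r$pct_flair,
         pct_enh = if (is.na(r$pct_enh)) NULL else r$pct_enh,
         rationale = as.list(r$rationale))
  })
  jsonlite::write_json(js, file.path(dir, "scores.json"), auto_unbox = TRUE,
                       digits = NA)
  if (plot) {
    long <- rbind(
      data.frame(date_days = tab$date_days, volume_cc = tab$flair_cc,
                 lesion = "T2w/FLAIR"),
      data.frame(date_days = tab$date_days, volume_cc = tab$enh_cc,
                 lesion = "ENH (CE-T1w)"))
    gp <- ggplot2::ggplot(long,
            ggplot2::aes(x = date_days, y = volume_cc, color = lesion)) +
      ggplot2::geom_line() + ggplot2::geom_point() +
      ggplot2::annotate("text", x = tab$date_days,
                        y = max(long$volume_cc) * 1.06,
                        label = paste0("BT-RADS ", toupper(tab$score)),
                        size = 3) +
      ggplot2::labs(x = "days since surgery", y = "lesion volume (cc)",
                    color = NULL, title = "Longitudinal lesion tracking") +
      ggplot2::theme_minimal()
    ggplot2::ggsave(file.path(dir, "volumes_plot.pdf"), gp, width = 7,
                    height = 4.5, device = "pdf")
  }
  invisible(tab)
}
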