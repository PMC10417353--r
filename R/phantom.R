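#' Specification of a synthetic post-operative MRI phantom
#'
#' Describes one synthetic post-surgical case: a spherical resection cavity
#' surrounded by a thin enhancing rim, an optional residual enhancing nodule
#' seated on the rim, and a larger spherical FLAIR-hyperintense edema region
#' that contains all of them. Geometry is spherical so every ground-truth
#' volume has a closed form. A blood-product crescent (hyperintense on FLAIR)
#' is painted inside the edema adjacent to the rim; it carries no separate
#' mask.
#'
#' The ground-truth radiotherapy targets are nested: GTV2 (the high-dose
#' target on CE-T1w) is cavity + rim + nodule, while GTV1 (the lower-dose
#' target on T2w/FLAIR) is the edema sphere united with GTV2, so GTV2 is
#' always a subset of GTV1.
#'
#' @param grid_shape integer triple of voxel counts (default 64^3).
#' @param spacing_mm positive voxel spacing in mm (default 2 mm isotropic).
#' @param seed integer seed controlling the Gaussian noise field.
#' @param cavity_center cavity center in 0-based voxel coordinates; default
#'   is the grid center.
#' @param cavity_radius_mm,rim_thickness_mm,edema_radius_mm lesion geometry in
#'   mm; `edema_radius_mm` must be at least `cavity_radius_mm +
#'   rim_thickness_mm` so GTV2 nests inside GTV1.
#' @param nodule_radius_mm residual enhancing nodule radius (0 = none). A
#'   nonzero nodule is placed just outside the rim along +x and must fit
#'   inside the edema sphere.
#' @param noise_sd Gaussian noise standard deviation as a fraction of the
#'   tissue intensity scale (100 arbitrary units).
#' @param tissue_means per-modality named intensity means; see
#'   [default_tissue_means()].
#' @param cavity_at_skull place the cavity tangent to the inner brain surface
#'   (so the resection abuts the skull); targets are clipped to the brain.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(64, 64, 64),
                         spacing_mm = c(2, 2, 2),
                         seed = 1L,
                         cavity_center = NULL,
                         cavity_radius_mm = 10,
                         rim_thickness_mm = 4,
                         edema_radius_mm = 22,
                         nodule_radius_mm = 3,
                         noise_sd = 0.02,
                         tissue_means = default_tissue_means(),
                         cavity_at_skull = FALSE) {
  grid_shape <- as.integer(grid_shape)
  spacing_mm <- as.numeric(spacing_mm)
  if (length(grid_shape) != 3L || any(grid_shape < 8L))
    stop("`grid_shape` must be an integer triple of at least 8 voxels per axis",
         call. = FALSE)
  if (any(spacing_mm <= 0)) stop("`spacing_mm` must be positive", call. = FALSE)
  if (cavity_radius_mm <= 0 || rim_thickness_mm <= 0)
    stop("cavity radius and rim thickness must be positive", call. = FALSE)
  if (nodule_radius_mm < 0 || noise_sd < 0)
    stop("nodule radius and noise must be non-negative", call. = FALSE)
  if (edema_radius_mm < cavity_radius_mm + rim_thickness_mm)
    stop("`edema_radius_mm` must be >= cavity_radius_mm + rim_thickness_mm ",
         "(GTV2 must nest inside GTV1)", call. = FALSE)
  if (nodule_radius_mm > 0 &&
      cavity_radius_mm + rim_thickness_mm + 2 * nodule_radius_mm > edema_radius_mm)
    stop("nodule does not fit inside the edema sphere: require ",
         "cavity + rim + 2*nodule <= edema radius", call. = FALSE)
  half_extent <- min(grid_shape * spacing_mm) / 2
  if (max(edema_radius_mm, cavity_radius_mm, rim_thickness_mm,
          nodule_radius_mm) >= half_extent)
    stop("grid too small: all radii must be strictly smaller than half the ",
         "physical extent", call. = FALSE)
  stopifnot(is.list(tissue_means),
            all(c("ce_t1w", "flair") %in% names(tissue_means)))
  classes <- c("background", "brain", "skull", "cavity", "rim_enhancement",
               "edema", "blood_product")
  for (m in c("ce_t1w", "flair"))
    if (!all(classes %in% names(tissue_means[[m]])))
      stop("tissue_means$", m, " must name all tissue classes", call. = FALSE)
  structure(list(grid_shape = grid_shape, spacing_mm = spacing_mm,
                 seed = as.integer(seed), cavity_center = cavity_center,
                 cavity_radius_mm = cavity_radius_mm,
                 rim_thickness_mm = rim_thickness_mm,
                 edema_radius_mm = edema_radius_mm,
                 nodule_radius_mm = nodule_radius_mm,
                 noise_sd = noise_sd, tissue_means = tissue_means,
                 cavity_at_skull = cavity_at_skull),
            class = "phantom_spec")
}

#' Default per-modality tissue intensity means
#'
#' Arbitrary-unit means (tissue scale 100) chosen for the qualitative
#' contrasts of post-operative MRI: on CE-T1w the cavity is dark and the
#' rim/nodule enhance brightly while edema is isointense to brain; on FLAIR
#' the edema and blood product are hyperintense and the cavity fluid is
#' suppressed.
#'
#' @return list with named numeric vectors `ce_t1w` and `flair`.
#' @export
default_tissue_means <- function() {
  list(
    ce_t1w = c(background = 0, brain = 100, skull = 150, cavity = 30,
               rim_enhancement = 200, edema = 100, blood_product = 110),
    flair = c(background = 0, brain = 100, skull = 60, cavity = 40,
              rim_enhancement = 140, edema = 190, blood_product = 230)
  )
}

# Evaluate an expression with a private RNG stream, restoring global state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Closed-form ground-truth target volumes of a phantom spec
#'
#' GTV2 is the sphere of radius cavity + rim plus the (disjoint) nodule
#' sphere; GTV1 is the edema sphere. Volumes in cc.
#'
#' @param spec a [phantom_spec()].
#' @return named numeric `c(gtv1_cc, gtv2_cc)`.
#' @export
analytic_volumes <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  sph <- function(r) 4 / 3 * pi * r^3
  r2 <- spec$cavity_radius_mm + spec$rim_thickness_mm
  c(gtv1_cc = sph(spec$edema_radius_mm) / 1000,
    gtv2_cc = (sph(r2) + sph(spec$nodule_radius_mm)) / 1000)
}

#' Generate one synthetic post-operative MRI phantom
#'
#' Builds co-registered CE-T1w and FLAIR volumes (with skull), brain and
#' skull masks, and ground-truth GTV1/GTV2 masks. Deterministic for a fixed
#' spec and seed. Intensities are tissue means plus Gaussian noise; air
#' outside the head stays exactly zero.
#'
#' @param spec a [phantom_spec()].
#' @return An object of class `phantom_case`: fields `ce_t1w`, `flair`
#'   (`volume_grid`s including skull), `brain_mask`, `skull_mask`,
#'   `gtv1_true`, `gtv2_true`, `enh_true` (rim + nodule), `cavity_true`,
#'   `analytic_gtv1_cc`, `analytic_gtv2_cc`, and the `spec`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  gs <- spec$grid_shape; sp <- spec$spacing_mm
  tm <- spec$tissue_means
  # physical voxel-center coordinates
  cx <- (seq_len(gs[1]) - 1) * sp[1]
  cy <- (seq_len(gs[2]) - 1) * sp[2]
  cz <- (seq_len(gs[3]) - 1) * sp[3]
  bc <- (gs - 1) / 2 * sp  # brain center (grid center)
  brain_r <- 0.75 * min(gs * sp) / 2
  skull_gap <- min(2, 0.04 * brain_r)
  skull_th <- min(4, 0.1 * brain_r)
  if (spec$edema_radius_mm >= brain_r)
    stop("edema sphere does not fit inside the brain for this grid",
         call. = FALSE)

  cav_c <- if (is.null(spec$cavity_center)) bc
           else as.numeric(spec$cavity_center) * sp
  if (spec$cavity_at_skull)
    cav_c <- bc + c(brain_r - spec$cavity_radius_mm, 0, 0)

  d2 <- function(center) {
    outer(outer((cx - center[1])^2, (cy - center[2])^2, "+"),
          (cz - center[3])^2, "+")
  }
  r_brain <- sqrt(d2(bc))
  r_cav <- sqrt(d2(cav_c))
  r1 <- spec$cavity_radius_mm
  r2 <- r1 + spec$rim_thickness_mm
  re <- spec$edema_radius_mm
  rn <- spec$nodule_radius_mm

  brain <- r_brain <= brain_r
  skull <- r_brain > brain_r + skull_gap &
           r_brain <= brain_r + skull_gap + skull_th
  cavity <- (r_cav <= r1) & brain
  rim_in <- (r_cav > r1 & r_cav <= (r1 + r2) / 2) & brain
  rim_out <- (r_cav > (r1 + r2) / 2 & r_cav <= r2) & brain
  rim <- rim_in | rim_out
  edema <- (r_cav <= re) & brain
  nodule <- array(FALSE, gs)
  if (rn > 0) {
    nod_c <- cav_c + c(r2 + rn, 0, 0)
    nodule <- (sqrt(d2(nod_c)) <= rn) & brain
  }
  # blood-product crescent: thin half-shell just outside the rim, inside GTV1
  bth <- min(3, (re - r2) / 2)
  xg <- array(rep(cx, times = gs[2] * gs[3]), gs)
  blood <- (r_cav > r2 & r_cav <= r2 + bth) & (xg < cav_c[1]) & brain &
    (bth > 0)

  gtv2 <- cavity | rim | nodule
  gtv1 <- (edema | gtv2) & brain

  paint <- function(means) {
    v <- array(0, gs)
    v[skull] <- means[["skull"]]
    v[brain] <- means[["brain"]]
    v[edema] <- means[["edema"]]
    v[blood] <- means[["blood_product"]]
    v[rim_in] <- 0.8 * means[["rim_enhancement"]]
    v[rim_out] <- means[["rim_enhancement"]]
    v[nodule] <- 1.2 * means[["rim_enhancement"]]
    v[cavity] <- means[["cavity"]]
    v
  }
  t1 <- paint(tm$ce_t1w)
  fl <- paint(tm$flair)
  if (spec$noise_sd > 0) {
    head_vox <- brain | skull
    n <- sum(head_vox)
    noise <- with_seed(spec$seed, rnorm(2 * n, sd = spec$noise_sd * 100))
    t1[head_vox] <- t1[head_vox] + noise[seq_len(n)]
    fl[head_vox] <- fl[head_vox] + noise[n + seq_len(n)]
  }
  av <- analytic_volumes(spec)
  as_mask <- function(m) volume_grid(array(as.numeric(m), gs), sp)
  structure(list(
    ce_t1w = volume_grid(t1, sp), flair = volume_grid(fl, sp),
    brain_mask = as_mask(brain), skull_mask = as_mask(skull),
    gtv1_true = as_mask(gtv1), gtv2_true = as_mask(gtv2),
    enh_true = as_mask((rim | nodule) & gtv2),
    cavity_true = as_mask(cavity),
    analytic_gtv1_cc = unname(av["gtv1_cc"]),
    analytic_gtv2_cc = unname(av["gtv2_cc"]),
    spec = spec), class = "phantom_case")
}

#' @export
print.phantom_case <- function(x, ...) {
  cat(sprintf("<phantom_case> %s voxels @ %s mm; GTV1 %.2f cc, GTV2 %.2f cc (analytic)\n",
              paste(dim(x$ce_t1w), collapse = "x"),
              paste(signif(x$ce_t1w$spacing_mm, 3), collapse = "x"),
              x$analytic_gtv1_cc, x$analytic_gtv2_cc))
  invisible(x)
}

#' Longitudinal trajectory for a phantom series
#'
#' Volume multipliers are relative to the first (baseline) visit:
#' `gtv1_volume_multiplier` rescales the edema (FLAIR lesion) volume and
#' `enh_volume_multiplier` rescales the enhancing compartment (rim + nodule)
#' volume.
#'
#' @param days_since_surgery strictly increasing integer visit days.
#' @param days_since_rt_completion integer days or NA per visit.
#' @param gtv1_volume_multiplier,enh_volume_multiplier positive /
#'   non-negative multipliers, one per visit (baseline entries should be 1).
#' @return An object of class `trajectory_spec` (a data.frame).
#' @export
trajectory_spec <- function(days_since_surgery,
                            days_since_rt_completion = NA_integer_,
                            gtv1_volume_multiplier = 1,
                            enh_volume_multiplier = 1) {
  n <- length(days_since_surgery)
  if (n < 1) stop("trajectory must contain at least one visit", call. = FALSE)
  if (n > 1 && any(diff(days_since_surgery) <= 0))
    stop("visit days must be strictly increasing", call. = FALSE)
  tr <- data.frame(
    days_since_surgery = as.integer(days_since_surgery),
    days_since_rt = as.integer(rep_len(days_since_rt_completion, n)),
    gtv1_volume_multiplier = rep_len(gtv1_volume_multiplier, n),
    enh_volume_multiplier = rep_len(enh_volume_multiplier, n))
  if (any(tr$gtv1_volume_multiplier <= 0))
    stop("gtv1 multipliers must be positive", call. = FALSE)
  if (any(tr$enh_volume_multiplier < 0))
    stop("enh multipliers must be non-negative", call. = FALSE)
  class(tr) <- c("trajectory_spec", "data.frame")
  tr
}

# Scale factor s on (rim thickness, nodule radius) so the analytic enhancing
# volume (shell + nodule) equals `mult` times its baseline value.
enh_scale_factor <- function(spec, mult) {
  r1 <- spec$cavity_radius_mm; rim <- spec$rim_thickness_mm
  rn <- spec$nodule_radius_mm
  vol <- function(s) ((r1 + s * rim)^3 - r1^3) + (s * rn)^3
  target <- mult * vol(1)
  if (mult == 1) return(1)
  if (target <= 0) return(0)
  upper <- 1
  while (vol(upper) < target) upper <- upper * 2
  uniroot(function(s) vol(s) - target, c(0, upper), tol = 1e-10)$root
}

#' Generate a longitudinal series of phantoms
#'
#' Lesion radii are rescaled per visit so that the ground-truth FLAIR lesion
#' (GTV1) and enhancing lesion (rim + nodule) volumes equal the baseline
#' volumes times the trajectory multipliers. Ground-truth visit volumes are
#' measured from the generated masks.
#'
#' @param spec baseline [phantom_spec()].
#' @param traj a [trajectory_spec()]; the first visit is the baseline.
#' @return list with `cases` (list of `phantom_case`) and `visits`, a
#'   data.frame with columns visit_index, date_days, days_since_rt,
#'   flair_cc, enh_cc, gtv1_cc, gtv2_cc, is_baseline.
#' @export
generate_series <- function(spec, traj) {
  stopifnot(inherits(spec, "phantom_spec"), inherits(traj, "trajectory_spec"))
  n <- nrow(traj)
  cases <- vector("list", n)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    m1 <- traj$gtv1_volume_multiplier[i]
    m2 <- traj$enh_volume_multiplier[i]
    s <- enh_scale_factor(spec, m2)
    spec_i <- spec
    spec_i$edema_radius_mm <- spec$edema_radius_mm * m1^(1 / 3)
    spec_i$rim_thickness_mm <- max(spec$rim_thickness_mm * s, 1e-9)
    spec_i$nodule_radius_mm <- spec$nodule_radius_mm * s
    spec_i$seed <- spec$seed + i - 1L
    if (spec_i$edema_radius_mm <
        spec_i$cavity_radius_mm + spec_i$rim_thickness_mm)
      stop("visit ", i, ": enhancing compartment outgrew the edema sphere",
           call. = FALSE)
    # rebuild through the validating constructor
    spec_i <- phantom_spec(
      grid_shape = spec_i$grid_shape, spacing_mm = spec_i$spacing_mm,
      seed = spec_i$seed, cavity_center = spec_i$cavity_center,
      cavity_radius_mm = spec_i$cavity_radius_mm,
      rim_thickness_mm = spec_i$rim_thickness_mm,
      edema_radius_mm = spec_i$edema_radius_mm,
      nodule_radius_mm = spec_i$nodule_radius_mm,
      noise_sd = spec_i$noise_sd, tissue_means = spec_i$tissue_means,
      cavity_at_skull = spec_i$cavity_at_skull)
    case <- generate_phantom(spec_i)
    cases[[i]] <- case
    rows[[i]] <- data.frame(
      visit_index = i,
      date_days = traj$days_since_surgery[i],
      days_since_rt = traj$days_since_rt[i],
      flair_cc = mask_volume_cc(case$gtv1_true),
      enh_cc = mask_volume_cc(case$enh_true),
      gtv1_cc = mask_volume_cc(case$gtv1_true),
      gtv2_cc = mask_volume_cc(case$gtv2_true),
      is_baseline = i == 1L)
  }
  list(cases = cases, visits = do.call(rbind, rows))
}
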