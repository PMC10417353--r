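test_that("phantom generation is deterministic and respects tissue means", {
  spec <- phantom_spec(grid_shape = rep(32, 3), spacing_mm = c(2, 2, 2),
                       seed = 4, noise_sd = 0)
  case <- generate_phantom(spec)
  # zero noise: every cavity voxel carries exactly the cavity mean on CE-T1w
  cav <- case$cavity_true$voxels == 1
  expect_true(all(case$ce_t1w$voxels[cav] ==
                    default_tissue_means()$ce_t1w[["cavity"]]))
  # FLAIR shows bright edema containing the cavity, dark cavity fluid
  edema_only <- case$gtv1_true$voxels == 1 & case$gtv2_true$voxels == 0
  expect_gt(mean(case$flair$voxels[edema_only]),
            mean(case$flair$voxels[case$brain_mask$voxels == 1 &
                                     case$gtv1_true$voxels == 0]))
  # bit-identical regeneration from the same spec + seed
  spec2 <- phantom_spec(grid_shape = rep(32, 3), spacing_mm = c(2, 2, 2),
                        seed = 9, noise_sd = 0.05)
  c1 <- generate_phantom(spec2)
  c2 <- generate_phantom(spec2)
  expect_identical(c1$ce_t1w$voxels, c2$ce_t1w$voxels)
  expect_identical(c1$flair$voxels, c2$flair$voxels)
})

test_that("voxel-counted volumes agree with the analytic closed forms", {
  # 10 mm cavity at 1 mm spacing: (4/3)*pi*10^3 = 4.19 cc
  spec <- phantom_spec(grid_shape = rep(64, 3), spacing_mm = c(1, 1, 1),
                       seed = 1, cavity_radius_mm = 10, rim_thickness_mm = 2,
                       edema_radius_mm = 14, nodule_radius_mm = 0)
  case <- generate_phantom(spec)
  cav_cc <- mask_volume_cc(case$cavity_true)
  expect_lt(abs(cav_cc - 4 / 3 * pi * 1000 / 1000) / (4 / 3 * pi), 0.05)
  # closed-form helper: cavity 10 + rim 2, no nodule -> GTV2 = 7.24 cc
  av <- analytic_volumes(spec)
  expect_equal(unname(av["gtv2_cc"]), 4 / 3 * pi * 12^3 / 1000,
               tolerance = 1e-12)
  expect_lt(abs(mask_volume_cc(case$gtv2_true) - av["gtv2_cc"]) / av["gtv2_cc"],
            0.05)
  expect_lt(abs(mask_volume_cc(case$gtv1_true) - av["gtv1_cc"]) / av["gtv1_cc"],
            0.05)
  # nested-equality limit: edema = cavity + rim gives GTV1 = GTV2
  spec_eq <- phantom_spec(cavity_radius_mm = 10, rim_thickness_mm = 2,
                          edema_radius_mm = 12, nodule_radius_mm = 0)
  av_eq <- analytic_volumes(spec_eq)
  expect_equal(unname(av_eq["gtv1_cc"]), unname(av_eq["gtv2_cc"]),
               tolerance = 1e-12)
  # cubic scaling: doubling all radii multiplies volumes by 8
  spec_x2 <- phantom_spec(grid_shape = rep(96, 3),
                          cavity_radius_mm = 20, rim_thickness_mm = 8,
                          edema_radius_mm = 44, nodule_radius_mm = 6)
  expect_equal(unname(analytic_volumes(spec_x2)),
               unname(8 * analytic_volumes(phantom_spec())), tolerance = 1e-12)
})

test_that("GTV2 nests inside GTV1 and GTV1 inside the brain for varied phantoms", {
  for (b in phantom_bank(4, seed0 = 300L, gs = 32L)) {
    case <- b$case
    expect_true(all(case$gtv2_true$voxels <= case$gtv1_true$voxels))
    expect_true(all(case$gtv1_true$voxels <= case$brain_mask$voxels))
    expect_equal(sum(case$skull_mask$voxels * case$brain_mask$voxels), 0)
  }
  # holds also when the cavity abuts the skull
  at_skull <- generate_phantom(phantom_spec(cavity_at_skull = TRUE))
  expect_true(all(at_skull$gtv2_true$voxels <= at_skull$gtv1_true$voxels))
  expect_true(all(at_skull$gtv1_true$voxels <= at_skull$brain_mask$voxels))
})

test_that("invalid phantom geometry is rejected", {
  expect_error(phantom_spec(cavity_radius_mm = 10, rim_thickness_mm = 4,
                            edema_radius_mm = 12), "nest")
  expect_error(phantom_spec(edema_radius_mm = 80), "half the physical extent")
  expect_error(phantom_spec(cavity_radius_mm = 10, rim_thickness_mm = 4,
                            edema_radius_mm = 15, nodule_radius_mm = 3),
               "nodule")
})

test_that("longitudinal series tracks the prescribed volume multipliers", {
  spec <- phantom_spec(grid_shape = rep(48, 3), spacing_mm = c(2, 2, 2),
                       seed = 6, cavity_radius_mm = 8, rim_thickness_mm = 3,
                       edema_radius_mm = 20, nodule_radius_mm = 2)
  traj <- trajectory_spec(days_since_surgery = c(0, 60, 120),
                          days_since_rt_completion = c(NA, 20, 80),
                          gtv1_volume_multiplier = c(1, 1.3, 0.8),
                          enh_volume_multiplier = c(1, 1.7, 0.5))
  ser <- generate_series(spec, traj)
  v <- ser$visits
  expect_equal(nrow(v), 3L)
  expect_identical(v$is_baseline, c(TRUE, FALSE, FALSE))
  expect_lt(abs(v$enh_cc[2] / v$enh_cc[1] - 1.7), 0.05 * 1.7)
  expect_lt(abs(v$enh_cc[3] / v$enh_cc[1] - 0.5), 0.05)
  expect_lt(abs(v$flair_cc[2] / v$flair_cc[1] - 1.3), 0.05 * 1.3)
  # enhancing compartment multiplier 0 collapses GTV2 onto the cavity
  ser0 <- generate_series(spec, trajectory_spec(c(0, 50),
                                                enh_volume_multiplier = c(1, 0)))
  case0 <- ser0$cases[[2]]
  expect_equal(sum(case0$enh_true$voxels), 0)
  expect_identical(case0$gtv2_true$voxels, case0$cavity_true$voxels)
  # single-visit trajectory: one baseline case
  ser1 <- generate_series(spec, trajectory_spec(0))
  expect_length(ser1$cases, 1L)
  expect_true(ser1$visits$is_baseline[1])
  expect_error(trajectory_spec(c(0, 0)), "strictly increasing")
})
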