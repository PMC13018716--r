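# synthetic case generators: determinism, stated-world properties

test_that("phantoms are deterministic, dosed and anatomically sane", {
  cfg <- synth_config(dims = c(32, 32, 32))
  a <- make_phantom(cfg, seed = 1)
  b <- make_phantom(cfg, seed = 1)
  expect_identical(a$dose_src$values, b$dose_src$values)
  expect_identical(a$oar_src$oar$values, b$oar_src$oar$values)

  # dose maximum equals the prescription at the target centre
  expect_equal(max(a$dose_src$values), cfg$prescription)
  expect_equal(drop(a$dose_fun(a$target$centre)), cfg$prescription)

  # voxelised organ volume within 10% of the analytic ellipsoid volume
  semi <- cfg$organs$oar[[1]]$semi_mm
  analytic_cc <- 4 / 3 * pi * prod(semi) / 1000
  vox_cc <- sum(a$oar_src$oar$values) * voxel_volume_cc(a$geometry)
  expect_lt(abs(vox_cc - analytic_cc) / analytic_cc, 0.10)

  # organs outside the grid raise
  bad <- synth_config(dims = c(8, 8, 8))
  expect_error(make_phantom(bad, seed = 1), "outside the grid")
})

test_that("truth deformations: identity, translation, smooth, inflation", {
  geom <- grid_geometry(c(0, 0, 0), c(3, 3, 3), c(24, 24, 24))
  z <- make_true_deformation(geom, list(type = "zero"), seed = 1)
  expect_true(all(z$vectors == 0))

  tr <- make_true_deformation(geom, list(type = "translation",
                                         translation = c(3, -1, 2)), seed = 1)
  expect_true(all(tr$vectors[, , , 1] == 3))
  expect_true(all(abs(jacobian_determinant(tr)$values - 1) < 1e-12))

  # amplitude 0 smooth field is the identity (plus zero translation)
  s0 <- make_true_deformation(geom, list(type = "smooth", amplitude = 0,
                                         n_bumps = 3, corr_mm = 40), seed = 2)
  expect_true(all(abs(s0$vectors) < 1e-12))

  sm <- make_true_deformation(geom, list(type = "smooth", amplitude = 4,
                                         corr_mm = 40, n_bumps = 4), seed = 3)
  expect_true(min(jacobian_determinant(sm)$values) > 0)
  expect_lte(max(abs(sm$vectors)), 4 * 4 + 1e-9)

  # inflation mode: interior Jacobian approaches factor^3 at the centre
  inf <- make_true_deformation(geom,
                               list(type = "zero",
                                    inflate = list(centre_frac = c(0.5, 0.5, 0.5),
                                                   radius_mm = 20,
                                                   factor = 1.1)),
                               seed = 4)
  jd <- jacobian_determinant(inf)$values
  centre_idx <- round(world_to_index(geom, 0.5 * (geom$dims - 1) * geom$spacing)) + 1
  j_ctr <- jd[centre_idx[1], centre_idx[2], centre_idx[3]]
  expect_lt(abs(j_ctr - 1.1^3), 0.05)
  expect_true(min(jd) > 0)
})

test_that("field families track the truth with controlled discordance", {
  geom <- grid_geometry(c(0, 0, 0), c(3, 3, 3), c(32, 32, 32))
  truth <- make_true_deformation(geom, list(type = "smooth", amplitude = 3,
                                            corr_mm = 40, n_bumps = 3),
                                 seed = 5)
  # sigma = 0: every field equals the truth
  f0 <- make_dvf_family(truth, list(M = 3, sigma = 0, corr_mm = 15), seed = 6)
  for (f in f0) expect_identical(f$vectors, truth$vectors)

  # per-axis RMS deviation from truth is sigma (exact by construction),
  # and the deviation field is smooth at the stated correlation length
  fam <- make_dvf_family(truth, list(M = 3, sigma = 1, corr_mm = 15), seed = 7)
  for (f in fam) {
    for (comp in 1:3) {
      dev <- f$vectors[, , , comp] - truth$vectors[, , , comp]
      expect_lt(abs(sqrt(mean(dev^2)) - 1), 0.15)
      # neighbouring voxels are strongly correlated at ell = 15 mm
      expect_gt(cor(as.numeric(dev[-1, , ]), as.numeric(dev[-32, , ])), 0.8)
    }
  }
  # different seeds give different fields
  fam2 <- make_dvf_family(truth, list(M = 3, sigma = 1, corr_mm = 15), seed = 8)
  expect_false(identical(fam[[1]]$vectors, fam2[[1]]$vectors))
  expect_error(make_dvf_family(truth, list(M = 1, sigma = 1, corr_mm = 15)),
               "M >= 2")
})

test_that("coherent failures are invisible to discordance but not to truth", {
  cfg <- synth_config(dims = c(36, 36, 36), failure = list(offset_mm = 9))
  case <- synth_case(cfg, seed = 11)
  expect_false(is.null(case$failure))
  region_idx <- mask_indices(case$failure$region)
  expect_gt(length(region_idx), 10)

  # interior offset ~ 9 mm applied identically to every field
  w <- attr(case$dvf_family, "failure")$weight
  interior <- region_idx[w > 0.999]
  expect_gt(length(interior), 0)
  # discordance in the failed region stays at the noise level, far below the
  # 9 mm coherent error
  kernels <- build_kernels(case$dvf_family, case$geometry_dst, interior)
  expect_lt(median(kernel_magnitude(kernels$kd)), 6)
  # mapped points sit ~ |offset| from the true mapped points in the interior
  m1 <- interpolate_field(case$dvf_family[[1]], case$geometry_dst, interior)
  true_pts <- case$true_points[interior, , drop = FALSE]
  err <- sqrt(rowSums((m1$points - true_pts)^2))
  expect_true(median(err) > 6)  # sigma-noise on top of the 9 mm offset

  # feathering: boundary offset at most half the interior offset
  surf <- intersect(region_idx,
                    region_idx[w <= 0.5 + 1e-9])
  expect_gt(length(surf), 0)

  # zero offset leaves the family untouched
  fam0 <- inject_coherent_failure(case$dvf_family, case$failure$region,
                                  c(0, 0, 0))
  expect_identical(fam0[[1]]$vectors, case$dvf_family[[1]]$vectors)

  # identical seeds give bit-identical cases end to end
  case2 <- synth_case(cfg, seed = 11)
  expect_identical(case$dose_src$values, case2$dose_src$values)
  expect_identical(case$dvf_family[[2]]$vectors, case2$dvf_family[[2]]$vectors)
  expect_identical(case$oar_dst[[1]]$values, case2$oar_dst[[1]]$values)
})

test_that("truth actually relates the two spaces (mask consistency)", {
  case <- synth_case(synth_config(dims = c(36, 36, 36)), seed = 19)
  mapped <- interpolate_field(case$dvf_true, case$geometry_dst)
  pb <- pullback_mask(case$oar_src[[1]], mapped, case$geometry_dst)
  expect_identical(pb$values, case$oar_dst[[1]]$values)
  agree <- surface_distance_metrics(pb, case$oar_dst[[1]])
  expect_equal(agree$mda, 0)
})
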