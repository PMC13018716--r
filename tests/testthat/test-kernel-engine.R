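# kernel engine: weights, centre, dimensions, membership, KS3/KS4 expansion

test_that("inverse distance weights follow IDW = 1/(1 + DTM)", {
  same <- mapped_point_set(rbind(c(2, 3, 4), c(2, 3, 4), c(2, 3, 4)))
  expect_equal(same$dtm, c(0, 0, 0))
  expect_equal(same$idw, c(1, 1, 1))

  # a point 1 mm from the mean gets weight 1/2
  two <- mapped_point_set(rbind(c(-1, 0, 0), c(1, 0, 0)))
  expect_equal(two$dtm, c(1, 1))
  expect_equal(two$idw, c(0.5, 0.5))

  cfg <- mapped_point_set(rbind(c(0, 5, 7), c(0, 5, 7), c(9, 5, 7)))
  expect_equal(cfg$dtm, c(3, 3, 6))
  expect_equal(cfg$idw, c(0.25, 0.25, 1 / 7))
  expect_error(mapped_point_set(matrix(c(1, 2, 3), nrow = 1)), "M = 2")
})

test_that("kernel centre is the IDW-weighted mean and damps outliers", {
  pt <- c(4, -1, 2)
  expect_equal(kernel_centre(mapped_point_set(rbind(pt, pt, pt))), pt)
  expect_equal(kernel_centre(mapped_point_set(rbind(c(0, 0, 0), c(4, 2, 6)))),
               c(2, 1, 3))

  cfg <- mapped_point_set(rbind(c(0, 5, 7), c(0, 5, 7), c(9, 5, 7)))
  kc <- kernel_centre(cfg)
  expect_equal(kc, c(2, 5, 7))  # exactly (9/7)/(9/14); closer to the pair than the mean 3

  # outlier damping property: |kc - pair| < |unweighted mean - pair| for any
  # outlier distance > 0
  for (d in c(0.5, 1, 3, 10, 40)) {
    mps <- mapped_point_set(rbind(c(0, 0, 0), c(0, 0, 0), c(d, 0, 0)))
    kc <- kernel_centre(mps)[1]
    expect_lt(abs(kc - 0), abs(d / 3 - 0))
    expect_gt(kc, 0)
  }
})

test_that("kernel dimensions match the weighted-SD formula and its reductions", {
  pt <- c(1, 2, 3)
  expect_equal(kernel_dims(mapped_point_set(rbind(pt, pt, pt))), c(0, 0, 0))

  # equal weights (points equidistant from their mean), x-deviations
  # {-d, 0, +d}: KD_x reduces to the Bessel-corrected sample SD = d
  for (d in c(1, 2.5, 7)) {
    mps <- mapped_point_set(rbind(c(-d, 0, 0), c(0, d * sqrt(3), 0),
                                  c(d, 0, 0)))
    expect_equal(diff(range(mps$idw)), 0, tolerance = 1e-12)
    expect_equal(kernel_dims(mps)[1], d, tolerance = 1e-12)
  }

  cfg <- mapped_point_set(rbind(c(0, 5, 7), c(0, 5, 7), c(9, 5, 7)))
  expect_equal(kernel_dims(cfg), c(sqrt(21), 0, 0), tolerance = 1e-12)

  # equal-weight reduction to the per-axis sample SD: M = 2 always has equal
  # weights; scaled/shifted tetrahedra have four equidistant points
  set.seed(42)
  tetra <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1))
  for (rep in 1:8) {
    pair <- matrix(rnorm(6, sd = 5), 2, 3)
    expect_equal(kernel_dims(mapped_point_set(pair)),
                 apply(pair, 2, sd), tolerance = 1e-9)
    pts <- tetra * runif(1, 0.5, 8) + matrix(rnorm(3), 4, 3, byrow = TRUE)
    expect_equal(kernel_dims(mapped_point_set(pts)),
                 apply(pts, 2, sd), tolerance = 1e-9)
  }
})

test_that("batch kernel construction agrees with the per-voxel operations", {
  g <- tiny_geom(8)
  set.seed(3)
  dvfs <- lapply(1:3, function(k) {
    displacement_field(array(rnorm(prod(g$dims) * 3, sd = 2),
                             dim = c(g$dims, 3)), g)
  })
  idx <- sample(prod(g$dims), 20)
  kernels <- build_kernels(dvfs, g, idx)
  for (t in c(1, 7, 20)) {
    pts <- t(sapply(dvfs, function(f) {
      map_points(f, voxel_centres(g, idx[t]))$points
    }))
    o <- oracle_kernel(pts)
    expect_equal(kernels$kc[t, ], o$kc, tolerance = 1e-12)
    expect_equal(kernels$kd[t, ], o$kd, tolerance = 1e-12)
  }
  expect_error(build_kernels(dvfs[1], g, idx), "M = 2")
})

test_that("membership equals exhaustive enumeration (randomised kernels)", {
  set.seed(99)
  for (rep in 1:40) {
    n <- sample(6:16, 1)
    sp <- runif(3, 1.5, 4)
    geom <- grid_geometry(runif(3, -10, 10), sp, rep(n, 3))
    ext <- (geom$dims - 1) * geom$spacing
    mask <- make_ellipsoid_mask(geom, geom$origin + runif(3, 0.3, 0.7) * ext,
                                runif(3, 0.15, 0.45) * ext)
    kc <- geom$origin + runif(3, -0.1, 1.1) * ext
    kd <- runif(3, 0, 6)
    r <- sample(c(0, 3, 6), 1)
    got <- kernel_membership(list(kc = kc, kd = kd, r = r), geom, mask)
    want <- oracle_membership(kc, kd, r, geom, mask$values)
    expect_identical(got, want)
  }
})

test_that("degenerate kernels claim exactly the voxel containing their centre", {
  geom <- tiny_geom(8)
  mask <- binary_mask(array(1, dim = geom$dims), geom)
  kc <- voxel_centres(geom, 200)
  got <- kernel_membership(list(kc = drop(kc), kd = c(0, 0, 0), r = 0),
                           geom, mask)
  expect_identical(got, 200L)

  # centre far outside a small organ with a small kernel: empty set
  org <- make_ellipsoid_mask(geom, c(6, 6, 6), c(5, 5, 5))
  expect_length(kernel_membership(list(kc = c(20, 20, 20), kd = c(1, 1, 1)),
                                  geom, org), 0)
})

test_that("KS3 expands empty kernels until the organ is sampled", {
  geom <- tiny_geom(10)
  # flat organ face: organ occupies x-index 0..5 (centres 0..15 mm)
  v <- array(0, dim = geom$dims)
  v[1:6, , ] <- 1
  org <- binary_mask(v, geom)

  idx <- c(5L, 6L)
  kernels <- structure(list(owner = idx,
                            kc = rbind(c(12, 15, 15), c(22, 15, 15)),
                            kd = matrix(0, 2, 3), r = c(0, 0),
                            ks3_steps = integer(2), ks4_steps = integer(2),
                            ks3_failed = logical(2), M = 3),
                       class = "road_kernels")
  e <- ks3_expand(kernels, geom, org)
  # kernel 1 already overlaps: unchanged
  expect_equal(e$kernels$r[1], 0)
  expect_equal(e$kernels$ks3_steps[1], 0L)
  # kernel 2 sits 7 mm beyond the last organ voxel centre: oracle loop
  steps <- 0
  repeat {
    m <- oracle_membership(c(22, 15, 15), c(0, 0, 0), steps * 3, geom,
                           org$values)
    if (length(m) > 0) break
    steps <- steps + 1
  }
  expect_equal(e$kernels$ks3_steps[2], steps)
  expect_equal(steps, 2)  # needs r + 1.5 >= 7 => two 3 mm increments
  expect_length(e$memberships[[2]], length(oracle_membership(
    c(22, 15, 15), c(0, 0, 0), 6, geom, org$values)))
  expect_false(any(e$kernels$ks3_failed))

  # empty organ: no overlap achievable within the cap -> flagged
  empty <- binary_mask(array(0, dim = geom$dims), geom)
  ef <- ks3_expand(kernels, geom, empty)
  expect_true(all(ef$kernels$ks3_failed))
  expect_true(all(ef$kernels$ks3_steps == 10))
})

test_that("KS4 covers a second lobe that no kernel initially samples", {
  geom <- grid_geometry(c(0, 0, 0), c(3, 3, 3), c(20, 12, 12))
  # lobe A at x ~ 9-21 mm, lobe B at x ~ 39-51 mm (18 mm gap)
  v <- array(0, dim = geom$dims)
  v[4:8, 4:8, 4:8] <- 1
  v[14:18, 4:8, 4:8] <- 1
  org <- binary_mask(v, geom)
  # destination voxels: lobe A region only; identity mapping
  dstv <- array(0, dim = geom$dims)
  dstv[4:8, 4:8, 4:8] <- 1
  dst_idx <- which(dstv == 1)
  dvfs <- lapply(1:3, function(k) identity_field(geom))
  kernels <- build_kernels(dvfs, geom, dst_idx)
  mem <- lapply(seq_along(dst_idx), function(i) {
    kernel_membership(kernels, geom, org, which_kernel = i)
  })
  rec0 <- sampling_record(mem, org)
  expect_equal(rec0$coverage, 0.5)  # lobe B entirely unsampled
  e4 <- ks4_expand(kernels, mem, geom, org)
  expect_true(e4$record$coverage > 0.99)
  expect_true(e4$complete)
  expect_true(any(e4$kernels$ks4_steps > 0))
  # only kernels nearest lobe B should have been expanded
  expanded <- which(e4$kernels$ks4_steps > 0)
  kc_x <- kernels$kc[, 1]
  expect_true(all(kc_x[expanded] >= sort(kc_x, decreasing = TRUE)[length(expanded)] - 1e-9))
  # coverage is monotone under expansion: r grew only
  expect_true(all(e4$kernels$r >= kernels$r))
})

test_that("KS4 terminates after exactly 10 iterations when voxels are unreachable", {
  geom <- grid_geometry(c(0, 0, 0), c(3, 3, 3), c(30, 8, 8))
  v <- array(0, dim = geom$dims)
  v[2:4, 3:6, 3:6] <- 1
  v[27:29, 3:6, 3:6] <- 1   # second lobe ~ 69 mm away: unreachable within 30 mm
  org <- binary_mask(v, geom)
  dstv <- array(0, dim = geom$dims)
  dstv[2:4, 3:6, 3:6] <- 1
  dvfs <- lapply(1:2, function(k) identity_field(geom))
  kernels <- build_kernels(dvfs, geom, which(dstv == 1))
  mem <- lapply(seq_along(kernels$owner), function(i) {
    kernel_membership(kernels, geom, org, which_kernel = i)
  })
  e4 <- ks4_expand(kernels, mem, geom, org)
  expect_equal(e4$iterations, 10L)
  expect_false(e4$complete)
  expect_lte(max(e4$kernels$r), 30 + 1e-9)
  expect_true(e4$record$coverage <= 0.99)

  # trigger not met: coverage already complete -> untouched
  mem_full <- lapply(seq_along(kernels$owner), function(i) mask_indices(org))
  e0 <- ks4_expand(kernels, mem_full, geom, org)
  expect_equal(e0$iterations, 0L)
  expect_identical(e0$kernels$r, kernels$r)
})

test_that("coverage is monotonically non-decreasing across KS3 and KS4 iterations", {
  set.seed(5)
  geom <- tiny_geom(14)
  org <- make_ellipsoid_mask(geom, c(20, 20, 20), c(12, 9, 9))
  dst <- make_ellipsoid_mask(geom, c(23, 20, 20), c(10, 9, 9))
  dvfs <- lapply(1:3, function(k) {
    displacement_field(array(rnorm(prod(geom$dims) * 3, sd = 3),
                             dim = c(geom$dims, 3)), geom)
  })
  kernels <- build_kernels(dvfs, geom, mask_indices(dst))
  mem <- lapply(seq_along(kernels$owner), function(i) {
    kernel_membership(kernels, geom, org, which_kernel = i)
  })
  cov0 <- sampling_record(mem, org)$coverage
  e3 <- ks3_expand(kernels, geom, org, memberships = mem)
  cov3 <- sampling_record(e3$memberships, org)$coverage
  expect_gte(cov3, cov0)
  # every non-failed kernel samples at least one organ voxel after KS3
  ok <- !e3$kernels$ks3_failed
  expect_true(all(lengths(e3$memberships)[ok] >= 1))
  e4 <- ks4_expand(e3$kernels, e3$memberships, geom, org)
  expect_gte(e4$record$coverage, cov3)
  expect_true(e4$complete || e4$iterations == 10L)
})
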