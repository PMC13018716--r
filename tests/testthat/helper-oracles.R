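# Independent brute-force oracles and tiny fixture builders used across the
# suite. The oracles deliberately use exhaustive enumeration / direct formula
# transliteration, not the package's optimised code paths.

# exhaustive ellipsoid membership over EVERY voxel of the grid
oracle_membership <- function(kc, kd, r, geom, mask_values) {
  delta <- geom$spacing / 2
  semi <- kd + r + delta
  ctr <- voxel_centres(geom)
  q <- ((ctr[, 1] - kc[1]) / semi[1])^2 +
       ((ctr[, 2] - kc[2]) / semi[2])^2 +
       ((ctr[, 3] - kc[3]) / semi[3])^2
  members <- which(q <= 1 & mask_values == 1)
  own <- round((kc - geom$origin) / geom$spacing)
  if (all(own >= 0) && all(own <= geom$dims - 1)) {
    ol <- 1L + own[1] + geom$dims[1] * (own[2] + geom$dims[2] * own[3])
    if (mask_values[ol] == 1) members <- union(members, ol)
  }
  sort(as.integer(members))
}

# direct transliteration of the printed kernel formulas for one point set
oracle_kernel <- function(points) {
  m <- nrow(points)
  ctr <- colMeans(points)
  dtm <- apply(points, 1, function(p) sqrt(sum((p - ctr)^2)))
  idw <- 1 / (1 + dtm)
  kc <- sapply(1:3, function(l) sum(idw * points[, l]) / sum(idw))
  kd <- sapply(1:3, function(l) {
    sqrt(sum(idw * (points[, l] - kc[l])^2) / (((m - 1) / m) * sum(idw)))
  })
  list(dtm = dtm, idw = idw, kc = kc, kd = kd)
}

# exhaustive symmetric surface distances (double loop over surface sets)
oracle_surface_metrics <- function(a, b) {
  surf <- function(m) {
    v <- m$values
    d <- dim(v)
    idx <- which(v == 1)
    ijk <- arrayInd(idx, d)
    keep <- logical(length(idx))
    for (t in seq_along(idx)) {
      p <- ijk[t, ]
      edge <- FALSE
      for (ax in 1:3) for (s in c(-1L, 1L)) {
        q <- p
        q[ax] <- q[ax] + s
        if (q[ax] < 1 || q[ax] > d[ax] || v[q[1], q[2], q[3]] == 0) edge <- TRUE
      }
      keep[t] <- edge
    }
    voxel_centres(m$geometry, idx[keep])
  }
  sa <- surf(a)
  sb <- surf(b)
  dmin <- function(from, to) {
    apply(from, 1, function(p) sqrt(min(colSums((t(to) - p)^2))))
  }
  dab <- dmin(sa, sb)
  dba <- dmin(sb, sa)
  list(mda = (mean(dab) + mean(dba)) / 2, hd = max(dab, dba))
}

# threshold-sweep consistency check for D_Vcc: the returned dose must lie
# between the doses bracketing the requested volume (one voxel of slack)
expect_dvcc_consistent <- function(result, doses, voxel_cc, v_cc) {
  expect_lte(sum(doses > result + 1e-9) * voxel_cc, v_cc + 1e-9)
  expect_gte(sum(doses >= result - 1e-9) * voxel_cc, v_cc - voxel_cc - 1e-9)
}

# small centred ellipsoid mask on a grid
make_ellipsoid_mask <- function(geom, centre, semi) {
  ctr <- voxel_centres(geom)
  q <- ((ctr[, 1] - centre[1]) / semi[1])^2 +
       ((ctr[, 2] - centre[2]) / semi[2])^2 +
       ((ctr[, 3] - centre[3]) / semi[3])^2
  binary_mask(as.numeric(q <= 1), geom)
}

# constant-translation displacement field
make_translation_field <- function(geom, t) {
  v <- array(0, dim = c(geom$dims, 3))
  for (comp in 1:3) v[, , , comp] <- t[comp]
  displacement_field(v, geom)
}

# small shared fixture: 12^3 grid at 3 mm
tiny_geom <- function(n = 12L, spacing = 3) {
  grid_geometry(c(0, 0, 0), rep(spacing, 3), rep(n, 3L))
}
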