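# Per-voxel uncertainty kernels from M mapped points. KS1: inverse-distance
# weighted kernel centre; KS2: weighted-SD ellipsoid dimensions clipped to the
# organ; KS3: isotropic expansion until the organ is sampled; KS4: coverage
# expansion until >99% of original organ dose voxels are sampled (or 10
# iterations, a +3 cm radius cap at a 3 mm grid).

#' Mapped point set for one destination voxel
#'
#' Holds the M source-space points identified by the M displacement fields for
#' one destination voxel, the Euclidean distance of each point to their
#' unweighted mean (DTM, mm) and the inverse distance weights
#' `IDW = 1 / (1 + DTM)`.
#'
#' @param points numeric M x 3 matrix of source-space points (mm), M >= 2.
#' @return An object of class `mapped_point_set` with elements `points`,
#'   `dtm`, `idw`.
#' @examples
#' mps <- mapped_point_set(rbind(c(0, 0, 0), c(0, 0, 0), c(9, 0, 0)))
#' mps$idw            # c(0.25, 0.25, 1/7)
#' kernel_centre(mps) # x component pulled towards the concordant pair
#' @export
mapped_point_set <- function(points) {
  points <- .as_point_matrix(points)
  if (nrow(points) < 2L) stop("at least M = 2 mapped points are required")
  ctr <- colMeans(points)
  dtm <- sqrt(rowSums(sweep(points, 2L, ctr)^2))
  structure(list(points = points, dtm = dtm, idw = 1 / (1 + dtm)),
            class = "mapped_point_set")
}

#' @rdname mapped_point_set
#' @export
compute_weights <- function(points) mapped_point_set(points)

#' Weighted kernel centre
#'
#' Per-axis inverse-distance-weighted mean of the M mapped points,
#' `kc_l = sum(IDW_i * l_i) / sum(IDW_i)`. Equals the unweighted mean when
#' all weights are equal; an outlier point is damped towards the concordant
#' ones.
#'
#' @param mps a [mapped_point_set()].
#' @return Length-3 numeric, source-space position (mm).
#' @export
kernel_centre <- function(mps) {
  stopifnot(inherits(mps, "mapped_point_set"))
  # computed relative to the first point so that coincident points give the
  # centre exactly (and the subtraction is well conditioned in general)
  ref <- mps$points[1L, ]
  ref + colSums(sweep(mps$points, 2L, ref) * mps$idw) / sum(mps$idw)
}

#' Weighted kernel semi-dimensions
#'
#' Per-axis ellipsoid semi-dimension
#' `KD_l = sqrt( sum(IDW_i (l_i - kc_l)^2) / (((M-1)/M) * sum(IDW_i)) )`.
#' With equal weights this reduces to the Bessel-corrected sample standard
#' deviation per axis.
#'
#' @param mps a [mapped_point_set()].
#' @param kc kernel centre (default [kernel_centre()] of `mps`).
#' @return Length-3 numeric semi-dimensions (mm), all >= 0.
#' @export
kernel_dims <- function(mps, kc = kernel_centre(mps)) {
  stopifnot(inherits(mps, "mapped_point_set"))
  m <- nrow(mps$points)
  dev2 <- sweep(mps$points, 2L, kc)^2
  sqrt(colSums(dev2 * mps$idw) / (((m - 1) / m) * sum(mps$idw)))
}

#' Build kernels for a set of destination voxels
#'
#' Vectorised KS1 + KS2 construction: for every requested destination voxel,
#' the M displacement fields are interpolated at the voxel centre, the
#' weighted kernel centre and semi-dimensions are computed, and a kernel
#' record is returned with zero cumulative expansion radius.
#'
#' @param dvfs list of M >= 2 [displacement_field()]s (destination space).
#' @param dst_geometry destination [grid_geometry()] (the dose grid).
#' @param dst_idx 1-based linear indices of the destination voxels to build
#'   kernels for (typically [mask_indices()] of the destination organ mask).
#' @return An object of class `road_kernels`: list with `owner` (linear
#'   indices), `kc` (K x 3 mm), `kd` (K x 3 mm), `r` (cumulative isotropic
#'   expansion, mm), `ks3_steps`, `ks4_steps`, `ks3_failed`, `M`.
#' @export
build_kernels <- function(dvfs, dst_geometry, dst_idx) {
  m <- length(dvfs)
  if (m < 2L) stop("at least M = 2 displacement fields are required")
  n <- length(dst_idx)
  p <- array(0, dim = c(n, 3L, m))
  for (k in seq_len(m)) {
    p[, , k] <- interpolate_field(dvfs[[k]], dst_geometry, dst_idx)$points
  }
  ctr <- apply(p, c(1L, 2L), mean)                    # unweighted mean, N x 3
  dtm <- matrix(0, n, m)
  for (k in seq_len(m)) dtm[, k] <- sqrt(rowSums((p[, , k] - ctr)^2))
  idw <- 1 / (1 + dtm)
  sw <- rowSums(idw)
  kc <- matrix(0, n, 3L)
  for (l in 1:3) {
    # relative to the first field's point: exact for coincident points
    kc[, l] <- p[, l, 1L] + rowSums(idw * (p[, l, ] - p[, l, 1L])) / sw
  }
  kd <- matrix(0, n, 3L)
  for (l in 1:3) {
    kd[, l] <- sqrt(rowSums(idw * (p[, l, ] - kc[, l])^2) / (((m - 1) / m) * sw))
  }
  structure(list(owner = as.integer(dst_idx), kc = kc, kd = kd,
                 r = numeric(n), ks3_steps = integer(n),
                 ks4_steps = integer(n), ks3_failed = logical(n), M = m),
            class = "road_kernels")
}

#' @export
print.road_kernels <- function(x, ...) {
  cat(sprintf("road_kernels: %d kernels from M = %d fields; mean KD (%.2f, %.2f, %.2f) mm; %d expanded (KS3), %d (KS4), %d failed\n",
              length(x$owner), x$M, mean(x$kd[, 1]), mean(x$kd[, 2]),
              mean(x$kd[, 3]), sum(x$ks3_steps > 0), sum(x$ks4_steps > 0),
              sum(x$ks3_failed)))
  invisible(x)
}

# Membership of one ellipsoid kernel among source voxel centres. The voxel
# containing kc is always included when inside the organ, so a degenerate
# (KD = 0) kernel still recovers its own centre sample.
.membership_one <- function(kc, kd, r, geometry, mask_values) {
  delta <- geometry$spacing / 2
  semi <- kd + r + delta
  d <- geometry$dims
  lo <- pmax(ceiling((kc - semi - geometry$origin) / geometry$spacing), 0)
  hi <- pmin(floor((kc + semi - geometry$origin) / geometry$spacing), d - 1)
  members <- integer(0)
  if (all(lo <= hi)) {
    ii <- seq.int(lo[1L], hi[1L])
    jj <- seq.int(lo[2L], hi[2L])
    kk <- seq.int(lo[3L], hi[3L])
    cx <- geometry$origin[1L] + ii * geometry$spacing[1L]
    cy <- geometry$origin[2L] + jj * geometry$spacing[2L]
    cz <- geometry$origin[3L] + kk * geometry$spacing[3L]
    tx <- ((cx - kc[1L]) / semi[1L])^2
    ty <- ((cy - kc[2L]) / semi[2L])^2
    tz <- ((cz - kc[3L]) / semi[3L])^2
    q <- outer(outer(tx, ty, "+"), tz, "+")
    inside <- which(q <= 1)
    if (length(inside)) {
      idx <- arrayInd(inside, .dim = c(length(ii), length(jj), length(kk)))
      lin <- 1L + (ii[idx[, 1L]]) + d[1L] * (jj[idx[, 2L]] + d[2L] * kk[idx[, 3L]])
      members <- lin[mask_values[lin] == 1]
    }
  }
  own <- round((kc - geometry$origin) / geometry$spacing)
  if (all(own >= 0) && all(own <= d - 1)) {
    ol <- 1L + own[1L] + d[1L] * (own[2L] + d[2L] * own[3L])
    if (mask_values[ol] == 1) members <- c(members, ol)
  }
  sort(unique(as.integer(members)))
}

#' Source voxels sampled by a kernel
#'
#' A source voxel belongs to the kernel iff its centre `c` satisfies
#' `sum_l ((c_l - kc_l) / (KD_l + r + delta_l))^2 <= 1` with `delta` equal to
#' half the source grid spacing per axis, AND the voxel carries organ mask
#' value 1. The voxel containing the kernel centre is always included when it
#' is inside the organ. An empty set is a legal result (consumed by
#' [ks3_expand()]).
#'
#' @param kernel list with `kc` (length 3, mm), `kd` (length 3, mm) and
#'   optionally `r` (mm, default 0); or a `road_kernels` object together with
#'   `which_kernel`.
#' @param geometry source [grid_geometry()].
#' @param oar_src source organ [binary_mask()].
#' @param which_kernel row to extract when `kernel` is a `road_kernels`.
#' @return Sorted integer vector of 1-based source linear voxel indices.
#' @export
kernel_membership <- function(kernel, geometry, oar_src, which_kernel = 1L) {
  if (inherits(kernel, "road_kernels")) {
    kernel <- list(kc = kernel$kc[which_kernel, ], kd = kernel$kd[which_kernel, ],
                   r = kernel$r[which_kernel])
  }
  r <- if (is.null(kernel$r)) 0 else kernel$r
  .membership_one(kernel$kc, kernel$kd, r, geometry, oar_src$values)
}

# memberships for all kernels (list of integer vectors)
.all_memberships <- function(kernels, geometry, mask_values,
                             subset = seq_along(kernels$owner),
                             current = NULL) {
  out <- if (is.null(current)) vector("list", length(kernels$owner)) else current
  for (i in subset) {
    out[[i]] <- .membership_one(kernels$kc[i, ], kernels$kd[i, ],
                                kernels$r[i], geometry, mask_values)
  }
  out
}

#' KS3: expand kernels that missed the organ
#'
#' Kernels whose membership is empty receive incremental isotropic expansions
#' (one source dose voxel, i.e. the largest source grid spacing, per step)
#' until they overlap the original organ. Kernels still empty at the radius
#' cap (`max_steps` increments, 30 mm at a 3 mm grid) are flagged
#' `ks3_failed` and fall back to the baseline dose downstream.
#'
#' @param kernels a [build_kernels()] result.
#' @param geometry source [grid_geometry()].
#' @param oar_src source organ [binary_mask()].
#' @param increment isotropic expansion step (mm); default the largest source
#'   grid spacing.
#' @param max_steps cap on the number of increments per kernel (default 10).
#' @param memberships optional precomputed membership list (recomputed when
#'   missing).
#' @return List with updated `kernels` and `memberships`.
#' @export
ks3_expand <- function(kernels, geometry, oar_src,
                       increment = max(geometry$spacing), max_steps = 10L,
                       memberships = NULL) {
  mv <- oar_src$values
  if (is.null(memberships)) {
    memberships <- .all_memberships(kernels, geometry, mv)
  }
  empty <- which(lengths(memberships) == 0L)
  for (i in empty) {
    while (length(memberships[[i]]) == 0L && kernels$ks3_steps[i] < max_steps) {
      kernels$r[i] <- kernels$r[i] + increment
      kernels$ks3_steps[i] <- kernels$ks3_steps[i] + 1L
      memberships[[i]] <- .membership_one(kernels$kc[i, ], kernels$kd[i, ],
                                          kernels$r[i], geometry, mv)
    }
    if (length(memberships[[i]]) == 0L) kernels$ks3_failed[i] <- TRUE
  }
  list(kernels = kernels, memberships = memberships)
}

#' Sampling record for one organ
#'
#' Tracks which source organ dose voxels have been sampled by at least one
#' kernel; `coverage = |sampled| / total` drives the KS4 trigger and stop.
#'
#' @param memberships list of membership index vectors (one per kernel).
#' @param oar_src source organ [binary_mask()].
#' @return An object of class `sampling_record`: `sampled` (sorted indices),
#'   `total`, `coverage`.
#' @export
sampling_record <- function(memberships, oar_src) {
  total <- sum(oar_src$values)
  sampled <- sort(unique(unlist(memberships, use.names = FALSE)))
  structure(list(sampled = as.integer(sampled), total = as.integer(total),
                 coverage = if (total > 0) length(sampled) / total else NA_real_),
            class = "sampling_record")
}

#' KS4: expand kernels towards unsampled organ voxels
#'
#' While more than `1 - coverage_threshold` of the original organ dose voxels
#' remain unsampled and fewer than `max_iter` iterations have run: the
#' fraction `f` of unsampled voxels is recomputed, and the `ceiling(f * K)`
#' kernels (minimum 1; ties broken by ascending owner index) whose centres
#' are closest in source space to any unsampled voxel centre are expanded by
#' one increment, their memberships recomputed, and the record updated.
#' Kernels already at the radius cap are selectable but are not grown further,
#' so termination after exactly `max_iter` iterations is guaranteed even when
#' voxels are unreachable; such an organ is flagged coverage-incomplete.
#'
#' @inheritParams ks3_expand
#' @param memberships membership list after [ks3_expand()].
#' @param coverage_threshold stop once coverage exceeds this (default 0.99).
#' @param max_iter global iteration cap (default 10).
#' @param r_cap cumulative radius cap (default `max_iter * increment`,
#'   i.e. +3 cm at a 3 mm grid).
#' @return List with `kernels`, `memberships`, `record` ([sampling_record()])
#'   and `iterations`, `complete`.
#' @export
ks4_expand <- function(kernels, memberships, geometry, oar_src,
                       increment = max(geometry$spacing),
                       coverage_threshold = 0.99, max_iter = 10L,
                       r_cap = max_iter * increment) {
  mv <- oar_src$values
  oar_idx <- which(mv == 1)
  record <- sampling_record(memberships, oar_src)
  k_total <- length(kernels$owner)
  iter <- 0L
  while (record$total > 0L && record$coverage <= coverage_threshold &&
         iter < max_iter && k_total > 0L) {
    unsampled <- setdiff(oar_idx, record$sampled)
    f <- length(unsampled) / record$total
    n_expand <- max(1L, ceiling(f * k_total))
    uc <- voxel_centres(geometry, unsampled)
    # distance from each kernel centre to the nearest unsampled voxel centre
    dmin <- rep(Inf, k_total)
    chunk <- 2048L
    for (s in seq(1L, length(unsampled), by = chunk)) {
      e <- min(s + chunk - 1L, length(unsampled))
      u <- uc[s:e, , drop = FALSE]
      d2 <- outer(rowSums(kernels$kc^2), rowSums(u^2), "+") -
        2 * kernels$kc %*% t(u)
      dmin <- pmin(dmin, sqrt(pmax(apply(d2, 1L, min), 0)))
    }
    ord <- order(dmin, kernels$owner)
    sel <- ord[seq_len(min(n_expand, k_total))]
    grow <- sel[kernels$r[sel] + increment <= r_cap + 1e-9]
    if (length(grow)) {
      kernels$r[grow] <- kernels$r[grow] + increment
      kernels$ks4_steps[grow] <- kernels$ks4_steps[grow] + 1L
      memberships <- .all_memberships(kernels, geometry, mv,
                                      subset = grow, current = memberships)
      record <- sampling_record(memberships, oar_src)
    }
    iter <- iter + 1L
  }
  list(kernels = kernels, memberships = memberships, record = record,
       iterations = iter,
       complete = is.na(record$coverage) || record$coverage > coverage_threshold)
}

#' Export kernels as a QA audit table
#'
#' @param kernels a `road_kernels` object.
#' @param dst_geometry destination grid (for owner voxel ijk columns).
#' @return A data.frame with owner index, owner ijk, kernel centre, per-axis
#'   semi-dimensions, cumulative expansion radius and expansion causes.
#' @export
kernel_audit_table <- function(kernels, dst_geometry) {
  ijk <- .ijk_index(dst_geometry, kernels$owner)
  data.frame(owner = kernels$owner,
             i = ijk[, 1L], j = ijk[, 2L], k = ijk[, 3L],
             kc_x = kernels$kc[, 1L], kc_y = kernels$kc[, 2L],
             kc_z = kernels$kc[, 3L],
             kd_x = kernels$kd[, 1L], kd_y = kernels$kd[, 2L],
             kd_z = kernels$kd[, 3L],
             r = kernels$r, ks3_steps = kernels$ks3_steps,
             ks4_steps = kernels$ks4_steps, ks3_failed = kernels$ks3_failed)
}
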