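# Dose resampling: turn kernels into robust per-voxel doses under the
# cumulative modes KS1-KS4 plus a fixed-radius comparator, apply the
# baseline-fallback rule (kernel dose below baseline -> keep baseline), and
# assemble the final robust distribution.

.PROVENANCE_CODES <- c("baseline" = 0L, "kernel-sample" = 1L,
                       "KS3-expanded" = 2L, "KS4-expanded" = 3L,
                       "baseline-fallback" = 4L)

#' Candidate source doses for one kernel
#'
#' KS1 samples only the source dose voxel containing the kernel centre (and
#' only when that voxel is inside the organ); KS2 and later sample the raw
#' (nearest, not interpolated) dose values of the kernel's membership set. An
#' empty candidate set is legal and resolves to the baseline downstream.
#'
#' @param kernel list with `kc`, `kd`, `r` (see [kernel_membership()]).
#' @param dose_src source [scalar_volume()] (Gy).
#' @param oar_src source organ [binary_mask()].
#' @param mode one of `"KS1"`, `"KS2"`, `"KS3"`, `"KS4"`.
#' @param membership optional precomputed membership (for KS2+).
#' @return Numeric vector of candidate doses (possibly empty).
#' @export
sample_candidates <- function(kernel, dose_src, oar_src,
                              mode = c("KS2", "KS1", "KS3", "KS4"),
                              membership = NULL) {
  mode <- match.arg(mode)
  geom <- dose_src$geometry
  if (mode == "KS1") {
    own <- round((kernel$kc - geom$origin) / geom$spacing)
    if (any(own < 0) || any(own > geom$dims - 1)) return(numeric(0))
    lin <- 1L + own[1L] + geom$dims[1L] * (own[2L] + geom$dims[2L] * own[3L])
    if (oar_src$values[lin] != 1) return(numeric(0))
    return(dose_src$values[lin])
  }
  if (is.null(membership)) {
    membership <- kernel_membership(kernel, geom, oar_src)
  }
  dose_src$values[membership]
}

#' Robust per-voxel dose from candidates
#'
#' Default (validated) statistic is the maximum of the candidate set and the
#' baseline value, so the baseline is retained whenever the kernel sample is
#' empty or lower. Alternative statistics (mean/median/percentile of the
#' candidates, still floored at the baseline) are exposed as a hook only.
#'
#' @param candidates numeric vector of candidate doses (Gy), possibly empty.
#' @param baseline_value baseline mapped dose at the voxel (Gy).
#' @param statistic `"max"` (default), `"mean"`, `"median"` or
#'   `"percentile"`.
#' @param probs percentile in `[0, 1]` when `statistic = "percentile"`.
#' @return Robust dose (Gy).
#' @export
robust_voxel_dose <- function(candidates, baseline_value,
                              statistic = c("max", "mean", "median",
                                            "percentile"),
                              probs = 0.95) {
  statistic <- match.arg(statistic)
  if (length(candidates) == 0L) return(baseline_value)
  s <- switch(statistic,
              max = max(candidates),
              mean = mean(candidates),
              median = stats::median(candidates),
              percentile = unname(stats::quantile(candidates, probs = probs)))
  max(s, baseline_value)
}

#' Fixed-radius spherical kernel comparator dose
#'
#' For every destination organ voxel a sphere of the given radius is centred
#' on the baseline mapped point — relocated to the nearest source-organ voxel
#' centre when that point falls outside the organ. Candidates are the source
#' organ voxels whose centres lie within `radius + delta` (per-axis `delta` =
#' half the source spacing, consistent with the ellipsoid convention); the
#' returned dose is the maximum of the candidates and the baseline.
#'
#' @param dose_src source [scalar_volume()] (Gy).
#' @param oar_src source organ [binary_mask()] (must be non-empty).
#' @param baseline_points N x 3 matrix of baseline mapped source points (mm),
#'   one row per destination organ voxel.
#' @param baseline_values baseline mapped dose (Gy) at those voxels.
#' @param radius sphere radius (mm), default 3.
#' @param statistic,probs see [robust_voxel_dose()].
#' @return Numeric vector of robust doses, one per destination organ voxel.
#' @export
fixed_kernel_dose <- function(dose_src, oar_src, baseline_points,
                              baseline_values, radius = 3,
                              statistic = "max", probs = 0.95) {
  geom <- dose_src$geometry
  oar_idx <- which(oar_src$values == 1)
  if (length(oar_idx) == 0L) stop("fixed_kernel_dose: empty organ mask")
  baseline_points <- .as_point_matrix(baseline_points)
  n <- nrow(baseline_points)
  stopifnot(length(baseline_values) == n)
  oc <- voxel_centres(geom, oar_idx)
  kd <- rep(radius, 3L)
  out <- numeric(n)
  for (i in seq_len(n)) {
    p <- baseline_points[i, ]
    own <- round((p - geom$origin) / geom$spacing)
    inside <- all(own >= 0) && all(own <= geom$dims - 1) &&
      oar_src$values[1L + own[1L] + geom$dims[1L] *
                       (own[2L] + geom$dims[2L] * own[3L])] == 1
    if (!inside) {
      # relocate the kernel centre to the closest point inside the organ
      p <- oc[which.min(colSums((t(oc) - p)^2)), ]
    }
    members <- .membership_one(p, kd, 0, geom, oar_src$values)
    out[i] <- robust_voxel_dose(dose_src$values[members], baseline_values[i],
                                statistic = statistic, probs = probs)
  }
  out
}

#' Robust doses for one organ under all kernel modes
#'
#' Runs the full kernel pipeline for a single organ: builds kernels from the
#' M fields at every destination organ voxel, computes the KS1/KS2 doses,
#' applies the KS3 and KS4 expansions, and returns per-voxel doses for every
#' mode together with kernel magnitudes, provenance flags and the coverage
#' record. All modes are cumulative and floored at the baseline mapped dose.
#'
#' @param dose_src source [scalar_volume()] (Gy).
#' @param oar_src source organ [binary_mask()].
#' @param oar_dst destination organ [binary_mask()].
#' @param dvfs list of M >= 2 [displacement_field()]s.
#' @param baseline_field [displacement_field()] used for the baseline mapped
#'   dose (defaults to `dvfs[[1]]`).
#' @param params a [road_params()] list.
#' @return List with `dst_idx`, per-mode dose vectors in `dose` (named
#'   `baseline`, `fixed`, `KS1`..`KS4`), `km` (per-mode kernel magnitudes for
#'   KS2..KS4), `provenance` (integer codes, see package docs), `kernels`,
#'   `record`, `ks4_iterations`, `coverage_complete`.
#' @export
resample_oar <- function(dose_src, oar_src, oar_dst, dvfs,
                         baseline_field = dvfs[[1L]],
                         params = road_params()) {
  dst_geom <- oar_dst$geometry
  dst_idx <- mask_indices(oar_dst)
  if (length(dst_idx) == 0L) stop("resample_oar: empty destination organ mask")
  if (sum(oar_src$values) == 0L) stop("resample_oar: empty source organ mask")
  src_geom <- dose_src$geometry
  increment <- if (is.null(params$increment)) max(src_geom$spacing) else params$increment

  bl <- interpolate_field(baseline_field, dst_geom, dst_idx)
  blv <- .pullback_values(dose_src, bl$points, params$interpolation)

  kernels <- build_kernels(dvfs, dst_geom, dst_idx)
  n <- length(dst_idx)

  # KS1: kernel-centre sample only
  ks1 <- numeric(n)
  for (i in seq_len(n)) {
    cand <- sample_candidates(list(kc = kernels$kc[i, ]), dose_src, oar_src,
                              mode = "KS1")
    ks1[i] <- robust_voxel_dose(cand, blv[i], statistic = params$statistic,
                                probs = params$probs)
  }

  mv <- oar_src$values
  mem2 <- .all_memberships(kernels, src_geom, mv)
  ks2 <- .mode_dose(mem2, dose_src, blv, params)

  e3 <- ks3_expand(kernels, src_geom, oar_src, increment = increment,
                   max_steps = params$max_expansions, memberships = mem2)
  kernels <- e3$kernels
  r_ks3 <- kernels$r
  ks3 <- .mode_dose(e3$memberships, dose_src, blv, params)

  e4 <- ks4_expand(kernels, e3$memberships, src_geom, oar_src,
                   increment = increment,
                   coverage_threshold = params$coverage_threshold,
                   max_iter = params$max_expansions,
                   r_cap = params$max_expansions * increment)
  kernels <- e4$kernels
  ks4 <- .mode_dose(e4$memberships, dose_src, blv, params)

  fixed <- fixed_kernel_dose(dose_src, oar_src, bl$points, blv,
                             radius = params$fixed_radius,
                             statistic = params$statistic, probs = params$probs)

  km <- list(KS2 = kernel_magnitude(kernels$kd),
             KS3 = kernel_magnitude(kernels$kd, r_ks3),
             KS4 = kernel_magnitude(kernels$kd, kernels$r))

  prov <- rep(.PROVENANCE_CODES[["kernel-sample"]], n)
  prov[kernels$ks3_steps > 0L] <- .PROVENANCE_CODES[["KS3-expanded"]]
  prov[kernels$ks4_steps > 0L] <- .PROVENANCE_CODES[["KS4-expanded"]]
  prov[kernels$ks3_failed] <- .PROVENANCE_CODES[["baseline-fallback"]]

  list(dst_idx = dst_idx,
       dose = list(baseline = blv, fixed = fixed, KS1 = ks1, KS2 = ks2,
                   KS3 = ks3, KS4 = ks4),
       km = km, provenance = prov, kernels = kernels, record = e4$record,
       ks4_iterations = e4$iterations, coverage_complete = e4$complete,
       baseline_points = bl$points)
}

# per-voxel robust dose from a membership list (KS3-failed -> baseline)
.mode_dose <- function(memberships, dose_src, baseline_values, params) {
  n <- length(baseline_values)
  out <- numeric(n)
  for (i in seq_len(n)) {
    out[i] <- robust_voxel_dose(dose_src$values[memberships[[i]]],
                                baseline_values[i],
                                statistic = params$statistic,
                                probs = params$probs)
  }
  out
}

# baseline values at arbitrary mapped points (0 Gy outside the source grid)
.pullback_values <- function(dose_src, pts, interpolation = "trilinear") {
  geom <- dose_src$geometry
  ci <- world_to_index(geom, pts)
  if (!is.matrix(ci)) ci <- matrix(ci, nrow = 1L)
  d <- geom$dims
  vals <- numeric(nrow(ci))
  if (interpolation == "trilinear") {
    inside <- ci[, 1L] >= 0 & ci[, 1L] <= d[1L] - 1L &
      ci[, 2L] >= 0 & ci[, 2L] <= d[2L] - 1L &
      ci[, 3L] >= 0 & ci[, 3L] <= d[3L] - 1L
    if (any(inside)) {
      vals[inside] <- .trilinear_sample(dose_src$values,
                                        ci[inside, , drop = FALSE])
    }
  } else {
    r <- round(ci)
    inside <- r[, 1L] >= 0 & r[, 1L] <= d[1L] - 1L &
      r[, 2L] >= 0 & r[, 2L] <= d[2L] - 1L &
      r[, 3L] >= 0 & r[, 3L] <= d[3L] - 1L
    if (any(inside)) {
      vals[inside] <- dose_src$values[.lin_index(geom, r[inside, , drop = FALSE])]
    }
  }
  vals
}

#' Combine per-organ robust doses with the baseline
#'
#' Voxels outside every organ take the baseline mapped dose; voxels inside
#' exactly one organ take that organ's robust dose; voxels shared by several
#' organs take the maximum of the competing robust doses (conservative,
#' consistent with worst-case sampling).
#'
#' @param oar_doses list of per-organ results, each a list with `dst_idx` and
#'   a numeric dose vector `values` of the same length.
#' @param baseline baseline mapped dose, a [scalar_volume()] on the
#'   destination grid.
#' @return A [scalar_volume()] on the destination grid.
#' @export
assemble_final <- function(oar_doses, baseline) {
  out <- baseline$values
  for (od in oar_doses) {
    stopifnot(length(od$dst_idx) == length(od$values))
    if (any(od$dst_idx < 1L | od$dst_idx > length(out))) {
      stop("assemble_final: organ indices outside the destination grid")
    }
    out[od$dst_idx] <- pmax(out[od$dst_idx], od$values)
  }
  scalar_volume(out, baseline$geometry)
}

#' Pipeline parameters
#'
#' Defaults mirror a 3 mm dose grid: expansion increment one dose voxel
#' (taken from the source grid when `NULL`), at most 10 expansions (+3 cm
#' radius), KS4 coverage threshold 0.99, deficit threshold 0.5 Gy, fixed
#' comparator radius 3 mm, worst-case (`max`) sampling statistic, trilinear
#' baseline dose interpolation.
#'
#' @param increment isotropic expansion step (mm); `NULL` = largest source
#'   grid spacing.
#' @param max_expansions cap on KS3 steps per kernel and KS4 iterations.
#' @param coverage_threshold KS4 stop threshold on sampled fraction.
#' @param deficit_threshold DVH deficit threshold (Gy).
#' @param fixed_radius fixed comparator kernel radius (mm).
#' @param statistic per-voxel sampling statistic (only `"max"` is validated).
#' @param probs percentile for `statistic = "percentile"`.
#' @param interpolation baseline dose interpolation, `"trilinear"` or
#'   `"nearest"`.
#' @return Named list of parameters.
#' @export
road_params <- function(increment = NULL, max_expansions = 10L,
                        coverage_threshold = 0.99, deficit_threshold = 0.5,
                        fixed_radius = 3, statistic = "max", probs = 0.95,
                        interpolation = c("trilinear", "nearest")) {
  list(increment = increment, max_expansions = as.integer(max_expansions),
       coverage_threshold = coverage_threshold,
       deficit_threshold = deficit_threshold, fixed_radius = fixed_radius,
       statistic = statistic, probs = probs,
       interpolation = match.arg(interpolation))
}

#' Run the full robust dose mapping pipeline
#'
#' Computes the baseline mapped dose on the whole destination grid, runs
#' [resample_oar()] for every organ, and assembles one destination dose
#' volume per mode (`baseline`, `fixed`, `KS1`..`KS4`) plus kernel-magnitude
#' and provenance volumes.
#'
#' @param dose_src source [scalar_volume()] (Gy).
#' @param oar_src named list of source organ [binary_mask()]s.
#' @param oar_dst named list of destination organ [binary_mask()]s (same
#'   names and order as `oar_src`).
#' @param dvfs list of M >= 2 [displacement_field()]s.
#' @param dst_geometry destination [grid_geometry()] (defaults to the first
#'   destination mask's grid).
#' @param baseline_field field for the baseline mapping (default
#'   `dvfs[[1]]`).
#' @param params a [road_params()] list.
#' @return An object of class `road_dose_map`: `geometry`, `dose` (named list
#'   of [scalar_volume()]s per mode), `km` (named list of per-mode KM
#'   [scalar_volume()]s, KS2..KS4), `provenance` ([scalar_volume()], integer
#'   codes 0 baseline / 1 kernel-sample / 2 KS3-expanded / 3 KS4-expanded /
#'   4 baseline-fallback), `oars` (per-organ results), `params`.
#' @export
road_map <- function(dose_src, oar_src, oar_dst, dvfs,
                     dst_geometry = NULL, baseline_field = dvfs[[1L]],
                     params = road_params()) {
  stopifnot(length(oar_src) == length(oar_dst))
  if (is.null(dst_geometry)) dst_geometry <- oar_dst[[1L]]$geometry
  for (m in oar_dst) {
    if (!same_geometry(m$geometry, dst_geometry)) {
      stop("destination masks must share the destination grid")
    }
  }
  mapped <- interpolate_field(baseline_field, dst_geometry)
  baseline <- pullback_dose(dose_src, mapped, dst_geometry,
                            interpolation = params$interpolation)
  oars <- vector("list", length(oar_src))
  names(oars) <- names(oar_src)
  for (k in seq_along(oar_src)) {
    oars[[k]] <- resample_oar(dose_src, oar_src[[k]], oar_dst[[k]], dvfs,
                              baseline_field = baseline_field, params = params)
  }
  modes <- c("fixed", "KS1", "KS2", "KS3", "KS4")
  dose <- list(baseline = baseline)
  for (mode in modes) {
    dose[[mode]] <- assemble_final(
      lapply(oars, function(o) list(dst_idx = o$dst_idx,
                                    values = o$dose[[mode]])),
      baseline)
  }
  km <- list()
  for (mode in c("KS2", "KS3", "KS4")) {
    kmv <- numeric(n_voxels(dst_geometry))
    for (o in oars) kmv[o$dst_idx] <- pmax(kmv[o$dst_idx], o$km[[mode]])
    km[[mode]] <- scalar_volume(kmv, dst_geometry)
  }
  provv <- integer(n_voxels(dst_geometry))
  for (o in oars) provv[o$dst_idx] <- pmax(provv[o$dst_idx], o$provenance)
  structure(list(geometry = dst_geometry, dose = dose, km = km,
                 provenance = scalar_volume(provv, dst_geometry),
                 oars = oars, params = params),
            class = "road_dose_map")
}

#' @export
print.road_dose_map <- function(x, ...) {
  cat(sprintf("road_dose_map: %d organ(s), modes %s\n", length(x$oars),
              paste(names(x$dose), collapse = ", ")))
  for (nm in names(x$oars)) {
    o <- x$oars[[nm]]
    cat(sprintf("  %s: %d voxels, coverage %.3f after %d KS4 iteration(s)%s\n",
                if (nzchar(nm)) nm else "<organ>", length(o$dst_idx),
                o$record$coverage, o$ks4_iterations,
                if (o$coverage_complete) "" else " [incomplete]"))
  }
  invisible(x)
}
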