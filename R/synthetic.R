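# Seeded synthetic test cases: phantom anatomy and dose, a smooth ground
# truth deformation, a family of plausible-but-discordant displacement
# fields standing in for independent DIR solutions, and localized coherent
# failures (the same error in every field) that discordance cannot see.

#' Synthetic case configuration
#'
#' The stated world for the generators. Positions are fractions of the
#' physical grid extent so the same anatomy scales with grid size. Defaults:
#' a 60^3 voxel grid at 3 mm; a 60 Gy prescription inside an ellipsoidal
#' target with a Gaussian falloff of about 8 mm; one ellipsoidal organ at
#' risk slightly overlapping the target edge so that the dose gradient runs
#' through it; a smooth global truth deformation of 4 mm amplitude; M = 3
#' fields whose per-axis noise has 2 mm RMS amplitude and 15 mm correlation
#' length (matching the low-single-digit-mm kernel magnitudes seen
#' clinically).
#'
#' @param dims,spacing,origin destination/source grid (shared by default).
#' @param prescription target dose (Gy).
#' @param target_centre_frac,target_semi_mm,falloff_mm dose model: ellipsoid
#'   centre (fraction of extent), semi-axes (mm) and Gaussian falloff scale
#'   (mm) outside the target surface.
#' @param organs named list; each organ is a list of lobes, each lobe a list
#'   with `centre_frac` and `semi_mm`.
#' @param jitter_mm per-axis uniform jitter applied to target and organ
#'   centres (mm) so seeds give distinct anatomies.
#' @param truth list: `type` (`"smooth"`, `"translation"`, `"zero"`),
#'   `amplitude` (mm), `corr_mm`, `n_bumps`, `translation` (mm, length 3),
#'   optional `inflate = list(centre_frac, radius_mm, factor)`.
#' @param family list: `M` fields, per-axis noise RMS `sigma` (mm),
#'   correlation length `corr_mm`.
#' @param failure `NULL`, or list `offset_mm` (magnitude, mm), `frac`
#'   (fraction of organ voxels, by true mapped dose, forming the failure
#'   region), `feather_mm` (boundary feathering).
#' @return Named configuration list.
#' @export
synth_config <- function(dims = c(60L, 60L, 60L), spacing = c(3, 3, 3),
                         origin = c(0, 0, 0), prescription = 60,
                         target_centre_frac = c(0.40, 0.5, 0.5),
                         target_semi_mm = c(12, 12, 12), falloff_mm = 8,
                         organs = list(oar = list(list(
                           centre_frac = c(0.52, 0.5, 0.5),
                           semi_mm = c(15, 12, 12)))),
                         jitter_mm = 2,
                         truth = list(type = "smooth", amplitude = 4,
                                      corr_mm = 40, n_bumps = 4L,
                                      translation = c(0, 0, 0),
                                      inflate = NULL),
                         family = list(M = 3L, sigma = 2, corr_mm = 15),
                         failure = NULL) {
  list(dims = as.integer(dims), spacing = spacing, origin = origin,
       prescription = prescription,
       target_centre_frac = target_centre_frac,
       target_semi_mm = target_semi_mm, falloff_mm = falloff_mm,
       organs = organs, jitter_mm = jitter_mm, truth = truth,
       family = family, failure = failure)
}

.extent <- function(geometry) (geometry$dims - 1L) * geometry$spacing

.frac_to_world <- function(geometry, frac) {
  geometry$origin + frac * .extent(geometry)
}

.inside_lobes <- function(pts, lobes) {
  inside <- rep(FALSE, nrow(pts))
  for (lb in lobes) {
    q <- sweep(sweep(pts, 2L, lb$centre), 2L, lb$semi, "/")
    inside <- inside | rowSums(q^2) <= 1
  }
  inside
}

.dose_at <- function(pts, target_centre, target_semi, falloff_mm,
                     prescription) {
  q <- sqrt(rowSums(sweep(sweep(pts, 2L, target_centre), 2L, target_semi,
                          "/")^2))
  s_mm <- exp(mean(log(target_semi)))  # mm per unit of q outside the surface
  d_out <- pmax(q - 1, 0) * s_mm
  prescription * exp(-(d_out / falloff_mm)^2 / 2)
}

#' Generate the phantom: grids, organ masks and the source dose
#'
#' Deterministic given the seed. The target and organ centres are jittered by
#' up to `jitter_mm` per axis; organs are voxelised by centre membership in
#' the analytic lobes; the dose is the prescription inside the target
#' ellipsoid with a Gaussian falloff outside, so at least one organ abuts the
#' dose gradient.
#'
#' @param config a [synth_config()].
#' @param seed integer seed, or `NULL` to use the current RNG stream.
#' @return List: `geometry` (shared source/destination [grid_geometry()]),
#'   `oar_src` (named list of [binary_mask()]s), `dose_src`
#'   ([scalar_volume()]), `target` (jittered centre/semi/falloff), `organs`
#'   (jittered analytic lobes), `dose_fun(pts)`, `inside_fun(pts, organ)`.
#' @export
make_phantom <- function(config = synth_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  geom <- grid_geometry(config$origin, config$spacing, config$dims)
  jit <- function() stats::runif(3L, -config$jitter_mm, config$jitter_mm)
  target_centre <- .frac_to_world(geom, config$target_centre_frac) + jit()
  organs <- lapply(config$organs, function(lobes) {
    lapply(lobes, function(lb) {
      list(centre = .frac_to_world(geom, lb$centre_frac) + jit(),
           semi = lb$semi_mm)
    })
  })
  ext <- .extent(geom)
  for (org in organs) for (lb in org) {
    if (any(lb$centre - lb$semi < geom$origin - geom$spacing) ||
        any(lb$centre + lb$semi > geom$origin + ext + geom$spacing)) {
      stop("organ extends outside the grid")
    }
  }
  ctr <- voxel_centres(geom)
  dose_fun <- function(pts) {
    .dose_at(.as_point_matrix(pts), target_centre, config$target_semi_mm,
             config$falloff_mm, config$prescription)
  }
  inside_fun <- function(pts, organ) {
    .inside_lobes(.as_point_matrix(pts), organs[[organ]])
  }
  oar_src <- lapply(names(organs), function(nm) {
    binary_mask(as.numeric(inside_fun(ctr, nm)), geom)
  })
  names(oar_src) <- names(organs)
  for (nm in names(oar_src)) {
    if (sum(oar_src[[nm]]$values) == 0) stop("organ '", nm, "' voxelised empty")
  }
  list(geometry = geom, oar_src = oar_src,
       dose_src = scalar_volume(dose_fun(ctr), geom),
       target = list(centre = target_centre, semi = config$target_semi_mm,
                     falloff_mm = config$falloff_mm,
                     prescription = config$prescription),
       organs = organs, dose_fun = dose_fun, inside_fun = inside_fun)
}

# periodic Gaussian low-pass of a 3-D array, correlation length ell (mm)
.gauss_smooth3d <- function(arr, spacing, ell) {
  d <- dim(arr)
  gax <- function(n, h) {
    f <- c(0:(floor(n / 2)), -(ceiling(n / 2) - 1):-1)[1:n] / (n * h)
    exp(-((2 * pi * f)^2 * ell^2) / 2)
  }
  g <- outer(outer(gax(d[1], spacing[1]), gax(d[2], spacing[2])),
             gax(d[3], spacing[3]))
  Re(stats::fft(stats::fft(arr) * g, inverse = TRUE)) / prod(d)
}

#' Generate a smooth, invertible ground-truth deformation
#'
#' Type `"smooth"` sums a few wide Gaussian-modulated displacement bumps of
#' at most `amplitude` mm each (plus any constant translation and optional
#' organ-inflation mode); `"translation"` is a constant field;
#' `"zero"` the identity. The Jacobian determinant is checked to be positive
#' everywhere; a folding draw is rejected and regenerated (up to 5 times).
#'
#' @param geometry the DVF grid (destination space).
#' @param truth the `truth` sub-list of [synth_config()].
#' @param seed integer seed, or `NULL` for the current RNG stream.
#' @return A [displacement_field()].
#' @export
make_true_deformation <- function(geometry, truth = synth_config()$truth,
                                  seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  type <- if (is.null(truth$type)) "smooth" else truth$type
  d <- geometry$dims
  for (attempt in 1:5) {
    v <- array(0, dim = c(d, 3L))
    tr <- if (is.null(truth$translation)) c(0, 0, 0) else truth$translation
    for (comp in 1:3) v[, , , comp] <- tr[comp]
    if (type == "smooth") {
      nb <- if (is.null(truth$n_bumps)) 4L else truth$n_bumps
      w <- if (is.null(truth$corr_mm)) 40 else truth$corr_mm
      amp <- if (is.null(truth$amplitude)) 4 else truth$amplitude
      ax <- lapply(1:3, function(a) {
        geometry$origin[a] + (0:(d[a] - 1L)) * geometry$spacing[a]
      })
      for (b in seq_len(nb)) {
        cb <- .frac_to_world(geometry, stats::runif(3L, 0.2, 0.8))
        dir <- stats::rnorm(3L)
        dir <- dir / sqrt(sum(dir^2))
        a_b <- amp * stats::runif(1L, 0.5, 1)
        g <- outer(outer(exp(-(ax[[1]] - cb[1])^2 / (2 * w^2)),
                         exp(-(ax[[2]] - cb[2])^2 / (2 * w^2))),
                   exp(-(ax[[3]] - cb[3])^2 / (2 * w^2)))
        for (comp in 1:3) v[, , , comp] <- v[, , , comp] + a_b * dir[comp] * g
      }
    }
    if (!is.null(truth$inflate)) {
      inf <- truth$inflate
      ic <- .frac_to_world(geometry, inf$centre_frac)
      rr <- inf$radius_mm
      ax <- lapply(1:3, function(a) {
        geometry$origin[a] + (0:(d[a] - 1L)) * geometry$spacing[a] - ic[a]
      })
      gx <- exp(-ax[[1]]^2 / (2 * rr^2))
      gy <- exp(-ax[[2]]^2 / (2 * rr^2))
      gz <- exp(-ax[[3]]^2 / (2 * rr^2))
      s <- inf$factor - 1
      v[, , , 1L] <- v[, , , 1L] + s * outer(outer(ax[[1]] * gx, gy), gz)
      v[, , , 2L] <- v[, , , 2L] + s * outer(outer(gx, ax[[2]] * gy), gz)
      v[, , , 3L] <- v[, , , 3L] + s * outer(outer(gx, gy), ax[[3]] * gz)
    }
    dvf <- displacement_field(v, geometry)
    if (type %in% c("zero", "translation")) return(dvf)
    jmin <- min(jacobian_determinant(dvf)$values)
    if (jmin > 0) return(dvf)
    warning(sprintf("truth deformation draw %d folds (min |J| = %.3f); regenerating",
                    attempt, jmin))
  }
  stop("could not generate an invertible truth deformation; reduce amplitude")
}

#' Generate a family of plausible, discordant displacement fields
#'
#' Each field is the truth plus its own smooth correlated noise field
#' (Gaussian-filtered white noise, per-axis RMS exactly `sigma` mm,
#' correlation length `corr_mm`), emulating independent registration
#' solutions whose discordance scales with the injected uncertainty.
#'
#' @param dvf_true the ground-truth [displacement_field()].
#' @param family the `family` sub-list of [synth_config()]: `M` (>= 2),
#'   `sigma` (mm, scalar or length 3), `corr_mm`.
#' @param seed integer seed, or `NULL` for the current RNG stream.
#' @return List of `M` [displacement_field()]s.
#' @export
make_dvf_family <- function(dvf_true, family = synth_config()$family,
                            seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- if (is.null(family$M)) 3L else as.integer(family$M)
  if (m < 2L) stop("family must have M >= 2 fields")
  sigma <- rep(family$sigma, length.out = 3L)
  ell <- family$corr_mm
  geom <- dvf_true$geometry
  d <- geom$dims
  out <- vector("list", m)
  for (k in seq_len(m)) {
    v <- dvf_true$vectors
    for (comp in 1:3) {
      if (sigma[comp] <= 0) next
      noise <- .gauss_smooth3d(array(stats::rnorm(prod(d)), dim = d),
                               geom$spacing, ell)
      noise <- noise * (sigma[comp] / sqrt(mean(noise^2)))
      v[, , , comp] <- v[, , , comp] + noise
    }
    out[[k]] <- displacement_field(v, geom)
  }
  out
}

#' Inject a coherent registration failure into every field
#'
#' Adds the SAME offset to all fields inside a destination-space region,
#' feathered smoothly to zero at the region boundary: inter-field
#' discordance stays low while the true mapping error is large — exactly the
#' scenario the conditional kernel expansions exist to catch.
#'
#' @param dvf_family list of [displacement_field()]s (common grid).
#' @param region [binary_mask()] on the same grid.
#' @param offset length-3 offset vector (mm).
#' @param feather_mm feathering length at the region boundary (mm); the
#'   default of one 3 mm dose voxel halves the offset on the region surface
#'   while leaving the interior at full strength.
#' @return The modified list of fields, with attribute `failure` recording
#'   the region and offset.
#' @export
inject_coherent_failure <- function(dvf_family, region, offset,
                                    feather_mm = 3) {
  geom <- dvf_family[[1L]]$geometry
  if (!same_geometry(region$geometry, geom)) {
    stop("failure region must live on the DVF grid")
  }
  idx <- mask_indices(region)
  if (length(idx) == 0L || all(offset == 0)) {
    attr(dvf_family, "failure") <- list(region = region, offset = offset)
    return(dvf_family)
  }
  surf <- .surface_indices(region)
  w <- rep(1, length(idx))
  if (length(surf) > 0L && feather_mm > 0) {
    dsurf <- .directed_distances(voxel_centres(geom, idx),
                                 voxel_centres(geom, surf))
    w <- pmin(1, (dsurf + min(geom$spacing) / 2) / feather_mm)
  }
  n <- n_voxels(geom)
  for (k in seq_along(dvf_family)) {
    for (comp in 1:3) {
      dvf_family[[k]]$vectors[idx + (comp - 1L) * n] <-
        dvf_family[[k]]$vectors[idx + (comp - 1L) * n] + offset[comp] * w
    }
  }
  attr(dvf_family, "failure") <- list(region = region, offset = offset,
                                      feather_mm = feather_mm, weight = w)
  dvf_family
}

#' Generate a complete seeded synthetic case
#'
#' Assembles phantom, truth deformation, field family and (optionally) a
#' coherent failure into one self-consistent case: destination organ masks
#' are the exact pull-back of the voxelised source organs through the truth
#' field, so the truth genuinely relates the two spaces. The failure region,
#' when requested, is the fraction of destination organ voxels with the
#' highest TRUE mapped dose (i.e. the part of the organ abutting the dose
#' gradient), and the offset pushes their mapped points directly down the
#' gradient (away from the target centre).
#'
#' @param config a [synth_config()].
#' @param seed integer seed; identical seeds give bit-identical cases.
#' @return An object of class `synthetic_case`: `geometry_src`,
#'   `geometry_dst`, `dose_src`, `oar_src`, `oar_dst`, `dvf_true`,
#'   `dvf_family`, `failure` (or `NULL`), `true_points`, `seed`, `config`.
#' @export
synth_case <- function(config = synth_config(), seed = 1L) {
  set.seed(seed)
  ph <- make_phantom(config, seed = NULL)
  geom <- ph$geometry
  dvf_true <- make_true_deformation(geom, config$truth, seed = NULL)
  mapped_true <- interpolate_field(dvf_true, geom)
  oar_dst <- lapply(ph$oar_src, pullback_mask, mapped = mapped_true,
                    dst_geometry = geom)
  family <- make_dvf_family(dvf_true, config$family, seed = NULL)
  failure <- NULL
  if (!is.null(config$failure)) {
    fc <- config$failure
    frac <- if (is.null(fc$frac)) 0.4 else fc$frac
    feather <- if (is.null(fc$feather_mm)) 3 else fc$feather_mm
    oar_idx <- mask_indices(oar_dst[[1L]])
    true_dose <- ph$dose_fun(mapped_true$points[oar_idx, , drop = FALSE])
    cut <- stats::quantile(true_dose, probs = 1 - frac, names = FALSE)
    sel <- oar_idx[true_dose >= cut]
    region_vals <- numeric(n_voxels(geom))
    region_vals[sel] <- 1
    region <- binary_mask(region_vals, geom)
    centroid <- colMeans(mapped_true$points[sel, , drop = FALSE])
    dir <- centroid - ph$target$centre
    nd <- sqrt(sum(dir^2))
    dir <- if (nd > 1e-9) dir / nd else c(1, 0, 0)
    offset <- dir * fc$offset_mm
    family <- inject_coherent_failure(family, region, offset,
                                      feather_mm = feather)
    failure <- list(region = region, offset = offset, feather_mm = feather)
  }
  structure(list(geometry_src = geom, geometry_dst = geom,
                 dose_src = ph$dose_src, oar_src = ph$oar_src,
                 oar_dst = oar_dst, dvf_true = dvf_true,
                 dvf_family = family, failure = failure,
                 target = ph$target, dose_fun = ph$dose_fun,
                 true_points = mapped_true$points, seed = seed,
                 config = config),
            class = "synthetic_case")
}

#' @export
print.synthetic_case <- function(x, ...) {
  cat(sprintf("synthetic_case (seed %d): %d^3-ish grid at (%g, %g, %g) mm, %d organ(s), M = %d fields%s\n",
              x$seed, x$geometry_dst$dims[1],
              x$geometry_dst$spacing[1], x$geometry_dst$spacing[2],
              x$geometry_dst$spacing[3], length(x$oar_src),
              length(x$dvf_family),
              if (is.null(x$failure)) ""
              else sprintf(", coherent failure |offset| = %.1f mm",
                           sqrt(sum(x$failure$offset^2)))))
  invisible(x)
}
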