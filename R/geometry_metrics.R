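# Geometric evaluation: kernel magnitude maps and summaries, surface distance
# metrics between contours (MDA, Hausdorff), correlations, and Jacobian
# determinant maps of displacement fields.

#' Kernel magnitude
#'
#' Root mean square of the per-axis effective kernel semi-dimensions. For the
#' expanded modes the cumulative isotropic radius enters each axis
#' (`KD_l + r`), so expansions grow the reported magnitude.
#'
#' @param kd K x 3 matrix (or length-3 vector) of semi-dimensions (mm).
#' @param r cumulative expansion radius per kernel (mm), default 0.
#' @return Numeric vector of kernel magnitudes (mm).
#' @examples
#' kernel_magnitude(c(3, 3, 3))    # 3
#' kernel_magnitude(c(3, 4, 0))    # sqrt(25/3)
#' @export
kernel_magnitude <- function(kd, r = 0) {
  if (!is.matrix(kd)) kd <- matrix(kd, nrow = 1L)
  sqrt(rowMeans((kd + r)^2))
}

#' Per-organ kernel magnitude summary
#'
#' Mean, interquartile range and maximum of the voxel-level KM distribution,
#' per mode (KS2/KS3/KS4), for one organ.
#'
#' @param oar_result one element of `road_map()$oars`.
#' @return data.frame with columns mode, mean_km, iqr_km, max_km.
#' @export
km_summary <- function(oar_result) {
  do.call(rbind, lapply(names(oar_result$km), function(mode) {
    km <- oar_result$km[[mode]]
    data.frame(mode = mode, mean_km = mean(km), iqr_km = stats::IQR(km),
               max_km = max(km))
  }))
}

# linear indices of face-connected surface voxels of a mask
.surface_indices <- function(mask) {
  v <- mask$values
  d <- dim(v)
  pad <- array(0L, dim = d + 2L)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- v
  core <- pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)]
  nb <- pad[1:d[1], 2:(d[2] + 1), 2:(d[3] + 1)] +
    pad[3:(d[1] + 2), 2:(d[2] + 1), 2:(d[3] + 1)] +
    pad[2:(d[1] + 1), 1:d[2], 2:(d[3] + 1)] +
    pad[2:(d[1] + 1), 3:(d[2] + 2), 2:(d[3] + 1)] +
    pad[2:(d[1] + 1), 2:(d[2] + 1), 1:d[3]] +
    pad[2:(d[1] + 1), 2:(d[2] + 1), 3:(d[3] + 2)]
  which(core == 1L & nb < 6L)
}

# directed nearest-surface distances from points a to points b (mm)
.directed_distances <- function(a, b) {
  out <- numeric(nrow(a))
  chunk <- 1024L
  b2 <- rowSums(b^2)
  for (s in seq(1L, nrow(a), by = chunk)) {
    e <- min(s + chunk - 1L, nrow(a))
    aa <- a[s:e, , drop = FALSE]
    d2 <- outer(rowSums(aa^2), b2, "+") - 2 * aa %*% t(b)
    out[s:e] <- sqrt(pmax(apply(d2, 1L, min), 0))
  }
  out
}

#' Surface distance metrics between two masks
#'
#' Surface voxels are mask voxels with at least one face neighbour outside
#' the mask. MDA is the symmetric mean surface distance (average of the two
#' directed means); HD is the full symmetric Hausdorff distance (maximum of
#' the two directed maxima). Distances are between surface voxel centres, in
#' mm. Both are 0 for identical masks and HD >= MDA always.
#'
#' @param a,b [binary_mask()]s on a common grid, both non-empty.
#' @return List with `mda`, `hd` (mm) and the directed components
#'   `mean_a_to_b`, `mean_b_to_a`, `max_a_to_b`, `max_b_to_a`.
#' @export
surface_distance_metrics <- function(a, b) {
  if (!same_geometry(a$geometry, b$geometry)) {
    stop("masks must share a common grid")
  }
  if (sum(a$values) == 0L) stop("surface_distance_metrics: mask 'a' is empty")
  if (sum(b$values) == 0L) stop("surface_distance_metrics: mask 'b' is empty")
  sa <- voxel_centres(a$geometry, .surface_indices(a))
  sb <- voxel_centres(b$geometry, .surface_indices(b))
  dab <- .directed_distances(sa, sb)
  dba <- .directed_distances(sb, sa)
  mda <- (mean(dab) + mean(dba)) / 2
  hd <- max(max(dab), max(dba))
  list(mda = mda, hd = hd,
       mean_a_to_b = mean(dab), mean_b_to_a = mean(dba),
       max_a_to_b = max(dab), max_b_to_a = max(dba))
}

#' Correlation between two series
#'
#' Product-moment (Pearson, default) or rank (Spearman) correlation with the
#' degenerate cases flagged rather than silently propagated.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return The coefficient in `[-1, 1]`, or `NA` with a warning when either
#'   series has zero variance.
#' @export
pearson_correlation <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (length(x) != length(y)) stop("series must have equal length")
  if (length(x) < 3L) stop("at least 3 paired observations are required")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("zero variance: correlation undefined")
    return(NA_real_)
  }
  stats::cor(x, y, method = method)
}

#' Jacobian determinant of a displacement field
#'
#' Determinant of `I + grad(u)` with gradients of the displacement taken by
#' central differences in mm (one-sided at grid edges). The identity field
#' and any rigid translation give exactly 1 everywhere; values below 1
#' indicate local contraction, above 1 local expansion, and values <= 0
#' folding.
#'
#' @param dvf a [displacement_field()] with at least 3 voxels per axis.
#' @return A [scalar_volume()] on the DVF grid.
#' @export
jacobian_determinant <- function(dvf) {
  d <- dvf$geometry$dims
  if (any(d < 3L)) stop("DVF grid must have at least 3 voxels per axis")
  sp <- dvf$geometry$spacing
  g <- vector("list", 9L)  # g[[3*(comp-1)+axis]] = d u_comp / d axis
  for (comp in 1:3) {
    u <- array(dvf$vectors[, , , comp], dim = d)
    for (axis in 1:3) {
      gp <- .axis_diff(u, axis) / sp[axis]
      g[[3L * (comp - 1L) + axis]] <- gp
    }
  }
  j11 <- 1 + g[[1]]; j12 <- g[[2]]; j13 <- g[[3]]
  j21 <- g[[4]]; j22 <- 1 + g[[5]]; j23 <- g[[6]]
  j31 <- g[[7]]; j32 <- g[[8]]; j33 <- 1 + g[[9]]
  det <- j11 * (j22 * j33 - j23 * j32) -
    j12 * (j21 * j33 - j23 * j31) +
    j13 * (j21 * j32 - j22 * j31)
  scalar_volume(det, dvf$geometry)
}

# central differences along one axis, one-sided at the edges (per unit index)
.axis_diff <- function(u, axis) {
  d <- dim(u)
  n <- d[axis]
  idx_p <- pmin(seq_len(n) + 1L, n)
  idx_m <- pmax(seq_len(n) - 1L, 1L)
  h <- (idx_p - idx_m)  # 2 in the interior, 1 at the edges
  pick <- function(i) {
    switch(axis,
           u[i, , , drop = FALSE],
           u[, i, , drop = FALSE],
           u[, , i, drop = FALSE])
  }
  out <- (pick(idx_p) - pick(idx_m))
  hh <- switch(axis,
               array(h, dim = d),
               aperm(array(h, dim = d[c(2, 1, 3)]), c(2, 1, 3)),
               aperm(array(h, dim = d[c(3, 1, 2)]), c(2, 3, 1)))
  array(out / hh, dim = d)
}

#' Export a kernel-magnitude heatmap slice
#'
#' Writes a PNG heat map of one axial (k) slice of a KM volume with organ
#' contour outlines and a mm colour scale. Deterministic given its inputs.
#'
#' @param km_volume KM [scalar_volume()] (mm).
#' @param masks named list of [binary_mask()]s to outline (same grid).
#' @param slice 1-based k index of the slice (default: the slice with the
#'   largest summed KM).
#' @param file output PNG path.
#' @param image optional background [scalar_volume()] (e.g. dose) shown in
#'   grey under the KM overlay.
#' @return `file`, invisibly.
#' @export
km_overlay_export <- function(km_volume, masks = list(), slice = NULL,
                              file = "km_overlay.png", image = NULL) {
  v <- km_volume$values
  if (is.null(slice)) {
    slice <- which.max(apply(v, 3L, sum))
  }
  geom <- km_volume$geometry
  xs <- geom$origin[1L] + (seq_len(geom$dims[1L]) - 1L) * geom$spacing[1L]
  ys <- geom$origin[2L] + (seq_len(geom$dims[2L]) - 1L) * geom$spacing[2L]
  grDevices::png(file, width = 900, height = 800)
  on.exit(grDevices::dev.off())
  graphics::par(mar = c(4, 4, 3, 6))
  if (!is.null(image)) {
    graphics::image(xs, ys, image$values[, , slice],
                    col = grDevices::grey.colors(64), xlab = "x (mm)",
                    ylab = "y (mm)", useRaster = TRUE)
    graphics::image(xs, ys, v[, , slice],
                    col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE,
                                                alpha = 0.6),
                    add = TRUE, useRaster = TRUE)
  } else {
    graphics::image(xs, ys, v[, , slice],
                    col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE),
                    xlab = "x (mm)", ylab = "y (mm)", useRaster = TRUE)
  }
  cols <- grDevices::palette.colors(max(1L, length(masks)))
  for (i in seq_along(masks)) {
    graphics::contour(xs, ys, masks[[i]]$values[, , slice], levels = 0.5,
                      add = TRUE, drawlabels = FALSE, col = cols[i], lwd = 2)
  }
  graphics::title(main = sprintf("Kernel magnitude (mm), slice k = %d [max %.1f mm]",
                                 slice, max(v[, , slice])))
  graphics::mtext(sprintf("KM range 0 - %.1f mm", max(v)), side = 4, line = 2)
  invisible(file)
}
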