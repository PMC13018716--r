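# Regular-grid geometry, scalar/vector volumes, interpolation and pull-back
# warping. Voxel-centre convention throughout: world(i) = origin + i * spacing
# with 0-based integer indices; all distances in millimetres.

#' Regular 3-D grid geometry
#'
#' Describes a regular voxel lattice by the world position (mm) of the centre
#' of voxel (0,0,0), the per-axis voxel size (mm) and the per-axis voxel
#' counts. Indices are 0-based and `world(i) = origin + i * spacing`.
#'
#' @param origin numeric length 3, world position (mm) of the centre of voxel
#'   (0,0,0).
#' @param spacing numeric length 3, strictly positive voxel size (mm).
#' @param dims integer length 3, voxel counts (all >= 1).
#' @return An object of class `grid_geometry`.
#' @examples
#' g <- grid_geometry(c(0, 0, 0), c(3, 3, 3), c(10, 10, 10))
#' index_to_world(g, c(1, 2, 3))
#' @export
grid_geometry <- function(origin, spacing, dims) {
  origin <- as.numeric(origin)
  spacing <- as.numeric(spacing)
  dims <- as.integer(dims)
  stopifnot(length(origin) == 3L, length(spacing) == 3L, length(dims) == 3L)
  if (any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("spacing must be strictly positive on all axes")
  }
  if (any(is.na(dims)) || any(dims < 1L)) stop("dims must be >= 1 on all axes")
  structure(list(origin = origin, spacing = spacing, dims = dims),
            class = "grid_geometry")
}

#' @export
print.grid_geometry <- function(x, ...) {
  cat(sprintf("grid_geometry: %d x %d x %d voxels, spacing (%g, %g, %g) mm, origin (%g, %g, %g) mm\n",
              x$dims[1], x$dims[2], x$dims[3],
              x$spacing[1], x$spacing[2], x$spacing[3],
              x$origin[1], x$origin[2], x$origin[3]))
  invisible(x)
}

n_voxels <- function(geometry) prod(geometry$dims)

#' Voxel volume in cubic centimetres
#' @param geometry a [grid_geometry()].
#' @return Voxel volume in cc.
#' @export
voxel_volume_cc <- function(geometry) prod(geometry$spacing) / 1000

same_geometry <- function(a, b, tol = 1e-9) {
  all(a$dims == b$dims) &&
    all(abs(a$origin - b$origin) <= tol) &&
    all(abs(a$spacing - b$spacing) <= tol)
}

.as_point_matrix <- function(p) {
  if (is.matrix(p)) {
    stopifnot(ncol(p) == 3L)
    p
  } else {
    stopifnot(length(p) == 3L)
    matrix(as.numeric(p), nrow = 1L)
  }
}

#' World to continuous index (and back)
#'
#' `world_to_index()` inverts the voxel-centre convention: index (0,0,0) maps
#' to the origin. Out-of-bounds positions are converted as-is (callers clip).
#' `index_to_world()` is its inverse on continuous indices.
#'
#' @param geometry a [grid_geometry()].
#' @param p world point(s), length-3 vector or an N x 3 matrix (mm).
#' @param i continuous 0-based index triple(s), vector or N x 3 matrix.
#' @return Matrix (N x 3) of continuous indices / world coordinates; a
#'   length-3 vector when the input was a vector.
#' @export
world_to_index <- function(geometry, p) {
  m <- .as_point_matrix(p)
  out <- sweep(sweep(m, 2L, geometry$origin, "-"), 2L, geometry$spacing, "/")
  if (!is.matrix(p)) out <- drop(out)
  out
}

#' @rdname world_to_index
#' @export
index_to_world <- function(geometry, i) {
  m <- .as_point_matrix(i)
  out <- sweep(sweep(m, 2L, geometry$spacing, "*"), 2L, geometry$origin, "+")
  if (!is.matrix(i)) out <- drop(out)
  out
}

# 1-based linear index from 0-based ijk matrix (no bounds checking)
.lin_index <- function(geometry, ijk) {
  d <- geometry$dims
  1L + ijk[, 1L] + d[1L] * (ijk[, 2L] + d[2L] * ijk[, 3L])
}

# 0-based ijk matrix from 1-based linear indices
.ijk_index <- function(geometry, lin) {
  arrayInd(lin, .dim = geometry$dims) - 1L
}

#' Voxel-centre world coordinates
#'
#' @param geometry a [grid_geometry()].
#' @param lin optional 1-based linear voxel indices (default: all voxels in
#'   array order, first axis fastest).
#' @return N x 3 matrix of world coordinates (mm).
#' @export
voxel_centres <- function(geometry, lin = NULL) {
  if (is.null(lin)) lin <- seq_len(n_voxels(geometry))
  index_to_world(geometry, .ijk_index(geometry, lin))
}

#' Scalar and binary volumes on a regular grid
#'
#' `scalar_volume()` stores one scalar per voxel (dose in Gy or similar);
#' `binary_mask()` stores a whole-voxel membership indicator (0/1, fractional
#' ownership is not represented).
#'
#' @param values numeric array with `dim == geometry$dims` (or a vector of
#'   matching length, reshaped in array order).
#' @param geometry a [grid_geometry()].
#' @return An object of class `scalar_volume` / `binary_mask`.
#' @export
scalar_volume <- function(values, geometry) {
  values <- .shape_values(values, geometry)
  structure(list(values = values, geometry = geometry), class = "scalar_volume")
}

#' @rdname scalar_volume
#' @export
binary_mask <- function(values, geometry) {
  values <- .shape_values(values, geometry)
  if (!all(values %in% c(0, 1))) stop("mask values must all be 0 or 1")
  structure(list(values = values, geometry = geometry), class = "binary_mask")
}

.shape_values <- function(values, geometry) {
  if (is.null(dim(values))) {
    if (length(values) != n_voxels(geometry)) {
      stop("value count does not equal the product of dims")
    }
    dim(values) <- geometry$dims
  } else if (!all(dim(values) == geometry$dims)) {
    stop("value array dimensions do not match the grid dims")
  }
  values
}

#' @export
print.scalar_volume <- function(x, ...) {
  cat(sprintf("scalar_volume: %d x %d x %d, range [%g, %g]\n",
              x$geometry$dims[1], x$geometry$dims[2], x$geometry$dims[3],
              min(x$values), max(x$values)))
  invisible(x)
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("binary_mask: %d x %d x %d, %d voxels set\n",
              x$geometry$dims[1], x$geometry$dims[2], x$geometry$dims[3],
              sum(x$values)))
  invisible(x)
}

#' 1-based linear indices of the voxels set in a mask
#' @param mask a [binary_mask()].
#' @return Integer vector of linear indices.
#' @export
mask_indices <- function(mask) which(mask$values == 1)

#' Displacement vector field on a destination-space grid
#'
#' Per-grid-point 3-vectors (mm). Convention: the mapped source-space point of
#' a destination position `x` is `x + v(x)` — vectors point from the regular
#' destination grid into the (non-regular) source space.
#'
#' @param vectors numeric 4-D array `dims x 3` (last axis = vector component),
#'   or an N x 3 matrix in array order.
#' @param geometry the DVF grid, a [grid_geometry()].
#' @return An object of class `displacement_field`.
#' @export
displacement_field <- function(vectors, geometry) {
  n <- n_voxels(geometry)
  if (is.matrix(vectors)) {
    stopifnot(nrow(vectors) == n, ncol(vectors) == 3L)
    vectors <- array(vectors, dim = c(geometry$dims, 3L))
  } else {
    d <- dim(vectors)
    if (length(d) != 4L || !all(d == c(geometry$dims, 3L))) {
      stop("vector array must have dim c(dims, 3)")
    }
  }
  structure(list(vectors = vectors, geometry = geometry),
            class = "displacement_field")
}

#' Identity displacement field on a grid
#' @param geometry a [grid_geometry()].
#' @return A [displacement_field()] with all-zero vectors.
#' @export
identity_field <- function(geometry) {
  displacement_field(array(0, dim = c(geometry$dims, 3L)), geometry)
}

# Vectorised trilinear sampling of a 3-D array at continuous 0-based indices.
# Indices are assumed already clamped to [0, n-1]; dims of size 1 are handled.
.trilinear_sample <- function(arr, ci) {
  d <- dim(arr)
  n <- nrow(ci)
  i0 <- matrix(0L, n, 3L)
  fr <- matrix(0, n, 3L)
  for (a in 1:3) {
    if (d[a] == 1L) next
    f0 <- pmin(pmax(floor(ci[, a]), 0), d[a] - 2)
    i0[, a] <- as.integer(f0)
    fr[, a] <- pmin(pmax(ci[, a] - f0, 0), 1)
  }
  out <- numeric(n)
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    w <- (if (dx) fr[, 1L] else 1 - fr[, 1L]) *
         (if (dy) fr[, 2L] else 1 - fr[, 2L]) *
         (if (dz) fr[, 3L] else 1 - fr[, 3L])
    nz <- w > 0
    if (!any(nz)) next
    lin <- 1L + (i0[nz, 1L] + dx * (d[1L] > 1L)) +
      d[1L] * ((i0[nz, 2L] + dy * (d[2L] > 1L)) +
                 d[2L] * (i0[nz, 3L] + dz * (d[3L] > 1L)))
    out[nz] <- out[nz] + w[nz] * arr[lin]
  }
  out
}

#' Map world points through a displacement field
#'
#' Trilinearly interpolates each vector component of `dvf` at arbitrary world
#' positions and returns the mapped source-space points `p + v(p)`. Points
#' outside the DVF grid's voxel-centre bounding box use the nearest-edge
#' vector and are flagged.
#'
#' @param dvf a [displacement_field()].
#' @param p world point(s), length-3 vector or N x 3 matrix (mm).
#' @return List with `points` (N x 3 mapped source points, mm) and `oob`
#'   (logical N, TRUE where the query fell outside the DVF box).
#' @export
map_points <- function(dvf, p) {
  pts <- .as_point_matrix(p)
  ci <- world_to_index(dvf$geometry, pts)
  if (!is.matrix(ci)) ci <- matrix(ci, nrow = 1L)
  d <- dvf$geometry$dims
  oob <- (ci[, 1L] < 0 | ci[, 1L] > d[1L] - 1L |
            ci[, 2L] < 0 | ci[, 2L] > d[2L] - 1L |
            ci[, 3L] < 0 | ci[, 3L] > d[3L] - 1L)
  for (a in 1:3) ci[, a] <- pmin(pmax(ci[, a], 0), d[a] - 1L)
  v <- matrix(0, nrow(pts), 3L)
  for (comp in 1:3) {
    v[, comp] <- .trilinear_sample(dvf$vectors[, , , comp, drop = FALSE] |>
                                     array(dim = d), ci)
  }
  list(points = pts + v, oob = oob)
}

#' Interpolate a displacement field onto a query grid
#'
#' Each query voxel centre receives a trilinearly interpolated vector; the
#' mapped point is the voxel-centre world position plus that vector. Query
#' centres outside the DVF bounding box use the nearest-edge vector and carry
#' a warning flag.
#'
#' @param dvf a [displacement_field()] (typically on a finer grid).
#' @param query_geometry the grid (e.g. the dose grid) to interpolate onto.
#' @param lin optional 1-based linear voxel indices of `query_geometry` to
#'   restrict the computation to (default: all voxels).
#' @return List with `points` (N x 3 mapped source points, mm) and `oob`
#'   (logical N).
#' @export
interpolate_field <- function(dvf, query_geometry, lin = NULL) {
  map_points(dvf, voxel_centres(query_geometry, lin))
}

#' Pull back a source dose volume onto a destination grid
#'
#' Creates a mapped ("baseline") dose: each destination voxel takes the source
#' dose at its mapped source point, by trilinear interpolation (TPS-like,
#' default) or nearest-voxel lookup. Points outside the source dose grid
#' receive 0 Gy and an out-of-field flag.
#'
#' @param dose_src source [scalar_volume()] (Gy).
#' @param mapped the result of [interpolate_field()] (or an N x 3 point
#'   matrix) for every voxel of `dst_geometry`.
#' @param dst_geometry destination [grid_geometry()].
#' @param interpolation `"trilinear"` or `"nearest"`.
#' @return A [scalar_volume()] on `dst_geometry`, with attribute
#'   `out_of_field` (logical array) marking voxels mapped outside the source
#'   dose grid.
#' @export
pullback_dose <- function(dose_src, mapped, dst_geometry,
                          interpolation = c("trilinear", "nearest")) {
  interpolation <- match.arg(interpolation)
  pts <- if (is.list(mapped)) mapped$points else .as_point_matrix(mapped)
  stopifnot(nrow(pts) == n_voxels(dst_geometry))
  ci <- world_to_index(dose_src$geometry, pts)
  d <- dose_src$geometry$dims
  vals <- numeric(nrow(pts))
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
      vals[inside] <- dose_src$values[.lin_index(dose_src$geometry,
                                                 r[inside, , drop = FALSE])]
    }
  }
  out <- scalar_volume(vals, dst_geometry)
  oof <- array(!inside, dim = dst_geometry$dims)
  attr(out, "out_of_field") <- oof
  out
}

#' Pull back a source binary mask onto a destination grid
#'
#' A destination voxel is inside the mapped structure iff its mapped source
#' point falls inside a source voxel with mask value 1 (nearest-voxel
#' membership, no partial volumes). Out-of-bounds points map to 0.
#'
#' @param mask_src source [binary_mask()].
#' @inheritParams pullback_dose
#' @return A [binary_mask()] on `dst_geometry`.
#' @export
pullback_mask <- function(mask_src, mapped, dst_geometry) {
  pts <- if (is.list(mapped)) mapped$points else .as_point_matrix(mapped)
  stopifnot(nrow(pts) == n_voxels(dst_geometry))
  r <- round(world_to_index(mask_src$geometry, pts))
  d <- mask_src$geometry$dims
  inside <- r[, 1L] >= 0 & r[, 1L] <= d[1L] - 1L &
    r[, 2L] >= 0 & r[, 2L] <= d[2L] - 1L &
    r[, 3L] >= 0 & r[, 3L] <= d[3L] - 1L
  vals <- numeric(nrow(pts))
  if (any(inside)) {
    vals[inside] <- mask_src$values[.lin_index(mask_src$geometry,
                                               r[inside, , drop = FALSE])]
  }
  binary_mask(vals, dst_geometry)
}
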