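# Minimal NIfTI-1 I/O. The pre-installed R stack has no NIfTI package, so a
# deliberately small reader/writer is provided: single-file .nii,
# little-endian, axis-aligned sform (no rotations/flips), float32/float64
# data, scalar 3-D volumes and 3-component vector fields (dim[0] = 5,
# intent NIFTI_INTENT_VECTOR). Displacements are stored in mm using the
# destination-to-source convention, documented in a JSON sidecar.

.NIFTI_HDR_SIZE <- 348L
.NIFTI_VOX_OFFSET <- 352
.NIFTI_INTENT_VECTOR <- 1007L

.nifti_write_header <- function(con, dims8, pixdim8, datatype, bitpix,
                                intent_code, origin, spacing) {
  writeBin(.NIFTI_HDR_SIZE, con, size = 4L, endian = "little")  # sizeof_hdr
  writeBin(raw(35L), con)                                       # unused
  writeBin(as.raw(0L), con)                                     # dim_info
  writeBin(as.integer(dims8), con, size = 2L, endian = "little")
  writeBin(numeric(3L), con, size = 4L, endian = "little")      # intent_p1-3
  writeBin(as.integer(intent_code), con, size = 2L, endian = "little")
  writeBin(as.integer(datatype), con, size = 2L, endian = "little")
  writeBin(as.integer(bitpix), con, size = 2L, endian = "little")
  writeBin(0L, con, size = 2L, endian = "little")               # slice_start
  writeBin(as.numeric(pixdim8), con, size = 4L, endian = "little")
  writeBin(.NIFTI_VOX_OFFSET, con, size = 4L, endian = "little")
  writeBin(1, con, size = 4L, endian = "little")                # scl_slope
  writeBin(0, con, size = 4L, endian = "little")                # scl_inter
  writeBin(0L, con, size = 2L, endian = "little")               # slice_end
  writeBin(as.raw(c(0L, 2L)), con)                              # slice_code, xyzt_units = mm
  writeBin(numeric(4L), con, size = 4L, endian = "little")      # cal_max..toffset
  writeBin(c(0L, 0L), con, size = 4L, endian = "little")        # glmax, glmin
  writeBin(raw(80L), con)                                       # descrip
  writeBin(raw(24L), con)                                       # aux_file
  writeBin(c(0L, 1L), con, size = 2L, endian = "little")        # qform=0, sform=1
  writeBin(numeric(6L), con, size = 4L, endian = "little")      # quatern b,c,d + qoffset x,y,z
  srow <- rbind(c(spacing[1], 0, 0, origin[1]),
                c(0, spacing[2], 0, origin[2]),
                c(0, 0, spacing[3], origin[3]))
  writeBin(as.numeric(t(srow)), con, size = 4L, endian = "little")
  writeBin(raw(16L), con)                                       # intent_name
  writeBin(c(charToRaw("n+1"), as.raw(0L)), con)                # magic
  writeBin(numeric(1L), con, size = 4L, endian = "little")      # extender pad
}

#' Write a volume or displacement field as NIfTI-1
#'
#' Scalar volumes and binary masks are written as 3-D float64 images;
#' displacement fields as 5-D images with three vector components
#' (`dim = c(nx, ny, nz, 1, 3)`, intent code 1007). Geometry goes into an
#' axis-aligned sform. A `.json` sidecar recording the grid and the
#' displacement convention is written alongside.
#'
#' @param x a [scalar_volume()], [binary_mask()] or [displacement_field()].
#' @param path output path ending in `.nii`.
#' @param sidecar write the JSON sidecar (default TRUE).
#' @return `path`, invisibly.
#' @export
write_nifti <- function(x, path, sidecar = TRUE) {
  geom <- x$geometry
  is_field <- inherits(x, "displacement_field")
  con <- file(path, "wb")
  on.exit(close(con))
  if (is_field) {
    dims8 <- c(5L, geom$dims, 1L, 3L, 1L, 1L)
    data <- as.numeric(x$vectors)
    intent <- .NIFTI_INTENT_VECTOR
  } else {
    dims8 <- c(3L, geom$dims, 1L, 1L, 1L, 1L)
    data <- as.numeric(x$values)
    intent <- 0L
  }
  pixdim8 <- c(1, geom$spacing, 1, 1, 1, 1)
  .nifti_write_header(con, dims8, pixdim8, datatype = 64L, bitpix = 64L,
                      intent_code = intent, origin = geom$origin,
                      spacing = geom$spacing)
  writeBin(data, con, size = 8L, endian = "little")
  if (sidecar) {
    meta <- list(
      origin_mm = geom$origin, spacing_mm = geom$spacing, dims = geom$dims,
      kind = if (is_field) "displacement_field"
             else if (inherits(x, "binary_mask")) "binary_mask" else "scalar_volume",
      convention = if (is_field)
        "vectors map destination voxel centres to source-space points; mapped = centre + vector; units mm"
      else "voxel-centre world convention, 0-based indices, units mm"
    )
    jsonlite::write_json(meta, paste0(tools::file_path_sans_ext(path), ".json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

.nifti_read_raw <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  sizeof_hdr <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  if (!identical(sizeof_hdr, .NIFTI_HDR_SIZE)) {
    stop("not a little-endian NIfTI-1 file: ", path)
  }
  seek(con, 40L)
  dims8 <- readBin(con, "integer", 8L, size = 2L, endian = "little")
  seek(con, 70L)
  datatype <- readBin(con, "integer", 1L, size = 2L, endian = "little")
  seek(con, 76L)
  pixdim8 <- readBin(con, "numeric", 8L, size = 4L, endian = "little")
  vox_offset <- readBin(con, "numeric", 1L, size = 4L, endian = "little")
  scl_slope <- readBin(con, "numeric", 1L, size = 4L, endian = "little")
  scl_inter <- readBin(con, "numeric", 1L, size = 4L, endian = "little")
  seek(con, 254L)
  sform_code <- readBin(con, "integer", 1L, size = 2L, endian = "little")
  seek(con, 280L)
  srow <- matrix(readBin(con, "numeric", 12L, size = 4L, endian = "little"),
                 nrow = 3L, byrow = TRUE)
  nd <- dims8[1L]
  shape <- dims8[2L:(1L + max(nd, 3L))]
  shape <- shape[shape > 0L]
  ntot <- prod(shape)
  seek(con, vox_offset)
  data <- switch(as.character(datatype),
    "16" = readBin(con, "numeric", ntot, size = 4L, endian = "little"),
    "64" = readBin(con, "numeric", ntot, size = 8L, endian = "little"),
    "4"  = readBin(con, "integer", ntot, size = 2L, endian = "little"),
    "8"  = readBin(con, "integer", ntot, size = 4L, endian = "little"),
    "2"  = as.integer(readBin(con, "raw", ntot)),
    stop("unsupported NIfTI datatype: ", datatype))
  if (length(data) != ntot) stop("truncated NIfTI data in ", path)
  if (scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0)) {
    data <- data * scl_slope + scl_inter
  }
  if (sform_code > 0L) {
    spacing <- c(srow[1L, 1L], srow[2L, 2L], srow[3L, 3L])
    origin <- srow[, 4L]
    rot <- srow[, 1:3]
    if (any(abs(rot[upper.tri(rot) | lower.tri(rot)]) > 1e-6)) {
      stop("only axis-aligned sforms are supported: ", path)
    }
    if (any(spacing <= 0)) stop("negative/zero sform spacings unsupported: ", path)
  } else {
    spacing <- abs(pixdim8[2:4])
    origin <- c(0, 0, 0)
  }
  list(shape = shape, data = data,
       geometry = grid_geometry(origin, spacing, shape[1:3]))
}

#' Read a NIfTI-1 scalar volume, mask or displacement field
#'
#' `read_nifti_volume()` returns a [scalar_volume()] (or [binary_mask()] when
#' `as_mask = TRUE`); `read_nifti_field()` expects a 3-component vector image
#' and returns a [displacement_field()].
#'
#' @param path path to a `.nii` file written by [write_nifti()] (or any
#'   little-endian axis-aligned NIfTI-1 of a supported datatype).
#' @param as_mask coerce to a [binary_mask()].
#' @return A volume/mask/field object.
#' @export
read_nifti_volume <- function(path, as_mask = FALSE) {
  r <- .nifti_read_raw(path)
  if (prod(r$shape) != n_voxels(r$geometry)) {
    stop("expected a 3-D scalar volume: ", path)
  }
  if (as_mask) binary_mask(r$data, r$geometry)
  else scalar_volume(r$data, r$geometry)
}

#' @rdname read_nifti_volume
#' @export
read_nifti_field <- function(path) {
  r <- .nifti_read_raw(path)
  ncomp <- prod(r$shape) / n_voxels(r$geometry)
  if (ncomp != 3) {
    stop("displacement field must have exactly 3 components, found ",
         ncomp, ": ", path)
  }
  displacement_field(array(r$data, dim = c(r$geometry$dims, 3L)), r$geometry)
}
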