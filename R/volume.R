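#' Grayscale microCT volume
#'
#' A `VolumeImage` wraps a 3D integer intensity array together with its
#' physical (isotropic) voxel size. Arrays are indexed `(z, y, x)` with `z`
#' the axial slice index, matching the slice-stack output of microCT
#' reconstruction: `vol$data[z, , ]` is one transverse slice.
#'
#' @param data 3D numeric array, dim `(nz, ny, nx)`; intensities must lie in
#'   `[0, 2^bit_depth - 1]`. At least 2 slices of at least 8x8 pixels.
#' @param voxel_size_um positive scalar, isotropic voxel edge length in
#'   micrometers. Anisotropic input is an error by design: all morphometry
#'   assumes isotropy.
#' @param bit_depth 8 (default) or 16.
#' @param source free-text provenance string.
#' @return An object of class `VolumeImage` with fields `data`,
#'   `voxel_size_um`, `bit_depth`, `source`.
#' @examples
#' v <- volume_image(array(0L, c(4, 16, 16)), voxel_size_um = 35)
#' dim(v$data)
#' @export
volume_image <- function(data, voxel_size_um, bit_depth = 8L,
                         source = "in-memory") {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array indexed (z, y, x)")
  d <- dim(data)
  if (d[1] < 2L || d[2] < 8L || d[3] < 8L)
    stop("volume must have at least 2 slices of at least 8x8 pixels")
  if (length(voxel_size_um) != 1L || !is.finite(voxel_size_um) ||
      voxel_size_um <= 0)
    stop("`voxel_size_um` must be a positive scalar (anisotropic voxels are not supported)")
  if (!bit_depth %in% c(8L, 16L)) stop("`bit_depth` must be 8 or 16")
  maxval <- 2^bit_depth - 1
  rng <- range(data)
  if (rng[1] < 0 || rng[2] > maxval)
    stop(sprintf("intensities out of range [0, %d]", maxval))
  storage.mode(data) <- "integer"
  structure(
    list(data = data, voxel_size_um = as.numeric(voxel_size_um),
         bit_depth = as.integer(bit_depth), source = as.character(source)),
    class = "VolumeImage")
}

#' Binary mask aligned to a volume
#'
#' @param data 3D logical array, dim `(nz, ny, nx)`.
#' @param voxel_size_um positive scalar voxel size in micrometers.
#' @return Object of class `BinaryMask`.
#' @examples
#' m <- binary_mask(array(FALSE, c(4, 16, 16)), 35)
#' mask_count(m)
#' @export
binary_mask <- function(data, voxel_size_um) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D logical array indexed (z, y, x)")
  if (!is.logical(data)) {
    data <- array(as.logical(data), dim(data))
  }
  if (anyNA(data)) stop("mask must not contain NA")
  if (length(voxel_size_um) != 1L || !is.finite(voxel_size_um) ||
      voxel_size_um <= 0)
    stop("`voxel_size_um` must be a positive scalar")
  structure(list(data = data, voxel_size_um = as.numeric(voxel_size_um)),
            class = "BinaryMask")
}

#' @export
print.VolumeImage <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<VolumeImage> %d slices of %dx%d, %d-bit, voxel %.3g um (%s)\n",
              d[1], d[2], d[3], x$bit_depth, x$voxel_size_um, x$source))
  invisible(x)
}

#' @export
print.BinaryMask <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<BinaryMask> %dx%dx%d (z,y,x), %d foreground voxels, voxel %.3g um\n",
              d[1], d[2], d[3], sum(x$data), x$voxel_size_um))
  invisible(x)
}

#' Number of foreground voxels in a mask
#' @param mask a `BinaryMask`.
#' @return Integer count.
#' @export
mask_count <- function(mask) {
  stopifnot(inherits(mask, "BinaryMask"))
  sum(mask$data)
}

# internal: voxel size in mm
vox_mm <- function(x) x$voxel_size_um / 1000

check_same_shape <- function(a, b) {
  if (!identical(dim(a$data), dim(b$data)))
    stop("shape mismatch between masks/volumes")
  invisible(TRUE)
}

# internal: coerce to logical array, validating shape against a reference
as_mask_array <- function(mask, ref_dim = NULL) {
  a <- if (inherits(mask, "BinaryMask")) mask$data else mask
  if (!is.null(ref_dim) && !identical(dim(a), ref_dim))
    stop("shape mismatch")
  a
}

#' Triangle surface mesh in physical coordinates
#'
#' Vertices are in millimeters, `(x, y, z)` columns; faces are 1-based
#' vertex index triples wound counter-clockwise seen from outside
#' (right-hand rule outward normals).
#'
#' @param vertices numeric matrix, n x 3, mm.
#' @param faces integer matrix, m x 3, 1-based indices into `vertices`.
#' @return Object of class `TriangleMesh`.
#' @export
triangle_mesh <- function(vertices, faces) {
  vertices <- as.matrix(vertices)
  faces <- as.matrix(faces)
  if (ncol(vertices) != 3L || ncol(faces) != 3L)
    stop("vertices and faces must have 3 columns")
  storage.mode(faces) <- "integer"
  if (nrow(faces) > 0 &&
      (min(faces) < 1L || max(faces) > nrow(vertices)))
    stop("face indices out of range")
  structure(list(vertices = vertices, faces = faces), class = "TriangleMesh")
}

#' @export
print.TriangleMesh <- function(x, ...) {
  cat(sprintf("<TriangleMesh> %d vertices, %d faces\n",
              nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

#' Enclosed volume of a closed mesh
#'
#' Signed volume by the divergence theorem (sum of origin-tetrahedra);
#' positive for consistently outward-oriented closed surfaces.
#'
#' @param mesh a `TriangleMesh`.
#' @return Volume in mm^3.
#' @export
mesh_volume <- function(mesh) {
  stopifnot(inherits(mesh, "TriangleMesh"))
  v <- mesh$vertices
  f <- mesh$faces
  if (nrow(f) == 0) return(0)
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c <- v[f[, 3], , drop = FALSE]
  cross <- cbind(b[, 2] * c[, 3] - b[, 3] * c[, 2],
                 b[, 3] * c[, 1] - b[, 1] * c[, 3],
                 b[, 1] * c[, 2] - b[, 2] * c[, 1])
  sum(rowSums(a * cross)) / 6
}
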