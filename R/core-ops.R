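#' Global intensity threshold
#'
#' Selects voxels with intensity in `[lo, hi]`, inclusive on both ends
#' (the convention of vendor task lists, whose printed air/body ranges
#' 0--55 and 55--255 deliberately overlap at the cut point). If `roi` is
#' given, voxels outside it are always excluded.
#'
#' @param volume a `VolumeImage`.
#' @param lo,hi intensity bounds in native image units (no rescaling is
#'   performed for 16-bit input; a warning reminds you when defaults meant
#'   for 8-bit data are used on 16-bit volumes).
#' @param roi optional `BinaryMask` restricting the selection.
#' @return A `BinaryMask`.
#' @examples
#' v <- volume_image(array(c(0L, 54L, 55L, 120L), c(2, 8, 8)),
#'                   voxel_size_um = 35)
#' m <- threshold_global(v, 55, 255)
#' @export
threshold_global <- function(volume, lo, hi, roi = NULL) {
  stopifnot(inherits(volume, "VolumeImage"))
  maxval <- 2^volume$bit_depth - 1
  if (lo > hi) stop("invalid range: lo > hi")
  if (lo < 0 || hi > maxval) stop("invalid range: outside bit depth")
  if (volume$bit_depth == 16L && hi <= 255)
    warning("16-bit volume thresholded with 8-bit-scale bounds; thresholds are not rescaled automatically")
  sel <- volume$data >= lo & volume$data <= hi
  if (!is.null(roi)) {
    check_same_shape(volume, roi)
    sel <- sel & roi$data
  }
  binary_mask(array(sel, dim(volume$data)), volume$voxel_size_um)
}

#' Voxelwise boolean combination of two masks
#'
#' @param a,b `BinaryMask` objects of identical shape.
#' @param op one of `"AND"`, `"OR"`, `"SUB"` (a and not b), `"XOR"`,
#'   `"NOT_A"` (complement of `a`; `b` ignored).
#' @return A `BinaryMask`.
#' @export
bitwise_combine <- function(a, b, op = c("AND", "OR", "SUB", "XOR", "NOT_A")) {
  op <- match.arg(op)
  stopifnot(inherits(a, "BinaryMask"))
  if (op != "NOT_A") {
    stopifnot(inherits(b, "BinaryMask"))
    check_same_shape(a, b)
  }
  out <- switch(op,
    AND = a$data & b$data,
    OR = a$data | b$data,
    SUB = a$data & !b$data,
    XOR = xor(a$data, b$data),
    NOT_A = !a$data)
  binary_mask(array(out, dim(a$data)), a$voxel_size_um)
}

#' Connected-component despeckling
#'
#' Foreground components use 26-connectivity in 3D and 8-connectivity in
#' 2D; background ("black") components the complementary 6/4-connectivity.
#' `space = "2D"` processes each z-slice independently (so `sweep` keeps
#' the largest object of every slice).
#'
#' Size ties in sweep mode are broken deterministically: the component
#' whose minimal `(z, y, x)` voxel is lexicographically smallest wins.
#'
#' @param mask a `BinaryMask`.
#' @param mode `"sweep_keep_largest"`, `"remove_white_smaller_than"` or
#'   `"remove_black_smaller_than"`.
#' @param space `"3D"` (default) or `"2D"`.
#' @param size_threshold voxel-count threshold for the size modes
#'   (components strictly smaller are removed/filled).
#' @return A `BinaryMask`.
#' @export
despeckle <- function(mask,
                      mode = c("sweep_keep_largest",
                               "remove_white_smaller_than",
                               "remove_black_smaller_than"),
                      space = c("3D", "2D"), size_threshold = NULL) {
  mode <- match.arg(mode)
  space <- match.arg(space)
  stopifnot(inherits(mask, "BinaryMask"))
  d <- dim(mask$data)
  if (mode == "sweep_keep_largest") {
    if (!any(mask$data)) stop("no objects: empty mask in sweep mode")
    conn <- if (space == "3D") 26L else 8L
    lab <- label_components(mask$data, conn)
    keep <- sweep_keep_ids(lab, per_slice = (space == "2D"))
    out <- array(lab$labels %in% keep, d)
    return(binary_mask(out, mask$voxel_size_um))
  }
  if (is.null(size_threshold) || size_threshold < 1)
    stop("size modes require size_threshold >= 1")
  if (mode == "remove_white_smaller_than") {
    conn <- if (space == "3D") 26L else 8L
    lab <- label_components(mask$data, conn)
    small <- which(lab$sizes < size_threshold)
    out <- mask$data
    out[lab$labels %in% small] <- FALSE
  } else {
    conn <- if (space == "3D") 6L else 4L
    lab <- label_components(!mask$data, conn)
    small <- which(lab$sizes < size_threshold)
    out <- mask$data
    out[lab$labels %in% small] <- TRUE
  }
  binary_mask(array(out, d), mask$voxel_size_um)
}

# internal: label wrapper around the C++ kernel
label_components <- function(arr, conn) {
  d <- dim(arr)
  res <- .label_components_cpp(as.logical(arr), d[1], d[2], d[3],
                               as.integer(conn))
  res$labels <- array(res$labels, d)
  res
}

# internal: which component ids survive a sweep. In 2D space, components
# never span slices, so the largest (tie: lexicographically smallest
# minimal voxel) is kept per slice.
sweep_keep_ids <- function(lab, per_slice) {
  k <- length(lab$sizes)
  if (k == 0L) return(integer(0))
  ord <- order(-lab$sizes, lab$min_z, lab$min_y, lab$min_x)
  if (!per_slice) return(ord[1])
  # component slice = min_z (per-slice connectivity confines each label)
  split_ids <- split(ord, lab$min_z[ord])
  vapply(split_ids, function(ids) ids[1], integer(1))
}

#' Structuring element descriptor
#'
#' @param shape `"round"` (Euclidean disc/ball of pixel centers within
#'   `radius`) or `"square"` (Chebyshev box).
#' @param radius non-negative integer radius in pixels; 0 is the single
#'   pixel (identity element).
#' @param space `"2D"` (applied independently per z-slice) or `"3D"`.
#' @return A `StructuringElement` list.
#' @export
structuring_element <- function(shape = c("round", "square"), radius,
                                space = c("2D", "3D")) {
  shape <- match.arg(shape)
  space <- match.arg(space)
  if (radius < 0 || radius != round(radius))
    stop("radius must be a non-negative integer")
  structure(list(shape = shape, radius = as.integer(radius), space = space),
            class = "StructuringElement")
}

#' Binary morphological operation
#'
#' Erosion, dilation, opening (erosion then dilation) and closing (dilation
#' then erosion) with a round or square structuring element. Padding beyond
#' the image border is background for dilation and foreground for erosion,
#' so closing never trims foreground at the border. `2D` elements act on
#' each z-slice independently.
#'
#' @param mask a `BinaryMask`.
#' @param op `"erosion"`, `"dilation"`, `"opening"` or `"closing"`.
#' @param element a [structuring_element()].
#' @param roi optional `BinaryMask`; if given the output is intersected
#'   with it.
#' @return A `BinaryMask`.
#' @examples
#' m <- binary_mask(array(FALSE, c(2, 16, 16)), 35)
#' m$data[, 6:10, 6:10] <- TRUE
#' er <- morphological_operation(m, "erosion", structuring_element("round", 1))
#' @export
morphological_operation <- function(mask,
                                    op = c("erosion", "dilation", "opening",
                                           "closing"),
                                    element, roi = NULL) {
  op <- match.arg(op)
  stopifnot(inherits(mask, "BinaryMask"),
            inherits(element, "StructuringElement"))
  d <- dim(mask$data)
  per_slice <- element$space == "2D"
  one <- function(arr, erode) {
    fn <- if (element$shape == "round") .morph_round_cpp else .morph_square_cpp
    array(fn(as.logical(arr), d[1], d[2], d[3], element$radius, per_slice,
             erode), d)
  }
  out <- switch(op,
    erosion = one(mask$data, TRUE),
    dilation = one(mask$data, FALSE),
    opening = one(one(mask$data, TRUE), FALSE),
    closing = one(one(mask$data, FALSE), TRUE))
  if (!is.null(roi)) {
    check_same_shape(mask, roi)
    out <- out & roi$data
  }
  binary_mask(array(out, d), mask$voxel_size_um)
}

#' Shrink-wrap an ROI around a body mask
#'
#' Per z-slice, returns the set of pixels enclosed by the outer contour of
#' the foreground, bridging surface openings of width up to `diameter`
#' pixels. Algorithm, per slice: (1) close the foreground with a round
#' element of radius `ceiling(diameter / 2)`; (2) flood-fill the background
#' from the slice border (4-connectivity) and take the complement as the
#' candidate wrap; (3) intersect with the hole-filled round dilation (same
#' radius) of the original foreground, so bridging can never extend the
#' wrap outward by more than the bridging radius (enclosed cavities remain
#' eligible). Slices with no foreground yield an empty ROI.
#'
#' @param body a `BinaryMask` of the object to wrap.
#' @param stretch_over_holes bridge surface openings (default `TRUE`); when
#'   `FALSE` the closing step is skipped and only interior holes are
#'   filled.
#' @param diameter maximum width in pixels of surface openings to bridge.
#' @return A `BinaryMask` (a superset of `body`).
#' @export
shrinkwrap_roi <- function(body, stretch_over_holes = TRUE, diameter = 4) {
  stopifnot(inherits(body, "BinaryMask"))
  if (!any(body$data)) stop("nothing to wrap: empty body mask")
  d <- dim(body$data)
  r <- as.integer(ceiling(diameter / 2))
  arr <- as.logical(body$data)
  if (stretch_over_holes && r > 0) {
    closed <- .morph_round_cpp(.morph_round_cpp(arr, d[1], d[2], d[3], r,
                                                TRUE, FALSE),
                               d[1], d[2], d[3], r, TRUE, TRUE)
  } else {
    closed <- arr
  }
  wrap <- .fill_holes_slices_cpp(closed, d[1], d[2], d[3])
  hull <- arr
  if (stretch_over_holes && r > 0) {
    hull <- .morph_round_cpp(hull, d[1], d[2], d[3], r, TRUE, FALSE)
  }
  hull <- .fill_holes_slices_cpp(hull, d[1], d[2], d[3])
  binary_mask(array(wrap & hull, d), body$voxel_size_um)
}
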