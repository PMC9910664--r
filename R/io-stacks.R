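#' Read a reconstructed slice stack into a VolumeImage
#'
#' Reads a directory of 2D grayscale slice images (PNG, TIFF or BMP; 8-bit
#' by default, 16-bit accepted for PNG/TIFF) whose filenames sort
#' lexicographically into z order, as produced by microCT reconstruction
#' software. The voxel size is taken from `voxel_size_um` if given,
#' otherwise from a co-located dataset log file (`*.log`, key
#' `Image Pixel Size (um)`).
#'
#' @param directory path containing the slice images.
#' @param pattern filename glob (e.g. `"slice*.png"`). Default matches all
#'   supported image files.
#' @param voxel_size_um optional voxel size override in micrometers.
#' @return A [volume_image()].
#' @seealso [write_roi_stack()], [read_dataset_log()]
#' @export
read_slice_stack <- function(directory, pattern = "*", voxel_size_um = NULL) {
  if (!dir.exists(directory)) stop("directory not found: ", directory)
  rx <- utils::glob2rx(pattern)
  files <- sort(list.files(directory, full.names = TRUE))
  files <- files[grepl(rx, basename(files))]
  files <- files[grepl("\\.(png|tif|tiff|bmp)$", files, ignore.case = TRUE)]
  if (length(files) < 2L)
    stop("inconsistent stack: need at least 2 matching slice files")
  slices <- lapply(files, read_slice_image)
  dims <- vapply(slices, function(s) dim(s$pixels), integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("inconsistent stack: slice dimensions differ")
  depths <- vapply(slices, function(s) s$bit_depth, integer(1))
  if (length(unique(depths)) != 1L)
    stop("inconsistent stack: slice bit depths differ")
  if (is.null(voxel_size_um)) {
    logs <- list.files(directory, pattern = "\\.log$", full.names = TRUE)
    meta <- NULL
    for (lg in logs) {
      meta <- tryCatch(read_dataset_log(lg), error = function(e) NULL)
      if (!is.null(meta)) break
    }
    if (is.null(meta))
      stop("missing voxel size: no `voxel_size_um` given and no parsable dataset log found")
    voxel_size_um <- meta$voxel_size_um
  }
  nz <- length(slices)
  ny <- dims[1, 1]
  nx <- dims[2, 1]
  data <- array(0L, c(nz, ny, nx))
  for (z in seq_len(nz)) data[z, , ] <- slices[[z]]$pixels
  volume_image(data, voxel_size_um, bit_depth = depths[1],
               source = normalizePath(directory))
}

# internal: read one slice; returns list(pixels = ny x nx integer matrix,
# bit_depth). Errors on color content.
read_slice_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    img <- png::readPNG(path)
    gray_from_unit(img, path)
  } else if (ext %in% c("tif", "tiff")) {
    img <- tiff::readTIFF(path)
    gray_from_unit(img, path)
  } else if (ext == "bmp") {
    read_bmp_gray(path)
  } else {
    stop("unsupported slice format: ", path)
  }
}

# png/tiff readers return values in [0,1]; infer 8 vs 16 bit from the value
# grid and rescale to native integer units.
gray_from_unit <- function(img, path) {
  if (length(dim(img)) == 3L) {
    if (dim(img)[3] >= 3L) {
      if (max(abs(img[, , 1] - img[, , 2])) > 1e-9 ||
          max(abs(img[, , 1] - img[, , 3])) > 1e-9)
        stop("not grayscale: ", path)
    }
    img <- img[, , 1]
  }
  v8 <- img * 255
  if (max(abs(v8 - round(v8))) < 1e-6) {
    list(pixels = matrix(as.integer(round(v8)), nrow(img), ncol(img)),
         bit_depth = 8L)
  } else {
    v16 <- img * 65535
    list(pixels = matrix(as.integer(round(v16)), nrow(img), ncol(img)),
         bit_depth = 16L)
  }
}

#' Write a binary mask as a monochrome slice stack
#'
#' One image per slice, pixel values 0/255 (8-bit), filenames
#' `<prefix><zero-padded z>.<format>`. Re-reading the stack with
#' [read_slice_stack()] reproduces the mask exactly.
#'
#' @param mask a `BinaryMask`.
#' @param directory output directory (created if needed).
#' @param prefix filename prefix.
#' @param format `"png"` (default), `"bmp"` or `"tiff"`.
#' @return Invisibly, the vector of files written.
#' @export
write_roi_stack <- function(mask, directory, prefix = "roi",
                            format = c("png", "bmp", "tiff")) {
  stopifnot(inherits(mask, "BinaryMask"))
  format <- match.arg(format)
  if (!dir.exists(directory))
    dir.create(directory, recursive = TRUE)
  d <- dim(mask$data)
  files <- character(d[1])
  for (z in seq_len(d[1])) {
    slice <- matrix(ifelse(mask$data[z, , ], 255L, 0L), d[2], d[3])
    f <- file.path(directory, sprintf("%s%04d.%s", prefix, z - 1L, format))
    write_gray_image(slice, f, format)
    files[z] <- f
  }
  invisible(files)
}

#' Write a VolumeImage as a grayscale slice stack
#'
#' @param volume a `VolumeImage`.
#' @param directory output directory (created if needed).
#' @param prefix filename prefix.
#' @param format `"png"` (default), `"bmp"` or `"tiff"`.
#' @param write_log also write a minimal dataset log carrying the voxel
#'   size, so the stack is self-describing (default `TRUE`).
#' @return Invisibly, the files written.
#' @export
write_volume_stack <- function(volume, directory, prefix = "slice",
                               format = c("png", "bmp", "tiff"),
                               write_log = TRUE) {
  stopifnot(inherits(volume, "VolumeImage"))
  format <- match.arg(format)
  if (volume$bit_depth != 8L && format == "bmp")
    stop("BMP output supports 8-bit volumes only")
  if (!dir.exists(directory)) dir.create(directory, recursive = TRUE)
  d <- dim(volume$data)
  files <- character(d[1])
  for (z in seq_len(d[1])) {
    slice <- matrix(volume$data[z, , ], d[2], d[3])
    f <- file.path(directory, sprintf("%s%04d.%s", prefix, z - 1L, format))
    write_gray_image(slice, f, format, bit_depth = volume$bit_depth)
    files[z] <- f
  }
  if (write_log) {
    log_path <- file.path(directory, paste0(prefix, "_dataset.log"))
    writeLines(c("[Reconstruction]",
                 sprintf("Image Pixel Size (um)=%.6g", volume$voxel_size_um)),
               log_path)
    files <- c(files, log_path)
  }
  invisible(files)
}

write_gray_image <- function(pixels, path, format, bit_depth = 8L) {
  maxval <- 2^bit_depth - 1
  if (format == "png") {
    png::writePNG(pixels / maxval, path)
  } else if (format == "tiff") {
    tiff::writeTIFF(pixels / maxval, path,
                    bits.per.sample = as.integer(bit_depth))
  } else {
    write_bmp_gray(pixels, path)
  }
  invisible(path)
}

# --- minimal 8-bit grayscale BMP codec (BITMAPINFOHEADER, 256-entry gray
# palette, bottom-up rows, 4-byte row padding) ---------------------------

write_bmp_gray <- function(pixels, path) {
  ny <- nrow(pixels)
  nx <- ncol(pixels)
  row_bytes <- ((nx + 3) %/% 4) * 4
  data_size <- row_bytes * ny
  offset <- 14L + 40L + 256L * 4L
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("BM"), con)
  writeBin(as.integer(offset + data_size), con, size = 4, endian = "little")
  writeBin(0L, con, size = 4, endian = "little")
  writeBin(as.integer(offset), con, size = 4, endian = "little")
  writeBin(40L, con, size = 4, endian = "little")
  writeBin(as.integer(nx), con, size = 4, endian = "little")
  writeBin(as.integer(ny), con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")
  writeBin(8L, con, size = 2, endian = "little")
  writeBin(0L, con, size = 4, endian = "little")          # no compression
  writeBin(as.integer(data_size), con, size = 4, endian = "little")
  writeBin(c(2835L, 2835L, 256L, 0L), con, size = 4, endian = "little")
  pal <- as.raw(rep(0:255, each = 4) * c(1, 1, 1, 0))
  pal[seq(4, length(pal), by = 4)] <- as.raw(0)
  writeBin(pal, con)
  pad <- raw(row_bytes - nx)
  for (y in ny:1) {                                        # bottom-up
    writeBin(as.raw(pixels[y, ]), con)
    if (length(pad)) writeBin(pad, con)
  }
  invisible(path)
}

read_bmp_gray <- function(path) {
  raw <- readBin(path, "raw", file.size(path))
  if (length(raw) < 54 || rawToChar(raw[1:2]) != "BM")
    stop("not a BMP file: ", path)
  u32 <- function(i) sum(as.integer(raw[i:(i + 3)]) * 256^(0:3))
  u16 <- function(i) sum(as.integer(raw[i:(i + 1)]) * 256^(0:1))
  offset <- u32(11)
  nx <- u32(19)
  ny <- u32(23)
  bpp <- u16(29)
  comp <- u32(31)
  if (bpp != 8L || comp != 0L)
    stop("only uncompressed 8-bit BMP is supported: ", path)
  # verify the palette is grayscale
  pal_n <- (offset - 54) %/% 4
  if (pal_n > 0) {
    pal <- matrix(as.integer(raw[55:(54 + pal_n * 4)]), nrow = 4)
    if (any(pal[1, ] != pal[2, ]) || any(pal[1, ] != pal[3, ]))
      stop("not grayscale: ", path)
  }
  row_bytes <- ((nx + 3) %/% 4) * 4
  px <- matrix(0L, ny, nx)
  for (r in seq_len(ny)) {
    start <- offset + (r - 1) * row_bytes
    px[ny - r + 1, ] <- as.integer(raw[(start + 1):(start + nx)])
  }
  list(pixels = px, bit_depth = 8L)
}

#' Parse a scanner dataset log file
#'
#' Reads the vendor-style `key=value` sectioned text log written next to
#' reconstructed stacks. Recognized keys: `Image Pixel Size (um)` (or
#' `Pixel Size (um)`), `Source Voltage (kV)`, `Source Current (uA)`,
#' `Rotation Step (deg)`, `Filter`. Unknown keys are ignored.
#'
#' @param path path to the log file.
#' @return An `AcquisitionMeta` list with `voxel_size_um` and any of `kv`,
#'   `ua`, `rotation_step_deg`, `filter` found.
#' @examples
#' f <- tempfile(fileext = ".log")
#' writeLines(c("[System]", "Image Pixel Size (um)=9.0"), f)
#' read_dataset_log(f)$voxel_size_um
#' @export
read_dataset_log <- function(path) {
  if (!file.exists(path)) stop("log file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  kv <- lines[grepl("=", lines, fixed = TRUE)]
  keys <- trimws(sub("=.*$", "", kv))
  vals <- trimws(sub("^[^=]*=", "", kv))
  get_num <- function(patterns) {
    for (p in patterns) {
      hit <- which(tolower(keys) == tolower(p))
      if (length(hit)) return(suppressWarnings(as.numeric(vals[hit[1]])))
    }
    NA_real_
  }
  vox <- get_num(c("Image Pixel Size (um)", "Pixel Size (um)",
                   "Image Pixel Size"))
  if (!is.finite(vox) || vox <= 0)
    stop("missing voxel size: no parsable pixel-size key in ", path)
  meta <- list(
    voxel_size_um = vox,
    kv = get_num(c("Source Voltage (kV)", "Voltage (kV)")),
    ua = get_num(c("Source Current (uA)", "Current (uA)")),
    rotation_step_deg = get_num(c("Rotation Step (deg)", "Rotation Step")))
  filt <- which(tolower(keys) == "filter")
  meta$filter <- if (length(filt)) vals[filt[1]] else NA_character_
  structure(meta, class = "AcquisitionMeta")
}

#' Read a mask back from a monochrome slice stack
#'
#' Convenience inverse of [write_roi_stack()]: any strictly positive pixel
#' is foreground.
#'
#' @inheritParams read_slice_stack
#' @param voxel_size_um voxel size in micrometers (required; ROI stacks
#'   carry no log by default).
#' @return A `BinaryMask`.
#' @export
read_roi_stack <- function(directory, pattern = "*", voxel_size_um) {
  vol <- read_slice_stack(directory, pattern, voxel_size_um)
  binary_mask(vol$data > 0L, vol$voxel_size_um)
}
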