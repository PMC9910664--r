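#' Write a triangle mesh to STL
#'
#' Binary STL by default (80-byte header, little-endian float32 triangles);
#' ASCII on request. Facet normals are computed from the right-hand-rule
#' vertex order.
#'
#' @param mesh a `TriangleMesh` (vertices in mm).
#' @param path output file path.
#' @param binary write binary STL (default) or ASCII.
#' @return Invisibly, `path`.
#' @seealso [read_stl()]
#' @export
write_mesh_stl <- function(mesh, path, binary = TRUE) {
  stopifnot(inherits(mesh, "TriangleMesh"))
  if (nrow(mesh$faces) == 0) stop("empty mesh")
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c <- v[f[, 3], , drop = FALSE]
  e1 <- b - a
  e2 <- c - a
  nrm <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
               e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
               e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  len <- sqrt(rowSums(nrm^2))
  len[len == 0] <- 1
  nrm <- nrm / len
  n <- nrow(f)
  if (binary) {
    con <- file(path, "wb")
    on.exit(close(con))
    header <- charToRaw(sprintf("%-80s", "patsr binary STL"))[1:80]
    writeBin(header, con)
    writeBin(as.integer(n), con, size = 4, endian = "little")
    # 12 floats + attribute count per triangle
    tri <- matrix(0, 12, n)
    tri[1:3, ] <- t(nrm)
    tri[4:6, ] <- t(a)
    tri[7:9, ] <- t(b)
    tri[10:12, ] <- t(c)
    raw_tris <- writeBin(as.numeric(tri), raw(), size = 4, endian = "little")
    raw_tris <- matrix(raw_tris, nrow = 48)
    blocks <- rbind(raw_tris, matrix(as.raw(0), 2, n))
    writeBin(as.vector(blocks), con)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("solid patsr", con)
    for (i in seq_len(n)) {
      writeLines(c(
        sprintf("  facet normal %.9g %.9g %.9g", nrm[i, 1], nrm[i, 2], nrm[i, 3]),
        "    outer loop",
        sprintf("      vertex %.9g %.9g %.9g", a[i, 1], a[i, 2], a[i, 3]),
        sprintf("      vertex %.9g %.9g %.9g", b[i, 1], b[i, 2], b[i, 3]),
        sprintf("      vertex %.9g %.9g %.9g", c[i, 1], c[i, 2], c[i, 3]),
        "    endloop",
        "  endfacet"), con)
    }
    writeLines("endsolid patsr", con)
  }
  invisible(path)
}

#' Read an STL file
#'
#' Reads binary or ASCII STL. Duplicate vertices (identical coordinates) are
#' merged so closed surfaces round-trip as connected meshes.
#'
#' @param path STL file path.
#' @return A `TriangleMesh`.
#' @export
read_stl <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- readBin(path, "raw", file.size(path))
  is_ascii <- length(raw) >= 5 &&
    identical(rawToChar(raw[1:5]), "solid") &&
    !is_binary_stl(raw)
  tri <- if (is_ascii) read_stl_ascii(path) else read_stl_binary(raw)
  # merge identical vertices
  key <- apply(tri, 1, function(r) paste(r, collapse = ","))
  uniq <- !duplicated(key)
  idx <- match(key, key[uniq])
  verts <- tri[uniq, , drop = FALSE]
  faces <- matrix(idx, ncol = 3, byrow = TRUE)
  triangle_mesh(verts, faces)
}

is_binary_stl <- function(raw) {
  if (length(raw) < 84) return(FALSE)
  n <- sum(as.integer(raw[81:84]) * 256^(0:3))
  length(raw) == 84 + 50 * n
}

read_stl_binary <- function(raw) {
  n <- sum(as.integer(raw[81:84]) * 256^(0:3))
  body <- raw[-(1:84)]
  blocks <- matrix(body, nrow = 50)
  floats <- readBin(as.vector(blocks[1:48, , drop = FALSE]), "numeric",
                    n = 12L * n, size = 4, endian = "little")
  m <- matrix(floats, nrow = 12)
  rbind_tris <- rbind(t(m[4:6, , drop = FALSE]),
                      t(m[7:9, , drop = FALSE]),
                      t(m[10:12, , drop = FALSE]))
  # interleave back to per-face ordering (v1, v2, v3 per face)
  ord <- as.vector(t(matrix(seq_len(3 * n), ncol = 3)))
  rbind_tris[ord, , drop = FALSE]
}

read_stl_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vlines <- grep("^\\s*vertex", lines, value = TRUE)
  nums <- lapply(strsplit(trimws(vlines), "\\s+"),
                 function(x) as.numeric(x[2:4]))
  do.call(rbind, nums)
}
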