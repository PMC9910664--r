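# Independent oracles used by the tests. These deliberately avoid the
# package's C++ kernels: labeling goes through igraph BFS on an adjacency
# list built by array shifts, run counting through rle(), thickness through
# direct pairwise enumeration of the inscribed-sphere definition.

# neighbor offsets for a connectivity scheme (26/6 in 3D, 8/4 per-slice)
conn_offsets <- function(conn) {
  offs <- expand.grid(dz = -1:1, dy = -1:1, dx = -1:1)
  offs <- offs[!(offs$dz == 0 & offs$dy == 0 & offs$dx == 0), ]
  if (conn %in% c(8, 4)) offs <- offs[offs$dz == 0, ]
  if (conn %in% c(6, 4))
    offs <- offs[abs(offs$dz) + abs(offs$dy) + abs(offs$dx) == 1, ]
  offs
}

# BFS component labeling oracle (igraph over shift-built adjacency)
oracle_label <- function(arr, conn = 26) {
  d <- dim(arr)
  idx <- array(seq_len(prod(d)), d)
  offs <- conn_offsets(conn)
  from <- integer(0)
  to <- integer(0)
  for (k in seq_len(nrow(offs))) {
    o <- as.integer(offs[k, ])
    z1 <- max(1, 1 + o[1]):min(d[1], d[1] + o[1])
    y1 <- max(1, 1 + o[2]):min(d[2], d[2] + o[2])
    x1 <- max(1, 1 + o[3]):min(d[3], d[3] + o[3])
    a <- idx[z1, y1, x1, drop = FALSE]
    b <- idx[z1 - o[1], y1 - o[2], x1 - o[3], drop = FALSE]
    ok <- arr[a] & arr[b]
    from <- c(from, a[ok])
    to <- c(to, b[ok])
  }
  fg <- which(arr)
  g <- igraph::graph_from_data_frame(
    data.frame(from = match(from, fg), to = match(to, fg)),
    directed = FALSE,
    vertices = data.frame(id = seq_along(fg)))
  comp <- igraph::components(g)
  labels <- array(0L, d)
  labels[fg] <- comp$membership
  list(labels = labels, sizes = as.integer(comp$csize))
}

# largest-component mask by the oracle (ties broken by smallest minimal
# (z, y, x) voxel, mirroring the documented contract)
oracle_keep_largest <- function(arr, conn = 26) {
  lab <- oracle_label(arr, conn)
  if (length(lab$sizes) == 0) return(array(FALSE, dim(arr)))
  best <- which(lab$sizes == max(lab$sizes))
  if (length(best) > 1) {
    d <- dim(arr)
    keyer <- function(l) {
      w <- which(lab$labels == l, arr.ind = TRUE)
      w <- w[order(w[, 1], w[, 2], w[, 3]), , drop = FALSE]
      sum(w[1, ] * c(prod(d[2:3]) * 0 + d[2] * d[3], d[3], 1))
    }
    best <- best[order(vapply(best, keyer, 0))][1]
  }
  array(lab$labels == best[1], dim(arr))
}

# per-slice border flood fill oracle (4-connectivity background)
oracle_fill_holes <- function(arr) {
  d <- dim(arr)
  out <- arr
  for (z in seq_len(d[1])) {
    sl <- matrix(arr[z, , ], d[2], d[3])
    bg <- !sl
    lab <- oracle_label(array(bg, c(1, d[2], d[3])), conn = 4)
    border_labels <- unique(c(lab$labels[1, 1, ], lab$labels[1, d[2], ],
                              lab$labels[1, , 1], lab$labels[1, , d[3]]))
    border_labels <- setdiff(border_labels, 0L)
    filled <- !(matrix(lab$labels[1, , ], d[2], d[3]) %in% border_labels)
    out[z, , ] <- filled | sl
  }
  out
}

# directed-secant oracle via rle(): per axis, count runs and VOI lengths of
# lines with at least one run
oracle_secant <- function(mask, roi = NULL) {
  d <- dim(mask)
  if (is.null(roi)) roi <- array(TRUE, d)
  per_axis <- function(get_line) {
    runs <- 0
    len <- 0
    for (i in seq_len(get_line("n1")))
      for (j in seq_len(get_line("n2"))) {
        m <- get_line("mask", i, j)
        r <- get_line("roi", i, j)
        rl <- rle(m & r)
        nr <- sum(rl$values)
        if (nr > 0) {
          runs <- runs + nr
          len <- len + sum(r)
        }
      }
    c(runs = runs, len = len)
  }
  ax <- function(axis) {
    if (axis == 1) per_axis(function(what, i, j) switch(what,
      n1 = d[2], n2 = d[3], mask = mask[, i, j], roi = roi[, i, j]))
    else if (axis == 2) per_axis(function(what, i, j) switch(what,
      n1 = d[1], n2 = d[3], mask = mask[i, , j], roi = roi[i, , j]))
    else per_axis(function(what, i, j) switch(what,
      n1 = d[1], n2 = d[2], mask = mask[i, j, ], roi = roi[i, j, ]))
  }
  list(z = ax(1), y = ax(2), x = ax(3))
}

# brute-force inscribed-sphere thickness oracle: direct enumeration over
# all candidate sphere centers
oracle_thickness_map <- function(arr) {
  d <- dim(arr)
  fg <- which(arr)
  bg <- which(!arr)
  co <- function(i) cbind((i - 1) %% d[1],
                          ((i - 1) %/% d[1]) %% d[2],
                          (i - 1) %/% (d[1] * d[2]))
  pf <- co(fg)
  pb <- co(bg)
  # radius at each candidate center: distance to nearest background center
  r <- vapply(seq_along(fg), function(k) {
    sqrt(min((pb[, 1] - pf[k, 1])^2 + (pb[, 2] - pf[k, 2])^2 +
             (pb[, 3] - pf[k, 3])^2))
  }, 0)
  th <- numeric(length(fg))
  for (k in seq_along(fg)) {
    s <- r[k] - 0.5
    cov <- (pf[, 1] - pf[k, 1])^2 + (pf[, 2] - pf[k, 2])^2 +
           (pf[, 3] - pf[k, 3])^2 <= s^2 + 1e-9
    th[cov] <- pmax(th[cov], 2 * r[k] - 1)
  }
  out <- array(0, d)
  out[fg] <- th
  out
}

# mesh integrity helpers
mesh_edge_check <- function(mesh) {
  f <- mesh$faces
  de <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
  directed_once <- !any(duplicated(paste(de[, 1], de[, 2])))
  ukey <- paste(pmin(de[, 1], de[, 2]), pmax(de[, 1], de[, 2]))
  undirected_twice <- all(table(ukey) == 2)
  list(directed_once = directed_once, undirected_twice = undirected_twice,
       watertight = directed_once && undirected_twice)
}

mesh_component_count <- function(mesh) {
  g <- igraph::graph_from_edgelist(
    rbind(mesh$faces[, 1:2], mesh$faces[, 2:3]), directed = FALSE)
  igraph::components(g)$no
}

# small random masks for property tests
random_mask <- function(dim, p = 0.4, voxel_size_um = 35) {
  binary_mask(array(runif(prod(dim)) < p, dim), voxel_size_um)
}

# small valid volume builder
tiny_volume <- function(values, dim = c(2, 8, 8), voxel_size_um = 35) {
  volume_image(array(rep_len(as.integer(values), prod(dim)), dim),
               voxel_size_um)
}

# reduced-scale thorax phantom for unit tests (half-size geometry with a
# proportionally reduced closing radius)
small_phantom <- function(seed = 7, ...) {
  generate_thorax_phantom(phantom_spec(shape = c(80, 128, 128),
                                       seed = seed, ...))
}

small_pats_params <- function(...) {
  pats_params(closing_radius = 20, ...)
}
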