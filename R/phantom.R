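# Synthetic thorax and calibration phantoms with voxel-level ground truth.
#
# The thorax phantom emulates a mouse chest at 35 um-class in vivo
# resolution: an ellipsoidal soft-tissue body in air, two lung fields of
# air-density parenchyma joined by a trachea and main bronchi, a recursive
# cylinder vessel tree per lung, optional spherical disease lesions, a
# medial heart, and additive Gaussian noise. All intensities sit well
# clear of the default 55 threshold so that validation probes the
# pipeline, not threshold luck.

#' Thorax phantom specification
#'
#' @param shape integer vector `(nz, ny, nx)`; default `c(200, 256, 256)`.
#' @param voxel_size_um voxel size; default 35 (in vivo class). Use 9 for
#'   ex vivo class geometry.
#' @param intensities named list of mean intensities (8-bit units):
#'   `background_air` 20, `body_tissue` 120, `lung_parenchyma` 35,
#'   `vessel` 130, `lesion` 110, `heart` 125.
#' @param noise_sd standard deviation of additive Gaussian noise (default
#'   6; intensities are rounded and clamped to `[0, 255]`).
#' @param lesion_volume_fraction target lesion volume as a fraction of the
#'   lung-field volume, in `[0, 0.5]`.
#' @param vessel_depth generations of the bifurcating vessel tree.
#' @param vessel_root_radius_px root vessel radius in pixels at the 256
#'   in-plane reference scale (scaled with `shape`).
#' @param seed integer seed; generation is deterministic given the spec.
#' @return A `PhantomSpec` list.
#' @export
phantom_spec <- function(shape = c(200, 256, 256), voxel_size_um = 35,
                         intensities = list(background_air = 20,
                                            body_tissue = 120,
                                            lung_parenchyma = 35,
                                            vessel = 130,
                                            lesion = 110,
                                            heart = 125),
                         noise_sd = 6, lesion_volume_fraction = 0,
                         vessel_depth = 4, vessel_root_radius_px = 14,
                         seed = 42L) {
  stopifnot(length(shape) == 3, all(shape >= 16), voxel_size_um > 0,
            noise_sd >= 0,
            lesion_volume_fraction >= 0, lesion_volume_fraction <= 0.5)
  ints <- intensities
  stopifnot(all(unlist(ints) >= 0), all(unlist(ints) <= 255))
  if (ints$lung_parenchyma > 55 || ints$background_air > 55)
    stop("air-class intensities must not exceed the default air threshold (55)")
  if (min(ints$body_tissue, ints$vessel, ints$lesion, ints$heart) < 55)
    stop("tissue-class intensities must not fall below the default tissue threshold (55)")
  structure(list(shape = as.integer(shape),
                 voxel_size_um = voxel_size_um,
                 intensities = ints, noise_sd = noise_sd,
                 lesion_volume_fraction = lesion_volume_fraction,
                 vessel_depth = vessel_depth,
                 vessel_root_radius_px = vessel_root_radius_px,
                 seed = as.integer(seed)),
            class = "PhantomSpec")
}

# internal: logical array of an axis-aligned ellipsoid; center/semi in
# voxel units on (z, y, x)
ellipsoid_mask <- function(shape, center, semi) {
  z <- (seq_len(shape[1]) - center[1]) / semi[1]
  y <- (seq_len(shape[2]) - center[2]) / semi[2]
  x <- (seq_len(shape[3]) - center[3]) / semi[3]
  oz <- array(z^2, shape)
  oy <- aperm(array(y^2, shape[c(2, 1, 3)]), c(2, 1, 3))
  ox <- aperm(array(x^2, shape[c(3, 2, 1)]), c(3, 2, 1))
  oz + oy + ox <= 1
}

# internal: paint a capsule (cylinder with spherical caps) of radius r
# between p0 and p1 into a logical array, touching only its bounding box
paint_capsule <- function(arr, p0, p1, r) {
  shape <- dim(arr)
  lo <- pmax(floor(pmin(p0, p1) - r - 1), 1)
  hi <- pmin(ceiling(pmax(p0, p1) + r + 1), shape)
  if (any(lo > hi)) return(arr)
  zi <- lo[1]:hi[1]; yi <- lo[2]:hi[2]; xi <- lo[3]:hi[3]
  gz <- array(zi, c(length(zi), length(yi), length(xi)))
  gy <- aperm(array(yi, c(length(yi), length(zi), length(xi))), c(2, 1, 3))
  gx <- aperm(array(xi, c(length(xi), length(yi), length(zi))), c(3, 2, 1))
  d <- p1 - p0
  len2 <- sum(d^2)
  if (len2 == 0) {
    dist2 <- (gz - p0[1])^2 + (gy - p0[2])^2 + (gx - p0[3])^2
  } else {
    t <- ((gz - p0[1]) * d[1] + (gy - p0[2]) * d[2] + (gx - p0[3]) * d[3]) / len2
    t <- pmin(pmax(t, 0), 1)
    dist2 <- (gz - (p0[1] + t * d[1]))^2 + (gy - (p0[2] + t * d[2]))^2 +
             (gx - (p0[3] + t * d[3]))^2
  }
  sub <- arr[zi, yi, xi]
  sub[dist2 <= r^2] <- TRUE
  arr[zi, yi, xi] <- sub
  arr
}

# internal: recursive bifurcating vessel tree inside a lung ellipsoid.
# Segments droop toward the lung long axis with randomized azimuths; child
# radii taper by 0.78 per generation (calibres below ~3 px are not
# resolvable at the 35 um class and are omitted from the tree).
vessel_tree <- function(shape, root, direction, length0, radius0, depth,
                        min_radius) {
  arr <- array(FALSE, shape)
  recurse <- function(p0, dir, len, r, d) {
    dir <- dir / sqrt(sum(dir^2))
    p1 <- p0 + dir * len
    arr <<- paint_capsule(arr, p0, p1, max(r, min_radius))
    if (d <= 0) return(invisible())
    for (k in 1:2) {
      ang <- runif(1, 0.4, 0.9) * (if (k == 1) 1 else -1)
      # rotate direction in a random plane: perturb with a random orthogonal
      rnd <- rnorm(3)
      ortho <- rnd - sum(rnd * dir) * dir
      ortho <- ortho / sqrt(sum(ortho^2))
      child_dir <- cos(ang) * dir + sin(ang) * ortho
      recurse(p1, child_dir, len * 0.78, r * 0.78, d - 1)
    }
  }
  recurse(root, direction, length0, radius0, depth)
  arr
}

#' Generate the synthetic mouse-thorax phantom
#'
#' Deterministic for a fixed spec (one seeded pseudo-random stream;
#' placement order: left vessel tree, right vessel tree, then lesions).
#' Lesion spheres are placed fully inside the lung fields until their
#' volume reaches `lesion_volume_fraction` times the lung-field volume;
#' the same seed yields a nested lesion sequence across fractions, so
#' phantom series are monotone by construction.
#'
#' @param spec a [phantom_spec()].
#' @return A `PhantomTruth` list: `volume` (`VolumeImage`), `masks` (named
#'   `BinaryMask`s: `body`, `lung_air`, `vessels`, `lesions`, `heart`,
#'   pairwise disjoint), and `spec`.
#' @export
generate_thorax_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "PhantomSpec"))
  with_seed(spec$seed, generate_thorax_impl(spec))
}

# run expr under a seeded RNG, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
         else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", .GlobalEnv))
        rm(".Random.seed", envir = .GlobalEnv)
    } else assign(".Random.seed", old, envir = .GlobalEnv)
  })
  set.seed(seed)
  force(expr)
}

generate_thorax_impl <- function(spec) {
  sh <- spec$shape
  nz <- sh[1]; ny <- sh[2]; nx <- sh[3]
  sc <- nx / 256  # in-plane reference scale
  ints <- spec$intensities

  body_region <- ellipsoid_mask(sh, c(0.50 * nz, 0.50 * ny, 0.50 * nx),
                                c(0.47 * nz, 0.40 * ny, 0.43 * nx))
  lung_l <- ellipsoid_mask(sh, c(0.50 * nz, 0.50 * ny, 0.50 * nx - 65 * sc),
                           c(0.30 * nz, 0.23 * ny, 22 * sc))
  lung_r <- ellipsoid_mask(sh, c(0.50 * nz, 0.50 * ny, 0.50 * nx + 65 * sc),
                           c(0.30 * nz, 0.23 * ny, 22 * sc))
  lungs <- lung_l | lung_r
  heart_region <- ellipsoid_mask(sh, c(0.52 * nz, 0.60 * ny, 0.50 * nx),
                                 c(0.16 * nz, 0.13 * ny, 24 * sc))
  heart_region <- heart_region & !lungs

  # airways: a short bronchial bridge joining the two lung air fields
  # across the mediastinum (kept compact so the per-slice closing of the
  # aerated ROI pockets as little mediastinal tissue as possible)
  airways <- array(FALSE, sh)
  r_air <- max(3, 5 * sc)
  airways <- paint_capsule(airways,
                           c(0.50 * nz, 0.42 * ny, 0.50 * nx - 65 * sc),
                           c(0.50 * nz, 0.42 * ny, 0.50 * nx + 65 * sc),
                           r_air)
  airways <- airways & body_region & !heart_region

  # vessel trees (one per lung, rooted at the hilum, drawn in order L, R)
  vessels <- array(FALSE, sh)
  min_r <- 3 * sc
  for (sgn in c(-1, 1)) {
    root <- c(0.50 * nz, 0.52 * ny, 0.50 * nx + sgn * 45 * sc)
    dir <- c(0.25, 0.1, sgn * 0.9)
    vessels <- vessels |
      vessel_tree(sh, root, dir, length0 = 0.16 * nz,
                  radius0 = spec$vessel_root_radius_px * sc,
                  depth = spec$vessel_depth, min_radius = min_r)
  }
  # confine the tree to the inner lung: subpleural microvasculature is
  # below this resolution class and is not modelled
  core <- ellipsoid_mask(sh, c(0.50 * nz, 0.50 * ny, 0.50 * nx - 65 * sc),
                         0.88 * c(0.30 * nz, 0.23 * ny, 22 * sc)) |
          ellipsoid_mask(sh, c(0.50 * nz, 0.50 * ny, 0.50 * nx + 65 * sc),
                         0.88 * c(0.30 * nz, 0.23 * ny, 22 * sc))
  vessels <- vessels & core

  # lesions: spheres fully inside a lung field, nested across fractions
  lesions <- array(FALSE, sh)
  lung_vol <- sum(lungs)
  target <- spec$lesion_volume_fraction * lung_vol
  if (target > 0) {
    placed <- 0
    attempts <- 0
    blocked <- vessels | airways  # lesion volume is counted net of these
    lung_list <- list(list(c(0.50 * nz, 0.50 * ny, 0.50 * nx - 65 * sc),
                           c(0.30 * nz, 0.23 * ny, 22 * sc)),
                      list(c(0.50 * nz, 0.50 * ny, 0.50 * nx + 65 * sc),
                           c(0.30 * nz, 0.23 * ny, 22 * sc)))
    while (placed < target) {
      attempts <- attempts + 1
      if (attempts > 4000) stop("lesion packing failed")
      side <- if (runif(1) < 0.5) 1 else 2
      cs <- lung_list[[side]]
      u <- runif(3, -1, 1)
      cen <- cs[[1]] + u * cs[[2]] * 0.8
      r <- runif(1, 8, 18) * sc
      remaining <- target - placed
      if (4 / 3 * pi * r^3 > remaining * 1.15)
        r <- max(4 * sc, (3 * remaining / (4 * pi))^(1 / 3))
      # sphere must stay inside the lung ellipsoid
      if (!all(cs[[2]] > r)) next
      frac <- sum(((cen - cs[[1]]) / (cs[[2]] - r))^2)
      if (frac > 1) next
      before <- sum(lesions & !blocked)
      lesions <- paint_capsule(lesions, cen, cen, r)
      placed <- sum(lesions & !blocked)
      if (placed == before && attempts > 2000) break
    }
  }
  lesions <- lesions & lungs & !vessels & !airways
  vessels <- vessels & !airways

  parenchyma <- lungs & !vessels & !lesions & !airways
  lung_air <- parenchyma | airways
  body_tissue <- body_region & !lungs & !airways & !heart_region

  vol <- array(ints$background_air, sh)
  vol[body_tissue] <- ints$body_tissue
  vol[heart_region] <- ints$heart
  vol[parenchyma] <- ints$lung_parenchyma
  vol[lesions] <- ints$lesion
  vol[vessels] <- ints$vessel
  vol[airways] <- ints$background_air
  if (spec$noise_sd > 0)
    vol <- vol + rnorm(length(vol), 0, spec$noise_sd)
  vol <- array(pmin(pmax(round(vol), 0), 255), sh)

  vx <- spec$voxel_size_um
  masks <- list(body = binary_mask(body_tissue, vx),
                lung_air = binary_mask(lung_air, vx),
                vessels = binary_mask(vessels, vx),
                lesions = binary_mask(lesions, vx),
                heart = binary_mask(heart_region, vx))
  structure(list(volume = volume_image(vol, vx,
                                       source = sprintf("thorax phantom seed %d",
                                                        spec$seed)),
                 masks = masks, spec = spec,
                 body_region = binary_mask(body_region, vx)),
            class = "PhantomTruth")
}

#' @export
print.PhantomTruth <- function(x, ...) {
  d <- dim(x$volume$data)
  cat(sprintf("<PhantomTruth> %dx%dx%d (z,y,x), masks: %s\n", d[1], d[2],
              d[3], paste(names(x$masks), collapse = ", ")))
  invisible(x)
}

#' Generate analytic calibration phantoms
#'
#' Simple geometries with exactly known masks, used as morphometry
#' oracles:
#' \describe{
#'   \item{sphere}{digitized solid sphere; `parameters$radius` (voxels),
#'     optional `margin`.}
#'   \item{slab_stack}{alternating slabs of `thickness` and gaps of `gap`
#'     voxels along `axis` (`"z"`, `"y"` or `"x"`).}
#'   \item{rod_grid}{parallel rods of `radius` on a square grid of
#'     `pitch`, running along `axis`.}
#'   \item{dried_lung}{ex vivo-style phantom: a pleural shell plus an
#'     internal vessel tree, tissue-bright on an air background, no body.}
#' }
#'
#' @param kind one of `"sphere"`, `"slab_stack"`, `"rod_grid"`,
#'   `"dried_lung"`.
#' @param parameters named list of kind-specific parameters (see Details);
#'   all kinds accept `shape`, `voxel_size_um`, `noise_sd` and `seed`.
#' @return A `PhantomTruth` with a single truth mask `foreground`.
#' @export
generate_calibration_phantom <- function(kind = c("sphere", "slab_stack",
                                                  "rod_grid", "dried_lung"),
                                         parameters = list()) {
  kind <- match.arg(kind)
  p <- parameters
  vx <- p$voxel_size_um %||% 35
  noise_sd <- p$noise_sd %||% 0
  seed <- p$seed %||% 1L
  fg <- switch(kind,
    sphere = {
      r <- p$radius %||% 25
      margin <- p$margin %||% 6
      n <- ceiling(2 * r + 2 * margin)
      sh <- p$shape %||% c(n, n, n)
      if (any(2 * r + 2 > sh)) stop("geometry exceeds volume bounds")
      ellipsoid_mask(sh, (sh + 1) / 2, c(r, r, r))
    },
    slab_stack = {
      t <- p$thickness %||% 5
      g <- p$gap %||% 15
      axis <- p$axis %||% "z"
      sh <- p$shape %||% c(80, 64, 64)
      period <- t + g
      ax <- match(axis, c("z", "y", "x"))
      if (is.na(ax)) stop("axis must be z, y or x")
      idx <- ((seq_len(sh[ax]) - 1) %% period) < t
      arr <- array(FALSE, sh)
      if (ax == 1) arr[idx, , ] <- TRUE
      if (ax == 2) arr[, idx, ] <- TRUE
      if (ax == 3) arr[, , idx] <- TRUE
      arr
    },
    rod_grid = {
      r <- p$radius %||% 4
      pitch <- p$pitch %||% 20
      sh <- p$shape %||% c(64, 64, 64)
      if (2 * r >= pitch) stop("geometry exceeds volume bounds: rods overlap")
      arr <- array(FALSE, sh)
      centers_y <- seq(pitch / 2, sh[2], by = pitch)
      centers_x <- seq(pitch / 2, sh[3], by = pitch)
      for (cy in centers_y)
        for (cx in centers_x)
          arr <- paint_capsule(arr, c(1, cy, cx), c(sh[1], cy, cx), r)
      arr
    },
    dried_lung = {
      sh <- p$shape %||% c(160, 160, 160)
      cen <- (sh + 1) / 2
      semi <- c(0.38 * sh[1], 0.33 * sh[2], 0.33 * sh[3])
      shell_t <- p$shell_thickness %||% 3
      outer <- ellipsoid_mask(sh, cen, semi)
      inner <- ellipsoid_mask(sh, cen, semi - shell_t)
      shell <- outer & !inner
      tree <- with_seed(seed, {
        root <- cen - c(semi[1] - shell_t, 0, 0)
        vessel_tree(sh, root, c(1, 0.15, 0.1),
                    length0 = 0.35 * sh[1],
                    radius0 = p$vessel_root_radius_px %||% 8,
                    depth = p$vessel_depth %||% 4, min_radius = 2)
      })
      shell | (tree & outer)
    })
  sh <- dim(fg)
  ints <- list(bg = 20, fg = if (kind == "dried_lung") 120 else 200)
  vol <- array(ints$bg, sh)
  vol[fg] <- ints$fg
  if (noise_sd > 0)
    vol <- with_seed(seed, array(pmin(pmax(round(vol + rnorm(length(vol), 0, noise_sd)), 0), 255), sh))
  else vol <- array(as.integer(vol), sh)
  structure(list(volume = volume_image(vol, vx,
                                       source = sprintf("%s calibration phantom", kind)),
                 masks = list(foreground = binary_mask(fg, vx)),
                 spec = c(list(kind = kind), p)),
            class = "PhantomTruth")
}
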