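test_that("global threshold is inclusive at both cut points", {
  v <- tiny_volume(c(0, 54, 55, 120, 255), dim = c(5, 8, 8))
  # (z, 1, 1) walks the value cycle
  body <- threshold_global(v, 55, 255)
  air <- threshold_global(v, 0, 55)
  vals <- v$data[, 1, 1]
  expect_equal(body$data[, 1, 1], vals >= 55)
  expect_equal(air$data[, 1, 1], vals <= 55)
  # 55 belongs to both printed ranges
  expect_true(all((body$data | air$data)))
  expect_equal(sum(body$data & air$data), sum(v$data == 55))
  # full range selects everything
  expect_true(all(threshold_global(v, 0, 255)$data))
  expect_error(threshold_global(v, 100, 50), "invalid range")
})

test_that("threshold partitions the ROI exactly at every cut point", {
  set.seed(21)
  v <- tiny_volume(sample(0:255, 4 * 16 * 16, replace = TRUE),
                   dim = c(4, 16, 16))
  roi <- random_mask(c(4, 16, 16), p = 0.6)
  for (t in c(1, 55, 128, 255)) {
    lo <- threshold_global(v, 0, t - 1, roi = roi)
    hi <- threshold_global(v, t, 255, roi = roi)
    expect_false(any(lo$data & hi$data))
    expect_identical(lo$data | hi$data, roi$data)
  }
  expect_false(any(threshold_global(v, 0, 255, roi = roi)$data & !roi$data))
})

test_that("bitwise operations match the voxelwise truth table", {
  d <- c(2, 8, 8)
  combos <- expand.grid(a = c(FALSE, TRUE), b = c(FALSE, TRUE))
  a <- binary_mask(array(rep(combos$a, length.out = prod(d)), d), 35)
  b <- binary_mask(array(rep(combos$b, length.out = prod(d)), d), 35)
  expect_identical(bitwise_combine(a, b, "AND")$data, a$data & b$data)
  expect_identical(bitwise_combine(a, b, "OR")$data, a$data | b$data)
  expect_identical(bitwise_combine(a, b, "SUB")$data, a$data & !b$data)
  expect_identical(bitwise_combine(a, b, "XOR")$data, xor(a$data, b$data))
  expect_identical(bitwise_combine(a, b, "NOT_A")$data, !a$data)
  # algebraic identities
  expect_identical(bitwise_combine(a, a, "AND")$data, a$data)
  na <- bitwise_combine(a, a, "NOT_A")
  expect_false(any(bitwise_combine(a, na, "AND")$data))
  # shape mismatch
  small <- binary_mask(array(FALSE, c(2, 8, 4)), 35)
  expect_error(bitwise_combine(a, small, "AND"), "shape mismatch")
})

test_that("sweep despeckle equals the BFS labeling oracle", {
  set.seed(22)
  for (i in 1:25) {
    m <- random_mask(c(12, 12, 12), p = runif(1, 0.05, 0.35))
    if (!any(m$data)) next
    sw <- despeckle(m, "sweep_keep_largest", space = "3D")
    expect_identical(sw$data, oracle_keep_largest(m$data, 26),
                     label = sprintf("iteration %d", i))
    # output is one connected component and a subset of the input
    expect_equal(length(oracle_label(sw$data, 26)$sizes), 1L)
    expect_false(any(sw$data & !m$data))
  }
})

test_that("sweep despeckle keeps known components and breaks ties deterministically", {
  m <- binary_mask(array(FALSE, c(8, 12, 12)), 35)
  m$data[1:2, 1:5, 1] <- TRUE      # 10 voxels
  m$data[6:8, 10, 10] <- TRUE      # 3 voxels
  sw <- despeckle(m, "sweep_keep_largest")
  expect_equal(sum(sw$data), 10)
  expect_true(all(sw$data[1:2, 1:5, 1]))

  single <- despeckle(sw, "sweep_keep_largest")
  expect_identical(single$data, sw$data)

  # equal sizes: lexicographically smallest minimal (z, y, x) voxel wins
  tie <- binary_mask(array(FALSE, c(6, 8, 8)), 35)
  tie$data[5, 1:3, 1] <- TRUE
  tie$data[2, 5:7, 5] <- TRUE
  kept <- despeckle(tie, "sweep_keep_largest")
  expect_true(all(kept$data[2, 5:7, 5]))
  expect_false(any(kept$data[5, , ]))

  expect_error(despeckle(binary_mask(array(FALSE, c(2, 8, 8)), 35),
                         "sweep_keep_largest"), "no objects")
})

test_that("size-threshold despeckle removes white and fills black speckles", {
  m <- binary_mask(array(FALSE, c(4, 16, 16)), 35)
  m$data[2:3, 2:7, 2:7] <- TRUE    # big block (72)
  m$data[1, 14, 14] <- TRUE        # speck (1)
  rw <- despeckle(m, "remove_white_smaller_than", size_threshold = 5)
  expect_false(any(rw$data[1, , ]))
  expect_true(all(rw$data[2:3, 2:7, 2:7]))

  holed <- binary_mask(array(TRUE, c(4, 16, 16)), 35)
  holed$data[2, 8, 8] <- FALSE
  rb <- despeckle(holed, "remove_black_smaller_than", size_threshold = 5)
  expect_true(all(rb$data))
})

test_that("2D despeckle treats each slice independently", {
  m <- binary_mask(array(FALSE, c(3, 16, 16)), 35)
  m$data[1, 2:4, 2:4] <- TRUE   # slice 1: 9 voxels
  m$data[1, 10, 10] <- TRUE     # slice 1: 1 voxel
  m$data[3, 12:13, 12:13] <- TRUE  # slice 3: 4 voxels
  sw <- despeckle(m, "sweep_keep_largest", space = "2D")
  expect_true(all(sw$data[1, 2:4, 2:4]))
  expect_false(sw$data[1, 10, 10])
  expect_true(all(sw$data[3, 12:13, 12:13]))
})

test_that("morphology matches known geometry and the subset chain", {
  # erosion of a 5x5 square by round radius 1 -> 3x3
  m <- binary_mask(array(FALSE, c(2, 11, 11)), 35)
  m$data[, 4:8, 4:8] <- TRUE
  er <- morphological_operation(m, "erosion",
                                structuring_element("round", 1, "2D"))
  expect_true(all(er$data[, 5:7, 5:7]))
  expect_equal(sum(er$data), 2 * 9)

  # closing a disc with an interior hole fills the hole (slice kept large
  # enough that the border-padding contract plays no role)
  y <- matrix(seq_len(128), 128, 128)
  x <- t(y)
  disc <- binary_mask(array(rep((y - 64)^2 + (x - 64)^2 <= 20^2, each = 2),
                            c(2, 128, 128)), 35)
  hd <- array(FALSE, c(2, 128, 128))
  hd[1, , ] <- hd[2, , ] <- ((y - 64)^2 + (x - 64)^2 <= 20^2) &
                            ((y - 64)^2 + (x - 64)^2 > 5^2)
  hole <- binary_mask(hd, 35)
  closed <- morphological_operation(hole, "closing",
                                    structuring_element("round", 40, "2D"))
  expect_true(closed$data[1, 64, 64])
  expect_identical(closed$data, disc$data)

  # subset chain: erosion <= id <= dilation; opening <= id <= closing
  set.seed(23)
  for (i in 1:10) {
    r <- sample(1:3, 1)
    el <- structuring_element(sample(c("round", "square"), 1), r,
                              sample(c("2D", "3D"), 1))
    mm <- random_mask(c(6, 20, 20), p = 0.45)
    ero <- morphological_operation(mm, "erosion", el)
    dil <- morphological_operation(mm, "dilation", el)
    opn <- morphological_operation(mm, "opening", el)
    cls <- morphological_operation(mm, "closing", el)
    expect_false(any(ero$data & !mm$data))
    expect_false(any(mm$data & !dil$data))
    expect_false(any(opn$data & !mm$data))
    expect_false(any(mm$data & !cls$data))
    # idempotence
    expect_identical(morphological_operation(opn, "opening", el)$data,
                     opn$data)
    expect_identical(morphological_operation(cls, "closing", el)$data,
                     cls$data)
  }
})

test_that("closing equals dilation followed by erosion with the same element", {
  set.seed(24)
  for (i in 1:100) {
    m <- random_mask(c(1, 32, 32), p = runif(1, 0.2, 0.6))
    r <- sample(1:4, 1)
    el <- structuring_element("round", r, "2D")
    cls <- morphological_operation(m, "closing", el)
    composed <- morphological_operation(
      morphological_operation(m, "dilation", el), "erosion", el)
    expect_identical(cls$data, composed$data)
  }
})

test_that("operators commute with translation away from borders", {
  set.seed(25)
  base <- array(FALSE, c(8, 24, 24))
  base[3:6, 8:14, 8:14] <- runif(4 * 7 * 7) < 0.5
  shift <- function(a, dz, dy, dx) {
    out <- array(FALSE, dim(a))
    d <- dim(a)
    out[(1 + dz):d[1], (1 + dy):d[2], (1 + dx):d[3]] <-
      a[1:(d[1] - dz), 1:(d[2] - dy), 1:(d[3] - dx)]
    out
  }
  m <- binary_mask(base, 35)
  ms <- binary_mask(shift(base, 1, 2, 2), 35)
  el <- structuring_element("round", 1, "3D")
  for (op in c("erosion", "dilation", "opening", "closing")) {
    a <- morphological_operation(m, op, el)
    b <- morphological_operation(ms, op, el)
    expect_identical(shift(a$data, 1, 2, 2), b$data, label = op)
  }
  sw_a <- despeckle(m, "sweep_keep_largest")
  sw_b <- despeckle(ms, "sweep_keep_largest")
  expect_identical(shift(sw_a$data, 1, 2, 2), sw_b$data)
})

test_that("shrink-wrap handles convex bodies, bridged and unbridged gaps", {
  # convex solid: wrap equals the solid
  sq <- binary_mask(array(FALSE, c(2, 24, 24)), 35)
  sq$data[, 6:18, 6:18] <- TRUE
  expect_identical(shrinkwrap_roi(sq, diameter = 4)$data, sq$data)

  # C-shaped annulus with a 3-pixel gap: diameter 4 bridges it
  ring <- array(FALSE, c(1, 40, 40))
  y <- matrix(seq_len(40), 40, 40)
  x <- t(y)
  rr <- (y - 20)^2 + (x - 20)^2
  ring[1, , ] <- rr <= 14^2 & rr >= 9^2
  cgap <- ring
  cgap[1, 19:21, 28:40] <- FALSE  # 3-px opening
  w <- shrinkwrap_roi(binary_mask(cgap, 35), diameter = 4)
  expect_true(all(w$data[1, 18:22, 18:22]))   # cavity included
  # superset of the input
  expect_false(any(cgap & !w$data))

  # 8-pixel gap is not bridged: cavity stays out
  cbig <- ring
  cbig[1, 17:24, 28:40] <- FALSE  # 8-px opening
  w2 <- shrinkwrap_roi(binary_mask(cbig, 35), diameter = 4)
  expect_false(any(w2$data[1, 20, 20]))

  expect_error(shrinkwrap_roi(binary_mask(array(FALSE, c(2, 8, 8)), 35)),
               "nothing to wrap")
})

test_that("shrink-wrap agrees with the border flood-fill oracle on solids", {
  set.seed(26)
  for (i in 1:8) {
    m <- array(FALSE, c(2, 24, 24))
    cy <- sample(10:14, 1); cx <- sample(10:14, 1); r <- sample(3:5, 1)
    y <- matrix(seq_len(24), 24, 24); x <- t(y)
    m[1, , ] <- m[2, , ] <- (y - cy)^2 + (x - cx)^2 <= r^2
    w <- shrinkwrap_roi(binary_mask(m, 35), diameter = 4)
    expect_identical(w$data, oracle_fill_holes(m))
  }
})
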