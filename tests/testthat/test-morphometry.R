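test_that("object volume follows the closed form and the sphere oracle", {
  m <- binary_mask(array(FALSE, c(12, 12, 12)), 35)
  m$data[seq_len(1000)] <- TRUE
  expect_equal(object_volume(m), 1000 * 0.035^3)
  expect_equal(object_volume(binary_mask(array(FALSE, c(2, 8, 8)), 35)), 0)

  sp <- generate_calibration_phantom("sphere", list(radius = 25))
  vox <- mask_count(sp$masks$foreground)
  expect_lt(abs(vox - 4 / 3 * pi * 25^3) / (4 / 3 * pi * 25^3), 0.02)
})

test_that("structure thickness recovers slabs, spheres and single voxels", {
  slab <- binary_mask(array(FALSE, c(30, 20, 20)), 1000)
  slab$data[11:20, , ] <- TRUE
  st <- structure_thickness(slab)
  expect_lte(abs(st$mean_vox - 10), 1)
  expect_equal(st$mean_mm, st$mean_vox * 1)

  single <- binary_mask(array(FALSE, c(5, 8, 8)), 1000)
  single$data[3, 4, 4] <- TRUE
  expect_equal(structure_thickness(single)$mean_vox, 1)

  # thickness scales linearly with slab thickness
  slab2 <- binary_mask(array(FALSE, c(30, 20, 20)), 1000)
  slab2$data[9:24, , ] <- TRUE   # 16 voxels
  st2 <- structure_thickness(slab2)
  expect_lt(abs(st2$mean_vox / st$mean_vox - 16 / 10), 0.1)

  expect_error(structure_thickness(binary_mask(array(FALSE, c(2, 8, 8)), 35)),
               "empty")
  expect_error(structure_thickness(binary_mask(array(TRUE, c(2, 8, 8)), 35)),
               "fills")
})

test_that("structure thickness matches the brute-force sphere-fitting oracle", {
  for (r in c(4, 6, 8)) {
    sp <- generate_calibration_phantom("sphere",
                                       list(radius = r, margin = 3,
                                            voxel_size_um = 1000))
    mask <- sp$masks$foreground
    st <- structure_thickness(mask)
    expect_lte(st$mean_vox, 2 * r)
    expect_gte(st$mean_vox, r)
    oracle <- oracle_thickness_map(mask$data)
    expect_equal(st$map, oracle, tolerance = 1e-9)
  }
  # random blobs: implementation equals definition-by-enumeration
  set.seed(31)
  for (i in 1:3) {
    m <- random_mask(c(10, 10, 10), p = 0.5, voxel_size_um = 1000)
    m$data[1, 1, 1] <- FALSE  # guarantee background
    if (!any(m$data)) next
    expect_equal(structure_thickness(m)$map, oracle_thickness_map(m$data),
                 tolerance = 1e-9)
  }
})

test_that("structure linear density matches closed forms and the rle oracle", {
  ss <- generate_calibration_phantom("slab_stack",
                                     list(thickness = 5, gap = 15,
                                          voxel_size_um = 1000))
  sl <- structure_linear_density(ss$masks$foreground)
  expect_equal(unname(sl$axis_per_mm["z"]), 1 / 20)
  # in-plane axes see one structure per occupied line over the cube edge
  expect_equal(unname(sl$axis_per_mm["y"]), 1 / 64)
  expect_equal(unname(sl$axis_per_mm["x"]), 1 / 64)

  solid <- binary_mask(array(TRUE, c(10, 10, 10)), 1000)
  sd <- structure_linear_density(solid)
  expect_equal(unname(sd$axis_per_mm), rep(1 / 10, 3))

  empty <- binary_mask(array(FALSE, c(4, 8, 8)), 1000)
  expect_equal(structure_linear_density(empty)$per_mm, 0)

  # random masks against the rle oracle, with and without a VOI
  set.seed(32)
  for (i in 1:5) {
    m <- random_mask(c(6, 9, 9), p = 0.3, voxel_size_um = 1000)
    roi <- random_mask(c(6, 9, 9), p = 0.7)
    got <- structure_linear_density(m, roi = roi)
    want <- oracle_secant(m$data, roi$data)
    for (ax in c("z", "y", "x")) {
      expect_equal(unname(got$runs[ax]), unname(want[[ax]]["runs"]))
      expect_equal(unname(got$length_mm[ax]), unname(want[[ax]]["len"]))
    }
  }
})

test_that("merging structures lowers the secant run count", {
  stack <- generate_calibration_phantom("slab_stack",
                                        list(thickness = 5, gap = 15,
                                             voxel_size_um = 1000))
  solid <- binary_mask(array(TRUE, dim(stack$masks$foreground$data)), 1000)
  runs_stack <- structure_linear_density(stack$masks$foreground)$runs["z"]
  runs_solid <- structure_linear_density(solid)$runs["z"]
  expect_lte(runs_solid, runs_stack / 2)
})

test_that("surface meshes are watertight with volume converging to voxel count", {
  errs <- c()
  for (r in c(10, 20)) {
    sp <- generate_calibration_phantom("sphere",
                                       list(radius = r, voxel_size_um = 1000))
    mesh <- surface_mesh(sp$masks$foreground)
    chk <- mesh_edge_check(mesh)
    expect_true(chk$watertight)
    vv <- mesh_volume(mesh)
    tv <- object_volume(sp$masks$foreground)
    errs <- c(errs, abs(vv - tv) / tv)
  }
  expect_lt(errs[2], 0.05)
  expect_lt(errs[2], errs[1])

  # single voxel: closed mesh, sub-voxel enclosed volume (midpoint vertices)
  sv <- binary_mask(array(FALSE, c(4, 8, 8)), 1000)
  sv$data[2, 4, 4] <- TRUE
  msv <- surface_mesh(sv)
  expect_true(mesh_edge_check(msv)$watertight)
  expect_gt(mesh_volume(msv), 0.1)
  expect_lt(mesh_volume(msv), 1.1)

  # two disjoint cubes give two closed surface components
  two <- binary_mask(array(FALSE, c(8, 12, 12)), 1000)
  two$data[2:3, 2:3, 2:3] <- TRUE
  two$data[6:7, 8:9, 8:9] <- TRUE
  m2 <- surface_mesh(two)
  expect_equal(mesh_component_count(m2), 2)
  expect_true(mesh_edge_check(m2)$watertight)

  expect_error(surface_mesh(binary_mask(array(FALSE, c(2, 8, 8)), 35)),
               "no surface")
  expect_error(surface_mesh(binary_mask(array(TRUE, c(2, 8, 8)), 35)),
               "no surface")
})

test_that("morphometry report combines volumes, thickness and density", {
  sp <- generate_calibration_phantom("sphere",
                                     list(radius = 8, voxel_size_um = 1000))
  m <- morphometry(sp$masks$foreground)
  d <- dim(sp$masks$foreground$data)
  expect_equal(m$total_volume_mm3, prod(d))
  expect_equal(m$object_volume_mm3, object_volume(sp$masks$foreground))
  expect_equal(m$volume_fraction, m$object_volume_mm3 / m$total_volume_mm3)
  expect_true(is.finite(m$structure_thickness_mm))
  expect_true(is.finite(m$structure_linear_density_per_mm))
  expect_equal(m$structure_linear_density_plate_per_mm,
               m$volume_fraction / m$structure_thickness_mm)

  # BV/TV is translation invariant
  shifted <- array(FALSE, d)
  shifted[, , ] <- sp$masks$foreground$data[c(2:d[1], 1), , ]
  m2 <- morphometry(binary_mask(shifted, 1000), values = "basic")
  expect_equal(m2$volume_fraction, m$volume_fraction)

  df <- write_morphometry_csv(list(sphere = m), tempfile(fileext = ".csv"))
  expect_equal(df$bv_mm3, m$object_volume_mm3)
})

test_that("ROI comparison and cohort correlation behave at the extremes", {
  set.seed(33)
  a <- random_mask(c(4, 12, 12), p = 0.4)
  expect_equal(compare_rois(a, a)$dice, 1)
  expect_equal(compare_rois(a, a)$jaccard, 1)

  b <- bitwise_combine(a, a, "NOT_A")
  cmp <- compare_rois(a, b)
  expect_equal(cmp$dice, 0)
  expect_equal(cmp$jaccard, 0)

  # dice = 2 jaccard / (1 + jaccard)
  c2 <- random_mask(c(4, 12, 12), p = 0.4)
  cmp2 <- compare_rois(a, c2)
  expect_equal(cmp2$dice, 2 * cmp2$jaccard / (1 + cmp2$jaccard))

  e <- binary_mask(array(FALSE, c(2, 8, 8)), 35)
  expect_message(cmp3 <- compare_rois(e, e), "empty")
  expect_equal(cmp3$dice, 1)

  cc <- cohort_correlation(c(1, 2, 3), c(2, 4, 6))
  expect_equal(cc$pearson_r, 1)
  expect_equal(cc$r_squared, 1)
  expect_error(cohort_correlation(1:3, 1:4), "equal length")
  expect_error(cohort_correlation(1:2, 1:2), "at least 3")
})
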