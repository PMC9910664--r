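test_that("phantom generation is deterministic and mask-consistent", {
  s <- phantom_spec(shape = c(60, 96, 96), seed = 42)
  a <- generate_thorax_phantom(s)
  b <- generate_thorax_phantom(s)
  expect_identical(a$volume$data, b$volume$data)
  expect_identical(a$masks$lesions$data, b$masks$lesions$data)

  # masks pairwise disjoint, all inside the body envelope
  nms <- names(a$masks)
  for (i in seq_along(nms))
    for (j in seq_along(nms))
      if (i < j)
        expect_false(any(a$masks[[i]]$data & a$masks[[j]]$data),
                     label = paste(nms[i], nms[j]))
  inside <- a$masks$lung_air$data | a$masks$vessels$data |
    a$masks$lesions$data
  expect_false(any(inside & !a$body_region$data))

  # a different seed changes the noise realization
  c2 <- generate_thorax_phantom(phantom_spec(shape = c(60, 96, 96),
                                             seed = 43))
  expect_false(identical(a$volume$data, c2$volume$data))
})

test_that("noise-free zero-lesion phantoms place tissue intensity exactly on vessels", {
  ph <- generate_thorax_phantom(phantom_spec(shape = c(60, 96, 96),
                                             noise_sd = 0, seed = 1))
  tis <- ph$volume$data >= 55
  lungs_region <- ph$masks$lung_air$data | ph$masks$vessels$data
  expect_identical(tis & lungs_region, ph$masks$vessels$data)
  expect_equal(mask_count(ph$masks$lesions), 0)
  # intensities respect the class margins
  expect_true(all(ph$volume$data[ph$masks$lung_air$data] <= 40))
  expect_true(all(ph$volume$data[ph$masks$vessels$data] >= 70))
})

test_that("lesion packing hits its volume target and stays nested", {
  s02 <- phantom_spec(shape = c(60, 96, 96), lesion_volume_fraction = 0.2,
                      seed = 42)
  ph <- generate_thorax_phantom(s02)
  lung_vol <- sum(ph$masks$lung_air$data | ph$masks$vessels$data |
                  ph$masks$lesions$data)
  frac <- mask_count(ph$masks$lesions) / lung_vol
  expect_lt(abs(frac - 0.2) / 0.2, 0.10)

  ph01 <- generate_thorax_phantom(
    phantom_spec(shape = c(60, 96, 96), lesion_volume_fraction = 0.1,
                 seed = 42))
  expect_lt(mask_count(ph01$masks$lesions), mask_count(ph$masks$lesions))

  expect_error(phantom_spec(lesion_volume_fraction = 0.9))
})

test_that("phantom air and tissue intensities respect the threshold guards", {
  expect_error(phantom_spec(intensities = list(background_air = 20,
                                               body_tissue = 120,
                                               lung_parenchyma = 60,
                                               vessel = 130, lesion = 110,
                                               heart = 125)),
               "air-class")
  expect_error(phantom_spec(intensities = list(background_air = 20,
                                               body_tissue = 50,
                                               lung_parenchyma = 35,
                                               vessel = 130, lesion = 110,
                                               heart = 125)),
               "tissue-class")
})

test_that("calibration phantoms match their analytic constructions", {
  sp <- generate_calibration_phantom("sphere", list(radius = 10))
  d <- dim(sp$masks$foreground$data)
  ctr <- (d + 1) / 2
  idx <- which(sp$masks$foreground$data, arr.ind = TRUE)
  rr <- sqrt(rowSums((sweep(idx, 2, ctr))^2))
  expect_lte(max(rr), 10 + 1e-9)

  ss <- generate_calibration_phantom("slab_stack",
                                     list(thickness = 5, gap = 15))
  prof <- apply(ss$masks$foreground$data, 1, all)
  expect_equal(which(prof), which(((seq_len(80) - 1) %% 20) < 5))

  rod <- generate_calibration_phantom("rod_grid",
                                      list(radius = 3, pitch = 16))
  expect_true(any(rod$masks$foreground$data))
  expect_error(generate_calibration_phantom("rod_grid",
                                            list(radius = 10, pitch = 16)),
               "exceeds")

  dl <- generate_calibration_phantom("dried_lung",
                                     list(shape = c(64, 64, 64), seed = 2))
  # tissue-bright foreground on air background, single connected object
  expect_true(all(dl$volume$data[dl$masks$foreground$data] >= 100))
  expect_true(all(dl$volume$data[!dl$masks$foreground$data] <= 30))
  lab <- oracle_label(dl$masks$foreground$data, 26)
  expect_equal(length(lab$sizes), 1L)
})

test_that("segmentation degrades gracefully with noise", {
  quality <- vapply(c(6, 20), function(sd) {
    ph <- generate_thorax_phantom(phantom_spec(shape = c(60, 96, 96),
                                               noise_sd = sd, seed = 11))
    # the reduced-scale lung is small enough to trip the plausibility
    # warning the pipeline emits below 1 mm^3; that is the intended
    # diagnostic, not a defect
    res <- suppressWarnings(
      pats_segment(ph$volume, pats_params(closing_radius = 15)))
    compare_rois(res$aerated_roi, ph$masks$lung_air)$dice
  }, 0)
  expect_gte(quality[1], quality[2])
  expect_gt(quality[1], 0.9)
})
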