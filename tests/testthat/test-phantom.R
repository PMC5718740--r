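test_that("balloon geometry validates its arguments", {
  expect_error(balloon_geometry(4, deformation_mm = 6))
  expect_error(balloon_geometry(-1))
  expect_error(balloon_geometry(4, source_offset_mm = c(1, 2)))
  b <- balloon_geometry(4, deformation_mm = 2)
  expect_equal(b$deformation_mode, "hemispherical_outward")
  expect_equal(prescription_point(b), c(3, 0, 0))
})

test_that("deform_balloon toggles the deformation mode", {
  b <- deform_balloon(balloon_geometry(4), 3)
  expect_equal(b$deformation_mm, 3)
  expect_equal(b$deformation_mode, "hemispherical_outward")
  b0 <- deform_balloon(b, 0)
  expect_equal(b0$deformation_mode, "none")
  expect_error(deform_balloon(b, 9))
})

test_that("surface radius follows the rigid hemispherical displacement", {
  b <- balloon_geometry(4, deformation_mm = 4)
  expect_equal(mammobrachy:::surface_radius(b, 1), 2.4)
  expect_equal(mammobrachy:::surface_radius(b, 0.2), 2.4)
  expect_equal(mammobrachy:::surface_radius(b, 0), 2.0)
  expect_equal(mammobrachy:::surface_radius(b, -1), 2.0)
  bt <- balloon_geometry(4, deformation_mm = 4, taper_power = 1)
  expect_equal(mammobrachy:::surface_radius(bt, 0.5), 2.2)
})

test_that("voxel phantom geometry matches the analytic balloon", {
  b <- balloon_geometry(4)
  expect_warning(ph <- build_phantom(b, half_extent_cm = 5, voxel_cm = 0.15),
                 "margin")
  d <- dim(ph$material_index)
  expect_true(all(d %% 2 == 1))
  mid <- (d[1] + 1) / 2
  expect_equal(ph$material_index[mid, mid, mid], 2L) # centre is filling
  # voxelised balloon volume vs 4/3 pi R^3
  vol <- sum(ph$material_index == 2L) * ph$voxel_cm^3
  expect_equal(vol, 4 / 3 * pi * 2^3, tolerance = 0.02)
  expect_error(build_phantom(balloon_geometry(12), half_extent_cm = 5),
               "larger than phantom")
})

test_that("deformed phantom is asymmetric along +z only", {
  b <- balloon_geometry(4, deformation_mm = 5)
  suppressWarnings(ph <- build_phantom(b, half_extent_cm = 4,
                                       voxel_cm = 0.1))
  d <- dim(ph$material_index)
  mid <- (d[1] + 1) / 2
  zcol <- ph$material_index[mid, mid, ]
  up <- sum(zcol[mid:d[3]] == 2L)
  down <- sum(zcol[1:mid] == 2L)
  expect_gt(up, down)
  xrow <- ph$material_index[, mid, mid]
  expect_equal(sum(xrow[mid:d[1]] == 2L), sum(xrow[1:mid] == 2L))
})

test_that("PTV mask is the 1 cm shell outside the surface", {
  b <- balloon_geometry(4)
  suppressWarnings(ph <- build_phantom(b, half_extent_cm = 4.5,
                                       voxel_cm = 0.15))
  m <- ptv_mask(ph, b)
  r <- mammobrachy:::phantom_radii(ph)
  expect_true(all(r[m] > 2 & r[m] <= 3))
  expect_false(any(m & ph$material_index == 2L))
  vol <- sum(m) * ph$voxel_cm^3
  expect_equal(vol, 4 / 3 * pi * (3^3 - 2^3), tolerance = 0.02)
})

test_that("phantoms round-trip through header + raw files", {
  b <- balloon_geometry(4, filling = contrast_mixture(50))
  suppressWarnings(ph <- build_phantom(b, half_extent_cm = 3.5,
                                       voxel_cm = 0.25))
  base <- tempfile()
  write_phantom(ph, base)
  ph2 <- read_phantom(base)
  expect_equal(ph2$material_index, ph$material_index)
  expect_equal(ph2$voxel_cm, ph$voxel_cm)
  expect_equal(ph2$origin, ph$origin)
  expect_equal(ph2$materials[[2]]$mass_fractions,
               ph$materials[[2]]$mass_fractions, tolerance = 1e-12)
})
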