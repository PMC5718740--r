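test_that("point dose is the normalised inverse-square law", {
  bal <- balloon_geometry(4)
  expect_equal(point_dose(3, balloon = bal), 3.4)
  expect_equal(point_dose(6, balloon = bal), 3.4 / 4)
  expect_equal(point_dose(1.5, balloon = bal), 3.4 * 4)
  expect_error(point_dose(0, balloon = bal), "positive")
  # a radial dose function modulates the profile
  m <- point_source_model(radial_function = function(r) exp(-0.01 * r))
  expect_equal(point_dose(3, m, bal), 3.4)
  expect_lt(point_dose(6, m, bal), 3.4 / 4)
})

test_that("shift ratios match the closed form and are monotone", {
  sr <- shift_ratios(4, 0:5)
  expect_equal(sr$enhancement, (3 / (3 - 0:5 / 10))^2, tolerance = 1e-12)
  expect_equal(sr$reduction, (3 / (3 + 0:5 / 10))^2, tolerance = 1e-12)
  expect_true(all(diff(sr$enhancement) > 0))
  expect_true(all(diff(sr$reduction) < 0))
  # smaller balloons see larger perturbations at equal shift
  for (s in 1:5) {
    e <- vapply(c(4, 5, 6), function(d) shift_ratios(d, s)$enhancement,
                numeric(1))
    expect_true(all(diff(e) < 0))
  }
  expect_error(shift_ratios(4, 6))
})

test_that("analytic DVH volume fractions are exact shell volumes", {
  bal <- balloon_geometry(4)
  dvh <- analytic_dvh(bal)
  expect_s3_class(dvh, "dvh")
  expect_equal(sum(dvh$volume_fraction), 1, tolerance = 1e-12)
  expect_equal(attr(dvh, "ptv_volume_cm3"), 4 / 3 * pi * (27 - 8))
  # volume receiving >= 34 Gy is the sphere of radius 3 minus the balloon
  cum <- cumulative_dvh(dvh)
  v34 <- sum(dvh$volume_fraction[dvh$dose_gy >= 34])
  expect_equal(v34, (3^3 - 2^3) / (27 - 8), tolerance = 1e-9)
  # highest bin reaches the inner-edge dose 34 * (3/2)^2 = 76.5 Gy
  expect_equal(max(dvh$dose_gy) + 0.25, ceiling(34 * (3 / 2)^2 / 0.5) * 0.5,
               tolerance = 1e-9)
})

test_that("DVH refinement leaves the cumulative curve invariant", {
  bal <- balloon_geometry(4, deformation_mm = 3)
  coarse <- analytic_dvh(bal, bin_width_gy = 0.5)
  fine <- analytic_dvh(bal, bin_width_gy = 0.05)
  cum_f <- cumulative_dvh(fine)
  # evaluate both cumulative curves at shared dose levels
  for (dgy in c(30, 34, 40, 50, 60)) {
    v_c <- sum(coarse$volume_fraction[coarse$dose_gy >= dgy])
    v_f <- sum(fine$volume_fraction[fine$dose_gy >= dgy])
    expect_equal(v_c, v_f, tolerance = 0.02)
  }
  expect_true(all(diff(cum_f$volume_fraction_ge) <= 1e-12))
})

test_that("analytic DVH agrees with a brute-force voxel DVH", {
  bal <- balloon_geometry(4, deformation_mm = 4)
  ph <- suppressWarnings(build_phantom(bal, half_extent_cm = 3.6,
                                       voxel_cm = 0.04))
  m <- ptv_mask(ph, bal)
  r <- mammobrachy:::phantom_radii(ph)[m]
  dose <- 10 * point_dose(r, balloon = bal)
  dvh <- analytic_dvh(bal)
  for (dgy in c(25, 30, 34, 45, 60)) {
    v_a <- sum(dvh$volume_fraction[dvh$dose_gy >= dgy])
    v_v <- mean(dose >= dgy)
    expect_equal(v_a, v_v, tolerance = 0.02)
  }
})

test_that("deformation moves PTV volume to lower doses", {
  d0 <- analytic_dvh(balloon_geometry(4))
  d4 <- analytic_dvh(balloon_geometry(4, deformation_mm = 4))
  expect_lt(min(d4$dose_gy), min(d0$dose_gy))
  # displaced-side outer edge: dose ratio (3.0/3.4)^2 at 4 mm
  expect_equal(min(cumulative_dvh(d4)$dose_gy) - 0.25,
               floor(34 * (3 / 3.4)^2 / 0.5) * 0.5, tolerance = 1e-9)
  m0 <- sum(d0$dose_gy * d0$volume_fraction)
  m4 <- sum(d4$dose_gy * d4$volume_fraction)
  expect_lt(m4, m0)
})

test_that("analytic_dvh validates arguments", {
  expect_error(analytic_dvh(balloon_geometry(4), drf = 0), "drf")
  expect_error(analytic_dvh(balloon_geometry(4), drf = 1.2), "drf")
  expect_error(analytic_dvh(balloon_geometry(4), bin_width_gy = 0),
               "bin_width")
})

test_that("DVHs round-trip to CSV", {
  dvh <- analytic_dvh(balloon_geometry(4))
  path <- tempfile(fileext = ".csv")
  write_dvh(dvh, path)
  back <- read.csv(path)
  expect_equal(back$dose_gy, dvh$dose_gy)
  expect_equal(back$volume_fraction, dvh$volume_fraction, tolerance = 1e-12)
})
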