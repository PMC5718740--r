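# Shared small water run reused by several tests in this file.
.water_run <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      bal <- balloon_geometry(4, filling = water())
      ph <- suppressWarnings(
        build_phantom(bal, half_extent_cm = 6.5, voxel_cm = 0.15))
      cache <<- list(
        balloon = bal, phantom = ph,
        grid = run_mc(ph, source_model(), ir192_spectrum(),
                      config = mc_config(n_histories = 2e5, seed = 42)))
    }
    cache
  }
})

test_that("config and settings validate their arguments", {
  expect_error(transport_settings(electron_transport = TRUE), "electron")
  expect_error(transport_settings(photon_cutoff_mev = 0))
  expect_error(mc_config(n_histories = 0))
  expect_error(mc_config(batches = 0))
  expect_error(run_mc(.water_run()$phantom,
                      settings = transport_settings(photon_cutoff_mev = 0.9)),
               "cutoff")
  expect_error(run_mc(.water_run()$phantom,
                      spectrum = ir192_spectrum()[0, ]),
               "empty spectrum")
})

test_that("fixed seed gives bit-identical doses; new seed differs", {
  bal <- balloon_geometry(4, filling = water())
  ph <- suppressWarnings(build_phantom(bal, half_extent_cm = 3.5,
                                       voxel_cm = 0.25))
  cfg <- mc_config(n_histories = 2e4, seed = 7)
  g1 <- run_mc(ph, config = cfg)
  g2 <- run_mc(ph, config = cfg)
  expect_identical(g1$dose, g2$dose)
  g3 <- run_mc(ph, config = mc_config(n_histories = 2e4, seed = 8))
  expect_false(identical(g1$dose, g3$dose))
})

test_that("uniform water dose is spherically symmetric (octants, 3 sigma)", {
  w <- .water_run()
  g <- w$grid
  r <- mammobrachy:::phantom_radii(w$phantom)
  d <- dim(g$dose)
  ax <- mammobrachy:::phantom_axis(w$phantom)
  sgn <- list(x = outer(outer(sign(ax), rep(1, d[2])), rep(1, d[3])),
              y = outer(outer(rep(1, d[1]), sign(ax)), rep(1, d[3])),
              z = outer(outer(rep(1, d[1]), rep(1, d[2])), sign(ax)))
  shell <- r > 2.8 & r < 3.2
  means <- c(); ses <- c()
  for (sx in c(-1, 1)) for (sy in c(-1, 1)) for (sz in c(-1, 1)) {
    oct <- shell & sgn$x * sx > 0 & sgn$y * sy > 0 & sgn$z * sz > 0
    v <- g$dose[oct]
    means <- c(means, mean(v))
    ses <- c(ses, sd(v) / sqrt(length(v)))
  }
  overall <- mean(means)
  expect_true(all(abs(means - overall) < 3 * sqrt(ses^2 + mean(ses)^2)))
})

test_that("dose times r^2 is slowly varying and matches the R oracle", {
  w <- .water_run()
  prof <- radial_profile(w$grid, w$balloon,
                         distances_cm = c(-1, 0, 1, 2, 3), band_cm = 0.1)
  dr2 <- prof$dose * (prof$distance_cm + 2)^2
  expect_lt(max(dr2) / min(dr2), 1.15) # < 15% variation on 1-5 cm
  orc <- oracle_water_mc(n = 2e5, seed = 99)
  for (i in seq_len(nrow(prof))) {
    r <- prof$distance_cm[i] + 2
    o <- orc$dose[which.min(abs(orc$r_cm - r))]
    expect_equal(prof$dose[i], o, tolerance = 0.05)
  }
})

test_that("track-length and interaction-site estimators agree", {
  bal <- balloon_geometry(4, filling = water())
  ph <- suppressWarnings(build_phantom(bal, half_extent_cm = 5,
                                       voxel_cm = 0.15))
  g_tl <- run_mc(ph, config = mc_config(n_histories = 1e5, seed = 5))
  g_is <- run_mc(ph, config = mc_config(n_histories = 4e5, seed = 6,
                                        estimator = "interaction_site"))
  p_tl <- radial_profile(g_tl, bal, c(0, 1), band_cm = 0.2)
  p_is <- radial_profile(g_is, bal, c(0, 1), band_cm = 0.2)
  expect_equal(p_tl$dose, p_is$dose, tolerance = 0.03)
})

test_that("batch uncertainty shrinks roughly as 1/sqrt(histories)", {
  bal <- balloon_geometry(4, filling = water())
  ph <- suppressWarnings(build_phantom(bal, half_extent_cm = 4,
                                       voxel_cm = 0.2))
  u <- vapply(c(2e4, 2e5), function(n) {
    g <- run_mc(ph, config = mc_config(n_histories = n, seed = 11))
    radial_profile(g, bal, 1, band_cm = 0.2)$rel_unc
  }, numeric(1))
  expect_gt(u[1] / u[2], sqrt(10) / 2.5)
  expect_lt(u[1] / u[2], sqrt(10) * 2.5)
})

test_that("common random numbers collapse the DRF variance", {
  cfg <- mc_config(n_histories = 1e5, seed = 42)
  # the small phantom triggers an expected scatter-margin warning
  paired <- suppressWarnings(mc_drf(4, 50, half_extent_cm = 5, config = cfg))
  # unpaired uncertainty from independent seeds, propagated in quadrature
  bal_c <- balloon_geometry(4, filling = contrast_mixture(50))
  bal_s <- balloon_geometry(4, filling = saline())
  ph_c <- suppressWarnings(build_phantom(bal_c, half_extent_cm = 5))
  ph_s <- suppressWarnings(build_phantom(bal_s, half_extent_cm = 5))
  p_c <- radial_profile(run_mc(ph_c, config = cfg), bal_c, 1)
  p_s <- radial_profile(
    run_mc(ph_s, config = mc_config(n_histories = 1e5, seed = 4242)),
    bal_s, 1)
  unpaired <- sqrt(p_c$rel_unc^2 + p_s$rel_unc^2)
  # pairing must remove most of the shared transport noise; the exact
  # reduction factor fluctuates with seed, so require a clear (not maximal)
  # collapse
  expect_lt(paired$rel_unc, 0.7 * unpaired)
  expect_equal(paired$drf, 0.936, tolerance = 0.02)
})

test_that("profile and drf input checking works", {
  w <- .water_run()
  expect_error(radial_profile(w$grid, w$balloon, 10), "outside")
  p1 <- radial_profile(w$grid, w$balloon, c(0, 1))
  p2 <- radial_profile(w$grid, w$balloon, c(0, 2))
  expect_error(drf(p1, p2), "different distance grids")
  expect_error(drf(p1, p1, x_cm = 5), "not on the profile")
  expect_s3_class(p1, "dose_profile")
  expect_named(p1, c("distance_cm", "dose", "rel_unc"))
})

test_that("uncertainty_at needs batch doses and a dosed region", {
  bal <- balloon_geometry(4, filling = water())
  ph <- suppressWarnings(build_phantom(bal, half_extent_cm = 3.5,
                                       voxel_cm = 0.25))
  g <- run_mc(ph, config = mc_config(n_histories = 2e4, seed = 1))
  msk <- mammobrachy:::phantom_radii(ph) < 3
  expect_error(uncertainty_at(g, msk), "keep_batch_dose")
  g2 <- run_mc(ph, config = mc_config(n_histories = 2e4, seed = 1,
                                      keep_batch_dose = TRUE))
  u <- uncertainty_at(g2, msk)
  expect_true(is.finite(u) && u > 0 && u < 0.2)
})
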