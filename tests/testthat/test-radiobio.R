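test_that("protraction factor G matches the double-integral definition", {
  p <- radiobiology_params()
  # Lea-Catcheside for constant rate over Tf, repair rate mu, per fraction:
  # g1 = (2 / (mu Tf)) (1 - (1 - exp(-mu Tf)) / (mu Tf)); numerically:
  mu <- p$repair_rate_per_h; tf <- p$fraction_time_h
  g1 <- 2 / tf^2 * stats::integrate(function(t) {
    vapply(t, function(ti) {
      stats::integrate(function(s) exp(-mu * (ti - s)), 0, ti,
                       rel.tol = 1e-10)$value
    }, numeric(1))
  }, 0, tf, rel.tol = 1e-9)$value
  expect_equal(protraction_g(p), g1 / p$n_fractions, tolerance = 1e-7)
  expect_equal(protraction_g(p), 0.09620202, tolerance = 1e-7)
})

test_that("G tends to the acute-fraction limit 1/n as Tf -> 0", {
  p <- radiobiology_params(fraction_time_h = 1e-7)
  expect_equal(protraction_g(p), 1 / p$n_fractions, tolerance = 1e-5)
  # and G decreases with longer delivery or faster repair
  g_long <- protraction_g(radiobiology_params(fraction_time_h = 1))
  expect_lt(g_long, protraction_g(radiobiology_params()))
})

test_that("BED follows the LQ protraction formula", {
  p <- radiobiology_params()
  D <- 34
  d <- D / p$n_fractions
  expect_equal(bed(D, p),
               D * (1 + protraction_g(p) * d / (p$alpha / p$beta)))
  expect_equal(bed(0, p), 0)
  expect_error(bed(-1, p))
})

test_that("surviving fraction combines LQ kill and repopulation", {
  p <- radiobiology_params()
  gam <- log(2) / p$doubling_time_d
  lnS <- -p$alpha * bed(34, p) + gam * p$treatment_time_d
  expect_equal(surviving_fraction(34, p), exp(lnS), tolerance = 1e-12)
  expect_equal(surviving_fraction(0, p), exp(gam * p$treatment_time_d))
  # the opposite sign convention suppresses survival instead
  pm <- radiobiology_params(repopulation_sign = -1)
  expect_lt(surviving_fraction(34, pm), surviving_fraction(34, p))
})

test_that("tcp_from_dvh equals the closed form on single-bin DVHs", {
  p <- radiobiology_params()
  for (D in c(20, 34, 50)) {
    dvh <- tibble::tibble(dose_gy = D, volume_fraction = 1)
    fit <- tcp_from_dvh(dvh, p)
    expect_equal(fit$tcp, exp(-p$k * surviving_fraction(D, p)),
                 tolerance = 1e-12)
  }
})

test_that("TCP is monotone in dose and bounded", {
  p <- radiobiology_params()
  tcp_at <- function(D) tcp_from_dvh(
    tibble::tibble(dose_gy = D, volume_fraction = 1), p)$tcp
  doses <- seq(5, 60, by = 5)
  tcps <- vapply(doses, tcp_at, numeric(1))
  expect_true(all(diff(tcps) > 0))
  expect_true(all(tcps >= 0 & tcps <= 1))
  # survival capped at 1: unirradiated volume cannot exceed k clonogens
  dvh <- tibble::tibble(dose_gy = c(0, 34), volume_fraction = c(0.5, 0.5))
  fit <- tcp_from_dvh(dvh, p)
  expect_gte(fit$tcp, exp(-p$k))
})

test_that("apply_drf scales doses only", {
  dvh <- analytic_dvh(balloon_geometry(4))
  s <- apply_drf(dvh, 0.95)
  expect_equal(s$dose_gy, dvh$dose_gy * 0.95)
  expect_equal(s$volume_fraction, dvh$volume_fraction)
  expect_error(apply_drf(dvh, 1.2), "drf")
})

test_that("tidy and glance return the documented shapes", {
  fit <- tcp_from_dvh(analytic_dvh(balloon_geometry(4)))
  td <- tidy(fit)
  expect_named(td, c("term", "estimate"))
  gl <- glance(fit)
  expect_true(all(c("tcp", "tcp_pct", "mean_dose_gy", "k") %in% names(gl)))
  expect_equal(nrow(gl), 1)
  expect_equal(gl$tcp_pct, 100 * fit$tcp)
})
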