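test_that("material constructor validates input", {
  expect_error(material("x", c(H = 0.5, O = 0.4), 1), "sum to 1")
  expect_error(material("x", c(H = -0.1, O = 1.1), 1), "negative")
  expect_error(material("x", c(Xx = 1), 1), "no elemental data")
  expect_error(material("x", c(H = 1), -1))
  m <- material("void", c(H = 1), 0)
  expect_s3_class(m, "brachy_material")
  expect_equal(m$density, 0)
})

test_that("water has the standard two-component composition", {
  w <- water()
  expect_equal(sum(w$mass_fractions), 1)
  expect_equal(unname(w$mass_fractions[["H"]]), 0.1119, tolerance = 1e-3)
  expect_equal(unname(w$mass_fractions[["O"]]), 0.8881, tolerance = 1e-3)
  expect_equal(w$density, 1.0)
})

test_that("saline defaults to water-equivalent and can carry NaCl", {
  expect_equal(saline()$mass_fractions, water()$mass_fractions)
  s <- saline(nacl = TRUE)
  expect_true(all(c("Na", "Cl") %in% names(s$mass_fractions)))
  expect_equal(sum(s$mass_fractions), 1)
  expect_equal(s$density, 1.005)
})

test_that("iopromide compound fractions follow the molecular formula", {
  io <- iopromide()
  aw <- atomic_weights()
  mw <- 18 * aw[["C"]] + 24 * aw[["H"]] + 3 * aw[["I"]] +
    3 * aw[["N"]] + 8 * aw[["O"]]
  expect_equal(unname(io$mass_fractions[["I"]]), 3 * aw[["I"]] / mw)
  expect_equal(sum(io$mass_fractions), 1)
  expect_equal(io$density, 1.409)
})

test_that("contrast mixture interpolates composition and density", {
  expect_equal(contrast_mixture(0)$mass_fractions, water()$mass_fractions)
  expect_equal(contrast_mixture(100)$mass_fractions,
               iopromide()$mass_fractions[
                 names(contrast_mixture(100)$mass_fractions)])
  m50 <- contrast_mixture(50)
  expect_equal(sum(m50$mass_fractions), 1)
  expect_equal(m50$density, (1.0 + 1.409) / 2)
  # mass fractions are linear in concentration
  m25 <- contrast_mixture(25)
  expect_equal(unname(m25$mass_fractions[["I"]]),
               unname(m50$mass_fractions[["I"]]) / 2)
  expect_error(contrast_mixture(101), "\\[0, 100\\]")
  expect_error(contrast_mixture(-1), "\\[0, 100\\]")
})

test_that("mixture rule equals brute-force element sum", {
  m <- contrast_mixture(50)
  tab <- element_data()
  # on tabulated energies interpolation is exact, so the comparison is strict
  for (E in tab$energy_mev[c(5, 17, 30, 44)]) {
    brute <- sum(vapply(names(m$mass_fractions), function(el) {
      d <- tab[tab$element == el & tab$energy_mev == E, ]
      m$mass_fractions[[el]] * d$total
    }, numeric(1)))
    expect_equal(mu_over_rho(m, E, "total"), brute, tolerance = 1e-10)
  }
  # off-grid: summing per-channel values equals the per-channel mixture rule
  for (E in c(0.07, 0.358, 0.612)) {
    per_channel <- mu_over_rho(m, E, "photoelectric") +
      mu_over_rho(m, E, "incoherent") + mu_over_rho(m, E, "coherent")
    expect_equal(per_channel, mu_over_rho(m, E, "total"), tolerance = 0.01)
  }
})

test_that("materials round-trip through plain text", {
  m <- contrast_mixture(37.5)
  path <- tempfile(fileext = ".txt")
  write_material(m, path)
  m2 <- read_material(path)
  expect_equal(m2$mass_fractions, m$mass_fractions, tolerance = 1e-12)
  expect_equal(m2$density, m$density)
  expect_equal(m2$name, m$name)
})

test_that("tidy gives a tibble of fractions", {
  td <- tidy(water())
  expect_s3_class(td, "tbl_df")
  expect_named(td, c("element", "mass_fraction"))
  expect_equal(sum(td$mass_fraction), 1)
})
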