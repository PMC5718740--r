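#' Standard atomic weights used by the material model
#'
#' @return Named numeric vector of atomic weights (g/mol) for the elements
#'   covered by the shipped attenuation tables.
#' @export
atomic_weights <- function() {
  c(H = 1.008, C = 12.011, N = 14.007, O = 15.999,
    Na = 22.990, Cl = 35.45, I = 126.904)
}

#' Elemental photon mass attenuation coefficients
#'
#' Per-channel (photoelectric, incoherent, coherent) mass attenuation
#' coefficients in cm^2/g for H, C, N, O, Na, Cl and I on a log-spaced energy
#' grid covering 0.048-1.02 MeV. Incoherent values are free-electron
#' Klein-Nishina; totals for the light elements are anchored to standard
#' published tables (see `data-raw/make_mu_tables.R` for the construction).
#'
#' @return A tibble with columns `element`, `energy_mev`, `photoelectric`,
#'   `incoherent`, `coherent` and `total` (all coefficients in cm^2/g).
#' @export
element_data <- function() {
  if (is.null(the$elements)) {
    path <- system.file("extdata", "mu_rho_elements.csv",
                        package = "mammobrachy", mustWork = TRUE)
    tab <- tibble::as_tibble(read.csv(path, stringsAsFactors = FALSE))
    tab$total <- tab$photoelectric + tab$incoherent + tab$coherent
    the$elements <- tab
  }
  the$elements
}

#' Klein-Nishina total cross section per electron
#'
#' @param energy_mev Photon energy in MeV.
#' @return Cross section in barn.
#' @export
kn_cross_section <- function(energy_mev) {
  k <- energy_mev / 0.51099895
  re2 <- 0.0794078 # classical electron radius squared, barn
  2 * pi * re2 * (
    (1 + k) / k^2 * (2 * (1 + k) / (1 + 2 * k) - log(1 + 2 * k) / k) +
      log(1 + 2 * k) / (2 * k) - (1 + 3 * k) / (1 + 2 * k)^2
  )
}

#' Mean fraction of photon energy transferred to the electron in incoherent
#' scattering
#'
#' Computed by numerical quadrature of the Klein-Nishina differential cross
#' section over the scattering angle; used to build the energy-transfer
#' coefficient for kerma scoring.
#'
#' @param energy_mev Photon energy in MeV (vectorised).
#' @return Dimensionless fraction in (0, 1).
#' @export
kn_transfer_fraction <- function(energy_mev) {
  vapply(energy_mev, function(E) {
    k <- E / 0.51099895
    mu <- seq(-1, 1, length.out = 2001) # cos(theta) grid
    x <- 1 / (1 + k * (1 - mu))         # E'/E
    dsdo <- 0.5 * x^2 * (x + 1 / x - (1 - mu^2))
    sig <- sum(dsdo)
    1 - sum(x * dsdo) / sig
  }, numeric(1))
}

.channels <- c("total", "photoelectric", "incoherent", "coherent")

# log-log interpolation of one element's channel onto arbitrary energies
.mu_element <- function(element, energy_mev, channel) {
  tab <- element_data()
  d <- tab[tab$element == element, ]
  if (nrow(d) == 0L) {
    stop("no attenuation table for element '", element, "'", call. = FALSE)
  }
  rng <- range(d$energy_mev)
  if (any(energy_mev < rng[1] | energy_mev > rng[2])) {
    stop("energy outside tabulated range [", signif(rng[1], 3), ", ",
         signif(rng[2], 3), "] MeV", call. = FALSE)
  }
  y <- d[[channel]]
  exp(approx(log(d$energy_mev), log(pmax(y, 1e-300)),
             xout = log(energy_mev))$y)
}

#' Mass attenuation coefficient of a material
#'
#' Combines the elemental tables with the standard mixture rule
#' sum_i w_i (mu/rho)_i, interpolating log-log in energy.
#'
#' @param material A [material()] object.
#' @param energy_mev Photon energy in MeV (vectorised).
#' @param channel One of `"total"`, `"photoelectric"`, `"incoherent"`,
#'   `"coherent"`.
#' @return Mass attenuation coefficient in cm^2/g.
#' @export
mu_over_rho <- function(material, energy_mev, channel = "total") {
  stopifnot(inherits(material, "brachy_material"))
  channel <- match.arg(channel, .channels)
  w <- material$mass_fractions
  out <- numeric(length(energy_mev))
  for (el in names(w)) {
    out <- out + w[[el]] * .mu_element(el, energy_mev, channel)
  }
  out
}

#' Linear attenuation coefficient of a material
#'
#' @inheritParams mu_over_rho
#' @return Linear attenuation coefficient in 1/cm
#'   (`mu_over_rho()` times density).
#' @export
linear_mu <- function(material, energy_mev, channel = "total") {
  mu_over_rho(material, energy_mev, channel) * material$density
}
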