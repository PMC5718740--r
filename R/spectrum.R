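#' Ir-192 photon line spectrum
#'
#' The standard Ir-192 decay line spectrum (gamma lines plus Pt/Os K x-rays)
#' restricted to \[0.060, 0.885\] MeV, collapsed to 34 lines, with intensities
#' normalised to sum to 1.
#'
#' @return A tibble of class `photon_spectrum` with columns `energy_mev` and
#'   `intensity`.
#' @export
ir192_spectrum <- function() {
  if (is.null(the$spectrum)) {
    path <- system.file("extdata", "ir192_spectrum.csv",
                        package = "mammobrachy", mustWork = TRUE)
    tab <- tibble::as_tibble(read.csv(path))
    tab$intensity <- tab$intensity / sum(tab$intensity)
    the$spectrum <- new_photon_spectrum(tab)
  }
  the$spectrum
}

new_photon_spectrum <- function(tab) {
  stopifnot(all(c("energy_mev", "intensity") %in% names(tab)),
            all(tab$intensity >= 0), sum(tab$intensity) > 0,
            !is.unsorted(tab$energy_mev))
  tab$intensity <- tab$intensity / sum(tab$intensity)
  class(tab) <- c("photon_spectrum", class(tab))
  tab
}

#' Intensity-weighted mean energy of a spectrum
#'
#' @param spectrum A spectrum tibble as returned by [ir192_spectrum()].
#' @return Mean photon energy in MeV.
#' @export
mean_energy <- function(spectrum) {
  sum(spectrum$energy_mev * spectrum$intensity) / sum(spectrum$intensity)
}

#' Write or read a photon spectrum as a plain-text table
#'
#' @param x A spectrum tibble (`energy_mev`, `intensity`).
#' @param path File path.
#' @return `write_spectrum()` returns `x` invisibly; `read_spectrum()` the
#'   parsed spectrum.
#' @export
write_spectrum <- function(x, path) {
  writeLines(c("energy_mev intensity",
               paste(format(x$energy_mev, digits = 15),
                     format(x$intensity, digits = 15))), path)
  invisible(x)
}

#' @rdname write_spectrum
#' @export
read_spectrum <- function(path) {
  tab <- read.table(path, header = TRUE)
  new_photon_spectrum(tibble::as_tibble(tab))
}
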