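#' Define a material from elemental mass fractions
#'
#' @param name Label for the material.
#' @param mass_fractions Named numeric vector of elemental mass fractions
#'   (names are element symbols covered by [element_data()]); must sum to 1
#'   within 1e-6.
#' @param density Mass density in g/cm^3 (>= 0; zero is allowed to express a
#'   void).
#' @return An object of class `brachy_material`.
#' @export
material <- function(name, mass_fractions, density) {
  stopifnot(is.character(name), length(name) == 1L,
            is.numeric(mass_fractions), !is.null(names(mass_fractions)),
            is.numeric(density), length(density) == 1L, density >= 0)
  unknown <- setdiff(names(mass_fractions), names(atomic_weights()))
  if (length(unknown) > 0) {
    stop("no elemental data for: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (any(mass_fractions < 0)) stop("negative mass fraction", call. = FALSE)
  if (abs(sum(mass_fractions) - 1) > 1e-6) {
    stop("mass fractions must sum to 1 (got ", sum(mass_fractions), ")",
         call. = FALSE)
  }
  structure(
    list(name = name,
         mass_fractions = mass_fractions[mass_fractions > 0],
         density = density),
    class = "brachy_material"
  )
}

#' @export
print.brachy_material <- function(x, ...) {
  cat("<material>", x$name, " (", x$density, "g/cm^3)\n")
  comp <- sprintf("%s %.4f", names(x$mass_fractions), x$mass_fractions)
  cat(" ", paste(comp, collapse = ", "), "\n")
  invisible(x)
}

#' Composition of a material as a tibble
#'
#' @param x A [material()] object.
#' @param ... Unused.
#' @return A tibble with columns `element` and `mass_fraction`.
#' @export
tidy.brachy_material <- function(x, ...) {
  tibble::tibble(element = names(x$mass_fractions),
                 mass_fraction = unname(x$mass_fractions))
}

#' Water
#'
#' @return Liquid water at 1.00 g/cm^3, mass fractions from the standard
#'   atomic weights (H 11.19%, O 88.81%).
#' @export
water <- function() {
  aw <- atomic_weights()
  m <- c(H = 2 * aw[["H"]], O = aw[["O"]])
  material("water", m / sum(m), 1.00)
}

#' Saline balloon filling
#'
#' The balloon filling used in place of plain water. Dosimetrically saline is
#' indistinguishable from water at these energies; an optional flag adds the
#' 0.9% NaCl by mass.
#'
#' @param nacl If `TRUE`, include 0.9% NaCl by mass (density 1.005 g/cm^3);
#'   default is plain water.
#' @return A [material()] object.
#' @export
saline <- function(nacl = FALSE) {
  if (!nacl) {
    m <- water()
    m$name <- "saline"
    return(m)
  }
  aw <- atomic_weights()
  wat <- water()$mass_fractions
  nacl_frac <- c(Na = aw[["Na"]], Cl = aw[["Cl"]])
  nacl_frac <- nacl_frac / sum(nacl_frac)
  material("saline", c(0.991 * wat, 0.009 * nacl_frac), 1.005)
}

#' Iopromide contrast compound
#'
#' The iodinated contrast agent C18H24I3N3O8 (molecular weight 791.1 g/mol by
#' standard atomic weights, 48.1% iodine by weight), at the density of the
#' undiluted commercial solution, 1.409 g/cm^3.
#'
#' @return A [material()] object.
#' @export
iopromide <- function() {
  aw <- atomic_weights()
  counts <- c(C = 18, H = 24, I = 3, N = 3, O = 8)
  m <- counts * aw[names(counts)]
  material("iopromide", m / sum(m), 1.409)
}

#' Contrast/water mixture filling the balloon
#'
#' Composition and density of a contrast solution at a given concentration:
#' mass fractions mix linearly in the concentration between water and the pure
#' compound, and density mixes volume-linearly between 1.00 and 1.409 g/cm^3.
#' This is the arithmetic that reproduces the published compositions of the
#' simulated contrast solutions at 15%, 50% and 100%.
#'
#' @param concentration_pct Contrast concentration in percent, in \[0, 100\].
#' @return A [material()] object.
#' @export
contrast_mixture <- function(concentration_pct) {
  stopifnot(is.numeric(concentration_pct), length(concentration_pct) == 1L)
  if (concentration_pct < 0 || concentration_pct > 100) {
    stop("concentration_pct must be in [0, 100]", call. = FALSE)
  }
  c_ <- concentration_pct / 100
  comp <- iopromide()
  wat <- water()
  els <- union(names(comp$mass_fractions), names(wat$mass_fractions))
  w <- setNames(numeric(length(els)), els)
  w[names(comp$mass_fractions)] <- c_ * comp$mass_fractions
  w[names(wat$mass_fractions)] <- w[names(wat$mass_fractions)] +
    (1 - c_) * wat$mass_fractions
  material(sprintf("contrast %g%%", concentration_pct), w,
           c_ * comp$density + (1 - c_) * wat$density)
}

#' Paraffin/bees-wax tissue substitute
#'
#' The in-house breast phantom material, modelled as CH2 at relative density
#' 0.926 (its elemental composition beyond the hydrocarbon assumption is not
#' specified).
#'
#' @return A [material()] object.
#' @export
soft_wax <- function() {
  aw <- atomic_weights()
  m <- c(C = aw[["C"]], H = 2 * aw[["H"]])
  material("soft wax", m / sum(m), 0.926)
}

#' Write or read a material as a plain-text table
#'
#' The format is a small key/value + table text file: a `name:` line, a
#' `density:` line, then `element fraction` rows.
#'
#' @param x A [material()] object.
#' @param path File path.
#' @return `write_material()` returns `x` invisibly; `read_material()` returns
#'   the parsed [material()].
#' @export
write_material <- function(x, path) {
  stopifnot(inherits(x, "brachy_material"))
  lines <- c(paste("name:", x$name),
             paste("density:", format(x$density, digits = 15)),
             paste(names(x$mass_fractions),
                   format(x$mass_fractions, digits = 15)))
  writeLines(lines, path)
  invisible(x)
}

#' @rdname write_material
#' @export
read_material <- function(path) {
  lines <- readLines(path)
  name <- sub("^name: ?", "", lines[1])
  density <- as.numeric(sub("^density: ?", "", lines[2]))
  parts <- strsplit(trimws(lines[-(1:2)]), "[[:space:]]+")
  w <- setNames(vapply(parts, function(p) as.numeric(p[2]), numeric(1)),
                vapply(parts, `[`, character(1), 1))
  material(name, w, density)
}
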