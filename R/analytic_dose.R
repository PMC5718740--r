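#' Analytic point-source dose model
#'
#' Dose per fraction around an isotropic point source normalised to the
#' prescription dose at 1 cm from the balloon surface, with an optional radial
#' dose function g(r) modulating the inverse-square law (default g == 1, pure
#' inverse square).
#'
#' @param prescription_gy Dose per fraction at the prescription point
#'   (default 3.4 Gy).
#' @param radial_function Optional function `g(r_cm)` (> 0 on 1-7 cm), e.g.
#'   fitted to a Monte Carlo water run; `NULL` means g == 1.
#' @return An object of class `point_source_model`.
#' @export
point_source_model <- function(prescription_gy = 3.4,
                               radial_function = NULL) {
  stopifnot(prescription_gy > 0)
  if (!is.null(radial_function)) {
    stopifnot(is.function(radial_function))
    if (any(radial_function(seq(1, 7, by = 0.5)) <= 0)) {
      stop("radial_function must be positive on 1-7 cm", call. = FALSE)
    }
  }
  structure(list(prescription_gy = prescription_gy,
                 radial_function = radial_function),
            class = "point_source_model")
}

#' Dose per fraction at a radius
#'
#' `dose(r) = prescription * ((R + 1) / r)^2 * g(r) / g(R + 1)` with R the
#' nominal balloon radius in cm.
#'
#' @param r_cm Distance from the source in cm (> 0, vectorised).
#' @param model A [point_source_model()].
#' @param balloon A [balloon_geometry()].
#' @return Dose in Gy per fraction.
#' @export
point_dose <- function(r_cm, model = point_source_model(),
                       balloon = balloon_geometry()) {
  if (any(r_cm <= 0)) stop("r_cm must be positive", call. = FALSE)
  r0 <- balloon_radius(balloon) + 1
  g <- model$radial_function
  gfac <- if (is.null(g)) 1 else g(r_cm) / g(r0)
  model$prescription_gy * (r0 / r_cm)^2 * gfac
}

#' Dose enhancement and reduction ratios for a shifted source
#'
#' For a source shifted by `s` mm from the balloon centre, the prescription
#' isodose point on the approach side sits at distance `R + 1 cm - s` from
#' the source (enhancement) and on the far side at `R + 1 cm + s`
#' (reduction).
#'
#' @param diameter_cm Balloon diameter in cm.
#' @param shift_mm Source shift in mm (0 to 5, vectorised).
#' @param model A [point_source_model()].
#' @return A tibble with columns `shift_mm`, `enhancement`, `reduction`.
#' @export
shift_ratios <- function(diameter_cm, shift_mm,
                         model = point_source_model()) {
  stopifnot(all(shift_mm >= 0), all(shift_mm <= 5))
  bal <- balloon_geometry(diameter_cm)
  r0 <- balloon_radius(bal) + 1
  s <- shift_mm / 10
  if (any(r0 - s <= 0)) stop("shift makes distance non-positive",
                             call. = FALSE)
  d0 <- point_dose(r0, model, bal)
  tibble::tibble(
    shift_mm = shift_mm,
    enhancement = point_dose(r0 - s, model, bal) / d0,
    reduction = point_dose(r0 + s, model, bal) / d0
  )
}

# invert the (strictly decreasing) radial dose to the radius receiving D
.radius_at_dose <- function(D_total, balloon, model, drf, n_fractions) {
  r0 <- balloon_radius(balloon) + 1
  scale <- n_fractions * drf
  if (is.null(model$radial_function)) {
    r0 * sqrt(scale * model$prescription_gy / D_total)
  } else {
    vapply(D_total, function(D) {
      stats::uniroot(function(r) {
        scale * point_dose(r, model, balloon) - D
      }, c(1e-3, 50), tol = 1e-10)$root
    }, numeric(1))
  }
}

# angular sectors of the (possibly deformed) PTV: weight = solid-angle
# fraction, rs = inner (surface) radius
.ptv_sectors <- function(balloon, n_theta = 64L) {
  R <- balloon_radius(balloon)
  d <- balloon$deformation_mm / 10
  if (balloon$deformation_mode != "hemispherical_outward" || d == 0) {
    return(tibble::tibble(weight = 1, rs = R))
  }
  if (balloon$taper_power == 0) {
    return(tibble::tibble(weight = c(0.5, 0.5), rs = c(R, R + d)))
  }
  edges <- seq(0, 1, length.out = n_theta + 1)
  mid <- (edges[-1] + edges[-(n_theta + 1)]) / 2
  tibble::tibble(
    weight = c(0.5, rep(0.5 / n_theta, n_theta)),
    rs = c(R, R + d * mid^balloon$taper_power)
  )
}

#' Analytic differential DVH over the PTV shell
#'
#' Total-dose differential dose-volume histogram of the 1 cm PTV shell around
#' the balloon, from the analytic point-source model with exact shell volumes.
#' The total dose at radius r is `n_fractions * point_dose(r) * drf`; for a
#' deformed balloon the displaced tissue receives the dose of its actual
#' radius while the plan normalisation stays at the nominal prescription
#' point.
#'
#' @param balloon A [balloon_geometry()].
#' @param model A [point_source_model()].
#' @param drf Dose reduction factor applied to all doses (in (0, 1]).
#' @param n_fractions Number of fractions (default 10).
#' @param bin_width_gy DVH bin width in Gy of total dose (default 0.5).
#' @return A tibble of class `dvh` with columns `dose_gy` (bin midpoint) and
#'   `volume_fraction` (sums to 1); bin edges, the PTV volume in cm^3 and the
#'   fraction count are attached as attributes.
#' @export
analytic_dvh <- function(balloon, model = point_source_model(), drf = 1,
                         n_fractions = 10, bin_width_gy = 0.5) {
  stopifnot(inherits(balloon, "balloon_geometry"))
  if (drf <= 0 || drf > 1) stop("drf must be in (0, 1]", call. = FALSE)
  if (bin_width_gy <= 0) stop("bin_width_gy must be positive", call. = FALSE)
  if (balloon$diameter_cm <= 0) stop("empty PTV", call. = FALSE)

  sect <- .ptv_sectors(balloon)
  dose_at <- function(r) n_fractions * drf * point_dose(r, model, balloon)
  d_lo <- min(dose_at(sect$rs + 1))
  d_hi <- max(dose_at(sect$rs))
  edges <- seq(floor(d_lo / bin_width_gy) * bin_width_gy,
               ceiling(d_hi / bin_width_gy) * bin_width_gy,
               by = bin_width_gy)

  vol <- numeric(length(edges) - 1)
  total <- 0
  for (i in seq_len(nrow(sect))) {
    rs <- sect$rs[i]
    # radius receiving each edge dose, clamped to this sector's shell
    re <- .radius_at_dose(pmin(pmax(edges, dose_at(rs + 1)), dose_at(rs)),
                          balloon, model, drf, n_fractions)
    re <- pmin(pmax(re, rs), rs + 1)
    v_edge <- (4 * pi / 3) * sect$weight[i] * re^3
    # dose decreases with radius: bin [e_j, e_j+1) occupies radii
    # (r(e_j+1), r(e_j)]
    vol <- vol + (v_edge[-length(v_edge)] - v_edge[-1])
    total <- total + (4 * pi / 3) * sect$weight[i] *
      ((rs + 1)^3 - rs^3)
  }
  out <- tibble::tibble(
    dose_gy = (edges[-1] + edges[-length(edges)]) / 2,
    volume_fraction = vol / total
  )
  out <- out[out$volume_fraction > 0 | c(TRUE, rep(FALSE, nrow(out) - 1)), ]
  out$volume_fraction <- out$volume_fraction / sum(out$volume_fraction)
  attr(out, "bin_width_gy") <- bin_width_gy
  attr(out, "ptv_volume_cm3") <- total
  attr(out, "n_fractions") <- n_fractions
  class(out) <- c("dvh", class(out))
  out
}

#' Cumulative view of a differential DVH
#'
#' @param dvh A differential DVH tibble (`dose_gy`, `volume_fraction`).
#' @return A tibble with `dose_gy` and `volume_fraction_ge`, the volume
#'   fraction receiving at least that dose.
#' @export
cumulative_dvh <- function(dvh) {
  o <- order(dvh$dose_gy)
  tibble::tibble(
    dose_gy = dvh$dose_gy[o],
    volume_fraction_ge = rev(cumsum(rev(dvh$volume_fraction[o])))
  )
}

#' Write a DVH as CSV (differential plus cumulative view)
#'
#' @param dvh A DVH tibble.
#' @param path File path.
#' @return `dvh`, invisibly.
#' @export
write_dvh <- function(dvh, path) {
  cum <- cumulative_dvh(dvh)
  out <- data.frame(dose_gy = dvh$dose_gy,
                    volume_fraction = dvh$volume_fraction,
                    volume_fraction_ge =
                      cum$volume_fraction_ge[match(dvh$dose_gy, cum$dose_gy)])
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(dvh)
}
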