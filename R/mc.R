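#' Photon transport settings
#'
#' Electrons are never transported: the engine scores kerma, which is adequate
#' at Ir-192 energies where secondary-electron ranges (< 2 mm in water) are
#' below the 1.5 mm scoring grid. The `electron_transport` flag records that
#' choice explicitly.
#'
#' @param photon_cutoff_mev Photon cutoff energy in MeV (default 0.06).
#'   Photons falling below it deposit their remaining energy locally.
#' @param electron_transport Must be `FALSE`; kerma approximation only.
#' @param coherent_scatter Include coherent (Thomson) scattering (default
#'   `TRUE`).
#' @return An object of class `transport_settings`.
#' @export
transport_settings <- function(photon_cutoff_mev = 0.06,
                               electron_transport = FALSE,
                               coherent_scatter = TRUE) {
  stopifnot(photon_cutoff_mev > 0)
  if (isTRUE(electron_transport)) {
    stop("electron transport is not implemented (kerma approximation only)",
         call. = FALSE)
  }
  structure(list(photon_cutoff_mev = photon_cutoff_mev,
                 electron_transport = FALSE,
                 coherent_scatter = isTRUE(coherent_scatter)),
            class = "transport_settings")
}

#' Monte Carlo run configuration
#'
#' @param n_histories Number of photon histories (>= 1).
#' @param seed Integer seed; fixed seed gives bit-identical results, and runs
#'   over different phantoms with the same seed share common random numbers
#'   history by history.
#' @param estimator `"track_length"` (kerma line integrals, the default) or
#'   `"interaction_site"` (analog deposits at collisions).
#' @param batches Number of statistically independent batches used for the
#'   uncertainty estimate (>= 2 for uncertainties).
#' @param keep_batch_dose Keep the per-batch voxel dose means (needed by
#'   [uncertainty_at()] for arbitrary regions; memory-heavy on large grids).
#' @return An object of class `mc_config`.
#' @export
mc_config <- function(n_histories = 1e6, seed = 1L,
                      estimator = c("track_length", "interaction_site"),
                      batches = 10L, keep_batch_dose = FALSE) {
  estimator <- match.arg(estimator)
  stopifnot(n_histories >= 1, batches >= 1, n_histories >= batches)
  structure(list(n_histories = n_histories, seed = as.numeric(seed),
                 estimator = estimator, batches = as.integer(batches),
                 keep_batch_dose = isTRUE(keep_batch_dose)),
            class = "mc_config")
}

#' Source capsule model
#'
#' The source is approximated as a uniformly, isotropically radiating
#' parallelepiped; the default extent is capsule-like (0.9 x 0.9 x 4.5 mm,
#' long axis along z).
#'
#' @param extent_mm Parallelepiped edge lengths in mm (all > 0).
#' @param position_mm Source centre offset from the balloon centre in mm
#'   (use the balloon's `source_offset_mm` for shift scenarios).
#' @return An object of class `source_model`.
#' @export
source_model <- function(extent_mm = c(0.9, 0.9, 4.5),
                         position_mm = c(0, 0, 0)) {
  stopifnot(length(extent_mm) == 3, all(extent_mm > 0),
            length(position_mm) == 3)
  structure(list(extent_mm = as.numeric(extent_mm),
                 position_mm = as.numeric(position_mm)),
            class = "source_model")
}

# per-material linear coefficient tables on a dense log-energy grid
.material_tables <- function(materials, settings, e_lo, e_hi, n_e = 160L) {
  egrid <- exp(seq(log(e_lo), log(e_hi), length.out = n_e))
  f_kn <- kn_transfer_fraction(egrid)
  n_mat <- length(materials)
  mu_tot <- mu_tr <- f_pe <- f_coh <- matrix(0, n_e, n_mat)
  for (m in seq_len(n_mat)) {
    pe <- linear_mu(materials[[m]], egrid, "photoelectric")
    inc <- linear_mu(materials[[m]], egrid, "incoherent")
    coh <- if (settings$coherent_scatter) {
      linear_mu(materials[[m]], egrid, "coherent")
    } else {
      rep(0, n_e)
    }
    tot <- pe + inc + coh
    mu_tot[, m] <- tot
    mu_tr[, m] <- pe + f_kn * inc
    f_pe[, m] <- pe / tot
    f_coh[, m] <- coh / tot
  }
  list(egrid = egrid, mu_tot = mu_tot, mu_tr = mu_tr,
       f_pe = f_pe, f_coh = f_coh,
       coh_scr = vapply(materials, .coherent_screening, numeric(1)),
       density = vapply(materials, `[[`, numeric(1), "density"))
}

# Per-material screening constant a_TF / (hbar c) in 1/MeV for the
# hydrogen-like form factor used in coherent-scatter sampling:
# a_TF = 0.885 a0 Z^(-1/3), hbar c / a0 = 3.731e-3 MeV, so
# scr(Z) = 0.885 / (3.731e-3 * Z^(1/3)). Elements are averaged weighted by
# their coherent cross-section contribution at 0.35 MeV (the spectrum mean;
# the weights vary slowly with energy).
.coherent_screening <- function(material) {
  z <- c(H = 1, C = 6, N = 7, O = 8, Na = 11, Cl = 17, I = 53)
  els <- names(material$mass_fractions)
  w <- material$mass_fractions *
    vapply(els, function(e) .mu_element(e, 0.35, "coherent"), numeric(1))
  sum(w * 0.885 / (3.731e-3 * z[els]^(1 / 3))) / sum(w)
}

#' Run the voxel photon Monte Carlo
#'
#' Transports photons sampled from the line spectrum through the phantom and
#' scores dose (energy per unit mass per history, Gy-proportional) on the
#' voxel grid, with per-batch statistics and radial-shell tallies around the
#' balloon centre.
#'
#' @param phantom A [build_phantom()] result.
#' @param source A [source_model()].
#' @param spectrum A photon spectrum tibble (default [ir192_spectrum()]).
#' @param settings [transport_settings()].
#' @param config [mc_config()].
#' @return An object of class `dose_grid`: arrays `dose` and
#'   `rel_uncertainty` over the phantom grid, radial-shell batch tallies, and
#'   run metadata.
#' @export
run_mc <- function(phantom, source = source_model(),
                   spectrum = ir192_spectrum(),
                   settings = transport_settings(), config = mc_config()) {
  stopifnot(inherits(phantom, "voxel_phantom"),
            inherits(source, "source_model"))
  if (nrow(spectrum) == 0) stop("empty spectrum", call. = FALSE)
  if (settings$photon_cutoff_mev >= min(spectrum$energy_mev)) {
    stop("photon cutoff at or above the lowest spectrum line", call. = FALSE)
  }
  intens <- spectrum$intensity / sum(spectrum$intensity)

  e_hi <- max(spectrum$energy_mev) * 1.001
  e_lo <- settings$photon_cutoff_mev * 0.95
  tabs <- .material_tables(phantom$materials, settings, e_lo, e_hi)

  dims <- dim(phantom$material_index)
  shell_bin_cm <- 0.05
  half <- max(abs(phantom$origin)) + phantom$voxel_cm
  n_shell <- as.integer(ceiling(sqrt(3) * half / shell_bin_cm)) + 2L

  res <- mc_transport_cpp(
    phantom$material_index, as.integer(dims), phantom$voxel_cm,
    phantom$origin,
    tabs$mu_tot, tabs$mu_tr, tabs$f_pe, tabs$f_coh, tabs$coh_scr,
    tabs$density,
    log(tabs$egrid[1]), diff(log(tabs$egrid[1:2])),
    source$position_mm / 10, source$extent_mm / 20,
    spectrum$energy_mev, cumsum(intens),
    settings$photon_cutoff_mev,
    match(config$estimator, c("track_length", "interaction_site")) - 1L,
    config$n_histories, config$batches, config$seed,
    shell_bin_cm, n_shell, config$keep_batch_dose)

  structure(
    list(dose = array(res$dose, dim = dims),
         rel_uncertainty = array(res$rel_uncertainty, dim = dims),
         shell_batch = res$shell_batch,
         shell_count = res$shell_count,
         shell_bin_cm = shell_bin_cm,
         batch_dose = if (config$keep_batch_dose) res$batch_dose,
         voxel_cm = phantom$voxel_cm, origin = phantom$origin,
         materials = phantom$materials,
         n_histories = config$n_histories, batches = config$batches,
         seed = config$seed, estimator = config$estimator),
    class = "dose_grid"
  )
}

#' @export
print.dose_grid <- function(x, ...) {
  cat("<dose grid>", paste(dim(x$dose), collapse = " x "), "voxels;",
      format(x$n_histories, big.mark = ","), "histories (",
      x$estimator, "estimator,", x$batches, "batches )\n")
  invisible(x)
}

# per-batch mean voxel dose across a set of radial shell bins
.shell_dose_batches <- function(grid, radius_cm, band_cm) {
  centers <- (seq_len(nrow(grid$shell_batch)) - 0.5) * grid$shell_bin_cm
  sel <- which(abs(centers - radius_cm) <= band_cm / 2)
  nv <- sum(grid$shell_count[sel])
  if (nv == 0) stop("no voxels in shell at radius ", radius_cm, " cm",
                    call. = FALSE)
  colSums(grid$shell_batch[sel, , drop = FALSE]) / nv
}

#' Radial dose profile around the balloon
#'
#' Spherical-shell average dose at given distances from the nominal balloon
#' surface (or, optionally, sampled along the +x reference axis only).
#'
#' @param grid A [run_mc()] dose grid.
#' @param balloon The [balloon_geometry()] of the run.
#' @param distances_cm Distances from the balloon surface in cm.
#' @param band_cm Radial averaging band (default one voxel).
#' @param geometry `"shell"` (default) for full spherical-shell averages,
#'   `"axis"` for voxels near the +x axis only.
#' @return A `dose_profile` tibble with columns `distance_cm`, `dose`,
#'   `rel_unc`, carrying the per-batch doses as an attribute.
#' @export
radial_profile <- function(grid, balloon, distances_cm,
                           band_cm = grid$voxel_cm,
                           geometry = c("shell", "axis")) {
  stopifnot(inherits(grid, "dose_grid"),
            inherits(balloon, "balloon_geometry"))
  geometry <- match.arg(geometry)
  R <- balloon_radius(balloon)
  rmax <- max(abs(grid$origin))
  if (any(distances_cm + R > rmax) || any(distances_cm + R < 0)) {
    stop("distance outside the dose grid", call. = FALSE)
  }
  if (geometry == "shell") {
    bm <- vapply(distances_cm, function(x) {
      .shell_dose_batches(grid, R + x, band_cm)
    }, numeric(grid$batches))
    bm <- matrix(bm, nrow = grid$batches) # batches x distances
  } else {
    if (is.null(grid$batch_dose)) {
      stop("axis profiles need `keep_batch_dose = TRUE` in mc_config()",
           call. = FALSE)
    }
    dims <- dim(grid$dose)
    ax <- grid$origin[1] + (seq_len(dims[1]) - 1L) * grid$voxel_cm
    mid <- (dims[2] + 1L) %/% 2L # origin is a voxel centre (odd grid)
    bm <- vapply(distances_cm, function(x) {
      sel <- which(abs(ax - (R + x)) <= band_cm / 2)
      vox <- sel + (mid - 1L) * dims[1] + (mid - 1L) * dims[1] * dims[2]
      colMeans(grid$batch_dose[vox, , drop = FALSE])
    }, numeric(grid$batches))
    bm <- matrix(bm, nrow = grid$batches)
  }
  dose <- colMeans(bm)
  rel_unc <- apply(bm, 2, sd) / sqrt(grid$batches) / dose
  out <- tibble::tibble(distance_cm = distances_cm, dose = dose,
                        rel_unc = rel_unc)
  attr(out, "batch_dose") <- bm
  attr(out, "balloon_radius_cm") <- R
  class(out) <- c("dose_profile", class(out))
  out
}

#' Dose reduction factor from paired profiles
#'
#' Ratio of the dose with contrast filling to the dose with saline filling at
#' the same distance from the balloon surface. When both profiles come from
#' common-random-number runs the per-batch ratios give the (much reduced)
#' statistical uncertainty of the ratio.
#'
#' @param contrast_profile,saline_profile [radial_profile()] results on the
#'   same distance grid.
#' @param x_cm Distance(s) from the balloon surface at which to evaluate.
#' @return A tibble with columns `distance_cm`, `drf`, `rel_unc`.
#' @export
drf <- function(contrast_profile, saline_profile,
                x_cm = contrast_profile$distance_cm) {
  if (!isTRUE(all.equal(contrast_profile$distance_cm,
                        saline_profile$distance_cm))) {
    stop("profiles are on different distance grids", call. = FALSE)
  }
  idx <- match(x_cm, contrast_profile$distance_cm)
  if (anyNA(idx)) stop("x_cm not on the profile distance grid", call. = FALSE)
  if (any(saline_profile$dose[idx] <= 0)) {
    stop("zero saline dose in denominator", call. = FALSE)
  }
  bc <- attr(contrast_profile, "batch_dose")[, idx, drop = FALSE]
  bs <- attr(saline_profile, "batch_dose")[, idx, drop = FALSE]
  ratio <- contrast_profile$dose[idx] / saline_profile$dose[idx]
  rb <- bc / bs
  rel_unc <- apply(rb, 2, sd) / sqrt(nrow(rb)) / colMeans(rb)
  tibble::tibble(distance_cm = x_cm, drf = ratio, rel_unc = rel_unc)
}

#' Paired common-random-number Monte Carlo DRF
#'
#' Convenience wrapper: builds saline- and contrast-filled phantoms of the
#' same diameter, runs both with the same seed (common random numbers), and
#' returns the dose reduction factor at the requested distances from the
#' balloon surface.
#'
#' @param diameter_cm Balloon diameter in cm.
#' @param concentration_pct Contrast concentration in percent.
#' @param x_cm Distances from the balloon surface (default 1 cm, the
#'   prescription point).
#' @param half_extent_cm,voxel_cm Phantom geometry (see [build_phantom()]).
#' @param config [mc_config()] used for both runs.
#' @param settings [transport_settings()].
#' @return A tibble with columns `distance_cm`, `drf`, `rel_unc`.
#' @export
mc_drf <- function(diameter_cm, concentration_pct, x_cm = 1,
                   half_extent_cm = diameter_cm / 2 + 5, voxel_cm = 0.15,
                   config = mc_config(), settings = transport_settings()) {
  run_one <- function(filling) {
    bal <- balloon_geometry(diameter_cm, filling = filling)
    ph <- build_phantom(bal, half_extent_cm = half_extent_cm,
                        voxel_cm = voxel_cm)
    g <- run_mc(ph, source_model(position_mm = bal$source_offset_mm),
                settings = settings, config = config)
    radial_profile(g, bal, x_cm)
  }
  drf(run_one(contrast_mixture(concentration_pct)), run_one(saline()))
}

#' Statistical uncertainty of the mean dose in a region
#'
#' Batch standard error of the mean dose over a voxel mask, divided by the
#' mean (fractional uncertainty). Requires the run to have kept per-batch
#' doses (`keep_batch_dose = TRUE`).
#'
#' @param grid A [run_mc()] dose grid.
#' @param region Logical mask over the grid.
#' @return Fractional standard error; `NA` (with a warning) if the region
#'   received no dose.
#' @export
uncertainty_at <- function(grid, region) {
  stopifnot(inherits(grid, "dose_grid"), is.logical(region))
  if (grid$batches < 2) stop("need >= 2 batches", call. = FALSE)
  if (is.null(grid$batch_dose)) {
    stop("run with `keep_batch_dose = TRUE` to use uncertainty_at()",
         call. = FALSE)
  }
  m <- colMeans(grid$batch_dose[as.vector(region), , drop = FALSE])
  if (mean(m) <= 0) {
    warning("region received no dose; uncertainty undefined")
    return(NA_real_)
  }
  sd(m) / sqrt(length(m)) / mean(m)
}
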