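#' Balloon applicator geometry
#'
#' Describes the spherical balloon, its filling, an optional outward
#' deformation of one hemisphere, and the dwell-position offset of the source.
#' Coordinates are in cm with the origin at the nominal source position (the
#' balloon centre); the deformation axis is +z and the reference/prescription
#' axis is +x.
#'
#' @param diameter_cm Balloon diameter in cm (4, 5 and 6 are the clinical
#'   sizes).
#' @param filling Balloon filling [material()]; defaults to [saline()].
#' @param deformation_mm Outward deformation of the +z hemisphere in mm
#'   (0 to 5).
#' @param deformation_mode `"none"` or `"hemispherical_outward"`.
#' @param source_offset_mm 3-vector, dwell-position offset from the balloon
#'   centre in mm (|offset| <= 5 mm for the clinical scenarios).
#' @param taper_power Exponent p of the angular taper of the deformation,
#'   displacement = d * cos(theta)^p over the deformed hemisphere. The default
#'   p = 0 displaces the hemisphere rigidly; p > 0 tapers the displacement
#'   smoothly to zero at the equator.
#' @return An object of class `balloon_geometry`.
#' @export
balloon_geometry <- function(diameter_cm = 4, filling = saline(),
                             deformation_mm = 0,
                             deformation_mode = c("none",
                                                  "hemispherical_outward"),
                             source_offset_mm = c(0, 0, 0),
                             taper_power = 0) {
  deformation_mode <- match.arg(deformation_mode)
  stopifnot(is.numeric(diameter_cm), diameter_cm >= 0,
            inherits(filling, "brachy_material"),
            is.numeric(deformation_mm), deformation_mm >= 0,
            deformation_mm <= 5,
            length(source_offset_mm) == 3, taper_power >= 0)
  if (deformation_mm > 0 && deformation_mode == "none") {
    deformation_mode <- "hemispherical_outward"
  }
  structure(
    list(diameter_cm = diameter_cm, filling = filling,
         deformation_mm = deformation_mm, deformation_mode = deformation_mode,
         source_offset_mm = as.numeric(source_offset_mm),
         taper_power = taper_power),
    class = "balloon_geometry"
  )
}

#' @export
print.balloon_geometry <- function(x, ...) {
  cat("<balloon>", x$diameter_cm, "cm diameter, filling:", x$filling$name,
      "\n  deformation:", x$deformation_mm, "mm (", x$deformation_mode,
      "), source offset:", paste(x$source_offset_mm, collapse = ", "),
      "mm\n")
  invisible(x)
}

balloon_radius <- function(balloon) balloon$diameter_cm / 2

#' Deform the balloon outward
#'
#' Displaces the +z hemisphere of the balloon surface outward by `d_mm`
#' millimetres (the planning-time dwell position and prescription are kept
#' from the nominal spherical plan).
#'
#' @param balloon A [balloon_geometry()].
#' @param d_mm Deformation in mm (0 to 5).
#' @return The updated [balloon_geometry()].
#' @export
deform_balloon <- function(balloon, d_mm) {
  stopifnot(inherits(balloon, "balloon_geometry"), d_mm >= 0, d_mm <= 5)
  balloon$deformation_mm <- d_mm
  balloon$deformation_mode <-
    if (d_mm > 0) "hemispherical_outward" else "none"
  balloon
}

# balloon surface radius (cm) as a function of cos(theta) to the +z axis
surface_radius <- function(balloon, cos_theta) {
  r <- rep(balloon_radius(balloon), length(cos_theta))
  if (balloon$deformation_mode == "hemispherical_outward" &&
      balloon$deformation_mm > 0) {
    up <- cos_theta > 0
    w <- if (balloon$taper_power == 0) 1 else cos_theta[up]^balloon$taper_power
    r[up] <- r[up] + balloon$deformation_mm / 10 * w
  }
  r
}

#' Prescription point of the nominal plan
#'
#' @param balloon A [balloon_geometry()].
#' @return Position (cm) of the point 1 cm from the nominal balloon surface on
#'   the +x reference axis (perpendicular to the deformation axis).
#' @export
prescription_point <- function(balloon) {
  c(balloon_radius(balloon) + 1, 0, 0)
}

#' Voxelise a balloon-in-tissue phantom
#'
#' Builds the material-index grid used by the Monte Carlo: a sphere (possibly
#' deformed) of filling material centred in a cube of tissue. Voxel membership
#' is decided by the voxel centre position. The grid is centred on the nominal
#' balloon centre with an odd number of voxels per axis so one voxel centre
#' sits at the origin.
#'
#' @param balloon A [balloon_geometry()].
#' @param tissue Surrounding [material()]; default [water()].
#' @param half_extent_cm Half-width of the cubic phantom in cm; at least the
#'   balloon radius + 5 cm for full-scatter geometry.
#' @param voxel_cm Voxel edge length in cm (default 0.15, the scoring grid).
#' @return An object of class `voxel_phantom`: fields `material_index`
#'   (integer array, 1 = tissue, 2 = filling), `materials`, `voxel_cm`,
#'   `origin` (centre of voxel \[1,1,1\], cm).
#' @export
build_phantom <- function(balloon, tissue = water(), half_extent_cm = 8,
                          voxel_cm = 0.15) {
  stopifnot(inherits(balloon, "balloon_geometry"), voxel_cm > 0)
  rmax <- balloon_radius(balloon) + balloon$deformation_mm / 10
  if (rmax >= half_extent_cm) {
    stop("balloon larger than phantom", call. = FALSE)
  }
  if (half_extent_cm < balloon_radius(balloon) + 5) {
    warning("phantom margin below 5 cm: scatter is not fully developed")
  }
  n <- 2L * floor(half_extent_cm / voxel_cm) + 1L
  half <- (n - 1L) / 2L
  ax <- (seq_len(n) - 1L - half) * voxel_cm
  idx <- array(1L, dim = c(n, n, n))
  if (balloon$diameter_cm > 0) {
    r2 <- outer(outer(ax^2, ax^2, `+`), ax^2, `+`)
    r <- sqrt(r2)
    cz <- outer(array(0, dim = c(n, n)), ax, `+`) # z coordinate per voxel
    ct <- ifelse(r > 0, cz / pmax(r, .Machine$double.eps), 0)
    rs <- array(surface_radius(balloon, as.numeric(ct)), dim = dim(r))
    idx[r <= rs] <- 2L
  }
  structure(
    list(material_index = idx,
         materials = list(tissue, balloon$filling),
         voxel_cm = voxel_cm,
         origin = rep(-half * voxel_cm, 3)),
    class = "voxel_phantom"
  )
}

#' @export
print.voxel_phantom <- function(x, ...) {
  d <- dim(x$material_index)
  cat("<voxel phantom>", paste(d, collapse = " x "), "voxels of",
      x$voxel_cm, "cm;", length(x$materials), "materials\n")
  invisible(x)
}

# voxel-centre coordinates along one axis
phantom_axis <- function(phantom, which = 1) {
  n <- dim(phantom$material_index)[which]
  phantom$origin[which] + (seq_len(n) - 1L) * phantom$voxel_cm
}

# array of voxel-centre distances from the balloon centre (origin)
phantom_radii <- function(phantom) {
  ax <- phantom_axis(phantom)
  sqrt(outer(outer(ax^2, ax^2, `+`), ax^2, `+`))
}

#' Planning-target-volume mask
#'
#' The PTV is the shell of tissue extending 10 mm outward from the (possibly
#' deformed) balloon surface; the balloon itself is excluded.
#'
#' @param phantom A [build_phantom()] result.
#' @param balloon The [balloon_geometry()] the phantom was built from.
#' @return Logical array over the phantom grid.
#' @export
ptv_mask <- function(phantom, balloon) {
  stopifnot(inherits(phantom, "voxel_phantom"),
            inherits(balloon, "balloon_geometry"))
  r <- phantom_radii(phantom)
  ax <- phantom_axis(phantom)
  n <- dim(r)[1]
  cz <- outer(array(0, dim = c(n, n)), ax, `+`)
  ct <- ifelse(r > 0, cz / pmax(r, .Machine$double.eps), 0)
  rs <- array(surface_radius(balloon, as.numeric(ct)), dim = dim(r))
  r > rs & r <= rs + 1
}

#' Write or read a voxel phantom (plain-text header + raw binary grid)
#'
#' @param phantom A [build_phantom()] result.
#' @param path Base path; `<path>.header` (text) and `<path>.raw` (integer
#'   binary, column-major) are written.
#' @return `write_phantom()` returns `phantom` invisibly; `read_phantom()` the
#'   parsed phantom.
#' @export
write_phantom <- function(phantom, path) {
  stopifnot(inherits(phantom, "voxel_phantom"))
  hdr <- c(paste("dim:", paste(dim(phantom$material_index), collapse = " ")),
           paste("voxel_cm:", format(phantom$voxel_cm, digits = 15)),
           paste("origin:", paste(format(phantom$origin, digits = 15),
                                  collapse = " ")),
           paste("n_materials:", length(phantom$materials)))
  for (m in phantom$materials) {
    hdr <- c(hdr, paste("material:", m$name),
             paste("density:", format(m$density, digits = 15)),
             paste("composition:",
                   paste(names(m$mass_fractions),
                         format(m$mass_fractions, digits = 15),
                         collapse = " ")))
  }
  writeLines(hdr, paste0(path, ".header"))
  con <- file(paste0(path, ".raw"), "wb")
  on.exit(close(con))
  writeBin(as.integer(phantom$material_index), con, size = 4L)
  invisible(phantom)
}

#' @rdname write_phantom
#' @export
read_phantom <- function(path) {
  hdr <- readLines(paste0(path, ".header"))
  val <- function(key) sub(paste0("^", key, ": ?"), "",
                           grep(paste0("^", key, ":"), hdr, value = TRUE))
  dims <- as.integer(strsplit(val("dim"), " ")[[1]])
  voxel <- as.numeric(val("voxel_cm"))
  origin <- as.numeric(strsplit(val("origin"), " ")[[1]])
  mat_names <- val("material")
  densities <- as.numeric(val("density"))
  comps <- strsplit(val("composition"), "[[:space:]]+")
  materials <- lapply(seq_along(mat_names), function(i) {
    p <- comps[[i]]
    w <- as.numeric(p[seq(2, length(p), 2)])
    names(w) <- p[seq(1, length(p), 2)]
    material(mat_names[i], w, densities[i])
  })
  con <- file(paste0(path, ".raw"), "rb")
  on.exit(close(con))
  idx <- readBin(con, "integer", n = prod(dims), size = 4L)
  structure(
    list(material_index = array(idx, dim = dims), materials = materials,
         voxel_cm = voxel, origin = origin),
    class = "voxel_phantom"
  )
}
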