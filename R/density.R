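#' Fresh volume of a root or branch segment
#'
#' Mean of the two elliptic woody end areas multiplied by the sample
#' length; for branches with measured pith diameters the mean elliptic pith
#' area times the length is subtracted. Roots (and cores) are never
#' pith-corrected.
#'
#' @param geometry a [segment_geometry()] with both ends' crosswise
#'   diameters and the length present.
#' @return Fresh volume, cm^3.
#' @examples
#' g <- segment_geometry("b1", "branch", 0.05, 10, 10, 10, 10)
#' segment_volume(g)  # 3.927 cm^3
#' @export
segment_volume <- function(geometry) {
  stopifnot(inherits(geometry, "segment_geometry"))
  if (geometry$organ == "stem_core")
    stop("use core_volume() for stem cores")
  dd <- c(geometry$end1_d1, geometry$end1_d2,
          geometry$end2_d1, geometry$end2_d2)
  if (!all(is.finite(dd)))
    stop("both ends' crosswise diameters are required for sample ",
         geometry$sample_id)
  a1 <- .ellipse_area_mm2(geometry$end1_d1, geometry$end1_d2)
  a2 <- .ellipse_area_mm2(geometry$end2_d1, geometry$end2_d2)
  area <- (a1 + a2) / 2
  if (geometry$organ == "branch" &&
      all(is.finite(c(geometry$pith_d1, geometry$pith_d2)))) {
    area <- area - .ellipse_area_mm2(geometry$pith_d1, geometry$pith_d2)
  }
  length_mm <- geometry$length_m * 1000
  area * length_mm / 1000  # mm^3 -> cm^3
}

#' Fresh volume of an increment core
#'
#' Cylinder volume from the corer's inner diameter and the (remoistened)
#' core length.
#'
#' @param core_length_mm core length, mm.
#' @param corer_diameter_mm inner diameter of the corer, mm (default 5).
#' @return Volume, cm^3.
#' @examples
#' core_volume(40)  # 0.7854 cm^3
#' @export
core_volume <- function(core_length_mm, corer_diameter_mm = 5) {
  if (!is.numeric(core_length_mm) || any(!is.finite(core_length_mm)) ||
      any(core_length_mm <= 0))
    stop("'core_length_mm' must be positive")
  if (!is.numeric(corer_diameter_mm) || any(!is.finite(corer_diameter_mm)) ||
      any(corer_diameter_mm <= 0))
    stop("'corer_diameter_mm' must be positive")
  pi * (corer_diameter_mm / 2)^2 * core_length_mm / 1000
}

#' Wood density
#'
#' Dry mass per fresh volume. Values outside the 0.2-1.2 g cm^-3 band that
#' covers virtually all tree wood trigger a warning (a sign of a unit error
#' or a mismeasured volume), but are returned unchanged.
#'
#' @param dry_mass_g oven-dry mass, g.
#' @param volume_cm3 fresh volume, cm^3.
#' @return Wood density, g cm^-3. Vectorized.
#' @examples
#' wood_density(0.5, 1.0)  # 0.5 g cm^-3
#' @export
wood_density <- function(dry_mass_g, volume_cm3) {
  if (!is.numeric(volume_cm3) || any(!is.finite(volume_cm3)) ||
      any(volume_cm3 <= 0))
    stop("'volume_cm3' must be positive")
  if (!is.numeric(dry_mass_g) || any(!is.finite(dry_mass_g)) ||
      any(dry_mass_g < 0))
    stop("'dry_mass_g' must be non-negative")
  wd <- dry_mass_g / volume_cm3
  out_of_band <- wd > 0 & (wd < 0.2 | wd > 1.2)
  if (any(out_of_band))
    warning(sum(out_of_band), " wood density value(s) outside the ",
            "0.2-1.2 g cm^-3 sanity band")
  wd
}

#' Wood density for every sample of a geometry table
#'
#' Computes fresh volume ([segment_volume()] for segments,
#' [core_volume()] for `organ == "stem_core"` rows) and wood density from
#' the dry mass column.
#'
#' @param geometry_table data frame with the [segment_geometry()] fields as
#'   columns, including `dry_mass_g` (and `core_length_mm` for cores).
#' @return Data frame with `sample_id`, `organ`, `fresh_volume_cm3`,
#'   `dry_mass_g`, `WD_g_cm3`.
#' @export
derive_density <- function(geometry_table) {
  geoms <- .geometry_from_table(geometry_table)
  rows <- lapply(geoms, function(geom) {
    vol <- if (geom$organ == "stem_core") core_volume(geom$core_length_mm)
           else segment_volume(geom)
    wd <- if (is.finite(geom$dry_mass_g)) wood_density(geom$dry_mass_g, vol)
          else NA_real_
    data.frame(sample_id = geom$sample_id, organ = geom$organ,
               fresh_volume_cm3 = vol, dry_mass_g = geom$dry_mass_g,
               WD_g_cm3 = wd, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
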