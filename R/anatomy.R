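#' Circle-equivalent diameter of a lumen area
#'
#' Converts a measured conduit lumen area to the diameter of a circle of the
#' same area. Area is the only size information an image-analysis measurement
#' preserves, so circle equivalence is the canonical diameter definition for
#' downstream hydraulic weighting.
#'
#' @param lumen_area conduit lumen area(s), um^2. All values must be
#'   positive.
#' @return Diameter(s) in um, `2 * sqrt(area / pi)`.
#' @examples
#' equivalent_diameter(100 * pi)  # radius-10 circle -> 20 um
#' @export
equivalent_diameter <- function(lumen_area) {
  if (!is.numeric(lumen_area) || length(lumen_area) < 1L ||
      any(!is.finite(lumen_area)) || any(lumen_area <= 0))
    stop("'lumen_area' must contain positive finite values (um^2)")
  2 * sqrt(lumen_area / pi)
}

#' Hydraulically weighted conduit diameter
#'
#' Summarizes a set of conduit diameters with the weight each conduit carries
#' in Hagen-Poiseuille flow. Two conventions are in circulation and both are
#' implemented: the ratio of the fifth to the fourth raw moment
#' (`"d5_over_d4"`, \eqn{\sum d^5 / \sum d^4}), and the fourth-root of the
#' mean fourth power (`"fourth_moment"`, \eqn{(\sum d^4 / n)^{1/4}}). The
#' d5/d4 form is the default because it weights conduits exactly as they
#' contribute to potential conductivity; both reduce to \eqn{d} when all
#' conduits are equal, and both are never smaller than the arithmetic mean.
#'
#' @param diameters conduit diameters, um. Non-empty, all positive.
#' @param method weighting convention, see Details.
#' @return Hydraulically weighted diameter, um.
#' @examples
#' hydraulic_diameter(c(10, 20))                   # 19.412
#' hydraulic_diameter(c(10, 20), "fourth_moment")  # 17.075
#' @export
hydraulic_diameter <- function(diameters,
                               method = c("d5_over_d4", "fourth_moment")) {
  method <- match.arg(method)
  if (!is.numeric(diameters) || length(diameters) < 1L ||
      any(!is.finite(diameters)) || any(diameters <= 0))
    stop("'diameters' must be a non-empty vector of positive values (um)")
  if (method == "d5_over_d4") {
    sum(diameters^5) / sum(diameters^4)
  } else {
    (mean(diameters^4))^0.25
  }
}

#' Conduit density
#'
#' Number of conduits per square millimetre of xylem cross-section, computed
#' from the conduit count and the woody area of the measured sector.
#'
#' @param n conduit count (non-negative integer).
#' @param sector_area woody area of the sector, um^2.
#' @return Conduit density, n mm^-2.
#' @examples
#' conduit_density(57, 0.5e6)  # 114 conduits per mm^2
#' @export
conduit_density <- function(n, sector_area) {
  if (!is.numeric(n) || length(n) != 1L || !is.finite(n) || n < 0)
    stop("'n' must be a single non-negative count")
  if (!is.numeric(sector_area) || length(sector_area) != 1L ||
      !is.finite(sector_area) || sector_area <= 0)
    stop("'sector_area' must be a single positive number (um^2)")
  n / (sector_area * 1e-6)
}

#' Conduit lumen fraction
#'
#' Percentage of the sector's woody area occupied by conduit lumina.
#'
#' @param lumen_areas conduit lumen areas, um^2 (may be empty or zero-length
#'   for a conduit-free sector).
#' @param sector_area woody area of the sector, um^2.
#' @return Lumen fraction in percent, within \[0, 100\].
#' @examples
#' lumen_fraction(c(1.1e5, 1.1e5), 1e6)  # 22 %
#' @export
lumen_fraction <- function(lumen_areas, sector_area) {
  if (!is.numeric(sector_area) || length(sector_area) != 1L ||
      !is.finite(sector_area) || sector_area <= 0)
    stop("'sector_area' must be a single positive number (um^2)")
  if (length(lumen_areas) == 0L) return(0)
  if (!is.numeric(lumen_areas) || any(!is.finite(lumen_areas)) ||
      any(lumen_areas < 0))
    stop("'lumen_areas' must be non-negative finite values (um^2)")
  total <- sum(lumen_areas)
  if (total > sector_area)
    stop("total lumen area exceeds sector area: inconsistent measurement")
  100 * total / sector_area
}

#' Potential xylem-specific conductivity (Hagen-Poiseuille)
#'
#' Theoretical conductivity per xylem area assuming ideal capillaries:
#' \deqn{K_{S,pot} = \frac{\pi \rho \sum D^4}{128\, \eta\, A_{xylem}}}
#' with diameters and area converted to SI (m, m^2) internally, water
#' density \eqn{\rho} in kg m\eqn{^{-3}} and viscosity \eqn{\eta} in MPa s,
#' so the result is in kg m\eqn{^{-1}} MPa\eqn{^{-1}} s\eqn{^{-1}}.
#' The value is strictly additive over conduits at fixed reference area and
#' scales with the fourth power of a uniform diameter rescaling.
#'
#' @param diameters conduit diameters, um. Non-empty, all positive.
#' @param reference_area xylem reference area the conduits were counted in,
#'   um^2 (the sector's woody area when derived from anatomy).
#' @param constants a [water_constants()] object.
#' @return Potential conductivity, kg m^-1 MPa^-1 s^-1.
#' @examples
#' potential_conductivity(50, 1e6)  # one 50-um conduit in 1 mm^2 -> 0.1528
#' @export
potential_conductivity <- function(diameters, reference_area,
                                   constants = water_constants()) {
  if (!is.numeric(diameters) || length(diameters) < 1L ||
      any(!is.finite(diameters)) || any(diameters <= 0))
    stop("'diameters' must be a non-empty vector of positive values (um)")
  if (!is.numeric(reference_area) || length(reference_area) != 1L ||
      !is.finite(reference_area) || reference_area <= 0)
    stop("'reference_area' must be a single positive number (um^2)")
  stopifnot(inherits(constants, "water_constants"))
  d_m <- diameters * 1e-6
  a_m2 <- reference_area * 1e-12
  pi * constants$rho * sum(d_m^4) / (128 * constants$eta * a_m2)
}

#' Anatomical hydraulic traits of a sector
#'
#' Computes the full set of anatomy-derived traits for one radial sector:
#' conduit density (CD), lumen fraction (F), arithmetic mean conduit
#' diameter, hydraulically weighted diameter (D_h) and potential
#' xylem-specific conductivity (KS_pot). Diameters are obtained from lumen
#' areas by circle equivalence; KS_pot uses the sector's woody area as its
#' reference area.
#'
#' @param conduits a [conduit_set()].
#' @param constants a [water_constants()] object.
#' @param dh_method convention for [hydraulic_diameter()].
#' @return An object of class `anatomy_traits`: a list with elements
#'   `sample_id`, `organ`, `n`, `CD` (n mm^-2), `F` (%), `D_mean` (um),
#'   `D_h` (um) and `KS_pot` (kg m^-1 MPa^-1 s^-1).
#' @examples
#' cs <- conduit_set("s1", "root", 45, 5e5, lumen_areas = c(1200, 900, 1500))
#' anatomy_traits(cs)
#' @export
anatomy_traits <- function(conduits, constants = water_constants(),
                           dh_method = c("d5_over_d4", "fourth_moment")) {
  stopifnot(inherits(conduits, "conduit_set"))
  dh_method <- match.arg(dh_method)
  d <- equivalent_diameter(conduits$lumen_areas)
  structure(list(
    sample_id = conduits$sample_id,
    organ = conduits$organ,
    n = length(d),
    CD = conduit_density(length(d), conduits$sector_area),
    F = lumen_fraction(conduits$lumen_areas, conduits$sector_area),
    D_mean = mean(d),
    D_h = hydraulic_diameter(d, dh_method),
    KS_pot = potential_conductivity(d, conduits$sector_area, constants)
  ), class = "anatomy_traits")
}

#' @export
print.anatomy_traits <- function(x, ...) {
  cat("Anatomy traits: sample", x$sample_id, "(", x$organ, ",", x$n,
      "conduits )\n")
  cat(sprintf("  CD %.1f mm^-2 | F %.2f %% | D_mean %.1f um | D_h %.1f um | KS_pot %.3f\n",
              x$CD, x$F, x$D_mean, x$D_h, x$KS_pot))
  invisible(x)
}

#' Derive anatomical traits for every sample of a conduit table
#'
#' Table-level interface to [anatomy_traits()]. The input holds one row per
#' conduit with the sector geometry repeated within a sample; lumen sizes may
#' be given as `lumen_area_um2` or `lumen_diameter_um`.
#'
#' @param conduit_table data frame with columns `sample_id`, `organ`,
#'   `sector_angle_deg`, `sector_area_um2`, and one of `lumen_area_um2` or
#'   `lumen_diameter_um`.
#' @param constants a [water_constants()] object.
#' @param dh_method convention for [hydraulic_diameter()].
#' @return Data frame with one row per sample and columns `sample_id`,
#'   `organ`, `n_conduits`, `CD_mm2`, `F_pct`, `D_mean_um`, `Dh_um`,
#'   `KSpot_kg_m_MPa_s`.
#' @export
derive_anatomy <- function(conduit_table, constants = water_constants(),
                           dh_method = c("d5_over_d4", "fourth_moment")) {
  dh_method <- match.arg(dh_method)
  need <- c("sample_id", "organ", "sector_angle_deg", "sector_area_um2")
  missing_cols <- setdiff(need, names(conduit_table))
  if (length(missing_cols))
    stop("conduit table lacks column(s): ", paste(missing_cols, collapse = ", "))
  has_area <- "lumen_area_um2" %in% names(conduit_table)
  has_diam <- "lumen_diameter_um" %in% names(conduit_table)
  if (!has_area && !has_diam)
    stop("conduit table needs 'lumen_area_um2' or 'lumen_diameter_um'")

  rows <- lapply(split(conduit_table, conduit_table$sample_id), function(g) {
    cs <- conduit_set(
      sample_id = g$sample_id[1L], organ = g$organ[1L],
      sector_angle = g$sector_angle_deg[1L],
      sector_area = g$sector_area_um2[1L],
      lumen_areas = if (has_area) g$lumen_area_um2 else NULL,
      lumen_diameters = if (!has_area) g$lumen_diameter_um else NULL)
    tr <- anatomy_traits(cs, constants, dh_method)
    data.frame(sample_id = tr$sample_id, organ = tr$organ,
               n_conduits = tr$n, CD_mm2 = tr$CD, F_pct = tr$F,
               D_mean_um = tr$D_mean, Dh_um = tr$D_h,
               KSpot_kg_m_MPa_s = tr$KS_pot, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
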