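#' Conduit lumen measurements within one radial sector
#'
#' Container for the conduit-level measurements taken in a randomly placed
#' radial sector ("wedge") of a cross-section: the sector geometry and the
#' lumen area of every conduit whose centroid falls inside the sector.
#' Lumen sizes may be supplied either as areas (the native output of image
#' analysis) or as circle-equivalent diameters; which one was supplied is
#' recorded in the object.
#'
#' @param sample_id identifier of the sample the sector belongs to.
#' @param organ `"root"` or `"branch"`.
#' @param sector_angle opening angle of the sector, degrees. Field practice
#'   uses 20-70 degrees; values outside that band are accepted with a
#'   warning.
#' @param sector_area total woody area of the sector, um^2.
#' @param lumen_areas numeric vector of conduit lumen areas, um^2. Exactly
#'   one of `lumen_areas` and `lumen_diameters` must be given.
#' @param lumen_diameters numeric vector of conduit lumen diameters, um.
#'
#' @return An object of class `conduit_set`: a list with elements
#'   `sample_id`, `organ`, `sector_angle`, `sector_area`, `lumen_areas`
#'   and `supplied` (`"areas"` or `"diameters"`).
#' @examples
#' cs <- conduit_set("s1", "root", sector_angle = 45,
#'                   sector_area = 5e5, lumen_areas = c(1200, 900, 1500))
#' cs
#' @seealso [anatomy_traits()] to derive hydraulic traits from the set.
#' @export
conduit_set <- function(sample_id, organ = c("root", "branch"),
                        sector_angle, sector_area,
                        lumen_areas = NULL, lumen_diameters = NULL) {
  organ <- match.arg(organ)
  if (!is.numeric(sector_area) || length(sector_area) != 1L ||
      !is.finite(sector_area) || sector_area <= 0)
    stop("'sector_area' must be a single positive number (um^2)")
  if (!is.numeric(sector_angle) || length(sector_angle) != 1L ||
      !is.finite(sector_angle) || sector_angle <= 0 || sector_angle >= 360)
    stop("'sector_angle' must be a single angle in (0, 360) degrees")
  if (sector_angle < 20 || sector_angle > 70)
    warning("sector angle ", format(sector_angle),
            " degrees is outside the usual 20-70 degree band")

  if (is.null(lumen_areas) == is.null(lumen_diameters))
    stop("supply exactly one of 'lumen_areas' or 'lumen_diameters'")
  if (is.null(lumen_areas)) {
    if (!is.numeric(lumen_diameters) || length(lumen_diameters) < 1L ||
        any(!is.finite(lumen_diameters)) || any(lumen_diameters <= 0))
      stop("'lumen_diameters' must be a non-empty vector of positive values (um)")
    lumen_areas <- pi * lumen_diameters^2 / 4
    supplied <- "diameters"
  } else {
    if (!is.numeric(lumen_areas) || length(lumen_areas) < 1L ||
        any(!is.finite(lumen_areas)) || any(lumen_areas <= 0))
      stop("'lumen_areas' must be a non-empty vector of positive values (um^2)")
    supplied <- "areas"
  }
  if (sum(lumen_areas) > sector_area)
    stop("total lumen area (", format(sum(lumen_areas)),
         " um^2) exceeds the sector area (", format(sector_area),
         " um^2): inconsistent measurement")

  structure(list(sample_id = sample_id, organ = organ,
                 sector_angle = sector_angle, sector_area = sector_area,
                 lumen_areas = as.numeric(lumen_areas), supplied = supplied),
            class = "conduit_set")
}

#' @export
print.conduit_set <- function(x, ...) {
  cat("Conduit set: sample", x$sample_id, "(", x$organ, ")\n")
  cat("  sector:", format(x$sector_angle), "deg,",
      format(x$sector_area), "um^2\n")
  cat("  conduits:", length(x$lumen_areas), "(supplied as", x$supplied, ")\n")
  cat("  lumen fraction:",
      format(round(100 * sum(x$lumen_areas) / x$sector_area, 2)), "%\n")
  invisible(x)
}

#' @export
length.conduit_set <- function(x) length(x$lumen_areas)
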