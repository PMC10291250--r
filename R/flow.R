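#' Segment geometry for conductivity and density measurements
#'
#' Describes a debarked root or branch segment (or an increment core) as
#' used for gravimetric conductivity and wood-density measurements: sample
#' length, two crosswise outer xylem diameters at each end, pith diameters
#' (branches, optional) and dry mass. End 1 is the basal end, end 2 the
#' distal end; conductivity measurements attach the basal end of branches
#' and the distal end of roots to the tubing, so the xylem reference area is
#' taken at that end.
#'
#' @param sample_id identifier.
#' @param organ `"root"`, `"branch"` or `"stem_core"`.
#' @param length_m sample length, m (typically 0.05 for branches and 0.10
#'   for roots; core length is given via `core_length_mm` instead).
#' @param end1_d1,end1_d2 crosswise xylem diameters at the basal end, mm.
#' @param end2_d1,end2_d2 crosswise xylem diameters at the distal end, mm.
#' @param pith_d1,pith_d2 crosswise pith diameters, mm (branches only; `NA`
#'   when the pith was not measured).
#' @param dry_mass_g oven-dry mass, g (optional, used for wood density).
#' @param core_length_mm length of an increment core, mm (stem cores only).
#'
#' @return An object of class `segment_geometry`.
#' @export
segment_geometry <- function(sample_id, organ = c("root", "branch", "stem_core"),
                             length_m = NA_real_,
                             end1_d1 = NA_real_, end1_d2 = NA_real_,
                             end2_d1 = NA_real_, end2_d2 = NA_real_,
                             pith_d1 = NA_real_, pith_d2 = NA_real_,
                             dry_mass_g = NA_real_, core_length_mm = NA_real_) {
  organ <- match.arg(organ)
  if (organ == "stem_core") {
    if (!is.finite(core_length_mm) || core_length_mm <= 0)
      stop("stem cores need a positive 'core_length_mm'")
  } else {
    if (!is.finite(length_m) || length_m <= 0)
      stop("'length_m' must be positive")
    dd <- c(end1_d1, end1_d2, end2_d1, end2_d2)
    if (any(is.finite(dd) & dd <= 0))
      stop("xylem diameters must be positive where present")
    pp <- c(pith_d1, pith_d2)
    if (any(is.finite(pp) & pp <= 0))
      stop("pith diameters must be positive where present")
    if (all(is.finite(c(pith_d1, end1_d1))) && pith_d1 >= end1_d1 ||
        all(is.finite(c(pith_d2, end1_d2))) && pith_d2 >= end1_d2)
      stop("pith diameters must be smaller than the xylem diameters")
  }
  structure(list(sample_id = sample_id, organ = organ, length_m = length_m,
                 end1_d1 = end1_d1, end1_d2 = end1_d2,
                 end2_d1 = end2_d1, end2_d2 = end2_d2,
                 pith_d1 = pith_d1, pith_d2 = pith_d2,
                 dry_mass_g = dry_mass_g, core_length_mm = core_length_mm),
            class = "segment_geometry")
}

#' @export
print.segment_geometry <- function(x, ...) {
  cat("Segment geometry: sample", x$sample_id, "(", x$organ, ")\n")
  if (x$organ == "stem_core") {
    cat("  core length:", format(x$core_length_mm), "mm\n")
  } else {
    cat("  length:", format(x$length_m), "m; basal",
        format(x$end1_d1), "x", format(x$end1_d2), "mm; distal",
        format(x$end2_d1), "x", format(x$end2_d2), "mm\n")
  }
  invisible(x)
}

# elliptic area from two crosswise diameters (mm) -> mm^2
.ellipse_area_mm2 <- function(d1, d2) pi * d1 * d2 / 4

#' Axial hydraulic conductivity from a flow record
#'
#' Converts a gravimetric flow measurement to axial conductivity
#' \eqn{K_h = F \cdot l / \Delta p} with the mass flow rate \eqn{F}
#' converted from g h\eqn{^{-1}} to kg s\eqn{^{-1}} and the hydrostatic
#' pressure head from kPa to MPa.
#'
#' @param flow_g_per_h mass flow rate, g h^-1 (the native unit of the
#'   flow meter).
#' @param pressure_kPa hydrostatic pressure head, kPa.
#' @param length_m sample length, m.
#' @return Axial conductivity, kg m MPa^-1 s^-1. Vectorized over the flow.
#' @examples
#' axial_conductivity(1, 2, 0.05)  # 6.944e-6
#' @export
axial_conductivity <- function(flow_g_per_h, pressure_kPa, length_m) {
  if (!is.numeric(pressure_kPa) || any(!is.finite(pressure_kPa)) ||
      any(pressure_kPa <= 0))
    stop("'pressure_kPa' must be positive")
  if (!is.numeric(length_m) || any(!is.finite(length_m)) || any(length_m <= 0))
    stop("'length_m' must be positive")
  if (!is.numeric(flow_g_per_h) || any(!is.finite(flow_g_per_h)) ||
      any(flow_g_per_h < 0))
    stop("'flow_g_per_h' must be non-negative")
  (flow_g_per_h * 1e-3 / 3600) * length_m / (pressure_kPa * 1e-3)
}

#' Xylem cross-sectional area of a segment
#'
#' Elliptic area from the two crosswise diameters at the measurement end:
#' the basal end for branches, the distal end for roots (the end attached to
#' the tubing). For branches the elliptic pith area is subtracted when pith
#' diameters are present.
#'
#' @param geometry a [segment_geometry()].
#' @param end `"auto"` picks the organ convention; `"basal"` or `"distal"`
#'   override it.
#' @return Xylem area, m^2.
#' @examples
#' g <- segment_geometry("r1", "root", 0.1, 4, 4, 4, 4)
#' xylem_area(g)  # 1.2566e-5 m^2
#' @export
xylem_area <- function(geometry, end = c("auto", "basal", "distal")) {
  stopifnot(inherits(geometry, "segment_geometry"))
  end <- match.arg(end)
  if (geometry$organ == "stem_core")
    stop("xylem_area() is defined for root and branch segments, not cores")
  if (end == "auto")
    end <- if (geometry$organ == "branch") "basal" else "distal"
  d1 <- if (end == "basal") geometry$end1_d1 else geometry$end2_d1
  d2 <- if (end == "basal") geometry$end1_d2 else geometry$end2_d2
  if (!all(is.finite(c(d1, d2))))
    stop("missing crosswise diameters at the ", end, " end of sample ",
         geometry$sample_id)
  area <- .ellipse_area_mm2(d1, d2)
  if (geometry$organ == "branch" &&
      all(is.finite(c(geometry$pith_d1, geometry$pith_d2)))) {
    pith <- .ellipse_area_mm2(geometry$pith_d1, geometry$pith_d2)
    if (pith >= area)
      stop("pith area is not smaller than the xylem area for sample ",
           geometry$sample_id)
    area <- area - pith
  }
  area * 1e-6  # mm^2 -> m^2
}

#' Select the maximum (post-flushing) conductivity
#'
#' Finds the stable plateau value among conductivities measured after
#' successive flushes. The plateau is the first flush whose relative
#' increase over the previous flush is below `stability_tol`; if the series
#' never stabilizes, the maximum across flushes is returned with a warning.
#' A single flush is its own plateau.
#'
#' @param kh_flush axial conductivities of the flush stages, in stage order.
#' @param stability_tol relative increase between successive flushes below
#'   which the series counts as stable (default 2\%).
#' @return A list with `kh_max` (the plateau conductivity), `stage_index`
#'   (which flush was selected) and `stable` (logical).
#' @examples
#' select_kmax(c(4.0, 4.8, 4.85))$kh_max  # 4.85
#' @export
select_kmax <- function(kh_flush, stability_tol = 0.02) {
  if (length(kh_flush) < 1L)
    stop("at least one flush-stage conductivity is required")
  if (any(!is.finite(kh_flush)) || any(kh_flush < 0))
    stop("flush conductivities must be non-negative")
  if (length(kh_flush) == 1L)
    return(list(kh_max = kh_flush[1L], stage_index = 1L, stable = TRUE))
  rel <- diff(kh_flush) / head(kh_flush, -1L)
  stable_at <- which(rel < stability_tol)
  if (length(stable_at)) {
    i <- stable_at[1L] + 1L
    list(kh_max = kh_flush[i], stage_index = i, stable = TRUE)
  } else {
    warning("conductivity never stabilized across flushes; using the maximum")
    i <- which.max(kh_flush)
    list(kh_max = kh_flush[i], stage_index = i, stable = FALSE)
  }
}

#' Xylem-specific conductivity
#'
#' @param kh axial conductivity, kg m MPa^-1 s^-1.
#' @param a_xylem xylem area, m^2.
#' @return K_h / A_xylem, kg m^-1 MPa^-1 s^-1.
#' @export
specific_conductivity <- function(kh, a_xylem) {
  if (!is.numeric(a_xylem) || any(!is.finite(a_xylem)) || any(a_xylem <= 0))
    stop("'a_xylem' must be positive")
  if (!is.numeric(kh) || any(!is.finite(kh)) || any(kh < 0))
    stop("'kh' must be non-negative")
  kh / a_xylem
}

#' Leaf-specific conductivity
#'
#' Maximum axial conductivity (after flushing) per one-sided distal leaf
#' area of the branch. The SI value is returned; `scale` is a pure reporting
#' multiplier for compatibility with other unit conventions and defaults to
#' 1.
#'
#' @param kh_max maximum axial conductivity, kg m MPa^-1 s^-1.
#' @param leaf_area one-sided distal leaf area, m^2.
#' @param scale reporting scale factor applied to the SI value.
#' @return Leaf-specific conductivity, kg m^-1 MPa^-1 s^-1 (times `scale`).
#' @export
leaf_specific_conductivity <- function(kh_max, leaf_area, scale = 1) {
  if (!is.numeric(leaf_area) || any(!is.finite(leaf_area)) ||
      any(leaf_area <= 0))
    stop("'leaf_area' must be positive")
  if (!is.numeric(kh_max) || any(!is.finite(kh_max)) || any(kh_max < 0))
    stop("'kh_max' must be non-negative")
  scale * kh_max / leaf_area
}

#' Huber value
#'
#' Sapwood-to-leaf-area ratio: the xylem cross-sectional area divided by
#' the one-sided distal leaf area. Typical branch values are of order
#' 10^-4 to 10^-3 m^2 m^-2.
#'
#' @param a_xylem xylem area, m^2.
#' @param leaf_area one-sided distal leaf area, m^2.
#' @return Huber value, m^2 m^-2.
#' @export
huber_value <- function(a_xylem, leaf_area) {
  if (!is.numeric(leaf_area) || any(!is.finite(leaf_area)) ||
      any(leaf_area <= 0))
    stop("'leaf_area' must be positive")
  if (!is.numeric(a_xylem) || any(!is.finite(a_xylem)) || any(a_xylem < 0))
    stop("'a_xylem' must be non-negative")
  a_xylem / leaf_area
}

#' Hydraulic traits of one sample from its flow records
#'
#' Processes the flow records of a single segment into its empirical
#' hydraulic traits: per-stage axial conductivities, the post-flushing
#' maximum (plateau) conductivity, xylem-specific conductivity, and - for
#' branches with a leaf area - leaf-specific conductivity and Huber value.
#' The pre-flush (initial) conductivity is retained as a native-state
#' diagnostic and never enters KS_hydr.
#'
#' @param records data frame of the sample's flow records with columns
#'   `stage` (`"initial"`, `"flush_1"`, `"flush_2"`, ...), `pressure_kPa`
#'   and `flow_g_per_h`. Record order in the table is irrelevant; only the
#'   stage labels order the flushes.
#' @param geometry the sample's [segment_geometry()].
#' @param leaf_area one-sided distal leaf area, m^2 (branches; `NA` to skip
#'   the leaf-referenced traits).
#' @param stability_tol passed to [select_kmax()].
#' @param kl_scale reporting scale for [leaf_specific_conductivity()].
#' @return An object of class `hydraulic_traits`: a list with `sample_id`,
#'   `organ`, `Kh_max`, `Kh_init` (NA when no initial stage was recorded),
#'   `A_xylem`, `KS_hydr`, `K_L`, `HV` and `kmax_stable`.
#' @export
hydraulic_traits <- function(records, geometry, leaf_area = NA_real_,
                             stability_tol = 0.02, kl_scale = 1) {
  stopifnot(inherits(geometry, "segment_geometry"))
  need <- c("stage", "pressure_kPa", "flow_g_per_h")
  if (!all(need %in% names(records)))
    stop("flow records need columns: ", paste(need, collapse = ", "))
  stage <- as.character(records$stage)
  kh <- axial_conductivity(records$flow_g_per_h, records$pressure_kPa,
                           geometry$length_m)

  is_flush <- grepl("^flush_[0-9]+$", stage)
  kh_init <- if (any(stage == "initial")) kh[stage == "initial"][1L] else NA_real_
  if (!any(is_flush)) {
    if (is.na(kh_init))
      stop("no flush-stage and no initial record for sample ",
           geometry$sample_id)
    warning("no flush records for sample ", geometry$sample_id,
            "; falling back to the initial conductivity")
    sel <- list(kh_max = kh_init, stage_index = NA_integer_, stable = FALSE)
  } else {
    ord <- order(as.integer(sub("^flush_", "", stage[is_flush])))
    sel <- select_kmax(kh[is_flush][ord], stability_tol)
  }

  a_xylem <- xylem_area(geometry)
  ks_hydr <- specific_conductivity(sel$kh_max, a_xylem)
  kl <- hv <- NA_real_
  if (geometry$organ == "branch" && is.finite(leaf_area)) {
    kl <- leaf_specific_conductivity(sel$kh_max, leaf_area, kl_scale)
    hv <- huber_value(a_xylem, leaf_area)
  }
  structure(list(sample_id = geometry$sample_id, organ = geometry$organ,
                 Kh_max = sel$kh_max, Kh_init = kh_init, A_xylem = a_xylem,
                 KS_hydr = ks_hydr, K_L = kl, HV = hv,
                 kmax_stable = sel$stable),
            class = "hydraulic_traits")
}

#' @export
print.hydraulic_traits <- function(x, ...) {
  cat("Hydraulic traits: sample", x$sample_id, "(", x$organ, ")\n")
  cat(sprintf("  Kh_max %.4g | A_xylem %.4g m^2 | KS_hydr %.4g\n",
              x$Kh_max, x$A_xylem, x$KS_hydr))
  if (is.finite(x$K_L))
    cat(sprintf("  K_L %.4g | HV %.4g m^2 m^-2\n", x$K_L, x$HV))
  invisible(x)
}

#' Derive hydraulic traits for every sample of a flow table
#'
#' Table-level interface to [hydraulic_traits()]: joins the flow records
#' with segment geometry (and optionally leaf areas) by `sample_id`.
#'
#' @param flow_table data frame with columns `sample_id`, `stage`,
#'   `pressure_kPa`, `flow_g_per_h`.
#' @param geometry_table data frame with the [segment_geometry()] fields as
#'   columns (`sample_id`, `organ`, `length_m`, `end1_d1` ... `pith_d2`,
#'   `dry_mass_g`).
#' @param leaf_table optional data frame with `sample_id`, `leaf_area_m2`.
#' @param stability_tol,kl_scale passed through.
#' @return Data frame with one row per sample: `sample_id`, `organ`,
#'   `Kh_max`, `Kh_init`, `A_xylem_m2`, `KShydr`, `KL`, `HV`,
#'   `kmax_stable`.
#' @export
derive_hydraulics <- function(flow_table, geometry_table, leaf_table = NULL,
                              stability_tol = 0.02, kl_scale = 1) {
  geoms <- .geometry_from_table(geometry_table)
  leaf <- if (!is.null(leaf_table))
    stats::setNames(leaf_table$leaf_area_m2, leaf_table$sample_id)
  rows <- lapply(split(flow_table, flow_table$sample_id), function(g) {
    sid <- as.character(g$sample_id[1L])
    geom <- geoms[[sid]]
    if (is.null(geom))
      stop("no segment geometry for sample ", sid)
    la <- if (!is.null(leaf) && sid %in% names(leaf)) leaf[[sid]] else NA_real_
    tr <- hydraulic_traits(g, geom, la, stability_tol, kl_scale)
    data.frame(sample_id = sid, organ = tr$organ, Kh_max = tr$Kh_max,
               Kh_init = tr$Kh_init, A_xylem_m2 = tr$A_xylem,
               KShydr = tr$KS_hydr, KL = tr$K_L, HV = tr$HV,
               kmax_stable = tr$kmax_stable, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# build a named list of segment_geometry objects from a table
.geometry_from_table <- function(geometry_table) {
  col <- function(g, nm) if (nm %in% names(g)) g[[nm]] else NA_real_
  out <- lapply(seq_len(nrow(geometry_table)), function(i) {
    g <- geometry_table[i, , drop = FALSE]
    segment_geometry(as.character(g$sample_id), as.character(g$organ),
                     length_m = col(g, "length_m"),
                     end1_d1 = col(g, "end1_d1"), end1_d2 = col(g, "end1_d2"),
                     end2_d1 = col(g, "end2_d1"), end2_d2 = col(g, "end2_d2"),
                     pith_d1 = col(g, "pith_d1"), pith_d2 = col(g, "pith_d2"),
                     dry_mass_g = col(g, "dry_mass_g"),
                     core_length_mm = col(g, "core_length_mm"))
  })
  stats::setNames(out, as.character(geometry_table$sample_id))
}
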