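#' Species-level calibration table of the synthetic study
#'
#' Default parameters of the 14-species synthetic community: five
#' drought-deciduous and eight evergreen angiosperm tree species plus one
#' gymnosperm, six trees each. Per species and organ the table holds the
#' hydraulically weighted conduit diameter (`Dh_*`, um), conduit density
#' (`CD_*`, n mm^-2) and the log-scale variance of the within-sector
#' lognormal diameter distribution (`sigma2_*`); the lumen fraction and the
#' Hagen-Poiseuille potential conductivity follow from these three, so they
#' are not free parameters. Wood densities (g cm^-3), tree heights (m) and
#' segment outer diameters (mm) complete the table. The values are
#' calibrated so that the deciduous/evergreen and root/branch group means
#' of D_h, CD, F, KS_pot and wood density reproduce the magnitudes observed
#' in seasonally dry subtropical highland forest trees.
#'
#' @return Data frame with one row per species.
#' @export
species_calibration <- function() {
  tab <- read.csv(text = "species,leaf_habit,Dh_root,CD_root,sigma2_root,Dh_branch,CD_branch,sigma2_branch,WD_root,WD_stem,WD_branch,height_m,height_sd_m
Albizia schimperiana,deciduous,101,31.1,0.0079,60.9,82.3,0.0373,0.60,0.49,0.62,10,2.5
Bridelia micrantha,deciduous,51.4,108,0.0080,60.5,82.4,0.0360,0.57,0.58,0.64,8,0.9
Combretum molle,deciduous,27.9,121,0.0256,25.3,178,0.0273,0.48,0.62,0.67,6,1.1
Croton macrostachyus,deciduous,122,33.6,0.0080,60.5,82.6,0.0362,0.39,0.47,0.50,11,4.5
Schefflera abyssinica,deciduous,47.5,107,0.0080,25.2,198,0.0423,0.38,0.44,0.74,16,3.6
Apodytes dimidiata,evergreen,104,52.2,0.0274,37.3,151,0.0080,0.53,0.57,0.63,16,3.1
Calpurnia aurea,evergreen,38.7,176,0.128,25.2,208,0.0489,0.67,0.75,0.61,8,1.7
Chionanthus mildbraedii,evergreen,30.8,132,0.0660,25.2,208,0.0488,0.77,0.82,0.78,12,6.5
Dovyalis abyssinica,evergreen,44.6,164,0.130,25.3,171,0.0211,0.53,0.71,0.64,7,0.7
Ekebergia capensis,evergreen,51.6,236,0.0413,60.5,82.4,0.0358,0.50,0.54,0.71,12,2.5
Maesa lanceolata,evergreen,81.6,74.9,0.0080,60.6,82.3,0.0345,0.48,0.56,0.50,6,1.8
Prunus africana,evergreen,51.7,134,0.130,25.2,208,0.0400,0.56,0.68,0.63,10,4.1
Teclea nobilis,evergreen,60.1,141,0.0501,26.0,209,0.0079,0.52,NA,0.75,7,0.9
Afrocarpus falcatus,gymnosperm,36,947,0.14,11.1,2782,0.004,0.42,0.46,0.48,13,2.9
", stringsAsFactors = FALSE)
  tab$root_d_mm <- ifelse(tab$leaf_habit == "deciduous", 3.82,
                          ifelse(tab$leaf_habit == "evergreen", 4.10, 4.0))
  tab$branch_d_mm <- 4.9
  tab
}

# expected lumen fraction (%) implied by (Dh, CD, sigma2) under the
# lognormal sector model: E[d^2] = (Dh * exp(-3.5 sigma2))^2
.expected_F <- function(Dh, CD, sigma2) {
  CD * (pi / 4) * (Dh * exp(-3.5 * sigma2))^2 * 1e-4
}

#' Configuration of the synthetic study generator
#'
#' Bundles the species calibration with the design constants and noise
#' levels of the emulated study: six trees per species, two root and three
#' branch segments per tree, sectors of 20-70 degrees holding on average
#' 57 +/- 27 conduits, a measured-to-potential conductivity ratio of 0.25,
#' flushing profiles that rise to a stable plateau, native-state plugging
#' between 0.3 and 1.0, and leaf areas set by habit-level Huber value
#' targets. All defaults are study-level constants; see the methods
#' vignette for their provenance and for which are calibrated vs. assumed.
#'
#' @param calibration species table, see [species_calibration()].
#' @param n_trees,n_root_samples,n_branch_samples design sizes.
#' @param ks_ratio target ratio of measured to potential specific
#'   conductivity.
#' @param flow_noise_sd log-scale SD of the mean-one multiplicative noise
#'   on the plateau conductivity.
#' @param plugging_range range of the native-state (pre-flush) conductivity
#'   as a fraction of the plateau.
#' @param conduits_per_sector mean and SD of the target conduit count per
#'   sector.
#' @param sector_angle_range sector opening angle range, degrees.
#' @param tree_dh_sd,tree_cd_sd log-scale SDs of the between-tree effects
#'   on conduit diameter scale and conduit density.
#' @param segment_d_sd between-sample SD of segment outer diameter, mm.
#' @param branch_pith_mm mean branch pith diameter, mm.
#' @param wd_tree_sd,wd_sample_sd between-tree and within-tree SDs of wood
#'   density, g cm^-3.
#' @param wd_f_slope within-species coupling of sample wood density to the
#'   sample's lumen-fraction deviation, g cm^-3 per percentage point
#'   (named: `root`, `branch`).
#' @param hv_target habit-level Huber value targets, m^2 m^-2.
#' @param leaf_area_sd log-scale SD of the mean-one leaf-area noise.
#' @param core_length_range stem core length range, mm.
#' @param discard_root_flow_species species whose root flow measurements
#'   are discarded (emulating an unusable measurement series), creating the
#'   missing-cell case the inference layer must handle.
#' @return An object of class `study_config` (a list).
#' @export
study_config <- function(calibration = species_calibration(),
                         n_trees = 6L, n_root_samples = 2L,
                         n_branch_samples = 3L,
                         ks_ratio = 0.25, flow_noise_sd = 0.15,
                         plugging_range = c(0.3, 1.0),
                         conduits_per_sector = c(mean = 57, sd = 27),
                         sector_angle_range = c(20, 70),
                         tree_dh_sd = 0.06, tree_cd_sd = 0.10,
                         segment_d_sd = 0.4, branch_pith_mm = 1.0,
                         wd_tree_sd = 0.03, wd_sample_sd = 0.04,
                         wd_f_slope = c(root = -0.005, branch = -0.002),
                         hv_target = c(deciduous = 26.4e-4,
                                       evergreen = 13.9e-4,
                                       gymnosperm = 0.696e-4),
                         leaf_area_sd = 0.2,
                         core_length_range = c(30, 60),
                         discard_root_flow_species = "Albizia schimperiana") {
  stopifnot(is.data.frame(calibration), nrow(calibration) >= 1L,
            ks_ratio > 0, ks_ratio < 1,
            flow_noise_sd >= 0, all(plugging_range > 0),
            diff(sector_angle_range) >= 0)
  fr <- .expected_F(calibration$Dh_root, calibration$CD_root,
                    calibration$sigma2_root)
  fb <- .expected_F(calibration$Dh_branch, calibration$CD_branch,
                    calibration$sigma2_branch)
  if (any(c(fr, fb) >= 100))
    stop("infeasible calibration: implied lumen fraction reaches 100%")
  structure(list(
    calibration = calibration, n_trees = as.integer(n_trees),
    n_root_samples = as.integer(n_root_samples),
    n_branch_samples = as.integer(n_branch_samples),
    ks_ratio = ks_ratio, flow_noise_sd = flow_noise_sd,
    plugging_range = plugging_range,
    conduits_per_sector = conduits_per_sector,
    sector_angle_range = sector_angle_range,
    tree_dh_sd = tree_dh_sd, tree_cd_sd = tree_cd_sd,
    segment_d_sd = segment_d_sd, branch_pith_mm = branch_pith_mm,
    wd_tree_sd = wd_tree_sd, wd_sample_sd = wd_sample_sd,
    wd_f_slope = wd_f_slope, hv_target = hv_target,
    leaf_area_sd = leaf_area_sd, core_length_range = core_length_range,
    discard_root_flow_species = discard_root_flow_species
  ), class = "study_config")
}

#' @export
print.study_config <- function(x, ...) {
  cat("Synthetic study configuration:\n")
  cat("  species:", nrow(x$calibration), "| trees/species:", x$n_trees,
      "| samples/tree:", x$n_root_samples, "root +", x$n_branch_samples,
      "branch\n")
  cat("  KS_hydr/KS_pot ratio:", x$ks_ratio,
      "| flow noise SD:", x$flow_noise_sd, "\n")
  invisible(x)
}

# mean-one lognormal multiplier
.lognoise <- function(n, sdlog) {
  if (sdlog == 0) return(rep(1, n))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Generate the conduit measurements of one sector
#'
#' Draws a radial sector for one sample: the opening angle is uniform over
#' the configured range, the target conduit count is normal (57 +/- 27 by
#' default, floored at 15), the sector area follows as count/density, the
#' realized count is Poisson, and conduit diameters are lognormal with the
#' species' and organ's calibrated median and log-variance. Lumen areas are
#' the circle areas of the drawn diameters; draws whose total lumen area
#' would exceed the sector area are rejected and redrawn.
#'
#' @param config a [study_config()].
#' @param species species name (must match the calibration table).
#' @param organ `"root"` or `"branch"`.
#' @param sample_id identifier for the emitted [conduit_set()].
#' @param seed optional integer; when given, the RNG is seeded first.
#' @param dh_factor,cd_factor multiplicative tree-level effects on the
#'   diameter scale and the conduit density.
#' @return A [conduit_set()].
#' @export
generate_conduits <- function(config, species, organ = c("root", "branch"),
                              sample_id = paste0(species, "_", organ),
                              seed = NULL, dh_factor = 1, cd_factor = 1) {
  stopifnot(inherits(config, "study_config"))
  organ <- match.arg(organ)
  if (!is.null(seed)) set.seed(seed)
  row <- config$calibration[config$calibration$species == species, ,
                            drop = FALSE]
  if (nrow(row) != 1L) stop("unknown species: ", species)
  dh <- row[[paste0("Dh_", organ)]] * dh_factor
  cd <- row[[paste0("CD_", organ)]] * cd_factor
  s2 <- row[[paste0("sigma2_", organ)]]
  if (.expected_F(dh, cd, s2) >= 100)
    stop("infeasible density x diameter combination (lumen fraction >= 100%)")

  angle <- stats::runif(1L, config$sector_angle_range[1L],
                        config$sector_angle_range[2L])
  target <- max(15, round(stats::rnorm(1L, config$conduits_per_sector["mean"],
                                       config$conduits_per_sector["sd"])))
  sector_area <- target / cd * 1e6            # um^2
  n <- max(1L, stats::rpois(1L, target))
  mu <- log(dh) - 4.5 * s2
  for (attempt in 1:25) {
    d <- stats::rlnorm(n, meanlog = mu, sdlog = sqrt(s2))
    areas <- pi * d^2 / 4
    if (sum(areas) <= sector_area) break
    if (attempt == 25)
      stop("could not draw a feasible sector after 25 attempts ",
           "(lumen areas exceed the sector)")
  }
  conduit_set(sample_id, organ, sector_angle = angle,
              sector_area = sector_area, lumen_areas = areas)
}

#' Generate the flow records of one sample
#'
#' Constructs flush-stage flow measurements whose plateau conductivity
#' equals `ks_ratio` times the sample's own potential conductivity (from
#' its conduit set) referenced to the segment's xylem area, with mean-one
#' multiplicative lognormal noise. Flushes rise along a fixed profile whose
#' final step is within the plateau-stability tolerance; the initial
#' (native) stage is the plateau times a plugging factor drawn from the
#' configured range. Pressure heads follow the organ convention (1 kPa
#' roots, 2 kPa branches).
#'
#' @param config a [study_config()].
#' @param conduits the sample's [conduit_set()].
#' @param geometry the sample's [segment_geometry()].
#' @param seed optional integer seed.
#' @return Data frame of flow records (`sample_id`, `stage`,
#'   `pressure_kPa`, `flow_g_per_h`) with attribute `kh_plateau` (the
#'   noise-free target is `kh_plateau / noise`).
#' @export
generate_flow <- function(config, conduits, geometry, seed = NULL) {
  stopifnot(inherits(config, "study_config"),
            inherits(conduits, "conduit_set"),
            inherits(geometry, "segment_geometry"))
  if (!is.null(seed)) set.seed(seed)
  ks_pot <- anatomy_traits(conduits)$KS_pot
  a_xylem <- xylem_area(geometry)
  pressure <- if (geometry$organ == "root") 1 else 2
  noise <- .lognoise(1L, config$flow_noise_sd)
  kh_plateau <- config$ks_ratio * ks_pot * a_xylem * noise

  profiles <- list(c(0.80, 0.985, 1.0), c(0.75, 0.92, 0.985, 1.0))
  profile <- profiles[[sample.int(length(profiles), 1L)]]
  plugging <- stats::runif(1L, config$plugging_range[1L],
                           config$plugging_range[2L])
  kh_stages <- c(kh_plateau * plugging, kh_plateau * profile)
  # invert K_h -> g/h at this head and length
  flow <- kh_stages * (pressure * 1e-3) / geometry$length_m * 3.6e6
  out <- data.frame(
    sample_id = geometry$sample_id,
    stage = c("initial", paste0("flush_", seq_along(profile))),
    pressure_kPa = pressure, flow_g_per_h = flow,
    stringsAsFactors = FALSE)
  attr(out, "kh_plateau") <- kh_plateau
  attr(out, "plugging") <- plugging
  out
}

# segment geometry draw for one sample (internal)
.generate_geometry <- function(config, row, organ, sample_id, d_factor = 1) {
  d_mean <- row[[paste0(organ, "_d_mm")]] * d_factor
  len <- if (organ == "root") 0.10 else 0.05
  dd <- pmax(1.5, stats::rnorm(4L, d_mean, 0.1))
  pith1 <- pith2 <- NA_real_
  if (organ == "branch") {
    pith1 <- min(max(0.4, stats::rnorm(1L, config$branch_pith_mm, 0.15)),
                 min(dd) / 3)
    pith2 <- min(max(0.4, stats::rnorm(1L, config$branch_pith_mm, 0.15)),
                 min(dd) / 3)
  }
  segment_geometry(sample_id, organ, length_m = len,
                   end1_d1 = dd[1L], end1_d2 = dd[2L],
                   end2_d1 = dd[3L], end2_d2 = dd[4L],
                   pith_d1 = pith1, pith_d2 = pith2)
}

#' Generate a complete synthetic study
#'
#' Emits the full CSV-ready bundle of an emulated field campaign: for every
#' species and tree, conduit sectors, segment geometry, flow records and
#' (for branches) leaf areas for the configured numbers of root and branch
#' samples, one stem core per tree (where the species' stem density is
#' known), and sample metadata. Wood density couples negatively to the
#' sample's realized lumen fraction within species. One species' root flow
#' records are discarded (configurable) so downstream inference must handle
#' the missing cell. Ground truth (tree effects, noise-free plateaus,
#' plugging factors) is retained for recovery tests.
#'
#' @param config a [study_config()].
#' @param seed integer seed for the single RNG stream of the study.
#' @return An object of class `synthetic_study`: list of data frames
#'   `metadata`, `conduits`, `flow`, `geometry`, `leaf_area`,
#'   `ground_truth`, plus `config` and `seed`.
#' @examples
#' \donttest{
#' study <- generate_study(study_config(), seed = 1)
#' head(study$metadata)
#' }
#' @export
generate_study <- function(config = study_config(), seed = 1L) {
  stopifnot(inherits(config, "study_config"))
  set.seed(seed)
  cal <- config$calibration
  meta <- list(); cond <- list(); flow <- list(); geom <- list()
  leaf <- list(); truth <- list()

  for (si in seq_len(nrow(cal))) {
    row <- cal[si, , drop = FALSE]
    code <- toupper(paste0(substr(sub(" .*", "", row$species), 1, 2),
                           substr(sub(".* ", "", row$species), 1, 2)))
    for (ti in seq_len(config$n_trees)) {
      tree_id <- paste0(code, "_T", ti)
      height <- max(2, stats::rnorm(1L, row$height_m, row$height_sd_m))
      dh_f <- .lognoise(1L, config$tree_dh_sd)
      cd_f <- .lognoise(1L, config$tree_cd_sd)
      wd_tree <- stats::rnorm(1L, 0, config$wd_tree_sd)

      for (organ in c("root", "branch")) {
        n_s <- if (organ == "root") config$n_root_samples
               else config$n_branch_samples
        f_expect <- .expected_F(row[[paste0("Dh_", organ)]] * dh_f,
                                row[[paste0("CD_", organ)]] * cd_f,
                                row[[paste0("sigma2_", organ)]])
        for (k in seq_len(n_s)) {
          sid <- paste0(tree_id, "_", toupper(substr(organ, 1, 1)), k)
          cs <- generate_conduits(config, row$species, organ, sid,
                                  dh_factor = dh_f, cd_factor = cd_f)
          g <- .generate_geometry(config, row, organ, sid)
          fl <- generate_flow(config, cs, g)

          # wood density: species target + tree effect + lumen-fraction
          # coupling + sample noise
          f_sample <- lumen_fraction(cs$lumen_areas, cs$sector_area)
          wd <- row[[paste0("WD_", organ)]] + wd_tree +
            config$wd_f_slope[[organ]] * (f_sample - f_expect) +
            stats::rnorm(1L, 0, config$wd_sample_sd)
          wd <- min(max(wd, 0.15), 1.2)
          g$dry_mass_g <- wd * segment_volume(g)

          la <- NA_real_
          if (organ == "branch") {
            hv <- config$hv_target[[row$leaf_habit]]
            la <- xylem_area(g) / hv * .lognoise(1L, config$leaf_area_sd)
            leaf[[sid]] <- data.frame(sample_id = sid, leaf_area_m2 = la,
                                      stringsAsFactors = FALSE)
          }

          discard <- organ == "root" &&
            row$species %in% config$discard_root_flow_species
          if (!discard) flow[[sid]] <- fl

          meta[[sid]] <- data.frame(
            sample_id = sid, species = row$species,
            leaf_habit = row$leaf_habit, tree_id = tree_id, organ = organ,
            height_m = height, stringsAsFactors = FALSE)
          cond[[sid]] <- data.frame(
            sample_id = sid, organ = organ,
            sector_angle_deg = cs$sector_angle,
            sector_area_um2 = cs$sector_area,
            lumen_area_um2 = cs$lumen_areas, stringsAsFactors = FALSE)
          geom[[sid]] <- data.frame(
            sample_id = sid, organ = organ, length_m = g$length_m,
            end1_d1 = g$end1_d1, end1_d2 = g$end1_d2,
            end2_d1 = g$end2_d1, end2_d2 = g$end2_d2,
            pith_d1 = g$pith_d1, pith_d2 = g$pith_d2,
            dry_mass_g = g$dry_mass_g, core_length_mm = NA_real_,
            stringsAsFactors = FALSE)
          truth[[sid]] <- data.frame(
            sample_id = sid, species = row$species, organ = organ,
            dh_factor = dh_f, cd_factor = cd_f,
            kh_plateau = attr(fl, "kh_plateau"),
            plugging = attr(fl, "plugging"),
            wd_true = wd, leaf_area_m2 = la,
            flow_discarded = discard, stringsAsFactors = FALSE)
        }
      }

      # one stem core per tree where the species' stem density is known
      if (is.finite(row$WD_stem)) {
        sid <- paste0(tree_id, "_S1")
        core_len <- stats::runif(1L, config$core_length_range[1L],
                                 config$core_length_range[2L])
        wd <- min(max(row$WD_stem + wd_tree +
                        stats::rnorm(1L, 0, config$wd_sample_sd), 0.15), 1.2)
        meta[[sid]] <- data.frame(
          sample_id = sid, species = row$species,
          leaf_habit = row$leaf_habit, tree_id = tree_id,
          organ = "stem_core", height_m = height, stringsAsFactors = FALSE)
        geom[[sid]] <- data.frame(
          sample_id = sid, organ = "stem_core", length_m = NA_real_,
          end1_d1 = NA_real_, end1_d2 = NA_real_,
          end2_d1 = NA_real_, end2_d2 = NA_real_,
          pith_d1 = NA_real_, pith_d2 = NA_real_,
          dry_mass_g = wd * core_volume(core_len),
          core_length_mm = core_len, stringsAsFactors = FALSE)
        truth[[sid]] <- data.frame(
          sample_id = sid, species = row$species, organ = "stem_core",
          dh_factor = NA_real_, cd_factor = NA_real_,
          kh_plateau = NA_real_, plugging = NA_real_, wd_true = wd,
          leaf_area_m2 = NA_real_, flow_discarded = FALSE,
          stringsAsFactors = FALSE)
      }
    }
  }

  bind <- function(x) {
    out <- do.call(rbind, x)
    rownames(out) <- NULL
    out
  }
  structure(list(metadata = bind(meta), conduits = bind(cond),
                 flow = bind(flow), geometry = bind(geom),
                 leaf_area = bind(leaf), ground_truth = bind(truth),
                 config = config, seed = seed),
            class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat("Synthetic study (seed", x$seed, "):",
      length(unique(x$metadata$species)), "species,",
      length(unique(x$metadata$tree_id)), "trees,",
      nrow(x$metadata), "samples\n")
  invisible(x)
}
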